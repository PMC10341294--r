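test_that("a lesion-free phantom is background plus noise with an empty mask", {
  sp <- phantom_spec(image_size = 96L, n_foci = 0L, seed = 3)
  ph <- generate_phantom(sp, 0)
  expect_equal(sum(ph$truth$pixels), 0)
  expect_true(all(ph$faf >= 0 & ph$faf <= 1))
  expect_true(abs(mean(ph$nir) - sp$nir_background_mean) < 0.05)
})

test_that("a smooth single focus has area close to pi r^2", {
  r <- 1.2
  sp <- phantom_spec(image_size = 128L, n_foci = 1L,
                     focus_centers = list(c(1.8, 1.2)), focus_radii = r,
                     lesion_boundary_roughness = 0, vessel_count = 0L,
                     opacity_artifact_prob = 0, seed = 5)
  ph <- generate_phantom(sp, 0)
  measured <- sum(ph$truth$pixels) * sp$scale_mm_per_px^2
  expect_lt(abs(measured - pi * r^2) / (pi * r^2), 0.05)
})

test_that("truth area grows by the configured rate per visit step", {
  sp <- phantom_spec(image_size = 128L, n_foci = 1L,
                     focus_centers = list(c(1.5, 1.0)), focus_radii = 1.0,
                     lesion_boundary_roughness = 0.1, vessel_count = 0L,
                     growth_rate_mm2_per_6mo = 1.0, seed = 8)
  areas <- sapply(0:2, function(v)
    sum(generate_phantom(sp, v)$truth$pixels) * sp$scale_mm_per_px^2)
  expect_true(all(diff(areas) > 0))           # growth monotone
  expect_equal(diff(areas), c(1, 1), tolerance = 0.12)
  # registration: lesion centers fixed, later visits contain earlier ones
  m0 <- generate_phantom(sp, 0)$truth$pixels
  m2 <- generate_phantom(sp, 2)$truth$pixels
  expect_true(all(m2[m0 == 1] == 1))
})

test_that("phantoms are deterministic per (seed, visit)", {
  sp <- phantom_spec(image_size = 64L, seed = 12)
  a <- generate_phantom(sp, 1)
  b <- generate_phantom(sp, 1)
  expect_identical(a$faf, b$faf)
  expect_identical(a$nir, b$nir)
  expect_identical(a$truth$pixels, b$truth$pixels)
  c2 <- generate_phantom(phantom_spec(image_size = 64L, seed = 13), 1)
  expect_false(identical(a$faf, c2$faf))
})

test_that("the fovea is dark on FAF only and never part of the truth", {
  sp <- phantom_spec(image_size = 128L, n_foci = 1L, seed = 4)
  ph <- generate_phantom(sp, 0)
  n <- sp$image_size
  ctr <- (n + 1) / 2
  rpx <- sp$fovea_radius_mm / sp$scale_mm_per_px
  ii <- which(abs(row(ph$faf) - ctr) <= rpx / 2 &
                abs(col(ph$faf) - ctr) <= rpx / 2)
  expect_true(all(ph$truth$pixels[ii] == 0))   # fovea spared in truth
  expect_lt(mean(ph$faf[ii]), 0.4 * sp$faf_background_mean)  # dark on FAF
  expect_gt(mean(ph$nir[ii]), 0.8 * sp$nir_background_mean)  # clean on NIR
})

test_that("simulate_grader reproduces truth at zero noise and degrades with noise", {
  sp <- phantom_spec(image_size = 96L, seed = 31)
  truth <- generate_phantom(sp, 0)$truth
  g0 <- simulate_grader(truth, 0, seed = 1)
  expect_identical(g0$pixels, truth$pixels)
  d_small <- sapply(1:8, function(i)
    dice_coefficient(simulate_grader(truth, 1, seed = i), truth))
  d_large <- sapply(1:8, function(i)
    dice_coefficient(simulate_grader(truth, 5, seed = i), truth))
  expect_gt(mean(d_small), mean(d_large))  # noise monotonicity
})

test_that("generate_cohort writes a complete, reproducible cohort", {
  d1 <- file.path(tempdir(), "coh_a")
  d2 <- file.path(tempdir(), "coh_b")
  unlink(c(d1, d2), recursive = TRUE)
  mf <- generate_cohort(5, visits = "SCR", out_dir = d1, seed = 42,
                        image_size = 64L)
  expect_equal(nrow(mf), 5)
  for (col in c("faf_path", "nir_path", "truth_mask_path",
                "grader1_mask_path", "grader2_mask_path"))
    expect_true(all(file.exists(file.path(d1, mf[[col]]))))
  # baseline areas within the eligibility window (unfiltered pixel count,
  # small discretization slack)
  areas <- sapply(seq_len(nrow(mf)), function(i) {
    m <- read_mask(file.path(d1, mf$truth_mask_path[i]),
                   mf$scale_mm_per_px[i])
    total_area(m)
  })
  expect_true(all(areas > 2.54 * 0.9 & areas < 17.78 * 1.1))
  mf2 <- generate_cohort(5, visits = "SCR", out_dir = d2, seed = 42,
                         image_size = 64L)
  expect_identical(mf$patient_id, mf2$patient_id)
  f1 <- readBin(file.path(d1, mf$truth_mask_path[1]), "raw", 1e6)
  f2 <- readBin(file.path(d2, mf2$truth_mask_path[1]), "raw", 1e6)
  expect_identical(f1, f2)  # byte-identical outputs from one seed
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
})

test_that("patient_split is disjoint and keeps visits together", {
  mf <- data.frame(patient_id = rep(sprintf("P%02d", 1:10), each = 3),
                   visit = rep(c("SCR", "M6", "M12"), 10))
  sp <- patient_split(mf, c(train = 0.8, val = 0.2), seed = 1)
  expect_equal(length(unique(sp$train$patient_id)), 8)
  expect_equal(length(unique(sp$val$patient_id)), 2)
  expect_length(intersect(sp$train$patient_id, sp$val$patient_id), 0)
  for (p in unique(mf$patient_id)) {
    in_train <- sum(sp$train$patient_id == p)
    expect_true(in_train %in% c(0L, 3L))  # all visits travel together
  }
  # cohort-shaped split: 183 patients at the 147/36 proportions
  big <- data.frame(patient_id = sprintf("Q%03d", 1:183), visit = "SCR")
  sb <- patient_split(big, c(train = 147 / 183, val = 36 / 183), seed = 2)
  expect_equal(length(unique(sb$train$patient_id)), 147)
  expect_equal(length(unique(sb$val$patient_id)), 36)
  expect_error(patient_split(mf[mf$patient_id == "P01", ],
                             c(a = 0.5, b = 0.25, c = 0.25)), "too few")
  expect_error(patient_split(mf, c(train = 0.6, val = 0.2)), "sum to 1")
})
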