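make_eval_cohort <- function(n_pat = 6, visits = "SCR", n = 40,
                             seed = 1, grader_noise = 1.0) {
  records <- list()
  set.seed(seed)
  for (i in seq_len(n_pat)) {
    for (v in visits) {
      px <- matrix(0L, n, n)
      sz <- sample(8:14, 1)
      r0 <- sample(3:(n - sz - 2), 1); c0 <- sample(3:(n - sz - 2), 1)
      px[r0:(r0 + sz), c0:(c0 + sz)] <- 1L
      truth <- lesion_mask(px, 0.1)
      g1 <- simulate_grader(truth, grader_noise, seed = seed + 100 * i + 1)
      g2 <- simulate_grader(truth, grader_noise, seed = seed + 100 * i + 2)
      records[[length(records) + 1L]] <- list(
        patient_id = sprintf("P%02d", i), visit = v,
        faf = matrix(0.5, n, n), nir = matrix(0.5, n, n), truth = truth,
        graders = list(grader1 = g1, grader2 = g2), scale_mm_per_px = 0.1)
    }
  }
  records
}

test_that("a model identical to grader 1 scores Dice 1 against it", {
  recs <- make_eval_cohort(5)
  masks <- list(UNet = lapply(recs, function(r) r$graders$grader1))
  rep <- evaluate_cohort(recs, masks, intervals = list())
  expect_equal(rep$dice[rep$dice$visit == "All", "grader1-UNet_mean"], 1)
  expect_equal(rep$dice[rep$dice$visit == "All", "grader1-UNet_sd"], 0)
  expect_lt(rep$dice[rep$dice$visit == "All", "grader2-UNet_mean"], 1)
})

test_that("the report lists exactly the five standard comparison pairs", {
  recs <- make_eval_cohort(4)
  masks <- list(UNet = lapply(recs, function(r) r$graders$grader1),
                YNet = lapply(recs, function(r) r$graders$grader2))
  rep <- evaluate_cohort(recs, masks, intervals = list())
  expect_setequal(rep$pairs,
                  c("grader1-UNet", "grader2-UNet", "grader1-YNet",
                    "grader2-YNet", "grader1-grader2"))
  expect_length(rep$pairs, 5)
})

test_that("pooled Dice equals the image-count-weighted recomputation", {
  recs <- make_eval_cohort(4, visits = c("SCR", "M6"))
  masks <- list(UNet = lapply(recs, function(r) r$graders$grader2))
  rep <- evaluate_cohort(recs, masks, intervals = list())
  d <- rep$dice
  for (p in rep$pairs) {
    per_visit <- d[d$visit != "All", ]
    pooled <- sum(per_visit[[paste0(p, "_mean")]] * per_visit$n) /
      sum(per_visit$n)
    expect_equal(d[d$visit == "All", paste0(p, "_mean")], pooled,
                 tolerance = 1e-12)
    expect_equal(d[d$visit == "All", paste0(p, "_mean")],
                 mean(rep$per_image[[p]]), tolerance = 1e-12)
  }
})

test_that("swapping source labels permutes but does not change report values", {
  recs <- make_eval_cohort(5)
  m1 <- lapply(recs, function(r) simulate_grader(r$truth, 1.5, seed = 7))
  m2 <- lapply(recs, function(r) simulate_grader(r$truth, 1.5, seed = 8))
  repA <- evaluate_cohort(recs, list(UNet = m1, YNet = m2),
                          intervals = list())
  repB <- evaluate_cohort(recs, list(UNet = m2, YNet = m1),
                          intervals = list())
  dA <- repA$dice[repA$dice$visit == "All", ]
  dB <- repB$dice[repB$dice$visit == "All", ]
  expect_equal(dA[["grader1-UNet_mean"]], dB[["grader1-YNet_mean"]])
  expect_equal(dA[["grader2-YNet_mean"]], dB[["grader2-UNet_mean"]])
  expect_equal(dA[["grader1-grader2_mean"]], dB[["grader1-grader2_mean"]])
})

test_that("records with a missing model mask are skipped and logged", {
  recs <- make_eval_cohort(5)
  masks <- list(UNet = lapply(recs, function(r) r$graders$grader1))
  masks$UNet[3] <- list(NULL)
  rep <- evaluate_cohort(recs, masks, intervals = list())
  expect_equal(nrow(rep$per_image), 4)
  expect_equal(rep$skipped$record, 3)
  expect_match(rep$skipped$reason, "UNet")
})

test_that("subgroup partitions cover all images and detect weak subgroups", {
  recs <- make_eval_cohort(8)
  # inject multifocality in half the cohort and degrade the model there
  masks <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    if (i %% 2 == 0) {
      px <- recs[[i]]$truth$pixels
      px[2:5, 2:5] <- 1L  # second far-away component -> multifocal
      recs[[i]]$truth <- lesion_mask(px, 0.1)
      recs[[i]]$graders$grader1 <- simulate_grader(recs[[i]]$truth, 1,
                                                   seed = 900 + i)
      recs[[i]]$graders$grader2 <- simulate_grader(recs[[i]]$truth, 1,
                                                   seed = 950 + i)
      masks[[i]] <- simulate_grader(recs[[i]]$truth, 6, seed = 990 + i)
    } else {
      masks[[i]] <- simulate_grader(recs[[i]]$truth, 0.5, seed = 990 + i)
    }
  }
  rep <- evaluate_cohort(recs, list(UNet = masks), intervals = list())
  sg <- subgroup_analysis(rep)
  foc <- sg[sg$covariate == "focality", ]
  expect_equal(sum(foc$n), nrow(rep$per_image))  # partition covers all
  uni <- foc$mean_dice[foc$level == "unifocal"]
  multi <- foc$mean_dice[foc$level == "multifocal"]
  expect_gt(uni, multi)  # injected low multifocal accuracy is detected
  # a partition collapsing to a single subgroup equals the pooled value
  fov <- sg[sg$covariate == "foveal_involvement", ]
  if (nrow(fov) == 1 && fov$n[1] >= 3) {
    gm_pairs <- setdiff(rep$pairs, "grader1-grader2")
    pooled <- mean(rowMeans(rep$per_image[, gm_pairs, drop = FALSE]))
    expect_equal(fov$mean_dice[1], pooled, tolerance = 1e-12)
  }
  # subgroups with < 3 members are NA
  expect_true(all(is.na(sg$mean_dice[sg$n < 3])))
})
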