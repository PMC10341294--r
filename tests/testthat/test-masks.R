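test_that("dice_coefficient matches its definition and conventions", {
  a <- matrix(0L, 6, 6); a[2:3, 2:3] <- 1L
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(0L, 6, 6); b[5:6, 5:6] <- 1L
  expect_equal(dice_coefficient(a, b), 0)
  # 4 px vs 4 px with 2 px overlap -> 0.5
  c1 <- matrix(0L, 4, 4); c1[1, 1:4] <- 1L
  c2 <- matrix(0L, 4, 4); c2[1, 3:4] <- 1L; c2[2, 1:2] <- 1L
  expect_equal(dice_coefficient(c1, c2), 0.5)
  empty <- matrix(0L, 6, 6)
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_equal(dice_coefficient(a, empty), 0)
  expect_error(dice_coefficient(a, matrix(0L, 5, 5)), "shape")
})

test_that("dice_coefficient is symmetric and agrees with a brute-force count", {
  set.seed(42)
  for (i in 1:20) {
    a <- random_mask(); b <- random_mask()
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
    expect_equal(dice_coefficient(a, b), oracle_dice(a, b), tolerance = 1e-12)
  }
})

test_that("reweight_mask handles degenerate lesions", {
  empty <- lesion_mask(matrix(0L, 8, 8), 0.1)
  expect_true(all(reweight_mask(empty)$weights == 0))
  single <- matrix(0L, 8, 8); single[4, 4] <- 1L
  w <- reweight_mask(lesion_mask(single, 0.1))$weights
  expect_equal(w[4, 4], 1.0)
  expect_equal(sum(w), 1.0)
  expect_error(reweight_mask(matrix(0.5, 4, 4)), "0 or 1")
  expect_error(reweight_mask(empty, interior_floor = 0.3), "interior_floor")
})

test_that("9x9 square lesion: border band is 1, centre follows the distance profile", {
  px <- matrix(0L, 13, 13); px[3:11, 3:11] <- 1L
  wm <- reweight_mask(lesion_mask(px, 0.1), interior_floor = 0.5,
                      edge_band_px = 1)
  w <- wm$weights
  d <- oracle_chebyshev(px)
  expect_true(all(w[px == 1 & d <= 1] == 1))
  centre <- w[7, 7]
  dmax <- max(d[px == 1])
  expected_centre <- max(0.5, 1 - d[7, 7] / dmax * 0.5)
  expect_equal(centre, expected_centre)
  expect_gte(centre, 0.5)
  expect_lt(centre, 1.0)
})

test_that("reweight_mask output satisfies the weighted-mask invariants", {
  set.seed(7)
  for (i in 1:100) {
    px <- random_mask(n = 20)
    wm <- reweight_mask(lesion_mask(px, 0.1))
    w <- wm$weights
    expect_true(all(w[px == 0] == 0))
    if (any(px == 1)) {
      expect_true(all(w[px == 1] >= 0.5))
      expect_true(all(w <= 1))
      # weight non-increasing with boundary distance
      d <- oracle_chebyshev(px)
      ins <- which(px == 1)
      ord <- order(d[ins])
      expect_true(all(diff(w[ins][ord]) <= 1e-12 |
                        diff(d[ins][ord]) == 0))
    }
  }
})

test_that("weighted_dice matches its formula and reduces to soft Dice", {
  px <- matrix(0L, 6, 6); px[2:4, 2:4] <- 1L
  m <- lesion_mask(px, 0.1)
  wm <- reweight_mask(m)
  # perfect prediction scores 1 for any valid weight map
  expect_equal(weighted_dice(px * 1.0, wm), 1)
  # all-zero prediction on a non-empty mask scores 0
  expect_equal(weighted_dice(px * 0.0, wm), 0)
  # uniform lesion weights == plain soft Dice, machine precision
  set.seed(3)
  for (i in 1:20) {
    g <- random_mask(n = 12)
    p <- matrix(runif(144), 12, 12)
    expect_equal(weighted_dice(p, g * 1.0), oracle_soft_dice(p, g),
                 tolerance = 1e-15)
  }
  # 3x3 with p = 0.5 everywhere, one lesion pixel of weight 1
  w3 <- matrix(0, 3, 3); w3[2, 2] <- 1
  p3 <- matrix(0.5, 3, 3)
  expect_equal(weighted_dice(p3, w3),
               oracle_weighted_dice(p3, w3, (w3 > 0) * 1L))
  expect_error(weighted_dice(matrix(0.5, 2, 2), wm), "grids differ")
})

test_that("weighted_dice agrees with the brute-force sum on random cases", {
  set.seed(11)
  for (i in 1:20) {
    g <- random_mask(n = 15)
    wm <- reweight_mask(lesion_mask(g, 0.1))
    p <- matrix(runif(225), 15, 15)
    expect_equal(weighted_dice(p, wm),
                 oracle_weighted_dice(p, wm$weights, g), tolerance = 1e-12)
  }
})

test_that("dice_loss is 1 - weighted_dice and its gradient matches finite differences", {
  set.seed(5)
  g <- matrix(0L, 5, 5); g[2:4, 2:3] <- 1L
  wm <- reweight_mask(lesion_mask(g, 0.1))
  p <- matrix(runif(25, 0.05, 0.95), 5, 5)
  expect_equal(dice_loss(p, wm), 1 - weighted_dice(p, wm))
  expect_equal(dice_loss(g * 1.0, wm), 0)
  expect_equal(dice_loss(g * 0.0, wm), 1)
  gr <- dice_loss_grad(p, wm)
  eps <- 1e-6
  for (k in sample(25, 10)) {
    pp <- p; pp[k] <- pp[k] + eps
    pm <- p; pm[k] <- pm[k] - eps
    fd <- (dice_loss(pp, wm) - dice_loss(pm, wm)) / (2 * eps)
    expect_equal(gr[k], fd, tolerance = 1e-4)
  }
})

test_that("binarize uses a strict threshold", {
  p <- matrix(0.5, 4, 4)
  expect_true(all(binarize(p)$pixels == 0))
  expect_true(all(binarize(matrix(0.51, 4, 4))$pixels == 1))
  set.seed(9)
  p <- matrix(runif(64), 8, 8)
  bz <- binarize(p, 0.3)$pixels
  for (i in 1:8) for (j in 1:8)
    expect_identical(bz[i, j], as.integer(p[i, j] > 0.3))
  expect_error(binarize(p, 1.5), "threshold")
})

test_that("lesion_spots filters by minimal area and sorts by size", {
  empty <- lesion_mask(matrix(0L, 10, 10), 0.05)
  expect_equal(nrow(lesion_spots(empty)), 0)
  px <- matrix(0L, 20, 20); px[3:12, 3:12] <- 1L
  m <- lesion_mask(px, 0.05)
  sp <- lesion_spots(m)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$area_mm2, 100 * 0.05^2)  # 0.25 mm2
  # speck below 0.05 mm2 at this scale (< 20 px) is disregarded
  px[17, 17] <- 1L
  m2 <- lesion_mask(px, 0.05)
  expect_equal(nrow(lesion_spots(m2)), 1)
  expect_equal(total_area(m2), 0.25)
  expect_equal(focality(m2), 1)
  # with the filter off both components count
  expect_equal(nrow(lesion_spots(m2, min_area_mm2 = 0)), 2)
})

test_that("component areas agree with an independent graph-based labeling", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (i in 1:10) {
    px <- random_mask(n = 18)
    m <- lesion_mask(px, 0.1)
    sp <- lesion_spots(m, min_area_mm2 = 0)
    expect_equal(sort(sp$pixel_count, decreasing = TRUE),
                 oracle_component_areas(px, 8))
    sp4 <- lesion_spots(m, min_area_mm2 = 0, connectivity = 4)
    expect_equal(sort(sp4$pixel_count, decreasing = TRUE),
                 oracle_component_areas(px, 4))
  }
})

test_that("total filtered area is invariant under rotation", {
  set.seed(17)
  for (i in 1:10) {
    px <- random_mask(n = 16)
    m0 <- lesion_mask(px, 0.08)
    r90 <- lesion_mask(t(px)[ncol(px):1, ], 0.08)
    expect_equal(total_area(m0), total_area(r90))
    expect_equal(focality(m0), focality(r90))
  }
})
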