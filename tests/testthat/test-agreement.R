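test_that("pearson_r matches the textbook formula and validates input", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  set.seed(21)
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("passing_bablok recovers exact lines", {
  x <- c(1, 2, 3, 5, 8)
  pb <- passing_bablok(x, x)
  expect_equal(pb$slope, 1)
  expect_equal(pb$intercept, 0)
  pb2 <- passing_bablok(x, 2 * x + 3)
  expect_equal(pb2$slope, 2)
  expect_equal(pb2$intercept, 3)
  expect_error(passing_bablok(rep(2, 4), 1:4), "identical")
})

test_that("passing_bablok slope equals the enumerate-all-pairs oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    x <- round(runif(n, 1, 18), 2)
    y <- round(1.1 * x + rnorm(n, 0, 0.8), 2)
    expect_identical(passing_bablok(x, y)$slope, oracle_pb_slope(x, y))
  }
})

test_that("passing_bablok is scale-equivariant in y", {
  # concordant fixture: all pairwise slopes positive, so the negative-slope
  # offset K stays 0 under any positive rescaling
  set.seed(33)
  x <- sort(runif(7, 1, 10)) + seq(0, 6)
  y <- 0.9 * x + runif(7, -0.2, 0.2)
  stopifnot(all(diff(y) / diff(x) > 0))
  b1 <- passing_bablok(x, y)$slope
  for (a in c(0.5, 2, 10))
    expect_equal(passing_bablok(x, a * y)$slope, a * b1, tolerance = 1e-12)
})

ba_fixture <- function(seed = 1, n_pat = 8) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_pat)) {
    base <- runif(1, 3, 12)
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%02d", i), visit = "SCR",
      source = c("G1", "G2", "net"),
      area_mm2 = c(base + rnorm(1, 0, 0.3), base + rnorm(1, 0, 0.3),
                   base + rnorm(1, 0, 0.5)))
  }
  do.call(rbind, rows)
}

test_that("generalized Bland-Altman uses grader-derived limits", {
  rec <- ba_fixture()
  ba <- generalized_bland_altman(rec, c("G1", "G2"))
  # grader differences sum to zero per observation
  gd <- ba$observations[ba$observations$source %in% c("G1", "G2"), ]
  sums <- tapply(gd$diff, paste(gd$patient_id, gd$visit), sum)
  expect_true(all(abs(sums) < 1e-12))
  # limits equal an explicit two-pass oracle over grader differences only
  expect_equal(unname(ba$limits), unname(oracle_ba_limits(gd$diff)),
               tolerance = 1e-12)
  # a source identical to the grader mean has zero differences
  rec2 <- rec
  means <- tapply(rec2$area_mm2[rec2$source != "net"], rec2$patient_id[rec2$source != "net"], mean)
  rec2$area_mm2[rec2$source == "net"] <- means[rec2$patient_id[rec2$source == "net"]]
  ba2 <- generalized_bland_altman(rec2, c("G1", "G2"))
  expect_equal(ba2$per_source$mean_diff[ba2$per_source$source == "net"], 0,
               tolerance = 1e-12)
  # constant +/- d offsets give +/- d/2 grader differences
  rec3 <- data.frame(patient_id = rep(c("A", "B", "C"), each = 2),
                     visit = "SCR", source = rep(c("G1", "G2"), 3),
                     area_mm2 = rep(c(5, 7), 3))
  ba3 <- generalized_bland_altman(rec3, c("G1", "G2"))
  expect_true(all(abs(abs(ba3$observations$diff) - 1) < 1e-12))
})

test_that("patient-visits lacking two graders are excluded with a warning", {
  rec <- ba_fixture()
  rec <- rec[!(rec$patient_id == "P01" & rec$source == "G2"), ]
  expect_warning(ba <- generalized_bland_altman(rec, c("G1", "G2")),
                 "excluded")
  expect_false("P01" %in% ba$observations$patient_id)
})

enl_fixture <- function() {
  data.frame(
    patient_id = rep(c("A", "B", "C"), each = 4),
    visit = rep(c("SCR", "M6"), 6),
    source = rep(rep(c("G1", "net"), each = 2), 3),
    area_mm2 = c(2.0, 3.2, 2.1, 3.0,   # A
                 5.0, 5.0, 5.2, 5.1,   # B
                 8.0, 9.5, 7.9, 9.6))  # C
}

test_that("enlargement computes per-patient deltas and cohort summaries", {
  en <- enlargement(enl_fixture(), c("SCR", "M6"))
  tabA <- en$table[en$table$patient_id == "A", ]
  expect_equal(tabA$delta_mm2[tabA$source == "G1"], 1.2)
  expect_equal(tabA$delta_mm2[tabA$source == "net"], 0.9)
  expect_equal(en$table$delta_mm2[en$table$patient_id == "B" &
                                    en$table$source == "G1"], 0)
  s <- en$summary
  g1 <- en$table$delta_mm2[en$table$source == "G1"]
  expect_equal(s$mean_delta[s$source == "G1"], mean(g1))
  expect_equal(s$se[s$source == "G1"], sd(g1) / sqrt(3))
})

test_that("enlargement excludes incomplete patients and honors complete-case", {
  rec <- enl_fixture()
  rec <- rec[!(rec$patient_id == "C" & rec$visit == "M6" &
                 rec$source == "net"), ]
  en <- enlargement(rec, c("SCR", "M6"))
  expect_false("C" %in%
                 en$table$patient_id[en$table$source == "net"])
  expect_true("C" %in% en$table$patient_id[en$table$source == "G1"])
  # complete-case restriction removes C for every source
  encc <- enlargement(rec, c("SCR", "M6"),
                      complete_case_visits = c("SCR", "M6"))
  expect_false("C" %in% encc$table$patient_id)
})

test_that("coefficient_of_variation follows the sample-SD convention", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  set.seed(41)
  d <- rnorm(10, 5, 1)
  for (k in c(0.1, 2, 7))
    expect_equal(coefficient_of_variation(k * d),
                 coefficient_of_variation(d), tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})
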