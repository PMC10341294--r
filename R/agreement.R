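#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(x, y)
}

#' Passing-Bablok method-comparison regression
#'
#' Non-parametric regression for method comparison: the slope is the
#' shifted median of all pairwise slopes `(y_j - y_i) / (x_j - x_i)`,
#' where slopes equal to -1 are discarded and the median index is offset by
#' the number of slopes below -1 (the classical handling of negative
#' reciprocals); the intercept is `median(y - slope * x)`.  Confidence
#' bounds use the rank-based method.
#'
#' @param x,y numeric vectors of equal length >= 3 (`x` not constant).
#' @param conf.level confidence level for the rank-based bounds.
#' @return Object of class `passing_bablok`: list with `slope`,
#'   `intercept`, `slope_ci`, `intercept_ci`, `n`.
#' @export
passing_bablok <- function(x, y, conf.level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1) stop("all x values identical")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  s <- ifelse(dx == 0 & dy == 0, NA_real_,
              ifelse(dx == 0, sign(dy) * Inf, dy / dx))
  s <- s[!is.na(s) & s != -1]
  s <- sort(s)
  nv <- length(s)
  if (nv == 0) stop("no valid pairwise slopes")
  k <- sum(s < -1)
  med_at <- function(pos) {
    pos <- pmin(pmax(pos, 1L), nv)
    s[pos]
  }
  slope <- if (nv %% 2 == 1) {
    med_at((nv + 1) %/% 2 + k)
  } else {
    mean(c(med_at(nv %/% 2 + k), med_at(nv %/% 2 + 1L + k)))
  }
  w <- stats::qnorm(1 - (1 - conf.level) / 2) *
    sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((nv - w) / 2)
  m2 <- nv - m1 + 1
  slope_ci <- c(med_at(m1 + k), med_at(m2 + k))
  intercept <- stats::median(y - slope * x)
  intercept_ci <- c(stats::median(y - slope_ci[2] * x),
                    stats::median(y - slope_ci[1] * x))
  structure(list(slope = slope, intercept = intercept,
                 slope_ci = slope_ci, intercept_ci = intercept_ci,
                 n = n, conf.level = conf.level),
            class = "passing_bablok")
}

#' @export
print.passing_bablok <- function(x, ...) {
  cat(sprintf("Passing-Bablok regression (n = %d)\n", x$n))
  cat(sprintf("  slope     %.4f  [%.4f, %.4f]\n", x$slope, x$slope_ci[1],
              x$slope_ci[2]))
  cat(sprintf("  intercept %.4f  [%.4f, %.4f]\n", x$intercept,
              x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Generalized multi-rater Bland-Altman analysis
#'
#' For every patient-visit the reference value is the mean of the grader
#' (reference-source) areas; each source's difference is its area minus
#' that mean.  The 95% limits of agreement (`mean +/- 1.96 SD`, sample SD)
#' are computed over the grader differences ONLY, and network sources are
#' judged against those grader-derived limits.  Patient-visits with fewer
#' than two reference sources are excluded with a warning.
#'
#' @param records data frame with columns `patient_id`, `visit`, `source`,
#'   `area_mm2` (one row per patient-visit-source).
#' @param reference_sources character vector of grader source labels.
#' @return Object of class `bland_altman`: `observations` (per
#'   patient-visit-source mean/difference), `per_source` (n and mean
#'   difference), `limits` (grader mean difference and 95% limits).
#' @export
generalized_bland_altman <- function(records, reference_sources) {
  stopifnot(all(c("patient_id", "visit", "source", "area_mm2") %in%
                  names(records)))
  key <- interaction(records$patient_id, records$visit, drop = TRUE)
  obs <- list()
  dropped <- 0L
  for (k in levels(key)) {
    g <- records[key == k, , drop = FALSE]
    ref <- g[g$source %in% reference_sources, , drop = FALSE]
    if (nrow(ref) < 2) { dropped <- dropped + 1L; next }
    xbar <- mean(ref$area_mm2)
    obs[[k]] <- data.frame(patient_id = g$patient_id[1],
                           visit = g$visit[1], source = g$source,
                           mean_area = xbar,
                           diff = g$area_mm2 - xbar)
  }
  if (dropped > 0)
    warning(dropped, " patient-visit(s) lack two reference sources; excluded")
  if (length(obs) == 0) stop("no patient-visit with >= 2 reference sources")
  observations <- do.call(rbind, obs)
  rownames(observations) <- NULL
  gd <- observations$diff[observations$source %in% reference_sources]
  mu <- mean(gd)
  sdev <- stats::sd(gd)
  limits <- c(mean = mu, lower = mu - 1.96 * sdev, upper = mu + 1.96 * sdev)
  per_source <- do.call(rbind, lapply(split(observations,
                                            observations$source),
    function(d) data.frame(source = d$source[1], n = nrow(d),
                           mean_diff = mean(d$diff),
                           within_limits = mean(d$diff >= limits["lower"] &
                                                  d$diff <= limits["upper"]))))
  rownames(per_source) <- NULL
  structure(list(observations = observations, per_source = per_source,
                 limits = limits, reference_sources = reference_sources),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Generalized Bland-Altman (grader-derived 95% limits)\n")
  cat(sprintf("  limits: %.4f [%.4f, %.4f]\n", x$limits["mean"],
              x$limits["lower"], x$limits["upper"]))
  print(x$per_source, row.names = FALSE)
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  o <- x$observations
  cols <- as.integer(factor(o$source))
  graphics::plot(o$mean_area, o$diff, col = cols, pch = 19,
                 xlab = "mean grader area (mm2)",
                 ylab = "source - grader mean (mm2)", ...)
  graphics::abline(h = x$limits, lty = c(1, 2, 2))
  graphics::legend("topright", legend = levels(factor(o$source)),
                   col = seq_along(levels(factor(o$source))), pch = 19,
                   cex = 0.8)
  invisible(x)
}

#' Lesion enlargement between two visits
#'
#' Computes the absolute change in GA area (mm2) from the start to the end
#' visit of `interval`, per patient and source.  Patients lacking either
#' endpoint for a source are excluded for that source.  With
#' `complete_case_visits` set, only patients having every listed visit for
#' every listed source are retained (the complete-case restriction used for
#' longitudinal mean-change comparisons).
#'
#' @param records area data frame (`patient_id`, `visit`, `source`,
#'   `area_mm2`).
#' @param interval length-2 character vector, e.g. `c("SCR", "M6")`.
#' @param complete_case_visits optional character vector of visits that
#'   must all be present (for all sources) for a patient to be used.
#' @param drop_outliers if `TRUE`, deltas with
#'   `|delta - median| > 5 * MAD` (per source) are removed before the
#'   summary.  Off by default.
#' @return Object of class `enlargement`: `table` (per patient-source
#'   `delta_mm2`) and `summary` (per source: n, mean delta, standard
#'   error).
#' @export
enlargement <- function(records, interval, complete_case_visits = NULL,
                        drop_outliers = FALSE) {
  stopifnot(length(interval) == 2)
  if (!is.null(complete_case_visits)) {
    keep <- vapply(split(records, records$patient_id), function(d) {
      all(vapply(unique(records$source), function(s)
        all(complete_case_visits %in% d$visit[d$source == s]), logical(1)))
    }, logical(1))
    records <- records[records$patient_id %in%
                         names(keep)[keep], , drop = FALSE]
  }
  rows <- list()
  for (s in unique(records$source)) {
    d <- records[records$source == s, , drop = FALSE]
    a0 <- d[d$visit == interval[1], c("patient_id", "area_mm2")]
    a1 <- d[d$visit == interval[2], c("patient_id", "area_mm2")]
    m <- merge(a0, a1, by = "patient_id", suffixes = c("_start", "_end"))
    if (nrow(m) == 0) next
    rows[[s]] <- data.frame(patient_id = m$patient_id, source = s,
                            interval = paste(interval, collapse = "->"),
                            delta_mm2 = m$area_mm2_end - m$area_mm2_start)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), source = character(),
               interval = character(), delta_mm2 = numeric())
  rownames(tab) <- NULL
  if (drop_outliers && nrow(tab) > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$source),
      function(idx) {
        d <- tab$delta_mm2[idx]
        md <- stats::median(d); madv <- stats::mad(d)
        if (madv == 0) idx else idx[abs(d - md) <= 5 * madv]
      }))
    tab <- tab[sort(keep), , drop = FALSE]
  }
  summ <- if (nrow(tab) > 0) {
    do.call(rbind, lapply(split(tab, tab$source), function(d)
      data.frame(source = d$source[1], n = nrow(d),
                 mean_delta = mean(d$delta_mm2),
                 se = stats::sd(d$delta_mm2) / sqrt(nrow(d)))))
  } else {
    data.frame(source = character(), n = integer(),
               mean_delta = numeric(), se = numeric())
  }
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, interval = interval),
            class = "enlargement")
}

#' @export
print.enlargement <- function(x, ...) {
  cat(sprintf("GA enlargement %s -> %s (mm2)\n", x$interval[1],
              x$interval[2]))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Coefficient of variation of per-patient area changes
#'
#' Sample SD divided by the mean.  Scale-invariant; undefined (error) when
#' the mean is zero.
#'
#' @param deltas numeric vector of per-patient changes.
#' @return Scalar CV.
#' @export
coefficient_of_variation <- function(deltas) {
  if (length(deltas) < 2) stop("need at least 2 values")
  m <- mean(deltas)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(deltas) / m
}
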