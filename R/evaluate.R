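#' Cohort-level agreement evaluation
#'
#' Computes the complete cross-sectional and longitudinal agreement report
#' between segmentation sources on a cohort: per-visit and pooled Dice
#' tables for every grader-model pair and the grader-grader pair, lesion
#' areas (after the minimal-spot filter), Pearson and Passing-Bablok
#' cross-sectional area agreement against the average grader, generalized
#' Bland-Altman limits derived from graders, and per-interval enlargement
#' with coefficients of variation.
#'
#' The "average grader" series is the per-image mean of the grader areas
#' (areas are averaged, not masks) and serves as the reference standard for
#' the network comparisons.
#'
#' @param records list of image-pair records (see [load_manifest()]); each
#'   record must carry the grader masks in `record$graders`.
#' @param model_masks named list (one element per model, e.g. `"UNet"`,
#'   `"YNet"`) of lists of [lesion_mask()] objects aligned with `records`.
#'   A record whose mask is `NULL` for some model is skipped for that
#'   model's comparisons (with a log entry in the returned `skipped`).
#' @param min_area_mm2 minimal-spot filter applied when measuring areas.
#' @param filter_predictions apply the minimal-spot filter to model/grader
#'   masks before Dice as well (default `FALSE`: the filter is a grading
#'   convention for areas; Dice uses raw masks).
#' @param cross_visit visit label used for the cross-sectional area
#'   agreement (default `"SCR"`).
#' @param intervals list of length-2 visit vectors for enlargement.
#' @param fovea_radius_mm radius of the central disc used to flag foveal
#'   involvement of the truth lesion.
#' @return Object of class `agreement_report`.
#' @export
evaluate_cohort <- function(records, model_masks = list(),
                            min_area_mm2 = 0.05,
                            filter_predictions = FALSE,
                            cross_visit = "SCR",
                            intervals = list(c("SCR", "M6"),
                                             c("SCR", "M12")),
                            fovea_radius_mm = 0.25) {
  grader_names <- names(records[[1]]$graders)
  if (length(grader_names) < 2)
    stop("need at least two grader sources per record")
  model_names <- names(model_masks)
  pairs <- c(unlist(lapply(model_names, function(m)
    paste(grader_names, m, sep = "-"))),
    if (length(grader_names) >= 2)
      utils::combn(grader_names, 2, paste, collapse = "-"))
  skipped <- list()
  per_image <- list()
  areas <- list()
  for (i in seq_along(records)) {
    r <- records[[i]]
    masks <- r$graders
    ok <- TRUE
    for (m in model_names) {
      mm <- model_masks[[m]][[i]]
      if (is.null(mm)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          record = i, patient_id = r$patient_id, visit = r$visit,
          reason = paste("missing", m, "mask"))
        ok <- FALSE
      } else masks[[m]] <- mm
    }
    if (!ok) next
    sc <- r$truth$scale_mm_per_px
    dice_row <- list(patient_id = r$patient_id, visit = r$visit)
    for (p in pairs) {
      ab <- strsplit(p, "-", fixed = TRUE)[[1]]
      ma <- masks[[ab[1]]]$pixels; mb <- masks[[ab[2]]]$pixels
      if (filter_predictions) {
        ma <- filter_mask_px(masks[[ab[1]]], min_area_mm2)
        mb <- filter_mask_px(masks[[ab[2]]], min_area_mm2)
      }
      dice_row[[p]] <- dice_coefficient(ma, mb)
    }
    # truth-derived covariates
    dice_row$truth_area <- total_area(r$truth, min_area_mm2)
    dice_row$focality <- focality(r$truth, min_area_mm2)
    dice_row$foveal <- foveal_involvement(r$truth, fovea_radius_mm)
    per_image[[length(per_image) + 1L]] <- as.data.frame(dice_row,
                                                         check.names = FALSE)
    srcs <- c(masks, list(truth = r$truth))
    for (s in names(srcs)) {
      areas[[length(areas) + 1L]] <- data.frame(
        patient_id = r$patient_id, visit = r$visit, source = s,
        area_mm2 = total_area(srcs[[s]], min_area_mm2))
    }
  }
  if (length(per_image) == 0) stop("no evaluable records")
  per_image <- do.call(rbind, per_image)
  areas <- do.call(rbind, areas)
  # average-grader area series
  ga <- areas[areas$source %in% grader_names, ]
  avg <- stats::aggregate(area_mm2 ~ patient_id + visit, data = ga, mean)
  avg$source <- "avg_grader"
  areas <- rbind(areas, avg[, names(areas)])
  dice_table <- build_dice_table(per_image, pairs)
  cross <- cross_sectional_agreement(areas, grader_names, model_names,
                                     cross_visit)
  ba <- generalized_bland_altman(
    areas[areas$source %in% c(grader_names, model_names) &
            areas$visit == cross_visit, ], grader_names)
  longit <- lapply(intervals, function(iv)
    longitudinal_agreement(areas, iv, grader_names, model_names))
  names(longit) <- vapply(intervals, paste, "", collapse = "->")
  structure(list(pairs = pairs, dice = dice_table, per_image = per_image,
                 areas = areas, cross_sectional = cross, bland_altman = ba,
                 longitudinal = longit,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else
                   NULL,
                 config = list(grader_sources = grader_names,
                               model_sources = model_names,
                               min_area_mm2 = min_area_mm2,
                               cross_visit = cross_visit,
                               fovea_radius_mm = fovea_radius_mm)),
            class = "agreement_report")
}

filter_mask_px <- function(mask, min_area_mm2) {
  spots <- lesion_spots(mask, min_area_mm2)
  px <- mask$pixels * 0L
  if (nrow(spots) == 0) return(px)
  lab <- label_components(mask$pixels, 8L)
  px[lab %in% spots$component_id] <- 1L
  px
}

foveal_involvement <- function(mask, fovea_radius_mm) {
  px <- mask$pixels
  n <- dim(px)
  sc <- mask$scale_mm_per_px
  ctr <- (n + 1) / 2
  rpx <- fovea_radius_mm / sc
  ri <- which(abs(seq_len(n[1]) - ctr[1]) <= rpx)
  ci <- which(abs(seq_len(n[2]) - ctr[2]) <= rpx)
  d2 <- outer((ri - ctr[1])^2, (ci - ctr[2])^2, "+")
  any(px[ri, ci][d2 <= rpx^2] == 1)
}

build_dice_table <- function(per_image, pairs) {
  visits <- intersect(VISIT_LEVELS, unique(per_image$visit))
  rows <- lapply(c("All", visits), function(v) {
    d <- if (v == "All") per_image else per_image[per_image$visit == v, ]
    row <- list(visit = v, n = nrow(d))
    for (p in pairs) {
      row[[paste0(p, "_mean")]] <- mean(d[[p]])
      row[[paste0(p, "_sd")]] <- stats::sd(d[[p]])
    }
    as.data.frame(row, check.names = FALSE)
  })
  do.call(rbind, rows)
}

cross_sectional_agreement <- function(areas, grader_names, model_names,
                                      cross_visit) {
  av <- areas[areas$visit == cross_visit, ]
  wide <- stats::reshape(av, idvar = "patient_id", timevar = "source",
                         direction = "wide", drop = "visit")
  names(wide) <- sub("^area_mm2\\.", "", names(wide))
  out <- list()
  cmp <- c(lapply(model_names, function(m) c(m, "avg_grader")),
           if (length(grader_names) >= 2) list(grader_names[1:2]))
  for (cc in cmp) {
    x <- wide[[cc[2]]]; y <- wide[[cc[1]]]
    keep <- stats::complete.cases(x, y)
    nm <- paste(cc[1], "vs", cc[2])
    out[[nm]] <- list(
      n = sum(keep),
      r = if (sum(keep) >= 3 && stats::sd(x[keep]) > 0 &&
              stats::sd(y[keep]) > 0) pearson_r(x[keep], y[keep]) else
                NA_real_,
      pb = tryCatch(passing_bablok(x[keep], y[keep]),
                    error = function(e) NULL))
  }
  out
}

longitudinal_agreement <- function(areas, interval, grader_names,
                                   model_names) {
  srcs <- c(grader_names, model_names, "avg_grader", "truth")
  enl <- enlargement(areas[areas$source %in% srcs, ], interval)
  tab <- enl$table
  wide <- stats::reshape(tab[, c("patient_id", "source", "delta_mm2")],
                         idvar = "patient_id", timevar = "source",
                         direction = "wide")
  names(wide) <- sub("^delta_mm2\\.", "", names(wide))
  cors <- list()
  cmp <- c(lapply(c(model_names, grader_names), function(m)
    c(m, "avg_grader")),
    if (length(grader_names) >= 2) list(grader_names[1:2]),
    lapply(intersect(c(grader_names, model_names), names(wide)),
           function(s) c(s, "truth")))
  for (cc in cmp) {
    if (!all(cc %in% names(wide))) next
    x <- wide[[cc[2]]]; y <- wide[[cc[1]]]
    keep <- stats::complete.cases(x, y)
    nm <- paste(cc[1], "vs", cc[2])
    cors[[nm]] <- if (sum(keep) >= 3 && stats::sd(x[keep]) > 0 &&
                      stats::sd(y[keep]) > 0)
      pearson_r(x[keep], y[keep]) else NA_real_
  }
  cv <- vapply(split(tab, tab$source), function(d)
    tryCatch(coefficient_of_variation(d$delta_mm2),
             error = function(e) NA_real_), numeric(1))
  list(enlargement = enl, correlations = cors, cv = cv)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report\n")
  cat(sprintf("  comparison pairs: %s\n", paste(x$pairs, collapse = ", ")))
  cat("  Dice (mean [SD]):\n")
  d <- x$dice
  for (i in seq_len(nrow(d))) {
    cells <- vapply(x$pairs, function(p)
      sprintf("%s %.3f (%.3f)", p, d[i, paste0(p, "_mean")],
              d[i, paste0(p, "_sd")]), character(1))
    cat(sprintf("    %-4s n=%3d  %s\n", d$visit[i], d$n[i],
                paste(cells, collapse = "  ")))
  }
  cat(sprintf("  cross-sectional area agreement at %s:\n",
              x$config$cross_visit))
  for (nm in names(x$cross_sectional)) {
    cs <- x$cross_sectional[[nm]]
    cat(sprintf("    %-24s r = %.3f (n = %d)", nm, cs$r, cs$n))
    if (!is.null(cs$pb))
      cat(sprintf(", PB slope %.3f intercept %.3f", cs$pb$slope,
                  cs$pb$intercept))
    cat("\n")
  }
  for (nm in names(x$longitudinal)) {
    lg <- x$longitudinal[[nm]]
    cat(sprintf("  enlargement %s: ", nm))
    s <- lg$enlargement$summary
    cat(paste(sprintf("%s %.2f+/-%.2f", s$source, s$mean_delta, s$se),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Export an agreement report
#'
#' Writes the tidy long-format CSV (`comparison`, `visit`, `metric`,
#' `value`) and a JSON summary next to it.
#'
#' @param report an `agreement_report`.
#' @param path_csv CSV output path.
#' @param path_json optional JSON output path.
#' @return Invisibly, the tidy data frame.
#' @export
write_report <- function(report, path_csv, path_json = NULL) {
  rows <- list()
  d <- report$dice
  for (i in seq_len(nrow(d))) {
    for (p in report$pairs) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = p, visit = d$visit[i], metric = "dice_mean",
        value = d[i, paste0(p, "_mean")])
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = p, visit = d$visit[i], metric = "dice_sd",
        value = d[i, paste0(p, "_sd")])
    }
  }
  for (nm in names(report$cross_sectional)) {
    cs <- report$cross_sectional[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = nm, visit = report$config$cross_visit,
      metric = "pearson_r", value = cs$r)
    if (!is.null(cs$pb)) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = nm, visit = report$config$cross_visit,
        metric = "pb_slope", value = cs$pb$slope)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = nm, visit = report$config$cross_visit,
        metric = "pb_intercept", value = cs$pb$intercept)
    }
  }
  for (nm in names(report$longitudinal)) {
    lg <- report$longitudinal[[nm]]
    s <- lg$enlargement$summary
    for (i in seq_len(nrow(s))) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = s$source[i], visit = nm, metric = "mean_enlargement",
        value = s$mean_delta[i])
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = s$source[i], visit = nm, metric = "enlargement_se",
        value = s$se[i])
    }
    for (cn in names(lg$correlations)) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cn, visit = nm, metric = "enlargement_r",
        value = lg$correlations[[cn]])
    }
    for (sv in names(lg$cv)) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = sv, visit = nm, metric = "cv",
        value = unname(lg$cv[sv]))
    }
  }
  tidy <- do.call(rbind, rows)
  utils::write.csv(tidy, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(
      pairs = report$pairs,
      dice = report$dice,
      limits = as.list(report$bland_altman$limits)),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tidy)
}

#' Subgroup analysis of segmentation accuracy
#'
#' Assesses whether network accuracy depends on baseline lesion area,
#' focality or foveal involvement.  Categorical partitions (unifocal vs
#' multifocal, fovea involved vs spared, baseline area split at the cohort
#' median) report the per-subgroup mean Dice over the grader-model pairs
#' and, where at least 3 images are available, the model-vs-average-grader
#' area correlation; subgroups with fewer than 3 members are reported as
#' `NA`.  The correlation of per-image Dice with the continuous baseline
#' area is attached as attribute `continuous_r`.
#'
#' @param report an `agreement_report` from [evaluate_cohort()].
#' @return `data.frame` of class `subgroup_analysis` with columns
#'   `covariate`, `level`, `n`, `mean_dice`, `r_area`.
#' @export
subgroup_analysis <- function(report) {
  pi_df <- report$per_image
  gm_pairs <- setdiff(report$pairs,
                      utils::combn(report$config$grader_sources, 2, paste,
                                   collapse = "-"))
  if (length(gm_pairs) == 0) gm_pairs <- report$pairs
  mean_pair_dice <- rowMeans(pi_df[, gm_pairs, drop = FALSE])
  med_area <- stats::median(pi_df$truth_area)
  groups <- list(
    focality = ifelse(pi_df$focality <= 1, "unifocal", "multifocal"),
    foveal_involvement = ifelse(pi_df$foveal, "involved", "spared"),
    baseline_area = ifelse(pi_df$truth_area <= med_area, "below_median",
                           "above_median"))
  areas <- report$areas
  model_names <- report$config$model_sources
  rows <- list()
  for (cv in names(groups)) {
    for (lv in unique(groups[[cv]])) {
      sel <- groups[[cv]] == lv
      n <- sum(sel)
      if (n < 3) {
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cv, level = lv, n = n, mean_dice = NA_real_,
          r_area = NA_real_)
        next
      }
      keys <- paste(pi_df$patient_id[sel], pi_df$visit[sel])
      akeys <- paste(areas$patient_id, areas$visit)
      sub_areas <- areas[akeys %in% keys, ]
      r_area <- NA_real_
      if (length(model_names) > 0) {
        wide <- stats::reshape(sub_areas, idvar = c("patient_id", "visit"),
                               timevar = "source", direction = "wide")
        names(wide) <- sub("^area_mm2\\.", "", names(wide))
        rs <- vapply(model_names, function(m) {
          x <- wide[["avg_grader"]]; y <- wide[[m]]
          keep <- stats::complete.cases(x, y)
          if (sum(keep) >= 3 && stats::sd(x[keep]) > 0 &&
              stats::sd(y[keep]) > 0) pearson_r(x[keep], y[keep]) else
                NA_real_
        }, numeric(1))
        r_area <- mean(rs, na.rm = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, level = lv, n = n,
        mean_dice = mean(mean_pair_dice[sel]), r_area = r_area)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "continuous_r") <-
    if (nrow(pi_df) >= 3 && stats::sd(pi_df$truth_area) > 0 &&
        stats::sd(mean_pair_dice) > 0)
      pearson_r(pi_df$truth_area, mean_pair_dice) else NA_real_
  class(out) <- c("subgroup_analysis", "data.frame")
  out
}
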