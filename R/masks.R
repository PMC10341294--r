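#' Binary GA lesion mask
#'
#' A lesion mask is a 2-d raster of 0/1 pixel values (1 = geographic atrophy)
#' together with an isotropic physical pixel scale in mm per pixel.  The
#' default scale corresponds to a 30-degree fundus field of about 8.85 mm
#' mapped onto the raster width; real acquisitions should carry their own
#' calibrated scale through the cohort manifest.
#'
#' @param pixels numeric or integer matrix containing only 0 and 1.
#' @param scale_mm_per_px positive scalar, mm per pixel.  `NULL` uses the
#'   30-degree-field default `8.85 / ncol(pixels)`.
#' @return An object of class `lesion_mask`: a list with elements `pixels`
#'   (integer matrix) and `scale_mm_per_px`.
#' @examples
#' m <- lesion_mask(matrix(c(0, 1, 1, 0), 2, 2), scale_mm_per_px = 0.05)
#' total_area(m, min_area_mm2 = 0)
#' @export
lesion_mask <- function(pixels, scale_mm_per_px = NULL) {
  pixels <- as.matrix(pixels)
  if (!all(pixels == 0 | pixels == 1))
    stop("lesion mask pixels must be exactly 0 or 1")
  if (is.null(scale_mm_per_px)) scale_mm_per_px <- 8.85 / ncol(pixels)
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1L ||
      !is.finite(scale_mm_per_px) || scale_mm_per_px <= 0)
    stop("scale_mm_per_px must be a positive scalar")
  structure(list(pixels = matrix(as.integer(pixels), nrow(pixels)),
                 scale_mm_per_px = as.numeric(scale_mm_per_px)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d x %d px, scale %.4f mm/px, %d lesion px (%.3f mm2 unfiltered)\n",
              nrow(x$pixels), ncol(x$pixels), x$scale_mm_per_px,
              sum(x$pixels), sum(x$pixels) * x$scale_mm_per_px^2))
  invisible(x)
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "lesion_mask")) return(x$pixels)
  if (inherits(x, "weighted_mask")) return(x$weights)
  as.matrix(x)
}

#' Dice similarity coefficient between two binary masks
#'
#' Computes `2|A n B| / (|A| + |B|)`.  Two empty masks are defined to agree
#' perfectly (Dice 1), so lesion-free controls compare as matches; an empty
#' versus a non-empty mask scores 0.
#'
#' @param a,b binary matrices or `lesion_mask` objects on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as_pixel_matrix(a); b <- as_pixel_matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("dice_coefficient: masks have different grid shapes")
  if (!all(a == 0 | a == 1) || !all(b == 0 | b == 1))
    stop("dice_coefficient: inputs must be binary")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Edge-reweighted training mask
#'
#' Derives a real-valued weight raster from a binary lesion mask that
#' emphasizes lesion borders over interiors: background pixels get weight 0,
#' lesion pixels within `edge_band_px` of the lesion boundary get weight 1,
#' and deeper interior pixels decay linearly with Chebyshev distance to the
#' background down to `interior_floor`.  The weighted raster is used as the
#' soft target of the training loss only; validation always uses the original
#' binary mask.
#'
#' @param mask a [lesion_mask()].
#' @param interior_floor minimum interior weight, in `[0.5, 1]`.
#' @param edge_band_px width (pixels) of the boundary band that keeps full
#'   weight 1.
#' @param profile optional `function(d, d_max)` mapping Chebyshev
#'   background-distance to interior weight, overriding the linear decay.
#'   Must return values in `[interior_floor, 1]`, non-increasing in `d`.
#' @return Object of class `weighted_mask`: list with `weights` (numeric
#'   matrix in `[0,1]`) and `source` (the input `lesion_mask`).
#' @export
reweight_mask <- function(mask, interior_floor = 0.5, edge_band_px = 1L,
                          profile = NULL) {
  if (!inherits(mask, "lesion_mask")) mask <- lesion_mask(mask)
  if (interior_floor < 0.5 || interior_floor > 1)
    stop("interior_floor must lie in [0.5, 1]")
  if (edge_band_px < 1) stop("edge_band_px must be >= 1")
  px <- mask$pixels
  w <- matrix(0, nrow(px), ncol(px))
  if (sum(px) == 0)
    return(structure(list(weights = w, source = mask), class = "weighted_mask"))
  bg <- 1L - px
  if (sum(bg) == 0) {
    # degenerate all-lesion raster: treat the raster border as the boundary
    d <- chamfer_border_distance(dim(px))
  } else {
    d <- chamfer_distance(bg, 1, 1)  # Chebyshev distance to background
  }
  lab <- label_components(px, 8L)
  dmax <- tapply(d[px == 1], lab[px == 1], max)
  inside <- which(px == 1)
  di <- d[inside]
  dm <- as.numeric(dmax[as.character(lab[inside])])
  wi <- if (is.null(profile)) {
    pmax(interior_floor, 1 - (di / dm) * (1 - interior_floor))
  } else {
    vapply(seq_along(di), function(k) profile(di[k], dm[k]), numeric(1))
  }
  wi[di <= edge_band_px] <- 1
  w[inside] <- wi
  structure(list(weights = w, source = mask), class = "weighted_mask")
}

# Chebyshev distance of each pixel to just outside the raster border
chamfer_border_distance <- function(dm) {
  i <- matrix(seq_len(dm[1]), dm[1], dm[2])
  j <- matrix(seq_len(dm[2]), dm[1], dm[2], byrow = TRUE)
  pmin(i, j, dm[1] + 1 - i, dm[2] + 1 - j)
}

#' @export
print.weighted_mask <- function(x, ...) {
  nz <- x$weights[x$weights > 0]
  cat(sprintf("<weighted_mask> %d x %d px, %d weighted px, weight range [%.3f, %.3f]\n",
              nrow(x$weights), ncol(x$weights), length(nz),
              if (length(nz)) min(nz) else 0, if (length(nz)) max(nz) else 0))
  invisible(x)
}

#' Weighted (modified) soft Dice coefficient
#'
#' Weight-inserted soft Dice between a probability map `p` and an
#' edge-reweighted mask derived from a binary ground truth `g`:
#' `2 * sum(v*p*g) / (sum(v*p) + sum(v*g))`, where the effective per-pixel
#' weight `v` equals the reweighted-mask value on lesion pixels (1 on the
#' border band, decaying towards the interior floor inside) and 1 on
#' background pixels.  Down-weighting interior pixels shifts the emphasis of
#' the induced loss onto lesion boundaries, while the unit background weight
#' keeps false positives penalized through the `sum(v*p)` term.  A perfect
#' prediction (`p == g`) scores 1 for any valid weight map, and when every
#' lesion weight is 1 the value is exactly the ordinary soft Dice
#' coefficient.
#'
#' @param pred numeric matrix of per-pixel probabilities in `[0,1]`.
#' @param wmask a [reweight_mask()] result, or a numeric weight matrix in
#'   which case the binary source mask is recovered as `w > 0`.
#' @return Scalar in `[0, 1]`.
#' @export
weighted_dice <- function(pred, wmask) {
  p <- as.matrix(pred)
  w <- as_pixel_matrix(wmask)
  if (!identical(dim(p), dim(w)))
    stop("weighted_dice: prediction and mask grids differ")
  if (any(p < 0 | p > 1)) stop("weighted_dice: probabilities outside [0,1]")
  g <- if (inherits(wmask, "weighted_mask")) wmask$source$pixels else (w > 0) * 1L
  v <- ifelse(g == 1, w, 1)
  s <- sum(v * p) + sum(v * g)
  if (s == 0) return(1)
  2 * sum(v * p * g) / s
}

#' Dice loss
#'
#' `1 - weighted_dice(pred, wmask)`; the quantity minimized during training.
#' @inheritParams weighted_dice
#' @return Non-negative scalar.
#' @seealso [dice_loss_grad()] for the analytic gradient used by the
#'   optimizer.
#' @export
dice_loss <- function(pred, wmask) 1 - weighted_dice(pred, wmask)

#' Gradient of the Dice loss with respect to the probability map
#'
#' @inheritParams weighted_dice
#' @return Numeric matrix `d loss / d pred`, same shape as `pred`.
#' @export
dice_loss_grad <- function(pred, wmask) {
  p <- as.matrix(pred)
  w <- as_pixel_matrix(wmask)
  if (!identical(dim(p), dim(w)))
    stop("dice_loss_grad: prediction and mask grids differ")
  g <- if (inherits(wmask, "weighted_mask")) wmask$source$pixels else (w > 0) * 1L
  v <- ifelse(g == 1, w, 1)
  s <- sum(v * p) + sum(v * g)
  if (s == 0) return(matrix(0, nrow(p), ncol(p)))
  n <- 2 * sum(v * p * g)
  v * (n - 2 * g * s) / s^2
}

#' Binarize a probability map
#'
#' Thresholds per-pixel probabilities with a strict inequality: a pixel is
#' lesion iff its probability is strictly greater than `threshold`, so a map
#' that sits exactly at the threshold stays background.
#'
#' @param pred numeric matrix of probabilities.
#' @param threshold scalar in `(0, 1)`, default 0.5.
#' @param scale_mm_per_px pixel scale forwarded to [lesion_mask()].
#' @return A [lesion_mask()].
#' @export
binarize <- function(pred, threshold = 0.5, scale_mm_per_px = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  p <- as.matrix(pred)
  lesion_mask((p > threshold) * 1L, scale_mm_per_px)
}

#' Lesion spots: connected components above a minimal area
#'
#' Labels connected lesion components and discards spots smaller than
#' `min_area_mm2` (default 0.05 mm2, about a 175-micron equivalent diameter —
#' the conventional minimal size for a countable GA lesion; smaller specks
#' are disregarded).  The number of surviving spots is the lesion focality.
#'
#' @param mask a [lesion_mask()].
#' @param min_area_mm2 minimal spot area in mm2; spots strictly smaller are
#'   dropped.
#' @param connectivity pixel adjacency, 4 or 8 (default 8).
#' @return `data.frame` with one row per surviving spot, sorted by area
#'   descending: `component_id`, `pixel_count`, `area_mm2`, `centroid_row`,
#'   `centroid_col` (1-based pixel coordinates).
#' @export
lesion_spots <- function(mask, min_area_mm2 = 0.05, connectivity = 8L) {
  if (!inherits(mask, "lesion_mask")) mask <- lesion_mask(mask)
  empty <- data.frame(component_id = integer(), pixel_count = integer(),
                      area_mm2 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric())
  if (sum(mask$pixels) == 0) return(empty)
  lab <- label_components(mask$pixels, as.integer(connectivity))
  ids <- sort(unique(lab[lab > 0]))
  px_area <- mask$scale_mm_per_px^2
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    data.frame(component_id = id, pixel_count = nrow(idx),
               area_mm2 = nrow(idx) * px_area,
               centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]))
  })
  out <- do.call(rbind, rows)
  out <- out[out$area_mm2 >= min_area_mm2, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out <- out[order(-out$area_mm2, out$component_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total lesion area in mm2
#'
#' Sum of the areas of all lesion spots surviving the minimal-area filter.
#'
#' @inheritParams lesion_spots
#' @return Scalar area in mm2.
#' @export
total_area <- function(mask, min_area_mm2 = 0.05, connectivity = 8L) {
  sum(lesion_spots(mask, min_area_mm2, connectivity)$area_mm2)
}

#' Lesion focality (number of spots)
#'
#' @inheritParams lesion_spots
#' @return Integer count of spots surviving the minimal-area filter.
#' @export
focality <- function(mask, min_area_mm2 = 0.05, connectivity = 8L) {
  nrow(lesion_spots(mask, min_area_mm2, connectivity))
}
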