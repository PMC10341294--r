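# Raster resampling. Images are resized bilinearly; masks use
# nearest-neighbour so the result stays binary.

interp_matrix <- function(n_in, n_out) {
  s <- n_in / n_out
  y <- (seq_len(n_out) - 0.5) * s + 0.5
  y0 <- floor(y)
  t <- y - y0
  y0 <- pmin(pmax(y0, 1), n_in)
  y1 <- pmin(y0 + 1, n_in)
  m <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  m[cbind(idx, y0)] <- m[cbind(idx, y0)] + (1 - t)
  m[cbind(idx, y1)] <- m[cbind(idx, y1)] + t
  m
}

#' Bilinear raster resize
#'
#' @param m numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return Resized numeric matrix.
#' @export
resize_bilinear <- function(m, out_h, out_w) {
  if (nrow(m) == out_h && ncol(m) == out_w) return(m)
  rh <- interp_matrix(nrow(m), out_h)
  rw <- interp_matrix(ncol(m), out_w)
  rh %*% m %*% t(rw)
}

#' Nearest-neighbour raster resize
#'
#' @inheritParams resize_bilinear
#' @return Resized matrix with only original values (safe for binary masks).
#' @export
resize_nearest <- function(m, out_h, out_w) {
  if (nrow(m) == out_h && ncol(m) == out_w) return(m)
  ri <- pmin(pmax(round((seq_len(out_h) - 0.5) * nrow(m) / out_h + 0.5), 1),
             nrow(m))
  ci <- pmin(pmax(round((seq_len(out_w) - 0.5) * ncol(m) / out_w + 0.5), 1),
             ncol(m))
  m[ri, ci, drop = FALSE]
}
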