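#' Read a grayscale raster (PNG or TIFF)
#'
#' Returns intensities in `[0, 1]`; multi-channel files are reduced to their
#' first channel.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("unreadable image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", path))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Write a grayscale raster as 8-bit PNG
#'
#' @param m numeric matrix in `[0, 1]`.
#' @param path output path.
#' @export
write_image8 <- function(m, path) {
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}

#' Read a binary lesion mask
#'
#' Accepts 0/255 (or 0/1) single-channel PNG/TIFF rasters.
#'
#' @param path file path.
#' @param scale_mm_per_px pixel scale for the resulting [lesion_mask()].
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path, scale_mm_per_px = NULL) {
  img <- read_image(path)
  u <- sort(unique(as.vector(img)))
  if (!all(u %in% c(0, 1)) && !all(abs(u - round(u * 255) / 255) < 1e-6 &
                                   round(u * 255) %in% c(0, 255)))
    stop("mask is not binary (0/255): ", path)
  lesion_mask((img > 0.5) * 1L, scale_mm_per_px)
}

#' Write a binary mask as 0/255 PNG
#'
#' @param mask a [lesion_mask()] or binary matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  px <- as_pixel_matrix(mask)
  png::writePNG(px * 1.0, path)
  invisible(path)
}

#' Write a probability map as 32-bit float TIFF
#'
#' @param prob numeric matrix in `[0, 1]`.
#' @param path output path.
#' @export
write_prob_tiff <- function(prob, path) {
  tiff::writeTIFF(prob, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a probability map written by [write_prob_tiff()]
#'
#' @param path file path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_prob_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

MANIFEST_COLUMNS <- c("patient_id", "visit", "faf_path", "nir_path",
                      "truth_mask_path", "scale_mm_per_px")

#' Load a cohort manifest into image-pair records
#'
#' Reads the manifest CSV (columns `patient_id`, `visit`, `faf_path`,
#' `nir_path`, `truth_mask_path`, `scale_mm_per_px`, optionally
#' `grader1_mask_path`/`grader2_mask_path`), loads all rasters and
#' validates each row: mask values must be binary and every mask must share
#' the image grid.  Rows lacking an NIR image are not errors — they are
#' excluded with the reason `"no corresponding NIR"`, mirroring the
#' exclusion rule for FAF-only acquisitions — and reported via the
#' `exclusions` attribute.  Any other defect (missing column, unreadable
#' file, grid mismatch) is a per-row error.
#'
#' @param path manifest CSV path, or a manifest `data.frame` carrying a
#'   `dir` attribute (as returned by [generate_cohort()]).
#' @return List of records (each: `patient_id`, `visit`, `faf`, `nir`,
#'   `truth`, optional `graders` named list, `scale_mm_per_px`), with
#'   attribute `exclusions`: data frame of excluded rows and reasons.
#' @export
load_manifest <- function(path) {
  if (is.data.frame(path)) {
    mf <- path
    base <- attr(mf, "dir")
    if (is.null(base)) base <- "."
  } else {
    if (!file.exists(path)) stop("manifest not found: ", path)
    mf <- utils::read.csv(path, stringsAsFactors = FALSE)
    base <- dirname(path)
  }
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(mf))
  if (length(missing_cols))
    stop("manifest lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "", NA_character_,
           ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p)))
  }
  records <- list()
  excl <- list()
  for (i in seq_len(nrow(mf))) {
    row <- mf[i, ]
    nir_path <- resolve(row$nir_path)
    if (is.na(nir_path) || !file.exists(nir_path)) {
      excl[[length(excl) + 1L]] <- data.frame(
        row = i, patient_id = row$patient_id, visit = row$visit,
        reason = "no corresponding NIR")
      next
    }
    faf <- tryCatch(read_image(resolve(row$faf_path)), error = function(e)
      stop("manifest row ", i, ": ", conditionMessage(e)))
    nir <- read_image(nir_path)
    truth <- tryCatch(
      read_mask(resolve(row$truth_mask_path), row$scale_mm_per_px),
      error = function(e)
        stop("manifest row ", i, ": ", conditionMessage(e)))
    if (!identical(dim(faf), dim(nir)))
      stop("manifest row ", i, ": FAF and NIR grids differ")
    if (!identical(dim(truth$pixels), dim(faf)))
      stop("manifest row ", i, ": mask grid does not match image grid")
    graders <- list()
    for (g in c("grader1_mask_path", "grader2_mask_path")) {
      if (!is.null(mf[[g]]) && !is.na(row[[g]]) && row[[g]] != "") {
        gm <- read_mask(resolve(row[[g]]), row$scale_mm_per_px)
        if (!identical(dim(gm$pixels), dim(faf)))
          stop("manifest row ", i, ": grader mask grid mismatch")
        graders[[sub("_mask_path", "", g)]] <- gm
      }
    }
    records[[length(records) + 1L]] <- list(
      patient_id = as.character(row$patient_id),
      visit = as.character(row$visit), faf = faf, nir = nir, truth = truth,
      graders = graders, scale_mm_per_px = row$scale_mm_per_px)
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(row = integer(), patient_id = character(),
               visit = character(), reason = character())
  attr(records, "exclusions") <- exclusions
  records
}
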