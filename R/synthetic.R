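VISIT_LEVELS <- c("SCR", "M6", "M12", "M18", "M24", "ET")

visit_index <- function(visit) {
  i <- match(visit, VISIT_LEVELS)
  if (any(is.na(i))) stop("unknown visit label: ",
                          paste(visit[is.na(i)], collapse = ", "))
  i - 1L
}

#' Phantom specification for a synthetic FAF/NIR pair
#'
#' Describes one synthetic eye: lesion geometry (uni- or multifocal foci
#' with smooth random-harmonic boundary roughness), channel statistics, the
#' foveal confound, vessel and opacity artifacts, and a longitudinal growth
#' rate.  The phantom emulates the salient properties of registered
#' 30-degree FAF/NIR fundus pairs in GA: lesions are sharply demarcated dark
#' (hypoautofluorescent) regions on a bright FAF background and appear with
#' much lower contrast on NIR; the fovea is a dark patch on FAF only, so it
#' mimics a lesion on FAF while NIR cleanly separates it.
#'
#' Intensities are on `[0, 1]` (8-bit gray / 255).  Lesion centers/radii are
#' in mm relative to the image center.
#'
#' @param image_size square raster size in px (default 256 at desk scale;
#'   768 mirrors the full working resolution).
#' @param scale_mm_per_px pixel scale; default maps an 8.85 mm 30-degree
#'   field onto the raster width.
#' @param n_foci number of lesion foci (0 for a lesion-free control).
#' @param focus_centers list of `c(x, y)` mm offsets, or `NULL` to draw.
#' @param focus_radii numeric radii in mm, or `NULL` to draw.
#' @param lesion_boundary_roughness amplitude of the low-order radial
#'   harmonics perturbing each focus boundary (0 = perfect circle).
#' @param faf_background_mean,faf_background_noise FAF background mean and
#'   Gaussian noise SD.
#' @param nir_background_mean,nir_background_noise same for NIR.
#' @param faf_lesion_mean,nir_lesion_mean lesion intensities on each
#'   channel; the NIR lesion contrast is deliberately weak.
#' @param fovea_center `c(x, y)` mm offset of the fovea (default image
#'   center).
#' @param fovea_radius_mm radius of the foveal dark patch.
#' @param fovea_faf_darkening multiplicative darkening of FAF inside the
#'   fovea, in `[0, 1]`; applied to the FAF channel only.
#' @param vessel_count number of dark vessel arcs drawn on both channels.
#' @param opacity_artifact_prob probability of one opacity streak artifact
#'   on FAF.
#' @param growth_rate_mm2_per_6mo added lesion area per 6-month visit step.
#' @param seed integer seed; all structural randomness derives from it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L,
                         scale_mm_per_px = 8.85 / image_size,
                         n_foci = 1L, focus_centers = NULL,
                         focus_radii = NULL,
                         lesion_boundary_roughness = 0.15,
                         faf_background_mean = 0.72,
                         faf_background_noise = 0.03,
                         nir_background_mean = 0.50,
                         nir_background_noise = 0.03,
                         faf_lesion_mean = 0.12, nir_lesion_mean = 0.38,
                         fovea_center = c(0, 0), fovea_radius_mm = 0.35,
                         fovea_faf_darkening = 0.7, vessel_count = 3L,
                         opacity_artifact_prob = 0.1,
                         growth_rate_mm2_per_6mo = 1.0, seed = 1L) {
  if (!is.null(focus_radii) && any(focus_radii <= 0))
    stop("focus radii must be positive")
  if (fovea_radius_mm <= 0) stop("fovea_radius_mm must be positive")
  if (fovea_faf_darkening < 0 || fovea_faf_darkening > 1)
    stop("fovea_faf_darkening must be in [0, 1]")
  if (growth_rate_mm2_per_6mo < 0) stop("growth rate must be >= 0")
  structure(as.list(environment()), class = "phantom_spec")
}

# smooth closed boundary: r(theta) = r0 * (1 + sum_h a_h cos + b_h sin)
draw_harmonics <- function(roughness, orders = 2:5) {
  list(orders = orders,
       a = stats::rnorm(length(orders), 0, roughness / orders),
       b = stats::rnorm(length(orders), 0, roughness / orders))
}

boundary_radius <- function(r0, harm, theta) {
  pert <- rep(0, length(theta))
  for (k in seq_along(harm$orders))
    pert <- pert + harm$a[k] * cos(harm$orders[k] * theta) +
      harm$b[k] * sin(harm$orders[k] * theta)
  # a Fourier boundary r0*(1+p) encloses area pi*r0^2*(1 + sum(a^2+b^2)/2);
  # normalize so the enclosed area is exactly pi*r0^2 for every draw
  norm <- sqrt(1 + sum(harm$a^2 + harm$b^2) / 2)
  (r0 / norm) * pmax(1 + pert, 0.2)
}

# structural draws shared by all visits of one phantom
phantom_structure <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  half <- spec$image_size * spec$scale_mm_per_px / 2
  n <- spec$n_foci
  centers <- spec$focus_centers
  radii <- spec$focus_radii
  if (n > 0 && is.null(radii)) radii <- stats::runif(n, 0.6, 1.5)
  if (n > 0 && is.null(centers)) {
    centers <- vector("list", n)
    for (k in seq_len(n)) {
      for (try in 1:200) {
        ang <- stats::runif(1, 0, 2 * pi)
        dst <- stats::runif(1, spec$fovea_radius_mm + radii[k] + 0.3,
                            max(half - radii[k] - 0.5,
                                spec$fovea_radius_mm + radii[k] + 0.4))
        cand <- dst * c(cos(ang), sin(ang))
        ok <- all(vapply(centers[seq_len(k - 1)], function(cc)
          sqrt(sum((cand - cc)^2)) > radii[k] + 0.2, logical(1)))
        if (ok) { centers[[k]] <- cand; break }
      }
      if (is.null(centers[[k]])) centers[[k]] <- dst * c(cos(ang), sin(ang))
    }
  }
  harms <- lapply(seq_len(max(n, 0)), function(k)
    draw_harmonics(spec$lesion_boundary_roughness))
  vessels <- lapply(seq_len(spec$vessel_count), function(v) {
    ang <- stats::runif(2, 0, 2 * pi)
    list(p0 = 1.05 * half * c(cos(ang[1]), sin(ang[1])),
         p1 = 1.05 * half * c(cos(ang[2]), sin(ang[2])),
         ctrl = stats::runif(2, -half / 2, half / 2),
         width = stats::runif(1, 0.03, 0.06))
  })
  opacity <- if (stats::runif(1) < spec$opacity_artifact_prob) {
    list(center = stats::runif(2, -half / 2, half / 2),
         angle = stats::runif(1, 0, pi),
         len = stats::runif(1, 0.8, 2.0), width = stats::runif(1, 0.08, 0.2),
         depth = stats::runif(1, 0.15, 0.3))
  } else NULL
  list(centers = centers, radii = radii, harms = harms, vessels = vessels,
       opacity = opacity)
}

#' Generate one synthetic FAF/NIR phantom visit
#'
#' Renders the FAF and NIR rasters and the ground-truth lesion mask for a
#' given visit of the phantom described by `spec`.  Lesion geometry (focus
#' centers, boundary harmonics, vessels) is fixed across visits — the visits
#' are pre-registered — while focus radii are scaled so that the total truth
#' area grows by `growth_rate_mm2_per_6mo` per 6-month visit step.  Output
#' is deterministic given `(spec$seed, visit_index)`.
#'
#' @param spec a [phantom_spec()].
#' @param visit_index integer >= 0: number of 6-month steps since screening
#'   (SCR = 0, M6 = 1, ...).
#' @return List with `faf`, `nir` (matrices in `[0,1]`) and `truth` (a
#'   [lesion_mask()]).
#' @export
generate_phantom <- function(spec, visit_index = 0L) {
  stopifnot(inherits(spec, "phantom_spec"), visit_index >= 0)
  st <- phantom_structure(spec)
  n <- spec$image_size
  sc <- spec$scale_mm_per_px
  half <- n * sc / 2
  x <- ((seq_len(n)) - (n + 1) / 2) * sc
  X <- matrix(x, n, n, byrow = TRUE)   # column -> x
  Y <- matrix(x, n, n)                 # row -> y
  truth <- matrix(0L, n, n)
  if (spec$n_foci > 0) {
    a0 <- sum(pi * st$radii^2)
    target <- a0 + spec$growth_rate_mm2_per_6mo * visit_index
    gs <- sqrt(target / a0)
    for (k in seq_len(spec$n_foci)) {
      cx <- st$centers[[k]][1]; cy <- st$centers[[k]][2]
      rmax <- st$radii[k] * gs * 1.6
      sub <- which(abs(X - cx) <= rmax & abs(Y - cy) <= rmax)
      dx <- X[sub] - cx; dy <- Y[sub] - cy
      r <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      rb <- boundary_radius(st$radii[k] * gs, st$harms[[k]], th)
      if (any(abs(cx) + rb * abs(cos(th)) > half |
              abs(cy) + rb * abs(sin(th)) > half))
        stop("lesion exceeds image bounds at visit ", visit_index)
      truth[sub[r <= rb]] <- 1L
    }
  }
  # fovea-sparing phenotype: the foveal disc is never part of the truth
  # lesion, even when the lesion surrounds it
  fd <- sqrt((X - spec$fovea_center[1])^2 + (Y - spec$fovea_center[2])^2)
  truth[fd <= spec$fovea_radius_mm] <- 0L
  faf <- matrix(spec$faf_background_mean, n, n)
  nir <- matrix(spec$nir_background_mean, n, n)
  faf[truth == 1L] <- spec$faf_lesion_mean
  nir[truth == 1L] <- spec$nir_lesion_mean
  # foveal dark confound: FAF channel only
  fov <- pmax(1 - fd / spec$fovea_radius_mm, 0)  # 1 at center -> 0 at rim
  faf <- faf * (1 - spec$fovea_faf_darkening * pmin(fov * 2, 1))
  # vessels: thin dark arcs on both channels
  for (v in st$vessels) {
    tt <- seq(0, 1, length.out = 4 * n)
    bx <- (1 - tt)^2 * v$p0[1] + 2 * tt * (1 - tt) * v$ctrl[1] + tt^2 * v$p1[1]
    by <- (1 - tt)^2 * v$p0[2] + 2 * tt * (1 - tt) * v$ctrl[2] + tt^2 * v$p1[2]
    ci <- round((by + half) / sc + 0.5); cj <- round((bx + half) / sc + 0.5)
    wpx <- max(1L, round(v$width / sc))
    for (o in -wpx:wpx) {
      ii <- ci + o
      keep <- ii >= 1 & ii <= n & cj >= 1 & cj <= n
      faf[cbind(ii[keep], cj[keep])] <-
        faf[cbind(ii[keep], cj[keep])] - 0.18
      nir[cbind(ii[keep], cj[keep])] <-
        nir[cbind(ii[keep], cj[keep])] - 0.12
    }
  }
  if (!is.null(st$opacity)) {
    u <- c(cos(st$opacity$angle), sin(st$opacity$angle))
    dxo <- X - st$opacity$center[1]; dyo <- Y - st$opacity$center[2]
    along <- dxo * u[1] + dyo * u[2]
    across <- -dxo * u[2] + dyo * u[1]
    faf <- faf - st$opacity$depth *
      exp(-(along / st$opacity$len)^2 - (across / st$opacity$width)^2)
  }
  noise_seed <- (abs(spec$seed) %% 1000003L) * 1009L + visit_index * 7919L + 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(noise_seed)
  faf <- faf + matrix(stats::rnorm(n * n, 0, spec$faf_background_noise), n, n)
  nir <- nir + matrix(stats::rnorm(n * n, 0, spec$nir_background_noise), n, n)
  list(faf = pmin(pmax(faf, 0), 1), nir = pmin(pmax(nir, 0), 1),
       truth = lesion_mask(truth, sc))
}

# package-level default; calibrated by simulation so that two independent
# simulated graders agree at a mean Dice close to the 0.94 intergrader
# anchor on default phantoms (see the methods vignette)
DEFAULT_GRADER_NOISE <- 2.7

#' Simulate a human grader annotation of a truth mask
#'
#' Perturbs the lesion boundary by a smooth random displacement field:
#' the signed quasi-Euclidean distance to the lesion boundary is thresholded
#' at a low-frequency Gaussian field of SD `grader_noise` (in pixels), so
#' the simulated grader dilates the lesion where the field is positive and
#' erodes it where negative, with spatially coherent strokes.  Zero noise
#' returns the truth mask exactly.
#'
#' @param truth a [lesion_mask()].
#' @param grader_noise displacement SD in pixels (>= 0).  The default is
#'   calibrated so that two independent simulated graders reach a mean
#'   pairwise Dice of about 0.94 on default phantoms.
#' @param seed integer seed.
#' @return A [lesion_mask()] on the same grid and scale.
#' @export
simulate_grader <- function(truth, grader_noise = DEFAULT_GRADER_NOISE,
                            seed = 1L) {
  stopifnot(inherits(truth, "lesion_mask"), grader_noise >= 0)
  if (grader_noise == 0) return(truth)
  px <- truth$pixels
  if (sum(px) == 0) return(truth)
  d_out <- chamfer_distance(px, 3, 4) / 3           # distance to lesion
  d_in <- chamfer_distance(1L - px, 3, 4) / 3       # distance to background
  s <- d_out - d_in                                 # >0 outside, <0 inside
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  step <- 16L
  gh <- ceiling(nrow(px) / step) + 1L
  gw <- ceiling(ncol(px) / step) + 1L
  coarse <- matrix(stats::rnorm(gh * gw, 0, grader_noise), gh, gw)
  eps <- resize_bilinear(coarse, nrow(px), ncol(px))
  lesion_mask((s <= eps) * 1L, truth$scale_mm_per_px)
}

#' Generate a synthetic longitudinal cohort on disk
#'
#' Draws one randomized [phantom_spec()] per patient (one eye per patient),
#' renders every requested visit, simulates two independent grader
#' annotations of each truth mask, writes all rasters as 8-bit PNG and
#' returns the cohort manifest.  Baseline total lesion area is drawn within
#' `baseline_area_range` (default 2.54-17.78 mm2, the conventional
#' eligibility window); for multifocal phantoms the largest focus is forced
#' to at least `multifocal_min_largest` (default 1.27 mm2).  Fully
#' reproducible: the same seed gives byte-identical files and manifest.
#'
#' @param n_patients number of patients (>= 1).
#' @param visits character vector of visit labels among
#'   `SCR, M6, M12, M18, M24, ET`.
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param image_size raster size in px.
#' @param growth_rate_mm2_per_6mo lesion growth per 6-month step.
#' @param grader_noise boundary noise (pixels) for the two simulated
#'   graders; 0 makes both graders copy the truth.  The default `NULL`
#'   scales the calibrated 256-px default with `image_size` so the
#'   physical (mm) displacement — and hence the intergrader Dice — is
#'   resolution-independent.
#' @param baseline_area_range admissible total baseline area (mm2).
#' @param multifocal_min_largest minimal largest-focus area (mm2) for
#'   multifocal phantoms.
#' @param p_multifocal probability that a phantom is multifocal (2-3 foci).
#' @param lesion_boundary_roughness forwarded to [phantom_spec()].
#' @return Manifest `data.frame` (columns `patient_id`, `visit`,
#'   `faf_path`, `nir_path`, `truth_mask_path`, `grader1_mask_path`,
#'   `grader2_mask_path`, `scale_mm_per_px`; paths relative to `out_dir`)
#'   with attribute `dir = out_dir`.  Also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_cohort <- function(n_patients, visits = c("SCR", "M6", "M12"),
                            out_dir, seed = 1L, image_size = 256L,
                            growth_rate_mm2_per_6mo = 1.0,
                            grader_noise = NULL,
                            baseline_area_range = c(2.54, 17.78),
                            multifocal_min_largest = 1.27,
                            p_multifocal = 0.4,
                            lesion_boundary_roughness = 0.15) {
  stopifnot(n_patients >= 1)
  if (is.null(grader_noise))
    grader_noise <- DEFAULT_GRADER_NOISE * image_size / 256
  vidx <- visit_index(visits)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  sc <- 8.85 / image_size
  half <- image_size * sc / 2
  max_step <- max(vidx)
  rows <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    pseed <- (abs(seed) %% 20000L) * 100000L + i
    set.seed(pseed)
    multifocal <- stats::runif(1) < p_multifocal
    nf <- if (multifocal) sample(2:3, 1) else 1L
    a_total <- stats::runif(1, baseline_area_range[1], baseline_area_range[2])
    if (nf == 1L) {
      areas <- a_total
    } else {
      # satellite foci are small in absolute terms; the dominant focus
      # carries the rest (and must satisfy the multifocal largest-focus
      # minimum)
      sec <- stats::runif(nf - 1L, 0.15, 0.8)
      max_sec <- a_total - multifocal_min_largest * 1.05
      if (sum(sec) > max_sec) sec <- sec * max_sec / sum(sec)
      areas <- c(a_total - sum(sec), sec)
    }
    radii <- sqrt(areas / pi)
    fovea_r <- 0.35
    # a focus large enough to contain the whole foveal disc is placed
    # centrally (fovea-sparing lesion surrounding the fovea); its radius is
    # inflated to compensate the carved-out foveal area so the measured
    # baseline total stays on target
    central <- radii[1] * (1 - 3 * lesion_boundary_roughness) >
      fovea_r + 0.3
    if (central) {
      areas[1] <- areas[1] + pi * fovea_r^2
      radii <- sqrt(areas / pi)
      a_total <- sum(areas)
    }
    grown <- sqrt((a_total + growth_rate_mm2_per_6mo * max_step) / a_total)
    centers <- place_foci(radii * grown, half, fovea_clear = 0.45,
                          central_first = central,
                          central_max = radii[1] *
                            (1 - 3 * lesion_boundary_roughness) -
                            fovea_r - 0.1)
    spec <- phantom_spec(
      image_size = image_size, n_foci = nf, focus_centers = centers,
      focus_radii = radii,
      lesion_boundary_roughness = lesion_boundary_roughness,
      growth_rate_mm2_per_6mo = growth_rate_mm2_per_6mo, seed = pseed)
    for (v in seq_along(visits)) {
      ph <- generate_phantom(spec, vidx[v])
      g1 <- simulate_grader(ph$truth, grader_noise, seed = pseed + 31L * v)
      g2 <- simulate_grader(ph$truth, grader_noise,
                            seed = pseed + 31L * v + 7L)
      base <- sprintf("%s_%s", pid, visits[v])
      paths <- c(faf = paste0(base, "_faf.png"),
                 nir = paste0(base, "_nir.png"),
                 truth = paste0(base, "_truth.png"),
                 g1 = paste0(base, "_g1.png"),
                 g2 = paste0(base, "_g2.png"))
      write_image8(ph$faf, file.path(out_dir, paths["faf"]))
      write_image8(ph$nir, file.path(out_dir, paths["nir"]))
      write_mask(ph$truth, file.path(out_dir, paths["truth"]))
      write_mask(g1, file.path(out_dir, paths["g1"]))
      write_mask(g2, file.path(out_dir, paths["g2"]))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, visit = visits[v],
        faf_path = unname(paths["faf"]), nir_path = unname(paths["nir"]),
        truth_mask_path = unname(paths["truth"]),
        grader1_mask_path = unname(paths["g1"]),
        grader2_mask_path = unname(paths["g2"]),
        scale_mm_per_px = sc)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "dir") <- out_dir
  manifest
}

# rejection-sample non-overlapping focus centers inside the raster border;
# radii already include the growth margin.  Small foci stay clear of the
# fovea; with central_first the first (largest) focus is placed near the
# image center so the foveal disc lies fully inside it at baseline.
place_foci <- function(radii, half, fovea_clear, central_first = FALSE,
                       central_max = 0) {
  n <- length(radii)
  centers <- vector("list", n)
  for (k in seq_len(n)) {
    best <- NULL
    for (try in 1:500) {
      ang <- stats::runif(1, 0, 2 * pi)
      if (k == 1 && central_first) {
        hi0 <- min(max(central_max, 0), half - radii[k] * 1.35 - 0.15)
        dst <- stats::runif(1, 0, max(hi0, 0))
      } else {
        lo <- fovea_clear + radii[k] * 1.45
        hi <- max(half - radii[k] * 1.35 - 0.15, lo + 0.05)
        dst <- stats::runif(1, lo, hi)
      }
      cand <- dst * c(cos(ang), sin(ang))
      # foci must stay disjoint even at full growth: separation exceeds
      # the sum of both (grown) radii
      ok <- all(vapply(seq_len(k - 1), function(kk)
        sqrt(sum((cand - centers[[kk]])^2)) >
          (radii[k] + radii[kk] + 0.2), logical(1)))
      if (ok) { best <- cand; break }
    }
    if (is.null(best)) best <- cand
    centers[[k]] <- best
  }
  centers
}

#' Patient-level train/validation split
#'
#' Splits a cohort manifest so that no patient appears in more than one
#' part and all visits of a patient travel together.
#'
#' @param manifest manifest `data.frame` (from [generate_cohort()] or read
#'   from CSV).
#' @param fractions named numeric vector summing to 1, e.g.
#'   `c(train = 0.8, val = 0.2)`.
#' @param seed integer seed for the patient shuffle.
#' @return Named list of manifests, one per fraction, each retaining the
#'   `dir` attribute of the input.
#' @export
patient_split <- function(manifest, fractions = c(train = 0.8, val = 0.2),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  pats <- unique(manifest$patient_id)
  np <- length(pats)
  counts <- floor(fractions * np)
  rem <- np - sum(counts)
  if (rem > 0) {
    extra <- order(fractions * np - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  if (any(counts == 0 & fractions > 0))
    stop("too few patients (", np, ") to honor the requested fractions")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shuffled <- sample(pats)
  out <- list()
  start <- 1L
  for (k in seq_along(counts)) {
    take <- shuffled[seq.int(start, length.out = counts[k])]
    part <- manifest[manifest$patient_id %in% take, , drop = FALSE]
    rownames(part) <- NULL
    attr(part, "dir") <- attr(manifest, "dir")
    out[[names(fractions)[k]]] <- part
    start <- start + counts[k]
  }
  out
}
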