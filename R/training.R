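#' Training configuration
#'
#' The default recipe is the one used for the full-scale networks: Adam,
#' batch size 4, initial learning rate 1e-3 multiplied by 0.1 every 30
#' epochs, 100 epochs, no early stopping.  Desk-scale experiments shrink
#' `epochs` but keep the optimizer and schedule.
#'
#' @param optimizer only `"adam"` is available.
#' @param lr0 initial learning rate (> 0).
#' @param lr_factor multiplicative decay factor in `(0, 1]`.
#' @param lr_step_epochs epochs between decays.
#' @param batch_size images per optimization step (>= 1).
#' @param epochs number of passes over the training set.
#' @param early_stopping if `TRUE`, stop when validation Dice has not
#'   improved for `patience` epochs.  Off by default (final-epoch weights
#'   are the trained model).
#' @param patience early-stopping patience in epochs.
#' @param keep_best if `TRUE` the returned model carries the weights of the
#'   best-validation-Dice epoch instead of the final epoch.  Off by default.
#' @param seed integer seed controlling batch shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", lr0 = 1e-3, lr_factor = 0.1,
                         lr_step_epochs = 30L, batch_size = 4L,
                         epochs = 100L, early_stopping = FALSE,
                         patience = 10L, keep_best = FALSE, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (lr0 <= 0) stop("lr0 must be > 0")
  if (lr_factor <= 0 || lr_factor > 1) stop("lr_factor must be in (0, 1]")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(optimizer = optimizer, lr0 = lr0, lr_factor = lr_factor,
                 lr_step_epochs = as.integer(lr_step_epochs),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stopping = isTRUE(early_stopping),
                 patience = as.integer(patience),
                 keep_best = isTRUE(keep_best), seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step schedule `lr0 * lr_factor^floor(epoch / lr_step_epochs)` with
#' 0-based epochs: with the defaults, epochs 0-29 run at 1e-3, 30-59 at
#' 1e-4, 60+ at 1e-5.
#'
#' @param config a [train_config()].
#' @param epoch integer epoch index, 0-based, >= 0.
#' @return Learning rate (scalar).
#' @export
lr_at_epoch <- function(config, epoch) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  config$lr0 * config$lr_factor^floor(epoch / config$lr_step_epochs)
}

adam_init <- function(params) {
  z <- lapply(params, function(p) p * 0)
  list(m = z, v = z, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

record_patients <- function(records)
  vapply(records, function(r) as.character(r$patient_id), character(1))

# Resize a record's rasters to the network grid (images bilinear, masks
# nearest-neighbour) and attach the reweighted training target.
prepare_record <- function(r, n, interior_floor, edge_band_px,
                           need_weight = TRUE) {
  faf <- resize_bilinear(r$faf, n, n)
  nir <- resize_bilinear(r$nir, n, n)
  truth_px <- resize_nearest(r$truth$pixels, n, n)
  truth <- lesion_mask(truth_px, r$truth$scale_mm_per_px *
                         nrow(r$truth$pixels) / n)
  out <- list(faf = faf, nir = nir, truth = truth)
  if (need_weight)
    out$wmask <- reweight_mask(truth, interior_floor, edge_band_px)
  out
}

#' Train a segmentation network
#'
#' Minimizes the Dice loss (1 minus the weighted soft Dice against
#' edge-reweighted versions of the ground-truth masks) with Adam.
#' Validation is always scored against the *original* binary masks: per
#' epoch the probability maps are binarized at 0.5 (strict) and the mean
#' Dice coefficient over the validation set is logged.  Training and
#' validation sets must be disjoint at the patient level; an overlap is a
#' hard error, not a warning.
#'
#' Runs are reproducible: the same model seed, data and `config$seed` give
#' identical weights and history to machine precision.
#'
#' @param model an untrained (or previously trained) `segnet` from
#'   [build_model()].
#' @param train_records,val_records lists of image-pair records: each a list
#'   with `patient_id`, `visit`, `faf`, `nir` (matrices in `[0,1]`) and
#'   `truth` (a [lesion_mask()]), e.g. from [load_manifest()] or
#'   [generate_cohort()].
#' @param config a [train_config()].
#' @param interior_floor,edge_band_px forwarded to [reweight_mask()] for the
#'   training targets.
#' @param verbose print one line per epoch.
#' @return The model with updated weights, `trained = TRUE` and a `history`
#'   data frame (`epoch` 0-based, `lr`, `train_loss`, `val_dice`).
#' @export
train_segnet <- function(model, train_records, val_records,
                         config = train_config(), interior_floor = 0.5,
                         edge_band_px = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "segnet"), inherits(config, "train_config"))
  tr_pat <- unique(record_patients(train_records))
  va_pat <- unique(record_patients(val_records))
  overlap <- intersect(tr_pat, va_pat)
  if (length(overlap) > 0)
    stop("train/validation sets overlap at the patient level: ",
         paste(overlap, collapse = ", "))
  n <- model$config$input_size
  tr <- lapply(train_records, prepare_record, n = n,
               interior_floor = interior_floor, edge_band_px = edge_band_px)
  va <- lapply(val_records, prepare_record, n = n,
               interior_floor = interior_floor, edge_band_px = edge_band_px,
               need_weight = FALSE)
  params <- model$params
  state <- adam_init(params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  hist <- vector("list", config$epochs)
  best <- list(dice = -Inf, params = NULL, epoch = NA_integer_)
  bad_epochs <- 0L
  n_logged <- 0L
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(config, epoch)
    ord <- sample.int(length(tr))
    losses <- numeric(0)
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      gsum <- NULL
      lsum <- 0
      for (k in b) {
        rec <- tr[[k]]
        mdl <- model; mdl$params <- params
        fwd <- segnet_forward(mdl, rec$faf, rec$nir, cache = TRUE)
        lsum <- lsum + dice_loss(fwd$prob, rec$wmask)
        dprob <- dice_loss_grad(fwd$prob, rec$wmask)
        g <- segnet_backward(mdl, fwd, dprob)
        gsum <- if (is.null(gsum)) g else
          Map(function(a, b2) a + b2, gsum, g[names(gsum)])
      }
      gavg <- lapply(gsum, function(x) x / length(b))
      st <- adam_step(params, gavg, state, lr)
      params <- st$params; state <- st$state
      losses <- c(losses, lsum / length(b))
    }
    mdl <- model; mdl$params <- params
    vd <- vapply(va, function(rec) {
      prob <- segnet_forward(mdl, rec$faf, rec$nir)$prob
      dice_coefficient(binarize(prob, 0.5,
                                rec$truth$scale_mm_per_px)$pixels,
                       rec$truth$pixels)
    }, numeric(1))
    val_dice <- if (length(vd)) mean(vd) else NA_real_
    n_logged <- n_logged + 1L
    hist[[n_logged]] <- data.frame(epoch = epoch, lr = lr,
                                   train_loss = mean(losses),
                                   val_dice = val_dice)
    if (verbose)
      message(sprintf("epoch %3d  lr %.1e  loss %.4f  val Dice %.4f",
                      epoch, lr, mean(losses), val_dice))
    if (!is.na(val_dice) && val_dice > best$dice) {
      best <- list(dice = val_dice, epoch = epoch,
                   params = if (config$keep_best) params else NULL)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
    }
    if (config$early_stopping && bad_epochs >= config$patience) break
  }
  model$params <- if (config$keep_best && !is.null(best$params))
    best$params else params
  model$trained <- TRUE
  history <- if (n_logged > 0) do.call(rbind, hist[seq_len(n_logged)]) else
    data.frame(epoch = integer(), lr = numeric(), train_loss = numeric(),
               val_dice = numeric())
  # validation scoring uses the original binary masks, never the
  # reweighted training targets
  attr(history, "val_mask_type") <- "original"
  model$history <- history
  model$train_config <- config
  model$best_val <- list(dice = best$dice, epoch = best$epoch)
  model
}

#' Predict a GA probability map for an FAF/NIR pair
#'
#' Resizes the pair to the network input grid (bilinear, no normalization),
#' runs the forward pass and resizes the probability map back to the
#' original raster grid.  A record without an NIR image is rejected: pairs
#' lacking the NIR modality are excluded from this pipeline.
#'
#' @param object a trained `segnet`.
#' @param faf FAF matrix in `[0,1]`, or a record list with `faf` and `nir`
#'   elements.
#' @param nir NIR matrix (omit when `faf` is a record).
#' @param ... unused.
#' @return Probability matrix on the original input grid.
#' @export
predict.segnet <- function(object, faf, nir = NULL, ...) {
  if (is.list(faf) && !is.matrix(faf)) {
    rec <- faf; faf <- rec$faf; nir <- rec$nir
  }
  if (is.null(nir))
    stop("record has no corresponding NIR image; pair excluded")
  h <- nrow(faf); w <- ncol(faf)
  n <- object$config$input_size
  prob <- segnet_forward(object, resize_bilinear(faf, n, n),
                         resize_bilinear(nir, n, n))$prob
  pm <- resize_bilinear(prob, h, w)
  pmin(pmax(pm, 0), 1)
}

#' Predict probability maps for a list of records
#'
#' @param model a trained `segnet`.
#' @param records list of image-pair records.
#' @return List of probability matrices, in input order.
#' @export
predict_records <- function(model, records)
  lapply(records, function(r) predict(model, r))

#' @export
summary.segnet <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("  validation Dice, last 5 epochs:\n")
    h <- utils::tail(object$history, 5)
    print(h, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.segnet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "train Dice loss", main = "training loss", ...)
  graphics::plot(h$epoch, h$val_dice, type = "l", xlab = "epoch",
                 ylab = "validation Dice", main = "validation Dice", ...)
  invisible(x)
}
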