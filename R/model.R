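#' Segmentation network configuration
#'
#' Describes an encoder-decoder segmentation network.  `family = "unet"` is a
#' single-encoder UNet taking the FAF and NIR rasters channel-stacked as one
#' 2-channel input; `family = "ynet"` encodes FAF and NIR with two separate
#' single-channel encoders (identical in architecture to the UNet encoder
#' except for the input channels), concatenates the two bottleneck
#' embeddings, and decodes with skip residuals taken from the FAF encoder
#' only.
#'
#' `depth` counts the encoder resolution stages (the last one being the
#' bottleneck); each stage before the bottleneck emits a skip residual and
#' halves the spatial grid, so a network of depth `d` carries `d - 1` skip
#' connections.  Channel width doubles each stage starting from
#' `base_channels`.
#'
#' @param family `"unet"` or `"ynet"`.
#' @param input_size square input size in pixels; must be divisible by
#'   `2^depth`.  Default 768 (the full-scale working resolution); 128 with
#'   `depth = 3`, `base_channels = 8` is the desk-scale profile used in the
#'   examples and tests.
#' @param depth integer >= 2, number of encoder stages.
#' @param base_channels channels of the first stage, >= 4.
#' @param seed integer seed for weight initialization.
#' @return Object of class `model_config`.
#' @export
model_config <- function(family = c("unet", "ynet"), input_size = 768L,
                         depth = 4L, base_channels = 32L, seed = 1L) {
  family <- match.arg(family)
  depth <- as.integer(depth); input_size <- as.integer(input_size)
  base_channels <- as.integer(base_channels)
  if (depth < 2L) stop("depth must be >= 2")
  if (base_channels < 4L) stop("base_channels must be >= 4")
  if (input_size %% (2L^depth) != 0L)
    stop("input_size must be divisible by 2^depth")
  structure(list(family = family, input_size = input_size, depth = depth,
                 base_channels = base_channels, seed = as.integer(seed)),
            class = "model_config")
}

pf <- function(...) paste0(...)

init_conv3 <- function(cout, cin) {
  matrix(stats::rnorm(cout * 9L * cin, 0, sqrt(2 / (9 * cin))), cout, 9L * cin)
}
init_upconv <- function(cout, cin) {
  matrix(stats::rnorm(cout * 4L * cin, 0, sqrt(2 / cin)), cout * 4L, cin)
}

init_encoder <- function(params, prefix, in_ch, channels) {
  d <- length(channels)
  cin <- in_ch
  for (i in seq_len(d - 1L)) {
    ci <- channels[i]
    params[[pf(prefix, "enc", i, ".c1.w")]] <- init_conv3(ci, cin)
    params[[pf(prefix, "enc", i, ".c1.b")]] <- numeric(ci)
    params[[pf(prefix, "enc", i, ".c2.w")]] <- init_conv3(ci, ci)
    params[[pf(prefix, "enc", i, ".c2.b")]] <- numeric(ci)
    cin <- ci
  }
  cd <- channels[d]
  params[[pf(prefix, "bott.c1.w")]] <- init_conv3(cd, cin)
  params[[pf(prefix, "bott.c1.b")]] <- numeric(cd)
  params[[pf(prefix, "bott.c2.w")]] <- init_conv3(cd, cd)
  params[[pf(prefix, "bott.c2.b")]] <- numeric(cd)
  params
}

#' Build a segmentation network
#'
#' Instantiates the network described by a [model_config()] with randomly
#' initialized weights (He-scaled Gaussian, biases zero), drawn
#' deterministically from `config$seed`: the same configuration and seed
#' always produce bitwise-identical weights.
#'
#' @param config a [model_config()].
#' @return Object of class `segnet`: list with `config`, `params` (named
#'   flat list of weight matrices/vectors), `trained` flag and `history`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  d <- config$depth
  channels <- config$base_channels * 2L^(0:(d - 1L))
  params <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  if (config$family == "unet") {
    params <- init_encoder(params, "", 2L, channels)
    bott_ch <- channels[d]
  } else {
    params <- init_encoder(params, "e1.", 1L, channels)
    params <- init_encoder(params, "e2.", 1L, channels)
    bott_ch <- 2L * channels[d]  # concatenated Z1 || Z2
  }
  cin <- bott_ch
  for (i in rev(seq_len(d - 1L))) {
    ci <- channels[i]
    params[[pf("up", i, ".w")]] <- init_upconv(ci, cin)
    params[[pf("up", i, ".b")]] <- numeric(ci)
    params[[pf("dec", i, ".c1.w")]] <- init_conv3(ci, 2L * ci)
    params[[pf("dec", i, ".c1.b")]] <- numeric(ci)
    params[[pf("dec", i, ".c2.w")]] <- init_conv3(ci, ci)
    params[[pf("dec", i, ".c2.b")]] <- numeric(ci)
    cin <- ci
  }
  params[["out.w"]] <- stats::rnorm(channels[1], 0, sqrt(1 / channels[1]))
  params[["out.b"]] <- 0
  structure(list(config = config, params = params, trained = FALSE,
                 history = NULL), class = "segnet")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

block_forward <- function(x, w1, b1, w2, b2) {
  a1 <- conv3_forward(x, w1, b1)
  h1 <- pmax(a1, 0)
  a2 <- conv3_forward(h1, w2, b2)
  h2 <- pmax(a2, 0)
  list(out = h2, x = x, h1 = h1, h2 = h2)
}

block_backward <- function(cache, w1, w2, dout) {
  da2 <- dout * (cache$h2 > 0)
  b2 <- conv3_backward(cache$h1, w2, da2)
  da1 <- b2$dx * (cache$h1 > 0)
  b1 <- conv3_backward(cache$x, w1, da1)
  list(dx = b1$dx, dw1 = b1$dw, db1 = b1$db, dw2 = b2$dw, db2 = b2$db)
}

encoder_forward <- function(p, prefix, x, d) {
  skips <- vector("list", d - 1L)
  blocks <- vector("list", d)
  pools <- vector("list", d - 1L)
  for (i in seq_len(d - 1L)) {
    blk <- block_forward(x, p[[pf(prefix, "enc", i, ".c1.w")]],
                         p[[pf(prefix, "enc", i, ".c1.b")]],
                         p[[pf(prefix, "enc", i, ".c2.w")]],
                         p[[pf(prefix, "enc", i, ".c2.b")]])
    skips[[i]] <- blk$out
    pl <- maxpool2_forward(blk$out)
    blocks[[i]] <- blk
    pools[[i]] <- pl
    x <- pl$out
  }
  blk <- block_forward(x, p[[pf(prefix, "bott.c1.w")]],
                       p[[pf(prefix, "bott.c1.b")]],
                       p[[pf(prefix, "bott.c2.w")]],
                       p[[pf(prefix, "bott.c2.b")]])
  blocks[[d]] <- blk
  list(z = blk$out, skips = skips, blocks = blocks, pools = pools)
}

encoder_backward <- function(p, prefix, enc, dz, skip_grads, grads) {
  d <- length(enc$blocks)
  bb <- block_backward(enc$blocks[[d]], p[[pf(prefix, "bott.c1.w")]],
                       p[[pf(prefix, "bott.c2.w")]], dz)
  grads[[pf(prefix, "bott.c1.w")]] <- bb$dw1
  grads[[pf(prefix, "bott.c1.b")]] <- bb$db1
  grads[[pf(prefix, "bott.c2.w")]] <- bb$dw2
  grads[[pf(prefix, "bott.c2.b")]] <- bb$db2
  dx <- bb$dx
  for (i in rev(seq_len(d - 1L))) {
    sk <- enc$skips[[i]]
    dh <- maxpool2_backward(dx, enc$pools[[i]]$idx, dim(sk)[1], dim(sk)[2])
    if (!is.null(skip_grads) && !is.null(skip_grads[[i]]))
      dh <- dh + skip_grads[[i]]
    bb <- block_backward(enc$blocks[[i]], p[[pf(prefix, "enc", i, ".c1.w")]],
                         p[[pf(prefix, "enc", i, ".c2.w")]], dh)
    grads[[pf(prefix, "enc", i, ".c1.w")]] <- bb$dw1
    grads[[pf(prefix, "enc", i, ".c1.b")]] <- bb$db1
    grads[[pf(prefix, "enc", i, ".c2.w")]] <- bb$dw2
    grads[[pf(prefix, "enc", i, ".c2.b")]] <- bb$db2
    dx <- bb$dx
  }
  grads
}

cat_channels <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

decoder_forward <- function(p, z, skips, d) {
  ups <- vector("list", d - 1L)
  blocks <- vector("list", d - 1L)
  zs <- vector("list", d - 1L)  # input to each upconv
  for (i in rev(seq_len(d - 1L))) {
    zs[[i]] <- z
    u <- upconv2_forward(z, p[[pf("up", i, ".w")]], p[[pf("up", i, ".b")]])
    xcat <- cat_channels(u, skips[[i]])
    blk <- block_forward(xcat, p[[pf("dec", i, ".c1.w")]],
                         p[[pf("dec", i, ".c1.b")]],
                         p[[pf("dec", i, ".c2.w")]],
                         p[[pf("dec", i, ".c2.b")]])
    ups[[i]] <- u
    blocks[[i]] <- blk
    z <- blk$out
  }
  H <- dim(z)[1]; W <- dim(z)[2]; C <- dim(z)[3]
  logits <- matrix(matrix(z, H * W, C) %*% p[["out.w"]] + p[["out.b"]], H, W)
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, logits = logits, zfinal = z, ups = ups, blocks = blocks,
       zs = zs)
}

decoder_backward <- function(p, dec, d, dprob, grads) {
  prob <- dec$prob
  dlogits <- dprob * prob * (1 - prob)
  H <- dim(dec$zfinal)[1]; W <- dim(dec$zfinal)[2]; C <- dim(dec$zfinal)[3]
  grads[["out.w"]] <- as.numeric(
    crossprod(matrix(dec$zfinal, H * W, C), as.vector(dlogits)))
  grads[["out.b"]] <- sum(dlogits)
  dz <- array(as.vector(dlogits) %o% p[["out.w"]], dim = c(H, W, C))
  skip_grads <- vector("list", d - 1L)
  for (i in seq_len(d - 1L)) {
    blk <- dec$blocks[[i]]
    bb <- block_backward(blk, p[[pf("dec", i, ".c1.w")]],
                         p[[pf("dec", i, ".c2.w")]], dz)
    grads[[pf("dec", i, ".c1.w")]] <- bb$dw1
    grads[[pf("dec", i, ".c1.b")]] <- bb$db1
    grads[[pf("dec", i, ".c2.w")]] <- bb$dw2
    grads[[pf("dec", i, ".c2.b")]] <- bb$db2
    cu <- dim(dec$ups[[i]])[3]
    dcat <- bb$dx
    du <- dcat[, , seq_len(cu), drop = FALSE]
    skip_grads[[i]] <- dcat[, , cu + seq_len(dim(dcat)[3] - cu), drop = FALSE]
    ub <- upconv2_backward(dec$zs[[i]], p[[pf("up", i, ".w")]], du)
    grads[[pf("up", i, ".w")]] <- ub$du
    grads[[pf("up", i, ".b")]] <- ub$db
    dz <- ub$dx
  }
  list(grads = grads, dz = dz, skip_grads = skip_grads)
}

as_channel_array <- function(m) array(m, dim = c(dim(m)[1], dim(m)[2], 1L))

# Full forward pass; with cache = TRUE all intermediates needed by
# segnet_backward are retained.
segnet_forward <- function(model, faf, nir, cache = FALSE) {
  cfg <- model$config
  n <- cfg$input_size
  if (!identical(dim(faf), c(n, n)) || !identical(dim(nir), c(n, n)))
    stop(sprintf("inputs must be %d x %d matrices", n, n))
  p <- model$params
  d <- cfg$depth
  if (cfg$family == "unet") {
    x <- cat_channels(as_channel_array(faf), as_channel_array(nir))
    enc <- encoder_forward(p, "", x, d)
    dec <- decoder_forward(p, enc$z, enc$skips, d)
    out <- list(prob = dec$prob, skips = enc$skips)
    if (cache) out$cache <- list(enc = enc, dec = dec)
  } else {
    e1 <- encoder_forward(p, "e1.", as_channel_array(faf), d)
    e2 <- encoder_forward(p, "e2.", as_channel_array(nir), d)
    z <- cat_channels(e1$z, e2$z)
    dec <- decoder_forward(p, z, e1$skips, d)
    out <- list(prob = dec$prob, skips = e1$skips)
    if (cache) out$cache <- list(enc1 = e1, enc2 = e2, dec = dec)
  }
  out
}

# Gradient of a scalar loss wrt all parameters, given dloss/dprob.
segnet_backward <- function(model, fwd, dprob) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  grads <- list()
  fwd$cache$dec$prob <- fwd$prob
  db <- decoder_backward(p, fwd$cache$dec, d, dprob, grads)
  grads <- db$grads
  if (cfg$family == "unet") {
    grads <- encoder_backward(p, "", fwd$cache$enc, db$dz, db$skip_grads,
                              grads)
  } else {
    cd <- dim(fwd$cache$enc1$z)[3]
    dz1 <- db$dz[, , seq_len(cd), drop = FALSE]
    dz2 <- db$dz[, , cd + seq_len(cd), drop = FALSE]
    grads <- encoder_backward(p, "e1.", fwd$cache$enc1, dz1, db$skip_grads,
                              grads)
    grads <- encoder_backward(p, "e2.", fwd$cache$enc2, dz2, NULL, grads)
  }
  grads
}

#' Forward pass of a UNet on an FAF/NIR pair
#'
#' Stacks the two rasters as a 2-channel input, encodes with the single
#' encoder and decodes with its skip residuals:
#' `Z,S = E(concat(FAF, NIR)); P = D(Z, S)`.
#'
#' @param model a `segnet` built with `family = "unet"`.
#' @param faf,nir square numeric matrices of size `config$input_size`,
#'   8-bit intensities rescaled to `[0,1]` but otherwise not normalized.
#' @return Probability matrix in `[0,1]`, same grid as the inputs.
#' @export
forward_unet <- function(model, faf, nir) {
  stopifnot(inherits(model, "segnet"), model$config$family == "unet")
  segnet_forward(model, faf, nir)$prob
}

#' Forward pass of a YNet on an FAF/NIR pair
#'
#' Encodes the two modalities separately, concatenates the bottleneck
#' embeddings and decodes using skip residuals from the FAF encoder only:
#' `Z1,S1 = E1(FAF); Z2,S2 = E2(NIR); P = D(concat(Z1, Z2), S1)`.
#' The NIR branch influences the output exclusively through its bottleneck
#' embedding `Z2`; the skip tensors delivered to the decoder are invariant to
#' any NIR perturbation.
#'
#' @inheritParams forward_unet
#' @param model a `segnet` built with `family = "ynet"`.
#' @return Probability matrix in `[0,1]`, same grid as the inputs.
#' @export
forward_ynet <- function(model, faf, nir) {
  stopifnot(inherits(model, "segnet"), model$config$family == "ynet")
  segnet_forward(model, faf, nir)$prob
}

#' Skip residuals delivered to the decoder
#'
#' Returns the list of skip feature tensors the decoder consumes for a given
#' input pair (for the YNet these come from the FAF encoder only).  Mainly
#' useful for architectural contract checks.
#'
#' @inheritParams forward_unet
#' @return List of 3-d arrays, finest resolution first.
#' @export
decoder_skips <- function(model, faf, nir) {
  segnet_forward(model, faf, nir)$skips
}

#' @export
print.segnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<segnet> %s, input %dx%d, depth %d, base channels %d, %s\n",
              toupper(cfg$family), cfg$input_size, cfg$input_size, cfg$depth,
              cfg$base_channels,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  cat(sprintf("  parameters: %s\n", format(n_parameters(x), big.mark = ",")))
  if (!is.null(x$history)) {
    h <- x$history
    cat(sprintf("  epochs: %d, final train loss %.4f, final val Dice %.4f\n",
                nrow(h), h$train_loss[nrow(h)], h$val_dice[nrow(h)]))
  }
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `segnet`.
#' @return Integer total parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
coef.segnet <- function(object, ...) object$params
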