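# Brute-force reference implementations used as independent oracles, plus
# small fixture builders.  These deliberately use naive loops / different
# algorithms from the package internals.

oracle_dice <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    inter <- inter + (a[i, j] == 1 && b[i, j] == 1)
    sa <- sa + a[i, j]; sb <- sb + b[i, j]
  }
  if (sa + sb == 0) return(1)
  2 * inter / (sa + sb)
}

oracle_soft_dice <- function(p, g) 2 * sum(p * g) / (sum(p) + sum(g))

oracle_weighted_dice <- function(p, w, g) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    v <- if (g[i, j] == 1) w[i, j] else 1
    num <- num + v * p[i, j] * g[i, j]
    den <- den + v * p[i, j] + v * g[i, j]
  }
  2 * num / den
}

# Chebyshev distance of every foreground pixel to the nearest background
# pixel, by exhaustive search
oracle_chebyshev <- function(px) {
  bg <- which(px == 0, arr.ind = TRUE)
  d <- matrix(Inf, nrow(px), ncol(px))
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (px[i, j] == 1 && nrow(bg) > 0)
      d[i, j] <- min(pmax(abs(bg[, 1] - i), abs(bg[, 2] - j)))
    if (px[i, j] == 0) d[i, j] <- 0
  }
  d
}

# connected components via igraph (independent algorithm)
oracle_component_areas <- function(px, connectivity = 8) {
  idx <- which(px == 1)
  if (length(idx) == 0) return(numeric(0))
  H <- nrow(px)
  coords <- arr.ind_from_linear(idx, H)
  key <- function(i, j) paste(i, j)
  nodes <- key(coords[, 1], coords[, 2])
  offs <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1),
          c(1, 0), c(1, 1)) else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  edges <- character(0)
  present <- new.env()
  for (k in seq_along(nodes)) assign(nodes[k], TRUE, envir = present)
  for (k in seq_len(nrow(coords))) {
    for (o in seq_len(nrow(offs))) {
      ni <- coords[k, 1] + offs[o, 1]; nj <- coords[k, 2] + offs[o, 2]
      nk <- key(ni, nj)
      if (exists(nk, envir = present, inherits = FALSE))
        edges <- c(edges, key(coords[k, 1], coords[k, 2]), nk)
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges)) g <- igraph::add_edges(g, match(edges, nodes))
  comp <- igraph::components(g)
  as.numeric(sort(tabulate(comp$membership), decreasing = TRUE))
}

arr.ind_from_linear <- function(idx, H) {
  cbind((idx - 1) %% H + 1, (idx - 1) %/% H + 1)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Passing-Bablok slope: explicit double loop over all pairs, the -1
# exclusion and the offset-by-K shifted median
oracle_pb_slope <- function(x, y) {
  s <- numeric(0)
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    s <- c(s, if (dx == 0) sign(dy) * Inf else dy / dx)
  }
  s <- sort(s[s != -1])
  nv <- length(s)
  k <- sum(s < -1)
  if (nv %% 2 == 1) s[(nv + 1) / 2 + k] else
    (s[nv / 2 + k] + s[nv / 2 + 1 + k]) / 2
}

# two-pass mean/SD Bland-Altman limits over grader differences
oracle_ba_limits <- function(diffs) {
  m <- 0
  for (d in diffs) m <- m + d
  m <- m / length(diffs)
  v <- 0
  for (d in diffs) v <- v + (d - m)^2
  sdd <- sqrt(v / (length(diffs) - 1))
  c(mean = m, lower = m - 1.96 * sdd, upper = m + 1.96 * sdd)
}

# random blobby binary mask
random_mask <- function(n = 24, p_seed = 0.04, grow = 2) {
  m <- matrix(rbinom(n * n, 1, p_seed), n, n)
  for (g in seq_len(grow)) {
    m2 <- m
    m2[-1, ] <- pmax(m2[-1, ], m[-n, ])
    m2[, -1] <- pmax(m2[, -1], m[, -n])
    m <- m2
  }
  m
}

# minimal in-memory image-pair record
make_record <- function(patient_id, visit = "SCR", n = 32,
                        scale = 8.85 / n, seed = 1) {
  set.seed(seed)
  px <- matrix(0L, n, n)
  r0 <- sample(5:(n - 10), 1)
  c0 <- sample(5:(n - 10), 1)
  px[r0:(r0 + 5), c0:(c0 + 5)] <- 1L
  truth <- lesion_mask(px, scale)
  faf <- matrix(0.7, n, n); faf[px == 1] <- 0.15
  nir <- matrix(0.5, n, n); nir[px == 1] <- 0.4
  list(patient_id = patient_id, visit = visit,
       faf = faf + matrix(rnorm(n * n, 0, 0.02), n, n),
       nir = nir + matrix(rnorm(n * n, 0, 0.02), n, n),
       truth = truth, graders = list(), scale_mm_per_px = scale)
}
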