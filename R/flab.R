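#' Fuzzy locally adaptive Bayesian (FLAB-style) delineation
#'
#' Two hard intensity classes (background and tumor, Gaussian) plus
#' \code{n_fuzzy_levels} fuzzy transition levels whose means and variances
#' interpolate between the classes at mixing fractions
#' \code{eps = l/(n_fuzzy_levels+1)}. Voxels are iteratively reassigned to
#' the level maximizing a local posterior in which each level's prior at a
#' voxel is its frequency among the voxel's 26-neighbors' current labels
#' (uniform at the first iteration); class means and variances are then
#' re-estimated with fuzzy voxels contributing weight \code{1-eps} to the
#' background class and \code{eps} to the tumor class. The procedure is
#' deterministic: initialization is a 2-means split started from the
#' intensity extremes, and the tumor class is the higher-mean class by
#' convention. The binary mask keeps hard tumor voxels plus fuzzy voxels
#' with \code{eps >= 0.5}, reduced to the hottest connected component.
#'
#' @param vol a \code{\link{suv_volume}}.
#' @param roi a \code{\link{roi_box}} covering at least 20 voxels.
#' @param params list with \code{n_fuzzy_levels} (default 3),
#'   \code{max_iter} (default 100), \code{tol} (relative label-change
#'   fraction, default 1e-3).
#' @return A \code{\link{binary_mask}}.
#' @export
segment_flab <- function(vol, roi,
                         params = list(n_fuzzy_levels = 3L, max_iter = 100L, tol = 1e-3)) {
  fit <- flab_fit(vol, roi, params)
  mask <- uncrop_mask(binary_mask(fit$grid, fit$tumor), vol$grid, fit$offset)
  connected_component_filter(mask, vol, roi)
}

#' Fit the FLAB intensity classes over an ROI
#'
#' The classification engine behind \code{\link{segment_flab}}, returning
#' the estimated class parameters and the hard/fuzzy label field so that
#' class recovery can be checked against fields with known generating
#' classes.
#'
#' @inheritParams segment_flab
#' @return List with \code{mu0}, \code{mu1}, \code{sd0}, \code{sd1},
#'   \code{tumor} (logical array over the ROI crop: voxels with tumor
#'   membership \code{eps >= 0.5}), \code{labels} (integer level field),
#'   \code{eps} (level mixing fractions), \code{iterations}, \code{grid}
#'   (crop grid) and \code{offset} (0-based crop offset in the parent grid).
#' @export
flab_fit <- function(vol, roi,
                     params = list(n_fuzzy_levels = 3L, max_iter = 100L, tol = 1e-3)) {
  stopifnot(inherits(vol, "suv_volume"))
  L <- as.integer(params$n_fuzzy_levels %||% 3L)
  max_iter <- as.integer(params$max_iter %||% 100L)
  tol <- params$tol %||% 1e-3
  stopifnot(L >= 1L, max_iter >= 1L)
  cr <- crop_to_roi(vol, roi)
  x <- cr$vol$values
  n <- length(x)
  if (n < 20L) stop("roi must contain at least 20 voxels")
  rng <- range(x)
  if (diff(rng) <= 0) stop("constant intensities in roi: classes unidentifiable")
  sig_floor <- 1e-6 * diff(rng)   # keeps likelihoods proper on noiseless input

  km <- kmeans2_deterministic(as.vector(x))
  mu0 <- km$mu[1]; mu1 <- km$mu[2]
  s0 <- max(km$sd[1], sig_floor); s1 <- max(km$sd[2], sig_floor)

  eps <- c(0, 1, seq_len(L) / (L + 1))   # level order: bg, tumor, fuzzy 1..L
  K <- length(eps)
  labels <- array(1L, dim = dim(x))
  nneigh <- boxsum27(array(1, dim = dim(x))) - 1
  it_done <- 0L

  for (it in seq_len(max_iter)) {
    mus <- (1 - eps) * mu0 + eps * mu1
    vars <- pmax((1 - eps) * s0^2 + eps * s1^2, sig_floor^2)
    score <- matrix(0, n, K)
    for (m in seq_len(K)) {
      ll <- stats::dnorm(as.vector(x), mus[m], sqrt(vars[m]), log = TRUE)
      if (it == 1L) {
        score[, m] <- ll   # uniform prior at the first sweep
      } else {
        onehot <- array(0, dim = dim(x)); onehot[labels == m] <- 1
        cnt <- boxsum27(onehot) - onehot
        score[, m] <- ll + log(as.vector(cnt) / as.vector(nneigh))
      }
    }
    new_labels <- array(max.col(score, ties.method = "first"), dim = dim(x))
    changed <- mean(new_labels != labels)
    labels <- new_labels
    it_done <- it
    w1 <- eps[as.vector(labels)]
    w0 <- 1 - w1
    if (sum(w0) <= 0 || sum(w1) <= 0) break
    mu0 <- sum(w0 * x) / sum(w0)
    mu1 <- sum(w1 * x) / sum(w1)
    s0 <- max(sqrt(sum(w0 * (x - mu0)^2) / sum(w0)), sig_floor)
    s1 <- max(sqrt(sum(w1 * (x - mu1)^2) / sum(w1)), sig_floor)
    if (mu1 < mu0) {  # tumor is the higher-mean class by convention
      tmp <- mu0; mu0 <- mu1; mu1 <- tmp
      tmp <- s0; s0 <- s1; s1 <- tmp
      labels <- relabel_swap(labels, eps)
    }
    if (it > 1L && changed < tol) break
  }
  list(mu0 = mu0, mu1 = mu1, sd0 = s0, sd1 = s1,
       tumor = array(eps[as.vector(labels)] >= 0.5, dim = dim(x)),
       labels = labels, eps = eps, iterations = it_done,
       grid = cr$vol$grid, offset = cr$offset)
}

## deterministic 1-D 2-means (Lloyd) started from the data extremes;
## returns class means and sds sorted ascending by mean
kmeans2_deterministic <- function(x, max_iter = 50L) {
  c0 <- min(x); c1 <- max(x)
  for (i in seq_len(max_iter)) {
    a <- abs(x - c0) <= abs(x - c1)
    n0 <- sum(a); n1 <- sum(!a)
    if (n0 == 0L || n1 == 0L) break
    new0 <- mean(x[a]); new1 <- mean(x[!a])
    conv <- abs(new0 - c0) < 1e-12 && abs(new1 - c1) < 1e-12
    c0 <- new0; c1 <- new1
    if (conv) break
  }
  a <- abs(x - c0) <= abs(x - c1)
  mu <- c(mean(x[a]), mean(x[!a]))
  sd2 <- c(stats::sd(x[a]), stats::sd(x[!a]))
  sd2[is.na(sd2)] <- 0
  o <- order(mu)
  list(mu = mu[o], sd = sd2[o])
}

## swap class identities: bg<->tumor, fuzzy level eps -> 1-eps (nearest level)
relabel_swap <- function(labels, eps) {
  new_of <- vapply(seq_along(eps), function(m) {
    which.min(abs(eps - (1 - eps[m])))
  }, integer(1))
  array(new_of[as.vector(labels)], dim = dim(labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
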