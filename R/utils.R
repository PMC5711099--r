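## Internal numerics shared by the phantom generator and the delineation arms.

## run expr with a private RNG stream seeded by `seed`; the caller's
## .Random.seed is untouched.
with_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

gaussian_kernel_1d <- function(sigma_vox, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma_vox))
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

## 1-D convolution along `axis` of a 3-D array with an odd symmetric-length
## kernel; pad = "reflect" (edge-mirrored, mass-conserving for interior
## structures) or "zero". Implemented as a banded-matrix multiply.
conv_axis <- function(a, kernel, axis, pad = c("reflect", "zero")) {
  pad <- match.arg(pad)
  d <- dim(a)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    w <- kernel[off + r + 1L]
    j <- seq_len(n) + off
    if (pad == "reflect") {
      # reflect about the edge voxels: index m maps to 2-m below, 2n-m above
      j <- ifelse(j < 1L, 2L - j, j)
      j <- ifelse(j > n, 2L * n - j, j)
      j <- pmin(pmax(j, 1L), n)
      K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + w
    } else {
      ok <- j >= 1L & j <= n
      K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + kernel[off + r + 1L]
    }
  }
  if (axis == 1L) {
    out <- K %*% matrix(a, nrow = n)
    array(out, dim = d)
  } else if (axis == 2L) {
    ap <- aperm(a, c(2, 1, 3))
    out <- array(K %*% matrix(ap, nrow = n), dim = d[c(2, 1, 3)])
    aperm(out, c(2, 1, 3))
  } else {
    ap <- aperm(a, c(3, 1, 2))
    out <- array(K %*% matrix(ap, nrow = n), dim = d[c(3, 1, 2)])
    aperm(out, c(2, 3, 1))
  }
}

## separable isotropic Gaussian blur given FWHM in mm and per-axis spacing
gaussian_blur <- function(a, fwhm_mm, spacing, pad = "reflect") {
  if (fwhm_mm <= 0) return(a)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    sv <- sigma_mm / spacing[axis]
    if (sv < 1e-6) next
    a <- conv_axis(a, gaussian_kernel_1d(sv), axis, pad = pad)
  }
  a
}

## sum over the 3x3x3 neighborhood (zero padding) of a 3-D numeric array
boxsum27 <- function(a) {
  k <- c(1, 1, 1)
  conv_axis(conv_axis(conv_axis(a, k, 1L, pad = "zero"), k, 2L, pad = "zero"),
            k, 3L, pad = "zero")
}

## 26-connected flood fill from a seed linear index, restricted to `member`
## (logical 3-D array). Returns a logical array of the reached component.
flood26 <- function(member, seed_lin) {
  d <- dim(member)
  comp <- array(FALSE, dim = d)
  if (!member[seed_lin]) return(comp)
  comp[seed_lin] <- TRUE
  frontier <- seed_lin
  nxy <- d[1] * d[2]
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  while (length(frontier) > 0L) {
    k0 <- (frontier - 1L) %/% nxy
    rem <- (frontier - 1L) %% nxy
    j0 <- rem %/% d[1]
    i0 <- rem %% d[1]
    cand <- integer(0)
    for (m in seq_len(nrow(offs))) {
      i <- i0 + offs[m, 1]; j <- j0 + offs[m, 2]; k <- k0 + offs[m, 3]
      ok <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
      if (!any(ok)) next
      lin <- k[ok] * nxy + j[ok] * d[1] + i[ok] + 1L
      cand <- c(cand, lin[member[lin] & !comp[lin]])
    }
    cand <- unique(cand)
    comp[cand] <- TRUE
    frontier <- cand
  }
  comp
}
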