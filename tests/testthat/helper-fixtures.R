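# Shared fixture builders. Everything is generated in code; seeds are fixed
# per test site so the suite is deterministic.

# noiseless plateau sphere on a small PET grid; all arms must recover truth
plateau_sphere_case <- function(radius = 10, uptake = 8, background = 1,
                                dims = c(20, 20, 20), seed = 7) {
  g <- image_grid(dims, c(4, 4, 4))
  ctr <- (dims - 1) * 4 / 2   # geometric center of the voxel-center lattice
  les <- lesion_spec(ctr, rep(radius, 3), uptake)
  sp <- phantom_spec(list(les), pet_grid = g, background_suv = background,
                     psf_fwhm = 0, noise_sd_at_background = 0, seed = seed)
  generate_phantom(sp)
}

# blurred sphere with the scanner-like 7 mm PSF, optional noise
blurred_sphere_case <- function(radius = 15, uptake = 8, background = 1,
                                noise = 0, dims = c(32, 32, 32), seed = 3) {
  g <- image_grid(dims, c(4, 4, 4))
  ctr <- rep((dims[1] - 1) * 4 / 2, 3)
  les <- lesion_spec(ctr, rep(radius, 3), uptake)
  sp <- phantom_spec(list(les), pet_grid = g, background_suv = background,
                     psf_fwhm = 7, noise_sd_at_background = noise, seed = seed)
  generate_phantom(sp)
}

# random 26-connected blob mask with per-slice holes filled (tumors are
# simply connected in-plane, matching the contour module's outer-boundary
# representation)
random_blob_mask <- function(seed, dims = c(16, 16, 10), spacing = c(4, 4, 4)) {
  g <- image_grid(dims, spacing)
  set.seed(seed)
  field <- array(stats::rnorm(prod(dims)), dim = dims)
  sm <- mtvbench:::gaussian_blur(field, 3 * mean(spacing), spacing)
  ctr_idx <- array(0, dim = dims)
  cc <- (dims - 1) / 2
  for (a in 1:3) {
    d1 <- (slice.index(ctr_idx, a) - 1 - cc[a]) / (dims[a] / 2.2)
    ctr_idx <- ctr_idx + d1^2
  }
  # bias the field towards a central blob so one component dominates
  score <- sm / stats::sd(sm) - 1.6 * ctr_idx
  mem <- score > stats::quantile(score, 0.93)
  if (!any(mem)) mem[cc[1] + 1, cc[2] + 1, cc[3] + 1] <- TRUE
  # keep the largest-by-count component (26-connectivity)
  seed_lin <- which(mem)[which.max(tabulate_component_sizes(mem))]
  comp <- mtvbench:::flood26(mem, largest_component_seed(mem))
  # fill in-plane holes so every slice component is simply connected
  for (k in seq_len(dims[3])) {
    sl <- matrix(comp[, , k], dims[1], dims[2])
    if (!any(sl)) next
    comp[, , k] <- fill_holes_2d(sl)
  }
  binary_mask(g, comp)
}

largest_component_seed <- function(mem) {
  remaining <- mem
  best_seed <- NA_integer_; best_n <- -1L
  while (any(remaining)) {
    s <- which(remaining)[1L]
    comp <- mtvbench:::flood26(remaining, s)
    n <- sum(comp)
    if (n > best_n) { best_n <- n; best_seed <- s }
    remaining <- remaining & !comp
  }
  best_seed
}

tabulate_component_sizes <- function(mem) rep(1L, sum(mem))

# fill holes of a 2-D logical slice: outside = 4-connected background
# region touching the border
fill_holes_2d <- function(sl) {
  d <- dim(sl)
  outside <- matrix(FALSE, d[1], d[2])
  frontier <- which((row(sl) == 1 | row(sl) == d[1] |
                     col(sl) == 1 | col(sl) == d[2]) & !sl)
  outside[frontier] <- TRUE
  while (length(frontier) > 0L) {
    i <- (frontier - 1L) %% d[1] + 1L
    j <- (frontier - 1L) %/% d[1] + 1L
    nxt <- integer(0)
    for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ii <- i + o[1]; jj <- j + o[2]
      ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
      lin <- (jj[ok] - 1L) * d[1] + ii[ok]
      nxt <- c(nxt, lin[!sl[lin] & !outside[lin]])
    }
    nxt <- unique(nxt)
    outside[nxt] <- TRUE
    frontier <- nxt
  }
  !outside
}

# rasterized sphere mask at given radius (mm) on an isotropic grid
sphere_mask <- function(radius, dims = c(24, 24, 24), spacing = 4) {
  g <- image_grid(dims, rep(spacing, 3))
  ctr <- (dims - 1) * spacing / 2
  les <- lesion_spec(ctr, rep(radius, 3), 1)
  binary_mask(g, mtvbench:::ellipsoid_member(g, les))
}

# the blurred-peak phantom family for the resampling-dialect experiment:
# heterogeneous high-contrast lesions whose hottest uptake is a focal
# blurred peak rather than a plateau
blurred_peak_case <- function(case_seed) {
  set.seed(case_seed)
  r <- stats::runif(1, 10, 18)
  ctr <- stats::runif(3, -6, 6)
  uptake <- stats::runif(1, 12, 20)
  les <- lesion_spec(ctr, rep(r, 3), uptake,
                     heterogeneity_sd = 0.5 * uptake, texture_scale = 5)
  sp <- phantom_spec(list(les),
                     pet_grid = image_grid(c(24, 24, 20), c(4, 4, 4), c(-46, -46, -38)),
                     background_suv = 2, psf_fwhm = 7,
                     noise_sd_at_background = 0.15,
                     seed = sample.int(1000000L, 1))
  generate_phantom(sp)
}
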