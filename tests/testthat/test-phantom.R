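test_that("noiseless unblurred sphere phantom is two-valued with correct truth volume", {
  case <- plateau_sphere_case(radius = 10, uptake = 8, background = 1)
  vals <- sort(unique(as.vector(case$pet$values)))
  expect_equal(vals, c(1, 8))
  v_analytic <- 4 / 3 * pi * 10^3 / 1000
  # rasterized truth within one voxel layer of the analytic volume
  shell <- 4 * pi * 10^2 * 4 / 1000   # surface x one voxel
  expect_lt(abs(mask_volume_ml(case$truth) - v_analytic), shell)
})

test_that("rasterized truth volume approximates the analytic ellipsoid volume", {
  case <- plateau_sphere_case(radius = 15, dims = c(24, 24, 24))
  v_analytic <- 4 / 3 * pi * 15^3 / 1000
  expect_equal(v_analytic, 14.137, tolerance = 1e-4)
  expect_lt(abs(mask_volume_ml(case$truth) - v_analytic) / v_analytic, 0.07)
  # brute-force center-count oracle agrees exactly with the rasterization
  g <- case$pet$grid
  ctr <- (g$dims - 1) * 4 / 2
  cnt <- 0L
  for (i in seq_len(g$dims[1])) for (j in seq_len(g$dims[2])) for (k in seq_len(g$dims[3])) {
    p <- (c(i, j, k) - 1) * 4
    if (sum((p - ctr)^2) <= 15^2) cnt <- cnt + 1L
  }
  expect_equal(sum(case$truth$member), cnt)
})

test_that("noise changes voxel values but not the truth mask; regeneration is bit-identical", {
  g <- image_grid(c(16, 16, 16), c(4, 4, 4))
  les <- lesion_spec(c(30, 30, 30), c(10, 10, 10), 8)
  mk <- function(seed) generate_phantom(phantom_spec(list(les), pet_grid = g,
    background_suv = 1, psf_fwhm = 5, noise_sd_at_background = 0.2, seed = seed))
  a <- mk(1); b <- mk(2); a2 <- mk(1)
  expect_identical(a$truth$member, b$truth$member)
  expect_false(identical(a$pet$values, b$pet$values))
  expect_identical(a$pet$values, a2$pet$values)
})

test_that("PSF blur conserves total signal for interior lesions", {
  g <- image_grid(c(24, 24, 24), c(4, 4, 4))
  les <- lesion_spec(c(46, 46, 46), c(10, 10, 10), 8)
  nob <- generate_phantom(phantom_spec(list(les), pet_grid = g, background_suv = 1,
                                       psf_fwhm = 0, noise_sd_at_background = 0, seed = 1))
  blr <- generate_phantom(phantom_spec(list(les), pet_grid = g, background_suv = 1,
                                       psf_fwhm = 7, noise_sd_at_background = 0, seed = 1))
  expect_lt(abs(sum(blr$pet$values) - sum(nob$pet$values)) / sum(nob$pet$values),
            0.005)
})

test_that("suv_stats over truth recovers the plateau uptake when psf and noise are 0", {
  case <- plateau_sphere_case(uptake = 6.5)
  st <- suv_stats(case$pet, case$truth)
  expect_equal(st$suv_max, 6.5)
  expect_equal(st$suv_mean, 6.5)
})

test_that("lesions outside the grid and confounders inside the roi are rejected", {
  g <- image_grid(c(10, 10, 10), c(4, 4, 4))
  far <- lesion_spec(c(500, 0, 0), c(5, 5, 5), 8)
  expect_error(generate_phantom(phantom_spec(list(far), pet_grid = g)),
               "outside the grid")
  les <- lesion_spec(c(18, 18, 18), c(8, 8, 8), 8)
  expect_error(phantom_spec(list(les), pet_grid = g,
                            confounders = list(lesion_spec(c(18, 18, 18), c(4, 4, 4), 10))),
               "outside the roi")
})

test_that("cohort generation is reproducible and spans the intended volume range", {
  co1 <- generate_cohort(n = 31, seed = 1)
  co2 <- generate_cohort(n = 31, seed = 1)
  expect_length(co1, 31)
  expect_identical(lapply(co1, function(cs) cs$spec), lapply(co2, function(cs) cs$spec))
  expect_identical(co1[[5]]$pet$values, co2[[5]]$pet$values)

  av <- vapply(co1, function(cs) cs$spec$lesions[[1]]$analytic_volume_ml, numeric(1))
  rg <- cohort_ranges()
  # sample mean within 2 SE of the closed-form log-normal mean
  mu_ln <- exp(rg$volume_meanlog + rg$volume_sdlog^2 / 2)
  sd_ln <- mu_ln * sqrt(exp(rg$volume_sdlog^2) - 1)
  expect_lt(abs(mean(av) - mu_ln), 2 * sd_ln / sqrt(31))
  # contrasts within the configured range
  up <- vapply(co1, function(cs) cs$spec$lesions[[1]]$uptake, numeric(1))
  expect_true(all(up >= rg$contrast_range[1] * rg$background_suv - 1e-9))
  expect_true(all(up <= rg$contrast_range[2] * rg$background_suv + 1e-9))
})

test_that("degenerate single-point ranges reproduce that exact lesion", {
  rg <- cohort_ranges()
  rg$volume_sdlog <- 0
  rg$contrast_range <- c(5, 5)
  rg$aspect_range <- c(1, 1)
  rg$heterogeneous_fraction <- 0
  co <- generate_cohort(n = 1, ranges = rg, seed = 9)
  les <- co[[1]]$spec$lesions[[1]]
  expect_equal(les$analytic_volume_ml, exp(rg$volume_meanlog), tolerance = 1e-10)
  expect_equal(les$uptake, 5 * rg$background_suv)
  expect_error(generate_cohort(n = 2, ranges = list(), seed = 1), "empty")
})

test_that("planning-CT grids have the clinical spacings and cover the PET extent", {
  fine <- make_ct_grid("fine")
  coarse <- make_ct_grid("coarse")
  expect_equal(fine$spacing, c(0.59, 0.59, 3))
  expect_equal(coarse$spacing, c(1.17, 1.17, 3))
  pet <- image_grid(c(64, 64, 48), c(4, 4, 4), c(-126, -126, -94))
  pext <- grid_extent(pet)
  for (gct in list(fine, coarse)) {
    e <- grid_extent(gct)
    expect_true(all(e$lo <= pext$lo + 1e-9))
    expect_true(all(e$hi >= pext$hi - 1e-9))
  }
})
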