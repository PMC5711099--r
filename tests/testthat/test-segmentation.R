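test_that("reference uptake dialects agree on flat regions and differ on peaks", {
  g <- image_grid(c(9, 9, 9), c(4, 4, 4))
  roi <- roi_box(c(-1, -1, -1), c(33, 33, 33))
  flat <- suv_volume(g, 4.2)
  expect_equal(reference_uptake(flat, roi, "max_voxel"), 4.2)
  expect_equal(reference_uptake(flat, roi, "neighborhood_mean5"), 4.2)

  v <- array(1, dim = c(9, 9, 9)); v[5, 5, 5] <- 10
  hot <- suv_volume(g, v)
  expect_equal(reference_uptake(hot, roi, "max_voxel"), 10)
  expect_equal(reference_uptake(hot, roi, "neighborhood_mean5"), (10 + 4) / 5)

  # corner max: fewer neighbors exist, the mean uses what is there
  v2 <- array(1, dim = c(9, 9, 9)); v2[1, 1, 1] <- 10
  expect_equal(reference_uptake(suv_volume(g, v2), roi, "neighborhood_mean5"),
               (10 + 4) / 5)
  expect_error(reference_uptake(hot, roi_box(c(100, 100, 100), c(101, 101, 101)),
                                "max_voxel"),
               "no voxel centers|does not intersect")
})

test_that("neighborhood_mean5 never exceeds max_voxel (random volumes)", {
  g <- image_grid(c(8, 8, 8), c(4, 4, 4))
  roi <- roi_box(c(-1, -1, -1), c(29, 29, 29))
  for (s in 1:25) {
    set.seed(s)
    vol <- suv_volume(g, array(runif(512, 0, 10), dim = c(8, 8, 8)))
    expect_lte(reference_uptake(vol, roi, "neighborhood_mean5"),
               reference_uptake(vol, roi, "max_voxel"))
  }
})

test_that("fixed threshold keeps >= threshold voxels and recovers plateau truth", {
  g <- image_grid(c(2, 2, 1), c(4, 4, 4))
  vol <- suv_volume(g, array(c(1, 2, 3, 10), dim = c(2, 2, 1)))
  roi <- roi_box(c(-2, -2, -2), c(6, 6, 6))
  m <- segment_fixed_threshold(vol, roi, 2.5)
  expect_equal(sum(m$member), 2L)   # the 3 and the 10, 26-connected

  bg <- suv_volume(g, 1)
  expect_equal(sum(segment_fixed_threshold(bg, roi, 2.5)$member), 0L)

  case <- plateau_sphere_case()
  expect_identical(segment_fixed_threshold(case$pet, case$roi, 2.5)$member,
                   case$truth$member)
})

test_that("relative threshold recovers plateau truth and dialects coincide there", {
  case <- plateau_sphere_case(uptake = 10, background = 1)
  m_max <- segment_relative_threshold(case$pet, case$roi, 0.45, "max_voxel")
  m_n5 <- segment_relative_threshold(case$pet, case$roi, 0.45, "neighborhood_mean5")
  expect_identical(m_max$member, case$truth$member)
  expect_identical(m_n5$member, m_max$member)
})

test_that("mean5 dialect mask contains the max dialect mask on noisy images", {
  for (s in 1:5) {
    case <- blurred_sphere_case(radius = 12, noise = 0.3, seed = 100 + s)
    m_max <- segment_relative_threshold(case$pet, case$roi, 0.45, "max_voxel")
    m_n5 <- segment_relative_threshold(case$pet, case$roi, 0.45, "neighborhood_mean5")
    # before the component filter the inclusion is strict set containment;
    # the filter keeps the same hottest component, preserving it
    expect_true(all(m_max$member <= m_n5$member))
  }
})

test_that("threshold masks are monotone in the threshold before filtering", {
  case <- blurred_sphere_case(noise = 0.2, seed = 42)
  rmem <- mtvbench:::roi_member(case$pet$grid, case$roi)
  for (t2 in c(2, 3, 4)) {
    m_hi <- rmem & case$pet$values >= t2 + 1
    m_lo <- rmem & case$pet$values >= t2
    expect_true(all(m_hi <= m_lo))
  }
})

test_that("connected component filter keeps the hottest blob only", {
  g <- image_grid(c(12, 12, 3), c(4, 4, 4))
  v <- array(1, dim = c(12, 12, 3))
  v[2:3, 2:3, 2] <- 5     # cool blob
  v[8:10, 8:10, 2] <- 9   # hot blob
  vol <- suv_volume(g, v)
  roi <- roi_box(c(-2, -2, -2), c(46, 46, 10))
  cand <- binary_mask(g, v >= 4)
  kept <- connected_component_filter(cand, vol, roi)
  expect_equal(sum(kept$member), 9L)
  expect_true(all(which(kept$member, arr.ind = TRUE)[, 1] >= 8))

  single <- binary_mask(g, v >= 8)
  expect_identical(connected_component_filter(single, vol, roi)$member, single$member)
  empty <- binary_mask(g, FALSE)
  expect_identical(connected_component_filter(empty, vol, roi)$member, empty$member)
})

test_that("confounders outside the roi are excluded from threshold masks", {
  g <- image_grid(c(24, 24, 16), c(4, 4, 4), c(-46, -46, -30))
  les <- lesion_spec(c(0, 0, 0), c(10, 10, 10), 8)
  conf <- lesion_spec(c(-38, -38, 0), c(8, 8, 8), 20)  # bladder-like, hot
  sp <- phantom_spec(list(les), pet_grid = g, background_suv = 1,
                     confounders = list(conf),
                     roi = roi_box(c(-20, -20, -20), c(20, 20, 20)),
                     psf_fwhm = 0, noise_sd_at_background = 0, seed = 1)
  case <- generate_phantom(sp)
  m <- segment_fixed_threshold(case$pet, case$roi, 2.5)
  expect_identical(m$member, case$truth$member)
})

test_that("FLAB recovers two well-separated Gaussian classes", {
  set.seed(42)
  dims <- c(12, 12, 12)
  g <- image_grid(dims, c(4, 4, 4))
  lab <- array(runif(prod(dims)) < 0.35, dim = dims)
  x <- array(rnorm(prod(dims), ifelse(lab, 8, 1), 0.5), dim = dims)
  x[x < 0] <- 0
  vol <- suv_volume(g, x)
  roi <- roi_box(c(-2, -2, -2), c(46, 46, 46))
  fit <- flab_fit(vol, roi)
  expect_lt(abs(fit$mu0 - 1) / 1, 0.05)
  expect_lt(abs(fit$mu1 - 8) / 8, 0.05)
  expect_gte(mean(fit$tumor == lab), 0.98)
})

test_that("FLAB segments the noiseless plateau sphere exactly and deterministically", {
  case <- plateau_sphere_case()
  m1 <- segment_flab(case$pet, case$roi)
  m2 <- segment_flab(case$pet, case$roi)
  expect_identical(m1$member, case$truth$member)
  expect_identical(m1$member, m2$member)
})

test_that("FLAB rejects degenerate inputs", {
  g <- image_grid(c(6, 6, 6), c(4, 4, 4))
  roi <- roi_box(c(-2, -2, -2), c(22, 22, 22))
  expect_error(segment_flab(suv_volume(g, 3), roi), "unidentifiable")
  tiny <- roi_box(c(-1, -1, -1), c(5, 5, 5))
  expect_error(segment_flab(suv_volume(g, array(runif(216), dim = c(6, 6, 6))), tiny),
               "20 voxels")
})

test_that("bilateral denoising preserves constants, bounds, and step edges", {
  g <- image_grid(c(10, 10, 10), c(4, 4, 4))
  const <- denoise_edge_preserving(suv_volume(g, 2.5))
  expect_equal(max(abs(const$values - 2.5)), 0)

  # 1-D style step: midpoint crossing must not move by a voxel
  v <- array(1, dim = c(10, 10, 10)); v[6:10, , ] <- 8
  den <- denoise_edge_preserving(suv_volume(g, v), spatial_sigma = 6, range_sigma = 1)
  expect_lte(max(den$values), 8); expect_gte(min(den$values), 1)
  prof <- den$values[, 5, 5]
  crossing <- which(prof >= 4.5)[1]
  expect_equal(crossing, 6L)
})

test_that("Richardson-Lucy deconvolution is conservative and re-sharpens", {
  g <- image_grid(c(15, 15, 15), c(4, 4, 4))
  v <- array(0.01, dim = c(15, 15, 15)); v[8, 8, 8] <- 20
  blurred <- suv_volume(g, mtvbench:::gaussian_blur(v, 8, c(4, 4, 4)))
  dec <- deconvolve(blurred, 8, 10)
  expect_gte(max(dec$values), max(blurred$values))
  expect_gte(min(dec$values), 0)
  expect_lt(abs(sum(dec$values) - sum(blurred$values)) / sum(blurred$values), 0.01)
  expect_identical(deconvolve(blurred, 0, 10)$values, blurred$values)
  expect_identical(deconvolve(blurred, 8, 0)$values, blurred$values)
})

test_that("GBM segments two-plateau images exactly and keeps the hottest voxel", {
  case <- plateau_sphere_case()
  m <- segment_gbm(case$pet, case$roi,
                   params = list(spatial_sigma = 6, range_sigma = 1,
                                 decon_iters = 0, psf_fwhm = 0))
  expect_identical(m$member, case$truth$member)
  hot <- which.max(ifelse(mtvbench:::roi_member(case$pet$grid, case$roi),
                          case$pet$values, -Inf))
  expect_true(m$member[hot])
})

test_that("GBM errors when the roi has no separable structure", {
  g <- image_grid(c(8, 8, 8), c(4, 4, 4))
  roi <- roi_box(c(-2, -2, -2), c(30, 30, 30))
  expect_error(segment_gbm(suv_volume(g, 4), roi), "single watershed basin")
})

test_that("GBM recovers a blurred sphere volume within 25% of analytic truth", {
  case <- blurred_sphere_case(radius = 15, uptake = 8, background = 1)
  m <- segment_gbm(case$pet, case$roi)
  v_analytic <- 4 / 3 * pi * 15^3 / 1000
  expect_lt(abs(mask_volume_ml(m) - v_analytic) / v_analytic, 0.25)
})

test_that("all six arms return masks inside the roi and are deterministic", {
  case <- blurred_sphere_case(radius = 12, noise = 0.15, seed = 21)
  rmem <- mtvbench:::roi_member(case$pet$grid, case$roi)
  for (cfg in default_arms()) {
    r1 <- run_segmentation(case$pet, case$roi, cfg)
    r2 <- run_segmentation(case$pet, case$roi, cfg)
    expect_identical(r1$mask$member, r2$mask$member)
    expect_true(all(!r1$mask$member | rmem), info = cfg$label)
    expect_equal(r1$volume_ml, mask_volume_ml(r1$mask))
  }
})
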