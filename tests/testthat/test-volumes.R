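test_that("voxel and mask volumes follow the grid geometry", {
  expect_equal(voxel_volume_ml(image_grid(c(144, 144, 144), c(4, 4, 4))), 0.064)
  expect_equal(voxel_volume_ml(image_grid(c(1024, 1024, 10), c(0.59, 0.59, 3))),
               0.0010443)
  expect_equal(voxel_volume_ml(image_grid(c(5, 5, 5), c(1, 1, 1))), 0.001)

  g <- image_grid(c(10, 10, 10), c(4, 4, 4))
  mem <- array(FALSE, dim = c(10, 10, 10)); mem[1:100] <- TRUE
  expect_equal(mask_volume_ml(binary_mask(g, mem)), 6.4)
  expect_equal(mask_volume_ml(binary_mask(g, FALSE)), 0)
  g1 <- image_grid(c(4, 4, 4), c(1, 1, 1))
  mem1 <- array(FALSE, dim = c(4, 4, 4)); mem1[1:2, 1:2, 1:2] <- TRUE
  expect_equal(mask_volume_ml(binary_mask(g1, mem1)), 0.008)
})

test_that("grid and volume constructors enforce their invariants", {
  expect_error(image_grid(c(0, 4, 4), c(1, 1, 1)), "dims")
  expect_error(image_grid(c(4, 4, 4), c(0, 1, 1)), "spacing")
  g <- image_grid(c(3, 3, 3), c(1, 1, 1))
  expect_error(suv_volume(g, array(-1, dim = c(3, 3, 3))), ">= 0")
  expect_error(suv_volume(g, array(NaN, dim = c(3, 3, 3))), "finite")
  expect_error(roi_box(c(0, 0, 0), c(0, 1, 1)), "lo < hi")
  expect_error(rigid_transform(matrix(2 * diag(3), 3, 3)), "orthonormal")
})

test_that("mask volume is additive over disjoint masks on one grid", {
  g <- image_grid(c(8, 8, 8), c(2, 3, 4))
  set.seed(1)
  a <- array(runif(512) < 0.3, dim = c(8, 8, 8))
  b <- array(runif(512) < 0.3, dim = c(8, 8, 8)) & !a
  expect_equal(mask_volume_ml(binary_mask(g, a)) + mask_volume_ml(binary_mask(g, b)),
               mask_volume_ml(binary_mask(g, a | b)))
})

test_that("suv_stats returns max and mean over the mask, erroring when empty", {
  g <- image_grid(c(2, 2, 1), c(4, 4, 4))
  vol <- suv_volume(g, array(c(1, 2, 3, 10), dim = c(2, 2, 1)))
  m <- binary_mask(g, TRUE)
  st <- suv_stats(vol, m)
  expect_equal(st$suv_max, 10)
  expect_equal(st$suv_mean, 4)
  one <- binary_mask(g, array(c(FALSE, TRUE, FALSE, FALSE), dim = c(2, 2, 1)))
  expect_equal(suv_stats(suv_volume(g, array(2.5, dim = c(2, 2, 1))), one),
               list(suv_max = 2.5, suv_mean = 2.5))
  expect_error(suv_stats(vol, binary_mask(g, FALSE)), "empty")
})

test_that("rigid transforms compose with their inverse to the identity", {
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xf <- rigid_transform(R, c(5, -3, 2))
  pts <- matrix(rnorm(30), 10, 3)
  back <- apply_transform(invert_transform(xf), apply_transform(xf, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("trilinear resampling is exact on identity and bounded by the source", {
  case <- plateau_sphere_case()
  out <- resample_suv(case$pet, case$pet$grid)
  expect_identical(out$values, case$pet$values)

  # constant volume stays constant on any interior target
  g <- image_grid(c(10, 10, 10), c(4, 4, 4))
  cvol <- suv_volume(g, 3.7)
  tgt <- image_grid(c(12, 12, 12), c(2.5, 2.5, 2.5), c(2, 2, 2))
  rs <- resample_suv(cvol, tgt)
  expect_equal(max(abs(rs$values - 3.7)), 0)

  # value-boundedness: single hot voxel onto a half-spacing grid
  v <- array(1, dim = c(9, 9, 9)); v[5, 5, 5] <- 50
  hot <- suv_volume(image_grid(c(9, 9, 9), c(4, 4, 4)), v)
  half <- image_grid(c(17, 17, 17), c(2, 2, 2))
  rs2 <- resample_suv(hot, half)
  expect_lte(max(rs2$values), max(v))
  expect_gte(min(rs2$values[rs2$values > 0]), 0)

  # brute-force trilinear oracle at a handful of points
  pts <- rbind(c(18, 18, 18), c(17, 16.5, 18.2), c(20, 14, 15))
  ora <- apply(pts, 1, function(p) {
    i0 <- floor(p / 4); f <- p / 4 - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      acc <- acc + w * v[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    acc
  })
  got <- mtvbench:::trilinear_sample(hot, pts)
  expect_equal(got, ora, tolerance = 1e-12)

  expect_error(resample_suv(hot, half, rigid_transform(diag(c(1, 1, -1)))),
               "orthonormal")
})

test_that("out-of-extent samples read 0 and masks resample by nearest neighbor", {
  g <- image_grid(c(4, 4, 4), c(4, 4, 4))
  vol <- suv_volume(g, 5)
  far <- image_grid(c(3, 3, 3), c(4, 4, 4), c(100, 100, 100))
  expect_equal(max(resample_suv(vol, far)$values), 0)

  m <- binary_mask(g, TRUE)
  expect_identical(resample_mask(m, g)$member, m$member)
  interior <- image_grid(c(5, 5, 5), c(2, 2, 2), c(1, 1, 1))
  expect_true(all(resample_mask(m, interior)$member))
})

test_that("sphere mask volume is stable under 4mm to 1mm nearest-neighbor resampling", {
  for (r in c(10, 12, 16)) {
    m <- sphere_mask(r, dims = c(16, 16, 16), spacing = 4)
    fine <- image_grid(c(61, 61, 61), c(1, 1, 1))
    mf <- resample_mask(m, fine)
    # the 1 mm lookup reproduces the 4 mm staircase up to half-voxel edges
    expect_lt(abs(mask_volume_ml(mf) - mask_volume_ml(m)) / mask_volume_ml(m),
              0.15)
  }
  # direct 1 mm rasterization of the analytic sphere is the volume oracle
  g1 <- image_grid(c(41, 41, 41), c(1, 1, 1))
  les <- lesion_spec(c(20, 20, 20), c(12, 12, 12), 1)
  v1 <- sum(mtvbench:::ellipsoid_member(g1, les)) * 0.001
  expect_lt(abs(v1 - 4 / 3 * pi * 12^3 / 1000) / (4 / 3 * pi * 12^3 / 1000), 0.02)
})

test_that("crop_to_roi preserves values and world coordinates", {
  case <- plateau_sphere_case()
  cr <- crop_to_roi(case$pet, case$roi)
  expect_true(all(cr$vol$grid$dims <= case$pet$grid$dims))
  # world position of crop voxel (1,1,1) must match parent voxel at offset
  off <- cr$offset
  expect_equal(cr$vol$grid$origin, case$pet$grid$origin + off * case$pet$grid$spacing)
  expect_equal(cr$vol$values[1, 1, 1],
               case$pet$values[off[1] + 1, off[2] + 1, off[3] + 1])
})
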