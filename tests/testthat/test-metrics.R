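test_that("conformity index counts intersection over union", {
  g <- image_grid(c(6, 6, 6), c(4, 4, 4))
  a <- array(FALSE, dim = c(6, 6, 6)); a[2:5, 2:5, 2:5] <- TRUE
  b <- array(FALSE, dim = c(6, 6, 6)); b[3:4, 3:4, 3:4] <- TRUE
  expect_equal(conformity_index(binary_mask(g, b), binary_mask(g, a)), 8 / 64)
  expect_equal(conformity_index(binary_mask(g, a), binary_mask(g, a)), 1)
  c2 <- array(FALSE, dim = c(6, 6, 6)); c2[1, 1, 1] <- TRUE
  expect_equal(conformity_index(binary_mask(g, a), binary_mask(g, c2)), 0)
  expect_error(conformity_index(binary_mask(g, FALSE), binary_mask(g, FALSE)),
               "both masks empty")
  g2 <- image_grid(c(6, 6, 6), c(2, 2, 2))
  expect_error(conformity_index(binary_mask(g, a), binary_mask(g2, a)),
               "different grids")
})

test_that("conformity index is symmetric and matches brute-force counting", {
  g <- image_grid(c(10, 10, 10), c(4, 4, 4))
  for (s in 1:30) {
    set.seed(s)
    a <- array(runif(1000) < 0.3, dim = c(10, 10, 10))
    b <- array(runif(1000) < 0.3, dim = c(10, 10, 10))
    if (!any(a | b)) next
    ma <- binary_mask(g, a); mb <- binary_mask(g, b)
    inter <- 0L; uni <- 0L
    for (i in which(a | b)) {
      if (a[i] && b[i]) inter <- inter + 1L
      uni <- uni + 1L
    }
    expect_identical(conformity_index(ma, mb), inter / uni)
    expect_identical(conformity_index(ma, mb), conformity_index(mb, ma))
  }
})

test_that("ci_summary descriptive statistics and degenerate cases", {
  s <- ci_summary(rep(1, 31))
  expect_equal(s$mean, 1); expect_equal(s$sd, 0)
  expect_true(s$exact_agreement); expect_true(is.na(s$t_p))
  s2 <- ci_summary(c(0, 1))
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$se, s2$sd / sqrt(2))
  set.seed(1)
  ci <- runif(31, 0.2, 0.8)
  s3 <- ci_summary(ci)
  expect_equal(s3$mean, mean(ci))
  expect_lt(s3$t_p, 0.001)   # far from H0: mean = 1
  expect_lt(s3$wilcoxon_p, 0.001)
  # permutation invariance
  s4 <- ci_summary(rev(ci))
  expect_equal(s4$mean, s3$mean); expect_equal(s4$t_p, s3$t_p)
})

test_that("ICC(2,1) equals the ANOVA mean-squares oracle", {
  icc_oracle <- function(x) {
    ns <- nrow(x); nr <- ncol(x)
    gm <- mean(x)
    MSR <- sum((rowMeans(x) - gm)^2) * nr / (ns - 1)
    MSC <- sum((colMeans(x) - gm)^2) * ns / (nr - 1)
    MSE <- (sum((x - gm)^2) - MSR * (ns - 1) - MSC * (nr - 1)) / ((ns - 1) * (nr - 1))
    (MSR - MSE) / (MSR + (nr - 1) * MSE + (nr / ns) * (MSC - MSE))
  }
  # hand-checkable 4x2 matrix
  x <- matrix(c(1, 2, 3, 4, 1.1, 2.2, 2.9, 4.3), ncol = 2)
  expect_equal(icc_agreement(x)$icc, icc_oracle(x), tolerance = 1e-10)
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(8, 10, 3), 4, 2)
    expect_equal(icc_agreement(x)$icc, icc_oracle(x), tolerance = 1e-10)
  }
})

test_that("ICC edge behavior: duplicated columns, independence, degenerate input", {
  set.seed(3)
  v <- rnorm(20, 30, 10)
  dup <- cbind(v, v)
  ic <- icc_agreement(dup)
  expect_equal(ic$icc, 1)
  expect_lte(ic$ci95_lower, ic$icc)

  set.seed(11)
  indep <- cbind(rnorm(31), rnorm(31))
  expect_lt(abs(icc_agreement(indep)$icc), 0.3)

  expect_error(icc_agreement(matrix(5, 4, 3)), "zero variance")
  expect_error(icc_agreement(matrix(1:3, 3, 1)), ">= 2")
})

test_that("paired tests follow the standard conventions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(paired_tests(x, x), list(t_p = 1, wilcoxon_p = 1))
  expect_error(paired_tests(x, x + 1), "undefined")
  set.seed(5)
  a <- rnorm(31); b <- a + rnorm(31, 0, 1)  # null shift
  p <- paired_tests(a, b)
  expect_gt(p$t_p, 0.001); expect_gt(p$wilcoxon_p, 0.001)
  set.seed(6)
  d <- rnorm(31, 3, 0.5)
  p2 <- paired_tests(a, a + d)
  expect_lt(p2$t_p, 1e-6)
})

test_that("Friedman test and Holm post-hocs behave across method counts", {
  set.seed(2)
  base <- rnorm(15, 20, 5)
  same <- cbind(a = base, b = base, c = base)
  fr <- friedman_volumes(same)
  expect_equal(fr$statistic, 0, tolerance = 1e-9)
  expect_gte(fr$p, 0.99)

  shifted <- cbind(a = base, b = base + rnorm(15, 0, 0.1),
                   c = base + 10 * sd(base))
  fr2 <- friedman_volumes(shifted)
  expect_lt(fr2$p, 0.001)
  expect_equal(nrow(fr2$posthoc), 3L)
  expect_true(all(fr2$posthoc$p_holm >= fr2$posthoc$p_raw - 1e-12))
  expect_lt(fr2$posthoc$p_holm[fr2$posthoc$pair == "a vs c"], 0.05)

  expect_error(friedman_volumes(same[, 1:2]), "paired_tests")
})

test_that("Bland-Altman statistics match the direct formulas", {
  b <- c(10, 12, 15, 20)
  expect_equal(bland_altman(b, b)$mean_diff, 0)
  ba <- bland_altman(b, b - 0.28)
  expect_equal(ba$mean_diff, -0.28)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$limits, c(-0.28, -0.28))
  set.seed(4)
  x <- runif(31, 5, 60); y <- x + rnorm(31, 0.2, 0.4)
  ba2 <- bland_altman(x, y)
  d <- y - x
  expect_equal(ba2$mean_diff, mean(d))
  expect_equal(ba2$sd_diff, sd(d))
  expect_equal(ba2$limits, mean(d) + c(-1.96, 1.96) * sd(d))
  expect_equal(ba2$cases$mean, (x + y) / 2)
})

test_that("relative volume variation is a percent of the reference", {
  expect_equal(relative_volume_variation(10, 10), 0)
  expect_equal(relative_volume_variation(10, 5), 50)
  expect_equal(relative_volume_variation(10, 24.2), 142)
  expect_error(relative_volume_variation(0, 5), "> 0")
})
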