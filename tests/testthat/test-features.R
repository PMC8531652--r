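test_that("kernel size formula matches direct evaluation", {
  # sigma 1, order 1: 3 + 0.25 + 2.5*5/(25+64) = 3.390..., next odd is 5
  expect_equal(gaussian_filter_size(1, 1, round = FALSE),
               3 + 0.25 + 12.5 / 89, tolerance = 1e-12)
  expect_equal(gaussian_filter_size(1, 1), 5L)
  # sigma 3, order 0: 3 * (3 + 15/117) = 9.3846..., next odd is 11
  expect_equal(gaussian_filter_size(3, 0, round = FALSE),
               3 * (3 - 2.5 * (-6) / (36 + 81)), tolerance = 1e-12)
  expect_equal(gaussian_filter_size(3, 0), 11L)
  # whole reference grid against the closed form
  for (s in c(1, 3, 6)) for (o in 0:2) {
    raw <- s * (3 + 0.25 * o - 2.5 * (o - 6) / ((o - 6)^2 + (o - 9)^2))
    expect_equal(gaussian_filter_size(s, o, round = FALSE), raw)
    got <- gaussian_filter_size(s, o)
    expect_true(got %% 2 == 1 && got >= raw)
  }
  # pre-rounding size is linear in sigma
  expect_equal(gaussian_filter_size(2, 2, round = FALSE),
               2 * gaussian_filter_size(1, 2, round = FALSE))
})

test_that("stack normalization is an exact min-max rescale", {
  st <- image_stack(array(c(10, 20, 30, 10, 20, 30, 10, 30), dim = c(2, 2, 2)))
  ns <- normalize_stack(st)
  expect_equal(sort(unique(as.vector(ns$data))), c(0, 0.5, 1))
  spanned <- image_stack(array(runif(64), dim = c(4, 4, 4)))
  spanned$data[1] <- 0; spanned$data[64] <- 1
  expect_identical(normalize_stack(spanned)$data, spanned$data)
  flat <- image_stack(array(3, dim = c(2, 2, 2)))
  expect_warning(nf <- normalize_stack(flat), "constant")
  expect_true(all(nf$data == 0))
})

test_that("Gaussian derivative responses obey calculus identities", {
  const <- array(0.7, dim = c(16, 16, 4))
  for (d in pycnoseg:::derivative_directions())
    expect_equal(max(abs(pycnoseg:::gaussian_derivative3d(const, 1, d))), 0)

  # ramp along x: first x-derivative equals the slope in the interior
  ramp <- array(0, dim = c(16, 32, 4))
  for (x in 1:32) ramp[, x, ] <- 0.02 * x
  dx <- pycnoseg:::gaussian_derivative3d(ramp, 1, c(0, 1, 0))
  expect_equal(dx[8, 10:22, 2], rep(0.02, 13), tolerance = 1e-10)

  # symmetric blob: first derivatives are antisymmetric about the center
  blob <- array(0, dim = c(21, 21, 1))
  for (y in 1:21) for (x in 1:21)
    blob[y, x, 1] <- exp(-((x - 11)^2 + (y - 11)^2) / 18)
  gx <- pycnoseg:::gaussian_derivative3d(blob, 1, c(0, 1, 0))
  expect_equal(gx[11, 11 + 1:5, 1], -gx[11, 11 - 1:5, 1], tolerance = 1e-10)
})

test_that("Laguerre-Gauss kernels have the stated symmetries", {
  k00 <- lgf_kernel(0, 0)
  expect_equal(k00, t(k00))
  expect_equal(k00, k00[, ncol(k00):1])              # mirror invariance
  expect_equal(k00, t(k00)[nrow(k00):1, ])           # 90 degree rotation

  # point reflection parity follows cos(l * theta): even l symmetric, odd l antisymmetric
  for (l in 0:2) {
    k <- lgf_kernel(1, l)
    flipped <- k[nrow(k):1, ncol(k):1]
    expect_equal(flipped, if (l %% 2 == 0) k else -k, tolerance = 1e-12)
  }

  # pointwise closed-form oracle at a probe grid point
  k <- lgf_kernel(2, 1, s = 0.5, q = 2, r = 0, size = 21)
  x <- 3; y <- -2
  u <- sqrt(x^2 + y^2) * 0.5
  lag <- function(p, t) if (p == 0) 1 else if (p == 1) 1 - t else 1 - 2 * t + t^2 / 2
  expected <- exp(-u^2 / 2) * u^(1 / 2) * cos(atan2(y, x)) * lag(2, u * atan(u))
  expect_equal(k[11 + y, 11 + x], expected, tolerance = 1e-12)

  expect_error(lgf_kernel(0, 1, r = 1, strict = TRUE), "r = 0")
  expect_silent(lgf_kernel(0, 1, r = 1))
})

test_that("coherency matches the per-pixel eigen-decomposition oracle", {
  set.seed(99)
  for (i in 1:5) {
    a <- array(runif(16 * 16), dim = c(16, 16, 1))
    st <- structure_tensor(a)
    C <- coherency_image(a)
    expect_true(all(C >= 0 & C <= 1))
    for (y in seq(1, 16, by = 3)) for (x in seq(1, 16, by = 3)) {
      J <- matrix(c(st$jxx[y, x, 1], st$jxy[y, x, 1],
                    st$jxy[y, x, 1], st$jyy[y, x, 1]), 2)
      ev <- eigen(J, symmetric = TRUE)$values
      want <- if (sum(ev) > 1e-12) ((ev[1] - ev[2]) / (ev[1] + ev[2]))^2 else 0
      expect_equal(C[y, x, 1], want, tolerance = 1e-8)
    }
  }
})

test_that("coherency hits its analytic extremes", {
  # constant image: zero tensor everywhere, C defined as 0
  expect_equal(max(coherency_image(array(1, dim = c(16, 16, 1)))), 0)
  # vertical stripes: pure 1D structure, C = 1 in the interior
  stripes <- array(0, dim = c(24, 24, 1))
  stripes[, seq(2, 24, by = 4), 1] <- 1
  C <- coherency_image(stripes)
  expect_true(all(C[8:16, 8:16, 1] > 0.999))
})

test_that("top-hat and entropy banks behave on flat and spotted images", {
  const <- array(0.4, dim = c(24, 24, 2))
  expect_equal(max(abs(tophat_filter(const, 5))), 0)
  expect_equal(max(abs(entropy_filter(const, 5))), 0)

  spot <- array(0, dim = c(31, 31, 1))
  for (y in 1:31) for (x in 1:31)
    if ((x - 16)^2 + (y - 16)^2 <= 2.5^2) spot[y, x, 1] <- 1
  t3 <- tophat_filter(spot, 3)[16, 16, 1]
  t7 <- tophat_filter(spot, 7)[16, 16, 1]
  expect_gte(t7, t3)
  expect_equal(tophat_filter(spot, 7)[16, 16, 1], 1)  # disc fully removed by opening
})

test_that("the reference configuration yields 116 uniquely named channels", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 116)
  expect_equal(anyDuplicated(reg$name), 0)
  gs <- small_synth(seed = 43)
  fv <- suppressWarnings(build_feature_volume(gs$stack, voxels = 1:500))
  expect_equal(ncol(fv$values), 116)
  expect_false(any(is.na(fv$values)))

  tophat_only <- feature_config(sigmas = numeric(0), lgf_p = integer(0),
                                lgf_l = integer(0), entropy_sizes = numeric(0))
  fv8 <- build_feature_volume(gs$stack, tophat_only, voxels = 1:100)
  expect_equal(ncol(fv8$values), 8)
})

test_that("feature volumes are deterministic and scale invariant", {
  gs <- small_synth(seed = 47)
  vox <- seq(1, prod(dim(gs$stack$data)), by = 97)
  f1 <- suppressWarnings(build_feature_volume(gs$stack, voxels = vox))
  f2 <- suppressWarnings(build_feature_volume(gs$stack, voxels = vox))
  expect_identical(f1$values, f2$values)
  scaled <- gs$stack
  scaled$data <- scaled$data * 37.5
  f3 <- suppressWarnings(build_feature_volume(scaled, voxels = vox))
  expect_equal(f3$values, f1$values, tolerance = 1e-12)
})

test_that("PCA decorrelates the fitting sample", {
  set.seed(5)
  x <- matrix(rnorm(400 * 12), 400, 12) %*% matrix(rnorm(144), 12, 12)
  m <- fit_pca(x)
  s <- project_pca(x, m)
  cv <- cov(s)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_true(all(diff(m$var_explained) <= 1e-12))
  expect_lte(sum(m$var_explained), 1 + 1e-12)
})

test_that("rank-1 data loads onto a single component", {
  v <- rnorm(6)
  x <- matrix(rep(v, each = 50), 50, 6)
  x <- x * runif(50, 0.5, 2)              # scaled copies of one vector
  m <- fit_pca(x, scale = FALSE)
  expect_gt(m$var_explained[1], 1 - 1e-9)
  expect_equal(components_for_variance(m, 0.95), 1)
})

test_that("components_for_variance is monotone in the target fraction", {
  set.seed(8)
  x <- matrix(rnorm(300 * 20), 300, 20)
  m <- fit_pca(x)
  ks <- vapply(c(0.95, 0.99, 0.999, 1), components_for_variance, 1L, model = m)
  expect_true(all(diff(ks) >= 0))
  expect_equal(ks[4], 20)
  expect_warning(fit_pca(matrix(rnorm(5 * 10), 5, 10)), "truncated")
})
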