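# Reconstruction and distribution-quality metrics.

test_that("rmse follows its closed form and homogeneity", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 5)), sqrt(4 / 3), tolerance = 1e-12)
  set.seed(1); a <- rnorm(50); b <- rnorm(50)
  expect_equal(rmse(3 * a, 3 * b), 3 * rmse(a, b), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "mismatch")
})

test_that("cc matches the Pearson formula and its affine limits", {
  expect_equal(cc(c(1, 2, 3), 2 * c(1, 2, 3) + 3), 1, tolerance = 1e-12)
  expect_equal(cc(c(1, 2, 3), c(3, 2, 1)), -1, tolerance = 1e-12)
  expect_equal(cc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8, tolerance = 1e-12)
  expect_error(cc(rep(1, 4), 1:4), "constant")
})

test_that("ssim equals the global-statistics formula and is 1 iff equal", {
  set.seed(2); a <- rnorm(40)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  expect_equal(ssim(rep(2, 5), rep(2, 5)), 1, tolerance = 1e-12)
  # direct evaluation oracle on a 4-element pair
  P <- c(1, 2, 3, 4); A <- c(2, 2, 4, 3)
  cfg <- metric_config()
  Lr <- max(A) - min(A)
  c1 <- (0.01 * Lr)^2; c2 <- (0.03 * Lr)^2
  mP <- mean(P); mA <- mean(A)
  vP <- mean((P - mP)^2); vA <- mean((A - mA)^2)
  cov <- mean((P - mP) * (A - mA))
  oracle <- ((2 * mP * mA + c1) * (2 * cov + c2)) /
    ((mP^2 + mA^2 + c1) * (vP + vA + c2))
  expect_equal(ssim(P, A, cfg), oracle, tolerance = 1e-12)
  expect_lt(ssim(a, a + 0.5), 1)
})

test_that("metrics are permutation-equivariant and ordered under noise", {
  set.seed(3)
  A <- rnorm(60); P <- A + rnorm(60, 0, 0.2)
  perm <- sample(60)
  expect_equal(rmse(P, A), rmse(P[perm], A[perm]), tolerance = 1e-14)
  expect_equal(cc(P, A), cc(P[perm], A[perm]), tolerance = 1e-14)
  expect_equal(ssim(P, A), ssim(P[perm], A[perm]), tolerance = 1e-14)
  # expectation ordering over 50 seeded draws at increasing noise
  res <- vapply(seq(0.05, 0.5, length.out = 5), function(s) {
    vals <- vapply(1:50, function(i) {
      set.seed(i)
      Pn <- A + rnorm(60, 0, s)
      c(rmse(Pn, A), cc(Pn, A), ssim(Pn, A))
    }, numeric(3))
    rowMeans(vals)
  }, numeric(3))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) < 0))
  expect_true(all(diff(res[3, ]) < 0))
})

test_that("mmd matches the brute-force estimator and is symmetric", {
  X <- c(0.0, 1.0); Y <- c(0.5, 1.5)
  cfg <- quality_config(bandwidth = 0.7)
  k <- function(a, b) exp(-(a - b)^2 / (2 * 0.7^2))
  est <- (2 * k(X[1], X[2])) / (2 * 1) + (2 * k(Y[1], Y[2])) / (2 * 1) -
    (2 / 4) * sum(outer(X, Y, k))
  expect_equal(mmd(X, Y, cfg), sqrt(max(est, 0)), tolerance = 1e-12)
  expect_equal(mmd(X, Y, cfg), mmd(Y, X, cfg), tolerance = 1e-14)
  # identical degenerate sets: all kernel values 1 -> 0
  expect_identical(mmd(rep(2, 3), rep(2, 4), quality_config(bandwidth = 1)), 0)
  expect_error(mmd(1, c(1, 2)), "at least 2")
})

test_that("kde_ise vanishes for identical samples and matches the separated limit", {
  set.seed(4); x <- rnorm(30)
  cfg <- quality_config(bandwidth = 0.4, grid_points = 2048L)
  expect_lt(kde_ise(x, x, cfg), 1e-8)
  expect_gte(kde_ise(x, x + 3, cfg), 0)
  # two single-point samples far apart: ISE -> 1 / (h * sqrt(pi))
  h <- 0.2
  cfg2 <- quality_config(bandwidth = h, grid_points = 4096L)
  val <- kde_ise(0, 50, cfg2)
  expect_lt(abs(val - 1 / (h * sqrt(pi))) / (1 / (h * sqrt(pi))), 0.02)
  expect_warning(kde_ise(rep(1, 5), rnorm(5)), "bandwidth floor")
})

test_that("lmmd averages per-window mmds over contiguous windows", {
  cfg <- quality_config(n_windows = 2L, bandwidth = 0.5)
  X <- c(0, 1, 4, 5); Y <- c(0.5, 1.5, 4.5, 5.5)
  w1 <- mmd(X[1:2], Y[1:2], cfg)
  w2 <- mmd(X[3:4], Y[3:4], cfg)
  expect_equal(lmmd(X, Y, cfg), mean(c(w1, w2)), tolerance = 1e-12)
  # single window reduces to mmd
  cfg1 <- quality_config(n_windows = 1L, bandwidth = 0.5)
  expect_equal(lmmd(X, Y, cfg1), mmd(X, Y, cfg1), tolerance = 1e-12)
  expect_identical(lmmd(rep(1, 8), rep(1, 8),
                        quality_config(n_windows = 2L, bandwidth = 1)), 0)
  expect_error(lmmd(1:4, 1:4, quality_config(n_windows = 3L)), "window")
})

test_that("knndc averages k-nearest distances and ignores Y order", {
  expect_equal(knndc(0, 3, quality_config(k_neighbors = 1L)), 3)
  # neighbors at distances 1 and 3 with k = 2 -> mean 2
  expect_equal(knndc(0, c(1, -3, 10), quality_config(k_neighbors = 2L)), 2)
  set.seed(5)
  X <- rnorm(10); Y <- rnorm(20)
  cfg <- quality_config(k_neighbors = 4L)
  expect_equal(knndc(X, Y, cfg), knndc(X, sample(Y), cfg), tolerance = 1e-12)
  expect_error(knndc(1, c(1, 2), quality_config(k_neighbors = 5L)), "at least k")
})

test_that("evaluate_reconstruction bundles the individual metrics", {
  m <- coarse_mesh()
  set.seed(6)
  truth <- conductivity_field(0.03 + runif(m$n_elements) / 100, m)
  pred <- conductivity_field(truth$values * (1 + rnorm(m$n_elements, 0, 0.05)), m)
  rep <- evaluate_reconstruction(pred, truth, ipst_seconds = 1.5)
  expect_equal(rep$rmse, rmse(pred, truth))
  expect_equal(rep$cc, cc(pred, truth))
  expect_equal(rep$ssim, ssim(pred, truth))
  expect_identical(rep$ipst_seconds, 1.5)
  perfect <- evaluate_reconstruction(truth, truth)
  expect_equal(unlist(perfect[, c("rmse", "cc", "ssim")]),
               c(rmse = 0, cc = 1, ssim = 1), tolerance = 1e-12)
  other <- conductivity_field(350, mid_mesh(), unit = "uS/cm")
  expect_error(evaluate_reconstruction(other, truth), "different meshes")
})
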