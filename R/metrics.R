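# Reconstruction metrics (RMSE, CC, SSIM) and boundary-voltage
# distribution-quality metrics (MMD, KDE-ISE, LMMD, KNNDC).

#' Reconstruction metric configuration
#'
#' SSIM stabilization constants follow the conventional rule
#' `c1 = (k1 * Lr)^2`, `c2 = (k2 * Lr)^2` with `Lr` the dynamic range
#' (max - min) of the reference field; for constant references a small
#' positive floor keeps the constants positive.
#'
#' @param ssim_k1,ssim_k2 SSIM constants (defaults 0.01, 0.03).
#' @param range_floor dynamic-range floor for degenerate references.
#' @return an object of class `eit_metric_config`.
#' @export
metric_config <- function(ssim_k1 = 0.01, ssim_k2 = 0.03,
                          range_floor = 1e-8) {
  structure(list(ssim_k1 = ssim_k1, ssim_k2 = ssim_k2,
                 range_floor = range_floor),
            class = "eit_metric_config")
}

#' Distribution-quality metric configuration
#'
#' @param n_windows window count for [lmmd()] (default 10).
#' @param k_neighbors neighbor count for [knndc()] (default 5).
#' @param grid_points integration grid size for [kde_ise()] (default 512).
#' @param bandwidth optional fixed kernel bandwidth; when `NULL`, MMD
#'   uses the median pairwise-distance heuristic and KDE Silverman's
#'   rule.
#' @return an object of class `eit_quality_config`.
#' @export
quality_config <- function(n_windows = 10L, k_neighbors = 5L,
                           grid_points = 512L, bandwidth = NULL) {
  stop_if(!is_count(n_windows) || !is_count(k_neighbors), "invalid counts")
  structure(list(n_windows = as.integer(n_windows),
                 k_neighbors = as.integer(k_neighbors),
                 grid_points = as.integer(grid_points),
                 bandwidth = bandwidth),
            class = "eit_quality_config")
}

as_values <- function(x) {
  if (inherits(x, "eit_field")) return(x$values)
  if (inherits(x, "eit_frame")) return(unclass(x))
  as.numeric(x)
}

#' Root-mean-square error
#'
#' @param P,A numeric vectors (or `eit_field`s) of equal length.
#' @return `sqrt(mean((P - A)^2))`.
#' @export
rmse <- function(P, A) {
  P <- as_values(P); A <- as_values(A)
  stop_if(length(P) != length(A), "length mismatch")
  sqrt(mean((P - A)^2))
}

#' Pearson correlation coefficient between two images
#'
#' @param P,A numeric vectors (or `eit_field`s) of equal length, both
#'   non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
cc <- function(P, A) {
  P <- as_values(P); A <- as_values(A)
  stop_if(length(P) != length(A), "length mismatch")
  stop_if(sd(P) == 0 || sd(A) == 0,
          "correlation undefined for constant input")
  cor(P, A)
}

#' Structural similarity index with global statistics
#'
#' Evaluated once over the whole element vector (fields are unstructured
#' per-element values, so no sliding window applies):
#' `(2 mP mA + c1)(2 cov + c2) / ((mP^2 + mA^2 + c1)(vP + vA + c2))`,
#' with population (1/N) variances and covariance.
#'
#' @param P,A numeric vectors (or `eit_field`s) of equal length.
#' @param config an [metric_config()].
#' @return SSIM value, at most 1, equal to 1 iff `P == A`.
#' @export
ssim <- function(P, A, config = metric_config()) {
  P <- as_values(P); A <- as_values(A)
  stop_if(length(P) != length(A), "length mismatch")
  n <- length(P)
  Lr <- max(A) - min(A)
  if (Lr <= 0) Lr <- config$range_floor
  c1 <- (config$ssim_k1 * Lr)^2
  c2 <- (config$ssim_k2 * Lr)^2
  mP <- mean(P); mA <- mean(A)
  vP <- mean((P - mP)^2); vA <- mean((A - mA)^2)
  cov <- mean((P - mP) * (A - mA))
  ((2 * mP * mA + c1) * (2 * cov + c2)) /
    ((mP^2 + mA^2 + c1) * (vP + vA + c2))
}

pair_dist <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  x2 <- rowSums(X^2); y2 <- rowSums(Y^2)
  d2 <- outer(x2, y2, "+") - 2 * X %*% t(Y)
  sqrt(pmax(d2, 0))
}

median_bandwidth <- function(X, Y) {
  Z <- rbind(as.matrix(X), as.matrix(Y))
  D <- pair_dist(Z, Z)
  d <- D[upper.tri(D)]
  h <- median(d)
  if (!is.finite(h) || h <= 0) h <- 1
  h
}

gauss_kernel <- function(D, h) exp(-D^2 / (2 * h^2))

#' Maximum mean discrepancy between two sample sets
#'
#' Square root of the unbiased two-sample estimator with a Gaussian
#' kernel (bandwidth from the median pairwise-distance heuristic unless
#' fixed in the config); negative estimates are clipped to 0 before the
#' root. Symmetric in its arguments.
#'
#' @param X,Y numeric vectors or matrices (rows = samples), each with at
#'   least 2 samples.
#' @param config an [quality_config()].
#' @export
mmd <- function(X, Y, config = quality_config()) {
  X <- as.matrix(as_values_mat(X)); Y <- as.matrix(as_values_mat(Y))
  n <- nrow(X); m <- nrow(Y)
  stop_if(n < 2L || m < 2L, "each sample set needs at least 2 points")
  h <- config$bandwidth %||% median_bandwidth(X, Y)
  Kxx <- gauss_kernel(pair_dist(X, X), h)
  Kyy <- gauss_kernel(pair_dist(Y, Y), h)
  Kxy <- gauss_kernel(pair_dist(X, Y), h)
  est <- (sum(Kxx) - sum(diag(Kxx))) / (n * (n - 1)) +
         (sum(Kyy) - sum(diag(Kyy))) / (m * (m - 1)) -
         2 * sum(Kxy) / (n * m)
  sqrt(max(est, 0))
}

as_values_mat <- function(x) {
  if (inherits(x, "eit_frame")) return(matrix(unclass(x)))
  if (is.matrix(x)) return(x)
  matrix(as.numeric(x))
}

silverman_bw <- function(x) {
  n <- length(x)
  s <- min(sd(x), IQR_safe(x) / 1.34)
  h <- 0.9 * s * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    warning("degenerate sample for Silverman rule; bandwidth floor applied")
    h <- 1e-3
  }
  h
}

IQR_safe <- function(x) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  d <- q[2] - q[1]
  if (d <= 0) sd(x) else d
}

#' Integrated squared difference of two kernel density estimates
#'
#' Builds Gaussian kernel density estimates of the two (univariate)
#' sample sets, each with its own bandwidth (Silverman's rule unless
#' fixed), and integrates the squared difference on a uniform grid
#' spanning the combined range plus three bandwidths.
#'
#' @param X,Y numeric vectors.
#' @param config an [quality_config()].
#' @return the integrated squared error (>= 0).
#' @export
kde_ise <- function(X, Y, config = quality_config()) {
  X <- as.numeric(as_values(X)); Y <- as.numeric(as_values(Y))
  hx <- config$bandwidth %||% silverman_bw(X)
  hy <- config$bandwidth %||% silverman_bw(Y)
  hmax <- max(hx, hy)
  lo <- min(X, Y) - 3 * hmax
  hi <- max(X, Y) + 3 * hmax
  g <- seq(lo, hi, length.out = config$grid_points)
  fx <- rowMeans(outer(g, X, function(a, b) stats::dnorm(a, b, hx)))
  fy <- rowMeans(outer(g, Y, function(a, b) stats::dnorm(a, b, hy)))
  dg <- g[2] - g[1]
  sum((fx - fy)^2) * dg
}

#' Local maximum mean discrepancy
#'
#' Partitions both (equal-length, ordered) sample sequences into
#' `n_windows` contiguous equal windows (remainder dropped) and averages
#' the per-window MMD.
#'
#' @param X,Y numeric vectors of equal length, at least 2 per window.
#' @param config an [quality_config()].
#' @export
lmmd <- function(X, Y, config = quality_config()) {
  X <- as.numeric(as_values(X)); Y <- as.numeric(as_values(Y))
  stop_if(length(X) != length(Y), "X and Y must have equal length")
  N <- config$n_windows
  w <- length(X) %/% N
  stop_if(w < 2L, "windows too small: need length >= 2 * n_windows")
  vals <- vapply(seq_len(N), function(i) {
    idx <- ((i - 1L) * w + 1L):(i * w)
    mmd(X[idx], Y[idx], config)
  }, 0)
  mean(vals)
}

#' k-nearest-neighbor distribution complexity
#'
#' For each point of `X`, the mean Euclidean distance to its `k` nearest
#' neighbors in `Y`; aggregated as the mean over all points of `X`.
#'
#' @param X,Y numeric vectors or matrices (rows = samples); `Y` must
#'   hold at least `k` points.
#' @param config an [quality_config()].
#' @export
knndc <- function(X, Y, config = quality_config()) {
  X <- as.matrix(as_values_mat(X)); Y <- as.matrix(as_values_mat(Y))
  k <- config$k_neighbors
  stop_if(nrow(Y) < k, "Y must contain at least k points")
  D <- pair_dist(X, Y)
  mean(apply(D, 1L, function(d) mean(sort(d)[seq_len(k)])))
}

#' Bundle reconstruction metrics into a report
#'
#' @param pred,truth `eit_field`s on the same mesh (fingerprints are
#'   compared when both carry one).
#' @param config an [metric_config()].
#' @param ipst_seconds optional solver-reported inverse-problem solving
#'   time to attach.
#' @return a one-row tibble with `rmse`, `cc`, `ssim`, `ipst_seconds`.
#' @export
evaluate_reconstruction <- function(pred, truth, config = metric_config(),
                                    ipst_seconds = NA_real_) {
  if (inherits(pred, "eit_field") && inherits(truth, "eit_field")) {
    stop_if(!identical(pred$mesh_hash, truth$mesh_hash),
            "fields live on different meshes")
  }
  P <- as_values(pred); A <- as_values(truth)
  stop_if(length(P) != length(A), "length mismatch")
  tibble::tibble(
    rmse = rmse(P, A),
    cc = cc(P, A),
    ssim = ssim(P, A, config),
    ipst_seconds = ipst_seconds
  )
}
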