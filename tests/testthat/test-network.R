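# Reconstruction network: shapes, loss, training mechanics, prediction.

tiny_net_spec <- function(n_out = 50L) {
  network_spec(output_dim = n_out, stage_depths = c(1L, 1L),
               stage_widths = c(4L, 8L), expansion = 2L)
}

test_that("the default architecture reproduces the printed shape chain", {
  spec <- network_spec(output_dim = 95295L)
  sh <- network_shapes(spec)
  expect_equal(sh$height[sh$layer == "stem"], 23L)
  expect_equal(sh$width[sh$layer == "stem"], 24L)
  expect_equal(sh$channels[sh$layer == "stem"], 64L)
  expect_equal(sh$height[sh$layer == "maxpool"], 12L)
  expect_equal(sh$width[sh$layer == "maxpool"], 12L)
  expect_equal(sh$channels[sh$layer == "gap"], 2048L)
  expect_equal(sh$channels[sh$layer == "fc"], 95295L)
  expect_identical(spec$pooled_dim, 2048L)
})

test_that("a real forward pass follows the declared shapes", {
  spec <- tiny_net_spec(11L)
  net <- build_network(spec, seed = 2)
  X <- array(rnorm(45 * 48 * 3), c(45L, 48L, 1L, 3L))
  # capture the stem activation by running the first op alone
  stem <- eit3d:::op_forward(net, net$ops[[1L]], X, FALSE, FALSE)
  expect_identical(dim(stem$y), c(23L, 24L, 4L, 3L))
  out <- eit3d:::net_forward(net, X, train = FALSE, keep_cache = FALSE)$out
  expect_identical(dim(out), c(11L, 3L))
  expect_error(eit3d:::net_forward(net, array(0, c(45L, 48L, 2L, 1L)),
                                   FALSE, FALSE), "channel")
})

test_that("amplified loss matches its definition", {
  expect_identical(amplified_loss(1:5, 1:5, 100), 0)
  set.seed(1); a <- rnorm(10); b <- rnorm(10)
  expect_equal(amplified_loss(a, b, 1), mean((a - b)^2), tolerance = 1e-14)
  expect_equal(amplified_loss(c(0.1, 0.1), c(0, 0), 100), 1.0,
               tolerance = 1e-12)
  expect_error(amplified_loss(1:3, 1:4), "mismatch")
})

test_that("analytic gradients agree with finite differences", {
  spec <- tiny_net_spec(7L)
  net <- build_network(spec, seed = 3)
  set.seed(1)
  X <- array(rnorm(45 * 48 * 2), c(45L, 48L, 1L, 2L))
  Tm <- matrix(rnorm(14), 7L, 2L)
  lossfn <- function(n) {
    mean((eit3d:::net_forward(n, X, TRUE, FALSE)$out - Tm)^2)
  }
  fw <- eit3d:::net_forward(net, X, train = TRUE, keep_cache = TRUE)
  grads <- eit3d:::net_backward(net, fw$caches,
                                2 * (fw$out - Tm) / length(Tm))
  for (chk in list(c("stem", "W"), c("stem_bn", "gamma"),
                   c("s1b1_conv2", "W"), c("s1b1_proj", "W"),
                   c("s2b1_bn3", "beta"), c("fc", "W"), c("fc", "b"))) {
    lay <- chk[1]; pn <- chk[2]; idx <- 2L; h <- 1e-5
    n1 <- net; n1$params[[lay]][[pn]][idx] <- n1$params[[lay]][[pn]][idx] + h
    n2 <- net; n2$params[[lay]][[pn]][idx] <- n2$params[[lay]][[pn]][idx] - h
    num <- (lossfn(n1) - lossfn(n2)) / (2 * h)
    expect_equal(grads[[lay]][[pn]][idx], num, tolerance = 1e-4)
  }
})

make_toy_set <- function(n, n_elem = 60L, seed = 1L) {
  # synthetic low-dimensional frame/field pairs for optimizer tests
  set.seed(seed)
  z <- matrix(runif(2 * n), 2L, n)
  frames <- matrix(0, 2160L, n)
  basis1 <- sin(seq_len(2160L) / 40); basis2 <- cos(seq_len(2160L) / 23)
  sigma <- matrix(0, n_elem, n)
  grid <- seq(0, 1, length.out = n_elem)
  for (i in seq_len(n)) {
    frames[, i] <- z[1L, i] * basis1 + z[2L, i] * basis2 +
      rnorm(2160L, 0, 0.01)
    sigma[, i] <- 0.03 + 0.01 * exp(-(grid - z[1L, i])^2 / 0.02) * z[2L, i]
  }
  structure(list(
    frames_clean = frames, frames_noisy = frames, sigma = sigma,
    specs = vector("list", n), split = rep(NA_character_, n),
    manifest = list(schema = "eit3d_sampleset_v1", mesh_hash = "toy",
                    protocol_hash = "toy")
  ), class = "eit_sampleset")
}

test_that("training is deterministic, bookkept and can overfit a tiny set", {
  set <- split_sampleset(make_toy_set(10L), ratio = 0.8, seed = 2)
  spec <- tiny_net_spec(60L)
  cfg <- train_config(epochs = 4L, batch_size = 4L, base_lr = 1e-2, seed = 7)
  m1 <- train_network(build_network(spec, seed = 5), set, cfg)
  m2 <- train_network(build_network(spec, seed = 5), set, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(nrow(m1$history), 4L)
  expect_true(all(is.finite(m1$history$train_loss)))
  # longer run overfits: final loss well below the initial loss
  cfg2 <- train_config(epochs = 60L, batch_size = 8L, base_lr = 1e-2,
                       seed = 7, lr_patience = 20L)
  m3 <- train_network(build_network(spec, seed = 5), set, cfg2)
  expect_lt(tail(m3$history$train_loss, 1), 0.1 * m3$history$train_loss[1])
})

test_that("prediction denormalizes, is deterministic and memorizes one sample", {
  set <- split_sampleset(make_toy_set(6L, seed = 3L), ratio = 0.5, seed = 2)
  spec <- tiny_net_spec(60L)
  cfg <- train_config(epochs = 80L, batch_size = 3L, base_lr = 1e-2,
                      seed = 7, lr_patience = 30L)
  model <- train_network(build_network(spec, seed = 5), set, cfg)
  tr1 <- which(set$split == "train")[1L]
  fm <- frame_to_featuremap(voltage_frame(set$frames_noisy[, tr1]))
  p1 <- predict(model, fm)
  expect_identical(dim(p1), c(60L, 1L))
  expect_identical(predict(model, fm), p1)
  expect_true(all(p1 > 0))
  expect_gt(cor(p1[, 1L], set$sigma[, tr1]), 0.99)
})

test_that("training validates inputs", {
  set <- make_toy_set(6L)
  spec <- tiny_net_spec(60L)
  net <- build_network(spec, seed = 1)
  expect_error(train_network(net, set, train_config(epochs = 1L)), "split")
  set2 <- split_sampleset(set, 0.5, 1)
  bad <- build_network(tiny_net_spec(61L), seed = 1)
  expect_error(train_network(bad, set2, train_config(epochs = 1L)),
               "output_dim")
})

test_that("symmetry permutations rotate fields and frames exactly", {
  m <- mid_mesh() # na = 32, still 16-fold symmetric
  p <- build_protocol()
  sym <- symmetry_permutations(m, p)
  expect_length(sym$elem_perms, 16L)
  expect_identical(sym$elem_perms[[1L]], seq_len(m$n_elements))
  s <- 5L
  ang <- s * 2 * pi / 16
  ctr0 <- c(1.6, 0.9, 3.4)
  ctr1 <- c(cos(ang) * ctr0[1] - sin(ang) * ctr0[2],
            sin(ang) * ctr0[1] + cos(ang) * ctr0[2], ctr0[3])
  f0 <- acrylic_field(m, acrylic_phantom_spec(list(
    list(kind = "sphere", center = ctr0, size = 1.2))))
  f1 <- acrylic_field(m, acrylic_phantom_spec(list(
    list(kind = "sphere", center = ctr1, size = 1.2))))
  expect_identical(f1$values, f0$values[sym$elem_perms[[s + 1L]]])
  cem <- cem_params()
  v0 <- unclass(extract_frame(solve_forward(m, f0, cem, p), p))
  v1 <- unclass(extract_frame(solve_forward(m, f1, cem, p), p))
  expect_rel_equal(v1, v0[sym$frame_perms[[s + 1L]]], 1e-9)
})
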