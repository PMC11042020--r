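# Phantom generators: gradient (maize-type) and acrylic inclusion fields.

test_that("radial decay and axial scale follow their closed forms", {
  expect_identical(radial_decay(0, 2), 1)
  expect_equal(radial_decay(2, 2), exp(-1), tolerance = 1e-12)
  x <- seq(0, 5, by = 0.25)
  expect_true(all(diff(radial_decay(x, 1.3)) < 0))
  expect_error(radial_decay(1, 0), "s must be")
  expect_equal(axial_scale(0, 0, 3, 1), 1)
  expect_equal(axial_scale((pi / 2 - 1) / 3, 0.2, 3, 1), 1.2)
  expect_equal(axial_scale((-pi / 2 - 1) / 3, 0.2, 3, 1), 0.8)
  z <- seq(-10, 10, by = 0.1)
  expect_true(all(axial_scale(z, 0.15, 2, 0.4) >= 0.85 - 1e-12))
  expect_true(all(axial_scale(z, 0.15, 2, 0.4) <= 1.15 + 1e-12))
})

test_that("maize gradient field matches a direct re-evaluation", {
  m <- coarse_mesh()
  spec <- maize_phantom_spec(center = c(0.4, -0.3, 4.2), a = 0.12, b = 1.4,
                             c = 0.7, bs = c(3, 5, 6), sigma_max = 350)
  f <- maize_field(m, spec)
  expect_length(f$values, m$n_elements)
  expect_true(all(f$values > 0))
  # brute-force oracle over centroids (cm)
  cen <- m$element_centroids * 100
  dxy <- sqrt((cen[, 1] - 0.4)^2 + (cen[, 2] + 0.3)^2)
  dz <- abs(cen[, 3] - 4.2)
  sz <- 1 + 0.12 * sin(1.4 * (cen[, 3] - 4.2) + 0.7)
  es <- exp(-dxy * sz / 3 - dxy * sz / 5 - dz / 6)
  expect_equal(f$values, 350e-4 * es, tolerance = 1e-12)
  expect_true(all(es > 0 & es <= 1))
  # element at the center attains sigma_max
  spec0 <- maize_phantom_spec(center = cen[17, ], a = 0, b = 1, c = 0,
                              bs = c(3, 5, 6), sigma_max = 350)
  f0 <- maize_field(m, spec0)
  expect_equal(f0$values[17], 0.035, tolerance = 1e-12)
  expect_warning(maize_field(m, maize_phantom_spec(center = c(20, 0, 4))),
                 "outside")
})

test_that("maize field is invariant under rigid translation", {
  m <- coarse_mesh()
  spec <- maize_phantom_spec(center = c(0.5, 0.2, 3.8), a = 0.1, b = 1,
                             c = 0.3, bs = c(4, 4, 5))
  f1 <- maize_field(m, spec)
  m2 <- m
  shift <- c(0.013, -0.007, 0.021) # metres
  m2$nodes <- sweep(m2$nodes, 2L, -shift)
  m2$element_centroids <- sweep(m2$element_centroids, 2L, -shift)
  m2$mesh_hash <- "shifted"
  spec2 <- spec; spec2$center <- spec$center + shift * 100
  f2 <- maize_field(m2, spec2)
  expect_equal(f2$values, f1$values, tolerance = 1e-12)
})

test_that("acrylic fields assign inclusion/background by centroid", {
  m <- mid_mesh()
  sp <- acrylic_phantom_spec(list(list(kind = "sphere", center = c(0, 0, 4),
                                       size = 1.8)))
  f <- acrylic_field(m, sp)
  cen <- m$element_centroids * 100
  inside <- rowSums(sweep(cen, 2L, c(0, 0, 4))^2) <= 1.8^2
  expect_true(any(inside))
  expect_equal(f$values[inside], rep(1e-8, sum(inside)))
  expect_equal(f$values[!inside], rep(0.035, sum(!inside)))
  # a shape that misses the domain leaves a uniform background
  far <- acrylic_field(m, acrylic_phantom_spec(list(
    list(kind = "sphere", center = c(40, 40, 40), size = 1))))
  expect_equal(far$values, rep(0.035, m$n_elements))
  # multiple overlapping shapes: inclusion wins
  multi <- acrylic_field(m, acrylic_phantom_spec(list(
    list(kind = "sphere", center = c(0, 0, 4), size = 1.8),
    list(kind = "cube", center = c(0, 0, 4), size = 3),
    list(kind = "cylinder", center = c(0, 0, 4), size = c(1.8, 2)))))
  expect_true(all(multi$values[inside] %in% c(1e-8, 0.035)))
  expect_gt(sum(multi$values == 1e-8), 0)
})

test_that("sphere inclusion volume is captured to within 10%", {
  m <- build_cylinder_mesh(cylinder_spec(), refinement = 3)
  r <- 2
  f <- acrylic_field(m, acrylic_phantom_spec(list(
    list(kind = "sphere", center = c(0, 0, 4), size = r))))
  vol_captured <- sum(m$element_volumes[f$values < 1e-4])
  vol_true <- 4 / 3 * pi * (r / 100)^3
  expect_lt(abs(vol_captured - vol_true) / vol_true, 0.10)
})

test_that("phantom sampler is seeded, in-range and kind-aware", {
  spec <- cylinder_spec()
  s1 <- phantom_sampler(spec, seed = 42)
  s2 <- phantom_sampler(spec, seed = 42)
  draws1 <- lapply(1:5, function(i) sample_phantom(s1, "sphere"))
  draws2 <- lapply(1:5, function(i) sample_phantom(s2, "sphere"))
  expect_identical(draws1, draws2)
  s3 <- phantom_sampler(spec, seed = 43)
  expect_false(identical(sample_phantom(s3, "sphere"), draws1[[1]]))
  # range respect over many draws
  s4 <- phantom_sampler(spec, seed = 7)
  centers <- t(vapply(1:200, function(i) {
    sample_phantom(s4, "sphere")$shapes[[1]]$center
  }, numeric(3)))
  expect_true(all(sqrt(centers[, 1]^2 + centers[, 2]^2) <= 0.6 * 5 + 1e-9))
  expect_true(all(centers[, 3] >= 0.2 * 8 - 1e-9 &
                    centers[, 3] <= 0.8 * 8 + 1e-9))
  # maize draws respect their invariants
  s5 <- phantom_sampler(spec, seed = 9)
  mz <- sample_phantom(s5, "maize")
  expect_s3_class(mz, "eit_maize_spec")
  expect_true(mz$a >= 0 && mz$a < 1 && all(mz$bs > 0))
  expect_error(phantom_sampler(spec, 1, ranges = list(bogus = c(0, 1))),
               "unknown")
})
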