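# SNR-controlled noise, detection-limit accounting, sample sets.

test_that("noise injection is a seeded, SNR-calibrated additive process", {
  set.seed(1)
  fr <- voltage_frame(rnorm(2160L, 0, 1e-4))
  expect_identical(add_noise(fr, noise_spec(NA)), fr)
  n1 <- add_noise(fr, noise_spec(40, seed = 5))
  n2 <- add_noise(fr, noise_spec(40, seed = 5))
  expect_identical(unclass(n1), unclass(n2))
  n3 <- add_noise(fr, noise_spec(40, seed = 6))
  expect_false(identical(unclass(n1), unclass(n3)))
  expect_error(add_noise(voltage_frame(rep(0, 2160L)), noise_spec(40)),
               "all-zero")
  # pooled noise matches the nominal sigma to 2% at ~1e5 draws
  pooled <- unlist(lapply(1:47, function(s)
    unclass(add_noise(fr, noise_spec(40, seed = s))) - unclass(fr)))
  sd_nom <- sqrt(mean(unclass(fr)^2)) * 10^(-40 / 20)
  expect_lt(abs(mean(pooled)) / sd_nom, 0.02)
  expect_lt(abs(sd(pooled) - sd_nom) / sd_nom, 0.02)
})

test_that("realized SNR tracks the target within half a dB", {
  set.seed(2)
  fr <- voltage_frame(rnorm(2160L, 0, 2e-4))
  v <- unclass(fr)
  realized <- vapply(1:200, function(s) {
    nz <- unclass(add_noise(fr, noise_spec(40, seed = 1000 + s)))
    10 * log10(mean(v^2) / mean((nz - v)^2))
  }, 0)
  expect_lt(abs(mean(realized) - 40), 0.5)
})

test_that("detection report counts |v| > 3 sigma with exact proportions", {
  rep1 <- detection_report(voltage_frame(c(1, 2, 10)), sigma = 1)
  expect_identical(rep1$n_pass, 1L)
  expect_equal(rep1$proportion, 1 / 3)
  expect_equal(rep1$threshold, 3)
  # sigma = 0: every nonzero measurement passes
  rep0 <- detection_report(voltage_frame(c(0, -2, 5)), sigma = 0)
  expect_identical(rep0$n_pass, 2L)
  z <- detection_report(voltage_frame(rep(0, 10)), sigma = 0)
  expect_identical(z$n_pass, 0L)
  # proportion * L = n_pass exactly, and monotone in SNR
  fx <- coarse_homog()
  props <- vapply(c(20, 30, 40, 50, 60), function(snr) {
    r <- detection_report(fx$frame, noise_spec(snr))
    expect_equal(r$proportion * r$L, as.numeric(r$n_pass), tolerance = 1e-12)
    r$proportion
  }, 0)
  expect_true(all(diff(props) >= 0))
})

test_that("sample sets are reproducible, regenerable and splittable", {
  m <- coarse_mesh()
  p <- build_protocol(); cem <- cem_params()
  sampler1 <- phantom_sampler(coarse_spec(), seed = 21)
  set1 <- generate_sampleset(m, cem, p, sampler1, n = 6,
                             noise = noise_spec(40, seed = 31))
  expect_identical(ncol(set1$frames_clean), 6L)
  expect_identical(nrow(set1$frames_clean), 2160L)
  expect_length(set1$specs, 6L)
  sampler2 <- phantom_sampler(coarse_spec(), seed = 21)
  set2 <- generate_sampleset(m, cem, p, sampler2, n = 6,
                             noise = noise_spec(40, seed = 31))
  expect_identical(set1$frames_noisy, set2$frames_noisy)
  # stored clean frame equals re-solving on the stored field
  i <- 3L
  f <- conductivity_field(set1$sigma[, i], m)
  v <- unclass(extract_frame(solve_forward(m, f, cem, p), p))
  expect_rel_equal(set1$frames_clean[, i], v, 1e-10)
  # split: exact sizes, partition
  sp <- split_sampleset(set1, ratio = 0.8, seed = 4)
  expect_identical(sum(sp$split == "train"), 4L)   # floor(0.8 * 6)
  expect_identical(sum(sp$split == "validation"), 2L)
  expect_false(any(is.na(sp$split)))
  expect_error(split_sampleset(set1, ratio = 1.2), "ratio")
  # i/o round trip
  path <- file.path(tempdir(), "set.rds")
  write_sampleset(sp, path)
  sp2 <- read_sampleset(path)
  expect_identical(sp2$frames_clean, sp$frames_clean)
  expect_identical(sp2$split, sp$split)
  expect_identical(sp2$manifest, sp$manifest)
  bad <- file.path(tempdir(), "bad.rds")
  saveRDS(list(1), bad)
  expect_error(read_sampleset(bad), "schema")
})

test_that("the 8:2 split of 20,000 samples is 16,000/4,000", {
  set <- structure(list(
    frames_clean = matrix(0, 2L, 20000L), frames_noisy = matrix(0, 2L, 20000L),
    sigma = matrix(1, 2L, 20000L), specs = vector("list", 20000L),
    split = rep(NA_character_, 20000L),
    manifest = list(schema = "eit3d_sampleset_v1")
  ), class = "eit_sampleset")
  sp <- split_sampleset(set, ratio = 0.8, seed = 1)
  expect_identical(sum(sp$split == "train"), 16000L)
  expect_identical(sum(sp$split == "validation"), 4000L)
})
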