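# Adjacent stimulation protocol and the feature reconfiguration.

test_that("protocol has the canonical drive sequence and counts", {
  p <- build_protocol()
  expect_identical(nrow(p$excitations), 48L)
  expect_true(all(vapply(p$measurements, nrow, 1L) == 45L))
  # ring-wise drive cycles (k+1, k), rings in order
  expect_equal(p$excitations[1, ], c(2L, 1L))
  expect_equal(p$excitations[16, ], c(1L, 16L))
  expect_equal(p$excitations[17, ], c(18L, 17L))
  expect_equal(p$excitations[32, ], c(17L, 32L))
  expect_equal(p$excitations[33, ], c(34L, 33L))
  expect_equal(p$excitations[48, ], c(33L, 48L))
})

test_that("measurement scheme reproduces the printed reconfiguration entries", {
  p <- build_protocol()
  g <- function(e) p$measurements[[e]]
  # drive (2,1): rows of the published block structure
  expect_equal(g(1)[1, ], c(3L, 4L)); expect_equal(g(1)[2, ], c(4L, 5L))
  expect_equal(g(1)[13, ], c(15L, 16L))
  expect_equal(g(1)[14, ], c(17L, 18L)); expect_equal(g(1)[15, ], c(18L, 19L))
  expect_equal(g(1)[29, ], c(32L, 17L))
  expect_equal(g(1)[30, ], c(33L, 34L)); expect_equal(g(1)[45, ], c(48L, 33L))
  # drive (3,2)
  expect_equal(g(2)[1, ], c(4L, 5L)); expect_equal(g(2)[13, ], c(16L, 1L))
  expect_equal(g(2)[14, ], c(18L, 19L)); expect_equal(g(2)[29, ], c(17L, 18L))
  expect_equal(g(2)[30, ], c(34L, 35L)); expect_equal(g(2)[45, ], c(33L, 34L))
  # drive (16,15)
  expect_equal(g(15)[1, ], c(1L, 2L)); expect_equal(g(15)[13, ], c(13L, 14L))
  expect_equal(g(15)[14, ], c(31L, 32L)); expect_equal(g(15)[15, ], c(32L, 17L))
  expect_equal(g(15)[29, ], c(30L, 31L))
  expect_equal(g(15)[30, ], c(47L, 48L)); expect_equal(g(15)[31, ], c(48L, 33L))
  expect_equal(g(15)[45, ], c(46L, 47L))
  # drive (18,17): other-ring blocks start at the pair aligned with the
  # drive's lower electrode
  expect_equal(g(17)[1, ], c(1L, 2L)); expect_equal(g(17)[16, ], c(16L, 1L))
  expect_equal(g(17)[17, ], c(19L, 20L)); expect_equal(g(17)[29, ], c(31L, 32L))
  expect_equal(g(17)[30, ], c(33L, 34L)); expect_equal(g(17)[45, ], c(48L, 33L))
  # drive (19,18)
  expect_equal(g(18)[1, ], c(2L, 3L)); expect_equal(g(18)[16, ], c(1L, 2L))
  expect_equal(g(18)[17, ], c(20L, 21L)); expect_equal(g(18)[29, ], c(32L, 17L))
  expect_equal(g(18)[30, ], c(34L, 35L)); expect_equal(g(18)[45, ], c(33L, 34L))
  # drive (17,32) and (34,33) and (33,48) spot checks
  expect_equal(g(32)[1, ], c(16L, 1L)); expect_equal(g(32)[2, ], c(1L, 2L))
  expect_equal(g(32)[17, ], c(18L, 19L)); expect_equal(g(32)[29, ], c(30L, 31L))
  expect_equal(g(32)[30, ], c(48L, 33L))
  expect_equal(g(33)[1, ], c(1L, 2L)); expect_equal(g(33)[17, ], c(17L, 18L))
  expect_equal(g(33)[33, ], c(35L, 36L)); expect_equal(g(33)[45, ], c(47L, 48L))
  expect_equal(g(48)[1, ], c(16L, 1L)); expect_equal(g(48)[17, ], c(32L, 17L))
  expect_equal(g(48)[18, ], c(17L, 18L)); expect_equal(g(48)[33, ], c(34L, 35L))
  expect_equal(g(48)[45, ], c(46L, 47L))
})

test_that("every drive excludes exactly its own pair and the two neighbors", {
  p <- build_protocol()
  for (e in seq_len(48L)) {
    drv <- p$excitations[e, ]
    mm <- p$measurements[[e]]
    # no measured pair shares an electrode with the drive pair
    expect_false(any(mm %in% drv))
    ring <- (drv[2] - 1L) %/% 16L
    ring_ids <- ring * 16L + 1:16
    in_ring <- mm[, 1] %in% ring_ids
    expect_identical(sum(in_ring), 13L)   # 16 - 3 excluded pairs
    expect_identical(sum(!in_ring), 32L)
    # measured pairs are ring-adjacent
    loc <- (mm - 1L) %% 16L
    expect_true(all((loc[, 2] - loc[, 1]) %% 16L == 1L))
  }
})

test_that("frame extraction is differential and symmetric under rotation", {
  p <- build_protocol()
  fx <- coarse_homog()
  # all-equal electrode potentials give a zero frame
  pot0 <- fx$potentials
  pot0$electrode <- matrix(1, 48L, 48L)
  expect_true(all(unclass(extract_frame(pot0, p)) == 0))
  # excitation-major layout: value (e-1)*45+m is U[out1,e]-U[out2,e]
  U <- fx$potentials$electrode
  v <- unclass(fx$frame)
  expect_identical(v[46L], U[p$measurements[[2]][1, 1], 2] -
                     U[p$measurements[[2]][1, 2], 2])
  # pattern mismatch is caught
  pot_bad <- fx$potentials
  pot_bad$excitations <- p$excitations[48:1, ]
  expect_error(extract_frame(pot_bad, p), "pattern")
})

test_that("frame <-> feature map is the exact transposed reshape", {
  v <- seq_len(2160L) + 0.5
  fr <- voltage_frame(v)
  fm <- frame_to_featuremap(fr)
  expect_identical(dim(fm), c(45L, 48L))
  expect_identical(fm[1L, 1L], v[1L])       # first measured value
  expect_identical(fm[45L, 1L], v[45L])
  expect_identical(fm[1L, 2L], v[46L])      # second excitation starts col 2
  back <- featuremap_to_frame(fm)
  expect_identical(as.numeric(back), v)
  # randomized round trip is bit-exact
  set.seed(99)
  for (i in 1:5) {
    r <- rnorm(2160L)
    expect_identical(as.numeric(featuremap_to_frame(frame_to_featuremap(
      voltage_frame(r)))), r)
  }
  ones <- matrix(1, 45L, 48L)
  expect_true(all(unclass(featuremap_to_frame(ones)) == 1))
  expect_error(frame_to_featuremap(1:10), "2,160")
  expect_error(featuremap_to_frame(matrix(0, 48L, 45L)), "45 x 48")
})

test_that("frame CSV round trips values and metadata", {
  set.seed(3)
  fr <- voltage_frame(rnorm(2160L), protocol_hash = "abc123",
                      snr_db = 40, noisy = TRUE)
  path <- file.path(tempdir(), "frame.csv")
  write_frame_csv(fr, path)
  fr2 <- read_frame_csv(path)
  expect_equal(unclass(fr2), unclass(fr), tolerance = 1e-15)
  expect_identical(attr(fr2, "protocol_hash"), "abc123")
  expect_identical(attr(fr2, "snr_db"), 40)
  expect_true(attr(fr2, "noisy"))
})
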