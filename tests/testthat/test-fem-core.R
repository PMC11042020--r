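# Mesh construction, CEM assembly, forward solves and the Jacobian.

test_that("cylinder mesh is geometrically valid and refines monotonically", {
  spec <- cylinder_spec()
  m1 <- build_cylinder_mesh(spec, refinement = 1)
  expect_true(all(m1$element_volumes > 0))
  # total volume within 2% of pi r^2 h (polygonal cross-section bias)
  expect_lt(abs(sum(m1$element_volumes) - pi * 0.05^2 * 0.08) /
              (pi * 0.05^2 * 0.08), 0.02)
  m2 <- build_cylinder_mesh(spec, refinement = 2)
  expect_gt(m2$n_elements, m1$n_elements)
  # boundary face count consistency: every boundary face belongs to 1 tet
  expect_true(nrow(m1$boundary_faces) > 0)
  expect_error(cylinder_spec(radius = -1), "radius")
  expect_error(cylinder_spec(ring_heights = c(2, 4, 9)), "ring_heights")
})

test_that("electrode placement gives 48 disjoint, evenly spaced patches", {
  m <- coarse_mesh()
  expect_length(m$electrode_faces, 48L)
  expect_true(all(lengths(m$electrode_faces) >= 1L))
  idx <- unlist(m$electrode_faces)
  expect_identical(anyDuplicated(idx), 0L)
  # consecutive in-ring electrode centers separated by 22.5 degrees
  centers <- vapply(1:16, function(k) {
    f <- m$boundary_faces[m$electrode_faces[[k]], , drop = FALSE]
    nodes <- m$nodes[as.vector(f), , drop = FALSE]
    ang <- atan2(mean(sin(atan2(nodes[, 2], nodes[, 1]))),
                 mean(cos(atan2(nodes[, 2], nodes[, 1])))) * 180 / pi
    round(ang, 6) %% 360
  }, 0)
  gaps <- diff(c(sort(centers), min(centers) + 360))
  expect_true(all(abs(gaps - 22.5) < 1))
  # band outside the cylinder is rejected
  expect_error(place_electrodes(m, cylinder_spec(ring_heights = c(0.1, 4, 6),
                                                 electrode_height = 0.5)),
               "outside")
})

test_that("assembled CEM system is symmetric, grounded and linear in sigma", {
  m <- coarse_mesh()
  sig <- conductivity_field(350, m, unit = "uS/cm")
  sys <- assemble_system(m, sig)
  S <- sys$matrix
  expect_lt(max(abs(S - Matrix::t(S))) / max(abs(S)), 1e-12)
  # constant potential vector (nodes + electrodes) is annihilated by the
  # sigma-dependent blocks (everything except the grounding row/col)
  n <- nrow(S)
  ones <- c(rep(1, n - 1L), 0)
  r <- as.numeric(S %*% ones)
  expect_lt(max(abs(r[seq_len(n - 1L)])) / max(abs(S)), 1e-10)
  sys2 <- assemble_system(m, conductivity_field(2 * sig$values, m))
  D <- sys2$matrix - 2 * S
  # doubling sigma doubles every sigma-scaled entry; only the grounding
  # entries (fixed at 1) differ
  expect_lt(max(abs(D[seq_len(n - 1L), seq_len(n - 1L)])) / max(abs(S)), 1e-12)
  expect_error(assemble_system(m, conductivity_field(350, mid_mesh(),
                                                     unit = "uS/cm")),
               "bound")
})

test_that("forward solves scale as 1/sigma and satisfy reciprocity", {
  fx <- coarse_homog()
  m <- fx$mesh; p <- build_protocol()
  v1 <- unclass(fx$frame)
  for (cfac in c(0.5, 2, 10)) {
    sig2 <- conductivity_field(fx$sigma$values * cfac, m)
    v2 <- unclass(extract_frame(solve_forward(m, sig2, cem_params(), p), p))
    expect_rel_equal(v2, v1 / cfac, 1e-10)
  }
  expect_identical(ncol(fx$potentials$electrode), 48L)
  # reciprocity on an inhomogeneous field: swap drive and measurement
  set.seed(42)
  sig <- conductivity_field(0.035 * exp(rnorm(m$n_elements, 0, 0.3)), m)
  pot <- solve_forward(m, sig, cem_params(), p)
  U <- pot$electrode; exc <- p$excitations
  for (pair in list(c(3L, 10L), c(5L, 40L), c(17L, 29L))) {
    a <- pair[1]; b <- pair[2]
    t_ab <- U[exc[b, 1], a] - U[exc[b, 2], a]
    t_ba <- U[exc[a, 1], b] - U[exc[a, 2], b]
    expect_lt(abs(t_ab - t_ba) / abs(t_ab), 1e-6)
  }
  expect_error(solve_forward(m, sig, cem_params(),
                             matrix(c(49L, 1L), 1L)), "electrode")
})

test_that("homogeneous frames are 16-fold rotationally consistent", {
  fx <- coarse_homog()
  f <- matrix(unclass(fx$frame), nrow = 45L)
  for (ring_first in c(1L, 17L, 33L)) {
    block <- f[, ring_first:(ring_first + 15L)]
    for (k in 2:16) {
      expect_rel_equal(block[, k], block[, 1], 1e-6)
    }
  }
})

test_that("Jacobian matches finite differences and the Euler identity", {
  m <- coarse_mesh()
  cem <- cem_params(); p <- build_protocol()
  set.seed(7)
  vals <- 0.035 * exp(rnorm(m$n_elements, 0, 0.3))
  sig <- conductivity_field(vals, m)
  J <- compute_jacobian(m, sig, cem, p)$matrix
  expect_identical(dim(J), c(2160L, m$n_elements))
  v <- unclass(extract_frame(solve_forward(m, sig, cem, p), p))
  expect_rel_equal(as.numeric(J %*% vals), -v, 1e-6)
  m2 <- prepare_fem(m, cem)
  h <- 1e-5
  for (e in c(1L, 97L, 205L, 336L)) {
    s1 <- vals; s1[e] <- vals[e] * (1 + h)
    s2 <- vals; s2[e] <- vals[e] * (1 - h)
    va <- unclass(extract_frame(solve_forward(m2, conductivity_field(s1, m2),
                                              cem, p), p))
    vb <- unclass(extract_frame(solve_forward(m2, conductivity_field(s2, m2),
                                              cem, p), p))
    fd <- (va - vb) / (2 * vals[e] * h)
    expect_rel_equal(J[, e], fd, 1e-3)
  }
})

test_that("mesh i/o round trips through .msh and .vtu and rejects other cells", {
  m <- coarse_mesh()
  for (ext in c("msh", "vtu")) {
    path <- file.path(tempdir(), paste0("roundtrip.", ext))
    write_mesh(m, path)
    m2 <- read_mesh(path, spec = coarse_spec())
    expect_equal(m2$nodes, m$nodes, tolerance = 1e-12)
    expect_identical(m2$n_elements, m$n_elements)
    expect_identical(dim(m2$tets), dim(m$tets))
    expect_length(m2$electrode_faces, 48L)
    # electrode assignments preserved (same faces per electrode)
    for (l in c(1L, 24L, 48L)) {
      expect_setequal(
        apply(m2$boundary_faces[m2$electrode_faces[[l]], , drop = FALSE],
              1, paste, collapse = "-"),
        apply(m$boundary_faces[m$electrode_faces[[l]], , drop = FALSE],
              1, paste, collapse = "-"))
    }
  }
  # hexahedral cells are rejected
  hexa <- file.path(tempdir(), "hexa.msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", "8",
               sprintf("%d %g %g %g", 1:8,
                       c(0, 1, 1, 0, 0, 1, 1, 0), c(0, 0, 1, 1, 0, 0, 1, 1),
                       c(0, 0, 0, 0, 1, 1, 1, 1)),
               "$EndNodes", "$Elements", "1",
               "1 5 2 0 0 1 2 3 4 5 6 7 8", "$EndElements"), hexa)
  expect_error(read_mesh(hexa), "unsupported")
  # missing electrode metadata: warning, electrodes unset
  m_no <- m; m_no$electrode_faces <- NULL
  bare <- file.path(tempdir(), "bare.vtu")
  write_mesh(m_no, bare)
  expect_warning(mb <- read_mesh(bare), "electrode")
  expect_null(mb$electrode_faces)
})

test_that("conductivity fields validate unit conversion and binding", {
  m <- coarse_mesh()
  f <- conductivity_field(350, m, unit = "uS/cm")
  expect_equal(f$values, rep(0.035, m$n_elements))
  expect_error(conductivity_field(c(1, 2), m), "length")
  expect_error(conductivity_field(-1, m), "finite and > 0")
  expect_equal(uScm_to_Sm(Sm_to_uScm(0.42)), 0.42)
})
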