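# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Coarse 336-element mesh with full-sector electrodes: cheap forward
# solves and a tractable finite-difference Jacobian.
coarse_mesh <- function() {
  if (is.null(.fixtures$coarse)) {
    spec <- cylinder_spec(electrode_angular_width = 22.5)
    .fixtures$coarse <- build_cylinder_mesh(spec, refinement = 1,
                                            na = 16, nr = 1)
  }
  .fixtures$coarse
}

coarse_spec <- function() cylinder_spec(electrode_angular_width = 22.5)

# Mid-size 2,016-element mesh (<= 3,000) for solver-physics and
# Gauss-Newton checks.
mid_mesh <- function() {
  if (is.null(.fixtures$mid)) {
    .fixtures$mid <- build_cylinder_mesh(cylinder_spec(), refinement = 1,
                                         na = 32, nr = 2)
  }
  .fixtures$mid
}

# One cached forward solution on the coarse mesh (homogeneous saline).
coarse_homog <- function() {
  if (is.null(.fixtures$homog)) {
    m <- coarse_mesh()
    sig <- conductivity_field(350, m, unit = "uS/cm")
    pot <- solve_forward(m, sig, cem_params(), build_protocol())
    .fixtures$homog <- list(mesh = m, sigma = sig, potentials = pot,
                            frame = extract_frame(pot, build_protocol()))
  }
  .fixtures$homog
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(max(abs(y)), .Machine$double.xmin), tol)
}
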