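#' Complete-electrode-model parameters
#'
#' The electrode--medium interface is modelled as a thin layer of the
#' medium itself: the per-area contact admittance of a face is
#' `sigma_face / l_c`, where the equivalent gap `l_c` is parameterized by
#' the contact impedance the interface presents at the nominal 350 uS/cm
#' background (`l_c = contact_impedance * 0.035 S/m`). With this
#' convention the assembled system is exactly homogeneous of degree one
#' in the conductivity field, so boundary frames obey
#' `v(c * sigma) = v(sigma) / c` and the Euler identity
#' `J %*% sigma = -v` to solver precision.
#'
#' @param contact_impedance per-electrode contact impedance at the nominal
#'   background, in ohm m^2 (scalar or one value per electrode;
#'   default 1e-4).
#' @param current_amplitude drive current in amperes (default 1e-3).
#' @return an object of class `eit_cem`.
#' @export
cem_params <- function(contact_impedance = 1e-4, current_amplitude = 1e-3) {
  stop_if(!is.numeric(contact_impedance) || any(contact_impedance <= 0),
          "contact_impedance must be > 0")
  stop_if(!is_number(current_amplitude) || current_amplitude <= 0,
          "current_amplitude must be > 0")
  structure(list(contact_impedance = contact_impedance,
                 current_amplitude = current_amplitude),
            class = "eit_cem")
}

# Barycentric gradients and volumes for all tets, vectorized via the
# adjugate of the 3x3 edge matrix. Returns grads as an N x 4 x 3 array.
fem_geometry <- function(mesh) {
  if (!is.null(mesh$.fem_geom)) return(mesh$.fem_geom)
  nodes <- mesh$nodes; tets <- mesh$tets
  p1 <- nodes[tets[, 1L], , drop = FALSE]
  a <- nodes[tets[, 2L], , drop = FALSE] - p1
  b <- nodes[tets[, 3L], , drop = FALSE] - p1
  c_ <- nodes[tets[, 4L], , drop = FALSE] - p1
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  # columns of inv(A) where A has rows a, b, c: grad of barycentric 2..4
  inv <- array(0, c(nrow(tets), 3L, 3L))
  inv[, 1L, 1L] <-  (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) / det
  inv[, 2L, 1L] <- -(b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) / det
  inv[, 3L, 1L] <-  (b[, 1] * c_[, 2] - b[, 2] * c_[, 1]) / det
  inv[, 1L, 2L] <- -(a[, 2] * c_[, 3] - a[, 3] * c_[, 2]) / det
  inv[, 2L, 2L] <-  (a[, 1] * c_[, 3] - a[, 3] * c_[, 1]) / det
  inv[, 3L, 2L] <- -(a[, 1] * c_[, 2] - a[, 2] * c_[, 1]) / det
  inv[, 1L, 3L] <-  (a[, 2] * b[, 3] - a[, 3] * b[, 2]) / det
  inv[, 2L, 3L] <- -(a[, 1] * b[, 3] - a[, 3] * b[, 1]) / det
  inv[, 3L, 3L] <-  (a[, 1] * b[, 2] - a[, 2] * b[, 1]) / det
  grads <- array(0, c(nrow(tets), 4L, 3L))
  grads[, 2L, ] <- inv[, , 1L]
  grads[, 3L, ] <- inv[, , 2L]
  grads[, 4L, ] <- inv[, , 3L]
  grads[, 1L, ] <- -(grads[, 2L, ] + grads[, 3L, ] + grads[, 4L, ])
  list(grads = grads, volume = det / 6)
}

triangle_area <- function(nodes, face) {
  u <- nodes[face[2L], ] - nodes[face[1L], ]
  v <- nodes[face[3L], ] - nodes[face[1L], ]
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  sqrt(sum(w^2)) / 2
}

# Geometric triplet lists: the full CEM system (conduction + contact) is
# sum_e sigma_e * S_geom_e plus the zero-mean grounding constraint.
# Triplets carry (i, j, geometric value, owning element).
cem_triplets <- function(mesh, cem) {
  stop_if(is.null(mesh$electrode_faces), "mesh has no electrode patches")
  geom <- fem_geometry(mesh)
  N <- mesh$n_elements
  nn <- nrow(mesh$nodes)
  nel <- length(mesh$electrode_faces)

  # conduction: K_e = V_e * G_e %*% t(G_e), 16 entries per element
  GG <- array(0, c(N, 4L, 4L))
  for (ii in 1:4) for (jj in 1:4) {
    GG[, ii, jj] <- geom$volume *
      (geom$grads[, ii, 1L] * geom$grads[, jj, 1L] +
       geom$grads[, ii, 2L] * geom$grads[, jj, 2L] +
       geom$grads[, ii, 3L] * geom$grads[, jj, 3L])
  }
  idx <- expand.grid(ii = 1:4, jj = 1:4)
  i_c <- as.vector(mesh$tets[, idx$ii])
  j_c <- as.vector(mesh$tets[, idx$jj])
  v_c <- as.vector(GG)
  e_c <- rep.int(seq_len(N), 16L)

  # contact: thin-layer interface, admittance sigma_owner / l_c per area
  zl <- rep(cem$contact_impedance, length.out = nel)
  lc <- zl * SIGMA_NOMINAL # equivalent gap, metres
  ci <- cj <- cv <- ce <- list()
  owner_all <- mesh$face_owner
  for (l in seq_len(nel)) {
    for (f in mesh$electrode_faces[[l]]) {
      face <- mesh$boundary_faces[f, ]
      A <- triangle_area(mesh$nodes, face)
      own <- owner_all[f]
      el_row <- nn + l
      # node-node surface mass
      mm <- A / 12 * (matrix(1, 3, 3) + diag(3))
      ci[[length(ci) + 1L]] <- rep(face, each = 3L)
      cj[[length(cj) + 1L]] <- rep(face, times = 3L)
      cv[[length(cv) + 1L]] <- as.vector(mm) / lc[l]
      ce[[length(ce) + 1L]] <- rep.int(own, 9L)
      # node-electrode coupling (both halves)
      ci[[length(ci) + 1L]] <- c(face, rep(el_row, 3L))
      cj[[length(cj) + 1L]] <- c(rep(el_row, 3L), face)
      cv[[length(cv) + 1L]] <- rep(-A / 3 / lc[l], 6L)
      ce[[length(ce) + 1L]] <- rep.int(own, 6L)
      # electrode diagonal
      ci[[length(ci) + 1L]] <- el_row
      cj[[length(cj) + 1L]] <- el_row
      cv[[length(cv) + 1L]] <- A / lc[l]
      ce[[length(ce) + 1L]] <- own
    }
  }
  list(i = c(i_c, unlist(ci)), j = c(j_c, unlist(cj)),
       val = c(v_c, unlist(cv)), elem = c(e_c, unlist(ce)),
       n_nodes = nn, n_electrodes = nel, dim = nn + nel + 1L)
}

#' Cache the geometric CEM triplets on a mesh
#'
#' Repeated forward solves on the same mesh (e.g. dataset generation)
#' reassemble the system for each new conductivity field; caching the
#' sigma-independent geometric triplets makes that a vector scaling.
#'
#' @param mesh an `eit_mesh` with electrodes.
#' @param cem a [cem_params()].
#' @return the mesh with the triplet cache attached.
#' @export
prepare_fem <- function(mesh, cem = cem_params()) {
  mesh$.cem_triplets <- cem_triplets(mesh, cem)
  mesh$.cem_hash <- fingerprint(cem)
  mesh
}

cached_triplets <- function(mesh, cem) {
  if (!is.null(mesh$.cem_triplets) &&
      identical(mesh$.cem_hash, fingerprint(cem))) {
    return(mesh$.cem_triplets)
  }
  cem_triplets(mesh, cem)
}

#' Assemble the complete-electrode-model linear system
#'
#' Builds the symmetric CEM stiffness system for a conductivity field:
#' the interior conduction block plus the electrode contact blocks, with
#' a Lagrange-multiplier row enforcing the zero-mean electrode-potential
#' grounding convention. Differential measurements are independent of
#' that convention.
#'
#' @param mesh an `eit_mesh` with electrodes placed.
#' @param sigma an `eit_field` bound to `mesh`.
#' @param cem a [cem_params()].
#' @return a list with the sparse system `matrix`, dimensions, and the
#'   cached geometric triplets (class `eit_system`).
#' @export
assemble_system <- function(mesh, sigma, cem = cem_params()) {
  check_binding(sigma, mesh)
  tri <- cached_triplets(mesh, cem)
  x <- tri$val * sigma$values[tri$elem]
  n <- tri$dim
  i <- c(tri$i, rep(n, tri$n_electrodes), tri$n_nodes + seq_len(tri$n_electrodes))
  j <- c(tri$j, tri$n_nodes + seq_len(tri$n_electrodes), rep(n, tri$n_electrodes))
  x <- c(x, rep(1, 2L * tri$n_electrodes))
  S <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  structure(list(matrix = S, triplets = tri, n_nodes = tri$n_nodes,
                 n_electrodes = tri$n_electrodes, mesh_hash = mesh$mesh_hash),
            class = "eit_system")
}

#' Adjacent-pair excitation pattern and drive matrix
#'
#' @param system an `eit_system` from [assemble_system()].
#' @param excitations an excitation pattern (see [build_protocol()]); a
#'   48 x 2 matrix of (in1, in2) electrode pairs.
#' @param current drive current amplitude (A).
#' @noRd
drive_matrix <- function(system, excitations, current) {
  nexc <- nrow(excitations)
  B <- matrix(0, system$triplets$dim, nexc)
  for (e in seq_len(nexc)) {
    B[system$n_nodes + excitations[e, 1L], e] <- current
    B[system$n_nodes + excitations[e, 2L], e] <- -current
  }
  B
}

#' Solve the EIT forward problem
#'
#' For every drive pair of the excitation pattern, injects plus/minus the
#' drive current on the pair and solves the CEM system by a sparse
#' factorization; the solution is accepted only when the relative
#' residual is at most 1e-10 (one step of iterative refinement is applied
#' if needed).
#'
#' @param mesh an `eit_mesh` with electrodes.
#' @param sigma an `eit_field` bound to `mesh`.
#' @param cem a [cem_params()].
#' @param excitations a 48 x 2 matrix of drive pairs, or an
#'   `eit_protocol` (its excitation pattern is used).
#' @return an object of class `eit_potentials` with per-excitation nodal
#'   potentials and electrode potentials (volts).
#' @examples
#' m <- build_cylinder_mesh(cylinder_spec(), 1, na = 16)
#' @export
solve_forward <- function(mesh, sigma, cem = cem_params(),
                          excitations = build_protocol()) {
  if (inherits(excitations, "eit_protocol")) excitations <- excitations$excitations
  stop_if(max(excitations) > length(mesh$electrode_faces),
          "excitation references an electrode the mesh does not have")
  sys <- assemble_system(mesh, sigma, cem)
  B <- drive_matrix(sys, excitations, cem$current_amplitude)
  S <- sys$matrix
  X <- tryCatch(as.matrix(Matrix::solve(S, B)),
                error = function(e) stop("forward solve failed (singular system?): ",
                                         conditionMessage(e), call. = FALSE))
  res <- S %*% X - B
  rel <- sqrt(sum(res^2)) / sqrt(sum(B^2))
  if (rel > 1e-10) { # one refinement pass
    X <- X + as.matrix(Matrix::solve(S, -res))
    res <- S %*% X - B
    rel <- sqrt(sum(res^2)) / sqrt(sum(B^2))
  }
  stop_if(rel > 1e-10, sprintf("linear solve residual %.3g exceeds 1e-10", rel))
  nn <- sys$n_nodes; nel <- sys$n_electrodes
  structure(list(
    nodal = X[seq_len(nn), , drop = FALSE],
    electrode = X[nn + seq_len(nel), , drop = FALSE],
    full = X,
    excitations = excitations,
    current = cem$current_amplitude,
    mesh_hash = mesh$mesh_hash
  ), class = "eit_potentials")
}

#' @export
print.eit_potentials <- function(x, ...) {
  cat(sprintf("<eit_potentials> %d excitations, %d nodes, %d electrodes\n",
              ncol(x$nodal), nrow(x$nodal), nrow(x$electrode)))
  invisible(x)
}

#' Sensitivity (Jacobian) matrix of the measurement frame
#'
#' Computes `J[l, n] = d v_l / d sigma_n` for the full frame by the
#' adjoint-field formulation: for measurement `l` (drive `d`, measured
#' adjacent pair `m`) and element `n`,
#' `J[l, n] = -(x_m' dS/dsigma_n x_d)`, where `dS/dsigma_n` is the exact
#' derivative of the assembled system (the per-element gradient-product
#' volume term plus the thin-layer interface term for elements owning
#' electrode faces). The adjacent measurement fields reuse the drive
#' solutions, since every measured pair is also a drive pair. The sign
#' convention satisfies `delta v ~ J delta sigma` and the Euler identity
#' `J %*% sigma = -v`.
#'
#' @inheritParams solve_forward
#' @param protocol an `eit_protocol` from [build_protocol()].
#' @return an object of class `eit_jacobian`: the dense `L x N` matrix
#'   plus protocol and mesh fingerprints.
#' @export
compute_jacobian <- function(mesh, sigma, cem = cem_params(),
                             protocol = build_protocol()) {
  stop_if(!inherits(protocol, "eit_protocol"), "protocol must be an eit_protocol")
  stop_if(max(protocol$excitations) > length(mesh$electrode_faces),
          "protocol references an electrode the mesh does not have")
  pot <- solve_forward(mesh, sigma, cem, protocol$excitations)
  X <- pot$full
  I0 <- cem$current_amplitude
  geom <- fem_geometry(mesh)
  N <- mesh$n_elements
  nexc <- nrow(protocol$excitations)
  nmeas <- nrow(protocol$measurements[[1L]])

  # per-element gradients of every drive solution: 3 matrices N x nexc
  U <- array(X[as.vector(mesh$tets), , drop = FALSE],
             c(N, 4L, nexc))
  G <- lapply(1:3, function(a) {
    geom$grads[, 1L, a] * U[, 1L, ] + geom$grads[, 2L, a] * U[, 2L, ] +
      geom$grads[, 3L, a] * U[, 3L, ] + geom$grads[, 4L, a] * U[, 4L, ]
  })

  # map each measured pair to the drive-pair index whose unit-current
  # field it reuses: measured (out1, out2) = reversed drive pair q
  pair_index <- integer(0)
  key <- paste(protocol$excitations[, 1L], protocol$excitations[, 2L])
  meas_q <- lapply(protocol$measurements, function(mm) {
    q <- match(paste(mm[, 2L], mm[, 1L]), key)
    stop_if(anyNA(q), "measured pair is not an adjacent drive pair")
    q
  })

  # interface contribution: per owning element a 48 x 48 pair-product
  tri <- cached_triplets(mesh, cem)
  contact <- tri$val[-seq_len(16L * N)]
  ci <- tri$i[-seq_len(16L * N)]
  cj <- tri$j[-seq_len(16L * N)]
  ce <- tri$elem[-seq_len(16L * N)]
  face_elems <- unique(ce)
  Cmap <- new.env(parent = emptyenv())
  for (e in face_elems) {
    sel <- which(ce == e)
    rows <- unique(c(ci[sel], cj[sel]))
    Sg <- matrix(0, length(rows), length(rows))
    ri <- match(ci[sel], rows); rj <- match(cj[sel], rows)
    for (t in seq_along(sel)) Sg[ri[t], rj[t]] <- Sg[ri[t], rj[t]] + contact[sel[t]]
    Xr <- X[rows, , drop = FALSE]
    assign(as.character(e), crossprod(Xr, Sg %*% Xr), envir = Cmap)
  }

  J <- matrix(0, nexc * nmeas, N)
  V <- geom$volume
  for (d in seq_len(nexc)) {
    q <- meas_q[[d]]
    block <- (G[[1L]][, q, drop = FALSE] * G[[1L]][, d] +
              G[[2L]][, q, drop = FALSE] * G[[2L]][, d] +
              G[[3L]][, q, drop = FALSE] * G[[3L]][, d]) * V
    rows <- (d - 1L) * nmeas + seq_len(nmeas)
    J[rows, ] <- t(block) / I0
    for (e in face_elems) {
      Ce <- get(as.character(e), envir = Cmap)
      J[rows, e] <- J[rows, e] + Ce[q, d] / I0
    }
  }
  stop_if(any(!is.finite(J)), "non-finite Jacobian entries")
  structure(list(matrix = J,
                 protocol_hash = protocol$protocol_hash,
                 mesh_hash = mesh$mesh_hash),
            class = "eit_jacobian")
}

#' @export
print.eit_jacobian <- function(x, ...) {
  cat(sprintf("<eit_jacobian> %d x %d\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}
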