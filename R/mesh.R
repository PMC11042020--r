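#' Cylindrical measurement-domain specification
#'
#' Describes the cylindrical tank geometry and its three rings of 16
#' boundary electrodes. Lengths are in centimetres (the configuration
#' convention); meshes store coordinates in metres.
#'
#' @param radius cylinder radius in cm (default 5).
#' @param height cylinder height in cm (default 8).
#' @param ring_heights axial positions (cm) of the three electrode rings,
#'   strictly inside `(0, height)`. Default `c(2, 4, 6)`: evenly spaced
#'   interior planes.
#' @param electrodes_per_ring electrodes per ring (default 16).
#' @param electrode_angular_width angular width of each electrode patch in
#'   degrees (default 10).
#' @param electrode_height axial extent of each electrode patch in cm
#'   (default 0.5).
#' @return an object of class `eit_cylinder_spec`.
#' @examples
#' spec <- cylinder_spec()
#' spec$radius
#' @export
cylinder_spec <- function(radius = 5, height = 8,
                          ring_heights = c(2, 4, 6),
                          electrodes_per_ring = 16L,
                          electrode_angular_width = 10,
                          electrode_height = 0.5) {
  stop_if(!is_number(radius) || radius <= 0, "radius must be > 0")
  stop_if(!is_number(height) || height <= 0, "height must be > 0")
  stop_if(!is.numeric(ring_heights) || length(ring_heights) < 1,
          "ring_heights must be a numeric vector")
  stop_if(any(ring_heights <= 0) || any(ring_heights >= height),
          "all ring_heights must lie strictly inside (0, height)")
  stop_if(!is_count(electrodes_per_ring),
          "electrodes_per_ring must be a positive integer")
  stop_if(!is_number(electrode_angular_width) || electrode_angular_width <= 0 ||
            electrode_angular_width > 360 / electrodes_per_ring * 2,
          "electrode_angular_width out of range")
  stop_if(!is_number(electrode_height) || electrode_height <= 0,
          "electrode_height must be > 0")
  structure(list(
    radius = radius, height = height,
    ring_heights = sort(as.numeric(ring_heights)),
    electrodes_per_ring = as.integer(electrodes_per_ring),
    electrode_angular_width = electrode_angular_width,
    electrode_height = electrode_height
  ), class = "eit_cylinder_spec")
}

#' @export
print.eit_cylinder_spec <- function(x, ...) {
  cat(sprintf(
    "<eit_cylinder_spec> R = %g cm, H = %g cm, %d electrodes (%d x %d rings)\n",
    x$radius, x$height, n_electrodes(x), x$electrodes_per_ring,
    length(x$ring_heights)))
  invisible(x)
}

n_electrodes <- function(spec) spec$electrodes_per_ring * length(spec$ring_heights)

# Axial node levels: the domain top/bottom and both rims of every electrode
# band are mandatory levels (so electrode patches are resolved by whole
# faces at any refinement); the remaining gaps are filled close to the
# uniform target spacing.
z_levels <- function(spec, refinement) {
  target <- spec$height / (2 * (refinement + 1))
  hw <- spec$electrode_height / 2
  mand <- sort(unique(c(0, spec$height,
                        spec$ring_heights - hw, spec$ring_heights + hw)))
  mand <- mand[mand >= 0 & mand <= spec$height]
  out <- numeric(0)
  for (i in seq_len(length(mand) - 1L)) {
    gap <- mand[i + 1L] - mand[i]
    k <- max(1L, ceiling(gap / target - 1e-9))
    out <- c(out, mand[i] + gap * (seq_len(k) - 1L) / k)
  }
  c(out, spec$height)
}

# 2-D disk triangulation on one z-level: a centre node, `nr` concentric
# rings of `na` nodes.  Returns per-level node offsets (1-based), triangle
# vertex triples and, per triangle edge, the "up" flag used by the
# rotation-equivariant prism splitting rule (edges are oriented
# centre->out, inner->outer and counterclockwise, which never produces a
# cyclic prism configuration).
disk_triangulation <- function(nr, na) {
  node_of <- function(i, j) { # ring i in 1..nr, azimuthal j (any integer)
    1L + (i - 1L) * na + (j %% na) + 1L
  }
  tri <- list(); ups <- list()
  for (j in seq_len(na) - 1L) { # core fan
    tri[[length(tri) + 1L]] <- c(1L, node_of(1L, j), node_of(1L, j + 1L))
    ups[[length(ups) + 1L]] <- c(TRUE, TRUE, FALSE)
  }
  if (nr > 1L) {
    for (i in seq_len(nr - 1L)) {
      for (j in seq_len(na) - 1L) {
        a <- node_of(i, j); b <- node_of(i, j + 1L)
        A <- node_of(i + 1L, j); B <- node_of(i + 1L, j + 1L)
        # diagonal a--B (inner-left to outer-right), intrinsic to the quad
        tri[[length(tri) + 1L]] <- c(a, B, A)
        ups[[length(ups) + 1L]] <- c(TRUE, FALSE, FALSE)
        tri[[length(tri) + 1L]] <- c(a, b, B)
        ups[[length(ups) + 1L]] <- c(TRUE, TRUE, FALSE)
      }
    }
  }
  list(tri = do.call(rbind, tri), ups = do.call(rbind, ups),
       n_nodes = 1L + nr * na)
}

# Split one triangular prism into 3 tetrahedra given the per-edge "up"
# flags (up[i]: the diagonal on the lateral quad over edge (v_i, v_{i+1})
# rises from bottom of v_i to top of v_{i+1}).
split_prism <- function(b, t, ups) {
  rot <- 0L
  while (!(ups[1L] && !ups[3L]) && rot < 3L) {
    b <- b[c(2L, 3L, 1L)]; t <- t[c(2L, 3L, 1L)]; ups <- ups[c(2L, 3L, 1L)]
    rot <- rot + 1L
  }
  stop_if(!(ups[1L] && !ups[3L]), "cyclic prism configuration")
  if (ups[2L]) {
    rbind(c(b[1L], b[2L], b[3L], t[3L]),
          c(b[1L], b[2L], t[3L], t[2L]),
          c(b[1L], t[1L], t[2L], t[3L]))
  } else {
    rbind(c(b[1L], b[2L], b[3L], t[2L]),
          c(b[1L], b[3L], t[3L], t[2L]),
          c(b[1L], t[1L], t[2L], t[3L]))
  }
}

tet_geometry <- function(nodes, tets) {
  p1 <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3L], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4L], , drop = FALSE] - p1
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
         e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
         e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  centroids <- (nodes[tets[, 1L], , drop = FALSE] +
                nodes[tets[, 2L], , drop = FALSE] +
                nodes[tets[, 3L], , drop = FALSE] +
                nodes[tets[, 4L], , drop = FALSE]) / 4
  list(det = det, volume = det / 6, centroids = centroids)
}

#' Build a structured tetrahedral cylinder mesh
#'
#' Layered, azimuthally symmetric mesher: each z-layer carries the same
#' fan-plus-annulus disk triangulation, and every vertical prism is split
#' into three tetrahedra by an intrinsic (rotation-equivariant) diagonal
#' rule, so a mesh with `na` azimuthal divisions is exactly invariant
#' under rotation by `360/na` degrees. With the default `na = 48`
#' (a multiple of 16) forward solutions on homogeneous fields are
#' 16-fold rotationally consistent to solver precision.
#'
#' @param spec an [cylinder_spec()].
#' @param refinement positive integer controlling radial and axial
#'   resolution; the element count grows monotonically with it.
#' @param na azimuthal divisions (default `3 * electrodes_per_ring`);
#'   must be a multiple of `electrodes_per_ring`.
#' @param nr radial divisions (default `refinement + 1`).
#' @param place_electrodes if `TRUE` (default) electrode patches are
#'   assigned via [place_electrodes()].
#' @return an object of class `eit_mesh`: nodes (metres), tetrahedra,
#'   boundary faces, electrode face sets, element centroids and volumes.
#' @examples
#' m <- build_cylinder_mesh(cylinder_spec(), refinement = 1)
#' m$n_elements
#' @export
build_cylinder_mesh <- function(spec, refinement = 1L, na = NULL, nr = NULL,
                                place_electrodes = TRUE) {
  stop_if(!inherits(spec, "eit_cylinder_spec"), "spec must be an eit_cylinder_spec")
  stop_if(!is_count(refinement), "refinement must be a positive integer")
  if (is.null(na)) na <- 3L * spec$electrodes_per_ring
  if (is.null(nr)) nr <- refinement + 1L
  stop_if(na %% spec$electrodes_per_ring != 0L,
          "na must be a multiple of electrodes_per_ring")
  stop_if(!is_count(nr), "nr must be a positive integer")

  zs <- z_levels(spec, refinement) / 100 # m
  R <- spec$radius / 100
  disk <- disk_triangulation(nr, na)
  npl <- disk$n_nodes
  nlev <- length(zs)

  theta <- 2 * pi * (seq_len(na) - 1L) / na
  ring_xy <- do.call(rbind, lapply(seq_len(nr), function(i) {
    r <- R * i / nr
    cbind(r * cos(theta), r * sin(theta))
  }))
  layer_xy <- rbind(c(0, 0), ring_xy)
  nodes <- do.call(rbind, lapply(zs, function(z) cbind(layer_xy, z)))
  dimnames(nodes) <- NULL

  ntri <- nrow(disk$tri)
  tets <- vector("list", (nlev - 1L) * ntri)
  k <- 0L
  for (l in seq_len(nlev - 1L)) {
    off_b <- (l - 1L) * npl; off_t <- l * npl
    for (ti in seq_len(ntri)) {
      k <- k + 1L
      tets[[k]] <- split_prism(disk$tri[ti, ] + off_b,
                               disk$tri[ti, ] + off_t,
                               disk$ups[ti, ])
    }
  }
  tets <- do.call(rbind, tets)

  geo <- tet_geometry(nodes, tets)
  flip <- geo$det < 0
  if (any(flip)) { # enforce positive orientation
    tmp <- tets[flip, 3L]; tets[flip, 3L] <- tets[flip, 4L]; tets[flip, 4L] <- tmp
    geo <- tet_geometry(nodes, tets)
  }
  stop_if(any(geo$det <= 0), "degenerate tetrahedra produced")

  bf <- boundary_faces_of(tets)
  mesh <- structure(list(
    nodes = nodes, tets = tets,
    boundary_faces = bf$faces, face_owner = bf$owner,
    electrode_faces = NULL,
    element_centroids = geo$centroids, element_volumes = geo$volume,
    n_elements = nrow(tets), spec = spec,
    na = na, nr = nr, z_levels = zs
  ), class = "eit_mesh")
  mesh$mesh_hash <- fingerprint(list(nodes, tets))
  if (place_electrodes) mesh <- place_electrodes(mesh, spec)
  mesh
}

# All boundary faces (each appearing in exactly one tet) plus the owning
# element of each; also validates that interior faces are shared by
# exactly two tets.
boundary_faces_of <- function(tets) {
  m <- nrow(tets)
  faces <- rbind(tets[, c(1L, 2L, 3L)], tets[, c(1L, 2L, 4L)],
                 tets[, c(1L, 3L, 4L)], tets[, c(2L, 3L, 4L)])
  owner <- rep.int(seq_len(m), 4L)
  sorted <- t(apply(faces, 1L, sort))
  key <- paste(sorted[, 1L], sorted[, 2L], sorted[, 3L])
  cnt <- table(key)
  stop_if(any(cnt > 2), "non-manifold mesh: face shared by > 2 tets")
  single <- key %in% names(cnt)[cnt == 1L]
  list(faces = sorted[single, , drop = FALSE], owner = owner[single])
}

#' Assign electrode patches to a mesh
#'
#' Selects, for each of the 48 electrodes (16 per ring, rings ordered by
#' ascending height, angular positions starting at 0 degrees and advancing
#' counterclockwise in steps of 360/16 = 22.5 degrees), the lateral
#' boundary faces whose centroid lies within the electrode's angular
#' window and axial band. The discrete electrode is the union of those
#' faces, so its effective area is mesh-quantized.
#'
#' @param mesh an `eit_mesh` built from `spec`.
#' @param spec the matching [cylinder_spec()].
#' @return the mesh with `electrode_faces` populated (a list of
#'   boundary-face row indices per electrode).
#' @export
place_electrodes <- function(mesh, spec = mesh$spec) {
  stop_if(!inherits(mesh, "eit_mesh"), "mesh must be an eit_mesh")
  stop_if(any(spec$ring_heights + spec$electrode_height / 2 > spec$height) ||
            any(spec$ring_heights - spec$electrode_height / 2 < 0),
          "electrode band extends outside the lateral surface")
  R <- spec$radius / 100
  bf <- mesh$boundary_faces
  rads <- sqrt(mesh$nodes[, 1L]^2 + mesh$nodes[, 2L]^2)
  lateral <- rads[bf[, 1L]] > R * (1 - 1e-8) &
             rads[bf[, 2L]] > R * (1 - 1e-8) &
             rads[bf[, 3L]] > R * (1 - 1e-8)
  cx <- (mesh$nodes[bf[, 1L], 1L] + mesh$nodes[bf[, 2L], 1L] + mesh$nodes[bf[, 3L], 1L]) / 3
  cy <- (mesh$nodes[bf[, 1L], 2L] + mesh$nodes[bf[, 2L], 2L] + mesh$nodes[bf[, 3L], 2L]) / 3
  cz <- (mesh$nodes[bf[, 1L], 3L] + mesh$nodes[bf[, 2L], 3L] + mesh$nodes[bf[, 3L], 3L]) / 3
  ang <- (atan2(cy, cx) * 180 / pi) %% 360

  epr <- spec$electrodes_per_ring
  nel <- n_electrodes(spec)
  efaces <- vector("list", nel)
  for (r in seq_along(spec$ring_heights)) {
    zc <- spec$ring_heights[r] / 100
    hw <- spec$electrode_height / 2 / 100
    for (k in seq_len(epr)) {
      th <- (k - 1L) * 360 / epr
      sel <- which(lateral &
                     ang_dist(ang, th) <= spec$electrode_angular_width / 2 + 1e-9 &
                     abs(cz - zc) <= hw + 1e-9)
      stop_if(length(sel) == 0L,
              "empty electrode patch (electrode ", (r - 1L) * epr + k,
              "): refine the mesh or widen the electrode")
      efaces[[(r - 1L) * epr + k]] <- sel
    }
  }
  all_idx <- unlist(efaces)
  stop_if(anyDuplicated(all_idx) > 0L, "electrode patches overlap")
  mesh$electrode_faces <- efaces
  mesh$mesh_hash <- fingerprint(list(mesh$nodes, mesh$tets, efaces))
  mesh
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("<eit_mesh> %d nodes, %d tetrahedra, %d boundary faces, %s\n",
              nrow(x$nodes), x$n_elements, nrow(x$boundary_faces),
              if (is.null(x$electrode_faces)) "no electrodes"
              else sprintf("%d electrodes", length(x$electrode_faces))))
  invisible(x)
}

#' Per-element conductivity field bound to a mesh
#'
#' @param values per-element conductivity; interpreted in S/m when
#'   `unit = "S/m"` (default) or converted from uS/cm when
#'   `unit = "uS/cm"`. A scalar is recycled to all elements.
#' @param mesh the `eit_mesh` the field lives on.
#' @param unit `"S/m"` or `"uS/cm"`.
#' @return an object of class `eit_field` (values in S/m, with the mesh
#'   fingerprint attached).
#' @examples
#' m <- build_cylinder_mesh(cylinder_spec(), 1)
#' bg <- conductivity_field(350, m, unit = "uS/cm")
#' @export
conductivity_field <- function(values, mesh, unit = c("S/m", "uS/cm")) {
  unit <- match.arg(unit)
  stop_if(!inherits(mesh, "eit_mesh"), "mesh must be an eit_mesh")
  if (length(values) == 1L) values <- rep(values, mesh$n_elements)
  stop_if(length(values) != mesh$n_elements,
          "field length must equal mesh n_elements")
  if (unit == "uS/cm") values <- uScm_to_Sm(values)
  stop_if(any(!is.finite(values)) || any(values <= 0),
          "conductivities must be finite and > 0")
  structure(list(values = as.numeric(values), mesh_hash = mesh$mesh_hash),
            class = "eit_field")
}

#' @export
print.eit_field <- function(x, ...) {
  cat(sprintf("<eit_field> %d elements, sigma in [%.3g, %.3g] S/m\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

check_binding <- function(field, mesh) {
  stop_if(!inherits(field, "eit_field"), "not an eit_field")
  stop_if(!identical(field$mesh_hash, mesh$mesh_hash),
          "conductivity field is not bound to this mesh")
  invisible(TRUE)
}
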