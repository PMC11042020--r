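# Exact rotational symmetry of the measurement setup.
#
# The structured mesher is equivariant under rotation by one electrode
# spacing (360/16 degrees) and the adjacent protocol enumerates drives
# and measured pairs in a rotation-equivariant order. Rotating a phantom
# by s spacings therefore permutes both the element vector and the
# boundary frame exactly; training uses this as loss-free data
# augmentation.

#' Exact rotation permutations of elements and frame positions
#'
#' For each rotation by `s = 0..15` electrode spacings, computes the
#' element permutation `eperm` and frame permutation `fperm` such that a
#' phantom rotated by `s` spacings has field `sigma[eperm]` and frame
#' `v[fperm]`. Requires a mesh whose azimuthal division count is a
#' multiple of 16 (the default mesher), on which the permutations are
#' exact by construction.
#'
#' @param mesh an `eit_mesh` built by [build_cylinder_mesh()] with
#'   16-fold symmetry.
#' @param protocol an `eit_protocol`.
#' @return an object of class `eit_symmetry`: lists `elem_perms` and
#'   `frame_perms`, each of 16 permutations (identity first).
#' @export
symmetry_permutations <- function(mesh, protocol = build_protocol()) {
  epr <- 16L
  step <- 2 * pi / epr
  cen <- mesh$element_centroids
  key <- function(M) sprintf("%.9f:%.9f:%.9f", M[, 1L], M[, 2L], M[, 3L])
  base_key <- key(cen)
  nexc <- nrow(protocol$excitations)
  nmeas <- nrow(protocol$measurements[[1L]])
  elem_perms <- vector("list", epr)
  frame_perms <- vector("list", epr)
  for (s in seq_len(epr) - 1L) {
    ang <- -s * step # source centroid: rotate back
    R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                3L, 3L)
    src <- cen %*% t(R)
    ep <- match(key(src), base_key)
    stop_if(anyNA(ep), "mesh is not 16-fold rotationally symmetric")
    elem_perms[[s + 1L]] <- ep
    # drive at local k measures what the drive at local k - s measured
    d_src <- vapply(seq_len(nexc), function(d) {
      r <- (d - 1L) %/% epr
      k <- (d - 1L) %% epr
      r * epr + ((k - s) %% epr) + 1L
    }, 0L)
    fp <- unlist(lapply(seq_len(nexc), function(d)
      (d_src[d] - 1L) * nmeas + seq_len(nmeas)))
    frame_perms[[s + 1L]] <- fp
  }
  structure(list(elem_perms = elem_perms, frame_perms = frame_perms,
                 mesh_hash = mesh$mesh_hash,
                 protocol_hash = protocol$protocol_hash),
            class = "eit_symmetry")
}
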