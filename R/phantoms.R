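# Ground-truth conductivity phantoms: acrylic-style inclusions in saline
# and the smooth centre-to-edge gradient field emulating the moisture
# distribution of a maize ear.

#' Acrylic inclusion phantom specification
#'
#' One or more near-insulating shapes (sphere, cylinder, cube) immersed
#' in a saline background. Defaults follow the standard tank setup:
#' background 350 uS/cm, inclusions 0.0001 uS/cm.
#'
#' @param shapes list of shape descriptors, each
#'   `list(kind = "sphere"|"cylinder"|"cube", center = c(x, y, z),
#'   size = ...)` with coordinates/sizes in cm: sphere `size = radius`;
#'   cylinder `size = c(radius, height)` (axis parallel to z);
#'   cube `size = edge`.
#' @param sigma_background background conductivity (uS/cm, default 350).
#' @param sigma_inclusion inclusion conductivity (uS/cm, default 0.0001).
#' @return an object of class `eit_acrylic_spec`.
#' @export
acrylic_phantom_spec <- function(shapes, sigma_background = 350,
                                 sigma_inclusion = 0.0001) {
  stop_if(!is.list(shapes) || length(shapes) < 1L, "need at least one shape")
  for (s in shapes) {
    stop_if(!s$kind %in% c("sphere", "cylinder", "cube"),
            "shape kind must be sphere, cylinder or cube")
    stop_if(length(s$center) != 3L, "shape center must be length 3")
    stop_if(any(s$size <= 0), "shape sizes must be > 0")
    if (s$kind == "cylinder") stop_if(length(s$size) != 2L,
                                      "cylinder size is c(radius, height)")
  }
  stop_if(sigma_background <= 0 || sigma_inclusion <= 0,
          "conductivities must be > 0")
  structure(list(shapes = shapes, sigma_background = sigma_background,
                 sigma_inclusion = sigma_inclusion),
            class = "eit_acrylic_spec")
}

#' Maize-ear gradient phantom specification
#'
#' Conductivity decays exponentially from a centre point, with an
#' axially modulated in-plane decay scale:
#' `s(z) = 1 + a * sin(b * z + c)` and
#' `Es = exp(-Dxy * s(z) / bs[1] - Dxy * s(z) / bs[2] - Dz / bs[3])`,
#' where `Dxy`/`Dz` are the in-plane/axial distances (cm) of an element
#' centroid from the centre and `z` is the centroid's axial offset from
#' the centre (so the field is invariant under rigid translation).
#' Element conductivity is `sigma_max * Es`.
#'
#' @param center 3D centre point (cm).
#' @param s radial decay scale for [radial_decay()] (cm, default 2).
#' @param a,b,c sinusoid amplitude (`0 <= a < 1`), angular frequency
#'   (rad/cm) and phase of the axial modulation.
#' @param bs length-3 vector of directional decay rates (cm), all > 0.
#' @param sigma_max conductivity at the centre (uS/cm, default 350).
#' @return an object of class `eit_maize_spec`.
#' @export
maize_phantom_spec <- function(center = c(0, 0, 4), s = 2,
                               a = 0.1, b = 1, c = 0,
                               bs = c(4, 4, 5), sigma_max = 350) {
  stop_if(length(center) != 3L, "center must be length 3")
  stop_if(!is_number(s) || s <= 0, "s must be > 0")
  stop_if(!is_number(a) || a < 0 || a >= 1, "a must satisfy 0 <= a < 1")
  stop_if(length(bs) != 3L || any(bs <= 0), "bs must be 3 positive rates")
  stop_if(!is_number(sigma_max) || sigma_max <= 0, "sigma_max must be > 0")
  structure(list(center = as.numeric(center), s = s, a = a, b = b, c = c,
                 bs = as.numeric(bs), sigma_max = sigma_max),
            class = "eit_maize_spec")
}

#' Exponential radial decay factor
#'
#' `f(x) = exp(-x / s)`: strictly decreasing in the distance `x`,
#' equal to 1 at the centre.
#'
#' @param x distance(s) from the centre, >= 0.
#' @param s decay scale, > 0.
#' @return decay factor(s) in (0, 1].
#' @examples
#' radial_decay(0, 2)  # 1
#' radial_decay(2, 2)  # exp(-1)
#' @export
radial_decay <- function(x, s) {
  stop_if(!is_number(s) || s <= 0, "s must be > 0")
  stop_if(any(x < 0), "x must be >= 0")
  exp(-x / s)
}

#' Axially modulated diffusion scale
#'
#' `s(z) = 1 + a * sin(b * z + c)`, bounded in `[1 - a, 1 + a]`.
#'
#' @param z axial position(s).
#' @param a amplitude, `0 <= a < 1`.
#' @param b angular frequency (rad per unit z).
#' @param c phase.
#' @export
axial_scale <- function(z, a, b, c) {
  stop_if(!is_number(a) || a < 0 || a >= 1, "a must satisfy 0 <= a < 1")
  1 + a * sin(b * z + c)
}

#' Evaluate the maize gradient field on a mesh
#'
#' @param mesh an `eit_mesh`.
#' @param spec an [maize_phantom_spec()].
#' @return an `eit_field` (values in S/m).
#' @export
maize_field <- function(mesh, spec) {
  stop_if(!inherits(spec, "eit_maize_spec"), "spec must be an eit_maize_spec")
  cen_cm <- mesh$element_centroids * 100
  lo <- apply(mesh$nodes * 100, 2L, min); hi <- apply(mesh$nodes * 100, 2L, max)
  if (any(spec$center < lo) || any(spec$center > hi)) {
    warning("phantom center lies outside the mesh bounding box")
  }
  dxy <- sqrt((cen_cm[, 1L] - spec$center[1L])^2 +
              (cen_cm[, 2L] - spec$center[2L])^2)
  dz <- abs(cen_cm[, 3L] - spec$center[3L])
  sz <- axial_scale(cen_cm[, 3L] - spec$center[3L], spec$a, spec$b, spec$c)
  es <- exp(-dxy * sz / spec$bs[1L] - dxy * sz / spec$bs[2L] - dz / spec$bs[3L])
  conductivity_field(spec$sigma_max * es, mesh, unit = "uS/cm")
}

shape_contains <- function(shape, pts_cm) {
  d <- sweep(pts_cm, 2L, shape$center)
  switch(shape$kind,
    sphere = rowSums(d^2) <= shape$size[1L]^2,
    cylinder = (d[, 1L]^2 + d[, 2L]^2 <= shape$size[1L]^2) &
               (abs(d[, 3L]) <= shape$size[2L] / 2),
    cube = apply(abs(d) <= shape$size[1L] / 2, 1L, all)
  )
}

#' Evaluate an acrylic inclusion field on a mesh
#'
#' Membership is decided by element centroid; overlapping shapes are
#' allowed (the inclusion conductivity wins).
#'
#' @param mesh an `eit_mesh`.
#' @param spec an [acrylic_phantom_spec()].
#' @return an `eit_field` (values in S/m).
#' @export
acrylic_field <- function(mesh, spec) {
  stop_if(!inherits(spec, "eit_acrylic_spec"), "spec must be an eit_acrylic_spec")
  pts <- mesh$element_centroids * 100
  inside <- rep(FALSE, mesh$n_elements)
  for (s in spec$shapes) inside <- inside | shape_contains(s, pts)
  vals <- ifelse(inside, spec$sigma_inclusion, spec$sigma_background)
  conductivity_field(vals, mesh, unit = "uS/cm")
}

#' Seeded random phantom sampler
#'
#' Draws phantom specifications uniformly from configured parameter
#' ranges; the same seed always reproduces the same sequence of draws.
#' Default ranges keep inclusion/gradient centres within the central 60%
#' of the cylinder both radially and axially.
#'
#' @param spec a [cylinder_spec()] providing the domain bounds.
#' @param seed integer seed.
#' @param ranges optional list overriding any of the default ranges
#'   (`center_r_frac`, `center_z_frac`, `sphere_radius`,
#'   `cylinder_radius`, `cylinder_height`, `cube_edge`, `a`, `b`, `c`,
#'   `bs12`, `bs3`, `s`), each a length-2 numeric `c(lo, hi)`.
#' @return an object of class `eit_sampler` (stateful: each
#'   [sample_phantom()] call advances the stream).
#' @export
phantom_sampler <- function(spec = cylinder_spec(), seed = 1L, ranges = list()) {
  defaults <- list(
    center_r_frac = c(0, 0.6), center_z_frac = c(0.2, 0.8),
    sphere_radius = c(0.6, 1.4), cylinder_radius = c(0.5, 1.2),
    cylinder_height = c(1.0, 2.5), cube_edge = c(1.0, 2.2),
    a = c(0, 0.2), b = c(0.5, 2), c = c(0, 2 * pi),
    bs12 = c(2, 6), bs3 = c(3, 8), s = c(1, 4)
  )
  unknown <- setdiff(names(ranges), names(defaults))
  stop_if(length(unknown) > 0, "unknown sampler range(s): ",
          paste(unknown, collapse = ", "))
  rg <- modifyList(defaults, ranges)
  for (nm in names(rg)) {
    stop_if(length(rg[[nm]]) != 2L || rg[[nm]][2L] < rg[[nm]][1L],
            "range ", nm, " must be c(lo, hi) with hi >= lo")
  }
  env <- new.env(parent = emptyenv())
  env$spec <- spec; env$seed <- as.integer(seed); env$count <- 0L
  env$ranges <- rg
  class(env) <- "eit_sampler"
  env
}

sampler_draw <- function(sampler, n) {
  # private RNG stream: seed derived from (seed, draw counter)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed((sampler$seed * 7919L + sampler$count * 104729L) %% .Machine$integer.max)
  sampler$count <- sampler$count + 1L
  runif(n)
}

#' Draw a random phantom specification
#'
#' @param sampler an [phantom_sampler()].
#' @param kind `"sphere"`, `"cylinder"`, `"cube"` (single acrylic
#'   inclusion of that shape), `"acrylic"` (shape kind drawn at random)
#'   or `"maize"`.
#' @return an `eit_acrylic_spec` or `eit_maize_spec`.
#' @export
sample_phantom <- function(sampler, kind = c("sphere", "cylinder", "cube",
                                             "acrylic", "maize")) {
  kind <- match.arg(kind)
  stop_if(!inherits(sampler, "eit_sampler"), "need an eit_sampler")
  u <- sampler_draw(sampler, 12L)
  rg <- sampler$ranges
  sp <- sampler$spec
  lerp <- function(r, t) r[1L] + (r[2L] - r[1L]) * t
  rc <- sp$radius * lerp(rg$center_r_frac, sqrt(u[1L]))
  th <- 2 * pi * u[2L]
  center <- c(rc * cos(th), rc * sin(th), sp$height * lerp(rg$center_z_frac, u[3L]))
  if (kind == "maize") {
    return(maize_phantom_spec(
      center = center, s = lerp(rg$s, u[4L]),
      a = lerp(rg$a, u[5L]), b = lerp(rg$b, u[6L]), c = lerp(rg$c, u[7L]),
      bs = c(lerp(rg$bs12, u[8L]), lerp(rg$bs12, u[9L]), lerp(rg$bs3, u[10L]))
    ))
  }
  if (kind == "acrylic") kind <- c("sphere", "cylinder", "cube")[1L + floor(u[11L] * 3) %% 3]
  shape <- switch(kind,
    sphere = list(kind = "sphere", center = center,
                  size = lerp(rg$sphere_radius, u[4L])),
    cylinder = list(kind = "cylinder", center = center,
                    size = c(lerp(rg$cylinder_radius, u[4L]),
                             lerp(rg$cylinder_height, u[5L]))),
    cube = list(kind = "cube", center = center, size = lerp(rg$cube_edge, u[4L]))
  )
  acrylic_phantom_spec(list(shape))
}
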