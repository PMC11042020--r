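# Internal helpers shared across modules.

#' Convert conductivity between microsiemens/cm and S/m
#'
#' Conductivity is stored in S/m throughout the package; configuration and
#' phantom specifications accept the field-convention unit uS/cm.
#' 1 uS/cm = 1e-4 S/m.
#'
#' @param x numeric vector of conductivities.
#' @return numeric vector in the target unit.
#' @examples
#' uScm_to_Sm(350)   # 0.035 S/m
#' Sm_to_uScm(0.035) # 350 uS/cm
#' @export
uScm_to_Sm <- function(x) x * 1e-4

#' @rdname uScm_to_Sm
#' @export
Sm_to_uScm <- function(x) x * 1e4

# Nominal background conductivity (S/m) at which electrode contact
# impedances are quoted; 350 uS/cm saline background.
SIGMA_NOMINAL <- 0.035

stop_if <- function(cond, ..., class = "eit3d_error") {
  if (cond) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = paste0(...), call = sys.call(-1))
    ))
  }
  invisible(NULL)
}

# Cheap structural fingerprint used to bind fields/frames/models to the
# mesh and protocol that produced them.  Polynomial rolling hash over the
# serialized object, reported as a fixed-width hex-like string.
fingerprint <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2L)
  b <- as.integer(raw)
  p1 <- 2147483647; m1 <- 31
  p2 <- 2038074743; m2 <- 37
  h1 <- 0; h2 <- 0
  # chunked Horner scheme keeps everything in exact double range
  chunk <- 1024L
  for (start in seq(1L, length(b), by = chunk)) {
    seg <- b[start:min(start + chunk - 1L, length(b))]
    for (v in seg) {
      h1 <- (h1 * m1 + v) %% p1
      h2 <- (h2 * m2 + v) %% p2
    }
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Wrapped angular distance in degrees, result in [0, 180].
ang_dist <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
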