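# Adjacent excitation/measurement protocol for the 3 x 16 electrode array.
#
# Electrodes are numbered 1..48: ring A (lowest) 1..16, ring B 17..32,
# ring C 33..48. Drives cycle (2,1), (3,2), ..., (16,15), (1,16) within a
# ring, rings in A, B, C order. For each drive, 45 adjacent pairs are
# measured: within the drive's own ring the 13 pairs not sharing an
# electrode with the drive, starting two positions past the drive;
# within each other ring all 16 pairs, starting at the local pair aligned
# with the drive's lower electrode; ring blocks always in A, B, C order.

local_to_global <- function(ring, k) (ring - 1L) * 16L + ((k - 1L) %% 16L) + 1L

#' Build the canonical adjacent stimulation protocol
#'
#' Deterministically constructs the 48 drive pairs and, per drive, the
#' ordered 45 measured adjacent pairs (48 x 45 = 2,160 measurements per
#' frame). The first drive is electrodes (2, 1) and its first measured
#' pair is (3, 4). The differential sign convention is
#' `v = phi(out1) - phi(out2)`.
#'
#' @return an object of class `eit_protocol` with fields `excitations`
#'   (48 x 2 integer matrix), `measurements` (list of 48 matrices,
#'   each 45 x 2) and `protocol_hash`.
#' @examples
#' p <- build_protocol()
#' p$excitations[1, ]      # 2 1
#' p$measurements[[1]][1, ] # 3 4
#' @export
build_protocol <- function() {
  exc <- matrix(0L, 48L, 2L)
  meas <- vector("list", 48L)
  idx <- 0L
  for (ring in 1:3) {
    for (k in 1:16) {
      idx <- idx + 1L
      exc[idx, ] <- c(local_to_global(ring, k + 1L), local_to_global(ring, k))
      blocks <- vector("list", 3L)
      for (r in 1:3) {
        if (r == ring) {
          j <- 0:12
          blocks[[r]] <- cbind(local_to_global(r, k + 2L + j),
                               local_to_global(r, k + 3L + j))
        } else {
          j <- 0:15
          blocks[[r]] <- cbind(local_to_global(r, k + j),
                               local_to_global(r, k + 1L + j))
        }
      }
      meas[[idx]] <- do.call(rbind, blocks)
    }
  }
  p <- list(excitations = exc, measurements = meas)
  p$protocol_hash <- fingerprint(p)
  structure(p, class = "eit_protocol")
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat(sprintf("<eit_protocol> %d excitations x %d measurements = %d values\n",
              nrow(x$excitations), nrow(x$measurements[[1L]]),
              nrow(x$excitations) * nrow(x$measurements[[1L]])))
  invisible(x)
}

#' Construct a boundary-voltage frame
#'
#' @param values numeric vector of differential voltages (V),
#'   excitation-major order.
#' @param protocol_hash fingerprint of the producing protocol (optional).
#' @param snr_db SNR tag in dB, or `NA` for a clean frame.
#' @param noisy logical flag.
#' @return an object of class `eit_frame`.
#' @export
voltage_frame <- function(values, protocol_hash = NA_character_,
                          snr_db = NA_real_, noisy = FALSE) {
  stop_if(!is.numeric(values) || any(!is.finite(values)),
          "frame values must be finite numerics")
  structure(as.numeric(values), class = "eit_frame",
            protocol_hash = protocol_hash, snr_db = snr_db, noisy = noisy)
}

#' @export
print.eit_frame <- function(x, ...) {
  cat(sprintf("<eit_frame> L = %d, RMS = %.4g V%s\n", length(x),
              sqrt(mean(unclass(x)^2)),
              if (isTRUE(attr(x, "noisy")))
                sprintf(", noisy (%g dB)", attr(x, "snr_db")) else ", clean"))
  invisible(x)
}

#' Extract the measurement frame from forward potentials
#'
#' Value at frame position `(e - 1) * 45 + m` is
#' `U[out1, e] - U[out2, e]` for excitation `e` and measured pair `m`.
#'
#' @param potentials an `eit_potentials` from [solve_forward()].
#' @param protocol an `eit_protocol`; its excitation pattern must match
#'   the one the potentials were solved under.
#' @return an `eit_frame` of length 2,160 (for the full protocol).
#' @export
extract_frame <- function(potentials, protocol = build_protocol()) {
  stop_if(!inherits(potentials, "eit_potentials"), "need eit_potentials")
  stop_if(!identical(dim(potentials$electrode)[2L], nrow(protocol$excitations)) ||
            !identical(unname(potentials$excitations),
                       unname(protocol$excitations)),
          "potentials were not solved under this protocol's excitation pattern")
  U <- potentials$electrode
  out <- unlist(lapply(seq_len(nrow(protocol$excitations)), function(e) {
    mm <- protocol$measurements[[e]]
    U[mm[, 1L], e] - U[mm[, 2L], e]
  }))
  voltage_frame(out, protocol_hash = protocol$protocol_hash)
}

#' Reconfigure a frame into the single-channel feature map
#'
#' Reshapes the 2,160-value excitation-major frame into the 48 x 45
#' excitation-by-measurement matrix and transposes it to the 45 x 48
#' single-channel feature map that the reconstruction network consumes.
#' The map at (row 1, column 1) is the first measured value of the first
#' drive. Exact inverse: [featuremap_to_frame()].
#'
#' @param frame an `eit_frame` (or numeric vector) of length 2,160.
#' @return an `eit_featuremap`: a 45 x 48 matrix.
#' @export
frame_to_featuremap <- function(frame) {
  v <- unclass(frame)
  stop_if(length(v) != 2160L, "frame must have length 2,160")
  m <- t(matrix(v, nrow = 45L)) # 48 x 45, rows = excitations
  structure(t(m), class = "eit_featuremap",
            protocol_hash = attr(frame, "protocol_hash"),
            snr_db = attr(frame, "snr_db"), noisy = attr(frame, "noisy"))
}

#' Invert the feature reconfiguration
#'
#' @param map an `eit_featuremap` (45 x 48 matrix).
#' @return the `eit_frame` whose reconfiguration is `map` (bit-exact
#'   round trip).
#' @export
featuremap_to_frame <- function(map) {
  stop_if(!is.matrix(map) || !identical(dim(map), c(45L, 48L)),
          "feature map must be 45 x 48")
  voltage_frame(as.vector(map),
                protocol_hash = attr(map, "protocol_hash"),
                snr_db = attr(map, "snr_db") %||% NA_real_,
                noisy = isTRUE(attr(map, "noisy")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write voltage frames as CSV
#'
#' One value per line; header comment lines carry the protocol hash and
#' noise metadata for interoperability with externally measured
#' 2,160-value frames.
#'
#' @param frame an `eit_frame`.
#' @param path file path.
#' @return `write_frame_csv` returns `path` invisibly; `read_frame_csv`
#'   returns an `eit_frame`.
#' @export
write_frame_csv <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# eit3d frame v1"),
    sprintf("# protocol_hash: %s", attr(frame, "protocol_hash") %||% NA),
    sprintf("# snr_db: %s", attr(frame, "snr_db")),
    sprintf("# noisy: %s", isTRUE(attr(frame, "noisy")))
  ), con)
  writeLines(sprintf("%.17g", unclass(frame)), con)
  invisible(path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  vals <- as.numeric(lines[!startsWith(lines, "#") & nzchar(lines)])
  stop_if(any(is.na(vals)), "malformed frame CSV")
  get_field <- function(key) {
    ln <- hdr[grepl(paste0("# ", key, ":"), hdr, fixed = TRUE)]
    if (length(ln) == 0L) return(NA)
    trimws(sub(paste0("# ", key, ":"), "", ln[1L], fixed = TRUE))
  }
  snr <- suppressWarnings(as.numeric(get_field("snr_db")))
  voltage_frame(vals, protocol_hash = as.character(get_field("protocol_hash")),
                snr_db = snr, noisy = identical(get_field("noisy"), "TRUE"))
}
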