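# SNR-controlled Gaussian measurement noise and detection-limit
# accounting.

#' Noise specification
#'
#' SNR is defined frame-wise on RMS amplitude: the noise standard
#' deviation is `RMS(frame) * 10^(-snr_db / 20)`.
#'
#' @param snr_db signal-to-noise ratio in dB, or `NULL`/`NA` for no
#'   noise.
#' @param seed integer seed for the noise stream.
#' @return an object of class `eit_noise`.
#' @export
noise_spec <- function(snr_db = 40, seed = 1L) {
  if (!is.null(snr_db) && !is.na(snr_db)) {
    stop_if(!is_number(snr_db), "snr_db must be finite")
  } else {
    snr_db <- NA_real_
  }
  structure(list(snr_db = snr_db, seed = as.integer(seed)),
            class = "eit_noise")
}

noise_sd <- function(frame, snr_db) {
  rms <- sqrt(mean(unclass(frame)^2))
  stop_if(rms == 0, "all-zero frame: RMS-based SNR scaling is undefined")
  rms * 10^(-snr_db / 20)
}

#' Add SNR-controlled Gaussian noise to a frame
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `RMS(frame) * 10^(-snr_db / 20)`; deterministic under the configured seed.
#' With no SNR configured the frame is returned unchanged.
#'
#' @param frame an `eit_frame`.
#' @param spec an [noise_spec()].
#' @return the noisy `eit_frame` (metadata records the SNR tag).
#' @export
add_noise <- function(frame, spec = noise_spec()) {
  stop_if(!inherits(spec, "eit_noise"), "spec must be an eit_noise")
  if (is.na(spec$snr_db)) return(frame)
  sdv <- noise_sd(frame, spec$snr_db)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(spec$seed)
  voltage_frame(unclass(frame) + rnorm(length(frame), 0, sdv),
                protocol_hash = attr(frame, "protocol_hash"),
                snr_db = spec$snr_db, noisy = TRUE)
}

#' Detection-limit report
#'
#' A measurement is considered usable when its magnitude exceeds the
#' noise mean plus three noise standard deviations. For the zero-mean
#' Gaussian model the threshold is `3 * sigma_noise`, with `sigma_noise`
#' derived from the clean frame's RMS and the configured SNR (or passed
#' explicitly via `sigma`).
#'
#' @param frame an `eit_frame` (the clean signal being assessed).
#' @param spec an [noise_spec()]; ignored when `sigma` is given.
#' @param sigma optional explicit noise standard deviation (V).
#' @return a tibble of class `eit_detection` with `n_pass`, `proportion`
#'   (`n_pass / L` exactly) and `threshold`.
#' @export
detection_report <- function(frame, spec = noise_spec(), sigma = NULL) {
  v <- unclass(frame)
  if (is.null(sigma)) {
    sigma <- if (is.na(spec$snr_db)) 0 else noise_sd(frame, spec$snr_db)
  }
  thr <- 3 * sigma
  n_pass <- sum(abs(v) > thr)
  out <- tibble::tibble(
    L = length(v), n_pass = n_pass, proportion = n_pass / length(v),
    threshold = thr, snr_db = spec$snr_db
  )
  class(out) <- c("eit_detection", class(out))
  out
}
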