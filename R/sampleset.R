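# Generation, splitting and persistence of voltage--conductivity sample
# sets.

#' Generate a voltage--conductivity sample set
#'
#' Draws `n` phantoms, solves the forward problem for each, extracts the
#' clean frame and adds SNR-controlled noise. Every per-sample seed is
#' recorded in the manifest so any clean frame can be re-derived from
#' its stored conductivity field.
#'
#' @param mesh an `eit_mesh` with electrodes.
#' @param cem a [cem_params()].
#' @param protocol an `eit_protocol`.
#' @param sampler an [phantom_sampler()].
#' @param n number of samples.
#' @param noise an [noise_spec()]; per-sample noise seeds are derived
#'   from its seed.
#' @param kind phantom kind passed to [sample_phantom()].
#' @param require_inhomogeneous redraw phantoms whose discretized field
#'   is constant (e.g. an inclusion too small to capture any element
#'   centroid); such samples carry no reconstruction target (default
#'   TRUE).
#' @return an object of class `eit_sampleset`: matrices `frames_clean`
#'   and `frames_noisy` (L x n), `sigma` (N x n, S/m), the phantom
#'   `specs`, a `split` label vector and a `manifest`.
#' @export
generate_sampleset <- function(mesh, cem, protocol, sampler, n,
                               noise = noise_spec(), kind = "sphere",
                               require_inhomogeneous = TRUE) {
  stop_if(!is_count(n), "n must be a positive integer")
  mesh <- prepare_fem(mesh, cem)
  L <- nrow(protocol$excitations) * nrow(protocol$measurements[[1L]])
  frames_clean <- matrix(0, L, n)
  frames_noisy <- matrix(0, L, n)
  sigma <- matrix(0, mesh$n_elements, n)
  specs <- vector("list", n)
  i <- 0L
  attempts <- 0L
  while (i < n) {
    attempts <- attempts + 1L
    stop_if(attempts > 5L * n, "too many failed forward solves")
    ph <- sample_phantom(sampler, kind)
    field <- if (inherits(ph, "eit_maize_spec")) maize_field(mesh, ph)
             else acrylic_field(mesh, ph)
    if (require_inhomogeneous && diff(range(field$values)) == 0) next
    pot <- tryCatch(solve_forward(mesh, field, cem, protocol$excitations),
                    error = function(e) {
                      warning("forward solve failed, redrawing phantom: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(pot)) next
    i <- i + 1L
    fr <- extract_frame(pot, protocol)
    frames_clean[, i] <- unclass(fr)
    nz <- if (is.na(noise$snr_db)) fr else
      add_noise(fr, noise_spec(noise$snr_db, seed = noise$seed + i))
    frames_noisy[, i] <- unclass(nz)
    sigma[, i] <- field$values
    specs[[i]] <- ph
  }
  structure(list(
    frames_clean = frames_clean, frames_noisy = frames_noisy,
    sigma = sigma, specs = specs,
    split = rep(NA_character_, n),
    manifest = list(
      schema = "eit3d_sampleset_v1",
      mesh_hash = mesh$mesh_hash, protocol_hash = protocol$protocol_hash,
      noise = noise, sampler_seed = sampler$seed, kind = kind, n = n
    )
  ), class = "eit_sampleset")
}

#' @export
print.eit_sampleset <- function(x, ...) {
  cat(sprintf("<eit_sampleset> %d samples, L = %d, N = %d elements%s\n",
              ncol(x$frames_clean), nrow(x$frames_clean), nrow(x$sigma),
              if (all(is.na(x$split))) "" else
                sprintf(" (%d train / %d validation)",
                        sum(x$split == "train", na.rm = TRUE),
                        sum(x$split == "validation", na.rm = TRUE))))
  invisible(x)
}

#' Split a sample set into training and validation parts
#'
#' Seeded random permutation; the training part receives
#' `floor(ratio * n)` samples and the labels partition the set.
#'
#' @param set an `eit_sampleset`.
#' @param ratio training fraction in (0, 1) (default 0.8).
#' @param seed integer seed.
#' @return the sample set with its `split` labels assigned.
#' @export
split_sampleset <- function(set, ratio = 0.8, seed = 1L) {
  stop_if(!inherits(set, "eit_sampleset"), "need an eit_sampleset")
  stop_if(!is_number(ratio) || ratio <= 0 || ratio >= 1,
          "ratio must lie in (0, 1)")
  n <- ncol(set$frames_clean)
  stop_if(n < 2L, "need at least 2 samples to split")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  perm <- sample.int(n)
  ntr <- floor(ratio * n)
  lbl <- rep("validation", n)
  lbl[perm[seq_len(ntr)]] <- "train"
  set$split <- lbl
  set$manifest$split <- list(ratio = ratio, seed = seed, n_train = ntr)
  set
}

#' Persist and restore sample sets
#'
#' Native R serialization of the complete container (frames, fields,
#' specs, manifest, split labels); the round trip is lossless.
#'
#' @param set an `eit_sampleset`.
#' @param path file path (conventionally `.rds`).
#' @return `write_sampleset` returns `path` invisibly; `read_sampleset`
#'   the restored `eit_sampleset`.
#' @export
write_sampleset <- function(set, path) {
  stop_if(!inherits(set, "eit_sampleset"), "need an eit_sampleset")
  saveRDS(set, path)
  invisible(path)
}

#' @rdname write_sampleset
#' @export
read_sampleset <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable sample-set container: ", conditionMessage(e),
         call. = FALSE))
  stop_if(!inherits(obj, "eit_sampleset") ||
            !identical(obj$manifest$schema, "eit3d_sampleset_v1"),
          "unrecognized sample-set schema")
  obj
}

# Feature-map array (45 x 48 x 1 x n) for a sample set, from the noisy
# frames when present.
sampleset_features <- function(set, use_noisy = TRUE) {
  fr <- if (use_noisy) set$frames_noisy else set$frames_clean
  n <- ncol(fr)
  X <- array(0, c(45L, 48L, 1L, n))
  for (i in seq_len(n)) X[, , 1L, i] <- matrix(fr[, i], nrow = 45L)
  X
}
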