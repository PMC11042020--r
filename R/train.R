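# Amplified-error training of the reconstruction network.

#' Training configuration
#'
#' Defaults follow the reference full-scale schedule: 50 epochs, batch
#' size 32, Adam at base learning rate 1e-4, mean-squared-error loss
#' amplified by `alpha = 100`, reduce-on-plateau learning-rate schedule
#' (factor 0.5, patience 5, on validation loss) and no weight decay.
#' Reduced-scale runs typically raise `base_lr` (fewer optimizer steps).
#'
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 32).
#' @param base_lr initial Adam learning rate (default 1e-4).
#' @param alpha error amplification factor of the loss (default 100).
#' @param lr_factor,lr_patience reduce-on-plateau schedule parameters.
#' @param weight_decay L2 regularization coefficient (default 0).
#' @param normalization target scaling: `"per_element"` (each element
#'   z-scored by its own training-split mean/sd, floored at 5% of the
#'   largest element sd -- this balances the loss between the rare
#'   anomaly-bearing elements and the constant background), `"range"`
#'   (global scaling to the unit interval) or `"standard"` (global
#'   z-score). Feature maps are always standardized per position by
#'   training-split mean/sd.
#' @param init_output_bias initialize the regression-head bias at the
#'   per-element mean of the normalized training targets (default TRUE).
#' @param seed integer seed controlling batch order (and, through
#'   [build_network()], initialization when the caller reuses it).
#' @return an object of class `eit_train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L, base_lr = 1e-4,
                         alpha = 100, lr_factor = 0.5, lr_patience = 5L,
                         weight_decay = 0,
                         normalization = c("per_element", "range", "standard"),
                         init_output_bias = TRUE, seed = 1L) {
  stop_if(!is_count(epochs) || !is_count(batch_size), "epochs/batch_size >= 1")
  stop_if(!is_number(base_lr) || base_lr <= 0, "base_lr must be > 0")
  stop_if(!is_number(alpha) || alpha <= 0, "alpha must be > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 base_lr = base_lr, alpha = alpha, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 weight_decay = weight_decay,
                 normalization = match.arg(normalization),
                 init_output_bias = isTRUE(init_output_bias),
                 seed = as.integer(seed)),
            class = "eit_train_config")
}

#' Amplified mean-squared-error loss
#'
#' `alpha * mean((pred - target)^2)`; `alpha = 1` reduces to plain MSE.
#' Amplifying the error raises the back-propagated gradient magnitude on
#' small-valued conductivity targets.
#'
#' @param pred,target numeric vectors/matrices of equal size.
#' @param alpha amplification factor.
#' @export
amplified_loss <- function(pred, target, alpha = 100) {
  stop_if(length(pred) != length(target), "pred/target length mismatch")
  alpha * mean((pred - target)^2)
}

# ---- Adam over the nested parameter list ------------------------------

# Adam moments live in an environment of pre-allocated buffers; the
# compiled kernel updates parameters and moments in place, avoiding
# per-step allocation of head-sized temporaries.
adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  for (lay in names(params)) {
    for (pn in names(params[[lay]])) {
      key <- paste0(lay, ".", pn)
      x <- params[[lay]][[pn]]
      assign(key, list(m = x * 0, v = x * 0), envir = st)
    }
  }
  st
}

adam_step <- function(params, grads, state, lr, t, wd = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (lay in names(grads)) {
    for (pn in names(grads[[lay]])) {
      g <- grads[[lay]][[pn]]
      if (is.null(g)) next
      key <- paste0(lay, ".", pn)
      st <- get(key, envir = state)
      nn_adam_step(params[[lay]][[pn]], g, st$m, st$v,
                   lr, beta1, beta2, eps, t, wd)
    }
  }
  params
}

#' Train the reconstruction network on a sample set
#'
#' Optimizes the amplified MSE between predicted and true normalized
#' conductivity vectors over the training split with Adam, evaluating
#' the validation split each epoch and applying the reduce-on-plateau
#' schedule. Fully deterministic under the config seed (initialization,
#' batch order).
#'
#' @param network an [build_network()] result whose `output_dim` matches
#'   the sample set's element count.
#' @param set a split `eit_sampleset` (see [split_sampleset()]).
#' @param config an [train_config()].
#' @param use_noisy train on the noisy frames (default TRUE).
#' @param augmentation an optional [symmetry_permutations()] object; when
#'   given, every training example is presented under a uniformly drawn
#'   rotation of the 16-fold symmetry group each time it is visited
#'   (exact, loss-free augmentation; validation is never augmented).
#' @param verbose print per-epoch losses.
#' @return an object of class `eit_model`: trained network,
#'   normalization statistics (training split only), per-epoch history
#'   tibble and a manifest binding mesh/protocol fingerprints.
#' @export
train_network <- function(network, set, config = train_config(),
                          use_noisy = TRUE, augmentation = NULL,
                          verbose = FALSE) {
  stop_if(!inherits(network, "eit_network"), "need an eit_network")
  stop_if(!inherits(set, "eit_sampleset"), "need an eit_sampleset")
  stop_if(all(is.na(set$split)), "sample set is not split; call split_sampleset()")
  stop_if(network$spec$output_dim != nrow(set$sigma),
          "network output_dim must equal the element count of the set")
  tr <- which(set$split == "train")
  va <- which(set$split == "validation")
  stop_if(length(tr) == 0L, "empty training split")

  if (!is.null(augmentation)) {
    stop_if(!inherits(augmentation, "eit_symmetry"),
            "augmentation must come from symmetry_permutations()")
    stop_if(!identical(augmentation$protocol_hash,
                       set$manifest$protocol_hash) ||
              !identical(augmentation$mesh_hash, set$manifest$mesh_hash),
            "augmentation permutations do not match this sample set")
  }
  Fm <- if (use_noisy) set$frames_noisy else set$frames_clean
  L <- nrow(Fm)
  stop_if(L != 45L * 48L, "training expects full 2,160-value frames")
  # per-position feature standardization from the training split only:
  # boundary frames share a large phantom-independent background pattern,
  # so pixel-wise centering is what exposes the informative anomaly
  mu_x <- rowMeans(Fm[, tr, drop = FALSE])
  sd_x <- sqrt(pmax(rowMeans(Fm[, tr, drop = FALSE]^2) - mu_x^2, 0))
  sd_x <- pmax(sd_x, max(sd_x) * 1e-6, .Machine$double.xmin)

  mu_x_arr <- array(mu_x, c(45L, 48L, 1L))
  sd_x_arr <- array(sd_x, c(45L, 48L, 1L))

  Tm <- set$sigma # N x n, S/m
  if (config$normalization == "per_element") {
    t_mu <- rowMeans(Tm[, tr, drop = FALSE])
    t_sd <- sqrt(pmax(rowMeans(Tm[, tr, drop = FALSE]^2) - t_mu^2, 0))
    t_sd <- pmax(t_sd, max(t_sd) * 0.05, .Machine$double.xmin)
    Tn <- (Tm - t_mu) / t_sd
    norm <- list(kind = "per_element", mu_x = mu_x_arr, sd_x = sd_x_arr,
                 mu = t_mu, sd = t_sd)
  } else if (config$normalization == "range") {
    t_lo <- min(Tm[, tr]); t_hi <- max(Tm[, tr])
    if (t_hi == t_lo) t_hi <- t_lo + 1
    Tn <- (Tm - t_lo) / (t_hi - t_lo)
    norm <- list(kind = "range", mu_x = mu_x_arr, sd_x = sd_x_arr,
                 lo = t_lo, hi = t_hi)
  } else {
    t_mu <- mean(Tm[, tr]); t_sd <- sd(Tm[, tr]); if (t_sd == 0) t_sd <- 1
    Tn <- (Tm - t_mu) / t_sd
    norm <- list(kind = "standard", mu_x = mu_x_arr, sd_x = sd_x_arr,
                 mu = t_mu, sd = t_sd)
  }
  if (config$init_output_bias) {
    network$params$fc$b <- rowMeans(Tn[, tr, drop = FALSE])
  }
  # private copies: the compiled optimizer updates parameters in place,
  # so the caller's network object must not share their storage
  network$params <- lapply(network$params, function(l) lapply(l, function(x) x + 0))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(config$seed)

  state <- adam_init(network$params)
  lr <- config$base_lr
  best_val <- Inf; wait <- 0L; tstep <- 0L
  hist <- vector("list", config$epochs)

  make_batch <- function(idx, rot = NULL) {
    Fb <- Fm[, idx, drop = FALSE]
    Tb <- Tn[, idx, drop = FALSE]
    if (!is.null(rot)) {
      for (j in seq_along(idx)) {
        k <- rot[j]
        if (k > 1L) {
          Fb[, j] <- Fb[augmentation$frame_perms[[k]], j]
          Tb[, j] <- Tb[augmentation$elem_perms[[k]], j]
        }
      }
    }
    Xb <- (Fb - mu_x) / sd_x
    dim(Xb) <- c(45L, 48L, 1L, length(idx))
    list(X = Xb, T = Tb)
  }

  eval_loss <- function(idx) {
    if (length(idx) == 0L) return(NA_real_)
    tot <- 0
    bs <- max(config$batch_size, 1L)
    for (start in seq(1L, length(idx), by = bs)) {
      b <- idx[start:min(start + bs - 1L, length(idx))]
      bb <- make_batch(b)
      out <- net_forward(network, bb$X, train = FALSE,
                         keep_cache = FALSE)$out
      tot <- tot + sum((out - bb$T)^2)
    }
    config$alpha * tot / (length(idx) * nrow(Tn))
  }

  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      b <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      rot <- if (is.null(augmentation)) NULL else
        sample.int(16L, length(b), replace = TRUE)
      bb <- make_batch(b, rot)
      fw <- net_forward(network, bb$X, train = TRUE, keep_cache = TRUE)
      network <- fw$net # running BN stats
      resid <- fw$out - bb$T
      loss <- config$alpha * mean(resid * resid)
      dout <- (2 * config$alpha / length(resid)) * resid
      grads <- net_backward(network, fw$caches, dout)
      tstep <- tstep + 1L
      network$params <- adam_step(network$params, grads, state, lr, tstep,
                                  wd = config$weight_decay)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
      stop_if(!is.finite(loss), "training diverged (non-finite loss)")
    }
    val_loss <- eval_loss(va)
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / nb,
                                 val_loss = val_loss, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5g  val %.5g  lr %.2g",
                      ep, ep_loss / nb, val_loss, lr))
    }
    monitor <- if (is.na(val_loss)) ep_loss / nb else val_loss
    if (monitor < best_val - 1e-12) {
      best_val <- monitor; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$lr_patience) { lr <- lr * config$lr_factor; wait <- 0L }
    }
  }

  structure(list(
    network = network, norm = norm,
    history = do.call(rbind, hist),
    config = config,
    manifest = list(mesh_hash = set$manifest$mesh_hash,
                    protocol_hash = set$manifest$protocol_hash,
                    n_train = length(tr), n_validation = length(va),
                    use_noisy = use_noisy)
  ), class = "eit_model")
}

#' @export
print.eit_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("<eit_model> %d epochs, final train loss %.4g, val loss %.4g\n",
              nrow(h), h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
  invisible(x)
}

#' Predict a conductivity field from a feature map
#'
#' Runs the trained network in inference mode (running batch statistics)
#' and denormalizes to S/m; predictions are floored at a tiny positive
#' value so the result is a valid conductivity field.
#'
#' @param object an `eit_model`.
#' @param map an `eit_featuremap` (45 x 48), a 2,160-value `eit_frame`,
#'   or a 45 x 48 x 1 x n array for batched prediction.
#' @param mesh optional `eit_mesh`; when given, the manifest binding is
#'   checked and `eit_field` objects are returned.
#' @param symmetry an optional [symmetry_permutations()] object; when
#'   given, the prediction is the symmetrized estimator: the mean of the
#'   16 back-rotated predictions over the rotation group of the setup.
#' @param ... unused.
#' @return a matrix (N x n) of conductivities in S/m, or `eit_field`(s)
#'   when `mesh` is supplied.
#' @export
predict.eit_model <- function(object, map, mesh = NULL, symmetry = NULL, ...) {
  if (inherits(map, "eit_frame")) map <- frame_to_featuremap(map)
  if (is.matrix(map)) {
    stop_if(!identical(dim(map), c(45L, 48L)), "feature map must be 45 x 48")
    map <- array(map, c(45L, 48L, 1L, 1L))
  }
  if (!is.null(mesh)) {
    stop_if(!identical(mesh$mesh_hash, object$manifest$mesh_hash),
            "model was trained on a different mesh")
  }
  forward_denorm <- function(arr) {
    X <- sweep(sweep(arr, 1:3, object$norm$mu_x), 1:3, object$norm$sd_x, "/")
    out <- net_forward(object$network, X, train = FALSE, keep_cache = FALSE)$out
    if (object$norm$kind == "range") {
      out * (object$norm$hi - object$norm$lo) + object$norm$lo
    } else {
      out * object$norm$sd + object$norm$mu # global or per-element scale
    }
  }
  if (is.null(symmetry)) {
    out <- forward_denorm(map)
  } else {
    stop_if(!inherits(symmetry, "eit_symmetry"),
            "symmetry must come from symmetry_permutations()")
    nmaps <- dim(map)[4L]
    Fr <- matrix(map, nrow = 45L * 48L) # frame order = column-major map
    out <- 0
    for (k in seq_along(symmetry$frame_perms)) {
      Fk <- Fr[symmetry$frame_perms[[k]], , drop = FALSE]
      ok <- forward_denorm(array(Fk, c(45L, 48L, 1L, nmaps)))
      if (k > 1L) ok <- ok[order(symmetry$elem_perms[[k]]), , drop = FALSE]
      out <- out + ok
    }
    out <- out / length(symmetry$frame_perms)
  }
  out <- pmax(out, 1e-12)
  if (!is.null(mesh)) {
    fields <- lapply(seq_len(ncol(out)), function(i)
      conductivity_field(out[, i], mesh))
    if (length(fields) == 1L) return(fields[[1L]])
    return(fields)
  }
  out
}

#' @rdname predict.eit_model
#' @param x an `eit_model`.
#' @method tidy eit_model
#' @export
tidy.eit_model <- function(x, ...) x$history

#' @rdname predict.eit_model
#' @method glance eit_model
#' @export
glance.eit_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h),
                 final_train_loss = h$train_loss[nrow(h)],
                 final_val_loss = h$val_loss[nrow(h)],
                 best_val_loss = suppressWarnings(min(h$val_loss, na.rm = TRUE)),
                 n_train = x$manifest$n_train,
                 n_validation = x$manifest$n_validation)
}
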