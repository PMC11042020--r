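# Residual bottleneck regression network: 45 x 48 single-channel feature
# map -> N-element conductivity vector. Tensors are (H, W, C, N) arrays;
# conv/pool kernels are compiled, batch norm and the head run in R.

#' Reconstruction network specification
#'
#' The default architecture is the standard 4-stage bottleneck residual
#' design: a 7x7/stride-2 stem (64 filters, padding 3), 3x3/stride-2 max
#' pooling, stages of depths (3, 4, 6, 3) at widths (64, 128, 256, 512)
#' with expansion 4 (so the pooled feature vector has length 2,048), a
#' global average pool and a single fully connected regression head of
#' `output_dim` conductivity outputs. The first block of a stage uses a
#' projection shortcut (downsampling variant); the remaining blocks use
#' identity shortcuts. All intermediate activations are rectified-linear.
#' Reduced `stage_depths`/`stage_widths` give the scaled-down variants
#' used for desk-scale experiments.
#'
#' @param output_dim number of conductivity outputs (bind to the mesh's
#'   `n_elements`).
#' @param stage_depths integer vector of blocks per stage.
#' @param stage_widths bottleneck widths per stage.
#' @param expansion bottleneck expansion factor (default 4).
#' @param stem_filters stem convolution filters (default
#'   `stage_widths[1]`).
#' @return an object of class `eit_network_spec`.
#' @examples
#' network_spec(output_dim = 95295)$pooled_dim # 2048
#' @export
network_spec <- function(output_dim,
                         stage_depths = c(3L, 4L, 6L, 3L),
                         stage_widths = c(64L, 128L, 256L, 512L),
                         expansion = 4L,
                         stem_filters = stage_widths[1L]) {
  stop_if(!is_count(output_dim), "output_dim must be a positive integer")
  stop_if(length(stage_depths) != length(stage_widths),
          "stage_depths and stage_widths must have equal length")
  stop_if(any(stage_depths < 1) || any(stage_widths < 1), "invalid stages")
  structure(list(
    input_shape = c(45L, 48L, 1L),
    stem = list(filters = as.integer(stem_filters), k = 7L, stride = 2L, pad = 3L),
    pool = list(k = 3L, stride = 2L, pad = 1L),
    stage_depths = as.integer(stage_depths),
    stage_widths = as.integer(stage_widths),
    expansion = as.integer(expansion),
    pooled_dim = as.integer(stage_widths[length(stage_widths)] * expansion),
    output_dim = as.integer(output_dim)
  ), class = "eit_network_spec")
}

conv_out <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

#' Layer-by-layer shape chain of the network
#'
#' @param spec an [network_spec()].
#' @return a tibble with one row per landmark layer (`layer`, `channels`,
#'   `height`, `width`).
#' @export
network_shapes <- function(spec) {
  h <- spec$input_shape[1L]; w <- spec$input_shape[2L]
  rows <- list(tibble::tibble(layer = "input", channels = 1L,
                              height = h, width = w))
  h <- conv_out(h, spec$stem$k, spec$stem$stride, spec$stem$pad)
  w <- conv_out(w, spec$stem$k, spec$stem$stride, spec$stem$pad)
  rows <- c(rows, list(tibble::tibble(layer = "stem", channels = spec$stem$filters,
                                      height = h, width = w)))
  h <- conv_out(h, spec$pool$k, spec$pool$stride, spec$pool$pad)
  w <- conv_out(w, spec$pool$k, spec$pool$stride, spec$pool$pad)
  rows <- c(rows, list(tibble::tibble(layer = "maxpool", channels = spec$stem$filters,
                                      height = h, width = w)))
  for (s in seq_along(spec$stage_depths)) {
    st <- if (s == 1L) 1L else 2L
    h <- conv_out(h, 3L, st, 1L); w <- conv_out(w, 3L, st, 1L)
    rows <- c(rows, list(tibble::tibble(
      layer = sprintf("stage%d", s),
      channels = spec$stage_widths[s] * spec$expansion,
      height = h, width = w)))
  }
  rows <- c(rows, list(
    tibble::tibble(layer = "gap", channels = spec$pooled_dim, height = 1L, width = 1L),
    tibble::tibble(layer = "fc", channels = spec$output_dim, height = 1L, width = 1L)))
  do.call(rbind, rows)
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Build an untrained reconstruction network
#'
#' Initializes all convolution weights with He-normal draws, batch-norm
#' scale/shift at (1, 0), and the regression head near zero (the head
#' bias is typically re-initialized to the training-target mean by
#' [train_network()]).
#'
#' @param spec an [network_spec()].
#' @param seed integer seed for the deterministic initialization.
#' @return an object of class `eit_network` (parameters, running batch
#'   statistics, op list).
#' @export
build_network <- function(spec, seed = 1L) {
  stop_if(!inherits(spec, "eit_network_spec"), "need an eit_network_spec")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)

  params <- list(); running <- list(); ops <- list()
  add_conv <- function(name, k, cin, cout, stride, pad) {
    params[[name]] <<- list(W = he_init(c(k, k, cin, cout), k * k * cin),
                            b = numeric(cout))
    list(kind = "conv", name = name, stride = stride, pad = pad)
  }
  add_bn <- function(name, c) {
    params[[name]] <<- list(gamma = rep(1, c), beta = numeric(c))
    running[[name]] <<- list(mu = numeric(c), var = rep(1, c))
    list(kind = "bn", name = name)
  }

  ops[[length(ops) + 1L]] <- add_conv("stem", spec$stem$k, 1L,
                                      spec$stem$filters,
                                      spec$stem$stride, spec$stem$pad)
  ops[[length(ops) + 1L]] <- add_bn("stem_bn", spec$stem$filters)
  ops[[length(ops) + 1L]] <- list(kind = "relu")
  ops[[length(ops) + 1L]] <- list(kind = "maxpool", k = spec$pool$k,
                                  stride = spec$pool$stride, pad = spec$pool$pad)
  cin <- spec$stem$filters
  for (s in seq_along(spec$stage_depths)) {
    w <- spec$stage_widths[s]
    cout <- w * spec$expansion
    for (j in seq_len(spec$stage_depths[s])) {
      stride <- if (j == 1L && s > 1L) 2L else 1L
      proj <- (j == 1L) # stage entry: projection shortcut
      pre <- sprintf("s%db%d", s, j)
      sub <- list(
        add_conv(paste0(pre, "_conv1"), 1L, cin, w, 1L, 0L),
        add_bn(paste0(pre, "_bn1"), w),
        add_conv(paste0(pre, "_conv2"), 3L, w, w, stride, 1L),
        add_bn(paste0(pre, "_bn2"), w),
        add_conv(paste0(pre, "_conv3"), 1L, w, cout, 1L, 0L),
        add_bn(paste0(pre, "_bn3"), cout)
      )
      if (proj) {
        sub$proj <- add_conv(paste0(pre, "_proj"), 1L, cin, cout, stride, 0L)
        sub$proj_bn <- add_bn(paste0(pre, "_proj_bn"), cout)
      }
      ops[[length(ops) + 1L]] <- list(kind = "block", prefix = pre,
                                      layers = sub, proj = proj)
      cin <- cout
    }
  }
  ops[[length(ops) + 1L]] <- list(kind = "gap")
  params$fc <- list(W = he_init(c(spec$pooled_dim, spec$output_dim),
                                spec$pooled_dim) / sqrt(2),
                    b = numeric(spec$output_dim))
  ops[[length(ops) + 1L]] <- list(kind = "fc", name = "fc")

  structure(list(spec = spec, params = params, running = running, ops = ops,
                 init_seed = as.integer(seed)),
            class = "eit_network")
}

#' @export
print.eit_network <- function(x, ...) {
  np <- sum(vapply(unlist(x$params, recursive = FALSE), length, 1))
  cat(sprintf("<eit_network> %d stages, pooled dim %d, output dim %d, %s parameters\n",
              length(x$spec$stage_depths), x$spec$pooled_dim,
              x$spec$output_dim, format(np, big.mark = ",")))
  invisible(x)
}

# ---- layer primitives -------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fw <- function(x, p, run, train) {
  d <- dim(x); C <- d[3L]; N <- d[4L]; HW <- d[1L] * d[2L]
  if (train) {
    st <- nn_chan_sums(x, NULL, HW, C, N)
    M <- HW * N
    mu <- st$s1 / M
    v <- st$s2 / M - mu^2
    run$mu <- (1 - BN_MOMENTUM) * run$mu + BN_MOMENTUM * mu
    run$var <- (1 - BN_MOMENTUM) * run$var + BN_MOMENTUM * v
  } else {
    mu <- run$mu; v <- run$var
  }
  ivar <- 1 / sqrt(v + BN_EPS)
  xhat <- nn_chan_affine(x, ivar, -mu * ivar, HW, C, N)
  y <- nn_chan_affine(xhat, p$gamma, p$beta, HW, C, N)
  list(y = y, cache = list(xhat = xhat, ivar = ivar, d = d), run = run)
}

bn_bw <- function(dy, p, cache) {
  d <- cache$d; C <- d[3L]; N <- d[4L]; HW <- d[1L] * d[2L]
  M <- HW * N # normalization count per channel
  st <- nn_chan_sums(dy, cache$xhat, HW, C, N)
  dbeta <- st$s1
  dgamma <- st$s2
  # dx = ivar * gamma * (dy - mean(dy) - xhat * mean(dy * xhat))
  dx <- nn_bn_bw_fuse(dy, cache$xhat, st$s1 / M, st$s2 / M,
                      cache$ivar * p$gamma, HW, C, N)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

gap_fw <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1L] * d[2L], d[3L] * d[4L])
  y <- matrix(colMeans(xm), d[3L], d[4L])
  list(y = y, cache = d)
}

gap_bw <- function(dy, d) {
  per <- 1 / (d[1L] * d[2L])
  dx <- array(rep(as.vector(dy), each = d[1L] * d[2L]) * per, d)
  dx
}

# ---- forward / backward over the op list ------------------------------

net_forward <- function(net, X, train = FALSE, keep_cache = train) {
  caches <- if (keep_cache) vector("list", length(net$ops)) else NULL
  x <- X
  for (oi in seq_along(net$ops)) {
    op <- net$ops[[oi]]
    res <- op_forward(net, op, x, train, keep_cache)
    x <- res$y
    if (keep_cache) caches[[oi]] <- res$cache
    if (train && !is.null(res$run_updates)) {
      for (nm in names(res$run_updates)) net$running[[nm]] <- res$run_updates[[nm]]
    }
  }
  list(out = x, caches = caches, net = net)
}

op_forward <- function(net, op, x, train, keep_cache) {
  switch(op$kind,
    conv = {
      p <- net$params[[op$name]]
      y <- nn_conv2d_fw(x, p$W, p$b, op$stride, op$pad)
      list(y = y, cache = if (keep_cache) list(x = x))
    },
    bn = {
      r <- bn_fw(x, net$params[[op$name]], net$running[[op$name]], train)
      ru <- NULL
      if (train) { ru <- list(); ru[[op$name]] <- r$run }
      list(y = r$y, cache = if (keep_cache) r$cache, run_updates = ru)
    },
    relu = {
      y <- nn_relu(x)
      list(y = y, cache = if (keep_cache) y)
    },
    maxpool = {
      r <- nn_maxpool_fw(x, op$k, op$stride, op$pad)
      list(y = r$y, cache = if (keep_cache) list(idx = r$idx, xdim = dim(x)))
    },
    block = block_forward(net, op, x, train, keep_cache),
    gap = {
      r <- gap_fw(x)
      list(y = r$y, cache = if (keep_cache) r$cache)
    },
    fc = {
      p <- net$params[[op$name]]
      list(y = crossprod(p$W, x) + p$b, cache = if (keep_cache) list(x = x))
    },
    stop("unknown op kind ", op$kind)
  )
}

block_forward <- function(net, op, x, train, keep_cache) {
  sub <- op$layers
  caches <- if (keep_cache) list()
  run_updates <- list()
  h <- x
  seq_ops <- sub[c(1L, 2L, 3L, 4L, 5L, 6L)]
  relu_caches <- list()
  for (i in seq_along(seq_ops)) {
    r <- op_forward(net, seq_ops[[i]], h, train, keep_cache)
    h <- r$y
    if (keep_cache) caches[[i]] <- r$cache
    if (!is.null(r$run_updates)) run_updates <- c(run_updates, r$run_updates)
    if (i %in% c(2L, 4L)) { # ReLU after bn1, bn2
      h <- nn_relu(h)
      if (keep_cache) relu_caches[[length(relu_caches) + 1L]] <- h
    }
  }
  if (op$proj) {
    r1 <- op_forward(net, sub$proj, x, train, keep_cache)
    r2 <- op_forward(net, sub$proj_bn, r1$y, train, keep_cache)
    sc <- r2$y
    if (keep_cache) { caches$proj <- r1$cache; caches$proj_bn <- r2$cache }
    if (!is.null(r1$run_updates)) run_updates <- c(run_updates, r1$run_updates)
    if (!is.null(r2$run_updates)) run_updates <- c(run_updates, r2$run_updates)
  } else {
    sc <- x
  }
  y <- nn_relu(nn_add(h, sc))
  if (keep_cache) {
    caches$out_y <- y
    caches$relu <- relu_caches
  }
  list(y = y, cache = caches,
       run_updates = if (length(run_updates)) run_updates else NULL)
}

net_backward <- function(net, caches, dout) {
  grads <- list()
  dx <- dout
  for (oi in rev(seq_along(net$ops))) {
    op <- net$ops[[oi]]
    r <- op_backward(net, op, dx, caches[[oi]])
    dx <- r$dx
    grads <- c(grads, r$grads)
  }
  grads
}

op_backward <- function(net, op, dy, cache) {
  switch(op$kind,
    conv = {
      p <- net$params[[op$name]]
      r <- nn_conv2d_bw(cache$x, p$W, dy, op$stride, op$pad)
      g <- list(); g[[op$name]] <- list(W = r$dw, b = r$db)
      list(dx = r$dx, grads = g)
    },
    bn = {
      r <- bn_bw(dy, net$params[[op$name]], cache)
      g <- list(); g[[op$name]] <- list(gamma = r$dgamma, beta = r$dbeta)
      list(dx = r$dx, grads = g)
    },
    relu = list(dx = nn_relu_bw(dy, cache), grads = NULL),
    maxpool = list(dx = nn_maxpool_bw(dy, cache$idx, cache$xdim), grads = NULL),
    block = block_backward(net, op, dy, cache),
    gap = list(dx = gap_bw(dy, cache), grads = NULL),
    fc = {
      p <- net$params[[op$name]]
      g <- list()
      g[[op$name]] <- list(W = cache$x %*% t(dy), b = rowSums(dy))
      list(dx = p$W %*% dy, grads = g)
    },
    stop("unknown op kind ", op$kind)
  )
}

block_backward <- function(net, op, dy, cache) {
  sub <- op$layers
  grads <- list()
  dy <- nn_relu_bw(dy, cache$out_y) # final ReLU
  # shortcut branch
  if (op$proj) {
    r2 <- op_backward(net, sub$proj_bn, dy, cache$proj_bn)
    grads <- c(grads, r2$grads)
    r1 <- op_backward(net, sub$proj, r2$dx, cache$proj)
    grads <- c(grads, r1$grads)
    dsc <- r1$dx
  } else {
    dsc <- dy
  }
  # main branch (reverse of conv1-bn1-relu-conv2-bn2-relu-conv3-bn3)
  dh <- dy
  for (i in c(6L, 5L, 4L, 3L, 2L, 1L)) {
    if (i == 4L) dh <- nn_relu_bw(dh, cache$relu[[2L]])
    if (i == 2L) dh <- nn_relu_bw(dh, cache$relu[[1L]])
    r <- op_backward(net, sub[[i]], dh, cache[[i]])
    dh <- r$dx
    grads <- c(grads, r$grads)
  }
  list(dx = dh + dsc, grads = grads)
}
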