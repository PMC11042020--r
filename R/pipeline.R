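# Orchestration of the pipeline stages; the thin command-line wrapper in
# inst/cli/eit3d dispatches to eit_run().

derive_seed <- function(master, stage) {
  offsets <- c(mesh = 11L, simulate = 101L, train = 211L, gn = 307L,
               noise = 401L, split = 503L)
  (as.integer(master) * 1009L + offsets[[stage]]) %% 2147483647L
}

artifact_path <- function(cfg, name) {
  dir.create(cfg$paths$workdir, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$paths$workdir, name)
}

need_artifact <- function(cfg, name, producer) {
  p <- artifact_path(cfg, name)
  stop_if(!file.exists(p), "missing artifact '", name,
          "': run the '", producer, "' command first")
  p
}

#' Run a pipeline stage
#'
#' Subcommands compose the package operations over a shared working
#' directory: `mesh` (build and save the mesh), `simulate` (generate a
#' split sample set), `train` (train the network), `reconstruct`
#' (network prediction for a sample or an external frame CSV), `gn`
#' (Gauss-Newton reconstruction), `evaluate` (metric report over the
#' validation split), `quality` (distribution-similarity metrics
#' between two frame CSVs) and `export` (field to `.vtu`). Every stage
#' derives its seed from the master seed, so partial pipelines are
#' reproducible. Artifacts are RDS/CSV/VTU files under
#' `config$paths$workdir`.
#'
#' @param command one of `"mesh"`, `"simulate"`, `"train"`,
#'   `"reconstruct"`, `"gn"`, `"evaluate"`, `"quality"`, `"export"`.
#' @param config an `eit_config` from [load_config()].
#' @param ... command-specific options: `sample` (index, for
#'   reconstruct/gn/export), `frame_csv` and `frame_csv2` (external
#'   frames), `out` (output path).
#' @return command-dependent: a file path, tibble report, or field;
#'   invisibly where the side effect is the point.
#' @export
eit_run <- function(command = c("mesh", "simulate", "train", "reconstruct",
                                "gn", "evaluate", "quality", "export"),
                    config = default_config(), ...) {
  command <- match.arg(command)
  opts <- list(...)
  switch(command,
    mesh = run_mesh(config),
    simulate = run_simulate(config),
    train = run_train(config),
    reconstruct = run_reconstruct(config, opts),
    gn = run_gn(config, opts),
    evaluate = run_evaluate(config),
    quality = run_quality(config, opts),
    export = run_export(config, opts)
  )
}

run_mesh <- function(cfg) {
  spec <- config_cylinder_spec(cfg)
  mesh <- build_cylinder_mesh(spec, refinement = cfg$mesh$refinement,
                              na = cfg$mesh$na, nr = cfg$mesh$nr)
  saveRDS(mesh, artifact_path(cfg, "mesh.rds"))
  message(sprintf("mesh: %d elements -> %s", mesh$n_elements,
                  artifact_path(cfg, "mesh.rds")))
  invisible(mesh)
}

run_simulate <- function(cfg) {
  mesh <- readRDS(need_artifact(cfg, "mesh.rds", "mesh"))
  cem <- config_cem(cfg)
  protocol <- build_protocol()
  sampler <- phantom_sampler(config_cylinder_spec(cfg),
                             seed = derive_seed(cfg$seed, "simulate"))
  snr <- cfg$noise$snr_db[1L]
  set <- generate_sampleset(mesh, cem, protocol, sampler,
                            n = cfg$dataset$n_samples,
                            noise = noise_spec(snr, derive_seed(cfg$seed, "noise")),
                            kind = cfg$phantom$kind)
  set <- split_sampleset(set, ratio = cfg$dataset$split_ratio,
                         seed = derive_seed(cfg$seed, "split"))
  write_sampleset(set, artifact_path(cfg, "samples.rds"))
  message(sprintf("simulate: %d samples at %g dB -> %s",
                  cfg$dataset$n_samples, snr, artifact_path(cfg, "samples.rds")))
  invisible(set)
}

run_train <- function(cfg) {
  set <- read_sampleset(need_artifact(cfg, "samples.rds", "simulate"))
  spec <- network_spec(output_dim = nrow(set$sigma),
                       stage_depths = cfg$network$stage_depths,
                       stage_widths = cfg$network$stage_widths,
                       expansion = cfg$network$expansion)
  net <- build_network(spec, seed = derive_seed(cfg$seed, "train"))
  tc <- train_config(epochs = cfg$train$epochs,
                     batch_size = cfg$train$batch_size,
                     base_lr = cfg$train$base_lr, alpha = cfg$train$alpha,
                     lr_factor = cfg$train$lr_factor,
                     lr_patience = cfg$train$lr_patience,
                     weight_decay = cfg$train$weight_decay,
                     normalization = cfg$train$normalization,
                     seed = derive_seed(cfg$seed, "train"))
  model <- train_network(net, set, tc, verbose = TRUE)
  saveRDS(model, artifact_path(cfg, "model.rds"))
  utils::write.csv(model$history, artifact_path(cfg, "training_log.csv"),
                   row.names = FALSE)
  message(sprintf("train: final val loss %.5g -> %s",
                  model$history$val_loss[nrow(model$history)],
                  artifact_path(cfg, "model.rds")))
  invisible(model)
}

run_reconstruct <- function(cfg, opts) {
  model <- readRDS(need_artifact(cfg, "model.rds", "train"))
  mesh <- readRDS(need_artifact(cfg, "mesh.rds", "mesh"))
  frame <- if (!is.null(opts$frame_csv)) {
    read_frame_csv(opts$frame_csv)
  } else {
    set <- read_sampleset(need_artifact(cfg, "samples.rds", "simulate"))
    i <- opts$sample %||% 1L
    voltage_frame(set$frames_noisy[, i])
  }
  field <- predict(model, frame, mesh = mesh)
  out <- opts$out %||% artifact_path(cfg, "reconstruction.vtu")
  export_vtk(field, mesh, out)
  message("reconstruct: -> ", out)
  invisible(field)
}

run_gn <- function(cfg, opts) {
  mesh <- readRDS(need_artifact(cfg, "mesh.rds", "mesh"))
  frame <- if (!is.null(opts$frame_csv)) {
    read_frame_csv(opts$frame_csv)
  } else {
    set <- read_sampleset(need_artifact(cfg, "samples.rds", "simulate"))
    i <- opts$sample %||% 1L
    voltage_frame(set$frames_noisy[, i])
  }
  gc <- gn_config(lambda = cfg$gn$lambda, prior = cfg$gn$prior,
                  max_iters = cfg$gn$max_iters,
                  step_halvings = cfg$gn$step_halvings,
                  sigma_floor = cfg$gn$sigma_floor)
  res <- gn_reconstruct(frame, mesh, config_cem(cfg), build_protocol(), gc)
  out <- opts$out %||% artifact_path(cfg, "gn_reconstruction.vtu")
  export_vtk(res$field, mesh, out)
  message(sprintf("gn: IPST %.2f s -> %s", res$ipst_seconds, out))
  invisible(res)
}

run_evaluate <- function(cfg) {
  model <- readRDS(need_artifact(cfg, "model.rds", "train"))
  set <- read_sampleset(need_artifact(cfg, "samples.rds", "simulate"))
  va <- which(set$split == "validation")
  stop_if(length(va) == 0L, "no validation samples to evaluate")
  X <- sampleset_features(set)[, , , va, drop = FALSE]
  pred <- predict(model, X)
  rows <- lapply(seq_along(va), function(k) {
    cbind(tibble::tibble(sample = va[k]),
          evaluate_reconstruction(pred[, k], set$sigma[, va[k]],
                                  metric_config(cfg$metrics$ssim_k1,
                                                cfg$metrics$ssim_k2)))
  })
  report <- do.call(rbind, rows)
  utils::write.csv(report, artifact_path(cfg, "evaluation.csv"),
                   row.names = FALSE)
  message(sprintf("evaluate: %d samples, mean CC %.3f -> %s",
                  nrow(report), mean(report$cc),
                  artifact_path(cfg, "evaluation.csv")))
  report
}

run_quality <- function(cfg, opts) {
  stop_if(is.null(opts$frame_csv) || is.null(opts$frame_csv2),
          "quality needs frame_csv and frame_csv2")
  X <- unclass(read_frame_csv(opts$frame_csv))
  Y <- unclass(read_frame_csv(opts$frame_csv2))
  qc <- quality_config(n_windows = cfg$quality$n_windows,
                       k_neighbors = cfg$quality$k_neighbors,
                       grid_points = cfg$quality$grid_points)
  tibble::tibble(mmd = mmd(X, Y, qc), kde_ise = kde_ise(X, Y, qc),
                 lmmd = lmmd(X, Y, qc), knndc = knndc(X, Y, qc))
}

run_export <- function(cfg, opts) {
  mesh <- readRDS(need_artifact(cfg, "mesh.rds", "mesh"))
  set <- read_sampleset(need_artifact(cfg, "samples.rds", "simulate"))
  i <- opts$sample %||% 1L
  field <- conductivity_field(set$sigma[, i], mesh)
  out <- opts$out %||% artifact_path(cfg, sprintf("truth_%03d.vtu", i))
  export_vtk(field, mesh, out)
  message("export: -> ", out)
  invisible(out)
}
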