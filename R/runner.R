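# Experiment runner: configuration handling, reproducibility manifest,
# checkpoints, and the train / evaluate / simulate-linear entry points.
#
# Checkpoints and saved datasets use RDS (no HDF5 bindings are assumed);
# round-tripping is bit-exact for double-precision weights.

#' Save / load a network checkpoint
#'
#' @param net A \code{hebbnet_network}.
#' @param path File path (conventionally \code{.rds}).
#' @return \code{save_checkpoint} returns \code{path} invisibly;
#'   \code{load_checkpoint} returns the network.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "hebbnet_network"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "hebbnet_network"))
  net
}

default_run_config <- function() {
  list(task = "train", arch = "simpnet", mode = "urfb", loss = "hinge",
       lr = 0.1, epochs = 1L, batch_size = 500L, mu = 1, sparsity = 0,
       seed = 1L, untied = FALSE, init = "independent",
       data = list(n_classes = 3L, image_size = 16L, channels = 1L,
                   n_per_class = 500L, jitter = 1L, noise_sd = 0.1),
       val_fraction = 0.1, out = NULL)
}

#' Read a run configuration file
#'
#' YAML or JSON, mirroring the CLI flags; unspecified fields take the
#' package defaults (learning rate 0.1, batch size 500, hinge loss with
#' mu = 1, the default toy dataset).
#'
#' @param path Config file path (\code{.yaml/.yml} or \code{.json}).
#' @return A complete run-config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  merge_config(default_run_config(), cfg)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

run_manifest <- function(cfg, outputs) {
  list(package = "hebbnet",
       version = as.character(utils::packageVersion("hebbnet")),
       config = cfg, seed = cfg$seed,
       derived_seeds = list(init = derive_seed(cfg$seed, "init"),
                            data = derive_seed(cfg$seed, "data"),
                            shuffle = derive_seed(cfg$seed, "shuffle", 1L)),
       outputs = outputs)
}

toy_from_config <- function(cfg) {
  d <- cfg$data
  ds <- make_toy_dataset(n_classes = d$n_classes, image_size = d$image_size,
                         channels = d$channels, n_per_class = d$n_per_class,
                         jitter = d$jitter, noise_sd = d$noise_sd,
                         seed = cfg$seed)
  split_dataset(ds, cfg$val_fraction, seed = cfg$seed)
}

#' Run an experiment from a configuration
#'
#' Dispatches on \code{config$task}: \code{"train"} (build, train and
#' evaluate a network on the configured toy dataset), \code{"evaluate"} (a
#' checkpoint against the toy dataset) or \code{"simulate-linear"} (the
#' epsilon sweep of the linear dynamics). When \code{config$out} is set, the
#' artifacts — metrics CSV, checkpoint, JSON manifest — are written there;
#' a rerun from the same config reproduces them bitwise (manifest
#' timestamps excluded: none are recorded).
#'
#' @param config A run-config list (see [read_run_config()]) or a path to a
#'   YAML/JSON config file.
#' @return List with the task's results (invisibly when writing to disk).
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(default_run_config(), config)
  out <- cfg$out
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  res <- switch(cfg$task,
    "train" = {
      dat <- toy_from_config(cfg)
      spec <- parse_architecture(cfg$arch, dim(dat$train$x)[1:3],
                                 cfg$data$n_classes, mode = cfg$mode,
                                 sparsity = cfg$sparsity, loss = cfg$loss,
                                 init = cfg$init, untied = cfg$untied)
      net <- build_network(spec, seed = cfg$seed)
      fit <- train_network(net, dat$train, dat$val,
                           list(eta = cfg$lr, batch_size = cfg$batch_size,
                                epochs = cfg$epochs, seed = cfg$seed,
                                mu = cfg$mu, verbose = isTRUE(cfg$verbose)))
      fit
    },
    "evaluate" = {
      net <- load_checkpoint(cfg$checkpoint)
      dat <- toy_from_config(cfg)
      list(val_error = evaluate(net, dat$val),
           train_error = evaluate(net, dat$train))
    },
    "simulate-linear" = {
      lc <- linear_sim_config(dims = cfg$dims %||% c(40L, 100L, 100L, 10L),
                              sd = cfg$sd %||% 0.2,
                              steps = cfg$steps %||% 1000L,
                              dt = cfg$dt %||% 0.005, seed = cfg$seed)
      traces <- sweep_linear(lc, cfg$epsilons %||% c(0, 0.25, 0.5, 1))
      list(traces = traces, frame = sweep_to_frame(traces))
    },
    stop("usage error: unknown task '", cfg$task, "'"))
  if (!is.null(out)) {
    if (!is.null(res$metrics))
      utils::write.csv(res$metrics, file.path(out, "metrics.csv"),
                       row.names = FALSE)
    if (!is.null(res$frame))
      utils::write.csv(res$frame, file.path(out, "linear_sweep.csv"),
                       row.names = FALSE)
    if (!is.null(res$network))
      save_checkpoint(res$network, file.path(out, "checkpoint.rds"))
    jsonlite::write_json(run_manifest(cfg, list.files(out)),
                         file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}

#' Matched-seed comparison of training modes
#'
#' Trains the same architecture on the same data with identical seeds under
#' each requested mode, so all runs share W(0), the shuffles and the
#' dropout draws, and differ only through the feedback rule. Produces a
#' side-by-side error-curve table.
#'
#' @param config Run-config list (task fields as for \code{"train"}).
#' @param modes Character vector from \code{c("bp", "urfb", "frfb")}.
#' @return List with \code{fits} (per-mode training results) and
#'   \code{report} — a data frame with one train/val error column pair per
#'   mode, one row per epoch.
#' @export
compare_modes <- function(config, modes = c("bp", "urfb", "frfb")) {
  cfg <- merge_config(default_run_config(), config)
  cfg$out <- NULL
  fits <- lapply(modes, function(m) {
    c2 <- cfg; c2$mode <- m
    run_experiment(c2)
  })
  names(fits) <- modes
  report <- data.frame(epoch = fits[[1]]$metrics$epoch)
  for (m in modes) {
    report[[paste0(m, "_train_error")]] <- fits[[m]]$metrics$train_error
    report[[paste0(m, "_val_error")]] <- fits[[m]]$metrics$val_error
  }
  list(fits = fits, report = report)
}
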