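# End-to-end orchestration: a single experiment config drives dataset
# generation, baselines, network training, and the single-unit /
# population analyses, with per-stage seeds derived from one master seed
# and every artifact stamped with the config hash.

#' Experiment configuration
#'
#' @param seed master seed; per-stage seeds are derived deterministically
#'   from it, so stages are independently reproducible.
#' @param dataset a [dataset_config()].
#' @param spec an [architecture_spec()] for the trained models.
#' @param tasks which task heads to train.
#' @param n_instantiations paired trained/untrained weight draws.
#' @param max_epochs training epoch cap.
#' @param analysis_layer layer used for the tuning summaries (default:
#'   the middle layer).
#' @param r2_threshold tuned-unit threshold.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              dataset = dataset_config(),
                              spec = desk_architecture(),
                              tasks = c("art", "tdt"),
                              n_instantiations = 2L,
                              max_epochs = 12L,
                              analysis_layer = NULL,
                              r2_threshold = 0.2) {
  cfg <- list(seed = seed, dataset = dataset, spec = spec, tasks = tasks,
              n_instantiations = n_instantiations, max_epochs = max_epochs,
              analysis_layer = analysis_layer, r2_threshold = r2_threshold)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Scalar fields of the YAML override the defaults of
#' [experiment_config()] and [dataset_config()].
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path))
    stop_pt(sprintf("config file not found: %s", path), "pt_io_error")
  y <- yaml::read_yaml(path)
  ds_args <- y$dataset %||% list()
  ds <- do.call(dataset_config, ds_args)
  spec <- if (!is.null(y$spec)) do.call(architecture_spec, y$spec)
          else desk_architecture()
  experiment_config(seed = y$seed %||% 1L, dataset = ds, spec = spec,
                    tasks = y$tasks %||% c("art", "tdt"),
                    n_instantiations = y$n_instantiations %||% 2L,
                    max_epochs = y$max_epochs %||% 12L)
}

#' Desk-scale reference architecture
#'
#' A small spatial-temporal model (one spatial layer, two temporal
#' layers) that trains in minutes on one CPU while preserving the
#' family's structure: muscles are integrated first, time afterwards,
#' with layer normalization and ReLU at every stage.
#'
#' @param seed instantiation seed.
#' @return an [architecture_spec()].
#' @export
desk_architecture <- function(seed = 1L) {
  architecture_spec("spatial-temporal", spatial_filters = 8,
                    temporal_filters = c(16, 16), spatial_kernel = 5,
                    temporal_kernel = 5, spatial_stride = 2,
                    temporal_stride = 3, seed = seed)
}

#' Run the full pipeline
#'
#' Stages: generate (dataset), baselines (pairwise SVMs + linear
#' decoder), train (paired untrained/trained models per task and
#' instantiation), analyze (tuning summaries per layer). Each stage
#' writes its artifact into `out_dir` (named by the config hash) and is
#' skipped on re-run when its artifact already exists.
#'
#' @param config an [experiment_config()].
#' @param out_dir artifact root; a subdirectory per config hash is used.
#' @param stages subset of stages to run.
#' @param verbose print progress.
#' @return invisibly, the artifact directory path.
#' @export
run_pipeline <- function(config = experiment_config(),
                         out_dir = tempfile("propriotask_"),
                         stages = c("generate", "baselines", "train",
                                    "analyze"),
                         verbose = TRUE) {
  art_dir <- file.path(out_dir, config$hash)
  dir.create(art_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  stamp <- list(config_hash = config$hash, seed = config$seed)
  run_stage <- function(name, f) {
    path <- file.path(art_dir, paste0(name, ".rds"))
    if (file.exists(path)) {
      say("stage ", name, ": cached")
      return(readRDS(path))
    }
    say("stage ", name, " ...")
    out <- tryCatch(f(), error = function(e)
      stop_pt(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "pt_stage_failed", stage = name))
    attr(out, "stamp") <- stamp
    saveRDS(out, path)
    out
  }

  ds <- NULL
  if ("generate" %in% stages || any(c("baselines", "train", "analyze") %in% stages)) {
    ds <- run_stage("dataset", function()
      generate_dataset(config$dataset, seed = derive_seed(config$seed, "dataset")))
  }
  if ("baselines" %in% stages) {
    run_stage("baselines", function() {
      tr <- which(ds$split == "train"); te <- which(ds$split == "test")
      Xf <- flatten_inputs(ds)
      svms <- train_pairwise_svms(Xf[tr, ], ds$labels[tr], cv = FALSE,
                                  seed = derive_seed(config$seed, "svm"))
      acc <- svm_accuracy(svms, Xf[te, ], ds$labels[te])
      lin <- linear_position_decoder(ds)
      list(svm = acc, linear_error_cm = lin$test_error_cm)
    })
  }
  models <- NULL
  if (any(c("train", "analyze") %in% stages)) {
    models <- run_stage("models", function() {
      out <- list()
      for (task in config$tasks) {
        for (k in seq_len(config$n_instantiations)) {
          sd_k <- derive_seed(config$seed, paste0(task, k))
          spec <- config$spec; spec$seed <- sd_k
          net0 <- build_network(spec, head = task)
          net1 <- train_network(net0, ds, task = task,
                                max_epochs = config$max_epochs, seed = sd_k)
          out[[paste(task, k, sep = "_")]] <-
            list(task = task, inst = k, untrained = net0, trained = net1)
        }
      }
      out
    })
  }
  if ("analyze" %in% stages) {
    run_stage("analysis", function() {
      hz <- which(ds$manifest$plane == "horizontal")
      if (length(hz) < 10) hz <- which(ds$manifest$plane == "vertical")
      hz <- hz[seq_len(min(length(hz), 200))]
      layer <- config$analysis_layer %||%
        max(1L, ceiling(length(models[[1]]$trained$layers) / 2))
      rows <- list()
      for (nm in names(models)) {
        md <- models[[nm]]
        for (state in c("untrained", "trained")) {
          fits <- layer_tuning_fits(md[[state]], ds, layer, hz, "direction",
                                    seed = derive_seed(config$seed, "fits"))
          tuned <- fits$test_r2 > config$r2_threshold &
            fits$test_r2 != 1 & fits$test_r2 >= -0.1
          rows[[paste(nm, state)]] <- data.frame(
            model = nm, task = md$task, inst = md$inst, state = state,
            layer = layer, n_tuned = sum(tuned),
            uniformity = if (any(tuned)) pd_uniformity(fits$theta_pd[tuned])
                         else NA_real_)
        }
      }
      do.call(rbind, rows)
    })
  }
  say("artifacts in ", art_dir)
  invisible(art_dir)
}
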