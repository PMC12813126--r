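# End-to-end orchestration: each stage reads the previous stage's artifacts,
# writes its own beside a manifest carrying the pipeline config hash, and
# refuses to mix artifacts produced under different configurations.

write_manifest <- function(dir, stage, hash, seed, extra = list()) {
  m <- c(list(stage = stage, config_hash = hash, seed = seed,
              package = as.character(utils::packageVersion("vcgmi"))), extra)
  jsonlite::write_json(m, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

check_manifest <- function(dir, stage, hash, producer) {
  f <- file.path(dir, paste0("manifest_", stage, ".json"))
  if (!file.exists(f))
    stopf("missing %s artifacts in %s: run %s first", stage, dir, producer)
  m <- jsonlite::read_json(f)
  if (!identical(m$config_hash, hash))
    stopf("config hash mismatch in %s (%s vs %s): artifacts come from a different configuration",
          f, m$config_hash, hash)
  invisible(m)
}

#' Assemble a pipeline configuration
#'
#' Bundles the stage parameters and the single master seed from which every
#' source of randomness (generator, folds, learner initializations,
#' permutation shuffles) is derived, plus the configuration hash stamped
#' into every artifact manifest.
#'
#' @param synthetic A [synthetic_config()] (its own seed is overridden by
#'   `seed`).
#' @param filter A [filter_spec()].
#' @param delineation A [delineation_config()].
#' @param aggregate Beat aggregation rule (`"median"` or `"mean"`).
#' @param families Optional classifier family subset.
#' @param k Cross-validation folds.
#' @param seed Master seed.
#' @return List of class `pipeline_config` (with `hash`).
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            filter = filter_spec(fs = synthetic$fs),
                            delineation = delineation_config(),
                            aggregate = "median", families = NULL,
                            k = 10, seed = 1L) {
  synthetic$seed <- derive_seed(seed, "generator")
  cfg <- list(synthetic = synthetic, filter = filter,
              delineation = delineation, aggregate = aggregate,
              families = families, k = k, seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Pipeline stages
#'
#' `pipeline_simulate()` writes a synthetic cohort (CSV records + ground
#' truth); `pipeline_extract()` computes `features.csv` from the cohort (or
#' from any directory of record CSVs); `pipeline_screen()` writes the
#' feature screen as `screen.csv`; `pipeline_train_grid()` writes
#' `grid_results.csv`; `pipeline_stack()` fits the stacking model and writes
#' `stack_report.json` plus `summary.csv`. Every stage is idempotent for a
#' fixed configuration and refuses upstream artifacts written under a
#' different configuration hash.
#'
#' @param config A [pipeline_config()].
#' @param dir Working directory for all artifacts.
#' @return The main artifact path (invisibly for writers); `pipeline_stack`
#'   returns the fitted [vcg_stack] invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$synthetic)
  write_cohort(cohort, file.path(dir, "cohort"))
  write_manifest(dir, "simulate", config$hash, config$seed,
                 list(n_records = length(cohort$records)))
  invisible(file.path(dir, "cohort"))
}

#' @rdname pipeline
#' @export
pipeline_extract <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  check_manifest(dir, "simulate", config$hash, "pipeline_simulate")
  cdir <- file.path(dir, "cohort")
  gt <- jsonlite::read_json(file.path(cdir, "ground_truth.json"))
  records <- lapply(names(gt), function(id)
    read_csv_record(file.path(cdir, paste0(id, ".csv")),
                    fs = config$synthetic$fs, record_id = id,
                    label = gt[[id]]$label[[1]]))
  ft <- cohort_features(records, spec = config$filter,
                        delineation = config$delineation,
                        aggregate = config$aggregate)
  write_feature_table(ft, file.path(dir, "features.csv"))
  write_manifest(dir, "extract", config$hash, config$seed,
                 list(n_records = nrow(ft)))
  invisible(file.path(dir, "features.csv"))
}

#' @rdname pipeline
#' @export
pipeline_screen <- function(config, dir) {
  check_manifest(dir, "extract", config$hash, "pipeline_extract")
  ft <- read_feature_table(file.path(dir, "features.csv"))
  sc <- screen_features(ft)
  utils::write.csv(as.data.frame(sc), file.path(dir, "screen.csv"),
                   row.names = FALSE)
  write_manifest(dir, "screen", config$hash, config$seed)
  invisible(file.path(dir, "screen.csv"))
}

#' @rdname pipeline
#' @export
pipeline_train_grid <- function(config, dir) {
  check_manifest(dir, "extract", config$hash, "pipeline_extract")
  ft <- read_feature_table(file.path(dir, "features.csv"))
  grid <- train_grid(ft, ft$label, seed = config$seed,
                     families = config$families, k = config$k)
  utils::write.csv(grid$summary, file.path(dir, "grid_results.csv"),
                   row.names = FALSE)
  write_manifest(dir, "train_grid", config$hash, config$seed,
                 list(n_configs = nrow(grid$summary),
                      n_unsupported = sum(!grid$summary$supported)))
  assign("last_grid", grid, envir = .vcgmi_state)
  invisible(file.path(dir, "grid_results.csv"))
}

.vcgmi_state <- new.env(parent = emptyenv())

#' @rdname pipeline
#' @export
pipeline_stack <- function(config, dir) {
  check_manifest(dir, "train_grid", config$hash, "pipeline_train_grid")
  ft <- read_feature_table(file.path(dir, "features.csv"))
  grid <- get0("last_grid", envir = .vcgmi_state)
  if (is.null(grid) || !identical(grid$labels, as.character(ft$label)) ||
      !identical(grid$seed, as.integer(config$seed)))
    grid <- train_grid(ft, ft$label, seed = config$seed,
                       families = config$families, k = config$k)
  stack <- vcg_stack(ft, ft$label, grid = grid, seed = config$seed, k = config$k)
  mm <- list()
  for (i in seq_len(nrow(stack$base_summary))) {
    idx <- stack$base_summary$index[i]
    fp <- grid$predictions[[idx]]
    cm <- confusion(grid$labels, fp$labels_pred)
    mm[[fp$config$family]] <- list(metrics = metrics(cm),
                                   auc = roc_auc(fp$scores, grid$labels)$auc,
                                   per_fold_accuracy = fp$per_fold_accuracy,
                                   confusion = cm)
  }
  mm[["STACKING"]] <- list(metrics = stack$metrics, auc = stack$roc$auc,
                           per_fold_accuracy = stack$per_fold_accuracy,
                           confusion = stack$confusion)
  write_report(mm, json_path = file.path(dir, "stack_report.json"),
               csv_path = file.path(dir, "summary.csv"),
               meta = list(seed = config$seed, config_hash = config$hash,
                           base_models = vapply(stack$base_configs, `[[`, "", "id")))
  write_manifest(dir, "stack", config$hash, config$seed)
  invisible(stack)
}
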