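# Run configuration: one YAML (or list) with sections dataset / backbone /
# train / aco / bench / output plus a global seed. Stage artifacts are
# files, so every stage is independently resumable and testable.

.config_keys <- list(
  dataset = c("root", "class_names", "test_fraction"),
  backbone = c("name", "num_classes", "pretrained", "weights_file"),
  train = c("epochs", "learning_rate", "minibatch", "skip_train"),
  aco = c("n_iterations", "n_ants", "subset_size", "alpha", "beta", "q0",
          "elitist", "ants_cap", "subset_cap", "fitness_holdout",
          "mu", "theta", "delta0", "prune_fraction", "heuristic_mode",
          "allow_prune_override"),
  bench = c("folds", "presets", "mode"),
  output = c("dir"),
  seed = NULL)

#' Validate a pipeline run configuration
#'
#' Checks section and key names (unknown keys are rejected), materializes
#' every stage configuration up front — so e.g. an out-of-range
#' `prune_fraction` fails here, before any compute — and fills defaults.
#'
#' @param config a named list or path to a YAML file with sections
#'   `dataset` (root, optional class_names/test_fraction), `backbone`
#'   (name, ...), `train`, `aco`, `bench`, `output` (dir) and a global
#'   `seed`.
#' @return the validated config with stage configs attached.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.config_keys))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in setdiff(names(config), "seed")) {
    bad <- setdiff(names(config[[sec]]), .config_keys[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$dataset$root)) stop("dataset$root is required", call. = FALSE)
  if (is.null(config$output$dir)) stop("output$dir is required", call. = FALSE)
  config$seed <- as.integer(config$seed %||% 1L)
  bk <- config$backbone %||% list()
  config$backbone <- list(name = bk$name %||% "resnet50",
                          num_classes = bk$num_classes %||% 5L,
                          pretrained = isTRUE(bk$pretrained),
                          weights_file = bk$weights_file)
  if (!config$backbone$name %in% .supported_backbones)
    stop("unsupported backbone '", config$backbone$name, "'", call. = FALSE)
  tr <- config$train %||% list()
  config$train_cfg <- train_config(
    epochs = tr$epochs %||% 100L,
    learning_rate = tr$learning_rate %||% 1e-4,
    minibatch = tr$minibatch %||% 64L,
    seed = derive_seed(config$seed, "train"))
  config$skip_train <- isTRUE(tr$skip_train)
  ac <- config$aco %||% list()
  config$aco_cfg <- do.call(aco_config, c(
    ac[intersect(names(ac), .config_keys$aco)],
    list(seed = derive_seed(config$seed, "select"))))
  bn <- config$bench %||% list()
  config$bench_folds <- as.integer(bn$folds %||% 10L)
  config$bench_presets <- bn$presets %||% "all"
  config$bench_mode <- bn$mode %||% "cv10"
  config$test_fraction <- config$dataset$test_fraction %||% 0.2
  config
}

#' Run the full classification pipeline
#'
#' Stages, in order: scan + stratified split of the image dataset; head
#' fine-tuning (unless `train$skip_train`) and deep-feature extraction;
#' ACO feature selection fit on the training rows and applied to the full
#' table; classifier benchmark on the reduced features. Each stage
#' persists its artifact (`manifest.csv`, `features.csv`,
#' `selection.json` + `features_reduced.csv`, `report/`) into the output
#' directory and is skipped on rerun if its artifact already exists
#' (`resume = TRUE`). A `run_metadata.json` sidecar records the package
#' version, the config echo and hash, and all derived stage seeds.
#'
#' @param config list or YAML path; see [validate_run_config()].
#' @param resume reuse existing stage artifacts (default TRUE).
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  cfg <- validate_run_config(config)
  out <- cfg$output$dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list(manifest = file.path(out, "manifest.csv"),
                features = file.path(out, "features.csv"),
                selection = file.path(out, "selection.json"),
                reduced = file.path(out, "features_reduced.csv"),
                report = file.path(out, "report"),
                metadata = file.path(out, "run_metadata.json"))

  meta <- list(package = "octaco",
               version = as.character(packageVersion("octaco")),
               config = cfg[setdiff(names(cfg), c("train_cfg", "aco_cfg"))],
               config_hash = obj_hash(cfg),
               seed = cfg$seed,
               stage_seeds = list(split = derive_seed(cfg$seed, "split"),
                                  train = derive_seed(cfg$seed, "train"),
                                  extract = derive_seed(cfg$seed, "extract"),
                                  select = derive_seed(cfg$seed, "select"),
                                  evaluate = derive_seed(cfg$seed, "evaluate")),
               started = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)

  stage <- function(name, artifact, fn) {
    if (resume && all(file.exists(artifact))) {
      log_msg("stage ", name, ": artifact present, skipping")
      return(invisible(NULL))
    }
    log_msg("stage ", name, ": running")
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  stage("split", paths$manifest, function() {
    m <- scan_dataset(cfg$dataset$root,
                      class_names = unlist(cfg$dataset$class_names) %||% NULL)
    m <- split_manifest(m, test_fraction = cfg$test_fraction,
                        seed = derive_seed(cfg$seed, "split"))
    write_manifest(m, paths$manifest)
  })
  stage("extract", paths$features, function() {
    m <- read_manifest(paths$manifest,
                       class_names = unlist(cfg$dataset$class_names) %||% NULL)
    model <- build_modified_backbone(cfg$backbone$name,
                                     num_classes = cfg$backbone$num_classes,
                                     pretrained = cfg$backbone$pretrained,
                                     weights_file = cfg$backbone$weights_file,
                                     seed = derive_seed(cfg$seed, "extract"))
    if (!cfg$skip_train) {
      ft <- finetune(model, m, cfg$train_cfg)
      model <- ft$model
      log_msg(sprintf("head training: final loss %.4f, train accuracy %.3f",
                      ft$loss_history[length(ft$loss_history)],
                      ft$train_accuracy))
    }
    tab <- extract_features(model, m)
    tab$provenance$split_assignment <- m$records$split
    write_feature_table(tab, paths$features)
  })
  stage("select", c(paths$selection, paths$reduced), function() {
    tab <- read_feature_table(paths$features)
    split_assign <- unlist(tab$provenance$split_assignment)
    train_tab <- if (!is.null(split_assign) && any(split_assign == "train")) {
      idx <- which(split_assign == "train")
      feature_table(tab$matrix[idx, , drop = FALSE], tab$labels[idx],
                    tab$class_names, tab$provenance)
    } else tab
    sel <- run_aco(train_tab, cfg$aco_cfg)
    write_selection(sel, paths$selection)
    write_feature_table(predict(sel, tab), paths$reduced)
  })
  stage("evaluate", file.path(paths$report, "report.csv"), function() {
    tab <- read_feature_table(paths$reduced)
    if (cfg$bench_mode == "holdout") {
      full <- read_feature_table(paths$features)
      mask <- unlist(full$provenance$split_assignment) == "test"
      rep <- crossval_evaluate(tab, presets = cfg$bench_presets,
                               seed = derive_seed(cfg$seed, "evaluate"),
                               mode = "holdout", holdout = mask)
    } else {
      rep <- crossval_evaluate(tab, presets = cfg$bench_presets,
                               folds = cfg$bench_folds,
                               seed = derive_seed(cfg$seed, "evaluate"))
    }
    write_report(rep, paths$report)
  })
  meta$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(paths)
}
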