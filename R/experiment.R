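#' Experiment configuration
#'
#' Describes a full comparison grid: datasets x preprocessing approaches x
#' classifiers, evaluated with the chosen metrics and summarised by the
#' aligned-ranks/Finner comparison. Each (dataset, classifier) pair is one
#' block; each approach is one treatment column.
#'
#' @param datasets named list; each entry is either a [synthetic_spec]
#'   (train set generated from it; a disjoint test set of half the
#'   training size per class is generated from the same class patterns
#'   with a shifted noise seed), a path to a class-folder tree (split
#'   80/20 stratified under the global seed), or
#'   `list(train = path, test = path)` for a fixed test tree.
#' @param approaches character subset of
#'   `c("traditional", "md", "cae")`.
#' @param classifiers named list of argument lists forwarded to
#'   [classifier_spec()] (e.g. `list(smallcnn = list(max_epochs = 10))`).
#' @param metrics character subset of `c("accuracy", "gm", "auc")`.
#' @param alpha significance level of the post-hoc comparison.
#' @param seed global seed; every stage derives its seed from it.
#' @param output_dir optional directory for metric CSVs, report JSONs and
#'   the run manifest.
#' @param cae_settings [cae_train_settings()] used to train the per-dataset
#'   autoencoder for the cae arm.
#' @param md_params list of [md_approach()] arguments.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(datasets, approaches = c("traditional", "md",
                                                       "cae"),
                              classifiers = list(smallcnn = list()),
                              metrics = c("accuracy", "gm", "auc"),
                              alpha = 0.05, seed = 1L, output_dir = NULL,
                              cae_settings = NULL, md_params = list()) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (length(datasets) < 1L || length(classifiers) < 1L)
    stop("need at least one dataset and one classifier", call. = FALSE)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  if (is.null(names(classifiers)))
    names(classifiers) <- paste0("clf", seq_along(classifiers))
  structure(list(datasets = datasets, approaches = approaches,
                 classifiers = classifiers, metrics = metrics,
                 alpha = alpha, seed = as.integer(seed),
                 output_dir = output_dir,
                 cae_settings = cae_settings, md_params = md_params),
            class = "experiment_config")
}

resolve_dataset <- function(entry, seed) {
  if (inherits(entry, "synthetic_spec")) {
    test_spec <- entry
    test_spec$samples_per_class <- max(1L, entry$samples_per_class %/% 2L)
    list(train = generate_dataset(entry),
         test = generate_dataset(test_spec, noise_seed = entry$seed + 77777L))
  } else if (is.character(entry)) {
    ds <- load_image_folder(entry)
    sp <- split_train_validation(ds, 0.2, seed = seed)
    list(train = sp$train, test = sp$validation)
  } else if (is.list(entry) && !is.null(entry$train)) {
    list(train = load_image_folder(entry$train),
         test = load_image_folder(entry$test))
  } else stop("unrecognised dataset entry", call. = FALSE)
}

#' Run the full comparison grid
#'
#' For every dataset: the cae arm first trains an autoencoder on that
#' dataset's training images; each approach then transforms train and test;
#' each classifier is fitted on the transformed training set and evaluated
#' on the transformed test set. Blocks are ordered dataset-major (config
#' dataset order x classifier order) and never reordered, so the
#' statistical reports are reproducible from the CSVs alone. With at least
#' two blocks and two approaches, a [far_compare()] report is produced per
#' metric. Any stage failure aborts with the failing
#' (dataset, approach, classifier) triple named; when an output directory
#' is configured, partial outputs are retained next to a `FAILED` marker.
#'
#' @param cfg an [experiment_config()].
#' @return A list with `tables` (one [metric_table] per metric), `reports`
#'   (one [far_compare()] report per metric, when computable) and `manifest`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  out_dir <- cfg$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  fail <- function(dataset, approach, classifier, err) {
    if (!is.null(out_dir))
      writeLines(sprintf("FAILED at (%s, %s, %s): %s", dataset, approach,
                         classifier, conditionMessage(err)),
                 file.path(out_dir, "FAILED"))
    stop(sprintf("experiment failed at (dataset=%s, approach=%s, classifier=%s): %s",
                 dataset, approach, classifier, conditionMessage(err)),
         call. = FALSE)
  }
  blocks <- as.vector(t(outer(names(cfg$datasets), names(cfg$classifiers),
                              paste, sep = "/")))
  tables <- lapply(cfg$metrics, function(m)
    matrix(NA_real_, length(blocks), length(cfg$approaches),
           dimnames = list(blocks, cfg$approaches)))
  names(tables) <- cfg$metrics
  log <- list()
  for (di in seq_along(cfg$datasets)) {
    dname <- names(cfg$datasets)[di]
    parts <- tryCatch(resolve_dataset(cfg$datasets[[di]], cfg$seed),
                      error = function(e) fail(dname, "-", "-", e))
    cae_model <- NULL
    if ("cae" %in% cfg$approaches) {
      settings <- cfg$cae_settings
      if (is.null(settings))
        settings <- cae_train_settings(max_epochs = 30L, patience = 5L,
                                       seed = cfg$seed)
      t0 <- proc.time()[["elapsed"]]
      cae_model <- tryCatch(train_cae(parts$train, settings),
                            error = function(e) fail(dname, "cae", "-", e))
      log[[length(log) + 1L]] <- list(stage = "train_cae", dataset = dname,
                                      seconds = proc.time()[["elapsed"]] - t0)
    }
    for (ap in cfg$approaches) {
      arm <- switch(ap, traditional = traditional_approach(),
                    md = do.call(md_approach, cfg$md_params),
                    cae = cae_approach(cae_model))
      tr <- tryCatch(apply_approach(arm, parts$train),
                     error = function(e) fail(dname, ap, "-", e))
      te <- tryCatch(apply_approach(arm, parts$test),
                     error = function(e) fail(dname, ap, "-", e))
      for (ci in seq_along(cfg$classifiers)) {
        cname <- names(cfg$classifiers)[ci]
        block <- paste(dname, cname, sep = "/")
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch({
          args <- c(list(n_classes = length(parts$train$class_names),
                         seed = cfg$seed), cfg$classifiers[[ci]])
          fitted <- do.call(classifier_spec, args)
          fitted <- fit_classifier(fitted, tr)
          evaluate_predictions(predict_proba(fitted, te), te$labels)
        }, error = function(e) fail(dname, ap, cname, e))
        for (m in cfg$metrics)
          tables[[m]][block, ap] <- switch(m, accuracy = res$accuracy,
                                           gm = res$gm, auc = res$auc)
        log[[length(log) + 1L]] <- list(stage = "fit_eval", dataset = dname,
                                        approach = ap, classifier = cname,
                                        seconds = proc.time()[["elapsed"]] - t0)
      }
    }
  }
  tables <- lapply(cfg$metrics, function(m)
    metric_table(tables[[m]], metric_name = m, higher_is_better = TRUE))
  names(tables) <- cfg$metrics
  reports <- list()
  for (m in cfg$metrics) {
    if (nrow(tables[[m]]$values) >= 2L && length(cfg$approaches) >= 2L)
      reports[[m]] <- far_compare(tables[[m]], cfg$alpha)
  }
  manifest <- list(seed = cfg$seed, approaches = cfg$approaches,
                   metrics = cfg$metrics, blocks = blocks,
                   alpha = cfg$alpha, log = log,
                   package_version = as.character(utils::packageVersion("caecnn")))
  if (!is.null(out_dir)) {
    for (m in cfg$metrics)
      write_metric_table(tables[[m]], file.path(out_dir,
                                                sprintf("metric_%s.csv", m)))
    for (m in names(reports))
      jsonlite::write_json(far_report_to_list(reports[[m]]),
                           file.path(out_dir, sprintf("far_%s.json", m)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(tables = tables, reports = reports, manifest = manifest)
}
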