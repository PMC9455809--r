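# End-to-end inter-patient pipeline: resample -> fiducials -> beat
# features -> MI selection (train side only) -> segment labels ->
# class-balanced forest -> evaluation on the held-out patients.

#' Pipeline configuration
#'
#' @param n_f Number of MI-selected conventional features (default 6).
#' @param n_trees Forest size (default 200).
#' @param seed Seed driving the MI estimator and the forest.
#' @param lead Lead used for beat morphology.
#' @param seglabel `NULL` (no context feature) or a list with
#'   `provider` (`"oracle"` or a `segment_classifier`), `overlap`
#'   (`"none"`/`"half"`), `length_s`, and for the oracle provider
#'   `label_set` and `error_rate`.
#' @param exclude_truncated Drop boundary-truncated beats from
#'   training/evaluation (default `FALSE`: keep them).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_f = 6, n_trees = 200, seed = 1L, lead = 1,
                            seglabel = NULL, exclude_truncated = FALSE) {
  if (!is.null(seglabel)) {
    known <- c("provider", "overlap", "length_s", "label_set",
               "error_rate", "seed")
    bad <- setdiff(names(seglabel), known)
    if (length(bad)) stop("unknown seglabel keys: ",
                          paste(bad, collapse = ", "))
    seglabel$overlap <- match.arg(seglabel$overlap %||% "none",
                                  c("none", "half"))
    seglabel$length_s <- seglabel$length_s %||% 60
    seglabel$error_rate <- seglabel$error_rate %||% 0
    seglabel$label_set <- seglabel$label_set %||% c("NSR", "AFIB_LIKE")
  }
  structure(list(n_f = n_f, n_trees = n_trees, seed = as.integer(seed),
                 lead = lead, seglabel = seglabel,
                 exclude_truncated = exclude_truncated),
            class = "pipeline_config")
}

entry_record <- function(entry) {
  if (inherits(entry, "ecg_record")) entry else entry$record
}

make_seg_provider <- function(cfg, dataset) {
  sl <- cfg$seglabel
  if (is.null(sl)) return(NULL)
  if (inherits(sl$provider, "segment_classifier")) return(sl$provider)
  if (identical(sl$provider, "oracle")) {
    truths <- lapply(dataset, function(e) e$truth)
    return(oracle_classifier(truths, label_set = sl$label_set,
                             error_rate = sl$error_rate,
                             seed = sl$seed %||% cfg$seed))
  }
  stop("unknown segment-label provider")
}

# feature table + AAMI label + segment-label columns for one record
prepare_beat_table <- function(entry, cfg, provider,
                               feature_cache = NULL) {
  rec <- entry_record(entry)
  feats <- if (!is.null(feature_cache) &&
               rec$record_id %in% names(feature_cache)) {
    feature_cache[[rec$record_id]]
  } else {
    beat_features(rec, lead = cfg$lead)
  }
  out <- dplyr::mutate(feats, class = aami_group(.data$symbol),
                       record_id = rec$record_id)
  if (!is.null(provider)) {
    labeling <- assign_segment_labels(
      rec, provider, length_s = cfg$seglabel$length_s,
      overlap = cfg$seglabel$overlap)
    out <- dplyr::bind_cols(out, seglabel_features(labeling))
  }
  if (cfg$exclude_truncated) out <- dplyr::filter(out, !.data$truncated)
  out
}

#' Run the full heartbeat-classification pipeline
#'
#' Trains on the `split$train` records and evaluates on the disjoint
#' `split$test` records (inter-patient protocol, asserted). MI feature
#' selection sees only training labels; test records are not touched
#' until the model is fitted.
#'
#' @param dataset Named list of records: each element an
#'   [ecg_record()] or a `list(record, truth)` pair from the synthetic
#'   generator.
#' @param split List with `train` and `test` record-id vectors.
#' @param config A [pipeline_config()].
#' @param feature_cache Optional named list (record id -> precomputed
#'   [beat_features()] table) to avoid recomputation across pipeline
#'   variants.
#' @param mi_table Optional precomputed [mi_rank()] table for the
#'   training side (the ranking depends only on the training features
#'   and labels, so pipeline variants that differ in the
#'   segment-label configuration can share it).
#' @return A `segbeat_run`: list with `report` (an `eval_report`),
#'   `mi_table`, `selected_features`, `model_features` (columns fed to
#'   the forest, before one-hot expansion), `model`, `predictions`
#'   tibble, `config`, `split`.
#' @export
run_pipeline <- function(dataset, split, config = pipeline_config(),
                         feature_cache = NULL, mi_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(intersect(split$train, split$test))) {
    stop("inter-patient violation: train and test records overlap")
  }
  missing <- setdiff(c(split$train, split$test), names(dataset))
  if (length(missing)) stop("records not in dataset: ",
                            paste(missing, collapse = ", "))
  provider <- make_seg_provider(config, dataset)

  train_tbl <- dplyr::bind_rows(lapply(
    dataset[split$train], prepare_beat_table, cfg = config,
    provider = provider, feature_cache = feature_cache))
  if (is.null(mi_table)) {
    mi_table <- mi_rank(train_tbl[, feature_names()], train_tbl$class,
                        seed = config$seed)
  }
  selected <- select_top(mi_table, config$n_f)
  seg_cols <- setdiff(names(train_tbl),
                      c(feature_names(), "beat", "symbol", "truncated",
                        "class", "record_id"))
  model_features <- c(selected, seg_cols)
  model <- train_forest(train_tbl[, model_features, drop = FALSE],
                        train_tbl$class, n_trees = config$n_trees,
                        seed = config$seed)

  test_tbl <- dplyr::bind_rows(lapply(
    dataset[split$test], prepare_beat_table, cfg = config,
    provider = provider, feature_cache = feature_cache))
  pred <- predict(model, test_tbl[, model_features, drop = FALSE])
  report <- evaluate_predictions(test_tbl$class, pred)
  structure(list(
    report = report, mi_table = mi_table, selected_features = selected,
    model_features = model_features, model = model,
    predictions = tibble::tibble(record_id = test_tbl$record_id,
                                 beat = test_tbl$beat,
                                 truth = test_tbl$class, pred = pred),
    config = config, split = split), class = "segbeat_run")
}

#' @export
print.segbeat_run <- function(x, ...) {
  cat(sprintf("<segbeat_run: %d train / %d test records>\n",
              length(x$split$train), length(x$split$test)))
  cat("selected features:", paste(x$model_features, collapse = ", "), "\n")
  print(x$report)
  invisible(x)
}

#' @export
tidy.segbeat_run <- function(x, ...) tidy(x$report)

#' @export
glance.segbeat_run <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(
    n_train_records = length(x$split$train),
    n_test_records = length(x$split$test)), glance(x$report))
}

#' Leave-one-patient-out tuning of the forest size
#'
#' For each candidate tree count, trains on all-but-one training
#' record and validates on the held-out record; folds equal the
#' number of training records, the objective is the fold-averaged
#' macro-F1, and ties go to the smaller forest.
#'
#' @param dataset As in [run_pipeline()].
#' @param train_ids Training record ids (>= 2).
#' @param grid Candidate `n_trees` values.
#' @param config A [pipeline_config()] (its `n_trees` is ignored).
#' @param feature_cache Optional feature cache (see [run_pipeline()]).
#' @return List with `best_n_trees` and `scores` (tibble: `n_trees`,
#'   `held_out`, `macro_f1`).
#' @export
lopo_tune <- function(dataset, train_ids, grid,
                      config = pipeline_config(),
                      feature_cache = NULL) {
  stopifnot(length(train_ids) >= 2)
  rows <- list()
  for (nd in grid) {
    cfg <- config
    cfg$n_trees <- nd
    for (held in train_ids) {
      run <- run_pipeline(dataset,
                          list(train = setdiff(train_ids, held),
                               test = held),
                          cfg, feature_cache = feature_cache)
      rows[[length(rows) + 1]] <- tibble::tibble(
        n_trees = nd, held_out = held,
        macro_f1 = run$report$macro_f1)
    }
  }
  scores <- dplyr::bind_rows(rows)
  by_nd <- scores |>
    dplyr::summarise(mean_f1 = mean(.data$macro_f1),
                     .by = "n_trees") |>
    dplyr::arrange(dplyr::desc(.data$mean_f1), .data$n_trees)
  list(best_n_trees = by_nd$n_trees[1], scores = scores,
       summary = by_nd)
}

#' Precompute beat-feature tables for a dataset
#'
#' @param dataset As in [run_pipeline()].
#' @param lead Morphology lead.
#' @return Named list of [beat_features()] tables keyed by record id.
#' @export
compute_feature_cache <- function(dataset, lead = 1) {
  out <- lapply(dataset, function(e) beat_features(entry_record(e),
                                                   lead = lead))
  stats::setNames(out, vapply(dataset,
                              function(e) entry_record(e)$record_id, ""))
}
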