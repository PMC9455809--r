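# Packaged desk-scale experiments: the segment-label uplift study on
# the canonical context dataset, and a scaled-down training run of the
# CNN rhythm classifier. Both are deterministic given their seeds and
# are what the test suite and the reproduction script execute.

#' Segment-label uplift experiment
#'
#' For each seed: generate the canonical context dataset (about 1500
#' beats in 20 records), run the pipeline without any segment label,
#' and run it with the oracle segment label at each requested error
#' rate (paired: same records, same features, same forest seed). The
#' uplift is the macro-F1 difference (with minus without).
#'
#' @param seeds Integer vector of dataset/pipeline seeds.
#' @param n_records Records per dataset.
#' @param error_rates Oracle error rates to evaluate (0 = perfect
#'   context). With a two-label rhythm set, rates above 0.5 make the
#'   label anti-correlated rather than uninformative (a label flip is
#'   a bijection), so the informative decay range is `[0, 0.5]`.
#' @param seg_length_s Segment length for the oracle labeling; 30 s
#'   aligns segments with the dataset's rhythm blocks.
#' @return Tibble with one row per (seed, error_rate): `seed`,
#'   `error_rate`, `macro_f1_base`, `macro_f1_seg`, `uplift`.
#' @export
segment_label_uplift <- function(seeds = 1:10, n_records = 20,
                                 error_rates = c(0, 0.25, 0.5),
                                 seg_length_s = 30) {
  rows <- list()
  for (sd in seeds) {
    ds <- generate_context_dataset(n_records = n_records, seed = sd)
    split <- context_split(ds)
    cache <- compute_feature_cache(ds)
    base <- run_pipeline(ds, split, pipeline_config(seed = sd),
                         feature_cache = cache)
    for (er in error_rates) {
      cfg <- pipeline_config(
        seed = sd,
        seglabel = list(provider = "oracle", overlap = "none",
                        length_s = seg_length_s, error_rate = er))
      seg <- run_pipeline(ds, split, cfg, feature_cache = cache,
                          mi_table = base$mi_table)
      rows[[length(rows) + 1]] <- tibble::tibble(
        seed = sd, error_rate = er,
        macro_f1_base = base$report$macro_f1,
        macro_f1_seg = seg$report$macro_f1,
        uplift = seg$report$macro_f1 - base$report$macro_f1)
    }
  }
  dplyr::bind_rows(rows)
}

#' Scaled-down CNN rhythm-classifier training run
#'
#' Generates single-rhythm-per-minute synthetic records, builds a
#' reduced instance of the CNN segment classifier (12 filters at a
#' 36 Hz input rate, dropout scaled to 0.15 to match the narrow
#' layers), trains on `n_train` 60 s segments and reports accuracy on
#' `n_test` held-out segments.
#'
#' @param seed Seed for data, initialization and training.
#' @param n_train,n_test Training and held-out segment counts.
#' @param epochs Training epochs.
#' @param n_filters,input_fs,fc,dropout Reduced-instance shape.
#' @return List with `accuracy` (held-out), `clf` (trained
#'   classifier), `n_train`, `n_test`.
#' @export
cnn_training_demo <- function(seed = 1L, n_train = 200, n_test = 50,
                              epochs = 30, n_filters = 12,
                              input_fs = 36, fc = c(32, 16),
                              dropout = 0.15) {
  n_records <- ceiling((n_train + n_test) / 2)
  ds <- lapply(stats::setNames(nm = sprintf("R%03d", seq_len(n_records))),
               function(id) {
    k <- as.integer(sub("^R", "", id))
    blocks <- if (k %% 2 == 0) {
      data.frame(label = c("NSR", "AFIB_LIKE"), duration_s = c(60, 60))
    } else {
      data.frame(label = c("AFIB_LIKE", "NSR"), duration_s = c(60, 60))
    }
    generate_ecg(synth_config(seed = seed * 31 + 7,
                              rhythm_blocks = blocks, noise_sd = 0.05),
                 id)
  })
  clf <- build_rhythm_cnn(c("NSR", "AFIB_LIKE"), input_fs = input_fs,
                          n_filters = n_filters, fc = fc,
                          dropout = dropout, seed = seed)
  td <- cnn_training_segments(ds, clf)
  ord <- with_local_rng(as.integer(seed), sample(nrow(td$x)))
  tr <- ord[seq_len(n_train)]
  te <- ord[n_train + seq_len(min(n_test, length(ord) - n_train))]
  clf <- train_rhythm_cnn(clf, td$x[tr, , drop = FALSE], td$labels[tr],
                          epochs = epochs, batch_size = 8, seed = seed)
  p <- predict_rhythm_cnn(clf, td$x[te, , drop = FALSE])
  pred <- clf$label_set[max.col(p, ties.method = "first")]
  list(accuracy = mean(pred == td$labels[te]), clf = clf,
       n_train = length(tr), n_test = length(te))
}
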