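# Record segmentation, segment preprocessing, and the per-beat
# rhythm-context feature: each beat inherits the rhythm class
# predicted for the segment(s) containing it, encoded either as one
# categorical label ID (no overlap) or as a multi-hot bit vector over
# the label set (half overlap).

#' Segment a record into fixed-length windows
#'
#' With `overlap = "none"` consecutive non-overlapping windows of
#' `length_s` partition the record (last partial window kept); with
#' `overlap = "half"` the stride is `length_s / 2` and segments are
#' generated until the record is covered (a trailing start that adds
#' no coverage is not emitted).
#'
#' @param rec An [ecg_record()].
#' @param length_s Segment length in seconds.
#' @param overlap `"none"` or `"half"`.
#' @return Tibble `segment`, `start_sample`, `end_sample` (1-based,
#'   inclusive).
#' @export
segment_record <- function(rec, length_s = 60, overlap = c("none", "half")) {
  overlap <- match.arg(overlap)
  stopifnot(inherits(rec, "ecg_record"), length_s > 0)
  n <- rec$n_samples
  L <- max(1L, as.integer(round(length_s * rec$fs)))
  stride <- if (overlap == "none") L else max(1L, L %/% 2L)
  starts <- integer(0); s <- 1L
  repeat {
    starts <- c(starts, s)
    if (s + L - 1L >= n) break
    s <- s + stride
    if (s > n) break
  }
  tibble::tibble(segment = seq_along(starts), start_sample = starts,
                 end_sample = pmin(starts + L - 1L, n))
}

#' Preprocess one ECG segment for a segment classifier
#'
#' Baseline removal by two consecutive median filters (200 ms then
#' 600 ms kernels), amplitude normalization by `scale` (the maximum
#' absolute baseline-free amplitude of the record; zero-safe),
#' resampling to `out_fs`, and cut/zero-pad to `out_len` samples
#' (defaults: 360 Hz and 21600 samples, i.e. 60 s).
#'
#' @param x Single-lead numeric waveform.
#' @param fs Its sampling rate, Hz.
#' @param out_fs Classifier input rate, Hz.
#' @param out_len Classifier input length, samples.
#' @param scale Amplitude divisor; default the segment's own max
#'   absolute value after baseline removal.
#' @return Numeric vector of length `out_len`.
#' @export
preprocess_segment <- function(x, fs, out_fs = 360, out_len = 21600,
                               scale = NULL) {
  y <- remove_baseline(x, fs)
  if (is.null(scale)) scale <- max(abs(y))
  if (scale > 0) y <- y / scale
  if (!isTRUE(all.equal(fs, out_fs))) {
    y <- fft_resample(y, as.integer(round(length(y) * out_fs / fs)))
  }
  if (length(y) >= out_len) y[seq_len(out_len)] else c(y, numeric(out_len - length(y)))
}

remove_baseline <- function(x, fs) {
  odd <- function(k) {
    k <- max(1L, as.integer(round(k)))
    k <- min(k, length(x) - (length(x) + 1L) %% 2L)
    if (k %% 2L == 0L) k + 1L else k
  }
  if (length(x) < 5) return(x - stats::median(x))
  b1 <- stats::runmed(x, odd(0.2 * fs))
  b2 <- stats::runmed(b1, odd(0.6 * fs))
  x - b2
}

#' Oracle segment classifier for synthetic records
#'
#' A test double standing in for a trained rhythm classifier: it
#' returns, with probability 1, the true rhythm label of the block
#' covering the majority of each segment, optionally corrupted at a
#' configured error rate (a uniformly chosen wrong label, seeded), to
#' emulate different segment-label quality levels.
#'
#' @param truths Named list of synthetic truth objects (one per record
#'   id, as produced by [generate_ecg()]), or a single truth object.
#' @param label_set Ordered rhythm label names (defines label IDs).
#' @param error_rate Probability that a segment gets a wrong label.
#' @param seed Seed for the corruption stream.
#' @return A `segment_classifier` of subclass
#'   `oracle_segment_classifier`.
#' @export
oracle_classifier <- function(truths, label_set = c("NSR", "AFIB_LIKE"),
                              error_rate = 0, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  if (!is.null(truths$beats)) truths <- list(truths)
  structure(list(label_set = label_set, segment_length_s = 60,
                 input_fs = 360, truths = truths,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = c("oracle_segment_classifier", "segment_classifier"))
}

#' Predict rhythm-class probabilities for record segments
#'
#' @param clf A `segment_classifier`.
#' @param rec An [ecg_record()].
#' @param bounds Output of [segment_record()].
#' @return Matrix (segments x labels) of probabilities.
#' @export
predict_segments <- function(clf, rec, bounds) {
  UseMethod("predict_segments")
}

#' @export
predict_segments.oracle_segment_classifier <- function(clf, rec, bounds) {
  truth <- if (!is.null(names(clf$truths)) &&
               rec$record_id %in% names(clf$truths)) {
    clf$truths[[rec$record_id]]
  } else {
    clf$truths[[1]]
  }
  if (!is.null(truth$truth)) truth <- truth$truth
  blocks <- truth$blocks
  lab <- vapply(seq_len(nrow(bounds)), function(i) {
    ov <- pmin(bounds$end_sample[i], blocks$end_sample) -
      pmax(bounds$start_sample[i], blocks$start_sample) + 1
    blocks$label[which.max(pmax(ov, 0))]
  }, "")
  if (clf$error_rate > 0) {
    lab <- with_local_rng(
      derive_record_seed(clf$seed * 7L + 13L, rec$record_id), {
        vapply(lab, function(l) {
          if (stats::runif(1) < clf$error_rate) {
            sample(setdiff(clf$label_set, l), 1)
          } else l
        }, "")
      })
  }
  probs <- matrix(0, nrow(bounds), length(clf$label_set),
                  dimnames = list(NULL, clf$label_set))
  probs[cbind(seq_len(nrow(bounds)), match(lab, clf$label_set))] <- 1
  probs
}

#' Assign segment labels to beats
#'
#' Segments the record, predicts a rhythm class per segment with the
#' given classifier, and encodes the result per beat: with no overlap
#' each beat gets the categorical label ID of its unique segment; with
#' half overlap each beat gets a multi-hot bit vector over the label
#' set (one bit per label predicted for any covering segment; interior
#' beats are covered by at most two segments).
#'
#' @param rec An [ecg_record()].
#' @param clf A `segment_classifier`.
#' @param length_s Segment length in seconds (default: the
#'   classifier's).
#' @param overlap `"none"` or `"half"`.
#' @return A `segment_labeling` object: list with `segments` (tibble
#'   `segment`, `start_sample`, `end_sample`, `label`), `probs`
#'   (segments x labels matrix), `overlap`, `label_set` and `beat` (a
#'   tibble with per-beat encoding: `label_id`/`label` for no overlap,
#'   `bit_<label>` columns for half overlap).
#' @export
assign_segment_labels <- function(rec, clf,
                                  length_s = clf$segment_length_s,
                                  overlap = c("none", "half")) {
  overlap <- match.arg(overlap)
  bounds <- segment_record(rec, length_s, overlap)
  probs <- predict_segments(clf, rec, bounds)
  pred <- clf$label_set[max.col(probs, ties.method = "first")]
  covers <- function(r) {
    which(bounds$start_sample <= r & bounds$end_sample >= r)
  }
  if (overlap == "none") {
    seg_of <- vapply(rec$r_peaks, function(r) covers(r)[1], 0L)
    if (anyNA(seg_of)) stop("internal error: beat outside all segments")
    beat <- tibble::tibble(
      beat = seq_along(rec$r_peaks),
      label = pred[seg_of],
      label_id = match(pred[seg_of], clf$label_set))
  } else {
    bits <- t(vapply(rec$r_peaks, function(r) {
      segs <- covers(r)
      if (!length(segs)) stop("internal error: beat outside all segments")
      as.integer(clf$label_set %in% pred[segs])
    }, integer(length(clf$label_set))))
    colnames(bits) <- paste0("bit_", clf$label_set)
    beat <- dplyr::bind_cols(
      tibble::tibble(beat = seq_along(rec$r_peaks)),
      tibble::as_tibble(bits))
  }
  structure(list(
    segments = dplyr::mutate(bounds, label = pred),
    probs = probs, overlap = overlap, label_set = clf$label_set,
    beat = beat), class = "segment_labeling")
}

#' Per-beat segment-label feature columns
#'
#' Converts a [assign_segment_labels()] result into feature columns
#' for the beat classifier: a single categorical factor `seg_label`
#' (no overlap; declared categorical, not ordinal) or 0/1 columns
#' `seg_<label>` (half overlap).
#'
#' @param labeling A `segment_labeling`.
#' @return Tibble with one row per beat.
#' @export
seglabel_features <- function(labeling) {
  stopifnot(inherits(labeling, "segment_labeling"))
  if (labeling$overlap == "none") {
    tibble::tibble(seg_label = factor(labeling$beat$label,
                                      levels = labeling$label_set))
  } else {
    out <- labeling$beat[, paste0("bit_", labeling$label_set)]
    stats::setNames(out, paste0("seg_", labeling$label_set))
  }
}
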