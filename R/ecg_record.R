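#' ECG record container
#'
#' An `ecg_record` holds a sampled ECG waveform (one or two leads, mV),
#' its sampling rate, and the beat annotation stream: R-peak sample
#' indices (1-based) with one MIT-BIH-alphabet symbol per beat.
#'
#' @param signal Numeric vector (single lead) or matrix with one column
#'   per lead, in mV.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param r_peaks Integer vector of R-peak sample indices, 1-based,
#'   strictly increasing, within `[1, n_samples]`.
#' @param beat_symbols Character vector of one-character beat symbols,
#'   same length as `r_peaks`.
#' @param record_id Record identifier string.
#'
#' @return An object of class `ecg_record` with fields `record_id`,
#'   `signal` (matrix, samples x leads), `fs`, `r_peaks`,
#'   `beat_symbols`, and derived `n_samples`, `duration_s`.
#' @export
ecg_record <- function(signal, fs, r_peaks, beat_symbols,
                       record_id = "record") {
  if (is.vector(signal)) signal <- matrix(as.numeric(signal), ncol = 1)
  storage.mode(signal) <- "double"
  stopifnot(is.numeric(fs), length(fs) == 1)
  if (fs <= 0) stop("fs must be positive")
  r_peaks <- as.integer(r_peaks)
  beat_symbols <- as.character(beat_symbols)
  if (length(r_peaks) != length(beat_symbols)) {
    stop("r_peaks and beat_symbols must have the same length")
  }
  n <- nrow(signal)
  if (length(r_peaks)) {
    bad <- which(diff(r_peaks) <= 0)
    if (length(bad)) {
      stop(sprintf("r_peaks not strictly increasing at index %d", bad[1]))
    }
    if (any(r_peaks < 1L) || any(r_peaks > n)) {
      stop("r_peaks outside the sampled signal")
    }
  }
  structure(
    list(record_id = as.character(record_id), signal = signal, fs = fs,
         r_peaks = r_peaks, beat_symbols = beat_symbols,
         n_samples = n, duration_s = n / fs),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d lead(s), %.1f s @ %g Hz, %d beats>\n",
              x$record_id, ncol(x$signal), x$duration_s, x$fs,
              length(x$r_peaks)))
  invisible(x)
}

#' Beat annotations as a tibble
#'
#' @param rec An `ecg_record`.
#' @return A tibble with columns `beat`, `r_peak`, `symbol`.
#' @export
beats <- function(rec) {
  stopifnot(inherits(rec, "ecg_record"))
  tibble::tibble(beat = seq_along(rec$r_peaks), r_peak = rec$r_peaks,
                 symbol = rec$beat_symbols)
}

#' Read an ECG record
#'
#' Two on-disk dialects are supported. The csv dialect is a pair of
#' plain-text files, `<id>.signal.csv` (one sample per row, one column
#' per lead, mV) and `<id>.beats.csv` (columns `r_peak_sample` (1-based)
#' and `symbol`). The wfdb dialect reads a standard header/.dat/.atr
#' triple (formats 212 and 16); see [read_wfdb()].
#'
#' @param path For csv: the record stem (with or without `.signal.csv`).
#'   For wfdb: the record stem (with or without `.hea`).
#' @param dialect `"csv"` or `"wfdb"`; `"auto"` picks by the files present.
#' @return An [ecg_record()].
#' @export
read_ecg <- function(path, dialect = c("auto", "csv", "wfdb")) {
  dialect <- match.arg(dialect)
  stem <- sub("\\.(signal\\.csv|beats\\.csv|hea|dat|atr)$", "", path)
  if (dialect == "auto") {
    dialect <- if (file.exists(paste0(stem, ".hea"))) "wfdb" else "csv"
  }
  if (dialect == "wfdb") return(read_wfdb(stem))
  sig_f <- paste0(stem, ".signal.csv")
  ann_f <- paste0(stem, ".beats.csv")
  if (!file.exists(sig_f)) stop("signal file not found: ", sig_f)
  if (!file.exists(ann_f)) {
    stop("missing annotations: beat file not found: ", ann_f)
  }
  sig <- as.matrix(utils::read.csv(sig_f))
  ann <- utils::read.csv(ann_f, colClasses = c("integer", "character"))
  meta_f <- paste0(stem, ".meta.json")
  fs <- if (file.exists(meta_f)) {
    jsonlite::read_json(meta_f)$fs
  } else {
    360
  }
  ecg_record(sig, fs, ann$r_peak_sample, ann$symbol,
             record_id = basename(stem))
}

#' Write an ECG record in the csv dialect
#'
#' @param rec An `ecg_record`.
#' @param dir Output directory (created if needed).
#' @return The record stem path, invisibly.
#' @export
write_ecg <- function(rec, dir) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, rec$record_id)
  sig <- as.data.frame(rec$signal)
  names(sig) <- paste0("lead", seq_len(ncol(sig)))
  utils::write.csv(sig, paste0(stem, ".signal.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(r_peak_sample = rec$r_peaks, symbol = rec$beat_symbols),
    paste0(stem, ".beats.csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, record_id = rec$record_id),
                       paste0(stem, ".meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' Resample an ECG record
#'
#' Fourier-domain resampling of every lead (band-limited
#' interpolation, zero group delay); R-peak indices are rescaled by
#' `fs_out/fs` and rounded to the nearest sample. The beat count is
#' always preserved.
#'
#' @param rec An `ecg_record`.
#' @param fs_out Target rate in Hz.
#' @return A resampled `ecg_record`.
#' @export
resample_ecg <- function(rec, fs_out) {
  stopifnot(inherits(rec, "ecg_record"), fs_out > 0)
  if (isTRUE(all.equal(fs_out, rec$fs))) return(rec)
  n_out <- as.integer(round(rec$n_samples * fs_out / rec$fs))
  sig <- apply(rec$signal, 2, fft_resample, n_out = n_out)
  if (is.vector(sig)) sig <- matrix(sig, ncol = 1)
  pk <- pmin(pmax(as.integer(round((rec$r_peaks - 1) * fs_out / rec$fs)) + 1L,
                  1L), n_out)
  # rounding collisions are possible only at extreme downsampling; keep
  # strict monotonicity by nudging forward
  if (length(pk) > 1) {
    for (i in 2:length(pk)) if (pk[i] <= pk[i - 1]) pk[i] <- pk[i - 1] + 1L
    pk <- pmin(pk, n_out)
  }
  ecg_record(sig, fs_out, pk, rec$beat_symbols, rec$record_id)
}

# Fourier-domain resampling to n_out samples over the same duration:
# truncate or zero-pad the spectrum, splitting the Nyquist bin when the
# retained band has even length (as in standard band-limited resampling)
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  m <- min(n, n_out)
  Xo <- complex(n_out)
  nh <- m %/% 2L
  Xo[1:(nh + 1L)] <- X[1:(nh + 1L)]
  if (nh >= 1L) {
    neg <- nh - (1L - m %% 2L)  # count of negative-frequency bins kept
    if (neg >= 1L) {
      Xo[(n_out - neg + 1L):n_out] <- X[(n - neg + 1L):n]
    }
    if (m %% 2L == 0L) {
      # shared Nyquist bin: halve and mirror to keep the signal real
      if (n_out > n) {
        Xo[nh + 1L] <- X[nh + 1L] / 2
        Xo[n_out - nh + 1L] <- X[nh + 1L] / 2
      } else {
        Xo[nh + 1L] <- X[nh + 1L] + X[n - nh + 1L]
      }
    }
  }
  Re(stats::fft(Xo, inverse = TRUE)) * n_out / n / n_out
}

#' Beat-window working rate (Hz) and window geometry
#'
#' Beat analysis operates at 150 Hz on windows spanning -250..+250 ms
#' around each R peak: 75 samples with R at local index 38 (1-based).
#' @name beat_window_geometry
#' @keywords internal
NULL

WORK_FS <- 150
WIN_HALF_MS <- 250
WIN_LEN <- 75L      # 2 * 0.250 * 150 + 1
R_LOCAL <- 38L      # 1-based centre index

#' Extract fixed beat windows
#'
#' Cuts one 75-sample window (-250..+250 ms at 150 Hz) from lead
#' `lead` around every annotated R peak. Windows that would cross a
#' record boundary are zero-padded on the missing side and flagged.
#'
#' @param rec An `ecg_record` sampled at 150 Hz (resample first;
#'   enforced).
#' @param lead Lead column used for beat morphology (default 1, the
#'   record's first stored lead).
#' @return A tibble with one row per beat: `beat`, `r_peak`, `symbol`,
#'   `truncated` (logical boundary flag) and `samples` (list column of
#'   length-75 numeric windows).
#' @export
extract_beat_windows <- function(rec, lead = 1) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!isTRUE(all.equal(rec$fs, WORK_FS))) {
    stop("record must be at the 150 Hz working rate; call resample_ecg()")
  }
  x <- rec$signal[, lead]
  n <- length(x)
  half <- (WIN_LEN - 1L) %/% 2L
  out <- purrr::map(rec$r_peaks, function(r) {
    lo <- r - half
    hi <- r + half
    w <- numeric(WIN_LEN)
    src <- max(lo, 1L):min(hi, n)
    w[src - lo + 1L] <- x[src]
    list(w = w, trunc = lo < 1L || hi > n)
  })
  tibble::tibble(
    beat = seq_along(rec$r_peaks),
    r_peak = rec$r_peaks,
    symbol = rec$beat_symbols,
    truncated = purrr::map_lgl(out, "trunc"),
    samples = purrr::map(out, "w"))
}
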