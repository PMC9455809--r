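# Heuristic per-beat delineation given annotated R peaks, at the
# 150 Hz working rate. Search windows and thresholds are standard
# delineation heuristics, exposed as arguments:
#   Q = argmin in [R-60 ms, R),  S = argmin in (R, R+60 ms],
#   P = argmax in [R-200 ms, R-60 ms), present when its amplitude rises
#       at least `p_threshold` mV above the local (median) baseline,
#   QRS onset/offset = first sample, moving outward from Q (resp. S),
#       where the 10 ms moving-average |slope| falls below
#       `slope_frac` of the maximum |slope| in the QRS region,
#       capped at +/-100 ms from R.

ms_to_samp <- function(ms, fs) as.integer(round(ms * fs / 1000))

#' Detect per-beat fiducial points
#'
#' @param rec An [ecg_record()] at the 150 Hz working rate.
#' @param lead Lead column (default 1).
#' @param p_threshold P-presence threshold: minimum P prominence above
#'   the local baseline, mV.
#' @param slope_frac Onset/offset slope threshold as a fraction of the
#'   maximum smoothed QRS slope.
#' @return A tibble, one row per beat: `beat`, `p_peak`, `q_peak`,
#'   `r_peak`, `s_peak`, `qrs_onset`, `qrs_offset` (1-based absolute
#'   sample indices; `p_peak` is `NA` when no P wave is found).
#' @export
detect_fiducials <- function(rec, lead = 1, p_threshold = 0.05,
                             slope_frac = 0.125) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!isTRUE(all.equal(rec$fs, WORK_FS))) {
    stop("record must be at the 150 Hz working rate; call resample_ecg()")
  }
  x <- rec$signal[, lead]
  n <- length(x)
  fs <- rec$fs
  w60 <- ms_to_samp(60, fs); w100 <- ms_to_samp(100, fs)
  w200 <- ms_to_samp(200, fs)
  # slope smoothing window: 10 ms, forced odd so the moving average
  # stays centred (at 150 Hz this is a single sample, i.e. no smoothing)
  sm_k <- max(1L, ms_to_samp(10, fs))
  if (sm_k %% 2L == 0L) sm_k <- sm_k + 1L
  slope <- abs(diff(x))
  sl_smooth <- if (sm_k > 1) {
    as.numeric(stats::filter(slope, rep(1 / sm_k, sm_k), sides = 2))
  } else slope
  sl_smooth[is.na(sl_smooth)] <- 0

  rows <- purrr::map(seq_along(rec$r_peaks), function(i) {
    r <- rec$r_peaks[i]
    q_lo <- max(1L, r - w60); s_hi <- min(n, r + w60)
    q_rng <- q_lo:max(q_lo, r - 1L)
    s_rng <- min(s_hi, r + 1L):s_hi
    q <- q_rng[which.min(x[q_rng])]
    s <- s_rng[which.min(x[s_rng])]

    p_lo <- max(1L, r - w200); p_hi <- r - w60 - 1L
    p <- NA_integer_
    if (p_hi > p_lo + 1L) {
      p_rng <- p_lo:p_hi
      base <- stats::median(x[p_rng])
      # the P candidate must be an interior local maximum, so that the
      # rising edge of a wide QRS leaking into the window is not taken
      v <- x[p_rng]
      k <- 2:(length(v) - 1)
      locmax <- k[v[k] >= v[k - 1] & v[k] >= v[k + 1]]
      if (length(locmax)) {
        cand <- p_rng[locmax[which.max(v[locmax])]]
        if (x[cand] - base >= p_threshold) p <- cand
      }
    }

    qrs_rng <- max(1L, r - w60):min(n, r + w60)
    thr <- slope_frac * max(sl_smooth[qrs_rng[-length(qrs_rng)]], 0)

    onset <- max(1L, r - w100)
    for (j in q:max(1L, r - w100)) {
      if (j < 1L || j > length(sl_smooth)) break
      if (sl_smooth[j] < thr) { onset <- j; break }
    }
    offset <- min(n, r + w100)
    for (j in s:min(n - 1L, r + w100)) {
      if (sl_smooth[j] < thr) { offset <- j; break }
    }
    onset <- min(onset, q); offset <- max(offset, s)
    # a P candidate inside the detected QRS complex is not a P wave
    if (!is.na(p) && p >= onset) p <- NA_integer_
    tibble::tibble(beat = i, p_peak = p, q_peak = q, r_peak = r,
                   s_peak = s, qrs_onset = onset, qrs_offset = offset)
  })
  dplyr::bind_rows(rows)
}

#' QRS widths at full, half and quarter level
#'
#' `qrsw` is the onset-to-offset width. `qrsw2`/`qrsw4` are the widths
#' of the span where the QRS-window signal exceeds
#' `min + 0.50 * range` (resp. `min + 0.25 * range`) of the window,
#' with linear interpolation at the level crossings so widths are
#' sub-sample continuous.
#'
#' @param rec An [ecg_record()] at 150 Hz.
#' @param fiducials Output of [detect_fiducials()] (or a compatible
#'   tibble with `qrs_onset`/`qrs_offset`).
#' @param lead Lead column (default 1).
#' @return A tibble: `beat`, `qrsw`, `qrsw2`, `qrsw4` in ms (all 0 when
#'   the window has zero amplitude range).
#' @export
qrs_widths <- function(rec, fiducials, lead = 1) {
  stopifnot(inherits(rec, "ecg_record"))
  x <- rec$signal[, lead]
  ms_per <- 1000 / rec$fs
  rows <- purrr::pmap(
    list(fiducials$beat, fiducials$qrs_onset, fiducials$qrs_offset),
    function(b, on, off) {
      if (is.na(on) || is.na(off) || off <= on) {
        return(tibble::tibble(beat = b, qrsw = 0, qrsw2 = 0, qrsw4 = 0))
      }
      w <- x[on:off]
      rng <- max(w) - min(w)
      if (rng <= 0) {
        return(tibble::tibble(beat = b, qrsw = 0, qrsw2 = 0, qrsw4 = 0))
      }
      tibble::tibble(
        beat = b,
        qrsw = (off - on) * ms_per,
        qrsw2 = level_width(w, min(w) + 0.50 * rng) * ms_per,
        qrsw4 = level_width(w, min(w) + 0.25 * rng) * ms_per)
    })
  dplyr::bind_rows(rows)
}

# width (in samples, sub-sample by linear interpolation) of the span
# between the first and last crossing of `level`
level_width <- function(w, level) {
  above <- w > level
  if (!any(above)) return(0)
  i1 <- which(above)[1]
  i2 <- utils::tail(which(above), 1)
  left <- if (i1 == 1) 1 else {
    i1 - (w[i1] - level) / (w[i1] - w[i1 - 1])
  }
  right <- if (i2 == length(w)) length(w) else {
    i2 + (w[i2] - level) / (w[i2] - w[i2 + 1])
  }
  right - left
}
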