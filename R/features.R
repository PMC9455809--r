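# Per-beat feature vector: 6 RR-interval features, 12 medical
# morphology features plus 13 locally-normalized twins (the 12 medical
# features and rr), and 48 mathematical morphology features (10
# five-part moments, 24 Daubechies-2 DWT coefficients, 14 Hermite
# basis-function coefficients). 79 features, fixed order, no NaN/Inf:
# every degenerate statistic maps to 0.

#' Names of the 79 per-beat features, in canonical order
#' @return Character vector of length 79.
#' @export
feature_names <- function() {
  medical <- c("amp_p", "amp_q", "amp_r", "amp_s", "diff_pq", "diff_qr",
               "diff_rs", "dist_p_qrson", "dist_qs", "qrsw", "qrsw2",
               "qrsw4")
  c("rr", "pre_rr", "post_rr", "pre_rr_over_rr", "post_rr_over_rr", "t_rr",
    medical,
    paste0(c(medical, "rr"), "_norm"),
    paste0("kurt_", 1:5), paste0("skew_", 1:5),
    paste0("dwt_", 1:24), paste0("hbf_", 1:14))
}

#' RR-interval features
#'
#' Intervals are in samples at the working rate. `t_rr` is the
#' t-statistic of the current interval against the trailing window of
#' up to 32 intervals (ending at and including the current one):
#' `(rr - mean) / (sd / sqrt(n_window))`, 0 when the window sd is 0 or
#' the window has fewer than 2 values. Intervals missing at the record
#' edges are replaced by the record-median interval.
#'
#' @param r_peaks R-peak sample indices (1-based, increasing).
#' @param t_window Trailing window length for `t_rr` (default 32).
#' @return Tibble with columns `rr`, `pre_rr`, `post_rr`,
#'   `pre_rr_over_rr`, `post_rr_over_rr`, `t_rr`, one row per beat.
#' @export
rr_features <- function(r_peaks, t_window = 32) {
  n <- length(r_peaks)
  if (n < 2) stop("rr features require at least 2 beats")
  iv <- diff(r_peaks)                       # iv[i] = interval ending at beat i+1
  med <- stats::median(iv)
  rr <- c(med, iv)                          # interval ending at beat i
  pre_rr <- c(med, med, iv[-length(iv)])    # interval ending at beat i-1
  post_rr <- c(iv, med)                     # interval ending at beat i+1
  t_rr <- vapply(seq_len(n), function(i) {
    win <- rr[max(1, i - t_window + 1):i]
    if (length(win) < 2) return(0)
    s <- stats::sd(win)
    if (!is.finite(s) || s == 0) return(0)
    (rr[i] - mean(win)) / (s / sqrt(length(win)))
  }, 0)
  tibble::tibble(rr = as.numeric(rr), pre_rr = as.numeric(pre_rr),
                 post_rr = as.numeric(post_rr),
                 pre_rr_over_rr = pre_rr / rr,
                 post_rr_over_rr = post_rr / rr,
                 t_rr = t_rr)
}

#' Medical morphology features
#'
#' Wave amplitudes are the signal values at the fiducial samples (0
#' when the point is absent); differences follow the first-minus-second
#' convention; distances are in ms; QRS widths come from
#' [qrs_widths()].
#'
#' @param rec An [ecg_record()] at 150 Hz.
#' @param fiducials Output of [detect_fiducials()].
#' @param lead Lead column.
#' @return Tibble with the 12 medical features, one row per beat.
#' @export
medical_features <- function(rec, fiducials, lead = 1) {
  x <- rec$signal[, lead]
  ms_per <- 1000 / rec$fs
  at <- function(idx) ifelse(is.na(idx), 0, x[ifelse(is.na(idx), 1L, idx)])
  amp_p <- at(fiducials$p_peak)
  amp_q <- at(fiducials$q_peak)
  amp_r <- at(fiducials$r_peak)
  amp_s <- at(fiducials$s_peak)
  w <- qrs_widths(rec, fiducials, lead = lead)
  tibble::tibble(
    amp_p = amp_p, amp_q = amp_q, amp_r = amp_r, amp_s = amp_s,
    diff_pq = amp_p - amp_q, diff_qr = amp_q - amp_r,
    diff_rs = amp_r - amp_s,
    dist_p_qrson = ifelse(is.na(fiducials$p_peak), 0,
                          (fiducials$qrs_onset - fiducials$p_peak) * ms_per),
    dist_qs = (fiducials$s_peak - fiducials$q_peak) * ms_per,
    qrsw = w$qrsw, qrsw2 = w$qrsw2, qrsw4 = w$qrsw4)
}

#' Local normalization by a trailing mean
#'
#' Each value is divided by the mean of the feature over the trailing
#' window of up to `window` beats ending at and including itself; a
#' zero (or non-finite) window mean maps to 0. Scale-invariant:
#' doubling the series leaves the output unchanged.
#'
#' @param values Per-beat numeric series of one feature.
#' @param window Trailing window in beats (default 32).
#' @return Normalized series of the same length.
#' @export
local_normalize <- function(values, window = 32) {
  stopifnot(window >= 1)
  n <- length(values)
  cs <- cumsum(values)
  lo <- pmax(0, seq_len(n) - window)
  m <- (cs - c(0, cs)[lo + 1]) / (seq_len(n) - lo)
  out <- ifelse(is.finite(m) & m != 0, values / m, 0)
  out[!is.finite(out)] <- 0
  out
}

#' Five-part moment features of a beat window
#'
#' Splits the 75-sample window into 5 parts of 15 samples and returns
#' the population excess kurtosis and skewness of each part
#' (zero-variance parts map to 0).
#'
#' @param samples Length-75 numeric beat window.
#' @return Named numeric vector `kurt_1..kurt_5`, `skew_1..skew_5`.
#' @export
segment_stats <- function(samples) {
  stopifnot(length(samples) == WIN_LEN)
  parts <- split(samples, rep(1:5, each = WIN_LEN / 5))
  kurt <- vapply(parts, function(p) {
    m2 <- mean((p - mean(p))^2)
    if (m2 <= 0) return(0)
    mean((p - mean(p))^4) / m2^2 - 3
  }, 0)
  skew <- vapply(parts, function(p) {
    m2 <- mean((p - mean(p))^2)
    if (m2 <= 0) return(0)
    mean((p - mean(p))^3) / m2^1.5
  }, 0)
  stats::setNames(c(kurt, skew),
                  c(paste0("kurt_", 1:5), paste0("skew_", 1:5)))
}

# Daubechies-2 analysis filters
DB2_LO <- c(-0.12940952255126037, 0.22414386804201339,
            0.83651630373780790, 0.48296291314453416)
DB2_HI <- c(-0.48296291314453416, 0.83651630373780790,
            -0.22414386804201339, -0.12940952255126037)

# one DWT analysis step with symmetric (edge-repeating) padding;
# output length floor((n + 3) / 2)
dwt_step <- function(x, filt) {
  fl <- length(filt)
  pad <- c(rev(x[seq_len(fl - 1)]), x, rev(x)[seq_len(fl - 1)])
  full <- stats::convolve(pad, rev(filt), type = "open")
  # keep the 'valid' part then every second sample
  valid <- full[fl:(fl + length(pad) - fl)]
  valid[seq(2, length(valid), by = 2)]
}

#' Daubechies-2 wavelet features of a beat window
#'
#' Three-level db2 decomposition with symmetric padding; the level-3
#' approximation coefficients followed by the level-3 detail
#' coefficients, truncated or zero-padded to exactly `n_out` values
#' (for a 75-sample window both blocks have 12 coefficients, so the
#' output is exactly 24 with no padding).
#'
#' @param samples Length-75 numeric beat window.
#' @param n_out Output length (default 24).
#' @return Named numeric vector `dwt_1..dwt_<n_out>`.
#' @export
dwt_features <- function(samples, n_out = 24) {
  a <- samples
  d <- NULL
  for (lev in 1:3) {
    d <- dwt_step(a, DB2_HI)
    a <- dwt_step(a, DB2_LO)
  }
  out <- c(a, d)
  if (length(out) >= n_out) out <- out[seq_len(n_out)]
  else out <- c(out, numeric(n_out - length(out)))
  stats::setNames(out, paste0("dwt_", seq_len(n_out)))
}

# orthonormal Hermite functions phi_0..phi_{n-1} at times t (ms) for
# width sigma (ms), by the stable normalized recurrence
hermite_basis <- function(t, sigma, n) {
  x <- t / sigma
  B <- matrix(0, length(t), n)
  B[, 1] <- pi^(-0.25) / sqrt(sigma) * exp(-x^2 / 2)
  if (n >= 2) B[, 2] <- sqrt(2) * x * B[, 1]
  if (n >= 3) {
    for (j in 3:n) {
      k <- j - 2  # phi_{k+1} from phi_k, phi_{k-1}
      B[, j] <- sqrt(2 / (k + 1)) * x * B[, j - 1] -
        sqrt(k / (k + 1)) * B[, j - 2]
    }
  }
  B
}

#' Hermite basis-function expansion of a beat window
#'
#' Least-squares projection of the window onto the first `n_coef`
#' orthonormal Hermite basis functions centred on the R peak, with the
#' width parameter sigma chosen from `sigma_grid_ms` to minimize the
#' reconstruction SSE.
#'
#' @param samples Length-75 numeric beat window (R at index 38).
#' @param fs Working rate, Hz (default 150).
#' @param n_coef Number of coefficients (default 14).
#' @param sigma_grid_ms Candidate sigma values in ms.
#' @return Named numeric vector `hbf_1..hbf_<n_coef>`; attributes
#'   `sigma_ms` (chosen width) and `sse` (reconstruction error).
#' @export
hermite_features <- function(samples, fs = WORK_FS, n_coef = 14,
                             sigma_grid_ms = c(10, 15, 20, 25, 30)) {
  stopifnot(length(samples) == WIN_LEN)
  t_ms <- (seq_len(WIN_LEN) - R_LOCAL) * 1000 / fs
  best <- NULL
  for (sg in sigma_grid_ms) {
    B <- hermite_basis(t_ms, sg, n_coef)
    cf <- tryCatch(qr.solve(B, samples), error = function(e) rep(0, n_coef))
    sse <- sum((samples - B %*% cf)^2)
    if (is.null(best) || sse < best$sse) best <- list(cf = cf, sse = sse,
                                                     sigma = sg)
  }
  out <- stats::setNames(as.numeric(best$cf), paste0("hbf_", seq_len(n_coef)))
  attr(out, "sigma_ms") <- best$sigma
  attr(out, "sse") <- best$sse
  out
}

# package-local cache for fixed window transforms
.transform_cache <- new.env(parent = emptyenv())

# 24 x 75 matrix applying dwt_features to a beat window
dwt_matrix <- function() {
  if (is.null(.transform_cache$dwt)) {
    .transform_cache$dwt <- vapply(seq_len(WIN_LEN), function(i) {
      e <- numeric(WIN_LEN); e[i] <- 1
      unname(dwt_features(e))
    }, numeric(24))
  }
  .transform_cache$dwt
}

# vectorized five-part moments, rows = beats
segment_stats_matrix <- function(Wm) {
  out <- matrix(0, nrow(Wm), 10,
                dimnames = list(NULL, c(paste0("kurt_", 1:5),
                                        paste0("skew_", 1:5))))
  plen <- WIN_LEN / 5
  for (j in 1:5) {
    P <- Wm[, ((j - 1) * plen + 1):(j * plen), drop = FALSE]
    mu <- rowMeans(P)
    Pc <- P - mu
    m2 <- rowMeans(Pc^2)
    ok <- m2 > 0
    out[ok, j] <- rowMeans(Pc^4)[ok] / m2[ok]^2 - 3
    out[ok, 5 + j] <- rowMeans(Pc^3)[ok] / m2[ok]^1.5
  }
  out
}

# vectorized Hermite projection with per-beat sigma selection
hermite_features_matrix <- function(Wm, fs = WORK_FS, n_coef = 14,
                                    sigma_grid_ms = c(10, 15, 20, 25, 30)) {
  t_ms <- (seq_len(WIN_LEN) - R_LOCAL) * 1000 / fs
  n <- nrow(Wm)
  best_sse <- rep(Inf, n)
  best_cf <- matrix(0, n, n_coef)
  for (sg in sigma_grid_ms) {
    B <- hermite_basis(t_ms, sg, n_coef)
    proj <- solve(crossprod(B), t(B))       # 14 x 75 LS projector
    cf <- Wm %*% t(proj)
    sse <- rowSums((Wm - cf %*% t(B))^2)
    take <- sse < best_sse
    best_sse[take] <- sse[take]
    best_cf[take, ] <- cf[take, , drop = FALSE]
  }
  colnames(best_cf) <- paste0("hbf_", seq_len(n_coef))
  best_cf
}

#' Full 79-feature table for a record
#'
#' Runs fiducial detection, window extraction and every feature family
#' and returns one row per beat. Non-finite values are mapped to 0, so
#' the table is always finite.
#'
#' @param rec An [ecg_record()] at any rate; it is resampled to the
#'   150 Hz working rate internally.
#' @param lead Lead used for beat morphology (default 1).
#' @param norm_window Trailing window for local normalization.
#' @return Tibble with `beat`, `symbol`, `truncated` and the 79
#'   features of [feature_names()].
#' @export
beat_features <- function(rec, lead = 1, norm_window = 32) {
  rec <- resample_ecg(rec, WORK_FS)
  fid <- detect_fiducials(rec, lead = lead)
  win <- extract_beat_windows(rec, lead = lead)
  rrf <- rr_features(rec$r_peaks)
  med <- medical_features(rec, fid, lead = lead)
  normed <- dplyr::bind_cols(med, rr = rrf$rr) |>
    purrr::map(local_normalize, window = norm_window) |>
    tibble::as_tibble() |>
    dplyr::rename_with(~ paste0(.x, "_norm"))
  # the window transforms are applied to all beats at once: the DWT is
  # linear (a fixed 24 x 75 matrix) and the Hermite projection uses one
  # precomputed least-squares projector per candidate sigma
  Wm <- do.call(rbind, win$samples)
  mom <- tibble::as_tibble(segment_stats_matrix(Wm))
  dwt_m <- Wm %*% t(dwt_matrix())
  colnames(dwt_m) <- paste0("dwt_", 1:24)
  dwt <- tibble::as_tibble(dwt_m)
  hbf <- tibble::as_tibble(hermite_features_matrix(Wm))
  out <- dplyr::bind_cols(
    win[, c("beat", "symbol", "truncated")],
    rrf, med, normed, mom, dwt, hbf)
  stopifnot(identical(names(out)[-(1:3)], feature_names()))
  dplyr::mutate(out, dplyr::across(
    dplyr::where(is.numeric), ~ ifelse(is.finite(.x), .x, 0)))
}
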