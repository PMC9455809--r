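test_that("rr features handle constant, windowed and edge cases", {
  # metronomic record: RR constant at 120 samples
  pk <- seq(1, by = 120, length.out = 40)
  rrf <- rr_features(pk)
  expect_true(all(rrf$rr == 120))
  expect_true(all(rrf$pre_rr == 120))
  expect_true(all(rrf$post_rr == 120))
  expect_true(all(rrf$pre_rr_over_rr == 1))
  expect_true(all(rrf$post_rr_over_rr == 1))
  expect_true(all(rrf$t_rr == 0))

  # brute-force windowed t-statistic on a step series
  iv <- c(rep(100, 31), 150)
  pk2 <- cumsum(c(1, iv))
  rrf2 <- rr_features(pk2)
  last <- nrow(rrf2)
  win <- c(rep(100, 31), 150)  # trailing 32 intervals incl current
  expect_equal(rrf2$t_rr[last],
               (150 - mean(win)) / (sd(win) / sqrt(32)))

  # first beat substitutes the record-median interval
  iv3 <- c(100, 110, 120, 130)
  rrf3 <- rr_features(cumsum(c(1, iv3)))
  expect_equal(rrf3$rr[1], median(iv3))
  expect_equal(rrf3$pre_rr_over_rr[1], 1)
  expect_equal(rrf3$post_rr[5], median(iv3))

  expect_error(rr_features(5), "at least 2 beats")
})

test_that("medical features follow the absence and sign conventions", {
  g <- clean_record(seed = 1)
  r150 <- resample_ecg(g$record, 150)
  fid <- detect_fiducials(r150)
  med <- medical_features(r150, fid)
  # amplitude oracle: template R amplitude is 1 mV; at 150 Hz the
  # triangular apex can fall between samples, so individual beats read
  # up to ~15% low while the mean stays close
  expect_true(all(abs(med$amp_r - 1.0) < 0.17))
  expect_lt(abs(mean(med$amp_r) - 1.0), 0.07)
  expect_equal(med$diff_qr, med$amp_q - med$amp_r)
  expect_equal(med$diff_rs, med$amp_r - med$amp_s)

  # absent P: amp_p = 0, diff_pq = -amp_q, dist_p_qrson = 0
  gp <- clean_record(seed = 2, class = "PVC")
  rp <- resample_ecg(gp$record, 150)
  fp <- detect_fiducials(rp)
  mp <- medical_features(rp, fp)
  expect_true(all(mp$amp_p == 0))
  expect_equal(mp$diff_pq, -mp$amp_q)
  expect_true(all(mp$dist_p_qrson == 0))
})

test_that("local normalization is a trailing-mean ratio", {
  expect_equal(local_normalize(rep(3, 10)), rep(1, 10))
  expect_equal(local_normalize(c(1, 1, 1, 2), window = 4)[4], 2 / 1.25)
  x <- abs(rnorm(50)) + 0.1
  expect_equal(local_normalize(x), local_normalize(2 * x))
  expect_equal(local_normalize(numeric(10)), numeric(10))
  # window restricts the trailing mean
  y <- c(10, 10, 1, 1)
  expect_equal(local_normalize(y, window = 2)[4], 1)
})

test_that("five-part moments match their population oracles", {
  expect_equal(unname(segment_stats(numeric(75))), numeric(10))

  # value-symmetric part: skewness exactly zero
  ramp <- -7:7
  s <- segment_stats(rep(ramp, 5))
  expect_equal(unname(s[paste0("skew_", 1:5)]), numeric(5))

  # oversampled moment oracle: standard-normal parts have skew ~ 0 and
  # excess kurtosis ~ 0 within 3 SE (n = 1500 per part)
  set.seed(42)
  n <- 1500
  z <- rnorm(n)
  m2 <- mean((z - mean(z))^2)
  sk <- mean((z - mean(z))^3) / m2^1.5
  ku <- mean((z - mean(z))^4) / m2^2 - 3
  expect_lt(abs(sk), 3 * sqrt(6 / n))
  expect_lt(abs(ku), 3 * sqrt(24 / n))
})

test_that("db2 wavelet features are linear with vanishing moments", {
  expect_equal(unname(dwt_features(numeric(75))), numeric(24))
  set.seed(1)
  x <- rnorm(75); y <- rnorm(75)
  expect_equal(dwt_features(2.5 * x), 2.5 * dwt_features(x))
  expect_equal(dwt_features(x + y), dwt_features(x) + dwt_features(y))
  # constant signal: detail block vanishes, approximation does not
  cc <- dwt_features(rep(3, 75))
  expect_lt(max(abs(cc[13:24])), 1e-8 * 3)
  expect_gt(max(abs(cc[1:12])), 1)
})

test_that("db2 coefficients match an independent wavelet implementation", {
  # expected values computed once with PyWavelets
  # (wavedec db2, symmetric padding, level 3; A3 then D3)
  set.seed(42)
  x <- rnorm(75)
  expected <- c(
    1.795602791563, 1.367165930538, 2.498625606802, -1.660100831067,
    -0.025235487631, -0.161217712528, -1.731455172165, 0.348932929853,
    -0.037212927264, 1.166051340716, -0.124890571768, -2.186968685573,
    0.313017989582, -0.563046061417, 1.070258264776, -1.216800512774,
    -1.029420267734, -1.686123904890, -0.498910125546, 1.063508094314,
    -1.118950421183, 1.167999382928, -0.502908237113, -0.691172157212)
  expect_equal(unname(dwt_features(x)), expected, tolerance = 1e-9)
})

test_that("Hermite projection recovers basis functions exactly", {
  t_ms <- (1:75 - 38) * 1000 / 150
  for (sg in c(10, 25)) {
    B <- segbeat:::hermite_basis(t_ms, sg, 14)
    h1 <- hermite_features(B[, 1])
    expect_equal(unname(h1[1]), 1, tolerance = 1e-8)
    expect_lt(max(abs(h1[-1])), 1e-6)
    expect_equal(attr(h1, "sigma_ms"), sg)
    h5 <- hermite_features(B[, 5])
    expect_equal(unname(h5[5]), 1, tolerance = 1e-8)
    expect_lt(max(abs(h5[-5])), 1e-6)
  }
  expect_equal(as.numeric(hermite_features(numeric(75))), numeric(14))
})

test_that("Hermite reconstruction error is non-increasing in order", {
  set.seed(3)
  w <- rnorm(75)
  t_ms <- (1:75 - 38) * 1000 / 150
  sses <- vapply(1:14, function(k) {
    B <- segbeat:::hermite_basis(t_ms, 20, k)
    cf <- qr.solve(B, w)
    sum((w - B %*% cf)^2)
  }, 0)
  expect_true(all(diff(sses) <= 1e-9))
})

test_that("the 79-feature table is complete, finite and deterministic", {
  expect_length(feature_names(), 79)
  for (ns in c(0, 0.1, 0.4)) {
    g <- generate_ecg(synth_config(seed = 5, duration_s = 30,
                                   noise_sd = ns), paste0("F", ns))
    ft <- beat_features(g$record)
    expect_identical(names(ft), c("beat", "symbol", "truncated",
                                  feature_names()))
    expect_true(all(vapply(ft[, feature_names()],
                           function(col) all(is.finite(col)), TRUE)))
  }
  g <- clean_record(seed = 6, duration_s = 30)
  expect_identical(beat_features(g$record), beat_features(g$record))
})

test_that("vectorized window transforms agree with the per-window ops", {
  g <- generate_ecg(synth_config(seed = 12, duration_s = 25,
                                 noise_sd = 0.1), "V1")
  r150 <- resample_ecg(g$record, 150)
  win <- extract_beat_windows(r150)
  ft <- beat_features(g$record)
  i <- min(7, nrow(ft))
  expect_equal(as.numeric(ft[i, paste0("dwt_", 1:24)]),
               unname(dwt_features(win$samples[[i]])))
  expect_equal(as.numeric(ft[i, paste0("hbf_", 1:14)]),
               unname(as.numeric(hermite_features(win$samples[[i]]))))
  expect_equal(as.numeric(ft[i, c(paste0("kurt_", 1:5),
                                  paste0("skew_", 1:5))]),
               unname(segment_stats(win$samples[[i]])))
})
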