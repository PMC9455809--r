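test_that("segmentation arithmetic matches the stride rules", {
  mk <- function(dur_s, fs = 100) {
    n <- dur_s * fs
    ecg_record(numeric(n), fs, c(n %/% 3, 2 * n %/% 3), c("N", "N"))
  }
  expect_equal(nrow(segment_record(mk(180), 60, "none")), 3)
  s5 <- segment_record(mk(180), 60, "half")
  expect_equal(nrow(s5), 5)
  expect_equal(s5$start_sample, 1 + (0:4) * 30 * 100)
  expect_equal(nrow(segment_record(mk(45), 60, "none")), 1)
  expect_equal(nrow(segment_record(mk(45), 60, "half")), 1)
})

test_that("partition and stride invariants hold for awkward lengths", {
  for (dur in c(31, 59, 60, 61, 150, 179)) {
    rec <- ecg_record(numeric(dur * 10), 10, c(5, 50), c("N", "N"))
    b_none <- segment_record(rec, 60, "none")
    # no-overlap: segments partition the record
    cover <- unlist(purrr::map2(b_none$start_sample, b_none$end_sample, `:`))
    expect_identical(sort(cover), seq_len(rec$n_samples))
    b_half <- segment_record(rec, 60, "half")
    if (nrow(b_half) > 1) {
      expect_true(all(diff(b_half$start_sample) == 60 * 10 / 2))
    }
    expect_gte(b_half$end_sample[nrow(b_half)], rec$n_samples)
  }
})

test_that("segment preprocessing yields the fixed-length classifier input", {
  # 45 s at 250 Hz -> padded to 21600 samples at 360 Hz
  x <- rnorm(45 * 250)
  out <- preprocess_segment(x, 250)
  expect_length(out, 21600)
  expect_equal(out[21000:21600], numeric(601))  # zero padding

  # slow sinusoid is baseline: removed by the 200/600 ms median cascade.
  # closed-form oracle: a 600 ms median of a 2 s sine clips its peaks
  # to sin(63 deg), leaving a residual of 1 - sin(63 deg) ~ 10.9%
  fs <- 360
  t <- (0:(60 * fs - 1)) / fs
  wander <- 0.8 * sin(2 * pi * t / 2)
  resid <- preprocess_segment(wander, fs, scale = 1)
  expect_lt(max(abs(resid)), ((1 - sin(63 / 180 * pi)) + 0.02) * 0.8)

  # zero signal: zero output, no division error
  expect_equal(preprocess_segment(numeric(3600), 360), numeric(21600))
})

test_that("oracle labels match the generating blocks and error rate", {
  blocks <- data.frame(label = c("NSR", "AFIB_LIKE"),
                       duration_s = c(60, 60))
  g <- generate_ecg(synth_config(seed = 4, rhythm_blocks = blocks,
                                 noise_sd = 0.05), "O1")
  clf <- oracle_classifier(g$truth)
  bounds <- segment_record(g$record, 60, "none")
  probs <- predict_segments(clf, g$record, bounds)
  expect_identical(clf$label_set[max.col(probs)], c("NSR", "AFIB_LIKE"))

  # error rate 1: no segment carries its true label
  clf1 <- oracle_classifier(g$truth, error_rate = 1, seed = 2)
  p1 <- predict_segments(clf1, g$record, bounds)
  expect_identical(clf$label_set[max.col(p1)], c("AFIB_LIKE", "NSR"))

  # error rate 0.3 over many segments: binomial oracle
  short <- generate_ecg(synth_config(seed = 5, duration_s = 600,
                                     noise_sd = 0), "O2")
  b2 <- segment_record(short$record, 2, "none")
  clf3 <- oracle_classifier(short$truth, error_rate = 0.3, seed = 9)
  p3 <- predict_segments(clf3, short$record, b2)
  err <- mean(clf3$label_set[max.col(p3)] != "NSR")
  se <- sqrt(0.3 * 0.7 / nrow(b2))
  expect_lt(abs(err - 0.3), 3 * se)
})

test_that("per-beat encoding follows the overlap mode", {
  blocks <- data.frame(label = c("NSR", "AFIB_LIKE"),
                       duration_s = c(60, 60))
  g <- generate_ecg(synth_config(seed = 6, rhythm_blocks = blocks,
                                 noise_sd = 0.05), "E1")
  clf <- oracle_classifier(g$truth)

  lab <- assign_segment_labels(g$record, clf, length_s = 60,
                               overlap = "none")
  tb <- g$truth$beats
  # beats in the first minute get ID(NSR) = 1, second minute ID 2
  expect_true(all(lab$beat$label_id[tb$rhythm == "NSR"] == 1))
  expect_true(all(lab$beat$label_id[tb$rhythm == "AFIB_LIKE"] == 2))
  # encoding is invertible: ID <-> name
  expect_identical(clf$label_set[lab$beat$label_id], lab$beat$label)

  labh <- assign_segment_labels(g$record, clf, length_s = 60,
                                overlap = "half")
  bits <- as.matrix(labh$beat[, c("bit_NSR", "bit_AFIB_LIKE")])
  expect_true(all(rowSums(bits) >= 1 & rowSums(bits) <= 2))
  # beats covered by one NSR-majority and one AFIB-majority segment
  # (60..90 s: segments starting at 30 s and 60 s) carry both bits
  mid <- tb$r_peak > 60 * 360 & tb$r_peak <= 90 * 360
  expect_true(all(rowSums(bits[mid, , drop = FALSE]) == 2))
  # the single-coverage head of the record has exactly one bit
  head_ <- tb$r_peak < 30 * 360
  expect_true(all(bits[head_, "bit_NSR"] == 1 &
                    bits[head_, "bit_AFIB_LIKE"] == 0))

  # single-segment record: all beats share one ID
  g1 <- clean_record(seed = 7, duration_s = 50)
  l1 <- assign_segment_labels(g1$record, oracle_classifier(g1$truth),
                              length_s = 60, overlap = "none")
  expect_length(unique(l1$beat$label_id), 1)
})

test_that("seglabel feature columns reflect the encoding", {
  g <- clean_record(seed = 8, duration_s = 50)
  clf <- oracle_classifier(g$truth)
  f_none <- seglabel_features(
    assign_segment_labels(g$record, clf, overlap = "none"))
  expect_identical(names(f_none), "seg_label")
  expect_s3_class(f_none$seg_label, "factor")
  f_half <- seglabel_features(
    assign_segment_labels(g$record, clf, overlap = "half"))
  expect_identical(names(f_half), c("seg_NSR", "seg_AFIB_LIKE"))
})
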