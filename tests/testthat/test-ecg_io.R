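test_that("record construction enforces the annotation invariants", {
  x <- sin(seq(0, 10, length.out = 1000))
  rec <- ecg_record(x, 360, c(100, 250), c("N", "V"))
  expect_s3_class(rec, "ecg_record")
  expect_equal(nrow(beats(rec)), 2)
  expect_equal(rec$duration_s, 1000 / 360)

  expect_error(ecg_record(x, 360, c(250, 100), c("N", "V")),
               "not strictly increasing at index 1")
  expect_error(ecg_record(x, 360, c(100, 100), c("N", "V")),
               "not strictly increasing")
  expect_error(ecg_record(x, 360, 1200, "N"), "outside")
  expect_error(ecg_record(x, 0, 100, "N"), "fs must be positive")
  expect_error(ecg_record(x, 360, c(1, 2), "N"), "same length")
})

test_that("csv dialect round-trips bit-exactly", {
  dir <- withr::local_tempdir()
  stem <- toy_csv_record(dir)
  rec <- read_ecg(stem, dialect = "csv")
  expect_equal(length(rec$r_peaks), 2)
  expect_identical(rec$beat_symbols, c("N", "V"))
  rec2 <- read_ecg(file.path(dir, "toy"))
  expect_identical(rec$signal, rec2$signal)

  dir2 <- withr::local_tempdir()
  write_ecg(rec, dir2)
  rec3 <- read_ecg(file.path(dir2, "toy"))
  expect_identical(rec3$signal, rec$signal)
  expect_identical(rec3$r_peaks, rec$r_peaks)
  expect_identical(rec3$fs, rec$fs)
})

test_that("a missing annotation stream is an explicit error", {
  dir <- withr::local_tempdir()
  stem <- toy_csv_record(dir)
  file.remove(paste0(stem, ".beats.csv"))
  expect_error(read_ecg(stem, dialect = "csv"), "missing annotations")
})

test_that("wfdb dialect round-trips through format 212", {
  dir <- withr::local_tempdir()
  g <- clean_record(seed = 3, duration_s = 20)
  rec <- g$record
  write_wfdb(rec, dir)
  back <- read_wfdb(file.path(dir, rec$record_id))
  expect_identical(back$r_peaks, rec$r_peaks)
  expect_identical(back$beat_symbols, rec$beat_symbols)
  expect_equal(back$fs, rec$fs)
  # amplitudes quantized at gain 200 adu/mV: error below one half adu
  expect_lt(max(abs(back$signal - rec$signal)), 0.5 / 200 + 1e-9)
})

test_that("format-212 packing matches a hand-computed byte example", {
  # samples 5 and -3: 12-bit two's complement 0x005 and 0xFFD packed as
  # low(s0), high-nibbles(s1|s0), low(s1)
  dir <- withr::local_tempdir()
  rec <- ecg_record(c(5, -3, 0, 0) / 200 + 1024 / 200 - 1024 / 200,
                    fs = 100, r_peaks = 1L, beat_symbols = "N",
                    record_id = "pack")
  # bypass quantization offsets: signal chosen so adc = value*200 + 1024
  write_wfdb(rec, dir)
  raw <- readBin(file.path(dir, "pack.dat"), "raw", 6)
  adc0 <- 5L + 1024L; adc1 <- -3L + 1024L
  expect_identical(as.integer(raw[1]), adc0 %% 256L)
  expect_identical(as.integer(raw[2]),
                   bitwOr(bitwShiftL(adc1 %/% 256L, 4), adc0 %/% 256L))
  expect_identical(as.integer(raw[3]), adc1 %% 256L)
})

test_that("resampling preserves beats, identity and dominant frequency", {
  g <- clean_record(seed = 2)
  rec <- g$record
  expect_identical(resample_ecg(rec, rec$fs), rec)

  r150 <- resample_ecg(rec, 150)
  expect_equal(length(r150$r_peaks), length(rec$r_peaks))
  expect_equal(r150$fs, 150)
  # exact-ratio peak mapping: 0-based sample 360 -> 150
  one <- ecg_record(sin(2 * pi * 5 * (0:719) / 360), 360, 361, "N")
  expect_equal(resample_ecg(one, 150)$r_peaks, 151L)
  # idempotence at the target rate
  expect_identical(resample_ecg(r150, 150), r150)

  # periodogram oracle: a 5 Hz sinusoid keeps its dominant frequency
  x <- sin(2 * pi * 5 * (0:(360 * 30 - 1)) / 360)
  sr <- resample_ecg(ecg_record(x, 360, c(10, 20), c("N", "N")), 150)
  sp <- stats::spec.pgram(stats::ts(sr$signal[, 1], frequency = 150),
                          plot = FALSE, taper = 0)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 5), 0.1)
})

test_that("beat windows are 75 samples with boundary padding flagged", {
  g <- clean_record(seed = 4)
  r150 <- resample_ecg(g$record, 150)
  win <- extract_beat_windows(r150)
  expect_true(all(lengths(win$samples) == 75))
  expect_equal(nrow(win), length(r150$r_peaks))

  # interior window geometry: R at 1-based local index 38,
  # covering samples r-37 .. r+37
  r <- r150$r_peaks[10]
  expect_equal(win$samples[[10]][38], r150$signal[r, 1])
  expect_equal(win$samples[[10]][1], r150$signal[r - 37, 1])

  # boundary beat: left side zero-padded and flagged
  xe <- numeric(300); xe[10] <- 1
  edge <- ecg_record(xe, 150, c(10, 200), c("N", "N"))
  we <- extract_beat_windows(edge)
  expect_true(we$truncated[1])
  expect_false(we$truncated[2])
  expect_equal(we$samples[[1]][seq_len(28)], numeric(28))
  expect_equal(we$samples[[1]][38], 1)

  expect_error(extract_beat_windows(g$record), "150 Hz")
})
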