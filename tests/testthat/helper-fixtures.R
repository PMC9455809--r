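# shared fixtures: small noise-free records and templates built in code

clean_config <- function(seed = 1, duration_s = 60,
                         beat_mix = c(NOR = 1, PVC = 0, SVP = 0), ...) {
  synth_config(seed = seed, duration_s = duration_s, beat_mix = beat_mix,
               noise_sd = 0, baseline_wander_amp = 0, ...)
}

clean_record <- function(seed = 1, class = "NOR", duration_s = 60, ...) {
  mix <- c(NOR = 0, PVC = 0, SVP = 0)
  mix[class] <- 1
  generate_ecg(clean_config(seed = seed, duration_s = duration_s,
                            beat_mix = mix, ...),
               paste0("T", class, seed))
}

# map truth sample indices from the generation rate to 150 Hz
truth_at_150 <- function(samples, fs_from) {
  ifelse(is.na(samples), NA_real_, round((samples - 1) * 150 / fs_from) + 1)
}

# two-beat toy record written in the csv dialect; returns the stem
toy_csv_record <- function(dir) {
  x <- numeric(400)
  x[c(100, 250)] <- 1
  rec <- ecg_record(x, fs = 360, r_peaks = c(100, 250),
                    beat_symbols = c("N", "V"), record_id = "toy")
  write_ecg(rec, dir)
}
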