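# Minimal WFDB dialect: header + .dat (formats 212, 16) + MIT .atr
# annotations. Covers the subset needed for MIT-BIH-style beat files;
# amplitudes are converted to mV via gain/baseline from the header.

# annotation type code <-> beat symbol (MIT-BIH alphabet)
WFDB_BEAT_CODES <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L,
  "e" = 34L, "f" = 38L)
WFDB_RHYTHM_CODE <- 28L  # '+', rhythm change; label in the AUX string

#' Read a WFDB record triple
#'
#' Reads `<stem>.hea`, `<stem>.dat` (format 212 or 16) and the beat
#' annotations in `<stem>.atr`. Beat annotation codes are mapped to the
#' 15-symbol MIT-BIH alphabet; rhythm-change (`+`) annotations are kept
#' in an `rhythms` attribute (sample, label from the AUX string).
#'
#' @param stem Path stem of the record (no extension).
#' @return An [ecg_record()]; attribute `rhythms` holds a tibble of
#'   rhythm-change annotations when present.
#' @export
read_wfdb <- function(stem) {
  hea_f <- paste0(stem, ".hea")
  if (!file.exists(hea_f)) stop("header not found: ", hea_f)
  hdr <- readLines(hea_f, warn = FALSE)
  hdr <- hdr[!grepl("^#", hdr) & nzchar(trimws(hdr))]
  top <- strsplit(trimws(hdr[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(strsplit(top[3], "/")[[1]][1]) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig_lines <- hdr[1 + seq_len(n_sig)]
  specs <- lapply(sig_lines, parse_wfdb_signal_line)
  fmt <- unique(vapply(specs, `[[`, 0, "format"))
  if (length(fmt) != 1 || !fmt %in% c(212, 16)) {
    stop("unsupported .dat format: ", paste(fmt, collapse = ","))
  }
  dat_f <- file.path(dirname(stem), specs[[1]]$file)
  raw <- readBin(dat_f, "raw", n = file.info(dat_f)$size)
  adc <- if (fmt == 212) decode_212(raw, n_sig) else decode_16(raw, n_sig)
  if (!is.na(n_samp)) adc <- adc[seq_len(min(nrow(adc), n_samp)), , drop = FALSE]
  sig <- sapply(seq_len(n_sig), function(j) {
    (adc[, j] - specs[[j]]$baseline) / specs[[j]]$gain
  })
  if (is.vector(sig)) sig <- matrix(sig, ncol = 1)
  atr_f <- paste0(stem, ".atr")
  if (!file.exists(atr_f)) stop("missing annotations: ", atr_f)
  ann <- read_mit_annotations(atr_f)
  is_beat <- ann$code %in% WFDB_BEAT_CODES
  sym <- names(WFDB_BEAT_CODES)[match(ann$code[is_beat], WFDB_BEAT_CODES)]
  rec <- ecg_record(sig, fs, ann$sample[is_beat] + 1L, sym,
                    record_id = basename(stem))
  rhy <- ann$code == WFDB_RHYTHM_CODE
  if (any(rhy)) {
    attr(rec, "rhythms") <- tibble::tibble(
      sample = ann$sample[rhy] + 1L, label = ann$aux[rhy])
  }
  rec
}

parse_wfdb_signal_line <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  gain_field <- if (length(f) >= 3) f[3] else "200"
  gain_field <- sub("/.*$", "", gain_field)
  baseline <- 0
  if (grepl("\\(", gain_field)) {
    baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    gain_field <- sub("\\(.*$", "", gain_field)
  }
  gain <- as.numeric(gain_field)
  if (!is.finite(gain) || gain == 0) gain <- 200
  # per WFDB, baseline defaults to the ADC zero (field 5) when absent
  if (baseline == 0 && length(f) >= 5 && !grepl("\\(", f[3])) {
    az <- suppressWarnings(as.numeric(f[5]))
    if (is.finite(az)) baseline <- az
  }
  list(file = f[1], format = as.numeric(sub("x.*|:.*|\\+.*", "", f[2])),
       gain = gain, baseline = baseline)
}

decode_212 <- function(raw, n_sig) {
  nb <- (length(raw) %/% 3) * 3
  b <- as.integer(raw[seq_len(nb)])
  b0 <- b[seq(1, nb, 3)]; b1 <- b[seq(2, nb, 3)]; b2 <- b[seq(3, nb, 3)]
  s0 <- bitwAnd(b1, 15L) * 256L + b0
  s1 <- bitwAnd(bitwShiftR(b1, 4L), 15L) * 256L + b2
  s0 <- ifelse(s0 > 2047L, s0 - 4096L, s0)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  inter <- as.vector(rbind(s0, s1))
  n <- (length(inter) %/% n_sig) * n_sig
  matrix(inter[seq_len(n)], ncol = n_sig, byrow = TRUE)
}

decode_16 <- function(raw, n_sig) {
  v <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
               signed = TRUE, endian = "little")
  n <- (length(v) %/% n_sig) * n_sig
  matrix(v[seq_len(n)], ncol = n_sig, byrow = TRUE)
}

read_mit_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  words <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                   signed = FALSE, endian = "little")
  i <- 1L; t <- 0L
  sample <- integer(0); code <- integer(0); aux <- character(0)
  pend_aux <- NA_character_
  while (i <= length(words)) {
    w <- words[i]
    a <- bitwShiftR(w, 10L)
    inc <- bitwAnd(w, 1023L)
    if (a == 0L && inc == 0L) break
    if (a == 59L) {            # SKIP: 4-byte interval, high word first
      hi <- words[i + 1L]; lo <- words[i + 2L]
      t <- t + hi * 65536L + lo
      i <- i + 3L
      next
    }
    if (a %in% c(60L, 61L, 62L)) {  # NUM/SUBTYP/CHN: modifier, no time
      i <- i + 1L
      next
    }
    if (a == 63L) {            # AUX: inc = byte count, padded to even
      nb <- inc
      bytes <- raw[(2L * i + 1L):(2L * i + nb)]
      pend_aux <- rawToChar(bytes[bytes != as.raw(0)])
      i <- i + 1L + (nb + nb %% 2L) %/% 2L
      if (length(sample)) aux[length(sample)] <- pend_aux
      next
    }
    t <- t + inc
    sample <- c(sample, t)
    code <- c(code, a)
    aux <- c(aux, NA_character_)
    i <- i + 1L
  }
  list(sample = sample, code = code, aux = aux)
}

#' Write a WFDB record triple (format 212)
#'
#' Quantizes the signal with gain 200 adu/mV and baseline 1024 (the
#' MIT-BIH convention), writes `<id>.hea`, `<id>.dat` and beat
#' annotations to `<id>.atr`.
#'
#' @param rec An [ecg_record()] whose beat symbols are in the 15-symbol
#'   MIT-BIH alphabet.
#' @param dir Output directory.
#' @return The record stem, invisibly.
#' @export
write_wfdb <- function(rec, dir) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, rec$record_id)
  gain <- 200; base <- 1024
  adc <- round(rec$signal * gain + base)
  adc <- pmin(pmax(adc, -2048), 2047)
  n_sig <- ncol(adc)
  hdr <- c(sprintf("%s %d %g %d", rec$record_id, n_sig, rec$fs,
                   nrow(adc)),
           sprintf("%s.dat 212 %g(%g)/mV 12 0 0 0 0 lead%d",
                   rec$record_id, gain, base, seq_len(n_sig)))
  writeLines(hdr, paste0(stem, ".hea"))
  inter <- as.integer(t(adc))
  if (length(inter) %% 2L) inter <- c(inter, 0L)
  s0 <- inter[seq(1, length(inter), 2)]
  s1 <- inter[seq(2, length(inter), 2)]
  u0 <- ifelse(s0 < 0L, s0 + 4096L, s0)
  u1 <- ifelse(s1 < 0L, s1 + 4096L, s1)
  bytes <- as.raw(rbind(
    bitwAnd(u0, 255L),
    bitwOr(bitwShiftL(bitwAnd(bitwShiftR(u1, 8L), 15L), 4L),
           bitwAnd(bitwShiftR(u0, 8L), 15L)),
    bitwAnd(u1, 255L)))
  writeBin(bytes, paste0(stem, ".dat"))
  write_mit_annotations(paste0(stem, ".atr"), rec$r_peaks - 1L,
                        rec$beat_symbols)
  invisible(stem)
}

write_mit_annotations <- function(path, samples0, symbols) {
  codes <- WFDB_BEAT_CODES[symbols]
  if (anyNA(codes)) {
    stop("symbols outside the MIT-BIH beat alphabet: ",
         paste(unique(symbols[is.na(codes)]), collapse = " "))
  }
  incs <- diff(c(0L, as.integer(samples0)))
  words <- integer(0)
  for (k in seq_along(incs)) {
    inc <- incs[k]
    if (inc > 1023L) {  # SKIP annotation carries the long interval
      words <- c(words, bitwShiftL(59L, 10L),
                 inc %/% 65536L, inc %% 65536L)
      inc <- 0L
    }
    words <- c(words, bitwOr(bitwShiftL(codes[[k]], 10L), inc))
  }
  words <- c(words, 0L)  # EOF
  words <- ifelse(words > 32767L, words - 65536L, words)  # signed 16-bit
  writeBin(as.integer(words), path, size = 2, endian = "little")
}
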