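# Record readers and writers.  CSV (columns time_s, ppg) is the primary
# interchange format; a minimal WFDB format-16 reader/writer covers the
# header + int16 signal layout used by bedside-monitor archives.  Ground
# truth of synthetic records travels as a JSON sidecar.

#' Write a waveform as CSV
#'
#' Comma-separated, header `time_s,ppg`, UTF-8, one row per sample.
#'
#' @param w a `waveform`.
#' @param path output file path.
#' @export
write_ppg_csv <- function(w, path) {
  stopifnot(is_waveform(w))
  utils::write.csv(data.frame(time_s = wave_time(w), ppg = w$samples),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a waveform from CSV
#'
#' Expects columns `time_s` and `ppg` (or any two columns read as time
#' and value).  The sampling rate is inferred from the time column and
#' checked for regularity.
#'
#' @param path CSV file path.
#' @return a `waveform`.
#' @export
read_ppg_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "ppg") %in% names(d))) {
    if (ncol(d) < 2L) stop("CSV must have time and value columns")
    names(d)[1:2] <- c("time_s", "ppg")
  }
  t <- d$time_s
  v <- d$ppg
  dt <- diff(t)
  if (any(!is.finite(dt)) || any(dt <= 0))
    stop("time column must be strictly increasing and finite")
  if (stats::sd(dt) > 1e-4 * mean(dt))
    stop("irregular sampling detected in time column")
  if (anyNA(v)) {
    runs <- rle(is.na(v))
    if (max(runs$lengths[runs$values]) > 1 / mean(dt))
      stop("NaN run longer than 1 s in signal")
    v <- stats::approx(t[!is.na(v)], v[!is.na(v)], xout = t, rule = 2)$y
  }
  waveform(v, fs = 1 / mean(dt), t0 = t[1])
}

#' Write a waveform as a WFDB format-16 record
#'
#' Produces `<name>.hea` and `<name>.dat` (16-bit little-endian integers)
#' with signal name `PPG`.  The ADC gain is chosen to span the signal's
#' range, so values are quantized to one part in ~32000 of the peak
#' amplitude.
#'
#' @param w a `waveform`.
#' @param name record name (no extension).
#' @param dir output directory.
#' @return the record base path, invisibly.
#' @export
write_wfdb <- function(w, name, dir = ".") {
  stopifnot(is_waveform(w))
  peak <- max(abs(w$samples), 1e-12)
  gain <- 32000 / peak
  dig <- as.integer(round(w$samples * gain))
  base <- file.path(dir, name)
  con <- file(paste0(base, ".dat"), "wb")
  writeBin(dig, con, size = 2L, endian = "little")
  close(con)
  hea <- c(sprintf("%s 1 %g %d", name, w$fs, length(dig)),
           sprintf("%s.dat 16 %.6f(0)/au 16 0 %d 0 0 PPG",
                   name, gain, dig[1]))
  writeLines(hea, paste0(base, ".hea"))
  invisible(base)
}

#' Read a WFDB format-16 record
#'
#' Minimal reader for single- or multi-channel format-16 records; returns
#' the channel named `PPG` (or the first channel).
#'
#' @param name record name (no extension).
#' @param dir directory containing `<name>.hea` and `<name>.dat`.
#' @return a `waveform`.
#' @export
read_wfdb <- function(name, dir = ".") {
  base <- file.path(dir, name)
  hea <- readLines(paste0(base, ".hea"))
  hd <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  nsig <- as.integer(hd[2])
  fs <- as.numeric(hd[3])
  nsamp <- as.integer(hd[4])
  sig_lines <- hea[2:(1 + nsig)]
  fields <- lapply(sig_lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  fmts <- vapply(fields, `[[`, character(1), 2)
  if (!all(fmts == "16"))
    stop("only WFDB format 16 is supported")
  desc <- vapply(fields, function(f) f[length(f)], character(1))
  ch <- which(desc == "PPG")
  if (!length(ch)) {
    if (nsig == 1L) ch <- 1L else stop("no PPG channel in record ", name)
  }
  gains <- vapply(fields, function(f) {
    g <- sub("\\(.*", "", f[3])
    g <- sub("/.*", "", g)
    as.numeric(g)
  }, numeric(1))
  con <- file(paste0(base, ".dat"), "rb")
  raw <- readBin(con, integer(), n = nsamp * nsig, size = 2L,
                 endian = "little", signed = TRUE)
  close(con)
  m <- matrix(raw, ncol = nsig, byrow = TRUE)
  waveform(m[, ch[1]] / gains[ch[1]], fs = fs)
}

#' Read a PPG record from disk
#'
#' @param path for `format = "csv"` the CSV file; for `format = "wfdb"`
#'   the record base path (with or without `.hea`).
#' @param format `"csv"` or `"wfdb"`.
#' @return a `waveform`.
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") return(read_ppg_csv(path))
  path <- sub("\\.hea$", "", path)
  read_wfdb(basename(path), dirname(path))
}

#' Write a synthetic record with its ground-truth sidecar
#'
#' Writes the PPG signal (CSV and/or WFDB) plus `<name>_truth.json`
#' holding the generative parameters, label and seed -- enough to
#' regenerate every truth component via [make_ppg()].
#'
#' @param record a [make_ppg()] record.
#' @param name record base name.
#' @param dir output directory.
#' @param format `"csv"`, `"wfdb"` or both.
#' @export
write_record <- function(record, name, dir = ".",
                         format = c("csv", "wfdb")) {
  stopifnot(inherits(record, "ppg_record"))
  format <- match.arg(format, several.ok = TRUE)
  if ("csv" %in% format)
    write_ppg_csv(record$ppg, file.path(dir, paste0(name, ".csv")))
  if ("wfdb" %in% format)
    write_wfdb(record$ppg, name, dir)
  spec <- record$truth$spec
  sdof <- record$truth$sdof
  truth <- list(
    label = record$truth$label, seed = record$truth$seed,
    fs = record$ppg$fs, duration = wave_duration(record$ppg),
    pulse = spec[setdiff(names(spec), character(0))],
    sdof = list(m0 = sdof$m0, c0 = sdof$c0, k0 = sdof$k0,
                gamma = as.list(sdof$gamma), x_b_scale = sdof$x_b_scale,
                drift_sins = sdof$drift_sins,
                drift_walk_amp = sdof$drift_walk_amp,
                noise_sd = sdof$noise_sd))
  jsonlite::write_json(truth, file.path(dir, paste0(name, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, name))
}
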