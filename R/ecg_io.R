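#' Read an ECG record from disk
#'
#' Supports two dialects. `format = "csv"`: a comment line `# fs=<Hz>`,
#' a header row of lead names, then one row per sample and one column per
#' lead (amplitudes in mV). `format = "wfdb"`: a PhysioNet-style `.hea`
#' header plus a format-16 `.dat` file (16-bit little-endian two's complement,
#' samples interleaved across signals); digital units are converted to mV as
#' `(adc - baseline) / gain`.
#'
#' @param path file path; for WFDB either the `.hea` file or the record stem.
#' @param format `"csv"` or `"wfdb"`.
#' @return An [ecg_record].
#' @seealso [write_record()]
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  switch(format, csv = read_record_csv(path), wfdb = read_record_wfdb(path))
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^#\\s*fs=", first))
    stopf("malformed header in %s: expected leading '# fs=<Hz>' line", path)
  fs <- suppressWarnings(as.numeric(sub("^#\\s*fs=", "", first)))
  if (!is.finite(fs) || fs <= 0)
    stopf("malformed header in %s: unparsable fs value", path)
  widths <- utils::count.fields(path, sep = ",", skip = 1L)
  if (length(unique(widths)) > 1L)
    stopf("parse error in %s: ragged rows (field counts %s)", path,
          paste(unique(widths), collapse = "/"))
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  if (nrow(df) < 1L) stopf("parse error in %s: no data rows", path)
  m <- as.matrix(df)
  if (!is.numeric(m)) stopf("parse error in %s: non-numeric samples", path)
  ecg_record(m, fs = fs, lead_names = colnames(df),
             record_id = sub("\\.[^.]*$", "", basename(path)))
}

read_record_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stopf("file not found: %s", hea)
  lines <- grep("^#", readLines(hea), invert = TRUE, value = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) < 4L)
    stopf("malformed header %s: record line needs name/nsig/fs/nsamp", hea)
  nsig <- as.integer(hdr[2L])
  fs <- as.numeric(sub("/.*$", "", hdr[3L]))
  nsamp <- as.integer(hdr[4L])
  if (is.na(nsig) || is.na(fs) || is.na(nsamp))
    stopf("malformed header %s: unparsable record line field", hea)
  if (length(lines) < 1L + nsig)
    stopf("malformed header %s: %d signal lines for %d signals",
          hea, length(lines) - 1L, nsig)
  gain <- numeric(nsig); baseline <- numeric(nsig)
  leads <- character(nsig); datfile <- character(nsig)
  for (s in seq_len(nsig)) {
    tok <- strsplit(trimws(lines[1L + s]), "\\s+")[[1L]]
    datfile[s] <- tok[1L]
    fmt <- sub("[x:+].*$", "", tok[2L])
    if (!identical(fmt, "16"))
      stopf("unsupported WFDB signal format '%s' in %s (only 16)", tok[2L], hea)
    gspec <- if (length(tok) >= 3L) tok[3L] else "200"
    g <- sub("\\(.*", "", sub("/.*$", "", gspec))
    gain[s] <- suppressWarnings(as.numeric(g))
    if (!is.finite(gain[s]) || gain[s] == 0) gain[s] <- 200
    b <- if (grepl("\\(", gspec)) sub("^.*\\(([-0-9]+)\\).*$", "\\1", gspec)
         else if (length(tok) >= 5L) tok[5L] else "0"
    baseline[s] <- suppressWarnings(as.numeric(b))
    if (!is.finite(baseline[s])) baseline[s] <- 0
    leads[s] <- if (length(tok) >= 9L)
      paste(tok[9:length(tok)], collapse = " ") else paste0("sig", s)
  }
  if (length(unique(datfile)) != 1L)
    stopf("multi-file WFDB records are not supported (%s)", hea)
  dat <- file.path(dirname(hea), datfile[1L])
  if (!file.exists(dat)) stopf("file not found: %s", dat)
  raw <- readBin(dat, "integer", n = nsig * nsamp, size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) < nsig * nsamp)
    stopf("parse error in %s: expected %d samples, found %d",
          dat, nsig * nsamp, length(raw))
  adc <- matrix(raw[seq_len(nsig * nsamp)], nrow = nsig)
  mv <- sweep(sweep(t(adc), 2L, baseline, `-`), 2L, gain, `/`)
  ecg_record(mv, fs = fs, lead_names = leads,
             record_id = sub("\\.hea$", "", basename(hea)))
}

#' Write an ECG record to CSV
#'
#' Emits the dialect read by [read_record()]: a `# fs=` comment line, a lead
#' name header, one data column per lead. Round-trips sample values at full
#' double precision.
#'
#' @param record an [ecg_record].
#' @param path output file path.
#' @param format only `"csv"`.
#' @export
write_record <- function(record, path, format = "csv") {
  format <- match.arg(format, "csv")
  if (!is_ecg_record(record)) stopf("`record` must be an ecg_record")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", record$fs), con)
  df <- as.data.frame(record$samples, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Min-max amplitude normalization
#'
#' Affine map of a sequence onto `[ymin, ymax]`:
#' `y = (ymax - ymin) * (x - min(x)) / (max(x) - min(x)) + ymin`.
#' Constant input has no well-defined map (zero denominator) and raises an
#' error. Applied per lead, it removes inter-lead amplitude differences
#' before the sliding-window embedding.
#'
#' @param x numeric vector of finite amplitudes, not all equal.
#' @param ymin,ymax target range, default `(-1, 1)` with `ymax > ymin`.
#' @return numeric vector with `min(y) == ymin` and `max(y) == ymax`.
#' @examples
#' mapminmax_normalize(c(2, 4, 6))   # -1 0 1
#' @export
mapminmax_normalize <- function(x, ymin = -1, ymax = 1) {
  if (!is.numeric(x) || length(x) < 1L) stopf("`x` must be non-empty numeric")
  if (!all(is.finite(x))) stopf("`x` must be finite")
  if (!(is.finite(ymin) && is.finite(ymax) && ymax > ymin))
    stopf("need finite ymax > ymin")
  xmin <- min(x); xmax <- max(x)
  if (xmax == xmin)
    stopf("constant input: min-max normalization is undefined")
  (ymax - ymin) * (x - xmin) / (xmax - xmin) + ymin
}

#' Per-lead min-max normalization of a record
#'
#' @param record an [ecg_record].
#' @inheritParams mapminmax_normalize
#' @return the record with each lead mapped onto `[ymin, ymax]`.
#' @export
normalize_record <- function(record, ymin = -1, ymax = 1) {
  record$samples <- apply(record$samples, 2L, mapminmax_normalize,
                          ymin = ymin, ymax = ymax)
  if (!is.matrix(record$samples))
    record$samples <- matrix(record$samples, ncol = n_leads(record))
  colnames(record$samples) <- record$lead_names
  record
}

#' Split a multi-lead record into single-lead records
#'
#' Lead order is preserved; the provisional quality label and sampling rate
#' propagate; record ids gain a `_<lead>` suffix.
#'
#' @param record an [ecg_record].
#' @return list of single-lead [ecg_record] objects, one per lead.
#' @export
split_leads <- function(record) {
  if (!is_ecg_record(record)) stopf("`record` must be an ecg_record")
  lapply(seq_len(n_leads(record)), function(i) {
    ecg_record(record$samples[, i, drop = FALSE], fs = record$fs,
               lead_names = record$lead_names[i], label = record$label,
               record_id = paste0(record$record_id, "_",
                                  record$lead_names[i]))
  })
}

#' Flag empty (flat-line) leads
#'
#' A lead is flagged "empty" when its longest run of consecutive samples
#' lying within `eps` of some constant covers at least `flat_fraction_threshold`
#' of the lead. The default tolerance scales with the lead's amplitude range
#' (`1e-4 * range`, or an absolute 1e-6 mV for degenerate leads), which makes
#' the detector invariant to DC offset and catches both flat lines and
#' saturated leads.
#'
#' @param record an [ecg_record].
#' @param flat_fraction_threshold fraction of the lead, in (0, 1], that the
#'   flat run must cover; default 0.95.
#' @param eps half-width of the amplitude band counted as "constant";
#'   `NULL` for the range-scaled default.
#' @return named logical vector, one flag per lead.
#' @export
detect_empty_leads <- function(record, flat_fraction_threshold = 0.95,
                               eps = NULL) {
  if (!is_ecg_record(record)) stopf("`record` must be an ecg_record")
  if (!(flat_fraction_threshold > 0 && flat_fraction_threshold <= 1))
    stopf("`flat_fraction_threshold` must lie in (0, 1]")
  n <- n_samples(record)
  flags <- vapply(seq_len(n_leads(record)), function(i) {
    x <- record$samples[, i]
    e <- eps
    if (is.null(e)) {
      rng <- max(x) - min(x)
      e <- if (rng > 0) 1e-4 * rng else 1e-6
    }
    longest_flat_run_cpp(x, 2 * e) >= flat_fraction_threshold * n
  }, logical(1L))
  names(flags) <- record$lead_names
  flags
}
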