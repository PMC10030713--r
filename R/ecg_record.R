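#' ECG record container
#'
#' An `ecg_record` holds a multi-lead sampled waveform: a numeric matrix with
#' one column per lead (amplitudes in mV), a sampling rate in Hz, ordered
#' lead names, an optional overall quality label, and a record identifier.
#'
#' @param samples numeric matrix (samples x leads) or a numeric vector for a
#'   single lead; amplitudes in millivolts.
#' @param fs sampling rate in Hz (> 0).
#' @param lead_names character vector of lead labels, one per column.
#' @param label optional quality label: `"acceptable"`, `"unacceptable"` or
#'   `"indeterminate"`.
#' @param record_id identifier, by convention the source file stem.
#'
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(matrix(sin(seq(0, 20, length.out = 500)), ncol = 1),
#'                   fs = 50, lead_names = "I", record_id = "demo")
#' duration_seconds(rec)
#' @export
ecg_record <- function(samples, fs, lead_names = NULL, label = NULL,
                       record_id = "record") {
  if (is.vector(samples) && is.numeric(samples))
    samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stopf("`samples` must be a numeric matrix or vector")
  if (nrow(samples) < 1L) stopf("record must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stopf("`fs` must be a single positive number (Hz)")
  if (is.null(lead_names)) {
    lead_names <- colnames(samples) %||% paste0("lead", seq_len(ncol(samples)))
  }
  if (length(lead_names) != ncol(samples))
    stopf("got %d lead names for %d leads", length(lead_names), ncol(samples))
  if (!is.null(label)) {
    label <- match.arg(label, c("acceptable", "unacceptable", "indeterminate"))
  }
  colnames(samples) <- lead_names
  structure(list(samples = samples, fs = as.numeric(fs),
                 lead_names = as.character(lead_names), label = label,
                 record_id = as.character(record_id)),
            class = "ecg_record")
}

#' @rdname ecg_record
#' @param x,rec an `ecg_record`.
#' @export
is_ecg_record <- function(x) inherits(x, "ecg_record")

#' @rdname ecg_record
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' @rdname ecg_record
#' @export
n_leads <- function(rec) ncol(rec$samples)

#' @rdname ecg_record
#' @export
duration_seconds <- function(rec) nrow(rec$samples) / rec$fs

#' @param ... ignored.
#' @rdname ecg_record
#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s': %d lead(s) x %d samples @ %g Hz (%.3g s)%s>\n",
              x$record_id, n_leads(x), n_samples(x), x$fs,
              duration_seconds(x),
              if (is.null(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}
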