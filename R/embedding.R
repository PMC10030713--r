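#' Sliding-window embedding parameters
#'
#' The delay embedding folds a length-`n` series into `t` points in `R^d`,
#' where `t = round(window_seconds * fs)` is the window length in samples and
#' `d = floor(n / t)` the ambient dimension per lead. Trailing samples beyond
#' `d * t` are discarded; a series shorter than one window is rejected.
#'
#' @param window_seconds window length in seconds.
#' @param fs sampling rate in Hz.
#' @param n series length in samples.
#' @return list with `t`, `d`, `window_seconds`, `fs`, `n`.
#' @export
embedding_params <- function(window_seconds, fs, n) {
  if (!(window_seconds > 0) || !(fs > 0)) stopf("window and fs must be > 0")
  t_win <- as.integer(round(window_seconds * fs))
  if (t_win < 1L) stopf("window of %g s is below one sample at %g Hz",
                        window_seconds, fs)
  if (n < t_win)
    stopf("series of %d samples cannot fill one %d-sample window; discarded",
          n, t_win)
  d <- n %/% t_win
  list(window_seconds = window_seconds, fs = fs, n = as.integer(n),
       t = t_win, d = as.integer(d))
}

#' Ambient dimension of the sliding-window point cloud
#'
#' `n_leads * floor(n / t)` with `n = round(duration_s * fs)` and
#' `t = round(window_seconds * fs)`. For 10-s, 500-Hz records this yields
#' the grids 100/50/33/25/20 (single lead, 0.1-0.5 s windows) and
#' 120/60/36/24/24 (12 leads, 1-5 s windows).
#'
#' @param duration_s segment duration in seconds.
#' @param fs sampling rate in Hz.
#' @param window_seconds window length in seconds.
#' @param n_leads number of leads stacked into the cloud.
#' @return integer dimension.
#' @examples
#' embedding_dimension(10, 500, 0.3, 1)   # 33
#' embedding_dimension(10, 500, 1, 12)    # 120
#' @export
embedding_dimension <- function(duration_s, fs, window_seconds, n_leads = 1L) {
  if (n_leads < 1L) stopf("`n_leads` must be >= 1")
  p <- embedding_params(window_seconds, fs, round(duration_s * fs))
  as.integer(n_leads) * p$d
}

#' Delay-embed a series into a point cloud
#'
#' Point `j` (for `j = 1..t`) has coordinates
#' `(x_j, x_{j+t}, ..., x_{j+(d-1)t})`: the series is cut into `d`
#' consecutive windows of `t` samples and window `i` supplies coordinate `i`
#' of every point.
#'
#' @param series numeric amplitude vector.
#' @param window_seconds window length in seconds (ignored when `params`
#'   given).
#' @param fs sampling rate in Hz (ignored when `params` given).
#' @param params optional precomputed [embedding_params()].
#' @param record_id provenance tag.
#' @return a `point_cloud`: a `t x d` numeric matrix (rows are points) with
#'   the embedding parameters attached as attributes.
#' @examples
#' sliding_window_embed(1:6, params = embedding_params(2, 1, 6))
#' @export
sliding_window_embed <- function(series, window_seconds = NULL, fs = NULL,
                                 params = NULL, record_id = NULL) {
  if (is.null(params)) params <- embedding_params(window_seconds, fs,
                                                  length(series))
  if (length(series) < params$t)
    stopf("series of %d samples cannot fill one %d-sample window; discarded",
          length(series), params$t)
  used <- params$d * params$t
  pts <- matrix(as.numeric(series[seq_len(used)]), nrow = params$t,
                ncol = params$d)
  if (!all(is.finite(pts))) stopf("series contains non-finite values")
  structure(pts, class = c("point_cloud", "matrix", "array"),
            params = params, record_id = record_id)
}

#' @rdname sliding_window_embed
#' @param x a `point_cloud`.
#' @export
is_point_cloud <- function(x) inherits(x, "point_cloud")

#' Stack per-lead point clouds into one cloud
#'
#' Coordinate-wise concatenation: point `j` of the stacked cloud is the
#' concatenation of point `j` from each lead, so the dimension is the sum of
#' the per-lead dimensions (e.g. 12 leads of d = 10 give d = 120). All
#' clouds must share one point count `t`.
#'
#' @param per_lead_clouds list of `point_cloud`s with equal row counts.
#' @return a single `point_cloud`.
#' @export
stack_leads <- function(per_lead_clouds) {
  stopifnot(length(per_lead_clouds) >= 1L,
            all(vapply(per_lead_clouds, is_point_cloud, logical(1L))))
  if (length(per_lead_clouds) == 1L) return(per_lead_clouds[[1L]])
  tt <- vapply(per_lead_clouds, nrow, integer(1L))
  if (length(unique(tt)) != 1L)
    stopf("mismatched point counts across leads: %s",
          paste(unique(tt), collapse = ", "))
  pts <- do.call(cbind, lapply(per_lead_clouds, unclass))
  p1 <- attr(per_lead_clouds[[1L]], "params")
  p1$d <- ncol(pts)
  structure(pts, class = c("point_cloud", "matrix", "array"),
            params = p1, record_id = attr(per_lead_clouds[[1L]], "record_id"))
}

#' @rdname sliding_window_embed
#' @param ... ignored.
#' @export
print.point_cloud <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<point_cloud: %d points in R^%d (t = %s, window %s s)>\n",
              nrow(x), ncol(x),
              if (is.null(p)) "?" else p$t,
              if (is.null(p)) "?" else format(p$window_seconds)))
  invisible(x)
}
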