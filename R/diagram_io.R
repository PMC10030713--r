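#' Persist a diagram as CSV (+ JSON provenance sidecar)
#'
#' Columns `dim`, `birth`, `death`; infinite deaths are written as `"inf"`.
#' Provenance (source, parameters) lands in `<path>.json`.
#'
#' @param diagram a [persistence_diagram].
#' @param path CSV path.
#' @export
write_diagram <- function(diagram, path) {
  stopifnot(is_persistence_diagram(diagram))
  df <- data.frame(dim = diagram$dimension,
                   birth = sprintf("%.17g", diagram$birth),
                   death = ifelse(is.infinite(diagram$death), "inf",
                                  sprintf("%.17g", diagram$death)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  prov <- list(source = attr(diagram, "source"),
               params = attr(diagram, "params"))
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(NULL)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = c("integer", "character",
                                             "character"))
  side <- paste0(path, ".json")
  prov <- if (file.exists(side)) jsonlite::read_json(side) else list()
  num <- function(x) ifelse(tolower(x) == "inf", Inf, as.numeric(x))
  persistence_diagram(df$dim, num(df$birth), num(df$death),
                      source = prov$source %||% "vr",
                      params = prov$params)
}

#' Persist a point cloud as CSV (+ JSON provenance sidecar)
#'
#' One point per row; embedding parameters go to `<path>.json`.
#'
#' @param cloud a `point_cloud`.
#' @param path CSV path.
#' @export
write_point_cloud <- function(cloud, path) {
  stopifnot(is_point_cloud(cloud))
  m <- unclass(cloud)
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  prov <- list(params = attr(cloud, "params"),
               record_id = attr(cloud, "record_id"))
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(NULL)
}
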