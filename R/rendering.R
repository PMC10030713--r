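#' Rendering style for barcode and diagram images
#'
#' Fixed-size square RGB rasters for the image classifier: H0 features in
#' blue, H1 in red on a white background, no axes or text by default
#' (`axis_mode = "none"`) so that image content depends only on the
#' diagram's geometry. Infinite bars are truncated at the right edge
#' (barcodes) or plotted on a top gutter line (diagrams).
#'
#' @param side_px image side in pixels (>= 32), default 224.
#' @param h0_color,h1_color,background RGB triples in 0..255.
#' @param bar_thickness_px bar thickness in pixels.
#' @param axis_mode `"none"` (classifier-bound) or `"plain"` (thin black
#'   frame + diagonal, for documentation figures).
#' @return a `render_style` list.
#' @export
render_style <- function(side_px = 224L, h0_color = c(0L, 0L, 255L),
                         h1_color = c(255L, 0L, 0L),
                         background = c(255L, 255L, 255L),
                         bar_thickness_px = 1L,
                         axis_mode = c("none", "plain")) {
  axis_mode <- match.arg(axis_mode)
  if (side_px < 32L) stopf("`side_px` must be at least 32")
  stopifnot(length(h0_color) == 3L, length(h1_color) == 3L,
            length(background) == 3L)
  if (identical(as.integer(h0_color), as.integer(h1_color)))
    stopf("H0 and H1 colors must be distinct")
  structure(list(side_px = as.integer(side_px),
                 h0_color = as.integer(h0_color),
                 h1_color = as.integer(h1_color),
                 background = as.integer(background),
                 bar_thickness_px = as.integer(bar_thickness_px),
                 axis_mode = axis_mode),
            class = "render_style")
}

new_raster <- function(style, provenance = NULL) {
  s <- style$side_px
  px <- array(0L, dim = c(s, s, 3L))
  for (ch in 1:3) px[, , ch] <- style$background[ch]
  structure(px, class = c("raster_image", "array"), provenance = provenance)
}

#' @rdname render_style
#' @param x object to test.
#' @export
is_raster_image <- function(x) inherits(x, "raster_image")

# map value -> column index in 1..side for a fixed abscissa range
value_to_px <- function(v, lo, hi, side) {
  if (hi <= lo) hi <- lo + 1
  pmin(side, pmax(1L, 1L + floor((v - lo) / (hi - lo) * (side - 1L))))
}

resolve_range <- function(diagram, value_range) {
  if (!is.null(value_range)) return(as.numeric(value_range))
  fin <- c(diagram$birth, diagram$death[is.finite(diagram$death)])
  if (!length(fin)) return(c(0, 1))
  lo <- min(0, fin)
  hi <- max(fin)
  if (hi <= lo) hi <- lo + 1
  c(lo, hi)
}

paint_frame <- function(px, style) {
  s <- style$side_px
  for (ch in 1:3) {
    px[1L, , ch] <- 0L; px[s, , ch] <- 0L
    px[, 1L, ch] <- 0L; px[, s, ch] <- 0L
  }
  px
}

#' Render a persistence barcode image
#'
#' One horizontal bar per birth-death pair, H0 bars below H1 bars, each in
#' its style color; bars are sorted by (dimension, birth, death) and spread
#' evenly over the image height. The abscissa spans `value_range`
#' (default: the diagram's own range; pass a dataset-wide range so bar
#' positions are comparable across images). Infinite bars run to the right
#' edge. Byte-deterministic for identical inputs.
#'
#' @param diagram a [persistence_diagram].
#' @param style a [render_style()].
#' @param value_range abscissa range `c(lo, hi)`, or `NULL`.
#' @return a `raster_image`: `side x side x 3` array of 0..255 integers.
#' @export
render_barcode <- function(diagram, style = render_style(),
                           value_range = NULL) {
  stopifnot(is_persistence_diagram(diagram))
  rng <- resolve_range(diagram, value_range)
  px <- new_raster(style, provenance = list(kind = "barcode",
                                            source = attr(diagram, "source"),
                                            value_range = rng,
                                            params = attr(diagram, "params")))
  s <- style$side_px
  if (style$axis_mode == "plain") px <- paint_frame(px, style)
  n <- nrow(diagram)
  if (n == 0L) return(px)
  ord <- order(diagram$dimension, diagram$birth, diagram$death)
  d <- diagram[ord, , drop = FALSE]
  margin <- max(2L, style$bar_thickness_px)
  rows <- round(seq(s - margin, margin, length.out = n))  # H0 at the bottom
  half <- (style$bar_thickness_px - 1L) %/% 2L
  for (i in seq_len(n)) {
    c0 <- value_to_px(d$birth[i], rng[1L], rng[2L], s)
    c1 <- if (is.finite(d$death[i]))
      value_to_px(d$death[i], rng[1L], rng[2L], s) else s
    col <- if (d$dimension[i] == 0L) style$h0_color else style$h1_color
    rr <- pmin(s, pmax(1L, (rows[i] - half):(rows[i] + half)))
    for (ch in 1:3) px[rr, c0:c1, ch] <- col[ch]
  }
  px
}

#' Render a persistence diagram image
#'
#' Scatter of (birth, death) points above the diagonal, H0/H1 in their
#' style colors as 3x3 pixel squares; the diagonal is drawn in black and
#' infinite deaths sit on a gutter line 4 pixels below the top edge. Both
#' axes span `value_range`. Byte-deterministic.
#'
#' @inheritParams render_barcode
#' @return a `raster_image`.
#' @export
render_diagram <- function(diagram, style = render_style(),
                           value_range = NULL) {
  stopifnot(is_persistence_diagram(diagram))
  rng <- resolve_range(diagram, value_range)
  px <- new_raster(style, provenance = list(kind = "diagram",
                                            source = attr(diagram, "source"),
                                            value_range = rng,
                                            params = attr(diagram, "params")))
  s <- style$side_px
  if (style$axis_mode == "plain") px <- paint_frame(px, style)
  # diagonal: death == birth, i.e. row (from top) s - col + 1
  for (cc in seq_len(s)) {
    rr <- s - cc + 1L
    px[rr, cc, ] <- 0L
  }
  gutter_row <- 4L
  if (nrow(diagram)) {
    for (i in seq_len(nrow(diagram))) {
      cc <- value_to_px(diagram$birth[i], rng[1L], rng[2L], s)
      rr <- if (is.finite(diagram$death[i]))
        s - value_to_px(diagram$death[i], rng[1L], rng[2L], s) + 1L
      else gutter_row
      col <- if (diagram$dimension[i] == 0L) style$h0_color else style$h1_color
      rs <- pmin(s, pmax(1L, (rr - 1L):(rr + 1L)))
      cs <- pmin(s, pmax(1L, (cc - 1L):(cc + 1L)))
      for (ch in 1:3) px[rs, cs, ch] <- col[ch]
    }
  }
  px
}

#' Block-mean downsample of a raster image
#'
#' Used inside the classifier backends: the 224-pixel renders are reduced
#' to `side` pixels by averaging (nearly) equal pixel blocks.
#'
#' @param image a `raster_image` or side x side x 3 array.
#' @param side target side in pixels.
#' @return numeric `side x side x 3` array in 0..1.
#' @export
downsample_image <- function(image, side = 64L) {
  a <- unclass(image)
  src <- dim(a)[1L]
  g <- ceiling(seq_len(src) * side / src)
  out <- array(0, dim = c(side, side, 3L))
  for (ch in 1:3) {
    m <- rowsum(a[, , ch], g) / as.vector(table(g))
    m <- t(rowsum(t(m), g) / as.vector(table(g)))
    out[, , ch] <- m
  }
  out / 255
}
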