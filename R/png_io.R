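# Minimal PNG codec: 8-bit RGB, no alpha, filter type 0, IDAT deflated via
# base memCompress (zlib stream). Self-contained so that image round-trips
# need no external imaging library; deterministic bytes for fixed input.

crc32_table <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L))
        bitwXor(bitwShiftR(cc, 1L), -306674912L)  # 0xEDB88320
      else bitwShiftR(cc, 1L)
    }
    tab[i + 1L] <- cc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  ints <- as.integer(bytes)
  tab <- crc32_table
  for (b in ints)
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

int_to_be4 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

be4_to_int <- function(r) sum(as.numeric(r) * c(16777216, 65536, 256, 1))

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_to_be4(length(data)), body, int_to_be4(crc32(body)))
}

#' Write a raster image as PNG
#'
#' 8-bit RGB, no alpha, scanline filter "None"; byte-deterministic under a
#' fixed zlib. Files round-trip exactly through [read_png()].
#'
#' @param image a `raster_image` (or height x width x 3 array of 0..255).
#' @param path output path.
#' @export
write_png <- function(image, path) {
  a <- unclass(image)
  if (length(dim(a)) != 3L || dim(a)[3L] != 3L)
    stopf("`image` must be a height x width x 3 array")
  if (any(a < 0 | a > 255)) stopf("pixel intensities must lie in 0..255")
  h <- dim(a)[1L]; w <- dim(a)[2L]
  interleaved <- aperm(array(as.integer(a), dim(a)), c(3L, 2L, 1L))
  bytes <- matrix(as.raw(interleaved), nrow = 3L * w)  # one column per row
  stream <- as.vector(rbind(matrix(as.raw(0L), nrow = 1L, ncol = h), bytes))
  ihdr <- c(int_to_be4(w), int_to_be4(h),
            as.raw(c(8L, 2L, 0L, 0L, 0L)))  # depth 8, truecolor RGB
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(stream, "gzip")),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(NULL)
}

#' Read a PNG written by [write_png()]
#'
#' Supports the subset this package emits: 8-bit RGB, non-interlaced,
#' filter type 0 on every scanline.
#'
#' @param path PNG file path.
#' @return a `raster_image` array of 0..255 integers.
#' @export
read_png <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  r <- readBin(path, "raw", n = file.size(path))
  if (!identical(r[1:8], as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))))
    stopf("%s is not a PNG file", path)
  pos <- 9L
  idat <- raw(0)
  w <- h <- NA_integer_
  while (pos + 7L <= length(r)) {
    len <- be4_to_int(r[pos:(pos + 3L)])
    type <- rawToChar(r[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) r[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") {
      w <- be4_to_int(data[1:4]); h <- be4_to_int(data[5:8])
      if (as.integer(data[9L]) != 8L || as.integer(data[10L]) != 2L)
        stopf("unsupported PNG flavor (need 8-bit RGB): %s", path)
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  stream <- memDecompress(idat, "gzip")
  stride <- 1L + 3L * w
  if (length(stream) != h * stride)
    stopf("corrupt PNG payload in %s", path)
  m <- matrix(stream, nrow = stride)
  if (any(m[1L, ] != as.raw(0L)))
    stopf("unsupported PNG scanline filter in %s (only None)", path)
  interleaved <- array(as.integer(m[-1L, , drop = FALSE]), dim = c(3L, w, h))
  structure(aperm(interleaved, c(3L, 2L, 1L)),
            class = c("raster_image", "array"))
}
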