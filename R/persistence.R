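#' Persistence diagram container
#'
#' A data frame of birth-death pairs, one row per topological feature:
#' `dimension` (0 = connected components, 1 = loops), `birth`, `death`
#' (`Inf` for essential features). The Betti number at scale `s` in
#' dimension `p` is the count of rows with `dimension == p` and
#' `birth <= s < death`. Zero-persistence pairs are excluded from diagrams.
#'
#' @param dimension integer vector of homology dimensions.
#' @param birth,death numeric vectors; `death >= birth`, `Inf` allowed.
#' @param source `"vr"` or `"sls"`.
#' @param params optional provenance (embedding parameters, max_scale, ...).
#' @return a `persistence_diagram` (also a data.frame), rows ordered by
#'   (dimension, birth, death).
#' @export
persistence_diagram <- function(dimension = integer(), birth = numeric(),
                                death = numeric(), source = "vr",
                                params = NULL) {
  stopifnot(length(dimension) == length(birth),
            length(birth) == length(death))
  if (any(death < birth)) stopf("death before birth in persistence pair")
  df <- data.frame(dimension = as.integer(dimension),
                   birth = as.numeric(birth), death = as.numeric(death))
  df <- df[order(df$dimension, df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("persistence_diagram", "data.frame"),
            source = source, params = params)
}

#' @rdname persistence_diagram
#' @param x a `persistence_diagram`.
#' @export
is_persistence_diagram <- function(x) inherits(x, "persistence_diagram")

#' @rdname persistence_diagram
#' @param ... ignored.
#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram (%s): %d pairs (H0: %d, H1: %d), %d essential>\n",
              attr(x, "source") %||% "?", nrow(x),
              sum(x$dimension == 0L), sum(x$dimension == 1L),
              sum(is.infinite(x$death))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Betti number read off a diagram
#'
#' @param diagram a [persistence_diagram].
#' @param scale filtration value at which to count live features.
#' @param dimension homology dimension.
#' @return integer count of bars alive at `scale`.
#' @export
betti_number <- function(diagram, scale, dimension = 0L) {
  sum(diagram$dimension == dimension & diagram$birth <= scale &
        scale < diagram$death)
}

pairwise_dist <- function(cloud) as.matrix(stats::dist(unclass(cloud)))

#' Default Vietoris-Rips scale cap
#'
#' The enclosing diameter for clouds of at most 200 points; the 90th
#' percentile of pairwise distances for larger clouds (triangle enumeration
#' is cubic in the worst case, so very large clouds get a softer cap).
#'
#' @param d dense pairwise distance matrix.
#' @return a scalar scale (distance units).
#' @export
default_max_scale <- function(d) {
  off <- d[lower.tri(d)]
  if (length(off) == 0L) return(0)
  if (nrow(d) <= 200L) max(off) else as.numeric(quantile(off, 0.9))
}

#' Build a Vietoris-Rips filtration
#'
#' All vertices enter at filtration value 0; an edge enters at the distance
#' between its endpoints when that distance is at most `max_scale`; a
#' triangle enters at its longest edge once all three edges are present.
#' Filtration values are *distances* (ball-diameter convention), and
#' simplices are ordered by (value, dimension, lexicographic vertex tuple).
#'
#' @param cloud a `point_cloud` or numeric matrix (rows are points).
#' @param max_scale distance cap; `NULL` for [default_max_scale()].
#' @param max_dim highest simplex dimension, at most 2 (triangles).
#' @return a `filtration`: list with `verts` (list of 1-based vertex
#'   tuples), `values`, `dims`, `max_scale`, `n_points`.
#' @export
build_vr_filtration <- function(cloud, max_scale = NULL, max_dim = 2L) {
  pts <- unclass(cloud)
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 1L)
  if (nrow(pts) < 1L) stopf("empty point cloud")
  if (!(max_dim %in% 0:2)) stopf("`max_dim` must be 0, 1 or 2")
  d <- pairwise_dist(pts)
  if (is.null(max_scale)) max_scale <- default_max_scale(d)
  if (max_scale < 0) stopf("`max_scale` must be nonnegative")
  n <- nrow(pts)
  verts <- lapply(seq_len(n), identity)
  values <- numeric(n)
  dims <- integer(n)
  if (max_dim >= 1L && n >= 2L) {
    idx <- which(lower.tri(d) & d <= max_scale, arr.ind = TRUE)
    if (nrow(idx)) {
      a <- pmin(idx[, 1L], idx[, 2L]); b <- pmax(idx[, 1L], idx[, 2L])
      verts <- c(verts, mapply(function(x, y) c(x, y), a, b,
                               SIMPLIFY = FALSE))
      values <- c(values, d[idx])
      dims <- c(dims, rep(1L, nrow(idx)))
    }
  }
  if (max_dim >= 2L && n >= 3L) {
    tri <- vr_triangles_cpp(d, max_scale)
    if (length(tri$i)) {
      verts <- c(verts, mapply(function(x, y, z) c(x, y, z),
                               tri$i, tri$j, tri$k, SIMPLIFY = FALSE))
      values <- c(values, tri$value)
      dims <- c(dims, rep(2L, length(tri$i)))
    }
  }
  k <- t(vapply(verts, function(v) c(v, 0L, 0L)[1:3], integer(3L)))
  o <- order(values, dims, k[, 1L], k[, 2L], k[, 3L])
  structure(list(verts = verts[o], values = values[o], dims = dims[o],
                 max_scale = max_scale, n_points = n),
            class = "filtration")
}

#' Persistence pairing by boundary-matrix reduction
#'
#' Standard left-to-right column reduction of the Z/2 boundary matrix in
#' filtration order. Unpaired creators become infinite bars.
#' Zero-persistence pairs (`birth == death`) are retained and flagged in the
#' `zero` column; [vr_persistence()] drops them.
#'
#' @param filtration a `filtration` from [build_vr_filtration()].
#' @return data.frame with columns `dimension`, `birth`, `death`, `zero`.
#' @export
reduce_boundary_matrix <- function(filtration) {
  stopifnot(inherits(filtration, "filtration"))
  m <- length(filtration$values)
  if (m == 0L) return(data.frame(dimension = integer(), birth = numeric(),
                                 death = numeric(), zero = logical()))
  key <- vapply(filtration$verts, paste, character(1L), collapse = ",")
  pos <- new.env(parent = emptyenv())
  for (i in seq_len(m)) assign(key[i], i, envir = pos)
  boundaries <- lapply(seq_len(m), function(i) {
    v <- filtration$verts[[i]]
    if (length(v) == 1L) return(integer())
    faces <- utils::combn(v, length(v) - 1L, simplify = FALSE)
    out <- vapply(faces, function(f) {
      p <- mget(paste(f, collapse = ","), envir = pos,
                ifnotfound = list(NA_integer_))[[1L]]
      if (is.na(p)) stopf("filtration integrity error: missing face")
      p
    }, integer(1L))
    if (any(out >= i))
      stopf("filtration integrity error: face ordered after its coface")
    out
  })
  red <- ph_reduce_cpp(boundaries)
  b <- red$pairs[, 1L]; dth <- red$pairs[, 2L]
  df <- data.frame(
    dimension = c(filtration$dims[b], filtration$dims[red$essential]),
    birth = c(filtration$values[b], filtration$values[red$essential]),
    death = c(filtration$values[dth], rep(Inf, length(red$essential))))
  df$zero <- df$birth == df$death
  df <- df[order(df$dimension, df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' H0 persistence via the minimum spanning tree
#'
#' The 0-dimensional Vietoris-Rips barcode of an n-point cloud is n bars
#' born at 0 whose n-1 finite deaths are exactly the minimum-spanning-tree
#' edge weights (sorted); the remaining bar is essential. This is the fast
#' path used by [vr_persistence()].
#'
#' @param cloud a `point_cloud` or numeric matrix.
#' @param max_scale deaths beyond this distance are reported as infinite
#'   (components never merge within the filtration); `NULL` for no cap.
#' @return data.frame with columns `dimension` (all 0), `birth` (all 0) and
#'   `death`.
#' @export
h0_via_mst <- function(cloud, max_scale = NULL) {
  pts <- unclass(cloud)
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 1L)
  if (nrow(pts) < 1L) stopf("empty point cloud")
  w <- mst_weights_cpp(pairwise_dist(pts))
  if (!is.null(max_scale)) {
    inf_extra <- sum(w > max_scale)
    w <- w[w <= max_scale]
  } else inf_extra <- 0L
  data.frame(dimension = 0L, birth = 0,
             death = c(w, rep(Inf, 1L + inf_extra)))
}

#' Vietoris-Rips persistence of a point cloud
#'
#' H0 via the minimum-spanning-tree fast path and H1 by reducing triangle
#' columns against the edge basis; both agree with full boundary-matrix
#' reduction ([reduce_boundary_matrix()]). Zero-persistence pairs are
#' dropped.
#'
#' @param cloud a `point_cloud` or numeric matrix (rows are points).
#' @param max_scale distance cap; `NULL` for [default_max_scale()].
#' @param max_homology_dim 0 or 1 (loops).
#' @return a [persistence_diagram] with source `"vr"`.
#' @examples
#' sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
#' vr_persistence(sq)  # one H1 pair: birth 1, death sqrt(2)
#' @export
vr_persistence <- function(cloud, max_scale = NULL, max_homology_dim = 1L) {
  pts <- unclass(cloud)
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 1L)
  if (nrow(pts) < 1L) stopf("empty point cloud")
  if (!(max_homology_dim %in% 0:1)) stopf("`max_homology_dim` must be 0 or 1")
  d <- pairwise_dist(pts)
  if (is.null(max_scale)) max_scale <- default_max_scale(d)
  h0 <- h0_via_mst(pts, max_scale = max_scale)
  h0 <- h0[h0$death > h0$birth, , drop = FALSE]
  dimension <- h0$dimension; birth <- h0$birth; death <- h0$death
  if (max_homology_dim >= 1L && nrow(pts) >= 3L) {
    h1 <- vr_h1_cpp(d, max_scale)
    keep <- h1$death > h1$birth
    dimension <- c(dimension, rep(1L, sum(keep)), rep(1L, length(h1$essential)))
    birth <- c(birth, h1$birth[keep], h1$essential)
    death <- c(death, h1$death[keep], rep(Inf, length(h1$essential)))
  }
  persistence_diagram(dimension, birth, death, source = "vr",
                      params = list(max_scale = max_scale,
                                    n_points = nrow(pts),
                                    embedding = attr(cloud, "params"),
                                    record_id = attr(cloud, "record_id")))
}

#' Sublevel-set persistence of a time series
#'
#' 0-dimensional persistence of the piecewise-linear graph of the series
#' filtered by amplitude: as the level `alpha` sweeps upward, a component is
#' born at each local minimum and two components merge at a local maximum,
#' where the younger one (higher birth; ties broken leftmost-is-elder) dies.
#' The component of the global minimum never dies: its bar is infinite.
#' Plateaus (equal consecutive values) are collapsed to a single node before
#' the sweep; zero-persistence pairs are dropped.
#'
#' @param series numeric vector, length >= 1, finite.
#' @param record_id provenance tag.
#' @return a [persistence_diagram] with source `"sls"` (all dimension 0).
#' @examples
#' sls_persistence(c(2, 0, 1, -1, 3))  # finite pair (0, 1); (-1, Inf)
#' @export
sls_persistence <- function(series, record_id = NULL) {
  if (length(series) < 1L) stopf("empty series")
  if (!all(is.finite(series))) stopf("series must be finite")
  v <- as.numeric(series)
  v <- v[c(TRUE, diff(v) != 0)]  # collapse plateaus
  res <- sls_pairs_cpp(v)
  keep <- res$death > res$birth
  persistence_diagram(
    dimension = rep(0L, sum(keep) + 1L),
    birth = c(res$birth[keep], res$essential_birth),
    death = c(res$death[keep], Inf),
    source = "sls",
    params = list(n = length(series), record_id = record_id))
}
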