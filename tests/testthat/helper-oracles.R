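# Independent brute-force oracles. These deliberately share no code with the
# package: the VR oracle reduces the full dense boundary matrix in plain R,
# and the sublevel oracle recomputes path-graph components from scratch at
# every threshold.

# Full unoptimized persistence of the VR filtration (dims 0-2) of a small
# point cloud. Returns all pairs incl. zero-persistence, plus essentials.
naive_vr_pairs <- function(pts, max_scale = NULL) {
  d <- as.matrix(stats::dist(pts))
  n <- nrow(pts)
  if (is.null(max_scale)) max_scale <- if (n > 1) max(d) else 0
  verts <- lapply(seq_len(n), identity)
  vals <- rep(0, n)
  dims <- rep(0L, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) if (d[i, j] <= max_scale) {
      verts[[length(verts) + 1L]] <- c(i, j)
      vals <- c(vals, d[i, j]); dims <- c(dims, 1L)
    }
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      mx <- max(d[i, j], d[i, k], d[j, k])
      if (mx <= max_scale) {
        verts[[length(verts) + 1L]] <- c(i, j, k)
        vals <- c(vals, mx); dims <- c(dims, 2L)
      }
    }
  }
  key3 <- t(vapply(verts, function(v) c(v, 0L, 0L)[1:3], numeric(3)))
  o <- order(vals, dims, key3[, 1], key3[, 2], key3[, 3])
  verts <- verts[o]; vals <- vals[o]; dims <- dims[o]
  m <- length(verts)
  keys <- vapply(verts, paste, character(1), collapse = ",")
  # dense Z/2 boundary matrix
  B <- matrix(FALSE, m, m)
  for (j in seq_len(m)) {
    v <- verts[[j]]
    if (length(v) > 1L) {
      for (f in utils::combn(v, length(v) - 1L, simplify = FALSE))
        B[match(paste(f, collapse = ","), keys), j] <- TRUE
    }
  }
  low <- function(col) if (any(col)) max(which(col)) else 0L
  lows <- integer(m)
  for (j in seq_len(m)) {
    repeat {
      l <- low(B[, j])
      if (l == 0L) break
      prev <- which(lows[seq_len(j - 1L)] == l)
      if (!length(prev)) break
      B[, j] <- xor(B[, j], B[, prev[1L]])
    }
    lows[j] <- low(B[, j])
  }
  pb <- which(lows > 0L)
  pairs <- data.frame(dimension = dims[lows[pb]], birth = vals[lows[pb]],
                      death = vals[pb])
  ess <- setdiff(which(lows == 0L), lows[pb])
  pairs <- rbind(pairs, data.frame(dimension = dims[ess], birth = vals[ess],
                                   death = rep(Inf, length(ess))))
  pairs[order(pairs$dimension, pairs$birth, pairs$death), , drop = FALSE]
}

# 0-dim sublevel persistence oracle: recompute connected components of
# {x <= alpha} on the path graph at every threshold, track component births
# (value + leftmost birth node), kill the younger at each merge.
naive_sls_pairs <- function(x) {
  alphas <- sort(unique(x))
  n <- length(x)
  comp_id <- rep(NA_integer_, n)
  births <- numeric(0)
  birth_at <- integer(0)
  pb <- numeric(0); pd <- numeric(0)
  for (a in alphas) {
    active <- x <= a
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    new_id <- rep(NA_integer_, n)
    for (s in which(r$values)) {
      idx <- starts[s]:ends[s]
      olds <- unique(comp_id[idx])
      olds <- olds[!is.na(olds)]
      if (length(olds) == 0L) {
        births <- c(births, a)
        birth_at <- c(birth_at, min(idx))
        new_id[idx] <- length(births)
      } else if (length(olds) == 1L) {
        new_id[idx] <- olds
      } else {
        o <- olds[order(births[olds], birth_at[olds])]
        for (y in o[-1L]) { pb <- c(pb, births[y]); pd <- c(pd, a) }
        new_id[idx] <- o[1L]
      }
    }
    comp_id <- new_id
  }
  keep <- pd > pb
  pr <- data.frame(birth = pb[keep], death = pd[keep])
  list(pairs = pr[order(pr$birth, pr$death), , drop = FALSE],
       essential_birth = min(x))
}

# sorted finite/infinite pair comparison helper
expect_same_pairs <- function(got, want, tol = 1e-10) {
  got <- got[order(got$dimension, got$birth, got$death), , drop = FALSE]
  want <- want[order(want$dimension, want$birth, want$death), , drop = FALSE]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$dimension, want$dimension)
  expect_equal(got$birth, want$birth, tolerance = tol)
  expect_equal(is.infinite(got$death), is.infinite(want$death))
  fin <- is.finite(want$death)
  expect_equal(got$death[fin], want$death[fin], tolerance = tol)
}
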