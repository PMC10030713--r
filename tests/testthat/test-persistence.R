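test_that("VR filtration contains exactly the simplices below the scale", {
  # three collinear points at 0, 1, 2 with max_scale 1: edges (1,2),(2,3)
  f <- build_vr_filtration(matrix(c(0, 1, 2), ncol = 1), max_scale = 1)
  expect_identical(sum(f$dims == 1L), 2L)
  expect_identical(sum(f$dims == 2L), 0L)
  edge_sets <- f$verts[f$dims == 1L]
  expect_true(all(vapply(edge_sets, function(v)
    identical(as.numeric(v), c(1, 2)) || identical(as.numeric(v), c(2, 3)),
    logical(1))))
  # unit square at sqrt(2): 4 vertices, 6 edges, 4 triangles
  f2 <- build_vr_filtration(unit_square(), max_scale = sqrt(2))
  expect_identical(as.integer(table(f2$dims)), c(4L, 6L, 4L))
  # max_scale 0: vertices only
  f0 <- build_vr_filtration(unit_square(), max_scale = 0)
  expect_identical(length(f0$values), 4L)
  # face-ordering invariant: values nondecreasing, faces precede cofaces
  expect_true(!is.unsorted(f2$values))
})

test_that("boundary reduction matches the hand-reduced filled triangle", {
  tri <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), ncol = 2, byrow = TRUE)
  pr <- reduce_boundary_matrix(build_vr_filtration(tri))
  h0 <- pr[pr$dimension == 0L, ]
  expect_identical(nrow(h0), 3L)
  expect_identical(sum(is.infinite(h0$death)), 1L)
  expect_equal(h0$death[is.finite(h0$death)], c(1, 1), tolerance = 1e-12)
  h1 <- pr[pr$dimension == 1L, ]
  expect_identical(nrow(h1), 1L)
  expect_true(h1$zero)  # loop filled the instant it is born
  # vertices-only filtration: n essential H0 classes, nothing else
  v <- reduce_boundary_matrix(build_vr_filtration(unit_square(),
                                                  max_scale = 0))
  expect_identical(nrow(v), 4L)
  expect_true(all(is.infinite(v$death)))
})

test_that("implementation matches the brute-force oracle on random clouds", {
  set.seed(101)
  for (i in 1:60) {
    pts <- random_cloud(sample(2:8, 1), d = sample(2:3, 1))
    want <- naive_vr_pairs(pts)
    f <- build_vr_filtration(pts)
    expect_same_pairs(reduce_boundary_matrix(f)[, 1:3], want)
    got <- vr_persistence(pts)  # reports dimensions 0-1 only
    expect_same_pairs(as.data.frame(got),
                      want[want$death > want$birth & want$dimension <= 1L, ,
                           drop = FALSE])
  }
})

test_that("H0 via MST equals reduction and Kruskal edge weights", {
  expect_identical(nrow(h0_via_mst(matrix(0, 1, 1))), 1L)
  line <- h0_via_mst(matrix(c(0, 1, 3), ncol = 1))
  expect_equal(line$death, c(1, 2, Inf))
  set.seed(33)
  for (i in 1:20) {
    pts <- random_cloud(sample(3:30, 1))
    deaths <- h0_via_mst(pts)$death
    g <- igraph::graph_from_adjacency_matrix(as.matrix(dist(pts)),
                                             weighted = TRUE,
                                             mode = "undirected")
    kruskal <- sort(igraph::E(igraph::mst(g))$weight)
    expect_equal(deaths[is.finite(deaths)], kruskal, tolerance = 1e-10)
  }
  # MST fast path agrees with full reduction H0
  for (i in 1:10) {
    pts <- random_cloud(sample(3:8, 1))
    red <- reduce_boundary_matrix(build_vr_filtration(pts))
    h0_red <- red[red$dimension == 0L & !red$zero, ]
    h0_mst <- h0_via_mst(pts)
    expect_equal(sort(h0_mst$death[is.finite(h0_mst$death)]),
                 sort(h0_red$death[is.finite(h0_red$death)]),
                 tolerance = 1e-10)
  }
})

test_that("VR diagrams satisfy the structural invariants", {
  sq <- unit_square()
  dg <- vr_persistence(sq)
  h1 <- dg[dg$dimension == 1L, ]
  expect_identical(nrow(h1), 1L)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))
  # Betti at scale 0 = point count; one essential bar for connected clouds
  set.seed(55)
  for (i in 1:10) {
    pts <- random_cloud(sample(2:15, 1))
    dgi <- vr_persistence(pts)  # default max_scale = diameter
    expect_identical(betti_number(dgi, 0, 0L), nrow(pts))
    expect_identical(sum(is.infinite(dgi$death[dgi$dimension == 0L])), 1L)
  }
  # Betti step function matches component counts at intermediate scales
  for (i in 1:8) {
    pts <- random_cloud(sample(3:8, 1))
    dgi <- vr_persistence(pts)
    d <- as.matrix(dist(pts))
    for (s in quantile(d[lower.tri(d)], c(0.25, 0.5, 0.75))) {
      adj <- (d <= s) * 1
      diag(adj) <- 0
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      expect_equal(betti_number(dgi, s, 0L),
                   as.integer(igraph::components(g)$no))
    }
  }
  # homogeneity: scaling coordinates scales all finite endpoints
  pts <- random_cloud(7)
  a <- 2.5
  d1 <- as.data.frame(vr_persistence(pts))
  d2 <- as.data.frame(vr_persistence(pts * a))
  expect_equal(d2$birth, a * d1$birth, tolerance = 1e-10)
  fin <- is.finite(d1$death)
  expect_equal(d2$death[fin], a * d1$death[fin], tolerance = 1e-10)
  # circle: a single dominant loop
  th <- 2 * pi * (0:11) / 12
  circ <- cbind(cos(th), sin(th))
  dgc <- vr_persistence(circ)
  h1c <- dgc[dgc$dimension == 1L, ]
  pers <- h1c$death - h1c$birth
  expect_identical(sum(pers == max(pers)), 1L)
  if (nrow(h1c) > 1L)
    expect_gt(max(pers), 10 * max(pers[-which.max(pers)]))
})

test_that("sublevel-set persistence matches the elder rule", {
  dg <- sls_persistence(c(2, 0, 1, -1, 3))
  expect_same_pairs(as.data.frame(dg),
                    data.frame(dimension = c(0L, 0L), birth = c(-1, 0),
                               death = c(Inf, 1)))
  inc <- sls_persistence(1:10)
  expect_identical(nrow(inc), 1L)
  expect_equal(inc$birth, 1)
  expect_true(is.infinite(inc$death))
  expect_error(sls_persistence(numeric(0)), "empty")
  expect_error(sls_persistence(c(1, NA, 2)), "finite")
})

test_that("sublevel persistence matches a brute-force union-find sweep", {
  set.seed(202)
  for (i in 1:120) {
    n <- sample(1:50, 1)
    x <- if (i %% 3 == 0) sample(round(rnorm(n), 1)) else rnorm(n)
    got <- sls_persistence(x)
    want <- naive_sls_pairs(x)
    expect_identical(sum(is.infinite(got$death)), 1L)
    expect_equal(got$birth[is.infinite(got$death)], want$essential_birth)
    gfin <- got[is.finite(got$death), ]
    expect_equal(nrow(gfin), nrow(want$pairs))
    o <- order(gfin$birth, gfin$death)
    expect_equal(gfin$birth[o], want$pairs$birth, tolerance = 1e-12)
    expect_equal(gfin$death[o], want$pairs$death, tolerance = 1e-12)
  }
  # duality sanity: the essential bar of -x is born at -max(x)
  x <- rnorm(40)
  neg <- sls_persistence(-x)
  expect_equal(neg$birth[is.infinite(neg$death)], -max(x))
})

test_that("diagram CSV round-trips including infinite deaths", {
  dg <- sls_persistence(c(2, 0, 1, -1, 3, 0.5, 2.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagram(dg, path)
  back <- read_diagram(path)
  expect_same_pairs(as.data.frame(back), as.data.frame(dg), tol = 1e-15)
  expect_identical(attr(back, "source"), "sls")
})
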