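test_that("standardize gives unit-variance columns and handles degeneracy", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  z <- standardize(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(apply(z, 2, stats::sd), c(a = 1, b = 1))
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_warning(z2 <- standardize(cbind(a = c(5, 5, 5), b = 1:3)), "constant")
  expect_equal(unname(z2[, "a"]), c(0, 0, 0))
  expect_equal(standardize(z), z)   # idempotent
  expect_error(standardize(m[1, , drop = FALSE]), ">= 2 rows")
})

test_that("distance_matrix is the Euclidean metric", {
  m <- rbind(c(0, 0, 0), c(3, 4, 0))
  d <- distance_matrix(m)
  expect_equal(unname(d), matrix(c(0, 5, 5, 0), 2))
  m2 <- rbind(c(1, 2), c(1, 2))
  expect_equal(distance_matrix(m2)[1, 2], 0)
  withr::local_seed(4)
  pts <- matrix(stats::rnorm(60), ncol = 3)
  d <- distance_matrix(pts)
  for (i in 1:20) for (j in 1:20) {
    expect_equal(d[i, j], sqrt(sum((pts[i, ] - pts[j, ])^2)))
  }
})

test_that("filter kinds behave as specified", {
  # 3 collinear equally spaced points: middle point least eccentric
  d <- distance_matrix(cbind(c(0, 1, 2)))
  expect_equal(filter_values(d, "eccentricity"), c(1, 2 / 3, 1))
  m <- cbind(support = c(0.1, 0.3, 0.2), confidence = c(0.5, 0.6, 0.9),
             lift = c(1, 2, 3))
  expect_equal(filter_values(d, "coordinate", matrix = m, coord = 1),
               c(0.1, 0.3, 0.2))
  expect_error(filter_values(d, "coordinate", matrix = m, coord = 9),
               "out of range")
  # max-variance projection of collinear points recovers their spacing
  pts <- cbind(1:5, 2 * (1:5), -(1:5))
  proj <- filter_values(distance_matrix(pts), "max_variance_projection",
                        matrix = pts)
  expect_equal(diff(abs(diff(proj))), rep(0, 3))
  # filter values are equivariant under point reordering
  perm <- c(3, 1, 2)
  expect_equal(filter_values(distance_matrix(m[perm, ]), "eccentricity"),
               filter_values(distance_matrix(m), "eccentricity")[perm])
})

test_that("build_cover produces the stated interval arithmetic", {
  cov0 <- build_cover(c(0, 10), n_intervals = 5, overlap = 0)
  expect_equal(unname(cov0$intervals[, "lo"]), c(0, 2, 4, 6, 8))
  expect_equal(unname(cov0$intervals[, "hi"]), c(2, 4, 6, 8, 10))
  cov5 <- build_cover(c(0, 10), n_intervals = 5, overlap = 0.5)
  L <- 10 / 3
  expect_equal(unname(cov5$intervals[, "lo"]),
               c(0, 5 / 3, 10 / 3, 5, 20 / 3))
  expect_equal(unname(cov5$intervals[, "hi"] - cov5$intervals[, "lo"]),
               rep(L, 5))
  expect_equal(unname(cov5$intervals[5, "hi"]), 10)
  expect_error(build_cover(c(0, 1), 5, overlap = 1), "\\[0, 1\\)")
  # constant filter values: one interval covering the value
  covc <- build_cover(rep(2, 4), 5, 0.5)
  expect_equal(covc$n_intervals, 1L)
  expect_equal(cover_preimages(rep(2, 4), covc)[[1]], 1:4)
})

test_that("every filter value lands in at least one interval", {
  withr::local_seed(12)
  for (i in 1:200) {
    fvals <- stats::runif(sample(2:40, 1), min = -50, max = 50)
    ov <- stats::runif(1, 0, 0.9)
    cov <- build_cover(fvals, sample(1:20, 1), ov)
    pre <- cover_preimages(fvals, cov)
    hit <- sort(unique(unlist(pre)))
    expect_equal(hit, seq_along(fvals))
    # a point can lie in at most ceil(1 / (1 - overlap)) intervals; for
    # overlap <= 1/2 that means at most two
    counts <- table(unlist(pre))
    expect_true(all(counts <= max(2, ceiling(1 / (1 - ov)))))
    if (ov <= 0.5) expect_true(all(counts <= 2))
  }
})

test_that("histogram-gap single linkage separates gapped 1-D clusters", {
  pos <- c(0, 0.1, 0.2, 5.0, 5.1)
  d <- distance_matrix(cbind(pos))
  cl <- cluster_preimage(seq_along(pos), d, num_bins = 10)
  cl <- cl[order(vapply(cl, min, integer(1)))]
  expect_equal(cl, list(1:3, 4:5))
  expect_equal(cluster_preimage(3L, d), list(3L))
  # equidistant points: no gap, one cluster
  simplex <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(cluster_preimage(1:3, distance_matrix(simplex)), list(1:3))
})

test_that("build_nerve links clusters sharing members across intervals", {
  g <- build_nerve(list(list(c(1L, 2L, 3L)), list(c(3L, 4L))))
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(g$edges$shared_count, 1L)
  g2 <- build_nerve(list(list(c(1L, 2L)), list(c(3L, 4L))))
  expect_equal(nrow(g2$edges), 0L)
  # same-interval clusters are never joined even though disjointness is
  # guaranteed by the partition property
  g3 <- build_nerve(list(list(c(1L, 2L), c(3L, 4L))))
  expect_equal(nrow(g3$edges), 0L)
})

test_that("a 1-D segment yields a connected, acyclic Mapper graph", {
  s <- seq(0, 10, length.out = 200)
  pts <- cbind(support = s / 3, confidence = 2 * s / 3, lift = 2 * s / 3)
  g <- run_mapper(pts, mapper_config(filter = "coordinate", coord = 1,
                                     n_intervals = 5, overlap = 0.5))
  comp <- mapper_components(g)
  expect_equal(length(unique(comp$component)), 1L)
  expect_equal(nrow(g$edges), nrow(g$nodes) - 1L)
  # every point belongs to exactly one cluster within each interval
  members <- split(g$nodes$members, g$nodes$interval_index)
  for (iv in members) {
    flat <- unlist(iv)
    expect_equal(anyDuplicated(flat), 0L)
  }
})

test_that("two well-separated blobs give two components, stably", {
  withr::local_seed(6)
  blob <- function(center, n = 30, spread = 0.1) {
    sweep(matrix(stats::rnorm(3 * n, sd = spread), ncol = 3), 2, center, `+`)
  }
  pts <- rbind(blob(c(0, 0, 0)), blob(c(10, 10, 10)))
  colnames(pts) <- c("support", "confidence", "lift")
  g <- run_mapper(pts, mapper_config())
  comp <- mapper_components(g)
  got <- lapply(split(g$nodes$members, comp$component),
                function(ms) sort(unique(as.integer(unlist(ms)))))
  expect_equal(length(got), 2L)
  expect_true(setequal(got[[1]], 1:30) || setequal(got[[1]], 31:60))
  # ±1% multiplicative perturbation leaves the component count unchanged
  pert <- pts * (1 + stats::runif(length(pts), -0.01, 0.01))
  g2 <- run_mapper(pert, mapper_config())
  expect_equal(length(unique(mapper_components(g2)$component)), 2L)
})

test_that("zero overlap with trivial clustering is the interval partition", {
  withr::local_seed(15)
  pts <- matrix(stats::rnorm(90), ncol = 3,
                dimnames = list(NULL, c("support", "confidence", "lift")))
  g <- run_mapper(pts, mapper_config(n_intervals = 4, overlap = 0,
                                     clusterer = "none"))
  expect_equal(nrow(g$edges), 0L)
  flat <- unlist(g$nodes$members)
  expect_equal(sort(as.integer(flat)), 1:30)
})

test_that("run_mapper is deterministic and handles a degenerate cloud", {
  pts <- matrix(rep(c(0.2, 0.6, 1.4), each = 10), ncol = 3,
                dimnames = list(NULL, c("support", "confidence", "lift")))
  w <- capture_warnings(g <- run_mapper(pts, mapper_config()))
  expect_true(any(grepl("constant", w)))
  expect_true(all(g$nodes$size == 10L))
  expect_equal(length(unique(mapper_components(g)$component)), 1L)
  withr::local_seed(21)
  pts2 <- matrix(stats::rnorm(120), ncol = 3,
                 dimnames = list(NULL, c("support", "confidence", "lift")))
  g1 <- run_mapper(pts2, mapper_config())
  g2 <- run_mapper(pts2, mapper_config())
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)
})

test_that("nerve metadata and exports are consistent", {
  withr::local_seed(33)
  m <- random_item_matrix(200, 8, p = 0.35)
  rules <- mine_rules(m, rule_filter(5, 0))
  im <- rule_index_matrix(rules)
  g <- run_mapper(im, mapper_config(n_intervals = 4, overlap = 0.4))
  # node means recompute from members; edge shared counts from intersections
  for (i in seq_len(nrow(g$nodes))) {
    ms <- g$nodes$members[[i]]
    expect_equal(g$nodes$size[i], length(ms))
    expect_equal(g$nodes$mean_support[i], mean(im[ms, "support"]))
    expect_equal(g$nodes$mean_lift[i], mean(im[ms, "lift"]))
  }
  by_id <- stats::setNames(g$nodes$members, g$nodes$node_id)
  iv <- stats::setNames(g$nodes$interval_index, g$nodes$node_id)
  for (k in seq_len(nrow(g$edges))) {
    e <- g$edges[k, ]
    expect_equal(e$shared_count,
                 length(intersect(by_id[[e$from]], by_id[[e$to]])))
    expect_true(iv[[e$from]] != iv[[e$to]])
  }
  td <- withr::local_tempdir()
  write_mapper_graphml(g, file.path(td, "g.graphml"))
  write_mapper_dot(g, file.path(td, "g.dot"))
  write_mapper_membership(g, file.path(td, "g.csv"))
  back <- igraph::read_graph(file.path(td, "g.graphml"), format = "graphml")
  expect_equal(igraph::vcount(back), nrow(g$nodes))
  expect_equal(igraph::ecount(back), nrow(g$edges))
  expect_equal(sort(igraph::V(back)$mean_support), sort(g$nodes$mean_support))
  memb <- utils::read.csv(file.path(td, "g.csv"))
  expect_equal(nrow(memb), sum(g$nodes$size))
})
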