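#' Assemble the rule-index matrix fed to Mapper
#'
#' Mapper operates on each rule as a point in the 3-dimensional index
#' space (support, confidence, lift). Rule ids are stable, human-readable
#' identifiers `"X->Y"` used to track which rules each graph node
#' contains.
#'
#' @param rules Rule tibble from [mine_rules()].
#' @return A numeric matrix with one row per rule, columns `support`,
#'   `confidence`, `lift`, and rownames the rule ids.
#' @export
rule_index_matrix <- function(rules) {
  m <- cbind(support = rules$support, confidence = rules$confidence,
             lift = rules$lift)
  rownames(m) <- paste0(rules$x_code, "->", rules$y_code)
  m
}

#' Column-wise z-score standardization
#'
#' The three rule indices live on different scales (fractions for support
#' and confidence, a ratio around 1 for lift), so Euclidean distances on
#' the raw values would be dominated by whichever column has the largest
#' spread. Standardization gives each column mean 0 and sample SD 1. A
#' constant column carries no metric information and is mapped to all
#' zeros with a warning.
#'
#' @param matrix Numeric matrix with >= 2 rows.
#' @return Matrix of the same shape, columns standardized.
#' @export
standardize <- function(matrix) {
  if (nrow(matrix) < 2L) stop("standardization needs >= 2 rows", call. = FALSE)
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    s <- stats::sd(matrix[, j])
    if (s == 0) {
      warning("column ", colnames(matrix)[j] %||% j,
              " is constant; standardized to zeros", call. = FALSE)
      out[, j] <- 0
    } else {
      out[, j] <- (matrix[, j] - mean(matrix[, j])) / s
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise Euclidean distance matrix
#'
#' @param matrix Numeric matrix, one point per row (standardize first when
#'   mixing scales).
#' @return A dense symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(matrix) {
  if (nrow(matrix) < 2L) stop("need >= 2 points", call. = FALSE)
  as.matrix(stats::dist(matrix, method = "euclidean"))
}

#' Filter (lens) values for the Mapper cover
#'
#' Maps every point to one real number, along which the overlapping cover
#' is built. Three filters are provided:
#'
#' * `"eccentricity"` (default): the mean distance from each point to all
#'   points — central points score low, outlying points high;
#' * `"coordinate"`: column `coord` of the (standardized) index matrix;
#' * `"max_variance_projection"`: projection onto the first principal
#'   direction of the index matrix.
#'
#' @param dist Distance matrix from [distance_matrix()] (used by
#'   eccentricity).
#' @param kind Filter kind.
#' @param matrix Index matrix (required for `coordinate` and
#'   `max_variance_projection`).
#' @param coord Column index for the coordinate filter (1 = support,
#'   2 = confidence, 3 = lift when the matrix comes from
#'   [rule_index_matrix()]).
#' @return Numeric vector, one filter value per point.
#' @export
filter_values <- function(dist, kind = c("eccentricity", "coordinate",
                                         "max_variance_projection"),
                          matrix = NULL, coord = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    eccentricity = unname(rowMeans(dist)),
    coordinate = {
      if (is.null(matrix)) stop("coordinate filter needs the index matrix", call. = FALSE)
      if (coord < 1L || coord > ncol(matrix)) {
        stop("coordinate index ", coord, " out of range 1..", ncol(matrix),
             call. = FALSE)
      }
      unname(matrix[, coord])
    },
    max_variance_projection = {
      if (is.null(matrix)) stop("projection filter needs the index matrix", call. = FALSE)
      pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
      unname(pc$x[, 1])
    }
  )
}

#' Build an overlapping interval cover of the filter range
#'
#' Covers the filter range `[min, max]` with `n_intervals` intervals of
#' equal length `L = R / (n_intervals - (n_intervals - 1) * overlap)`
#' where `R = max - min`; interval i starts at
#' `min + (i - 1) * L * (1 - overlap)`, so consecutive intervals share
#' exactly the fraction `overlap` of their length. Interval membership is
#' half-open on the right (the last interval is closed), so with zero
#' overlap the cover is an exact partition and with positive overlap every
#' interior point lies in at most two intervals.
#'
#' Constant filter values are covered by a single unit-length interval
#' centred on the value.
#'
#' @param fvals Numeric vector of filter values.
#' @param n_intervals Number of intervals (>= 1).
#' @param overlap Overlap fraction in `[0, 1)`.
#' @return An object of class `mapper_cover`: list with `intervals`
#'   (n x 2 matrix of lo/hi), `overlap`, `n_intervals`.
#' @export
build_cover <- function(fvals, n_intervals = 5L, overlap = 0.5) {
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L) stop("n_intervals must be >= 1", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)", call. = FALSE)
  lo <- min(fvals); hi <- max(fvals)
  if (hi == lo) {
    intervals <- matrix(c(lo - 0.5, lo + 0.5), ncol = 2)
  } else {
    L <- (hi - lo) / (n_intervals - (n_intervals - 1) * overlap)
    starts <- lo + (seq_len(n_intervals) - 1L) * L * (1 - overlap)
    intervals <- cbind(starts, starts + L)
    # the last interval analytically ends at the range maximum; guard the
    # rounding of lo + (n-1)*stride + L so the maximum is always covered
    intervals[n_intervals, 2] <- max(intervals[n_intervals, 2], hi)
  }
  colnames(intervals) <- c("lo", "hi")
  structure(list(intervals = intervals, overlap = overlap,
                 n_intervals = nrow(intervals)),
            class = "mapper_cover")
}

#' Assign points to the intervals of a cover
#'
#' @param fvals Filter values.
#' @param cover A [build_cover()] result.
#' @return List of integer index vectors, one per interval (points whose
#'   filter value falls in the interval).
#' @export
cover_preimages <- function(fvals, cover) {
  n <- cover$n_intervals
  lapply(seq_len(n), function(i) {
    lo <- cover$intervals[i, "lo"]; hi <- cover$intervals[i, "hi"]
    if (i == n) which(fvals >= lo & fvals <= hi)
    else which(fvals >= lo & fvals < hi)
  })
}

#' Cluster an interval preimage by single linkage with a histogram-gap cut
#'
#' Builds the single-linkage dendrogram of the member points and chooses
#' the cut threshold at the left edge of the first empty bin of a
#' `num_bins`-bin histogram of the merge distances — the classical Mapper
#' clustering heuristic: a gap in the merge-distance distribution
#' separates within-cluster from between-cluster linkage. With no empty
#' bin (or fewer than two distinct merge distances) all members form one
#' cluster; a singleton input is its own cluster.
#'
#' @param member_ids Integer indices of the points in the interval.
#' @param dist Full distance matrix.
#' @param num_bins Number of histogram bins (default 10).
#' @return List of integer vectors partitioning `member_ids`.
#' @export
cluster_preimage <- function(member_ids, dist, num_bins = 10L) {
  if (length(member_ids) == 0L) stop("empty preimage", call. = FALSE)
  if (length(member_ids) == 1L) return(list(member_ids))
  sub <- dist[member_ids, member_ids, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(sub), method = "single")
  h <- hc$height
  cut_h <- Inf
  # a height range at rounding-noise scale carries no gap information
  spread <- max(h) - min(h) > 1e-9 * max(abs(h), 1)
  if (spread) {
    breaks <- seq(min(h), max(h), length.out = num_bins + 1L)
    counts <- graphics::hist(h, breaks = breaks, plot = FALSE)$counts
    gap <- which(counts == 0L)
    if (length(gap) > 0L) cut_h <- breaks[gap[1]]
  }
  grp <- if (is.finite(cut_h)) stats::cutree(hc, h = cut_h) else rep(1L, length(member_ids))
  unname(split(member_ids, grp))
}

#' Build the nerve graph of the clustered cover
#'
#' One node per cluster; an edge joins two clusters from different
#' intervals whenever they share at least one point, weighted by the
#' intersection size. Clusters within the same interval partition the
#' preimage and are never joined. Node metadata records the interval
#' index, cluster size and the mean of each index column over members,
#' for coloring graph drawings by rule strength.
#'
#' @param clusters_by_interval List (per interval) of lists of integer
#'   member vectors, as produced by [cluster_preimage()] over
#'   [cover_preimages()].
#' @param matrix Index matrix providing per-point metadata (optional).
#' @param rule_ids Character ids of the points (default rownames of
#'   `matrix`, else point indices).
#' @return An object of class `mapper_graph`: list with tibbles `nodes`
#'   (`node_id`, `interval_index`, `size`, `mean_support`,
#'   `mean_confidence`, `mean_lift`, list-column `members`) and `edges`
#'   (`from`, `to`, `shared_count`).
#' @export
build_nerve <- function(clusters_by_interval, matrix = NULL, rule_ids = NULL) {
  flat <- list(); interval_of <- integer()
  for (i in seq_along(clusters_by_interval)) {
    for (cl in clusters_by_interval[[i]]) {
      flat[[length(flat) + 1L]] <- sort(cl)
      interval_of <- c(interval_of, i)
    }
  }
  n_nodes <- length(flat)
  if (!is.null(matrix) && is.null(rule_ids)) rule_ids <- rownames(matrix)
  node_mean <- function(col) {
    if (is.null(matrix) || !col %in% colnames(matrix)) return(rep(NA_real_, n_nodes))
    vapply(flat, function(m) mean(matrix[m, col]), double(1))
  }
  members_chr <- lapply(flat, function(m) {
    if (is.null(rule_ids)) as.character(m) else rule_ids[m]
  })
  nodes <- tibble::tibble(
    node_id = sprintf("n%02d_%02d", interval_of,
                      as.integer(stats::ave(interval_of, interval_of,
                                            FUN = seq_along))),
    interval_index = interval_of,
    size = vapply(flat, length, integer(1)),
    mean_support = node_mean("support"),
    mean_confidence = node_mean("confidence"),
    mean_lift = node_mean("lift"),
    members = members_chr
  )
  from <- character(); to <- character(); shared <- integer()
  if (n_nodes >= 2L) {
    for (i in seq_len(n_nodes - 1L)) {
      for (j in seq(i + 1L, n_nodes)) {
        if (interval_of[i] == interval_of[j]) next
        s <- length(intersect(flat[[i]], flat[[j]]))
        if (s > 0L) {
          from <- c(from, nodes$node_id[i]); to <- c(to, nodes$node_id[j])
          shared <- c(shared, s)
        }
      }
    }
  }
  structure(list(nodes = nodes,
                 edges = tibble::tibble(from = from, to = to,
                                        shared_count = shared)),
            class = "mapper_graph")
}

#' Configure a Mapper run
#'
#' @param filter Filter kind (see [filter_values()]); default
#'   eccentricity.
#' @param coord Coordinate index for the coordinate filter.
#' @param n_intervals,overlap Cover parameters; defaults 5 intervals with
#'   50% overlap.
#' @param num_bins Histogram bins for the clustering cut (default 10).
#' @param standardize Z-score the index columns before distances (default
#'   `TRUE`).
#' @param clusterer `"single_gap"` (default) for single linkage with the
#'   histogram-gap cut, or `"none"` to treat each interval preimage as one
#'   cluster.
#' @return An object of class `mapper_config`.
#' @export
mapper_config <- function(filter = c("eccentricity", "coordinate",
                                     "max_variance_projection"),
                          coord = 1L, n_intervals = 5L, overlap = 0.5,
                          num_bins = 10L, standardize = TRUE,
                          clusterer = c("single_gap", "none")) {
  structure(list(filter = match.arg(filter), coord = as.integer(coord),
                 n_intervals = as.integer(n_intervals), overlap = overlap,
                 num_bins = as.integer(num_bins),
                 standardize = isTRUE(standardize),
                 clusterer = match.arg(clusterer)),
            class = "mapper_config")
}

#' Run the full Mapper chain on an index matrix
#'
#' Composes standardization, the distance matrix, the filter, the
#' overlapping cover, per-interval clustering and the nerve. The chain is
#' fully deterministic: identical input and config always yield the
#' identical graph.
#'
#' @param matrix Numeric index matrix, one point (rule) per row.
#' @param config A [mapper_config()].
#' @return A `mapper_graph` (see [build_nerve()]); its attributes
#'   `fvals` and `cover` expose the intermediate filter values and cover.
#' @export
run_mapper <- function(matrix, config = mapper_config()) {
  stopifnot(inherits(config, "mapper_config"))
  if (nrow(matrix) < 2L) stop("Mapper needs >= 2 points", call. = FALSE)
  vals <- if (config$standardize) standardize(matrix) else matrix
  dist <- distance_matrix(vals)
  fvals <- filter_values(dist, config$filter, matrix = vals,
                         coord = config$coord)
  cover <- build_cover(fvals, config$n_intervals, config$overlap)
  preimages <- cover_preimages(fvals, cover)
  clusters <- lapply(preimages, function(members) {
    if (length(members) == 0L) return(list())
    if (config$clusterer == "none") return(list(members))
    cluster_preimage(members, dist, config$num_bins)
  })
  graph <- build_nerve(clusters, matrix = matrix)
  attr(graph, "fvals") <- fvals
  attr(graph, "cover") <- cover
  graph
}

#' Connected components of a Mapper graph
#'
#' Component labels are deterministic presentation labels (`"A"`, `"B"`,
#' ...) ordered by descending total member count, ties broken by the
#' lexicographically smallest member rule id.
#'
#' @param graph A `mapper_graph`.
#' @return A tibble with columns `node_id` and `component`.
#' @export
mapper_components <- function(graph) {
  g <- as_igraph(graph)
  comp <- igraph::components(g)$membership
  nodes <- graph$nodes
  node_comp <- comp[nodes$node_id]
  sizes <- vapply(split(nodes$size, node_comp), sum, double(1))
  min_member <- vapply(split(nodes$members, node_comp),
                       function(ms) min(unlist(ms)), character(1))
  ranked <- names(sizes)[order(-sizes, min_member)]
  labels <- stats::setNames(make.unique(rep(LETTERS, length.out = length(ranked))),
                            ranked)
  tibble::tibble(node_id = nodes$node_id,
                 component = unname(labels[as.character(node_comp)]))
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat("Mapper graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      length(unique(mapper_components(x)$component)), "connected component(s)\n")
  invisible(x)
}
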