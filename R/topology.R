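#' Per-node topology metrics
#'
#' Standard topology metrics on the underlying (undirected, simplified)
#' graph, with directed in-/out-degree variants taken from the directed
#' network itself. `stress` counts the geodesics passing through a node
#' (summed over unordered pairs of distinct endpoints);
#' `multi_edge_partner_count` counts neighbors connected by more than one
#' directed edge (e.g. reciprocal pairs); `neighborhood_connectivity` is the
#' mean degree of a node's neighbors. Local clustering coefficients of
#' degree-0/1 nodes are reported as 0 so all values stay finite.
#'
#' @param net Directed igraph network (weakly connected).
#' @return data.frame with one row per node.
#' @export
topology_metrics <- function(net) {
  und <- igraph::as_undirected(net, mode = "collapse")
  und <- igraph::simplify(und)
  nodes <- igraph::V(und)$name
  deg <- igraph::degree(und)
  cc <- igraph::transitivity(und, type = "local", isolates = "zero")
  d <- igraph::distances(und)
  finite_d <- d
  finite_d[!is.finite(finite_d)] <- NA
  aspl <- vapply(seq_len(nrow(d)), function(i) {
    vals <- finite_d[i, -i]
    if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
  }, numeric(1L))
  ecc <- vapply(seq_len(nrow(d)), function(i) {
    vals <- finite_d[i, -i]
    if (all(is.na(vals))) 0 else max(vals, na.rm = TRUE)
  }, numeric(1L))
  nbc <- vapply(seq_along(nodes), function(i) {
    nb <- igraph::neighbors(und, i)
    if (length(nb) == 0L) 0 else mean(deg[nb])
  }, numeric(1L))
  # stress: number of shortest paths through each node, per unordered pair
  stress <- setNames(numeric(length(nodes)), nodes)
  for (s in seq_along(nodes)) {
    asp <- igraph::all_shortest_paths(und, from = s, to = igraph::V(und))$res
    for (p in asp) {
      if (length(p) > 2L) {
        interior <- igraph::as_ids(p)[-c(1L, length(p))]
        stress[interior] <- stress[interior] + 1
      }
    }
  }
  stress <- stress / 2
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  adj <- adj[nodes, nodes, drop = FALSE]
  both <- adj + t(adj)
  diag(both) <- 0
  multi <- as.integer(rowSums(both > 1))
  data.frame(
    node = nodes,
    in_degree = unname(igraph::degree(net, v = nodes, mode = "in")),
    out_degree = unname(igraph::degree(net, v = nodes, mode = "out")),
    degree = unname(deg),
    betweenness = unname(igraph::betweenness(und)),
    closeness = unname(suppressWarnings(igraph::closeness(und))),
    clustering_coefficient = unname(cc),
    eccentricity = unname(ecc),
    stress = unname(stress),
    avg_shortest_path_length = unname(aspl),
    neighborhood_connectivity = unname(nbc),
    multi_edge_partner_count = unname(multi),
    stringsAsFactors = FALSE
  )
}

#' Compare a metric between two node classes (Mann-Whitney U)
#'
#' Two-sided Wilcoxon rank-sum test: exact enumeration when both groups have
#' at most 10 members and no ties, tie-corrected normal approximation
#' otherwise.
#'
#' @param metrics data.frame with a `node` column and metric columns (e.g.
#'   from [topology_metrics()]).
#' @param labels Named vector mapping node to class label.
#' @param metric_name Column of `metrics` to compare.
#' @param class_a,class_b Class labels to compare.
#' @return List with `U` (statistic for `class_a`) and `p_value`.
#' @export
compare_classes <- function(metrics, labels, metric_name, class_a, class_b) {
  stopifnot(metric_name %in% names(metrics))
  x <- metrics[[metric_name]][metrics$node %in% names(labels)[labels == class_a]]
  y <- metrics[[metric_name]][metrics$node %in% names(labels)[labels == class_b]]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both classes must be non-empty (",
         class_a, ": ", length(x), ", ", class_b, ": ", length(y), ")")
  }
  small <- length(x) <= 10L && length(y) <= 10L
  ties <- anyDuplicated(c(x, y)) > 0L
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = small && !ties, correct = !small || ties)
  )
  list(U = unname(res$statistic), p_value = min(1, unname(res$p.value)))
}
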