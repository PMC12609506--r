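#' Fold-change-based edge weights
#'
#' Assigns each edge the weight `W_ij = 1 / |log2FC_i * log2FC_j|` when both
#' endpoints are significantly regulated with non-zero fold change, so that
#' strongly co-regulated interactions become cheap to traverse. Edges with a
#' non-significant or missing endpoint get a penalty weight of
#' `na_penalty_factor` times the largest finite weight in the network:
#' traversable, but strongly discouraged. If no edge has two significant
#' endpoints, all edges get a constant weight (with a warning), reducing the
#' extraction to unweighted shortest paths.
#'
#' @param net Directed igraph network.
#' @param stats Gene statistics table.
#' @param na_penalty_factor Multiplier for the penalty weight (default 10).
#' @return `net` with a positive `weight` edge attribute.
#' @export
compute_edge_weights <- function(net, stats, na_penalty_factor = 10) {
  stopifnot(igraph::ecount(net) > 0L)
  edges <- igraph::as_data_frame(net, what = "edges")
  fc <- setNames(stats$log2fc, stats$gene)
  sig <- setNames(stats$significant, stats$gene)
  ok <- function(g) !is.na(sig[g]) & sig[g] & !is.na(fc[g]) & fc[g] != 0
  informative <- ok(edges$from) & ok(edges$to)
  w <- rep(NA_real_, nrow(edges))
  w[informative] <- 1 / abs(fc[edges$from[informative]] *
                              fc[edges$to[informative]])
  if (!any(informative)) {
    warning("no edge joins two significant genes; using constant weights")
    w[] <- 1
  } else {
    w[!informative] <- na_penalty_factor * max(w[informative])
  }
  igraph::set_edge_attr(net, "weight", value = unname(w))
}

# Lexicographically smallest minimum-weight path from `from` to `to`.
# d_from: distances from `from` to all nodes; d_to: distances from all nodes
# to `to` (mode "in"). Greedy: at each step take the smallest-named
# out-neighbor that stays on a shortest path.
lex_shortest_path <- function(net, from, to, weights, d_from, d_to,
                              tol = 1e-9) {
  total <- d_from[to]
  if (!is.finite(total)) return(NULL)
  path <- from
  cur <- from
  names_all <- igraph::V(net)$name
  while (cur != to) {
    inc <- igraph::incident(net, cur, mode = "out")
    h <- names_all[igraph::head_of(net, inc)]
    t2 <- names_all[igraph::tail_of(net, inc)]
    heads <- ifelse(h == cur, t2, h)  # undirected edges may store cur as head
    keep <- heads != cur              # ignore self-loops
    heads <- heads[keep]
    w <- weights[as.integer(inc)][keep]
    on_sp <- abs((total - d_to[cur]) + w + d_to[heads] - total) <=
      tol * max(1, abs(total))
    cand <- heads[on_sp]
    if (length(cand) == 0L) return(NULL) # numerically degenerate; give up
    nxt <- sort(cand)[1L]
    path <- c(path, nxt)
    cur <- nxt
  }
  path
}

#' Controllable subnetwork: cheapest paths from critical to indispensable
#'
#' For every ordered (source, sink) pair with `source` critical and `sink`
#' indispensable, finds one minimum-weight directed path (Dijkstra on the
#' fold-change edge weights; ties broken toward the lexicographically
#' smallest node sequence) and returns the union of all retained paths.
#' Unreachable pairs are recorded, not errors.
#'
#' @param weighted Directed igraph network with a `weight` edge attribute,
#'   from [compute_edge_weights()].
#' @param sources Character vector (typically the critical nodes).
#' @param sinks Character vector (typically the indispensable nodes).
#' @return List of class `tep_subnetwork`: `graph` (union of retained
#'   paths), `retained_paths` (list of node sequences), `pairs` (data.frame
#'   with source, sink, reachable flag, path weight).
#' @export
extract_controllable_subnetwork <- function(weighted, sources, sinks) {
  if (length(sources) == 0L || length(sinks) == 0L) {
    stop("source and sink sets must be non-empty")
  }
  stopifnot("weight" %in% igraph::edge_attr_names(weighted))
  w <- igraph::E(weighted)$weight
  stopifnot(all(w > 0))
  nodes <- igraph::V(weighted)$name
  sources <- intersect(sort(sources), nodes)
  sinks <- intersect(sort(sinks), nodes)
  d_to <- igraph::distances(weighted, v = nodes, to = sinks, mode = "out",
                            weights = w)
  paths <- list()
  pairs <- list()
  for (s in sources) {
    d_from <- igraph::distances(weighted, v = s, to = nodes, mode = "out",
                                weights = w)[1L, ]
    for (t in sinks) {
      if (s == t) next
      reachable <- is.finite(d_from[t])
      pairs[[length(pairs) + 1L]] <- data.frame(
        source = s, sink = t, reachable = reachable,
        weight = if (reachable) unname(d_from[t]) else NA_real_,
        stringsAsFactors = FALSE)
      if (!reachable) next
      p <- lex_shortest_path(weighted, s, t, w, d_from, d_to[, t])
      if (!is.null(p)) paths[[length(paths) + 1L]] <- p
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(source = character(0), sink = character(0),
               reachable = logical(0), weight = numeric(0))
  sub <- subgraph_from_paths(weighted, paths)
  structure(list(graph = sub, retained_paths = paths, pairs = pairs),
            class = "tep_subnetwork")
}

subgraph_from_paths <- function(net, paths) {
  if (length(paths) == 0L) {
    return(igraph::induced_subgraph(net, integer(0)))
  }
  eids <- unique(unlist(lapply(paths, function(p) {
    if (length(p) < 2L) return(integer(0))
    as.integer(igraph::get_edge_ids(net, rbind(p[-length(p)], p[-1L])))
  })))
  igraph::subgraph_from_edges(net, eids, delete.vertices = TRUE)
}

#' @export
print.tep_subnetwork <- function(x, ...) {
  cat("Subnetwork:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges from", length(x$retained_paths),
      "retained path(s);", sum(!x$pairs$reachable),
      "unreachable pair(s)\n")
  invisible(x)
}

#' Node weights: degree times absolute log2 fold change
#'
#' Significant genes get `degree * |log2FC|`; genes that are not
#' significantly regulated get `degree * nonsig_fc` (default 1e-6), which
#' rounds to 0 at the 2-decimal reporting precision used in result tables.
#'
#' @param net Directed or undirected igraph network, or a named numeric
#'   vector of node degrees.
#' @param stats Gene statistics table.
#' @param nonsig_fc Substitute fold change for non-significant genes.
#' @return Named numeric vector of node weights.
#' @export
compute_node_weights <- function(net, stats, nonsig_fc = 1e-6) {
  if (igraph::is_igraph(net)) {
    degs <- igraph::degree(net, mode = "all")
  } else {
    stopifnot(is.numeric(net), !is.null(names(net)))
    degs <- net
  }
  fc <- setNames(stats$log2fc, stats$gene)
  sig <- setNames(stats$significant, stats$gene)
  g <- names(degs)
  use_fc <- !is.na(sig[g]) & sig[g] & !is.na(fc[g])
  w <- ifelse(use_fc, abs(fc[g]), nonsig_fc) * degs
  setNames(unname(w), g)
}

#' Proximity gene scores (Knode)
#'
#' Scores each node by the summed centered weight of the other nodes within
#' geodesic distance `s`:
#' `K_i(s) = (2/p) * sum_{j != i, d(i,j) <= s} (p_j - pbar)`, where `p_j` is
#' the weight of node `j`, `p` their total and `pbar` their mean. Nodes
#' embedded in a neighborhood of heavier-than-average nodes score high. When
#' `s` has several values the per-distance scores are averaged (an area
#' under the score profile); the default is the single distance `s = 2`.
#'
#' @param net Undirected (or directed; distances follow edges both ways)
#'   igraph network.
#' @param node_weights Named weights from [compute_node_weights()].
#' @param s Neighborhood radius (geodesic distance), possibly a vector.
#' @return Named numeric vector of scores.
#' @export
compute_gene_scores <- function(net, node_weights, s = 2) {
  nodes <- igraph::V(net)$name
  w <- node_weights[nodes]
  stopifnot(!anyNA(w))
  p <- sum(w)
  if (p == 0) stop("all node weights are zero; gene scores are undefined")
  centered <- w - mean(w)
  d <- igraph::distances(net, mode = "all", weights = NA)
  per_s <- vapply(s, function(si) {
    within <- is.finite(d) & d <= si
    diag(within) <- FALSE
    as.numeric((2 / p) * (within %*% centered))
  }, numeric(length(nodes)))
  scores <- if (length(s) > 1L) rowMeans(per_s) else as.numeric(per_s)
  setNames(scores, nodes)
}

#' Top fraction of a score vector
#'
#' Returns the `ceiling(fraction * N)` highest-scoring nodes; ties at the
#' cut value are all included.
#'
#' @param scores Named numeric vector.
#' @param fraction Fraction in (0, 1].
#' @return Character vector of node names.
#' @export
select_top_fraction <- function(scores, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * length(scores))
  cut <- sort(scores, decreasing = TRUE)[k]
  picked <- names(scores)[scores >= cut]
  if (length(picked) > k) {
    message("tie at the cut value: returning ", length(picked),
            " nodes instead of ", k)
  }
  sort(picked)
}

#' Score subnetwork: unweighted paths between top-score and top-weight nodes
#'
#' Union of one unweighted shortest path per unordered (top-score,
#' top-weight) pair; tie-break toward the lexicographically smallest node
#' sequence. Node prioritization already reflects regulation here, so edge
#' weights are deliberately not used. A node present in both sets
#' contributes no self-path.
#'
#' @param net Undirected igraph network.
#' @param top_scores,top_weights Character vectors of node names.
#' @return A `tep_subnetwork` (see [extract_controllable_subnetwork()]).
#' @export
extract_score_subnetwork <- function(net, top_scores, top_weights) {
  if (length(top_scores) == 0L || length(top_weights) == 0L) {
    stop("top-score and top-weight sets must be non-empty")
  }
  nodes <- igraph::V(net)$name
  top_scores <- intersect(sort(top_scores), nodes)
  top_weights <- intersect(sort(top_weights), nodes)
  unit <- igraph::set_edge_attr(net, "weight",
                                value = rep(1, igraph::ecount(net)))
  w <- igraph::E(unit)$weight
  seen <- character(0)
  paths <- list()
  pairs <- list()
  for (a in top_scores) {
    d_from <- igraph::distances(unit, v = a, to = nodes, weights = w)[1L, ]
    for (b in top_weights) {
      if (a == b) next
      key <- paste(sort(c(a, b)), collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      # orient the pair lexicographically so the retained path sequence is
      # the smallest among both traversal directions
      lo <- sort(c(a, b))[1L]
      hi <- sort(c(a, b))[2L]
      reachable <- is.finite(d_from[b])
      pairs[[length(pairs) + 1L]] <- data.frame(
        source = lo, sink = hi, reachable = reachable,
        weight = if (reachable) unname(d_from[b]) else NA_real_,
        stringsAsFactors = FALSE)
      if (!reachable) next
      d_lo <- igraph::distances(unit, v = lo, to = nodes, weights = w)[1L, ]
      d_hi <- igraph::distances(unit, v = nodes, to = hi, weights = w)[, 1L]
      p <- lex_shortest_path(unit, lo, hi, w, d_lo, d_hi)
      if (!is.null(p)) paths[[length(paths) + 1L]] <- p
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(source = character(0), sink = character(0),
               reachable = logical(0), weight = numeric(0))
  sub <- subgraph_from_paths(net, paths)
  structure(list(graph = sub, retained_paths = paths, pairs = pairs),
            class = "tep_subnetwork")
}
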