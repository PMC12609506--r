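# Independent oracles used across the suite. These deliberately avoid the
# package's own matching code: numeric Kalman ranks with random edge
# weights, igraph's bipartite matcher, and literal brute-force evaluation.

# Seeded random directed graph with lexicographic node names.
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  df <- data.frame(source = edges$from, target = edges$to,
                   sign = sample(c(-1L, 1L), sum(keep), replace = TRUE))
  signed_digraph(df, nodes = nodes)
}

# Numeric generic rank of the Kalman controllability matrix for inputs at
# `inputs`, maximized over `draws` random weight draws.
kalman_rank <- function(net, inputs, draws = 5) {
  nodes <- sort(igraph::V(net)$name)
  n <- length(nodes)
  edges <- igraph::as_data_frame(net, what = "edges")
  best <- 0L
  for (d in seq_len(draws)) {
    A <- matrix(0, n, n, dimnames = list(nodes, nodes))
    if (nrow(edges) > 0L) {
      A[cbind(edges$to, edges$from)] <- runif(nrow(edges), 0.5, 1.5)
    }
    B <- matrix(0, n, length(inputs))
    B[cbind(match(inputs, nodes), seq_along(inputs))] <- 1
    K <- B
    blk <- B
    for (k in seq_len(n - 1L)) {
      blk <- A %*% blk
      K <- cbind(K, blk)
    }
    best <- max(best, qr(K)$rank)
  }
  best
}

# Brute-force minimum number of independent control inputs: smallest k such
# that k generic (dense) input columns reach full Kalman generic rank. Dense
# columns let one input signal attach to several nodes, which is the
# quantity the matching count N - |M*| measures (a dedicated-input reading
# fails on perfectly matched cycles unreachable from the unmatched nodes).
brute_min_inputs <- function(net, draws = 5) {
  nodes <- sort(igraph::V(net)$name)
  n <- length(nodes)
  edges <- igraph::as_data_frame(net, what = "edges")
  for (k in seq_len(n)) {
    for (d in seq_len(draws)) {
      A <- matrix(0, n, n, dimnames = list(nodes, nodes))
      if (nrow(edges) > 0L) {
        A[cbind(edges$to, edges$from)] <- runif(nrow(edges), 0.5, 1.5)
      }
      B <- matrix(runif(n * k, 0.5, 1.5) *
                    sample(c(-1, 1), n * k, replace = TRUE), n, k)
      K <- B
      blk <- B
      for (j in seq_len(n - 1L)) {
        blk <- A %*% blk
        K <- cbind(K, blk)
      }
      if (qr(K)$rank == n) return(k)
    }
  }
  n
}

# Maximum matching size of the bipartite representation via igraph,
# optionally restricted to a subset of usable in-copies.
ig_matching_size <- function(net, keep_in = igraph::V(net)$name) {
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  edges <- igraph::as_data_frame(net, what = "edges")
  edges <- edges[edges$to %in% keep_in, , drop = FALSE]
  bip <- igraph::make_empty_graph(directed = FALSE)
  bip <- igraph::add_vertices(bip, 2L * n,
                              name = c(paste0("out_", nodes),
                                       paste0("in_", nodes)),
                              type = rep(c(FALSE, TRUE), each = n))
  if (nrow(edges) > 0L) {
    bip <- igraph::add_edges(bip, rbind(paste0("out_", edges$from),
                                        paste0("in_", edges$to)))
  }
  igraph::max_bipartite_match(bip)$matching_size
}

# Enumerate all minimum driver sets by subset testing: S (|S| = N_D) is an
# MDS iff some matching saturates the in-copies of all other nodes.
enumerate_mds_oracle <- function(net) {
  nodes <- sort(igraph::V(net)$name)
  n <- length(nodes)
  msize <- ig_matching_size(net)
  nd <- max(n - msize, 1L)
  sets <- combn(nodes, nd, simplify = FALSE)
  valid <- Filter(function(S) {
    rest <- setdiff(nodes, S)
    ig_matching_size(net, keep_in = rest) == length(rest)
  }, sets)
  valid
}

# All-simple-paths minimum-weight oracle for shortest-path extraction.
exhaustive_min_path_weight <- function(net, from, to, weights) {
  paths <- igraph::all_simple_paths(net, from = from, to = to,
                                    mode = "out")
  if (length(paths) == 0L) return(Inf)
  min(vapply(paths, function(p) {
    ids <- igraph::as_ids(p)
    eid <- igraph::get_edge_ids(net, rbind(ids[-length(ids)], ids[-1L]))
    sum(weights[as.integer(eid)])
  }, numeric(1L)))
}

# Literal double-loop Knode evaluation.
knode_double_loop <- function(net, w, s) {
  nodes <- igraph::V(net)$name
  d <- igraph::distances(net, mode = "all", weights = NA)
  p <- sum(w[nodes])
  pbar <- mean(w[nodes])
  out <- setNames(numeric(length(nodes)), nodes)
  for (i in nodes) {
    acc <- 0
    for (j in nodes) {
      if (i == j) next
      if (is.finite(d[i, j]) && d[i, j] <= s) acc <- acc + (w[j] - pbar)
    }
    out[i] <- 2 / p * acc
  }
  out
}

# Tiny tab-delimited file helper.
write_tsv_tmp <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  path
}
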