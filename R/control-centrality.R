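# Dense O(n^3) assignment solver (potentials + Dijkstra-style row insertion,
# the classic shortest-augmenting-path formulation). cost must be a square
# matrix of finite values; returns the minimum total cost of a perfect
# matching between rows and columns.
assignment_cost <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  big <- .Machine$double.xmax / 16
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  j_virtual <- n + 1L
  for (i in seq_len(n)) {
    p[j_virtual] <- i
    j0 <- j_virtual
    minv <- rep(big, n)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(n)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        idx <- free[upd]
        minv[idx] <- cur[upd]
        way[idx] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      used_cols <- which(used)
      u[p[used_cols]] <- u[p[used_cols]] + delta
      v[used_cols] <- v[used_cols] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the alternating path back to the virtual column
    while (j0 != j_virtual) {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
    }
  }
  total <- 0
  for (j in seq_len(n)) total <- total + cost[p[j], j]
  total
}

#' Control centrality: generic dimension controllable from one node
#'
#' The control centrality of a node is the generic dimension of the subspace
#' that a single input attached to that node can steer. By the structural
#' controllability results for linear systems this equals the maximum number
#' of state vertices covered by one stem (a directed path starting at the
#' input node) together with vertex-disjoint cycles, all inside the set of
#' vertices reachable from the node.
#'
#' The maximization is solved exactly as a 0/1-cost assignment problem on an
#' auxiliary graph: an input vertex `u` with the link `u -> node`, a return
#' link `v -> u` from every reachable vertex, a zero-cost link per network
#' edge, and a unit-cost slack per vertex (vertex left uncovered). The
#' minimum assignment cost is the number of uncovered reachable vertices, so
#' the centrality is `|R(node)| - mincost`. An isolated node has centrality
#' 1 (it can always steer itself).
#'
#' @param net Directed igraph network.
#' @param nodes Character vector of node names (default: all nodes).
#' @return Named integer vector of centralities in `[1, N]`.
#' @export
control_centrality <- function(net, nodes = igraph::V(net)$name) {
  unknown <- setdiff(nodes, igraph::V(net)$name)
  if (length(unknown) > 0L) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  }
  out <- setNames(integer(length(nodes)), nodes)
  for (nd in nodes) {
    reach <- igraph::subcomponent(net, nd, mode = "out")
    sub <- igraph::induced_subgraph(net, reach)
    rnames <- sort(igraph::V(sub)$name)
    m <- length(rnames)
    if (igraph::ecount(sub) == 0L) {
      out[nd] <- 1L
      next
    }
    idx <- setNames(seq_len(m) + 1L, rnames)  # slot 1 is the input vertex u
    size <- m + 1L
    big <- size + 1
    cost <- matrix(big, size, size)
    cost[1L, idx[nd]] <- 0                    # u -> node starts the stem
    cost[2L:size, 1L] <- 0                    # any vertex may close back to u
    diag(cost)[2L:size] <- 1                  # slack: vertex left uncovered
    edges <- igraph::as_data_frame(sub, what = "edges")
    cost[cbind(idx[edges$from], idx[edges$to])] <- 0
    out[nd] <- as.integer(round(m - assignment_cost(cost)))
  }
  out
}
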