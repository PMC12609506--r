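# Bipartite representation of a directed graph: every node v contributes an
# out-copy and an in-copy; a directed edge u -> v becomes the bipartite link
# out(u) -- in(v). Self-loops link out(v) -- in(v), so a self-looped node can
# match itself. Matchings of this graph encode structural controllability:
# nodes with an unmatched in-copy are driver nodes.

bipartite_rep <- function(net) {
  nodes <- sort(igraph::V(net)$name)
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  edges <- igraph::as_data_frame(net, what = "edges")
  adj_out <- vector("list", n)   # adj_out[[u]]: in-copies reachable from out(u)
  adj_in <- vector("list", n)    # adj_in[[v]]: out-copies adjacent to in(v)
  for (k in seq_len(n)) {
    adj_out[[k]] <- integer(0)
    adj_in[[k]] <- integer(0)
  }
  if (nrow(edges) > 0L) {
    us <- idx[edges$from]
    vs <- idx[edges$to]
    dup <- duplicated(paste(us, vs))
    us <- us[!dup]; vs <- vs[!dup]
    adj_out <- split(vs, factor(us, levels = seq_len(n)))
    adj_in <- split(us, factor(vs, levels = seq_len(n)))
    adj_out <- lapply(adj_out, function(x) sort(unname(x)))
    adj_in <- lapply(adj_in, function(x) sort(unname(x)))
  }
  list(nodes = nodes, n = n, adj_out = adj_out, adj_in = adj_in)
}

# One augmenting-path search (Kuhn). adj: list out -> in-copy neighbors in
# the order they should be tried; ok_in: logical mask of usable in-copies.
# match_in/match_out are integer vectors (0 = unmatched), modified and
# returned in a list.
kuhn_try <- function(u, adj, ok_in, match_in, match_out, visited) {
  # recursion depth is bounded by the matching size; fine at these scales
  visit <- function(u) {
    for (v in adj[[u]]) {
      if (!ok_in[v] || visited[v]) next
      visited[v] <<- TRUE
      if (match_in[v] == 0L || visit(match_in[v])) {
        match_in[v] <<- u
        match_out[u] <<- v
        return(TRUE)
      }
    }
    FALSE
  }
  found <- visit(u)
  list(found = found, match_in = match_in, match_out = match_out)
}

# Maximum matching by repeated augmentation, optionally warm-started from an
# existing partial matching. out_order controls determinism: processing
# out-copies (and their adjacency, pre-ordered in adj) in lexicographic node
# order yields the canonical matching.
kuhn_matching <- function(adj, n, ok_out = rep(TRUE, n), ok_in = rep(TRUE, n),
                          match_in = integer(n), match_out = integer(n),
                          out_order = seq_len(n)) {
  for (u in out_order) {
    if (!ok_out[u] || match_out[u] != 0L) next
    if (length(adj[[u]]) == 0L) next
    visited <- logical(n)
    res <- kuhn_try(u, adj, ok_in, match_in, match_out, visited)
    match_in <- res$match_in
    match_out <- res$match_out
  }
  list(match_in = match_in, match_out = match_out, size = sum(match_in > 0L))
}

# Drop a matching's pairs that touch forbidden copies, then re-augment.
rematch <- function(rep, base, ok_out = rep(TRUE, rep$n),
                    ok_in = rep(TRUE, rep$n), shuffle = FALSE) {
  match_in <- base$match_in
  match_out <- base$match_out
  for (v in which(match_in > 0L)) {
    u <- match_in[v]
    if (!ok_in[v] || !ok_out[u]) {
      match_in[v] <- 0L
      match_out[u] <- 0L
    }
  }
  adj <- rep$adj_out
  order_out <- seq_len(rep$n)
  if (shuffle) {
    adj <- lapply(adj, function(x) if (length(x) > 1L) sample(x) else x)
    order_out <- sample(order_out)
  }
  kuhn_matching(adj, rep$n, ok_out, ok_in, match_in, match_out, order_out)
}

#' Maximum matching of the bipartite representation
#'
#' Computes a maximum-cardinality matching of the bipartite representation of
#' a directed network (out-copy/in-copy splitting; self-loops allowed to
#' match a node with itself). With `seed = NULL` the canonical deterministic
#' matching is returned: out-copies and their neighbors are processed in
#' lexicographic node order. With a seed, node and adjacency order are
#' randomized, which samples alternative maximum matchings.
#'
#' @param net Directed igraph network.
#' @param seed Integer seed for a randomized matching, or `NULL` (canonical).
#' @return Object of class `tep_matching`: list with `pairs` (data.frame of
#'   matched `from`/`to` node names), `size`, `drivers` (nodes whose in-copy
#'   is unmatched), and the internal index vectors.
#' @export
maximum_matching <- function(net, seed = NULL) {
  stopifnot(igraph::vcount(net) > 0L)
  rep <- bipartite_rep(net)
  m <- with_local_seed(seed, {
    adj <- rep$adj_out
    order_out <- seq_len(rep$n)
    if (!is.null(seed)) {
      adj <- lapply(adj, function(x) if (length(x) > 1L) sample(x) else x)
      order_out <- sample(order_out)
    }
    kuhn_matching(adj, rep$n, out_order = order_out)
  })
  matched <- which(m$match_in > 0L)
  structure(list(
    nodes = rep$nodes,
    pairs = data.frame(from = rep$nodes[m$match_in[matched]],
                       to = rep$nodes[matched], stringsAsFactors = FALSE),
    size = m$size,
    drivers = rep$nodes[m$match_in == 0L],
    match_in = m$match_in,
    match_out = m$match_out,
    seed = seed
  ), class = "tep_matching")
}

#' @export
print.tep_matching <- function(x, ...) {
  cat("Maximum matching: size", x$size, "on", length(x$nodes), "nodes;",
      length(x$drivers), "driver(s)\n")
  invisible(x)
}

#' Driver node count and set
#'
#' Driver nodes are the nodes whose in-copy is unmatched under a maximum
#' matching; the minimum number of driver nodes is `max(N - |M*|, 1)`. When
#' the matching is perfect every single node is a valid driver set, and by
#' convention the lexicographically smallest node is reported.
#'
#' @param net Directed igraph network.
#' @param matching Optional precomputed [maximum_matching()].
#' @return List with `n_drivers` and `drivers` (character vector).
#' @export
driver_count_and_set <- function(net, matching = NULL) {
  if (is.null(matching)) matching <- maximum_matching(net)
  n <- length(matching$nodes)
  n_d <- max(n - matching$size, 1L)
  drivers <- matching$drivers
  if (length(drivers) == 0L) drivers <- matching$nodes[1L]
  list(n_drivers = n_d, drivers = drivers)
}

#' Minimum steering node set
#'
#' One concrete minimum driver set: the driver set of the canonical
#' (deterministic) maximum matching. It always contains every critical node
#' and has exactly `max(N - |M*|, 1)` members.
#'
#' @param net Directed igraph network.
#' @return Character vector of node names.
#' @export
minimum_steering_set <- function(net) {
  driver_count_and_set(net)$drivers
}

# Enumerate the driver sets of all maximum matchings (distinct MDSs).
# Exponential in the worst case; callers restrict to small graphs.
enumerate_mds <- function(rep, msize) {
  n <- rep$n
  found <- new.env(parent = emptyenv())
  used_out <- logical(n)
  assign_count <- 0L
  recurse <- function(v, matched) {
    if (matched + (n - v + 1L) < msize) return(invisible())
    if (v > n) {
      if (matched == msize) {
        drivers <- which(!in_matched)
        key <- paste(drivers, collapse = ",")
        if (is.null(found[[key]])) found[[key]] <- drivers
      }
      return(invisible())
    }
    # option 1: leave in(v) unmatched
    in_matched[v] <<- FALSE
    recurse(v + 1L, matched)
    # option 2: match in(v) with a free out-neighbor
    for (u in rep$adj_in[[v]]) {
      if (used_out[u]) next
      used_out[u] <<- TRUE
      in_matched[v] <<- TRUE
      recurse(v + 1L, matched + 1L)
      used_out[u] <<- FALSE
      in_matched[v] <<- FALSE
    }
    invisible()
  }
  in_matched <- logical(n)
  recurse(1L, 0L)
  lapply(as.list(found), identity)
}
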