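#' Classify nodes by membership in minimum driver sets
#'
#' A node is *critical* when it is a driver (unmatched) in every maximum
#' matching, *redundant* when it is matched in every maximum matching (never
#' a driver), and *intermittent* otherwise. Every in-degree-0 node is
#' critical, since its in-copy has no bipartite link at all.
#'
#' When the network has a perfect matching every singleton is a valid
#' minimum driver set, so all nodes are classified intermittent (the
#' "always matched implies redundant" reading would contradict their MDS
#' membership); this special case is also reflected in [control_capacity()],
#' which then assigns 1/N to every node.
#'
#' @param net Directed igraph network.
#' @return Named character vector (`critical`/`intermittent`/`redundant`).
#' @export
classify_mds_membership <- function(net) {
  rep <- bipartite_rep(net)
  n <- rep$n
  base <- kuhn_matching(rep$adj_out, n)
  msize <- base$size
  out <- setNames(rep(NA_character_, n), rep$nodes)
  if (msize == n) {
    out[] <- "intermittent"
    return(out)
  }
  for (v in seq_len(n)) {
    indeg <- length(rep$adj_in[[v]])
    if (indeg == 0L) {
      out[v] <- "critical"
      next
    }
    # redundant <=> removing in(v) drops the maximum matching size
    ok_in <- rep(TRUE, n); ok_in[v] <- FALSE
    m_wo <- rematch(rep, base, ok_in = ok_in)
    if (m_wo$size == msize - 1L) {
      out[v] <- "redundant"
      next
    }
    # v is unmatched in some maximum matching; critical <=> it is unmatched
    # in all of them, i.e. no in-neighbor u extends to a maximum matching
    # through the link out(u) -- in(v)
    if (base$match_in[v] != 0L) {
      out[v] <- "intermittent"
      next
    }
    saturable <- FALSE
    for (u in rep$adj_in[[v]]) {
      ok_out <- rep(TRUE, n); ok_out[u] <- FALSE
      m_uv <- rematch(rep, base, ok_out = ok_out, ok_in = ok_in)
      if (m_uv$size == msize - 1L) {
        saturable <- TRUE
        break
      }
    }
    out[v] <- if (saturable) "intermittent" else "critical"
  }
  out
}

#' Classify nodes by the effect of their removal on the driver count
#'
#' Removes each node (with its incident edges), recomputes the minimum
#' driver count `N_D' = max(N - 1 - |M'|, 1)`, and labels the node
#' *indispensable* (`N_D' > N_D`), *dispensable* (`N_D' < N_D`) or *neutral*
#' (unchanged).
#'
#' @param net Directed igraph network with at least 2 nodes.
#' @return Named character vector
#'   (`indispensable`/`neutral`/`dispensable`).
#' @export
classify_node_removal <- function(net) {
  rep <- bipartite_rep(net)
  n <- rep$n
  if (n < 2L) stop("node-removal classification needs at least 2 nodes")
  base <- kuhn_matching(rep$adj_out, n)
  n_d <- max(n - base$size, 1L)
  out <- setNames(rep(NA_character_, n), rep$nodes)
  for (v in seq_len(n)) {
    ok <- rep(TRUE, n); ok[v] <- FALSE
    m <- rematch(rep, base, ok_out = ok, ok_in = ok)
    n_d_v <- max((n - 1L) - m$size, 1L)
    out[v] <- if (n_d_v > n_d) "indispensable"
      else if (n_d_v < n_d) "dispensable" else "neutral"
  }
  out
}

# Basis-exchange random walk over minimum driver sets. The node sets
# saturable by a maximum matching form a transversal matroid, so the
# symmetric exchange walk (swap one saturated node for one unsaturated node,
# accept when the result is still saturable) is a Metropolis chain whose
# stationary distribution is uniform over the matroid bases -- equivalently,
# uniform over the MDSs (their complements). Every proposal costs a single
# re-augmentation of the current matching.
sample_mds_walk <- function(rep, base, n_samples, burn, thin) {
  n <- rep$n
  msize <- base$size
  cur <- base
  ok_in <- rep(FALSE, n)
  ok_in[cur$match_in > 0L] <- TRUE
  # nodes with in-degree 0 can never be saturated; never propose them
  eligible <- which(lengths(rep$adj_in) > 0L)
  hits <- integer(n)
  total_steps <- burn + n_samples * thin
  taken <- 0L
  for (step in seq_len(total_steps)) {
    inside <- which(ok_in)
    outside <- setdiff(eligible, inside)
    if (length(outside) > 0L) {
      v <- inside[sample.int(length(inside), 1L)]
      w <- outside[sample.int(length(outside), 1L)]
      ok_try <- ok_in
      ok_try[v] <- FALSE
      ok_try[w] <- TRUE
      cand <- rematch(rep, cur, ok_in = ok_try)
      if (cand$size == msize) {
        cur <- cand
        ok_in <- ok_try
      }
    }
    if (step > burn && (step - burn) %% thin == 0L) {
      unmatched <- which(cur$match_in == 0L)
      hits[unmatched] <- hits[unmatched] + 1L
      taken <- taken + 1L
    }
  }
  hits / taken
}

#' Control capacity of every node
#'
#' The control capacity of a node is the fraction of minimum driver sets
#' (MDSs) that contain it. For networks with at most `exact_below` nodes all
#' maximum matchings are enumerated and the distinct driver sets counted
#' exactly; larger networks are estimated from `n_samples` maximum matchings
#' drawn by a basis-exchange random walk whose stationary distribution is
#' uniform over the MDSs. Critical nodes have capacity 1 and redundant nodes
#' capacity 0 by construction; in the perfect-matching special case every
#' node gets capacity `1/N` (every singleton is an MDS).
#'
#' @param net Directed igraph network.
#' @param n_samples Number of sampled driver sets when sampling.
#' @param seed Seed for the sampling mode.
#' @param exact_below Enumerate exactly when `N <=` this value (default 12).
#' @return Named numeric vector in `[0, 1]`.
#' @export
control_capacity <- function(net, n_samples = 1000, seed = NULL,
                             exact_below = 12) {
  stopifnot(n_samples >= 1)
  rep <- bipartite_rep(net)
  n <- rep$n
  base <- kuhn_matching(rep$adj_out, n)
  msize <- base$size
  if (msize == n) {
    return(setNames(rep(1 / n, n), rep$nodes))
  }
  cls <- classify_mds_membership(net)
  cap <- setNames(numeric(n), rep$nodes)
  if (n <= exact_below) {
    sets <- enumerate_mds(rep, msize)
    hits <- integer(n)
    for (s in sets) hits[s] <- hits[s] + 1L
    cap[] <- hits / length(sets)
  } else {
    cap[] <- with_local_seed(if (is.null(seed)) 1L else seed, {
      sample_mds_walk(rep, base, n_samples, burn = 10L * n,
                      thin = max(2L, n %/% 2L))
    })
  }
  cap[cls == "critical"] <- 1
  cap[cls == "redundant"] <- 0
  cap
}

#' Full per-node controllability profile
#'
#' Convenience wrapper computing, for every node: canonical driver status,
#' both classification schemes, control capacity, membership in the minimum
#' steering set, and (optionally) control centrality.
#'
#' @param net Directed igraph network.
#' @param n_samples,seed,exact_below Passed to [control_capacity()].
#' @param centrality Compute control centrality for every node (can be slow
#'   on large networks; see [control_centrality()]).
#' @return data.frame with one row per node.
#' @export
node_control_profiles <- function(net, n_samples = 1000, seed = NULL,
                                  exact_below = 12, centrality = FALSE) {
  matching <- maximum_matching(net)
  drv <- driver_count_and_set(net, matching)
  mds <- classify_mds_membership(net)
  removal <- classify_node_removal(net)
  cap <- control_capacity(net, n_samples = n_samples, seed = seed,
                          exact_below = exact_below)
  nodes <- matching$nodes
  prof <- data.frame(
    node = nodes,
    is_driver_canonical = nodes %in% drv$drivers,
    mds_class = unname(mds[nodes]),
    removal_class = unname(removal[nodes]),
    control_capacity = unname(cap[nodes]),
    in_mss = nodes %in% minimum_steering_set(net),
    stringsAsFactors = FALSE
  )
  if (isTRUE(centrality)) {
    prof$control_centrality <- unname(control_centrality(net, nodes))
  }
  attr(prof, "n_drivers") <- drv$n_drivers
  prof
}
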