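sig_stats <- function(genes, lfc) {
  as_gene_stats(data.frame(gene = genes, log2fc = lfc,
                           adj_p = ifelse(is.na(lfc), NA, 1e-4),
                           avg_expr = 2), fc_threshold = 0)
}

test_that("edge weights are reciprocal absolute fold-change products", {
  net <- signed_digraph(data.frame(
    source = c("a", "b", "c"), target = c("b", "c", "d"), sign = 1L))
  st <- sig_stats(c("a", "b", "c", "d"), c(2, 0.5, -1, NA))
  w <- igraph::E(compute_edge_weights(net, st))$weight
  # a->b: 1/|2*0.5| = 1; b->c: 1/|0.5*-1| = 2; c->d penalized: 10 * 2 = 20
  expect_equal(w, c(1, 2, 20))
  st2 <- sig_stats(c("a", "b", "c", "d"), c(-1, 2, 0.5, NA))
  w2 <- igraph::E(compute_edge_weights(net, st2))$weight
  expect_equal(w2[1], 0.5)   # |-1 * 2| = 2 -> 1/2
  # one non-significant endpoint with max finite weight 4 -> penalty 40
  net2 <- signed_digraph(data.frame(source = c("a", "b"),
                                    target = c("b", "c"), sign = 1L))
  st3 <- sig_stats(c("a", "b", "c"), c(0.5, 0.5, NA))
  w3 <- igraph::E(compute_edge_weights(net2, st3))$weight
  expect_equal(w3, c(4, 40))  # 1/|0.5*0.5| = 4; penalized edge 10 * 4
})

test_that("a network with no informative edge falls back to constant weights", {
  net <- signed_digraph(data.frame(source = "a", target = "b", sign = 1L))
  st <- sig_stats(c("a", "b"), c(NA, NA))
  expect_warning(w <- compute_edge_weights(net, st), "no edge joins")
  expect_true(all(igraph::E(w)$weight > 0))
})

weighted_toy <- function(edges, weights) {
  net <- signed_digraph(edges)
  # set weights in the graph's own edge order
  e <- igraph::as_data_frame(net, what = "edges")
  key <- paste(e$from, e$to)
  igraph::set_edge_attr(net, "weight",
                        value = weights[match(key, names(weights))])
}

test_that("controllable subnetwork takes cheap detours and unions shared edges", {
  net <- weighted_toy(
    data.frame(source = c("a", "a", "m", "b"),
               target = c("d", "m", "d", "m"), sign = 1L),
    c("a d" = 1.0, "a m" = 0.1, "m d" = 0.1, "b m" = 0.3))
  out <- extract_controllable_subnetwork(net, sources = c("a", "b"),
                                         sinks = "d")
  expect_equal(out$retained_paths,
               list(c("a", "m", "d"), c("b", "m", "d")))
  e <- igraph::as_data_frame(out$graph, what = "edges")
  expect_equal(nrow(e), 3L)  # m->d shared, counted once
  expect_false(any(e$from == "a" & e$to == "d"))
})

test_that("equal-weight path ties break to the lexicographically smallest sequence", {
  net <- weighted_toy(
    data.frame(source = c("a", "a", "b", "c"),
               target = c("b", "c", "d", "d"), sign = 1L),
    c("a b" = 1, "a c" = 1, "b d" = 1, "c d" = 1))
  out <- extract_controllable_subnetwork(net, "a", "d")
  expect_equal(out$retained_paths[[1]], c("a", "b", "d"))
})

test_that("unreachable pairs are logged, not errors; empty sets are errors", {
  net <- weighted_toy(data.frame(source = "a", target = "b", sign = 1L),
                      c("a b" = 1))
  out <- extract_controllable_subnetwork(net, "b", "a")
  expect_false(out$pairs$reachable)
  expect_equal(igraph::vcount(out$graph), 0L)
  expect_error(extract_controllable_subnetwork(net, character(0), "a"),
               "non-empty")
})

test_that("Dijkstra extraction equals the exhaustive path oracle on small graphs", {
  for (seed in 1:20) {
    net <- random_digraph(8, 0.3, 1300 + seed)
    if (igraph::ecount(net) == 0) next
    set.seed(seed)
    net <- igraph::set_edge_attr(net, "weight",
                                 value = round(runif(igraph::ecount(net),
                                                     0.1, 2), 3))
    nodes <- igraph::V(net)$name
    w <- igraph::E(net)$weight
    out <- extract_controllable_subnetwork(net, nodes[1:2], nodes[7:8])
    for (r in seq_len(nrow(out$pairs))) {
      pw <- exhaustive_min_path_weight(net, out$pairs$source[r],
                                       out$pairs$sink[r], w)
      if (out$pairs$reachable[r]) {
        expect_equal(out$pairs$weight[r], pw, tolerance = 1e-9)
      } else {
        expect_equal(pw, Inf)
      }
    }
    # every edge of the subnetwork lies on a retained path
    e <- igraph::as_data_frame(out$graph, what = "edges")
    on_path <- unique(do.call(rbind, lapply(out$retained_paths, function(p) {
      data.frame(from = p[-length(p)], to = p[-1])
    })))
    expect_true(all(paste(e$from, e$to) %in%
                      paste(on_path$from, on_path$to)))
  }
})

test_that("node weights reproduce the published worked rows", {
  degs <- c(P2RY12 = 1, GRB2 = 37, ZERO = 0)
  st <- as_gene_stats(data.frame(
    gene = c("P2RY12", "GRB2", "ZERO"),
    log2fc = c(-0.49, NA, 1),
    adj_p = c(1e-4, NA, 1e-4),
    avg_expr = 2), fc_threshold = 0)
  w <- compute_node_weights(degs, st)
  expect_equal(unname(w["P2RY12"]), 0.49)
  expect_equal(unname(round(w["GRB2"], 2)), 0)    # 37 * 1e-6 rounds to 0
  expect_equal(unname(w["GRB2"]), 3.7e-5)
  expect_equal(unname(w["ZERO"]), 0)
})

test_that("all 16 published high-score rows are weight-consistent", {
  fx <- load_reference_fixtures()
  hs <- fx$high_score_nodes
  st <- high_score_gene_stats(hs)
  w <- compute_node_weights(setNames(as.numeric(hs$degree), hs$gene), st)
  for (i in seq_len(nrow(hs))) {
    g <- hs$gene[i]
    if (is.na(hs$log2fc[i])) {
      expect_equal(unname(round(w[g], 2)), 0, info = g)
    } else {
      expect_lte(abs(w[[g]] - hs$weight[i]), 0.2)
    }
  }
})

test_that("gene scores match direct evaluation on the weighted path", {
  path <- undirected_network(data.frame(source = c("x", "y"),
                                        target = c("y", "z")))
  w <- c(x = 4, y = 1, z = 1)
  k <- compute_gene_scores(path, w, s = 1)
  expect_equal(unname(k[c("x", "y", "z")]), c(-1 / 3, 1 / 3, -1 / 3))
  # equal weights center to zero everywhere
  expect_equal(unname(compute_gene_scores(path, c(x = 2, y = 2, z = 2))),
               rep(0, 3))
  # s >= diameter: closed form, total deviation minus own deviation
  k2 <- compute_gene_scores(path, w, s = 5)
  p <- sum(w)
  expect_equal(unname(k2), unname(2 / p * (0 - (w - mean(w)))))
  expect_error(compute_gene_scores(path, c(x = 0, y = 0, z = 0)),
               "zero")
})

test_that("gene scores equal the literal double loop on seeded graphs up to N = 50", {
  for (seed in c(21, 22, 23)) {
    set.seed(seed)
    n <- sample(20:50, 1)
    g <- igraph::sample_gnp(n, 0.08)
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    w <- setNames(runif(n, 0, 5), igraph::V(g)$name)
    for (s in 1:3) {
      expect_equal(compute_gene_scores(g, w, s = s),
                   knode_double_loop(g, w, s), tolerance = 1e-12)
    }
  }
})

test_that("scaling node weights leaves the score ranking unchanged", {
  set.seed(4)
  g <- igraph::sample_gnp(30, 0.12)
  igraph::V(g)$name <- sprintf("v%02d", 1:30)
  w <- setNames(runif(30, 0.1, 5), igraph::V(g)$name)
  k1 <- compute_gene_scores(g, w, s = 2)
  k2 <- compute_gene_scores(g, 7.3 * w, s = 2)
  expect_equal(order(k1), order(k2))
  expect_equal(k2, k1, tolerance = 1e-9)  # K is scale-invariant: 2/p absorbs c
})

test_that("top-fraction selection honors the ceiling rule and ties", {
  scores <- setNames(seq_len(550), sprintf("g%03d", 1:550))
  expect_length(select_top_fraction(scores, 0.10), 55L)
  expect_length(select_top_fraction(setNames(1:10, letters[1:10]), 0.10), 1L)
  tied <- c(a = 3, b = 2, c = 2, d = 1)
  expect_message(top <- select_top_fraction(tied, 0.5), "tie")
  expect_setequal(top, c("a", "b", "c"))
})

test_that("score subnetwork uses unweighted paths with lexicographic ties", {
  net <- undirected_network(data.frame(
    source = c("a", "a", "b", "c", "a"),
    target = c("b", "c", "d", "d", "z"), sign = 0L))
  out <- extract_score_subnetwork(net, top_scores = c("a"),
                                  top_weights = c("d", "z"))
  expect_true(any(vapply(out$retained_paths, identical, logical(1),
                         c("a", "b", "d"))))
  # adjacent pair contributes the single edge; shared node no self-path
  out2 <- extract_score_subnetwork(net, c("a"), c("a", "z"))
  expect_equal(out2$retained_paths, list(c("a", "z")))
  expect_error(extract_score_subnetwork(net, character(0), "a"),
               "non-empty")
})
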