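make_records <- function(source, target, sign = 1L, directed = TRUE,
                         curation = 3L) {
  data.frame(source = source, target = target, is_directed = directed,
             sign = sign, curation_effort = curation,
             stringsAsFactors = FALSE)
}

test_that("curation filter keeps signed, directed, well-curated records", {
  rec <- rbind(
    make_records("a", "b", curation = 2L),            # curation too low
    make_records("b", "c", curation = 3L),            # boundary: kept
    make_records("c", "d", sign = 0L),                # unsigned
    make_records("d", "e", directed = FALSE),         # undirected
    make_records("e", "f", curation = 10L))
  out <- filter_curated_interactions(rec, reconstruction_config())
  expect_equal(out$source, c("b", "e"))
  # only the curation filter when signed/directed not required
  cfg2 <- reconstruction_config(require_signed_directed = FALSE)
  out2 <- filter_curated_interactions(rec, cfg2)
  expect_equal(out2$source, c("b", "c", "d", "e"))
  # planted count: 4 of 10 synthetic records meet all criteria
  rec10 <- make_records(letters[1:10], LETTERS[1:10],
                        sign = c(1L, 1L, 0L, -1L, 1L, 0L, -1L, 1L, 1L, 0L),
                        directed = c(rep(TRUE, 8), FALSE, FALSE),
                        curation = c(5L, 2L, 5L, 3L, 1L, 9L, 4L, 3L, 8L, 7L))
  expect_equal(nrow(filter_curated_interactions(rec10)), 4L)
})

test_that("expression node selection is inclusive at the threshold and via proteomes", {
  st <- as_gene_stats(data.frame(
    gene = c("AT", "LOW1", "LOW2", "HIGH"),
    log2fc = 0, adj_p = 1, avg_expr = c(1.0, 0.2, 0.2, 5)))
  sel <- select_expressed_nodes(st, list(c("LOW1")), reconstruction_config())
  expect_true(all(c("AT", "HIGH", "LOW1") %in% sel))
  expect_false("LOW2" %in% sel)
})

test_that("edge sign prediction follows the fold-change product rule", {
  expect_equal(predict_edge_sign(0.7, 0.6, TRUE), 1L)
  expect_equal(predict_edge_sign(0.7, -0.6, TRUE), -1L)
  expect_equal(predict_edge_sign(0.7, 0.6, FALSE), 0L)
  expect_equal(predict_edge_sign(0.7, NA, TRUE), 0L)
  expect_equal(predict_edge_sign(c(1, -1, 2), c(1, 1, NA), c(TRUE, TRUE, TRUE)),
               c(1L, -1L, 0L))
})

test_that("contradiction removal drops only knowable disagreements", {
  net <- signed_digraph(data.frame(
    source = c("a", "b", "c"), target = c("b", "c", "d"),
    sign = c(1L, -1L, 1L)))
  st <- as_gene_stats(data.frame(
    gene = c("a", "b", "c", "d"),
    log2fc = c(1, -1, 1, 0.1),
    adj_p = c(0.001, 0.001, 0.001, 0.8),
    avg_expr = 2))
  out <- remove_contradictions(net, st)
  e <- igraph::as_data_frame(out, what = "edges")
  expect_false(any(e$from == "a" & e$to == "b"))  # curated +1, predicted -1
  expect_true(any(e$from == "b" & e$to == "c"))   # curated -1, predicted -1
  expect_true(any(e$from == "c" & e$to == "d"))   # predicted unknown: kept
  expect_equal(igraph::graph_attr(out, "n_contradictions"), 1L)
})

test_that("contradiction removal never touches edges with a non-significant end", {
  total_removed <- 0L
  for (seed in 1:5) {
    net <- random_digraph(12, 0.25, seed)
    set.seed(seed + 100)
    st <- as_gene_stats(data.frame(
      gene = igraph::V(net)$name,
      log2fc = rnorm(12, 0, 2),
      adj_p = runif(12, 0, 0.1),
      avg_expr = 2))
    out <- remove_contradictions(net, st)
    removed <- igraph::difference(net, out)
    e <- igraph::as_data_frame(removed, what = "edges")
    sig <- setNames(st$significant, st$gene)
    total_removed <- total_removed + nrow(e)
    expect_true(nrow(e) == 0L || all(sig[e$from] & sig[e$to]),
                info = paste("seed", seed))
  }
  expect_gt(total_removed, 0L)  # the property was actually exercised
})

test_that("largest weakly connected component with lexicographic tie-break", {
  big <- make_records(c("a", "b", "c", "d"), c("b", "c", "d", "e"))
  small <- make_records(c("x", "y"), c("y", "z"))
  net <- signed_digraph(rbind(big, small))
  lcc <- largest_connected_component(net)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c", "d", "e"))
  # equal sizes: component containing the smallest label wins
  tie <- signed_digraph(rbind(
    make_records(c("AKT1", "M1", "M2"), c("M1", "M2", "M3")),
    make_records(c("ZYX", "Q1", "Q2"), c("Q1", "Q2", "Q3"))))
  expect_true("AKT1" %in% igraph::V(largest_connected_component(tie))$name)
  # swapping labels flips the winner
  tie2 <- signed_digraph(rbind(
    make_records(c("ZYX", "M1", "M2"), c("M1", "M2", "M3")),
    make_records(c("AKT1", "Q1", "Q2"), c("Q1", "Q2", "Q3"))))
  expect_true("AKT1" %in% igraph::V(largest_connected_component(tie2))$name)
  expect_error(largest_connected_component(
    igraph::make_empty_graph(directed = TRUE)), "empty")
})

test_that("signaling network reconstruction logs planted contradiction removals", {
  set.seed(9)
  n <- 44
  nodes <- sprintf("v%02d", seq_len(n))
  src <- sample(nodes, 90, replace = TRUE)
  tgt <- sample(nodes, 90, replace = TRUE)
  keep <- src != tgt
  rec <- make_records(src[keep], tgt[keep], curation = 5L)
  rec <- rec[!duplicated(paste(rec$source, rec$target)), ]
  # plant exactly 8 contradictions on dedicated nodes: curated +1 edges with
  # significant, discordant fold changes at their ends
  p_src <- sprintf("pS%02d", 1:8)
  p_tgt <- sprintf("pT%02d", 1:8)
  rec <- rbind(rec, make_records(p_src, p_tgt, curation = 5L))
  st <- as_gene_stats(data.frame(
    gene = c(nodes, p_src, p_tgt),
    log2fc = c(rnorm(n, 0, 0.1), rep(2, 8), rep(-2, 8)),
    adj_p = c(rep(0.9, n), rep(1e-5, 16)),
    avg_expr = 2))
  net <- build_signaling_network(rec, st)
  expect_equal(igraph::graph_attr(net, "n_contradictions"), 8L)
  prov <- igraph::graph_attr(net, "provenance")
  expect_true(all(diff(prov$n_edges) <= 0))  # monotone non-increasing
  # determinism
  net2 <- build_signaling_network(rec, st)
  expect_true(igraph::identical_graphs(net, net2))
  # every retained node has an edge
  expect_true(min(igraph::degree(net)) >= 1)
})

test_that("reconstruction fails cleanly when nothing is expressed", {
  rec <- make_records("a", "b")
  st <- as_gene_stats(data.frame(gene = c("a", "b"), log2fc = 0, adj_p = 1,
                                 avg_expr = 0.1))
  expect_error(build_signaling_network(rec, st), "no interactions remain")
})

test_that("DEG subnetwork keeps edges touching a DEG and prunes isolates", {
  net <- signed_digraph(data.frame(
    source = c("d1", "d2", "x", "y", "d3", "u"),
    target = c("x", "y", "y", "z", "z", "w"),
    sign = c(1L, 1L, 1L, 1L, 1L, 1L)))
  st <- as_gene_stats(data.frame(
    gene = c("d1", "d2", "d3", "x", "y", "z", "u", "w"),
    log2fc = c(1, 1, -1, 0, 0, 0, 0, 0),
    adj_p = c(1e-4, 1e-4, 1e-4, 1, 1, 1, 1, 1),
    avg_expr = 2))
  sub <- build_deg_subnetwork(net, st)
  e <- igraph::as_data_frame(sub, what = "edges")
  expect_equal(nrow(e), 3L)           # d1->x, d2->y, d3->z; u->w dropped
  expect_false("u" %in% igraph::V(sub)$name)
  # no DEGs -> empty
  st0 <- st; st0$significant <- FALSE
  expect_equal(igraph::ecount(build_deg_subnetwork(net, st0)), 0L)
  # all nodes DEGs -> same as contradiction-filtered net
  stall <- as_gene_stats(data.frame(
    gene = st$gene, log2fc = 1, adj_p = 1e-4, avg_expr = 2))
  suball <- build_deg_subnetwork(net, stall)
  expect_equal(igraph::ecount(suball),
               igraph::ecount(remove_contradictions(net, stall)))
})

test_that("expanded interactome is undirected, deduplicated, largest component", {
  rec <- rbind(
    make_records("a", "b", directed = TRUE),
    make_records("b", "a", directed = TRUE),     # reverse duplicate
    make_records(c("b", "c", "d", "a", "e", "f", "g", "e", "f", "h"),
                 c("c", "d", "e", "d", "f", "g", "e", "a", "a", "i"),
                 directed = FALSE, sign = 0L, curation = 0L))
  st <- as_gene_stats(data.frame(gene = letters[1:9], log2fc = 0, adj_p = 1,
                                 avg_expr = 2))
  net <- build_expanded_interactome(rec, st)
  expect_false(igraph::is_directed(net))
  e <- igraph::as_data_frame(net, what = "edges")
  expect_equal(sum((e$from == "a" & e$to == "b") |
                     (e$from == "b" & e$to == "a")), 1L)
  expect_false("h" %in% igraph::V(net)$name)  # detached pair dropped
  expect_setequal(igraph::V(net)$name, c("a", "b", "c", "d", "e", "f", "g"))
})
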