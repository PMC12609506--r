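#' Configuration for network reconstruction
#'
#' @param min_curation Minimum curation effort for an interaction to be kept
#'   (inclusive, default 3).
#' @param expr_threshold Minimum average expression for a node to count as
#'   expressed (inclusive, default 1).
#' @param fc_threshold,p_threshold DEG thresholds (strict, defaults 0.58 and
#'   0.05).
#' @param require_signed_directed Keep only directed interactions with a
#'   non-zero sign (default TRUE; switched off for the expanded interactome).
#' @return A list of class `tep_recon_config`.
#' @export
reconstruction_config <- function(min_curation = 3, expr_threshold = 1,
                                  fc_threshold = 0.58, p_threshold = 0.05,
                                  require_signed_directed = TRUE) {
  stopifnot(min_curation >= 0, expr_threshold > 0, fc_threshold > 0,
            p_threshold > 0)
  structure(list(min_curation = min_curation, expr_threshold = expr_threshold,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 require_signed_directed = require_signed_directed),
            class = "tep_recon_config")
}

#' Keep only well-curated (and optionally signed, directed) interactions
#'
#' @param records Interaction records.
#' @param cfg A [reconstruction_config()].
#' @return The filtered records.
#' @export
filter_curated_interactions <- function(records,
                                        cfg = reconstruction_config()) {
  keep <- records$curation_effort >= cfg$min_curation
  if (isTRUE(cfg$require_signed_directed)) {
    keep <- keep & records$is_directed & records$sign != 0L
  }
  records[keep, , drop = FALSE]
}

#' Select nodes expressed in platelets
#'
#' A gene is selected when its average expression is at least
#' `cfg$expr_threshold` or it appears in any of the supplied protein-presence
#' sets (proteomics detection rescues low-expression genes).
#'
#' @param stats Gene statistics table from [as_gene_stats()].
#' @param proteome_sets List of character vectors of detected protein symbols.
#' @param cfg A [reconstruction_config()].
#' @return Character vector of selected gene symbols.
#' @export
select_expressed_nodes <- function(stats, proteome_sets = list(),
                                   cfg = reconstruction_config()) {
  stopifnot(nrow(stats) > 0L)
  detected <- unique(unlist(proteome_sets, use.names = FALSE))
  expressed <- !is.na(stats$avg_expr) & stats$avg_expr >= cfg$expr_threshold
  sort(unique(c(stats$gene[expressed], intersect(stats$gene, detected),
                setdiff(detected, stats$gene))))
}

#' Predict the sign of an interaction from fold changes
#'
#' The predicted sign is the sign of the product of the two endpoints' log2
#' fold changes, but only when both genes are significantly regulated with a
#' non-zero fold change; otherwise the prediction is 0 (unknown), because the
#' regulation of non-significant genes is uninformative.
#'
#' @param fc_source,fc_target log2 fold changes (may be `NA`).
#' @param both_significant Logical; are both endpoints significant DEGs?
#' @return Integer vector in \{-1, 0, +1\}.
#' @export
predict_edge_sign <- function(fc_source, fc_target, both_significant) {
  prod <- fc_source * fc_target
  out <- ifelse(both_significant & !is.na(prod) & prod != 0,
                sign(prod), 0L)
  as.integer(out)
}

edge_sign_prediction <- function(net, stats) {
  edges <- igraph::as_data_frame(net, what = "edges")
  fc <- setNames(stats$log2fc, stats$gene)
  sig <- setNames(stats$significant, stats$gene)
  fc_s <- fc[edges$from]
  fc_t <- fc[edges$to]
  both <- !is.na(sig[edges$from]) & sig[edges$from] &
    !is.na(sig[edges$to]) & sig[edges$to]
  predict_edge_sign(fc_s, fc_t, both)
}

#' Remove sign contradictions between curated and predicted interactions
#'
#' An edge is removed iff its curated sign and its fold-change-predicted sign
#' are both known (non-zero) and disagree. Unknown predictions (either
#' endpoint non-significant) can never contradict.
#'
#' @param net Signed digraph with edge attribute `sign`.
#' @param stats Gene statistics table.
#' @return The filtered graph, with attribute `n_contradictions` recording
#'   the number of removed edges.
#' @export
remove_contradictions <- function(net, stats) {
  if (igraph::ecount(net) == 0L) {
    return(igraph::set_graph_attr(net, "n_contradictions", 0L))
  }
  predicted <- edge_sign_prediction(net, stats)
  curated <- igraph::E(net)$sign
  drop <- predicted != 0L & curated != 0L & predicted != curated
  out <- igraph::delete_edges(net, which(drop))
  igraph::set_graph_attr(out, "n_contradictions", sum(drop))
}

#' Largest weakly connected component
#'
#' Returns the induced subgraph on the largest (weakly) connected component.
#' Size ties break toward the component containing the lexicographically
#' smallest node name.
#'
#' @param net igraph graph.
#' @return The induced subgraph.
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("network is empty")
  comp <- igraph::components(net, mode = "weak")
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  if (length(cand) > 1L) {
    mins <- vapply(cand, function(k) {
      min(igraph::V(net)$name[comp$membership == k])
    }, character(1L))
    cand <- cand[order(mins)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == cand[1L]))
}

provenance_row <- function(step, net) {
  data.frame(step = step, n_nodes = igraph::vcount(net),
             n_edges = igraph::ecount(net), stringsAsFactors = FALSE)
}

#' Build the platelet signaling network
#'
#' Runs the reconstruction steps in order: curation/sign/direction filter,
#' expression-based node selection, duplicate collapse, contradiction
#' removal, and reduction to the largest weakly connected component. A
#' provenance log of node/edge counts after every step is attached as the
#' graph attribute `provenance`.
#'
#' @param records Interaction records from [parse_interaction_table()].
#' @param stats Gene statistics table.
#' @param proteome_sets List of protein-presence symbol sets.
#' @param cfg A [reconstruction_config()].
#' @return Signed digraph with graph attributes `provenance` and
#'   `n_contradictions`.
#' @export
build_signaling_network <- function(records, stats, proteome_sets = list(),
                                    cfg = reconstruction_config()) {
  curated <- filter_curated_interactions(records, cfg)
  nodes <- select_expressed_nodes(stats, proteome_sets, cfg)
  expressed <- curated[curated$source %in% nodes & curated$target %in% nodes,
                       , drop = FALSE]
  if (nrow(expressed) == 0L) {
    stop("no interactions remain after curation and expression filtering")
  }
  net <- signed_digraph(expressed)
  prov <- rbind(
    data.frame(step = "input", n_nodes = length(unique(c(records$source,
                                                         records$target))),
               n_edges = nrow(records), stringsAsFactors = FALSE),
    data.frame(step = "curation_filter",
               n_nodes = length(unique(c(curated$source, curated$target))),
               n_edges = nrow(curated), stringsAsFactors = FALSE),
    provenance_row("expression_filter", net)
  )
  net <- remove_contradictions(net, stats)
  prov <- rbind(prov, provenance_row("contradiction_removal", net))
  net <- igraph::delete_vertices(net, which(igraph::degree(net) == 0L))
  if (igraph::vcount(net) == 0L) {
    stop("no connected nodes remain after contradiction removal")
  }
  lcc <- largest_connected_component(net)
  prov <- rbind(prov, provenance_row("largest_component", lcc))
  lcc <- igraph::set_graph_attr(lcc, "provenance", prov)
  lcc
}

deg_genes <- function(stats) stats$gene[stats$significant]

#' Extract the subnetwork around differentially expressed genes
#'
#' Keeps the edges with at least one DEG endpoint, re-applies contradiction
#' removal, and prunes nodes left without any edge.
#'
#' @param net Signaling network from [build_signaling_network()].
#' @param stats Gene statistics table.
#' @return Signed digraph (possibly empty).
#' @export
build_deg_subnetwork <- function(net, stats) {
  degs <- deg_genes(stats)
  edges <- igraph::as_data_frame(net, what = "edges")
  keep <- edges$from %in% degs | edges$to %in% degs
  sub <- igraph::subgraph_from_edges(net, which(keep), delete.vertices = TRUE)
  sub <- remove_contradictions(sub, stats)
  igraph::delete_vertices(sub, which(igraph::degree(sub) == 0L))
}

#' Build the expanded undirected platelet interactome
#'
#' Incorporates all interactions regardless of direction, sign or curation
#' effort, applies the same expression/proteomics node filter, deduplicates
#' unordered pairs, and keeps the largest connected component.
#'
#' @inheritParams build_signaling_network
#' @return igraph undirected graph with a `provenance` attribute.
#' @export
build_expanded_interactome <- function(records, stats, proteome_sets = list(),
                                       cfg = reconstruction_config()) {
  nodes <- select_expressed_nodes(stats, proteome_sets, cfg)
  expressed <- records[records$source %in% nodes & records$target %in% nodes,
                       , drop = FALSE]
  if (nrow(expressed) == 0L) {
    stop("no interactions remain after expression filtering")
  }
  net <- undirected_network(expressed)
  net <- igraph::delete_vertices(net, which(igraph::degree(net) == 0L))
  lcc <- largest_connected_component(net)
  prov <- rbind(
    data.frame(step = "input",
               n_nodes = length(unique(c(records$source, records$target))),
               n_edges = nrow(records), stringsAsFactors = FALSE),
    provenance_row("expression_filter", net),
    provenance_row("largest_component", lcc)
  )
  igraph::set_graph_attr(lcc, "provenance", prov)
}
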