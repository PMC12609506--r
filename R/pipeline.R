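#' Run the full target-discovery pipeline
#'
#' Orchestrates the network-based target-discovery strategies end to end:
#' signaling-network reconstruction, controllability classification,
#' fold-change-weighted controllable subnetwork (cheapest paths from
#' critical to indispensable nodes), node weights and proximity gene scores
#' on the expanded undirected interactome with its top-decile score
#' subnetwork, and drug/combination ranking against the indispensable nodes
#' of the controllable subnetwork. Every stochastic step derives its seed
#' from `seed`, so a rerun with the same inputs is identical.
#'
#' Inputs may be file paths (parsed with the package readers) or already
#' parsed data.frames. An empty or missing drug table degrades gracefully:
#' the pipeline completes through scoring and the drug stage reports no
#' candidates.
#'
#' @param interactions Interaction table path or data.frame.
#' @param gene_stats Gene statistics path or data.frame.
#' @param proteome_sets List of protein-presence symbol vectors.
#' @param drugs Drug-target table path or data.frame, or `NULL`.
#' @param drug_interactions Drug-interaction pair path/data.frame or `NULL`.
#' @param cfg A [reconstruction_config()].
#' @param seed Integer seed for control-capacity sampling.
#' @param n_samples Control-capacity samples.
#' @param s Knode neighborhood radius.
#' @param fraction Top fraction for score/weight node selection.
#' @param anchor Anchor drug for combinations (default: top-ranked drug).
#' @param max_combo_size Maximum combination size including the anchor.
#' @param centrality_max_nodes Compute control centrality for the
#'   critical/indispensable nodes only when the network has at most this
#'   many nodes (the assignment solve is cubic per node).
#' @param extra_gene_sets Optional named list of precomputed gene sets
#'   (e.g. module or pathway hits from expression-only strategies); they are
#'   only intersected with drug targets for the report, not re-derived.
#' @param out_dir Optional directory for per-stage TSV/GraphML artifacts.
#' @return Object of class `tep_report` (a list of per-stage results).
#' @export
run_pipeline <- function(interactions, gene_stats, proteome_sets = list(),
                         drugs = NULL, drug_interactions = NULL,
                         cfg = reconstruction_config(), seed = 1L,
                         n_samples = 200L, s = 2, fraction = 0.10,
                         anchor = NULL, max_combo_size = 3L,
                         centrality_max_nodes = 150L,
                         extra_gene_sets = NULL, out_dir = NULL) {
  records <- if (is.character(interactions))
    parse_interaction_table(interactions) else interactions
  stats <- if (is.character(gene_stats))
    parse_gene_stats(gene_stats, fc_threshold = cfg$fc_threshold,
                     p_threshold = cfg$p_threshold) else gene_stats
  drug_tab <- if (is.character(drugs)) parse_drug_table(drugs) else drugs
  ddi <- if (is.character(drug_interactions))
    parse_drug_interactions(drug_interactions) else drug_interactions

  net <- build_signaling_network(records, stats, proteome_sets, cfg)
  prov <- igraph::graph_attr(net, "provenance")

  profiles <- node_control_profiles(net, n_samples = n_samples, seed = seed)
  n_drivers <- attr(profiles, "n_drivers")
  topo <- topology_metrics(net)
  profiles <- merge(profiles, topo, by = "node", sort = TRUE)

  critical <- profiles$node[profiles$mds_class == "critical"]
  indisp <- profiles$node[profiles$removal_class == "indispensable"]
  if (igraph::vcount(net) <= centrality_max_nodes) {
    focus <- union(critical, indisp)
    cc <- control_centrality(net, focus)
    profiles$control_centrality <- unname(cc[profiles$node])
  }

  comparisons <- NULL
  if (length(critical) > 0L && length(indisp) > 0L) {
    labels <- setNames(rep(NA_character_, nrow(profiles)), profiles$node)
    labels[critical] <- "critical"
    labels[indisp] <- "indispensable"
    comparisons <- do.call(rbind, lapply(
      c("degree", "betweenness", "closeness", "clustering_coefficient"),
      function(mn) {
        cmp <- compare_classes(profiles, labels, mn, "indispensable",
                               "critical")
        data.frame(metric = mn, U = cmp$U, p_value = cmp$p_value,
                   stringsAsFactors = FALSE)
      }))
  }

  controllable <- NULL
  if (length(critical) > 0L && length(indisp) > 0L) {
    weighted <- compute_edge_weights(net, stats)
    controllable <- extract_controllable_subnetwork(weighted, critical,
                                                    indisp)
  }

  expanded <- build_expanded_interactome(records, stats, proteome_sets, cfg)
  node_w <- compute_node_weights(expanded, stats)
  scores <- compute_gene_scores(expanded, node_w, s = s)
  top_w <- select_top_fraction(node_w, fraction)
  top_s <- select_top_fraction(scores, fraction)
  score_sub <- extract_score_subnetwork(expanded, top_s, top_w)

  deg_sub <- build_deg_subnetwork(net, stats)

  drug_section <- list(status = "no candidates", ranking = NULL,
                       combinations = NULL)
  if (!is.null(drug_tab) && nrow(drug_tab) > 0L) {
    target_nodes <- if (!is.null(controllable) &&
                          igraph::vcount(controllable$graph) > 0L) {
      intersect(indisp, igraph::V(controllable$graph)$name)
    } else indisp
    actionable <- filter_actionable(drug_tab)
    mapping <- map_targets(target_nodes, actionable)
    if (length(mapping) > 0L) {
      ranking <- rank_drugs(mapping)
      anchor_drug <- if (is.null(anchor)) ranking$drug[1L] else anchor
      prof_for_rank <- if ("control_centrality" %in% names(profiles)) {
        pr <- profiles[, c("node", "control_centrality", "betweenness")]
        pr$control_centrality[is.na(pr$control_centrality)] <- 0
        pr
      } else NULL
      combos <- rank_combinations(
        actionable[actionable$target %in% target_nodes, , drop = FALSE],
        anchor = anchor_drug, interactions = ddi,
        node_profiles = prof_for_rank,
        max_size = max_combo_size)
      drug_section <- list(status = "ok", ranking = ranking,
                           combinations = combos, anchor = anchor_drug,
                           target_nodes = target_nodes)
    }
  }

  gene_set_overlap <- NULL
  if (!is.null(extra_gene_sets) && !is.null(drug_tab)) {
    gene_set_overlap <- lapply(extra_gene_sets, function(gs) {
      sort(unique(drug_tab$target[drug_tab$target %in% gs]))
    })
  }

  report <- structure(list(
    seed = seed,
    config = cfg,
    provenance = prov,
    n_contradictions = igraph::graph_attr(net, "n_contradictions"),
    network = net,
    n_drivers = n_drivers,
    profiles = profiles,
    class_counts = list(
      mds = table(factor(profiles$mds_class,
                         levels = c("critical", "intermittent",
                                    "redundant"))),
      removal = table(factor(profiles$removal_class,
                             levels = c("indispensable", "neutral",
                                        "dispensable")))),
    comparisons = comparisons,
    controllable_subnetwork = controllable,
    deg_subnetwork = deg_sub,
    expanded_interactome = expanded,
    node_weights = node_w,
    gene_scores = scores,
    top_weight_nodes = top_w,
    top_score_nodes = top_s,
    score_subnetwork = score_sub,
    drugs = drug_section,
    gene_set_overlap = gene_set_overlap
  ), class = "tep_report")

  if (!is.null(out_dir)) write_artifacts(report, out_dir)
  report
}

write_artifacts <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  tsv(report$provenance, "provenance.tsv")
  prof <- report$profiles
  num <- vapply(prof, is.numeric, logical(1L))
  prof[num] <- lapply(prof[num], function(x) round(x, 6))
  tsv(prof, "node_profiles.tsv")
  export_network(report$network, file.path(out_dir, "signaling_network.graphml"),
                 "graphml")
  if (!is.null(report$controllable_subnetwork) &&
        igraph::vcount(report$controllable_subnetwork$graph) > 0L) {
    export_network(report$controllable_subnetwork$graph,
                   file.path(out_dir, "controllable_subnetwork.graphml"),
                   "graphml")
  }
  sc <- data.frame(node = names(report$gene_scores),
                   weight = round(unname(report$node_weights[
                     names(report$gene_scores)]), 6),
                   gene_score = round(unname(report$gene_scores), 6))
  tsv(sc, "gene_scores.tsv")
  if (!is.null(report$drugs$ranking)) tsv(report$drugs$ranking,
                                          "drug_ranking.tsv")
  if (!is.null(report$drugs$combinations)) {
    comb <- report$drugs$combinations
    comb$strength_score <- round(comb$strength_score, 6)
    tsv(comb, "drug_combinations.tsv")
  }
  invisible(out_dir)
}

#' @export
print.tep_report <- function(x, ...) {
  cat("tepnet pipeline report\n")
  cat("  network:", igraph::vcount(x$network), "nodes,",
      igraph::ecount(x$network), "edges;", x$n_drivers, "driver(s)\n")
  cat("  MDS classes:",
      paste(names(x$class_counts$mds), as.integer(x$class_counts$mds),
            sep = "=", collapse = ", "), "\n")
  cat("  removal classes:",
      paste(names(x$class_counts$removal),
            as.integer(x$class_counts$removal), sep = "=", collapse = ", "),
      "\n")
  if (!is.null(x$controllable_subnetwork)) {
    cat("  controllable subnetwork:",
        igraph::vcount(x$controllable_subnetwork$graph), "nodes,",
        igraph::ecount(x$controllable_subnetwork$graph), "edges\n")
  }
  cat("  drug stage:", x$drugs$status, "\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Markdown gives one section per stage (network sizes, class counts, top
#' targets and drugs, combination table); JSON is a faithful round-trippable
#' summary of the same content.
#'
#' @param report A `tep_report` from [run_pipeline()].
#' @param path Output file path.
#' @param format `"markdown"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("markdown", "json")) {
  format <- match.arg(format)
  top_targets <- head(report$profiles[
    order(-as.integer(report$profiles$removal_class == "indispensable"),
          -report$profiles$betweenness), "node"], 10L)
  summary_list <- list(
    seed = report$seed,
    network = list(nodes = igraph::vcount(report$network),
                   edges = igraph::ecount(report$network),
                   n_drivers = report$n_drivers,
                   n_contradictions_removed = report$n_contradictions),
    provenance = report$provenance,
    mds_classes = as.list(setNames(as.integer(report$class_counts$mds),
                                   names(report$class_counts$mds))),
    removal_classes = as.list(setNames(
      as.integer(report$class_counts$removal),
      names(report$class_counts$removal))),
    controllable_subnetwork = if (is.null(report$controllable_subnetwork))
      NULL else list(
        nodes = igraph::vcount(report$controllable_subnetwork$graph),
        edges = igraph::ecount(report$controllable_subnetwork$graph)),
    top_targets = top_targets,
    top_weight_nodes = report$top_weight_nodes,
    top_score_nodes = report$top_score_nodes,
    drugs = list(
      status = report$drugs$status,
      ranking = if (is.null(report$drugs$ranking)) NULL else
        head(report$drugs$ranking, 10L),
      combinations = if (is.null(report$drugs$combinations)) NULL else
        head(report$drugs$combinations, 10L))
  )
  if (format == "json") {
    jsonlite::write_json(summary_list, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", pretty = TRUE)
    return(invisible(path))
  }
  md <- c("# Pipeline report", "",
          "## Network reconstruction", "",
          paste0("- nodes: ", summary_list$network$nodes),
          paste0("- edges: ", summary_list$network$edges),
          paste0("- contradictory edges removed: ",
                 summary_list$network$n_contradictions_removed),
          "",
          paste(utils::capture.output(print(report$provenance)),
                collapse = "\n"),
          "", "## Controllability", "",
          paste0("- drivers: ", report$n_drivers),
          paste0("- MDS classes: ",
                 paste(names(report$class_counts$mds),
                       as.integer(report$class_counts$mds), sep = "=",
                       collapse = ", ")),
          paste0("- removal classes: ",
                 paste(names(report$class_counts$removal),
                       as.integer(report$class_counts$removal), sep = "=",
                       collapse = ", ")),
          "", "## Controllable subnetwork", "",
          if (is.null(summary_list$controllable_subnetwork))
            "- not constructed (no critical or no indispensable nodes)"
          else paste0("- ", summary_list$controllable_subnetwork$nodes,
                      " nodes, ", summary_list$controllable_subnetwork$edges,
                      " edges"),
          "", "## Gene scores", "",
          paste0("- top-weight nodes: ",
                 paste(summary_list$top_weight_nodes, collapse = ", ")),
          paste0("- top-score nodes: ",
                 paste(summary_list$top_score_nodes, collapse = ", ")),
          "", "## Ranked targets", "",
          paste0("- ", paste(summary_list$top_targets, collapse = ", ")),
          "", "## Drugs", "",
          paste0("- status: ", report$drugs$status))
  if (!is.null(report$drugs$ranking)) {
    md <- c(md, "",
            paste(utils::capture.output(print(head(report$drugs$ranking,
                                                   10L))), collapse = "\n"))
  }
  if (!is.null(report$drugs$combinations)) {
    md <- c(md, "", "### Combinations", "",
            paste(utils::capture.output(
              print(head(report$drugs$combinations[, c(
                "members", "n_covered", "strength_score",
                "control_score")], 10L))), collapse = "\n"))
  }
  writeLines(md, path)
  invisible(path)
}
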