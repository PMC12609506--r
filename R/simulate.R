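#' Configuration for the synthetic input generator
#'
#' Defaults emulate the scale and statistical structure of a curated human
#' signaling snapshot restricted to one cell type: a sparse directed network
#' with a heavy-tailed out-degree distribution, a long-tailed curation-count
#' distribution in which only a minority of interactions are well curated, a
#' gene table where a minority of genes are genuinely differentially
#' expressed with effect sizes comfortably above the DEG cutoff, and a drug
#' table biased toward high-degree (druggable hub) targets.
#'
#' @param seed Base seed; all generators are pure functions of (cfg, seed).
#' @param n_nodes,n_edges Raw interactome size (default 400 nodes, 8000
#'   interactions). Deliberately much denser than the final network: the
#'   curation/sign/direction filter keeps only a small, well-curated core
#'   and the expression filter then restricts to expressed genes, mirroring
#'   how a signaling network is distilled from a bulk interactome snapshot.
#' @param frac_directed_signed Fraction of interactions that are directed
#'   and signed (the rest are undirected/unsigned, only usable by the
#'   expanded interactome).
#' @param curation_size,curation_mu Negative-binomial parameters of the
#'   curation-effort counts (long-tailed; defaults put roughly 10% of
#'   interactions at a curation effort of 3 or more).
#' @param frac_significant Fraction of genes with a planted expression
#'   change.
#' @param de_effect_mean,de_effect_sd Absolute log2FC distribution of
#'   planted DEGs.
#' @param null_sd log2FC spread of unregulated genes.
#' @param n_drugs,targets_per_drug,frac_approved,frac_known_action,frac_interacting_pairs
#'   Drug-table parameters.
#' @return List of class `tep_sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_nodes = 400L, n_edges = 8000L,
                              frac_directed_signed = 0.55,
                              curation_size = 0.35, curation_mu = 0.9,
                              frac_significant = 0.15,
                              de_effect_mean = 1.2, de_effect_sd = 0.4,
                              null_sd = 0.15,
                              n_drugs = 40L, targets_per_drug = 3L,
                              frac_approved = 0.7, frac_known_action = 0.7,
                              frac_interacting_pairs = 0.1) {
  fracs <- c(frac_directed_signed, frac_significant, frac_approved,
             frac_known_action, frac_interacting_pairs)
  stopifnot(all(fracs >= 0 & fracs <= 1), n_nodes >= 2)
  if (n_edges > as.double(n_nodes)^2) {
    stop("infeasible edge count: n_edges exceeds n_nodes^2")
  }
  structure(as.list(environment())[c(
    "seed", "n_nodes", "n_edges", "frac_directed_signed", "curation_size",
    "curation_mu", "frac_significant", "de_effect_mean", "de_effect_sd",
    "null_sd", "n_drugs", "targets_per_drug", "frac_approved",
    "frac_known_action", "frac_interacting_pairs")],
    class = "tep_sim_config")
}

sim_node_names <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate a curated interactome
#'
#' Draws directed edges with a heavy-tailed out-degree distribution
#' (preferential attachment on out-degree: each new edge picks its source
#' with probability proportional to out-degree + 1 and its target
#' uniformly), assigns directedness/sign with probability
#' `frac_directed_signed`, and curation efforts from a negative binomial.
#'
#' @param cfg A [simulation_config()].
#' @return Interaction-record data.frame (see [parse_interaction_table()]).
#' @export
simulate_interactome <- function(cfg) {
  nodes <- sim_node_names(cfg$n_nodes)
  with_local_seed(cfg$seed, {
    n <- cfg$n_nodes
    outdeg <- rep(0L, n)
    seen <- new.env(parent = emptyenv())
    src <- integer(cfg$n_edges)
    tgt <- integer(cfg$n_edges)
    k <- 0L
    attempts <- 0L
    while (k < cfg$n_edges && attempts < 50L * cfg$n_edges) {
      attempts <- attempts + 1L
      s <- sample.int(n, 1L, prob = outdeg + 1)
      t <- sample.int(n, 1L)
      if (s == t) next
      key <- paste0(s, "_", t)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      k <- k + 1L
      src[k] <- s
      tgt[k] <- t
      outdeg[s] <- outdeg[s] + 1L
    }
    if (k < cfg$n_edges) stop("could not place the requested edge count")
    directed <- runif(k) < cfg$frac_directed_signed
    sgn <- ifelse(directed, ifelse(runif(k) < 0.5, 1L, -1L), 0L)
    data.frame(
      source = nodes[src], target = nodes[tgt],
      is_directed = directed, sign = sgn,
      curation_effort = rnbinom(k, size = cfg$curation_size,
                                mu = cfg$curation_mu),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a differential-expression gene table
#'
#' Plants `frac_significant` of the genes with absolute log2 fold changes
#' from `Normal(de_effect_mean, de_effect_sd)` (random sign) and near-zero
#' raw p-values; the rest get null fold changes (`Normal(0, null_sd)`) and
#' uniform raw p-values. Raw p-values are Benjamini-Hochberg adjusted inside
#' the simulator, so the output table matches what a differential-expression
#' tool would emit and must never be re-adjusted downstream. Average
#' expression is log-normal.
#'
#' @param cfg A [simulation_config()].
#' @param nodes Character vector of gene symbols.
#' @return Gene statistics data.frame (see [as_gene_stats()]), with the
#'   planted truth in the `planted` column.
#' @export
simulate_gene_stats <- function(cfg, nodes) {
  stopifnot(length(nodes) > 0L)
  with_local_seed(cfg$seed + 1L, {
    n <- length(nodes)
    planted <- runif(n) < cfg$frac_significant
    lfc <- numeric(n)
    lfc[planted] <- sample(c(-1, 1), sum(planted), replace = TRUE) *
      abs(rnorm(sum(planted), cfg$de_effect_mean, cfg$de_effect_sd))
    lfc[!planted] <- rnorm(sum(!planted), 0, cfg$null_sd)
    p_raw <- numeric(n)
    p_raw[planted] <- rbeta(sum(planted), 0.05, 20) * 1e-4
    p_raw[!planted] <- runif(sum(!planted))
    stats <- as_gene_stats(data.frame(
      gene = nodes,
      log2fc = lfc,
      adj_p = p.adjust(p_raw, method = "BH"),
      avg_expr = rlnorm(n, meanlog = 0.5, sdlog = 1),
      stringsAsFactors = FALSE))
    stats$planted <- planted[match(stats$gene, nodes)]
    stats
  })
}

#' Simulate drug-target and drug-interaction tables
#'
#' Drug target sets are biased toward high-degree nodes (hubs are
#' empirically more druggable); pass a plain character vector to switch the
#' bias off. Inhibition constants are log-uniform on \[1, 1e4\] nM,
#' known for half the pairs. Interaction pairs are sampled without
#' self-pairs.
#'
#' @param cfg A [simulation_config()].
#' @param nodes Either a character vector of node names (uniform targeting)
#'   or a named numeric vector of node degrees (degree-biased targeting).
#' @return List with `drugs` (drug-target data.frame) and `interactions`
#'   (pair data.frame).
#' @export
simulate_drug_tables <- function(cfg, nodes) {
  stopifnot(length(nodes) > 0L)
  if (is.numeric(nodes)) {
    stopifnot(!is.null(names(nodes)))
    symbols <- names(nodes)
    prob <- nodes + 1
  } else {
    symbols <- nodes
    prob <- rep(1, length(nodes))
  }
  with_local_seed(cfg$seed + 2L, {
    drug_names <- sprintf("DRUG%02d", seq_len(cfg$n_drugs))
    rows <- lapply(seq_len(cfg$n_drugs), function(i) {
      k <- min(length(symbols), max(1L, rpois(1L, cfg$targets_per_drug)))
      tg <- sample(symbols, k, prob = prob)
      data.frame(drug = drug_names[i], target = tg, stringsAsFactors = FALSE)
    })
    drugs <- do.call(rbind, rows)
    per_drug_approved <- setNames(runif(cfg$n_drugs) < cfg$frac_approved,
                                  drug_names)
    per_drug_known <- setNames(runif(cfg$n_drugs) < cfg$frac_known_action,
                               drug_names)
    drugs$approved <- unname(per_drug_approved[drugs$drug])
    drugs$known_action <- unname(per_drug_known[drugs$drug])
    ki <- 10^runif(nrow(drugs), 0, 4)
    ki[runif(nrow(drugs)) < 0.5] <- NA_real_
    drugs$ki_nM <- ki
    all_pairs <- t(combn(drug_names, 2L))
    n_int <- round(cfg$frac_interacting_pairs * nrow(all_pairs))
    idx <- if (n_int > 0L) sample.int(nrow(all_pairs), n_int) else integer(0)
    interactions <- data.frame(drug_a = all_pairs[idx, 1L],
                               drug_b = all_pairs[idx, 2L],
                               stringsAsFactors = FALSE)
    list(drugs = drugs, interactions = interactions)
  })
}

#' Write a full set of simulated pipeline inputs
#'
#' Writes `interactions.tsv`, `gene_stats.tsv`, `drugs.tsv` and
#' `drug_interactions.tsv` into a directory, in the formats the parsers
#' read.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_inputs <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  records <- simulate_interactome(cfg)
  stats <- simulate_gene_stats(cfg, sim_node_names(cfg$n_nodes))
  deg <- table(c(records$source, records$target))
  degv <- setNames(as.numeric(deg), names(deg))
  dt <- simulate_drug_tables(cfg, degv)
  paths <- c(
    interactions = file.path(dir, "interactions.tsv"),
    gene_stats = file.path(dir, "gene_stats.tsv"),
    drugs = file.path(dir, "drugs.tsv"),
    drug_interactions = file.path(dir, "drug_interactions.tsv"))
  irec <- data.frame(
    source_genesymbol = records$source,
    target_genesymbol = records$target,
    is_directed = as.integer(records$is_directed),
    is_stimulation = as.integer(records$sign == 1L),
    is_inhibition = as.integer(records$sign == -1L),
    curation_effort = records$curation_effort)
  write.table(irec, paths["interactions"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  gs <- data.frame(gene = stats$gene, logFC = stats$log2fc,
                   adj.P.Val = stats$adj_p, AveExpr = stats$avg_expr)
  write.table(gs, paths["gene_stats"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dt$drugs, paths["drugs"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dt$interactions, paths["drug_interactions"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
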