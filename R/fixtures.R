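#' Built-in worked-example fixtures
#'
#' Loads the worked-example reference tables shipped with the package and a
#' small library of named toy graphs used throughout the documentation and
#' tests:
#'
#' * `drug_targets`: approved drugs targeting the indispensable nodes of a
#'   controllable subnetwork (drug-target long table).
#' * `high_score_nodes`: targetable high-score nodes of an expanded platelet
#'   interactome (degree, log2FC, node weight, gene score, drugs; `log2fc`
#'   is `NA` for non-significant rows, printed as `--` in the source table).
#' * `toy_graphs`: `chain3` (a->b->c), `star4` (h->a, h->b, h->c), `cycle3`
#'   (a->b->c->a), and `detour` (a direct edge bypassed by a two-step detour
#'   that becomes cheaper once fold-change weights are attached).
#'
#' @return List with `drug_targets`, `high_score_nodes`, `toy_graphs`.
#' @export
load_reference_fixtures <- function() {
  drug_targets <- parse_drug_table(
    system.file("extdata", "reference_drug_targets.tsv",
                package = "tepnet", mustWork = TRUE))
  raw <- read.delim(
    system.file("extdata", "reference_high_score_nodes.tsv",
                package = "tepnet", mustWork = TRUE),
    stringsAsFactors = FALSE, colClasses = "character")
  high_score_nodes <- data.frame(
    gene = raw$gene,
    degree = as.integer(raw$degree),
    log2fc = num_or_na(raw$log2fc, "log2FC"),
    weight = as.numeric(raw$weight),
    gene_score = as.numeric(raw$gene_score),
    drugs = raw$drugs,
    stringsAsFactors = FALSE)
  toy <- list(
    chain3 = signed_digraph(data.frame(
      source = c("a", "b"), target = c("b", "c"), sign = c(1L, 1L))),
    star4 = signed_digraph(data.frame(
      source = c("h", "h", "h"), target = c("a", "b", "c"),
      sign = c(1L, 1L, -1L))),
    cycle3 = signed_digraph(data.frame(
      source = c("a", "b", "c"), target = c("b", "c", "a"),
      sign = c(1L, 1L, 1L))),
    detour = signed_digraph(data.frame(
      source = c("a", "a", "m"), target = c("d", "m", "d"),
      sign = c(1L, 1L, 1L)))
  )
  list(drug_targets = drug_targets, high_score_nodes = high_score_nodes,
       toy_graphs = toy)
}

#' Gene statistics table implied by the high-score node fixture
#'
#' Rebuilds a gene statistics table from the `high_score_nodes` fixture. The
#' source table encodes significance by whether a log2 fold change is
#' printed at all (`--` marks non-significant rows, whose node weight is
#' exactly 0), so the flag is derived from the presence of a value: printed
#' rows get a tiny adjusted p and a zero fold-change threshold, `--` rows
#' stay non-significant. Used to recompute the printed node weights.
#'
#' @param high_score_nodes The `high_score_nodes` element of
#'   [load_reference_fixtures()].
#' @return Gene statistics data.frame.
#' @export
high_score_gene_stats <- function(high_score_nodes) {
  as_gene_stats(data.frame(
    gene = high_score_nodes$gene,
    log2fc = high_score_nodes$log2fc,
    adj_p = ifelse(is.na(high_score_nodes$log2fc), NA_real_, 1e-6),
    avg_expr = 1,
    stringsAsFactors = FALSE),
    fc_threshold = 0)
}
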