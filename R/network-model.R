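#' Column dialect for curated interaction tables
#'
#' Maps the canonical field names used by the package onto the column headers
#' of an OmniPath-style export. Override individual entries to read tables
#' with different headers.
#'
#' @param source,target,is_directed,is_stimulation,is_inhibition,curation_effort
#'   Column names in the file.
#' @return A named list of column names.
#' @export
interaction_dialect <- function(source = "source_genesymbol",
                                target = "target_genesymbol",
                                is_directed = "is_directed",
                                is_stimulation = "is_stimulation",
                                is_inhibition = "is_inhibition",
                                curation_effort = "curation_effort") {
  list(source = source, target = target, is_directed = is_directed,
       is_stimulation = is_stimulation, is_inhibition = is_inhibition,
       curation_effort = curation_effort)
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(trimws(as.character(x))) %in% c("1", "true", "t", "yes", "y")
}

#' Read a curated interaction table
#'
#' Parses a tab-delimited interaction export into one record per row with a
#' single sign per interaction: +1 stimulation, -1 inhibition, 0
#' unknown/unsigned. Rows flagged as both stimulating and inhibiting are
#' ambiguous curation and get sign 0 with a warning. Malformed rows (empty
#' endpoint symbols, negative curation counts) are reported with their line
#' numbers and dropped.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect Header map from [interaction_dialect()].
#' @return A data.frame of interaction records with columns `source`,
#'   `target`, `is_directed`, `sign`, `curation_effort`.
#' @export
parse_interaction_table <- function(path, dialect = interaction_dialect()) {
  if (!file.exists(path)) stop("interaction table not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("interaction table is empty: ", path)
  for (field in c("source", "target")) {
    if (!dialect[[field]] %in% names(raw)) {
      stop("interaction table is missing mandatory column '",
           dialect[[field]], "' (", field, ")")
    }
  }
  pick <- function(field, default) {
    col <- dialect[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  rec <- data.frame(
    source = trimws(as.character(raw[[dialect$source]])),
    target = trimws(as.character(raw[[dialect$target]])),
    is_directed = as_flag(pick("is_directed", TRUE)),
    stim = as_flag(pick("is_stimulation", FALSE)),
    inhib = as_flag(pick("is_inhibition", FALSE)),
    curation_effort = suppressWarnings(
      as.numeric(pick("curation_effort", 0))),
    stringsAsFactors = FALSE
  )
  bad <- rec$source == "" | rec$target == "" |
    is.na(rec$curation_effort) | rec$curation_effort < 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed interaction row(s) at line(s) ",
            paste(which(bad) + 1L, collapse = ", "))
    rec <- rec[!bad, , drop = FALSE]
  }
  ambiguous <- rec$stim & rec$inhib
  if (any(ambiguous)) {
    warning(sum(ambiguous),
            " row(s) flagged as both stimulation and inhibition; sign set to 0")
  }
  rec$sign <- ifelse(ambiguous, 0L,
                     ifelse(rec$stim, 1L, ifelse(rec$inhib, -1L, 0L)))
  rec$curation_effort <- as.integer(round(rec$curation_effort))
  rownames(rec) <- NULL
  rec[, c("source", "target", "is_directed", "sign", "curation_effort")]
}

missing_tokens <- c("NA", "N/A", "--", "")

num_or_na <- function(x, what) {
  x <- trimws(as.character(x))
  miss <- is.na(x) | x %in% missing_tokens
  out <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(out)
  if (any(bad)) {
    stop("non-numeric ", what, " value(s) that are not a recognized missing ",
         "token: ", paste(unique(x[bad]), collapse = ", "))
  }
  out[miss] <- NA_real_
  out
}

#' Build a gene statistics table from a data.frame
#'
#' Normalizes a per-gene differential-expression table and computes the
#' significance flag: a gene is significant iff its log2 fold change and
#' adjusted p-value are both present, `|log2fc| > fc_threshold` and
#' `adj_p < p_threshold` (strict inequalities, matching the usual DEG call).
#' Duplicate symbols collapse to the row with the smallest adjusted p-value.
#'
#' @param df data.frame with columns `gene`, `log2fc`, `adj_p`, `avg_expr`.
#' @param fc_threshold Absolute log2 fold-change cutoff (default 0.58).
#' @param p_threshold Adjusted p-value cutoff (default 0.05).
#' @return data.frame with columns `gene`, `log2fc`, `adj_p`, `avg_expr`,
#'   `significant`.
#' @export
as_gene_stats <- function(df, fc_threshold = 0.58, p_threshold = 0.05) {
  stopifnot(all(c("gene", "log2fc", "adj_p", "avg_expr") %in% names(df)))
  out <- data.frame(
    gene = as.character(df$gene),
    log2fc = num_or_na(df$log2fc, "log2FC"),
    adj_p = num_or_na(df$adj_p, "adjusted p"),
    avg_expr = num_or_na(df$avg_expr, "average expression"),
    stringsAsFactors = FALSE
  )
  if (any(out$adj_p < 0 | out$adj_p > 1, na.rm = TRUE)) {
    stop("adjusted p-values must lie in [0, 1]")
  }
  if (anyDuplicated(out$gene)) {
    key <- ifelse(is.na(out$adj_p), Inf, out$adj_p)
    out <- out[order(out$gene, key), , drop = FALSE]
    out <- out[!duplicated(out$gene), , drop = FALSE]
  }
  out$significant <- !is.na(out$log2fc) & !is.na(out$adj_p) &
    abs(out$log2fc) > fc_threshold & out$adj_p < p_threshold
  rownames(out) <- NULL
  out
}

#' Read a gene statistics table
#'
#' Reads a limma-style tab-delimited table of per-gene statistics and
#' computes the significance flag (see [as_gene_stats()]). The tokens
#' `"NA"`, `"--"` and the empty string are treated as missing values.
#'
#' @param path Path to a tab-delimited file.
#' @param fc_threshold,p_threshold DEG thresholds passed to [as_gene_stats()].
#' @param dialect Named list mapping the canonical fields `gene`, `log2fc`,
#'   `adj_p`, `avg_expr` to column headers; limma's `logFC`, `adj.P.Val`,
#'   `AveExpr` are accepted by default.
#' @return A gene statistics data.frame.
#' @export
parse_gene_stats <- function(path, fc_threshold = 0.58, p_threshold = 0.05,
                             dialect = NULL) {
  if (!file.exists(path)) stop("gene statistics table not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (nrow(raw) == 0L) stop("gene statistics table is empty: ", path)
  synonyms <- list(
    gene = c("gene", "Gene", "symbol", "gene_symbol"),
    log2fc = c("log2fc", "logFC", "log2FC", "log2FoldChange"),
    adj_p = c("adj_p", "adj.P.Val", "padj", "adjusted_p"),
    avg_expr = c("avg_expr", "AveExpr", "baseMean", "avgexpr")
  )
  cols <- lapply(names(synonyms), function(field) {
    wanted <- if (!is.null(dialect) && !is.null(dialect[[field]]))
      dialect[[field]] else synonyms[[field]]
    hit <- intersect(wanted, names(raw))
    if (length(hit) == 0L) {
      stop("gene statistics table is missing a column for '", field, "'")
    }
    raw[[hit[1L]]]
  })
  names(cols) <- names(synonyms)
  as_gene_stats(as.data.frame(cols, stringsAsFactors = FALSE),
                fc_threshold = fc_threshold, p_threshold = p_threshold)
}

#' Construct a signed directed network
#'
#' Builds an [igraph][igraph::igraph-package] directed graph from interaction
#' records, collapsing parallel `(source, target)` records into a single edge.
#' When collapsed records disagree on sign (+1 and -1 for the same pair) the
#' edge gets sign 0 with a warning; curation efforts are summed. Self-loops
#' are permitted.
#'
#' @param records Interaction records (data.frame with `source`, `target`,
#'   `sign`, optionally `curation_effort`).
#' @param nodes Optional character vector of extra nodes to include.
#' @return An igraph directed graph with edge attributes `sign` and
#'   `curation_effort`.
#' @export
signed_digraph <- function(records, nodes = NULL) {
  if (nrow(records) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
    if (!is.null(nodes)) g <- igraph::add_vertices(g, length(nodes), name = nodes)
    return(g)
  }
  if (is.null(records$curation_effort)) records$curation_effort <- 0L
  key <- paste(records$source, records$target, sep = "\r")
  sign_agg <- tapply(records$sign, key, function(s) {
    s <- unique(s[s != 0])
    if (length(s) == 1L) s else 0L
  })
  conflict <- tapply(records$sign, key, function(s) {
    all(c(-1L, 1L) %in% s)
  })
  if (any(conflict)) {
    warning(sum(conflict),
            " interaction pair(s) with conflicting curated signs; sign set to 0")
  }
  cur_agg <- tapply(records$curation_effort, key, sum)
  parts <- do.call(rbind, strsplit(names(sign_agg), "\r", fixed = TRUE))
  edges <- data.frame(source = parts[, 1L], target = parts[, 2L],
                      sign = as.integer(sign_agg),
                      curation_effort = as.integer(cur_agg),
                      stringsAsFactors = FALSE)
  all_nodes <- sort(unique(c(edges$source, edges$target, nodes)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = all_nodes)
  g
}

#' Construct an undirected network
#'
#' Collapses interaction records to unordered pairs, ignoring directedness
#' and sign; duplicate pairs (including reversed duplicates) become a single
#' edge. Self-loops are dropped.
#'
#' @param records Interaction records (data.frame with `source`, `target`).
#' @param nodes Optional character vector of extra nodes to include.
#' @return An igraph undirected graph.
#' @export
undirected_network <- function(records, nodes = NULL) {
  keep <- records$source != records$target
  records <- records[keep, , drop = FALSE]
  a <- pmin(records$source, records$target)
  b <- pmax(records$source, records$target)
  edges <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  all_nodes <- sort(unique(c(edges$a, edges$b, nodes)))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = all_nodes)
}

sif_relation <- function(sign) {
  ifelse(sign > 0, "activates", ifelse(sign < 0, "inhibits", "interacts"))
}

#' Export a network to a standard format
#'
#' Writes a network as a tab-delimited edge list (`tsv`), a Cytoscape SIF
#' file (`sif`, relations `activates`/`inhibits`/`interacts`) or GraphML
#' (`graphml`). [parse_network()] reads each format back; a round trip
#' reproduces the node and edge sets exactly.
#'
#' @param net igraph graph (directed or undirected).
#' @param path Output file path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (igraph::vcount(net) == 0L) stop("cannot export an empty network")
  edges <- igraph::as_data_frame(net, what = "edges")
  sgn <- if ("sign" %in% names(edges)) edges$sign else rep(0L, nrow(edges))
  if (format == "tsv") {
    out <- data.frame(source = edges$from, target = edges$to, sign = sgn)
    if ("weight" %in% names(edges)) out$weight <- edges$weight
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  } else if (format == "sif") {
    out <- data.frame(source = edges$from, relation = sif_relation(sgn),
                      target = edges$to)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, fileEncoding = "UTF-8")
  } else {
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path File path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @param directed Whether tsv/sif content describes a directed graph.
#' @return An igraph graph.
#' @export
parse_network <- function(path, format = c("tsv", "sif", "graphml"),
                          directed = TRUE) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    edges <- data.frame(source = df$source, target = df$target,
                        sign = as.integer(df$sign), stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("source", "relation", "target")
    edges <- data.frame(
      source = df$source, target = df$target,
      sign = ifelse(df$relation == "activates", 1L,
                    ifelse(df$relation == "inhibits", -1L, 0L)),
      stringsAsFactors = FALSE)
  }
  if (directed) signed_digraph(edges) else undirected_network(edges)
}
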