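#' Read a drug-target table
#'
#' One row per (drug, target) pair with approval and known-pharmacological-
#' action flags and an optional inhibition constant in nM.
#'
#' @param path Tab-delimited file with columns `drug`, `target`, `approved`,
#'   `known_action`, and optionally `ki_nM`.
#' @return data.frame with those columns (`ki_nM` as numeric, `NA` when
#'   unknown).
#' @export
parse_drug_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug", "target") %in% names(df)))
  if (is.null(df$approved)) df$approved <- TRUE
  if (is.null(df$known_action)) df$known_action <- TRUE
  df$approved <- as_flag(df$approved)
  df$known_action <- as_flag(df$known_action)
  df$ki_nM <- if (is.null(df$ki_nM)) NA_real_ else
    suppressWarnings(as.numeric(df$ki_nM))
  df[, c("drug", "target", "approved", "known_action", "ki_nM")]
}

#' Read a drug-drug interaction pair table
#'
#' @param path Tab-delimited file with columns `drug_a`, `drug_b`.
#' @return data.frame of symmetric interaction pairs.
#' @export
parse_drug_interactions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_a", "drug_b") %in% names(df)))
  df[, c("drug_a", "drug_b")]
}

#' Map prioritized nodes to the drugs that target them
#'
#' @param nodes Character vector of prioritized gene symbols.
#' @param drugs Drug-target table (see [parse_drug_table()]).
#' @return Named list: drug -> character vector of covered nodes. Drugs
#'   covering nothing are dropped.
#' @export
map_targets <- function(nodes, drugs) {
  hit <- drugs[drugs$target %in% nodes, , drop = FALSE]
  if (nrow(hit) == 0L) return(setNames(list(), character(0)))
  cov <- lapply(split(hit$target, hit$drug), function(x) sort(unique(x)))
  cov[order(names(cov))]
}

#' Rank drugs by target coverage
#'
#' Descending coverage count; ties break alphabetically by drug name.
#'
#' @param mapping Output of [map_targets()].
#' @return data.frame with columns `drug`, `n_targets`, `targets`.
#' @export
rank_drugs <- function(mapping) {
  stopifnot(length(mapping) > 0L)
  out <- data.frame(
    drug = names(mapping),
    n_targets = vapply(mapping, length, integer(1L)),
    targets = vapply(mapping, paste, character(1L), collapse = ", "),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_targets, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep clinically actionable drugs
#'
#' Retains only approved drugs with known pharmacological action.
#'
#' @param drugs Drug-target table.
#' @return Filtered table; a message logs the drug counts before and after.
#' @export
filter_actionable <- function(drugs) {
  keep <- drugs$approved & drugs$known_action
  out <- drugs[keep, , drop = FALSE]
  message("actionable filter: ", length(unique(drugs$drug)), " -> ",
          length(unique(out$drug)), " drugs")
  rownames(out) <- NULL
  out
}

interacts <- function(a, b, interactions) {
  if (is.null(interactions) || nrow(interactions) == 0L) return(FALSE)
  any((interactions$drug_a == a & interactions$drug_b == b) |
        (interactions$drug_a == b & interactions$drug_b == a))
}

# Inhibition-strength contribution of one covered target: strictly
# decreasing in the inhibition constant, finite for any ki >= 0; unknown
# ki contributes 0.
strength_contrib <- function(ki) {
  ifelse(is.na(ki), 0, 1 / log10(ki + 10))
}

#' Rank anchored drug combinations
#'
#' Builds all combinations of the anchor drug plus up to `max_size - 1`
#' partner drugs that neither interact with the anchor nor with each other,
#' and ranks them lexicographically by (1) number of covered targets
#' (union, descending), (2) inhibition strength score (sum over covered
#' targets of a strictly ki-decreasing contribution, using each target's
#' lowest ki among the members), and (3) a control score (sum over covered
#' targets of their control-centrality and betweenness ranks, when
#' `node_profiles` is supplied). Fully deterministic; remaining ties break
#' alphabetically on the member names.
#'
#' @param drugs Drug-target table restricted to the prioritized nodes.
#' @param anchor Anchor drug name (must appear in `drugs`).
#' @param interactions Interaction pair table or `NULL`.
#' @param node_profiles Optional data.frame with columns `node`,
#'   `control_centrality`, `betweenness`.
#' @param max_size Maximum combination size including the anchor.
#' @return data.frame with one row per combination, best first.
#' @export
rank_combinations <- function(drugs, anchor, interactions = NULL,
                              node_profiles = NULL, max_size = 3) {
  all_drugs <- sort(unique(drugs$drug))
  if (!anchor %in% all_drugs) stop("anchor drug not found: ", anchor)
  partners <- setdiff(all_drugs, anchor)
  partners <- partners[!vapply(partners, interacts, logical(1L),
                               b = anchor, interactions = interactions)]
  combos <- list(anchor)
  if (max_size >= 2L && length(partners) > 0L) {
    for (k in seq_len(min(max_size - 1L, length(partners)))) {
      sets <- combn(partners, k, simplify = FALSE)
      ok <- vapply(sets, function(s) {
        if (length(s) < 2L) return(TRUE)
        prs <- combn(s, 2L, simplify = FALSE)
        !any(vapply(prs, function(p) interacts(p[1L], p[2L], interactions),
                    logical(1L)))
      }, logical(1L))
      combos <- c(combos, lapply(sets[ok], function(s) c(anchor, s)))
    }
  }
  ctrl_rank <- NULL
  if (!is.null(node_profiles)) {
    stopifnot(all(c("node", "control_centrality", "betweenness") %in%
                    names(node_profiles)))
    ctrl_rank <- setNames(
      rank(node_profiles$control_centrality) + rank(node_profiles$betweenness),
      node_profiles$node)
  }
  rows <- lapply(combos, function(members) {
    sub <- drugs[drugs$drug %in% members, , drop = FALSE]
    covered <- sort(unique(sub$target))
    best_ki <- vapply(covered, function(tg) {
      kis <- sub$ki_nM[sub$target == tg]
      if (all(is.na(kis))) NA_real_ else min(kis, na.rm = TRUE)
    }, numeric(1L))
    strength <- sum(strength_contrib(best_ki))
    control <- if (is.null(ctrl_rank)) 0 else
      sum(ctrl_rank[covered], na.rm = TRUE)
    data.frame(members = paste(sort(members), collapse = " + "),
               size = length(members),
               n_covered = length(covered),
               covered_targets = paste(covered, collapse = ", "),
               strength_score = strength,
               control_score = control,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_covered, -out$strength_score, -out$control_score,
                   out$members), , drop = FALSE]
  rownames(out) <- NULL
  out
}
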