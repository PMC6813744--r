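# Hypergeometric over-representation of gene sets per exposure condition,
# the ">2 mapped DEGs" reporting filter, and the chemical-pathway bipartite
# network export.

#' Hypergeometric gene-set over-representation
#'
#' One-sided upper-tail test: with `n_universe` genes of which
#' `n_set_in_universe` belong to the set, drawing `n_deg` DEGs, the p-value is
#' `P(X >= n_hit)` for hypergeometric `X`. P-values are Benjamini-Hochberg
#' adjusted across all sets tested for the condition; a set is `significant`
#' when `p_adjusted < alpha`.
#'
#' @param degs character vector of DEG IDs (must be a subset of `universe`).
#' @param universe character vector: the analyzable gene set of the test
#'   system (the post-filter gene list).
#' @param collection `GeneSetCollection` (named list of gene-ID vectors).
#' @param alpha significance level on the adjusted p; default 0.05.
#' @param condition optional condition key recorded on the result.
#' @return data.frame, one row per set: `condition`, `set_id`, `n_universe`,
#'   `n_set_in_universe`, `n_deg`, `n_hit`, `p_value`, `p_adjusted`,
#'   `significant`, `hit_genes` (list column).
#' @export
hypergeom_enrich <- function(degs, universe, collection, alpha = 0.05,
                             condition = NA_character_) {
  degs <- unique(degs)
  universe <- unique(universe)
  stray <- setdiff(degs, universe)
  if (length(stray) > 0) {
    stop("DEG(s) not in universe: ", paste(head(stray, 5), collapse = ", "))
  }
  n_universe <- length(universe)
  n_deg <- length(degs)
  rows <- lapply(names(collection), function(set_id) {
    set_in_univ <- intersect(collection[[set_id]], universe)
    hits <- intersect(degs, set_in_univ)
    m <- length(set_in_univ)
    q <- length(hits)
    p <- phyper(q - 1, m, n_universe - m, n_deg, lower.tail = FALSE)
    data.frame(condition = condition, set_id = set_id,
               n_universe = n_universe, n_set_in_universe = m,
               n_deg = n_deg, n_hit = q, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out$hit_genes <- lapply(names(collection), function(set_id) {
    intersect(degs, intersect(collection[[set_id]], universe))
  })
  rownames(out) <- NULL
  out
}

#' Reporting filter for enrichment results
#'
#' A pathway is reported for a condition when it is significant and has more
#' than two DEGs mapping to it (`n_hit >= min_hits`, default 3).
#'
#' @param results data.frame from [hypergeom_enrich()].
#' @param min_hits minimum mapped-DEG count; default 3.
#' @return the filtered rows.
#' @export
filter_reported <- function(results, min_hits = 3) {
  results[results$significant & results$n_hit >= min_hits, , drop = FALSE]
}

#' Chemical-pathway bipartite network
#'
#' An edge (chemical, pathway) is present when the pathway passes
#' [filter_reported()] in at least one exposure condition of that chemical.
#' Pathways linked to exactly one chemical carry `unique = TRUE` (the
#' chemical-specific pathways of the network rendering).
#'
#' @param per_condition_results data.frame stacking [hypergeom_enrich()]
#'   outputs whose `condition` column holds parseable condition keys.
#' @param min_hits passed to [filter_reported()].
#' @return data.frame `(chemical, set_id, unique)`, one row per edge.
#' @export
chemical_pathway_network <- function(per_condition_results, min_hits = 3) {
  kept <- filter_reported(per_condition_results, min_hits)
  if (nrow(kept) == 0) {
    return(data.frame(chemical = character(0), set_id = character(0),
                      unique = logical(0), stringsAsFactors = FALSE))
  }
  kept$chemical <- parse_condition_key(kept$condition)$chemical
  edges <- unique(kept[, c("chemical", "set_id")])
  degree <- table(edges$set_id)
  edges$unique <- unname(degree[edges$set_id]) == 1L
  rownames(edges) <- NULL
  edges
}

#' Export the chemical-pathway network as edge and attribute TSVs
#' @param edges output of [chemical_pathway_network()].
#' @param edge_path 2-column edge TSV.
#' @param attr_path node attribute TSV (`node`, `type`, `unique`).
#' @return `edges`, invisibly.
#' @export
write_pathway_network <- function(edges, edge_path, attr_path) {
  write.table(edges[, c("chemical", "set_id")], edge_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  chems <- unique(edges$chemical)
  nodes <- rbind(
    data.frame(node = chems, type = rep("chemical", length(chems)),
               unique = rep(NA, length(chems)), stringsAsFactors = FALSE),
    unique(data.frame(node = edges$set_id,
                      type = rep("pathway", nrow(edges)),
                      unique = edges$unique, stringsAsFactors = FALSE)))
  write.table(nodes, attr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}
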