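# Parallelogram analysis: per-system frequency-based selection of genes,
# pathways, and metabolites, ortholog translation of the human sets, and
# three-way overlap reporting across rat in vivo, rat in vitro, and human
# in vitro test systems. Items conserved across the three systems are
# inferred to be relevant to humans in vivo.

#' Frequently observed items across exposure conditions
#'
#' An item is frequent when it appears in at least `threshold_fraction` of the
#' conditions (inclusive: 1 of 20 conditions is frequent at 5%). Each test
#' system is thresholded against its own condition count.
#'
#' @param per_condition_items named list: condition key -> character vector of
#'   items observed in that condition (DEGs, reported pathways, called
#'   metabolites).
#' @param threshold_fraction frequency threshold; default 0.05.
#' @return character vector of frequent items; attribute `frequency` carries
#'   the per-item condition fractions.
#' @export
frequent_items <- function(per_condition_items, threshold_fraction = 0.05) {
  stopifnot(length(per_condition_items) >= 1,
            threshold_fraction >= 0, threshold_fraction <= 1)
  n_cond <- length(per_condition_items)
  counts <- table(unlist(lapply(per_condition_items, unique)))
  freq <- setNames(as.numeric(counts) / n_cond, names(counts))
  out <- if (length(freq) > 0) names(freq)[freq >= threshold_fraction] else character(0)
  attr(out, "frequency") <- freq
  out
}

#' Translate human gene IDs to rat gene IDs
#'
#' Every mapping of every input gene is emitted (one-to-many orthologs expand
#' rather than drop), deduplicated; unmapped genes are counted in the log and
#' in the `n_unmapped` attribute. `drop_ambiguous = TRUE` instead discards
#' genes with more than one rat ortholog.
#'
#' @param human_items character vector of human gene IDs.
#' @param ortholog `OrthologMap` data.frame `(human_gene, rat_gene)`.
#' @param drop_ambiguous drop one-to-many genes instead of expanding?
#' @return character vector of rat gene IDs with attribute `n_unmapped`.
#' @export
map_orthologs <- function(human_items, ortholog, drop_ambiguous = FALSE) {
  human_items <- unique(human_items)
  hits <- ortholog[ortholog$human_gene %in% human_items, , drop = FALSE]
  if (drop_ambiguous) {
    multi <- names(which(table(hits$human_gene) > 1))
    hits <- hits[!hits$human_gene %in% multi, , drop = FALSE]
  }
  unmapped <- setdiff(human_items, hits$human_gene)
  if (length(unmapped) > 0) {
    stx_log("ORTHO_UNMAPPED", sprintf("%d human gene(s) with no rat ortholog",
                                      length(unmapped)))
  }
  out <- unique(hits$rat_gene)
  attr(out, "n_unmapped") <- length(unmapped)
  out
}

#' Three-way overlap of per-system item sets
#'
#' Computes all seven exclusive Venn regions and the triple intersection over
#' a common ID space (human gene sets must be ortholog-translated first).
#'
#' @param set_a,set_b,set_c character vectors.
#' @param labels names of the three systems; default
#'   `c("rat_in_vivo", "rat_in_vitro", "human_in_vitro")`.
#' @return object of class `OverlapReport`: list with `labels`, `sets`,
#'   `regions` (named integer vector of the 7 exclusive region sizes),
#'   `triple` (member vector), and `union_size`.
#' @export
three_way_overlap <- function(set_a, set_b, set_c,
                              labels = c("rat_in_vivo", "rat_in_vitro",
                                         "human_in_vitro")) {
  stopifnot(length(labels) == 3)
  sets <- list(unique(set_a), unique(set_b), unique(set_c))
  names(sets) <- labels
  all_items <- unique(c(sets[[1]], sets[[2]], sets[[3]]))
  member <- vapply(sets, function(s) all_items %in% s,
                   logical(length(all_items)))
  if (length(all_items) == 1) member <- matrix(member, nrow = 1)
  region_of <- c("100", "010", "110", "001", "101", "011", "111")
  key <- apply(member, 1, function(m) paste(as.integer(m), collapse = ""))
  regions <- setNames(integer(7), region_of)
  tab <- table(key)
  regions[names(tab)] <- as.integer(tab)
  names(regions) <- c(labels[1], labels[2],
                      paste(labels[1], labels[2], sep = "&"),
                      labels[3],
                      paste(labels[1], labels[3], sep = "&"),
                      paste(labels[2], labels[3], sep = "&"),
                      paste(labels, collapse = "&"))
  triple <- all_items[key == "111"]
  structure(list(labels = labels, sets = sets, regions = regions,
                 triple = triple, union_size = length(all_items)),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat("Three-way overlap (", paste(x$labels, collapse = " / "), ")\n", sep = "")
  for (i in seq_along(x$regions)) {
    cat(sprintf("  %-55s %d\n", names(x$regions)[i], x$regions[i]))
  }
  cat(sprintf("  union: %d; triple intersection: %d item(s)\n",
              x$union_size, length(x$triple)))
  if (length(x$triple) > 0) {
    cat("  ", paste(sort(x$triple), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Hierarchical clustering of a score matrix on both axes
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) applied to
#' rows (metabolites) and columns (conditions) independently, trees cut to the
#' requested cluster counts. Deterministic given input order.
#'
#' @param scores numeric metabolites x conditions matrix (e.g. `X_s` values).
#' @param k_metabolite,k_condition cluster counts; default 3 each.
#' @return list `(metabolite_clusters, condition_clusters)` of named integer
#'   assignment vectors, plus the two `hclust` trees.
#' @export
cluster_scores <- function(scores, k_metabolite = 3, k_condition = 3) {
  stopifnot(is.matrix(scores), all(is.finite(scores)),
            k_metabolite >= 1, k_condition >= 1)
  if (k_metabolite > nrow(scores)) stop("k_metabolite exceeds row count")
  if (k_condition > ncol(scores)) stop("k_condition exceeds column count")
  row_tree <- hclust(dist(scores), method = "ward.D2")
  col_tree <- hclust(dist(t(scores)), method = "ward.D2")
  list(metabolite_clusters = cutree(row_tree, k = k_metabolite),
       condition_clusters = cutree(col_tree, k = k_condition),
       metabolite_tree = row_tree, condition_tree = col_tree)
}

#' Dose-level composition of condition clusters
#'
#' @param condition_clusters named integer vector (condition key -> cluster).
#' @param metadata optional; dose levels are parsed from the condition keys,
#'   so this argument is only needed for keys that are not canonical
#'   (`data.frame` with `condition` and `dose_level`).
#' @return data.frame `(cluster, dose_level, n, pct)`; `pct` is the
#'   integer-rounded percentage of the cluster's conditions at that dose.
#' @export
dose_composition <- function(condition_clusters, metadata = NULL) {
  keys <- names(condition_clusters)
  if (is.null(metadata)) {
    metadata <- parse_condition_key(keys)
  }
  dose <- metadata$dose_level[match(keys, metadata$condition)]
  if (anyNA(dose)) stop("condition(s) without a dose level")
  out <- do.call(rbind, lapply(sort(unique(condition_clusters)), function(cl) {
    in_cl <- condition_clusters == cl
    tab <- table(dose[in_cl])
    data.frame(cluster = cl, dose_level = names(tab), n = as.integer(tab),
               pct = as.integer(round_half_up(100 * as.integer(tab) / sum(in_cl))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
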