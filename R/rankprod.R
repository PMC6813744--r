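# Rank-product differential expression with permutation-based pfp
# (percentage of false prediction) estimation.
#
# For one exposure condition with n_t treatment and n_c control replicates,
# the two-class construction forms all k = n_t * n_c pairwise log2 fold
# changes. Within each comparison the genes are ranked (rank 1 = most extreme
# in the tested direction, average ranks on ties) and the rank product is the
# geometric mean rank across comparisons. Significance comes from permutations
# that shuffle gene labels independently within every comparison column; the
# expected number of permuted rank products at or below each observed value,
# divided by the observed rank position, estimates the pfp, which is then
# monotonized (cumulative maximum along increasing rank product) and clipped
# to [0, 1].

#' Pairwise treatment-vs-control fold changes for one condition
#'
#' @param study an `ExpressionStudy`.
#' @param condition a condition key (`"chemical|dose|duration|system"`).
#' @return numeric matrix genes x k (k = n_treatment * n_control), each column
#'   one treatment-replicate minus control-replicate log2 difference.
#' @export
pairwise_fold_changes <- function(study, condition) {
  stopifnot(inherits(study, "ExpressionStudy"))
  md <- study$metadata
  keys <- sample_group_key(md)
  trt_idx <- which(keys == condition)
  if (length(trt_idx) == 0) stop("no treatment samples for condition: ", condition)
  ctl_group <- paste0("control:", md$control_group[trt_idx[1]])
  ctl_idx <- which(keys == ctl_group)
  if (length(ctl_idx) == 0) stop("no control samples for condition: ", condition)
  pairs <- expand.grid(t = trt_idx, c = ctl_idx)
  fc <- study$values[, pairs$t, drop = FALSE] -
    study$values[, pairs$c, drop = FALSE]
  colnames(fc) <- paste0(md$sample_id[pairs$t], "_vs_", md$sample_id[pairs$c])
  fc
}

#' Per-comparison extremity ranks
#'
#' Rank 1 is the largest fold change for `direction = "up"`, the smallest for
#' `"down"`; ties receive average ranks.
#'
#' @param fc genes x comparisons matrix.
#' @param direction `"up"` or `"down"`.
#' @return matrix of ranks with the dimensions of `fc`.
#' @keywords internal
comparison_ranks <- function(fc, direction = c("up", "down")) {
  direction <- match.arg(direction)
  signed <- if (direction == "up") -fc else fc
  apply(signed, 2, rank, ties.method = "average")
}

#' Rank-product statistic
#'
#' @param fc genes x comparisons numeric matrix of log2 fold changes.
#' @param direction `"up"` or `"down"`.
#' @return data.frame `(gene, rp, rank_position)` in input gene order;
#'   `rp` is the geometric mean rank (>= 1), `rank_position` the 1-based
#'   position of the gene when sorted by increasing `rp` (ties broken by
#'   input order).
#' @export
rank_product <- function(fc, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (nrow(fc) < 2) stop("rank product needs at least 2 genes")
  ranks <- comparison_ranks(fc, direction)
  rp <- exp(rowMeans(log(ranks)))
  data.frame(gene = rownames(fc), rp = unname(rp),
             rank_position = rank(rp, ties.method = "first"),
             stringsAsFactors = FALSE)
}

#' Permutation pfp for the rank product
#'
#' Each permutation independently shuffles gene labels within every comparison
#' column and recomputes all rank products. The expected count
#' `E(g) = #\{permuted rp <= rp(g)\} / n_permutations` divided by the rank
#' position of gene `g` gives the pfp, which is monotonized by cumulative
#' maximum along increasing `rp` and clipped to `[0, 1]`.
#'
#' @param fc genes x comparisons numeric matrix.
#' @param direction `"up"` or `"down"`.
#' @param n_permutations number of label permutations; default 1000.
#' @param seed integer seed (mandatory for reproducibility).
#' @return data.frame `(gene, rp, rank_position, e_value, pfp)` in input gene
#'   order.
#' @export
estimate_pfp <- function(fc, direction = c("up", "down"),
                         n_permutations = 1000, seed) {
  direction <- match.arg(direction)
  stopifnot(n_permutations >= 1)
  if (missing(seed)) stop("estimate_pfp requires an explicit seed")
  res <- rank_product(fc, direction)
  ranks <- comparison_ranks(fc, direction)
  G <- nrow(ranks)
  k <- ncol(ranks)
  log_ranks <- log(ranks)
  # permuting gene labels within a column permutes that column's fixed rank
  # multiset, so each permutation draws one random matching of the columns
  perm_log_rp <- withr_seed(seed, {
    out <- numeric(G * n_permutations)
    for (b in seq_len(n_permutations)) {
      s <- log_ranks[sample.int(G), 1]
      if (k > 1) {
        for (j in 2:k) s <- s + log_ranks[sample.int(G), j]
      }
      out[((b - 1) * G + 1):(b * G)] <- s
    }
    out
  })
  perm_rp_sorted <- sort(exp(perm_log_rp / k))
  # counts of permuted rp <= observed rp, tolerant of float ties
  e_value <- findInterval(res$rp * (1 + 1e-12), perm_rp_sorted) / n_permutations
  pfp_raw <- e_value / res$rank_position
  ord <- order(res$rank_position)
  pfp_mono <- numeric(G)
  pfp_mono[ord] <- cummax(pfp_raw[ord])
  res$e_value <- e_value
  res$pfp <- pmin(pfp_mono, 1)
  res
}

# run code under a temporary RNG state restored afterwards
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Call differentially expressed genes from up/down pfp results
#'
#' Strict inequality `pfp < pfp_cutoff` in either direction. A gene passing in
#' both directions (possible only under pathological ties) keeps the direction
#' with the smaller rank product, with a logged warning.
#'
#' @param up_result,down_result outputs of [estimate_pfp()] on the same gene
#'   universe.
#' @param pfp_cutoff FDR-analogue cutoff; default 0.05.
#' @param condition optional condition key recorded on the result.
#' @return `DEGTable`: data.frame `(condition, gene, direction, rp, pfp)`.
#' @export
call_degs <- function(up_result, down_result, pfp_cutoff = 0.05,
                      condition = NA_character_) {
  if (!identical(sort(up_result$gene), sort(down_result$gene))) {
    stop("up and down results cover different gene universes")
  }
  up <- up_result[up_result$pfp < pfp_cutoff, , drop = FALSE]
  down <- down_result[down_result$pfp < pfp_cutoff, , drop = FALSE]
  both <- intersect(up$gene, down$gene)
  if (length(both) > 0) {
    stx_log("DEG_BOTH_DIRECTIONS",
            sprintf("gene(s) significant in both directions, keeping smaller rp: %s",
                    paste(both, collapse = ", ")), level = "WARN")
    for (g in both) {
      if (up$rp[up$gene == g] <= down$rp[down$gene == g]) {
        down <- down[down$gene != g, , drop = FALSE]
      } else {
        up <- up[up$gene != g, , drop = FALSE]
      }
    }
  }
  out <- rbind(
    if (nrow(up) > 0) data.frame(condition = condition, gene = up$gene,
                                 direction = "up", rp = up$rp, pfp = up$pfp,
                                 stringsAsFactors = FALSE),
    if (nrow(down) > 0) data.frame(condition = condition, gene = down$gene,
                                   direction = "down", rp = down$rp,
                                   pfp = down$pfp, stringsAsFactors = FALSE))
  if (is.null(out)) {
    out <- data.frame(condition = character(0), gene = character(0),
                      direction = character(0), rp = numeric(0),
                      pfp = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("DEGTable", "data.frame")
  out
}

#' Rank-product DEG calling for every condition of a study
#'
#' Convenience wrapper running [pairwise_fold_changes()], [estimate_pfp()] in
#' both directions, and [call_degs()] per exposure condition.
#'
#' @param study an `ExpressionStudy` (already filtered).
#' @param pfp_cutoff pfp cutoff; default 0.05.
#' @param n_permutations permutations per condition; default 1000.
#' @param seed integer seed; each condition uses a distinct sub-seed derived
#'   deterministically from it.
#' @return `DEGTable` stacking all conditions.
#' @export
study_degs <- function(study, pfp_cutoff = 0.05, n_permutations = 1000, seed) {
  if (missing(seed)) stop("study_degs requires an explicit seed")
  md <- study$metadata
  trt <- md[md$dose_level != "control", , drop = FALSE]
  conditions <- unique(condition_key(trt$chemical, trt$dose_level,
                                     trt$duration, trt$test_system))
  tables <- lapply(seq_along(conditions), function(i) {
    fc <- pairwise_fold_changes(study, conditions[i])
    sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
    up <- estimate_pfp(fc, "up", n_permutations, seed = sub_seed)
    down <- estimate_pfp(fc, "down", n_permutations, seed = sub_seed + 1L)
    call_degs(up, down, pfp_cutoff, condition = conditions[i])
  })
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  class(out) <- c("DEGTable", "data.frame")
  out
}
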