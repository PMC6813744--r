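# Post-normalization preprocessing: non-specific gene filtering, replicate
# averaging, per-condition log-ratios, and the ternary fold-change
# discretization used for reporting.

#' Canonical key of an exposure condition
#'
#' An exposure condition is one (chemical, dose level, duration, test system)
#' cell; the key `"chemical|dose|duration|system"` is the column identity of
#' the fold-change matrix and the unit of all per-condition analyses.
#'
#' @param chemical,dose_level,duration,test_system character vectors
#'   (recycled).
#' @return character vector of condition keys.
#' @export
condition_key <- function(chemical, dose_level, duration, test_system) {
  paste(chemical, dose_level, duration, test_system, sep = "|")
}

#' Split condition keys back into their fields
#' @param keys character vector of `"chemical|dose|duration|system"` keys.
#' @return data.frame with columns `condition`, `chemical`, `dose_level`,
#'   `duration`, `test_system`.
#' @export
parse_condition_key <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 4L
  if (any(bad)) stop("malformed condition key(s): ",
                     paste(keys[bad], collapse = ", "))
  data.frame(condition = keys,
             chemical = vapply(parts, `[[`, character(1), 1L),
             dose_level = vapply(parts, `[[`, character(1), 2L),
             duration = vapply(parts, `[[`, character(1), 3L),
             test_system = vapply(parts, `[[`, character(1), 4L),
             stringsAsFactors = FALSE)
}

#' Non-specific gene filtering
#'
#' Removes genes with no external annotation (the stand-in for probe sets
#' lacking an Entrez ID) and genes of low variance across all samples. The
#' variance threshold is the `variance_quantile` quantile of the per-gene
#' variance distribution, computed once on the annotation-surviving genes;
#' genes strictly below it are dropped. The computed threshold is returned as
#' attribute `variance_cutoff` on the result, and passing it back via
#' `variance_cutoff` reproduces the same filter exactly (re-deriving the
#' quantile on an already-filtered study would shift the threshold).
#'
#' An optional minimum-expression floor (`min_expression`) drops genes whose
#' maximum group mean falls below a fixed level, standing in for
#' present/absent detection calls; it is disabled (`-Inf`) by default.
#'
#' @param study an `ExpressionStudy`.
#' @param annotation named vector/list mapping gene ID to an external ID, with
#'   `NA`/`NULL`/missing meaning unannotated; `NULL` keeps all genes.
#' @param variance_quantile fraction in `[0, 1)`; default 0.25.
#' @param variance_cutoff optional explicit variance threshold overriding the
#'   quantile computation.
#' @param min_expression optional floor on the max per-group mean log2
#'   intensity; default `-Inf` (off).
#' @return filtered `ExpressionStudy` with attribute `variance_cutoff`.
#' @export
filter_genes <- function(study, annotation = NULL, variance_quantile = 0.25,
                         variance_cutoff = NULL, min_expression = -Inf) {
  stopifnot(inherits(study, "ExpressionStudy"),
            variance_quantile >= 0, variance_quantile < 1)
  values <- study$values
  n0 <- nrow(values)
  if (!is.null(annotation)) {
    ann <- unlist(annotation)[rownames(values)]
    keep_ann <- !is.na(ann)
    stx_log("FILTER_ANNOT", sprintf("%d gene(s) dropped: no external annotation",
                                    sum(!keep_ann)))
    values <- values[keep_ann, , drop = FALSE]
  }
  if (nrow(values) == 0) stop("all genes removed by annotation filter")
  vars <- apply(values, 1, var)
  if (is.null(variance_cutoff)) {
    variance_cutoff <- unname(quantile(vars, variance_quantile))
  }
  keep_var <- vars >= variance_cutoff
  stx_log("FILTER_VAR", sprintf(
    "%d gene(s) dropped: variance below %.4g (quantile %.2f)",
    sum(!keep_var), variance_cutoff, variance_quantile))
  values <- values[keep_var, , drop = FALSE]
  if (is.finite(min_expression) && nrow(values) > 0) {
    gm <- average_replicates(expression_study(values, study$metadata))
    keep_expr <- apply(gm, 1, max) >= min_expression
    stx_log("FILTER_EXPR", sprintf(
      "%d gene(s) dropped: max group mean below %.3g",
      sum(!keep_expr), min_expression))
    values <- values[keep_expr, , drop = FALSE]
  }
  if (nrow(values) == 0) stop("all ", n0, " genes removed by filtering")
  out <- expression_study(values, study$metadata)
  attr(out, "variance_cutoff") <- variance_cutoff
  out
}

#' Group key for every sample of a study
#'
#' Treatment samples group by their exposure-condition key; control samples
#' group by `control:<control_group>` so a shared control group is averaged
#' once however many conditions it serves.
#'
#' @param metadata sample metadata data.frame.
#' @return character vector of group keys, one per row.
#' @keywords internal
sample_group_key <- function(metadata) {
  ifelse(metadata$dose_level == "control",
         paste0("control:", metadata$control_group),
         condition_key(metadata$chemical, metadata$dose_level,
                       metadata$duration, metadata$test_system))
}

#' Average replicate log2 intensities per group
#'
#' @param study an `ExpressionStudy`.
#' @return numeric matrix genes x groups of mean log2 intensities; columns are
#'   condition keys for treatment groups and `control:<group>` for control
#'   groups. Attribute `control_pairing` maps each condition key to its
#'   control column.
#' @export
average_replicates <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  keys <- sample_group_key(study$metadata)
  groups <- unique(keys)
  means <- vapply(groups, function(g) {
    cols <- which(keys == g)
    rowMeans(study$values[, cols, drop = FALSE])
  }, numeric(nrow(study$values)))
  means <- matrix(means, nrow = nrow(study$values),
                  dimnames = list(rownames(study$values), groups))
  trt <- study$metadata[study$metadata$dose_level != "control", , drop = FALSE]
  pairing <- setNames(paste0("control:", trt$control_group),
                      condition_key(trt$chemical, trt$dose_level,
                                    trt$duration, trt$test_system))
  pairing <- pairing[!duplicated(names(pairing))]
  attr(means, "control_pairing") <- pairing
  means
}

#' Per-condition log2 fold changes
#'
#' `log2FC(gene, condition) = mean(treatment) - mean(control)`; values are
#' already in log2 space so the difference of means is the log-ratio.
#'
#' @param group_means output of [average_replicates()] (or any genes x groups
#'   matrix).
#' @param control_pairing named character vector: condition key -> control
#'   column; defaults to the attribute set by [average_replicates()].
#' @return `FoldChangeMatrix`: numeric matrix genes x condition keys with
#'   attribute `conditions` (parsed key data.frame).
#' @export
compute_log_ratios <- function(group_means,
                               control_pairing = attr(group_means,
                                                      "control_pairing")) {
  if (is.null(control_pairing) || length(control_pairing) == 0) {
    stop("no control pairing supplied")
  }
  missing_ctl <- setdiff(unname(control_pairing), colnames(group_means))
  if (length(missing_ctl) > 0) {
    stop("control group column(s) missing from group means: ",
         paste(missing_ctl, collapse = ", "))
  }
  missing_trt <- setdiff(names(control_pairing), colnames(group_means))
  if (length(missing_trt) > 0) {
    stop("treatment condition column(s) missing from group means: ",
         paste(missing_trt, collapse = ", "))
  }
  fc <- group_means[, names(control_pairing), drop = FALSE] -
    group_means[, unname(control_pairing), drop = FALSE]
  colnames(fc) <- names(control_pairing)
  attr(fc, "conditions") <- parse_condition_key(colnames(fc))
  class(fc) <- c("FoldChangeMatrix", class(fc))
  fc
}

#' Discretize log2 fold changes into up/none/down
#'
#' `up` for values strictly above `cutoff`, `down` for values strictly below
#' `-cutoff`, `none` inside the closed band `[-cutoff, cutoff]`. The default
#' band of 0.6 log2 units is the reporting convention for fold-change
#' heatmaps.
#'
#' @param fc numeric matrix (or vector) of log2 fold changes.
#' @param cutoff positive log2 threshold; default 0.6.
#' @return character matrix/vector of `"up"`, `"none"`, `"down"` with the
#'   dimensions of `fc`.
#' @export
discretize_fc <- function(fc, cutoff = 0.6) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  out <- ifelse(fc > cutoff, "up", ifelse(fc < -cutoff, "down", "none"))
  if (is.matrix(fc)) dimnames(out) <- dimnames(fc)
  out
}

#' Write a fold-change matrix as TSV
#' @param fc `FoldChangeMatrix`.
#' @param path output path; first column `gene_id`, then condition keys.
#' @return `fc`, invisibly.
#' @export
write_fold_changes <- function(fc, path) {
  df <- data.frame(gene_id = rownames(fc), unclass(fc), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fc)
}

#' Read a fold-change matrix from TSV
#' @param path TSV written by [write_fold_changes()].
#' @return `FoldChangeMatrix`.
#' @export
read_fold_changes <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  fc <- as.matrix(df[, -1, drop = FALSE])
  rownames(fc) <- df[[1]]
  attr(fc, "conditions") <- parse_condition_key(colnames(fc))
  class(fc) <- c("FoldChangeMatrix", class(fc))
  fc
}
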