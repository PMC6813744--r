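# Readers and writers for every external format the pipeline touches.
# All gene IDs are opaque strings; no species prefix conventions are imposed.

REQUIRED_METADATA_COLS <- c("sample_id", "chemical", "dose_level", "duration",
                            "test_system", "replicate", "control_group")
DOSE_LEVELS <- c("control", "low", "medium", "high")
TEST_SYSTEMS <- c("rat_in_vivo", "rat_in_vitro", "human_in_vitro")

#' Construct an expression study
#'
#' The pipeline's entry point: a genes x samples matrix of normalized log2
#' intensities plus per-sample exposure metadata. Control pairing is explicit:
#' every sample carries a `control_group` key; treatment samples name the
#' control group they are compared against, control samples name their own
#' group (a control group may serve several conditions, the shared-control
#' pattern of repeated-dose study designs).
#'
#' @param values numeric matrix, rownames = gene IDs, colnames = sample IDs.
#' @param metadata data.frame with columns `sample_id`, `chemical`,
#'   `dose_level` (`control`/`low`/`medium`/`high`), `duration`,
#'   `test_system` (`rat_in_vivo`/`rat_in_vitro`/`human_in_vitro`),
#'   `replicate`, `control_group`.
#' @return an object of class `ExpressionStudy`: list with elements `values`
#'   and `metadata` (metadata rows ordered as the matrix columns).
#' @export
expression_study <- function(values, metadata) {
  stopifnot(is.matrix(values), is.numeric(values), is.data.frame(metadata))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene IDs in matrix")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs in matrix")
  if (!all(is.finite(values))) stop("expression values must be finite")
  missing_cols <- setdiff(REQUIRED_METADATA_COLS, names(metadata))
  if (length(missing_cols) > 0) {
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample IDs in metadata")
  unknown <- setdiff(colnames(values), metadata$sample_id)
  if (length(unknown) > 0) {
    stop("samples in matrix but not in metadata: ",
         paste(unknown, collapse = ", "))
  }
  bad_dose <- setdiff(unique(metadata$dose_level), DOSE_LEVELS)
  if (length(bad_dose) > 0) {
    stop("unknown dose_level values: ", paste(bad_dose, collapse = ", "))
  }
  bad_sys <- setdiff(unique(metadata$test_system), TEST_SYSTEMS)
  if (length(bad_sys) > 0) {
    stop("unknown test_system values: ", paste(bad_sys, collapse = ", "))
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  # every treatment condition needs >=1 control sample in its control group
  trt <- metadata[metadata$dose_level != "control", , drop = FALSE]
  ctl <- metadata[metadata$dose_level == "control", , drop = FALSE]
  orphan <- setdiff(unique(trt$control_group), unique(ctl$control_group))
  if (length(orphan) > 0) {
    stop("treatment samples reference control groups with no control samples: ",
         paste(orphan, collapse = ", "))
  }
  structure(list(values = values, metadata = metadata),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$metadata$test_system), collapse = ", ")))
  cat(sprintf("  chemicals: %s\n",
              paste(setdiff(unique(x$metadata$chemical), ""), collapse = ", ")))
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' @param matrix_path TSV with header `gene_id` then sample IDs; one row per
#'   gene, log2 intensities.
#' @param metadata_path TSV with the metadata columns of [expression_study()].
#' @return an `ExpressionStudy`.
#' @export
read_expression_study <- function(matrix_path, metadata_path) {
  mat_df <- read.delim(matrix_path, check.names = FALSE,
                       stringsAsFactors = FALSE)
  if (names(mat_df)[1] != "gene_id") {
    stop("expression matrix must have first column 'gene_id', got '",
         names(mat_df)[1], "'")
  }
  genes <- as.character(mat_df[[1]])
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric cells in expression matrix")
  rownames(values) <- genes
  metadata <- read.delim(metadata_path, check.names = FALSE,
                         colClasses = "character")
  if ("replicate" %in% names(metadata)) {
    metadata$replicate <- as.integer(metadata$replicate)
  }
  expression_study(values, metadata)
}

#' Write an expression study to TSV files
#'
#' Inverse of [read_expression_study()] up to float formatting.
#'
#' @param study an `ExpressionStudy`.
#' @param matrix_path,metadata_path output paths.
#' @return `study`, invisibly.
#' @export
write_expression_study <- function(study, matrix_path, metadata_path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  df <- data.frame(gene_id = rownames(study$values),
                   study$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$metadata, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(study)
}

#' Read a gene-set collection (GMT)
#'
#' One set per line: set ID, description, then tab-separated member gene IDs.
#' Duplicate members within a set are dropped with a log notice; duplicate set
#' IDs and empty member lists are errors.
#'
#' @param path GMT file.
#' @return named list of character vectors with a `description` attribute
#'   (named character vector), class `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(short), collapse = ", "))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate gene-set IDs in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  descs <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) {
    members <- f[-c(1, 2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) stop("gene set '", f[1], "' has no members")
    if (anyDuplicated(members)) {
      stx_log("GMT_DUP_MEMBER",
              sprintf("set '%s': %d duplicate member(s) dropped",
                      f[1], sum(duplicated(members))))
      members <- unique(members)
    }
    members
  })
  names(sets) <- ids
  structure(sets, description = setNames(descs, ids),
            class = "GeneSetCollection")
}

#' Write a gene-set collection (GMT)
#' @param collection named list of gene-ID vectors (class `GeneSetCollection`
#'   or plain named list).
#' @param path output GMT path.
#' @return `collection`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  descs <- attr(collection, "description")
  if (is.null(descs)) descs <- setNames(names(collection), names(collection))
  lines <- vapply(names(collection), function(id) {
    paste(c(id, descs[[id]], collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' Read a transcription-factor target table
#'
#' TSV with columns `tf`, `target`, `mode` (`activation`/`repression`/
#' `unknown`), the shape of TRRUST-style regulatory databases. Duplicate
#' (tf, target) pairs are dropped with a log notice; self-loops are kept but
#' flagged in the log.
#'
#' @param path TSV file.
#' @return data.frame `(tf, target, mode)`, class `TFTargetMap`.
#' @export
read_tf_targets <- function(path) {
  df <- read.delim(path, colClasses = "character")
  need <- c("tf", "target", "mode")
  if (!all(need %in% names(df))) {
    stop("TF target table must have columns: ", paste(need, collapse = ", "))
  }
  bad_mode <- setdiff(unique(df$mode), c("activation", "repression", "unknown"))
  if (length(bad_mode) > 0) {
    stop("unknown TF mode values: ", paste(bad_mode, collapse = ", "))
  }
  dup <- duplicated(df[, c("tf", "target")])
  if (any(dup)) {
    stx_log("TF_DUP_PAIR", sprintf("%d duplicate (tf, target) pair(s) dropped",
                                   sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  self <- df$tf == df$target
  if (any(self)) {
    stx_log("TF_SELF_LOOP", sprintf("self-loop(s) kept for TF(s): %s",
                                    paste(unique(df$tf[self]), collapse = ", ")))
  }
  rownames(df) <- NULL
  class(df) <- c("TFTargetMap", "data.frame")
  df
}

#' Read an ortholog mapping table
#'
#' TSV with columns `human_gene`, `rat_gene`. One-to-many and many-to-one
#' mappings are permitted and preserved; exact duplicate rows are dropped at
#' load with a log notice.
#'
#' @param path TSV file.
#' @return data.frame `(human_gene, rat_gene)`, class `OrthologMap`.
#' @export
read_orthologs <- function(path) {
  df <- read.delim(path, colClasses = "character")
  need <- c("human_gene", "rat_gene")
  if (!all(need %in% names(df))) {
    stop("ortholog table must have columns: ", paste(need, collapse = ", "))
  }
  dup <- duplicated(df[, need])
  if (any(dup)) {
    stx_log("ORTHO_DUP", sprintf("%d duplicate ortholog row(s) dropped", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("OrthologMap", "data.frame")
  df
}

#' Construct a metabolic model
#'
#' A stoichiometric model: reactions with bounds and GPR rules, metabolites
#' with an `exchangeable` flag, and the metabolites x reactions matrix `S`.
#' Exchange reactions are the boundary reactions touching exactly one
#' metabolite; positive flux through an exchange is secretion, negative is
#' uptake.
#'
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`, `gpr`.
#' @param metabolites data.frame with columns `id`, `name`, `exchangeable`
#'   (logical).
#' @param S numeric matrix, metabolites x reactions (dimnames set from IDs).
#' @return object of class `MetabolicModel`: the inputs plus parsed GPR trees
#'   (`gpr_trees`) and the exchange-reaction ID set (`exchange_reactions`).
#' @export
metabolic_model <- function(reactions, metabolites, S) {
  stopifnot(is.data.frame(reactions), is.data.frame(metabolites),
            is.matrix(S))
  need_r <- c("id", "name", "lb", "ub", "gpr")
  need_m <- c("id", "name", "exchangeable")
  if (!all(need_r %in% names(reactions))) {
    stop("reactions need columns: ", paste(need_r, collapse = ", "))
  }
  if (!all(need_m %in% names(metabolites))) {
    stop("metabolites need columns: ", paste(need_m, collapse = ", "))
  }
  if (ncol(S) != nrow(reactions) || nrow(S) != nrow(metabolites)) {
    stop("S must be |metabolites| x |reactions|")
  }
  dimnames(S) <- list(metabolites$id, reactions$id)
  bad_bounds <- reactions$lb > reactions$ub
  if (any(bad_bounds)) {
    stop("lb > ub for reaction(s): ",
         paste(reactions$id[bad_bounds], collapse = ", "))
  }
  gpr_trees <- lapply(seq_len(nrow(reactions)), function(i) {
    tryCatch(parse_gpr(reactions$gpr[i]),
             error = function(e) stop("reaction '", reactions$id[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(gpr_trees) <- reactions$id
  n_mets <- colSums(S != 0)
  # boundary reactions: exactly one nonzero stoichiometric entry
  exchange <- reactions$id[n_mets == 1L]
  for (rid in exchange) {
    met <- metabolites$id[S[, rid] != 0]
    if (!metabolites$exchangeable[metabolites$id == met]) {
      stx_log("EXCH_UNFLAGGED",
              sprintf("exchange reaction '%s' touches metabolite '%s' not flagged exchangeable",
                      rid, met), level = "WARN")
    }
  }
  orphan_rxn <- reactions$id[n_mets == 0L]
  if (length(orphan_rxn) > 0) {
    stop("reaction(s) with all-zero stoichiometry: ",
         paste(orphan_rxn, collapse = ", "))
  }
  structure(list(reactions = reactions, metabolites = metabolites, S = S,
                 gpr_trees = gpr_trees, exchange_reactions = exchange),
            class = "MetabolicModel")
}

#' @export
print.MetabolicModel <- function(x, ...) {
  cat(sprintf("MetabolicModel: %d metabolites x %d reactions (%d exchange)\n",
              nrow(x$metabolites), nrow(x$reactions),
              length(x$exchange_reactions)))
  invisible(x)
}

#' Read a metabolic model from JSON
#'
#' Canonical document shape:
#' `{"metabolites": [{"id", "name", "exchangeable"}, ...],`
#' `"reactions": [{"id", "name", "lb", "ub", "gpr", "stoich": {met: coef}}, ...]}`.
#' GPR strings are parsed eagerly so malformed rules fail at load, naming the
#' offending reaction.
#'
#' @param path JSON model file.
#' @return a `MetabolicModel`.
#' @export
read_metabolic_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!all(c("metabolites", "reactions") %in% names(doc))) {
    stop("model JSON must have 'metabolites' and 'reactions' keys")
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               exchangeable = isTRUE(m$exchangeable),
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = r$id, name = r$name %||% r$id,
               lb = as.numeric(r$lb), ub = as.numeric(r$ub),
               gpr = if (is.null(r$gpr)) "" else as.character(r$gpr),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(mets$id)) stop("duplicate metabolite IDs in model")
  if (anyDuplicated(rxns$id)) stop("duplicate reaction IDs in model")
  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
  for (r in doc$reactions) {
    for (met in names(r$stoich)) {
      if (!met %in% mets$id) {
        stop("reaction '", r$id, "' references unknown metabolite '", met, "'")
      }
      S[met, r$id] <- as.numeric(r$stoich[[met]])
    }
  }
  metabolic_model(rxns, mets, S)
}

#' Write a metabolic model to JSON
#' @param model a `MetabolicModel`.
#' @param path output JSON path.
#' @return `model`, invisibly.
#' @export
write_metabolic_model <- function(model, path) {
  stopifnot(inherits(model, "MetabolicModel"))
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, exchangeable = m$exchangeable)
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    sto <- model$S[, r$id]
    sto <- sto[sto != 0]
    list(id = r$id, name = r$name, lb = r$lb, ub = r$ub, gpr = r$gpr,
         stoich = as.list(sto))
  })
  jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
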