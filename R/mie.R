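# Molecular-initiating-event (MIE) activation scoring. The MIEs of the liver
# steatosis adverse outcome pathway are ligand-activated transcription
# factors; their activation is read out as the fraction of their regulatory
# target genes called differentially expressed for a chemical at any dose or
# duration.

#' Round half away from zero
#'
#' Integer display convention for percentage cells (26.67 -> 27, 38.46 -> 38).
#' @param x numeric.
#' @return numeric of rounded integers.
#' @keywords internal
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map MIE target genes into the analyzable universe
#'
#' @param tf_map `TFTargetMap` data.frame `(tf, target, mode)`.
#' @param mies character vector of MIE (transcription factor) gene IDs.
#' @param universe character vector: the post-filter gene list of the test
#'   system.
#' @return named list MIE -> character vector of mapped targets (targets of
#'   the MIE present in the universe); attribute `unmapped` lists MIEs with no
#'   records in `tf_map` at all.
#' @export
map_targets <- function(tf_map, mies, universe) {
  stopifnot(length(universe) > 0)
  universe <- unique(universe)
  mapped <- lapply(mies, function(mie) {
    targets <- unique(tf_map$target[tf_map$tf == mie])
    intersect(targets, universe)
  })
  names(mapped) <- mies
  unmapped <- mies[!mies %in% unique(tf_map$tf)]
  if (length(unmapped) > 0) {
    stx_log("MIE_UNMAPPED", sprintf("MIE(s) with no TF-target records: %s",
                                    paste(unmapped, collapse = ", ")))
  }
  attr(mapped, "unmapped") <- unmapped
  mapped
}

#' Score MIE activation per chemical
#'
#' For each chemical, the DEG set is the union over all of its exposure
#' conditions (any dose or duration, either direction). A cell counts the
#' differentially expressed targets of the MIE, reports the integer-rounded
#' percentage of mapped targets, and is flagged when the unrounded percentage
#' exceeds `flag_threshold`. Only MIEs with strictly more than `min_mapped`
#' mapped targets appear.
#'
#' @param deg_table `DEGTable` whose `condition` column holds parseable
#'   condition keys (or a data.frame with columns `chemical` and `gene`).
#' @param mapped named list from [map_targets()].
#' @param min_mapped MIEs must have `n_mapped > min_mapped`; default 10.
#' @param flag_threshold percentage above which a cell is flagged; default 20.
#' @return `MIEActivationTable`: data.frame `(chemical, mie, n_de, n_mapped,
#'   pct, flagged)`, one row per chemical x retained MIE.
#' @export
score_mie_activation <- function(deg_table, mapped, min_mapped = 10,
                                 flag_threshold = 20) {
  if (!"chemical" %in% names(deg_table)) {
    deg_table$chemical <- parse_condition_key(deg_table$condition)$chemical
  }
  keep_mies <- names(mapped)[vapply(mapped, length, integer(1)) > min_mapped]
  dropped <- setdiff(names(mapped), keep_mies)
  if (length(dropped) > 0) {
    stx_log("MIE_TOO_FEW_TARGETS",
            sprintf("MIE(s) with <= %d mapped targets omitted: %s",
                    min_mapped, paste(dropped, collapse = ", ")))
  }
  chemicals <- unique(deg_table$chemical)
  rows <- lapply(chemicals, function(chem) {
    deg_union <- unique(deg_table$gene[deg_table$chemical == chem])
    do.call(rbind, lapply(keep_mies, function(mie) {
      n_mapped <- length(mapped[[mie]])
      n_de <- length(intersect(deg_union, mapped[[mie]]))
      pct_exact <- 100 * n_de / n_mapped
      data.frame(chemical = chem, mie = mie, n_de = n_de,
                 n_mapped = n_mapped,
                 pct = as.integer(round_half_up(pct_exact)),
                 flagged = pct_exact > flag_threshold,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chemical = character(0), mie = character(0),
                      n_de = integer(0), n_mapped = integer(0),
                      pct = integer(0), flagged = logical(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("MIEActivationTable", "data.frame")
  out
}
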