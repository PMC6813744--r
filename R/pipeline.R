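# Pipeline orchestration: simulate -> prep -> deg -> enrich -> mie -> timbr
# -> overlap, driven by one YAML config with per-stage parameter blocks and
# content-hash stage caching. Every stage reads and writes plain-text files
# under the configured output directory, so stages can also be run
# individually (the file contracts are the interface).

PIPELINE_STAGES <- c("simulate", "prep", "deg", "enrich", "mie", "timbr",
                     "overlap")

#' Default pipeline configuration
#'
#' One block per stage; every analysis threshold has a key here with its
#' standard default (fold-change discretization band 0.6, pfp cutoff 0.05,
#' enrichment alpha 0.05 with >2 mapped DEGs, MIE table restricted to >10
#' mapped targets with the 20% flag, TIMBR weight scale 0.5 /
#' opt fraction 0.9 / call cutoff 0.1, 5% frequency threshold, 3 clusters per
#' axis).
#'
#' @param out_dir output directory for all stage files.
#' @param seed global seed; stages derive sub-seeds deterministically.
#' @return nested configuration list.
#' @export
default_config <- function(out_dir = "steatox_out", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    test_systems = c("rat_in_vivo", "rat_in_vitro", "human_in_vitro"),
    simulate = list(
      n_genes = 300,
      chemicals = c("chemA", "chemB", "chemC"),
      dose_levels = c("low", "medium", "high"),
      durations = c("24h", "8d"),
      replicates_per_group = 3,
      deg_fraction_by_dose = list(low = 0.02, medium = 0.05, high = 0.10),
      effect_size = 1.5,
      noise_sd = 0.3,
      baseline_mean = 7,
      baseline_sd = 2,
      n_conserved_genes = 8,
      conserved_shift = 2,
      unannotated_fraction = 0.05,
      n_sets = 12,
      n_tfs = 6,
      n_internal_metabolites = 3,
      n_exchange = 6,
      human_prefix = "h_"
    ),
    prep = list(variance_quantile = 0.25, min_expression = NULL,
                fc_cutoff = 0.6),
    deg = list(pfp_cutoff = 0.05, n_permutations = 1000),
    enrich = list(alpha = 0.05, min_hits = 3),
    mie = list(min_mapped = 10, flag_threshold = 20),
    timbr = list(opt_fraction = 0.9, scale = 0.5, baseline = 1.0,
                 cutoff = 0.1),
    overlap = list(threshold_fraction = 0.05, k_metabolite = 3,
                   k_condition = 3)
  )
}

#' Read and validate a pipeline configuration
#'
#' User values are merged over [default_config()]; keys not present in the
#' defaults are rejected (typo safety).
#'
#' @param path YAML config file, or `NULL` for pure defaults.
#' @param ... direct overrides applied after the file (e.g. `seed = 7`).
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL, ...) {
  config <- default_config()
  merge_checked <- function(base, user, prefix = "") {
    for (key in names(user)) {
      full <- paste0(prefix, key)
      if (!key %in% names(base)) stop("unknown config key: ", full)
      if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
        base[[key]] <- merge_checked(base[[key]], as.list(user[[key]]),
                                     paste0(full, "."))
      } else {
        base[[key]] <- user[[key]]
      }
    }
    base
  }
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    config <- merge_checked(config, user)
  }
  overrides <- list(...)
  if (length(overrides) > 0) config <- merge_checked(config, overrides)
  config$seed <- as.integer(config$seed)
  config
}

# -- caching ------------------------------------------------------------------

stage_hash <- function(input_files, params) {
  input_files <- input_files[file.exists(input_files)]
  file_md5 <- unname(tools::md5sum(input_files))
  blob <- jsonlite::toJSON(list(files = file_md5, params = params),
                           auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(blob), tmp)
  unname(tools::md5sum(tmp))
}

read_manifest <- function(out_dir) {
  path <- file.path(out_dir, "manifest.json")
  if (file.exists(path)) jsonlite::read_json(path) else list()
}

write_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

stage_cached <- function(out_dir, stage, hash, outputs) {
  manifest <- read_manifest(out_dir)
  entry <- manifest[[stage]]
  !is.null(entry) && identical(entry$hash, as.character(hash)) &&
    all(file.exists(file.path(out_dir, outputs)))
}

record_stage <- function(out_dir, stage, hash, outputs) {
  manifest <- read_manifest(out_dir)
  manifest[[stage]] <- list(hash = as.character(hash), outputs = outputs,
                            time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  write_manifest(out_dir, manifest)
}

# atomically write via a temp file in the same directory
atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

stx_path <- function(config, ...) file.path(config$out_dir, ...)

# -- stages -------------------------------------------------------------------

#' Run one pipeline stage
#'
#' Stages read their inputs from, and write their outputs to,
#' `config$out_dir`. A stage whose inputs and parameters are unchanged since
#' the recorded manifest entry is skipped with a log notice.
#'
#' @param name one of `simulate`, `prep`, `deg`, `enrich`, `mie`, `timbr`,
#'   `overlap`.
#' @param config configuration list from [read_pipeline_config()].
#' @param force rerun even when cached.
#' @return character vector of the stage's output files, invisibly.
#' @export
run_stage <- function(name, config, force = FALSE) {
  name <- match.arg(name, PIPELINE_STAGES)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(name,
               simulate = stage_simulate, prep = stage_prep, deg = stage_deg,
               enrich = stage_enrich, mie = stage_mie, timbr = stage_timbr,
               overlap = stage_overlap)
  spec <- fn(config, plan_only = TRUE)
  missing_in <- spec$inputs[!file.exists(stx_path(config, spec$inputs))]
  if (length(missing_in) > 0) {
    stop("stage '", name, "' missing upstream output(s): ",
         paste(missing_in, collapse = ", "))
  }
  hash <- stage_hash(stx_path(config, spec$inputs), spec$params)
  if (!force && stage_cached(config$out_dir, name, hash, spec$outputs)) {
    stx_log("STAGE_SKIP", sprintf("stage '%s' up to date; skipped", name))
    return(invisible(stx_path(config, spec$outputs)))
  }
  stx_log("STAGE_RUN", sprintf("running stage '%s'", name))
  fn(config, plan_only = FALSE)
  record_stage(config$out_dir, name, hash, spec$outputs)
  invisible(stx_path(config, spec$outputs))
}

#' Run the full pipeline
#'
#' @param config configuration list from [read_pipeline_config()].
#' @param stages stage names to run in order; default all.
#' @param force rerun stages even when cached.
#' @return list of headline results: the three `OverlapReport`s, cluster
#'   assignments, and dose composition (read back from the overlap outputs).
#' @export
run_pipeline <- function(config = read_pipeline_config(),
                         stages = PIPELINE_STAGES, force = FALSE) {
  for (stage in stages) run_stage(stage, config, force = force)
  collect_overlap_results(config)
}

system_files <- function(config, template) {
  sprintf(template, config$test_systems)
}

stage_simulate <- function(config, plan_only = FALSE) {
  p <- config$simulate
  outputs <- c(system_files(config, "expr_%s.tsv"),
               system_files(config, "meta_%s.tsv"),
               system_files(config, "annotation_%s.tsv"),
               system_files(config, "truth_%s.tsv"),
               "gene_sets.gmt", "tf_targets.tsv", "orthologs.tsv",
               "model_rat.json", "model_human.json", "mies.txt")
  if (plan_only) {
    return(list(inputs = character(0), outputs = outputs,
                params = list(p = p, seed = config$seed,
                              systems = config$test_systems)))
  }
  rat_genes <- sprintf("g%04d", seq_len(p$n_genes))
  conserved <- withr_seed(config$seed,
                          sample(rat_genes, p$n_conserved_genes))
  ann <- generate_annotations(rat_genes, n_sets = p$n_sets, n_tfs = p$n_tfs,
                              seed = config$seed + 101L,
                              human_prefix = p$human_prefix)
  # plant one pathway built around the conserved genes: it becomes genuinely
  # enriched in every system, the conserved-pathway analogue of the conserved
  # gene list
  planted_set <- unique(c(conserved,
                          withr_seed(config$seed + 13L,
                                     sample(rat_genes, max(2, p$n_conserved_genes %/% 2)))))
  ann$gene_sets[["P000"]] <- planted_set
  attr(ann$gene_sets, "description")["P000"] <- "planted conserved pathway"
  # conserved genes must survive ortholog translation for the human system
  ortho <- ann$orthologs
  missing_h <- setdiff(conserved, ortho$rat_gene)
  if (length(missing_h) > 0) {
    ortho <- rbind(ortho, data.frame(
      human_gene = paste0(p$human_prefix, missing_h), rat_gene = missing_h,
      stringsAsFactors = FALSE))
    class(ortho) <- c("OrthologMap", "data.frame")
  }
  atomic_write(function(f) write_gmt(ann$gene_sets, f),
               stx_path(config, "gene_sets.gmt"))
  atomic_write(function(f) write.table(ann$tf_targets, f, sep = "\t",
                                       quote = FALSE, row.names = FALSE),
               stx_path(config, "tf_targets.tsv"))
  atomic_write(function(f) write.table(ortho, f, sep = "\t", quote = FALSE,
                                       row.names = FALSE),
               stx_path(config, "orthologs.tsv"))
  mies <- unique(ann$tf_targets$tf)
  atomic_write(function(f) writeLines(mies, f), stx_path(config, "mies.txt"))
  for (i in seq_along(config$test_systems)) {
    system <- config$test_systems[i]
    is_human <- grepl("^human", system)
    gene_ids <- if (is_human) paste0(p$human_prefix, rat_genes) else rat_genes
    cons <- if (is_human) paste0(p$human_prefix, conserved) else conserved
    design <- study_design(
      n_genes = p$n_genes, chemicals = p$chemicals,
      dose_levels = p$dose_levels, durations = p$durations,
      test_system = system, replicates_per_group = p$replicates_per_group,
      deg_fraction_by_dose = unlist(p$deg_fraction_by_dose),
      effect_size = p$effect_size, noise_sd = p$noise_sd,
      baseline_mean = p$baseline_mean, baseline_sd = p$baseline_sd,
      gene_ids = gene_ids, conserved_genes = cons,
      conserved_shift = p$conserved_shift,
      unannotated_fraction = p$unannotated_fraction,
      seed = config$seed + 211L * i)
    gen <- generate_expression_study(design)
    write_expression_study(gen$study,
                           stx_path(config, sprintf("expr_%s.tsv", system)),
                           stx_path(config, sprintf("meta_%s.tsv", system)))
    atomic_write(function(f) write.table(gen$truth, f, sep = "\t",
                                         quote = FALSE, row.names = FALSE),
                 stx_path(config, sprintf("truth_%s.tsv", system)))
    ann_df <- data.frame(gene_id = names(gen$annotation),
                         external_id = unname(gen$annotation),
                         stringsAsFactors = FALSE)
    atomic_write(function(f) write.table(ann_df, f, sep = "\t", quote = FALSE,
                                         row.names = FALSE),
                 stx_path(config, sprintf("annotation_%s.tsv", system)))
  }
  rat_model <- generate_toy_model(p$n_internal_metabolites, p$n_exchange,
                                  rat_genes, seed = config$seed + 307L)
  write_metabolic_model(rat_model, stx_path(config, "model_rat.json"))
  # human model: same reconciled topology, GPR genes relabeled to human IDs
  human_model <- rat_model
  human_model$reactions$gpr <- vapply(rat_model$reactions$gpr, function(gpr) {
    if (!nzchar(gpr)) return("")
    for (g in rev(rat_genes)) {
      gpr <- gsub(paste0("\\b", g, "\\b"), paste0(p$human_prefix, g), gpr)
    }
    gpr
  }, character(1), USE.NAMES = FALSE)
  human_model <- metabolic_model(human_model$reactions,
                                 human_model$metabolites, human_model$S)
  write_metabolic_model(human_model, stx_path(config, "model_human.json"))
  invisible(outputs)
}

read_system_study <- function(config, system, filtered = FALSE) {
  prefix <- if (filtered) "filtered_" else ""
  read_expression_study(
    stx_path(config, sprintf("%sexpr_%s.tsv", prefix, system)),
    stx_path(config, sprintf("meta_%s.tsv", system)))
}

stage_prep <- function(config, plan_only = FALSE) {
  inputs <- c(system_files(config, "expr_%s.tsv"),
              system_files(config, "meta_%s.tsv"),
              system_files(config, "annotation_%s.tsv"))
  outputs <- c(system_files(config, "filtered_expr_%s.tsv"),
               system_files(config, "fc_%s.tsv"),
               system_files(config, "fc_discrete_%s.tsv"))
  if (plan_only) {
    return(list(inputs = inputs, outputs = outputs, params = config$prep))
  }
  for (system in config$test_systems) {
    study <- read_system_study(config, system)
    ann_df <- read.delim(stx_path(config, sprintf("annotation_%s.tsv", system)),
                         colClasses = "character")
    annotation <- setNames(ann_df$external_id, ann_df$gene_id)
    annotation[annotation == "" | annotation == "NA"] <- NA
    min_expr <- config$prep$min_expression
    filtered <- filter_genes(study, annotation,
                             variance_quantile = config$prep$variance_quantile,
                             min_expression = if (is.null(min_expr)) -Inf else min_expr)
    atomic_write(function(f) {
      write.table(data.frame(gene_id = rownames(filtered$values),
                             filtered$values, check.names = FALSE),
                  f, sep = "\t", quote = FALSE, row.names = FALSE)
    }, stx_path(config, sprintf("filtered_expr_%s.tsv", system)))
    fc <- compute_log_ratios(average_replicates(filtered))
    write_fold_changes(fc, stx_path(config, sprintf("fc_%s.tsv", system)))
    disc <- discretize_fc(fc, cutoff = config$prep$fc_cutoff)
    atomic_write(function(f) {
      write.table(data.frame(gene_id = rownames(disc), disc,
                             check.names = FALSE),
                  f, sep = "\t", quote = FALSE, row.names = FALSE)
    }, stx_path(config, sprintf("fc_discrete_%s.tsv", system)))
  }
  invisible(outputs)
}

stage_deg <- function(config, plan_only = FALSE) {
  inputs <- c(system_files(config, "filtered_expr_%s.tsv"),
              system_files(config, "meta_%s.tsv"))
  outputs <- system_files(config, "degs_%s.tsv")
  if (plan_only) {
    return(list(inputs = inputs, outputs = outputs,
                params = c(config$deg, seed = config$seed)))
  }
  for (i in seq_along(config$test_systems)) {
    system <- config$test_systems[i]
    study <- read_system_study(config, system, filtered = TRUE)
    degs <- study_degs(study, pfp_cutoff = config$deg$pfp_cutoff,
                       n_permutations = config$deg$n_permutations,
                       seed = config$seed + 401L * i)
    atomic_write(function(f) write.table(degs, f, sep = "\t", quote = FALSE,
                                         row.names = FALSE),
                 stx_path(config, sprintf("degs_%s.tsv", system)))
  }
  invisible(outputs)
}

read_deg_table <- function(config, system) {
  df <- read.delim(stx_path(config, sprintf("degs_%s.tsv", system)),
                   colClasses = c(condition = "character",
                                  gene = "character",
                                  direction = "character"))
  class(df) <- c("DEGTable", "data.frame")
  df
}

#' Translate a per-system DEG table and universe to the shared (rat) ID space
#' @keywords internal
translate_if_human <- function(genes, system, orthologs) {
  if (grepl("^human", system)) map_orthologs(genes, orthologs) else genes
}

stage_enrich <- function(config, plan_only = FALSE) {
  inputs <- c(system_files(config, "degs_%s.tsv"),
              system_files(config, "filtered_expr_%s.tsv"),
              "gene_sets.gmt", "orthologs.tsv")
  outputs <- c(system_files(config, "enrich_%s.tsv"),
               "pathway_edges.tsv", "pathway_nodes.tsv")
  if (plan_only) {
    return(list(inputs = inputs, outputs = outputs, params = config$enrich))
  }
  collection <- read_gmt(stx_path(config, "gene_sets.gmt"))
  orthologs <- read_orthologs(stx_path(config, "orthologs.tsv"))
  for (system in config$test_systems) {
    study <- read_system_study(config, system, filtered = TRUE)
    universe <- translate_if_human(rownames(study$values), system, orthologs)
    degs <- read_deg_table(config, system)
    conditions <- unique(degs$condition)
    res <- do.call(rbind, lapply(conditions, function(cond) {
      cond_degs <- translate_if_human(degs$gene[degs$condition == cond],
                                      system, orthologs)
      hypergeom_enrich(intersect(cond_degs, universe), universe, collection,
                       alpha = config$enrich$alpha, condition = cond)
    }))
    if (is.null(res)) {
      res <- hypergeom_enrich(character(0), universe, collection,
                              alpha = config$enrich$alpha,
                              condition = "none")[0, ]
    }
    res$hit_genes <- vapply(res$hit_genes, paste, character(1),
                            collapse = ",")
    atomic_write(function(f) write.table(res, f, sep = "\t", quote = FALSE,
                                         row.names = FALSE),
                 stx_path(config, sprintf("enrich_%s.tsv", system)))
  }
  # chemical-pathway network from the rat in vivo system
  ref <- read.delim(stx_path(config, "enrich_rat_in_vivo.tsv"))
  edges <- chemical_pathway_network(ref, min_hits = config$enrich$min_hits)
  write_pathway_network(edges, stx_path(config, "pathway_edges.tsv"),
                        stx_path(config, "pathway_nodes.tsv"))
  invisible(outputs)
}

stage_mie <- function(config, plan_only = FALSE) {
  inputs <- c("degs_rat_in_vivo.tsv", "filtered_expr_rat_in_vivo.tsv",
              "tf_targets.tsv", "mies.txt")
  outputs <- "mie_table.tsv"
  if (plan_only) {
    return(list(inputs = inputs, outputs = outputs, params = config$mie))
  }
  tf_map <- read_tf_targets(stx_path(config, "tf_targets.tsv"))
  mies <- readLines(stx_path(config, "mies.txt"))
  study <- read_system_study(config, "rat_in_vivo", filtered = TRUE)
  mapped <- map_targets(tf_map, mies, rownames(study$values))
  degs <- read_deg_table(config, "rat_in_vivo")
  table <- score_mie_activation(degs, mapped,
                                min_mapped = config$mie$min_mapped,
                                flag_threshold = config$mie$flag_threshold)
  atomic_write(function(f) write.table(table, f, sep = "\t", quote = FALSE,
                                       row.names = FALSE),
               stx_path(config, "mie_table.tsv"))
  invisible(outputs)
}

stage_timbr <- function(config, plan_only = FALSE) {
  inputs <- c(system_files(config, "fc_%s.tsv"),
              system_files(config, "degs_%s.tsv"),
              "model_rat.json", "model_human.json")
  outputs <- system_files(config, "timbr_%s.tsv")
  if (plan_only) {
    return(list(inputs = inputs, outputs = outputs, params = config$timbr))
  }
  for (system in config$test_systems) {
    model_file <- if (grepl("^human", system)) "model_human.json" else "model_rat.json"
    model <- read_metabolic_model(stx_path(config, model_file))
    fc <- read_fold_changes(stx_path(config, sprintf("fc_%s.tsv", system)))
    degs <- read_deg_table(config, system)
    res <- timbr_study(model, fc, degs,
                       opt_fraction = config$timbr$opt_fraction,
                       scale = config$timbr$scale,
                       baseline = config$timbr$baseline,
                       cutoff = config$timbr$cutoff)
    atomic_write(function(f) write.table(res, f, sep = "\t", quote = FALSE,
                                         row.names = FALSE),
                 stx_path(config, sprintf("timbr_%s.tsv", system)))
  }
  invisible(outputs)
}

stage_overlap <- function(config, plan_only = FALSE) {
  inputs <- c(system_files(config, "degs_%s.tsv"),
              system_files(config, "enrich_%s.tsv"),
              system_files(config, "timbr_%s.tsv"),
              "orthologs.tsv")
  outputs <- c("overlap_genes.json", "overlap_pathways.json",
               "overlap_metabolites.json", "frequent_items.tsv",
               "metabolite_clusters.tsv", "condition_clusters.tsv",
               "dose_composition.tsv")
  if (plan_only) {
    return(list(inputs = inputs, outputs = outputs, params = config$overlap))
  }
  orthologs <- read_orthologs(stx_path(config, "orthologs.tsv"))
  thr <- config$overlap$threshold_fraction
  freq_rows <- list()
  per_class_sets <- list(gene = list(), pathway = list(), metabolite = list())
  for (system in config$test_systems) {
    degs <- read_deg_table(config, system)
    all_conditions <- all_system_conditions(config, system)
    by_cond <- split(degs$gene, factor(degs$condition, levels = all_conditions))
    freq_genes <- frequent_items(by_cond, thr)
    per_class_sets$gene[[system]] <-
      translate_if_human(as.character(freq_genes), system, orthologs)
    enr <- read.delim(stx_path(config, sprintf("enrich_%s.tsv", system)))
    reported <- filter_reported(enr, min_hits = config$enrich$min_hits)
    by_cond_p <- split(reported$set_id,
                       factor(reported$condition, levels = all_conditions))
    per_class_sets$pathway[[system]] <-
      as.character(frequent_items(by_cond_p, thr))
    tim <- read.delim(stx_path(config, sprintf("timbr_%s.tsv", system)))
    changed <- tim[tim$call != "unchanged", , drop = FALSE]
    by_cond_m <- split(changed$metabolite,
                       factor(changed$condition, levels = all_conditions))
    per_class_sets$metabolite[[system]] <-
      as.character(frequent_items(by_cond_m, thr))
    for (cls in names(per_class_sets)) {
      items <- per_class_sets[[cls]][[system]]
      freq_rows[[paste(system, cls)]] <- data.frame(
        test_system = rep(system, length(items)),
        class = rep(cls, length(items)),
        item = items, stringsAsFactors = FALSE)
    }
  }
  freq_df <- do.call(rbind, freq_rows)
  atomic_write(function(f) write.table(freq_df, f, sep = "\t", quote = FALSE,
                                       row.names = FALSE),
               stx_path(config, "frequent_items.tsv"))
  for (cls in names(per_class_sets)) {
    sets <- per_class_sets[[cls]][config$test_systems]
    report <- three_way_overlap(sets[[1]], sets[[2]], sets[[3]],
                                labels = config$test_systems)
    out_file <- stx_path(config, sprintf("overlap_%ss.json", cls))
    jsonlite::write_json(
      list(labels = report$labels,
           regions = as.list(report$regions),
           triple = report$triple,
           union_size = report$union_size,
           per_system_counts = lapply(report$sets, length)),
      out_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  # cluster the rat in vivo TIMBR score matrix
  tim <- read.delim(stx_path(config, "timbr_rat_in_vivo.tsv"))
  score_mat <- score_matrix(tim)
  k_m <- min(config$overlap$k_metabolite, nrow(score_mat))
  k_c <- min(config$overlap$k_condition, ncol(score_mat))
  clusters <- cluster_scores(score_mat, k_metabolite = k_m, k_condition = k_c)
  atomic_write(function(f) write.table(
    data.frame(metabolite = names(clusters$metabolite_clusters),
               cluster = unname(clusters$metabolite_clusters)),
    f, sep = "\t", quote = FALSE, row.names = FALSE),
    stx_path(config, "metabolite_clusters.tsv"))
  atomic_write(function(f) write.table(
    data.frame(condition = names(clusters$condition_clusters),
               cluster = unname(clusters$condition_clusters)),
    f, sep = "\t", quote = FALSE, row.names = FALSE),
    stx_path(config, "condition_clusters.tsv"))
  comp <- dose_composition(clusters$condition_clusters)
  atomic_write(function(f) write.table(comp, f, sep = "\t", quote = FALSE,
                                       row.names = FALSE),
               stx_path(config, "dose_composition.tsv"))
  invisible(outputs)
}

# every treatment condition of a system (denominator of the frequency rule)
all_system_conditions <- function(config, system) {
  md <- read.delim(stx_path(config, sprintf("meta_%s.tsv", system)),
                   colClasses = "character")
  trt <- md[md$dose_level != "control", , drop = FALSE]
  unique(condition_key(trt$chemical, trt$dose_level, trt$duration,
                       trt$test_system))
}

# long TIMBR result -> metabolites x conditions X_s matrix
score_matrix <- function(timbr_df) {
  mets <- unique(timbr_df$metabolite)
  conds <- unique(timbr_df$condition)
  mat <- matrix(NA_real_, length(mets), length(conds),
                dimnames = list(mets, conds))
  mat[cbind(match(timbr_df$metabolite, mets),
            match(timbr_df$condition, conds))] <- timbr_df$X_s
  if (anyNA(mat)) mat[is.na(mat)] <- 0
  mat
}

collect_overlap_results <- function(config) {
  reports <- lapply(c("gene", "pathway", "metabolite"), function(cls) {
    jsonlite::read_json(stx_path(config, sprintf("overlap_%ss.json", cls)),
                        simplifyVector = TRUE)
  })
  names(reports) <- c("genes", "pathways", "metabolites")
  list(overlaps = reports,
       metabolite_clusters = read.delim(stx_path(config, "metabolite_clusters.tsv")),
       condition_clusters = read.delim(stx_path(config, "condition_clusters.tsv")),
       dose_composition = read.delim(stx_path(config, "dose_composition.tsv")))
}
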