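# Synthetic-data generators: expression studies with planted dose-dependent
# differential expression, a toy stoichiometric model with GPR rules over the
# synthetic gene universe, gene sets, TF-target maps, and ortholog tables.
# Every generator is a pure function of (design, seed) and returns its ground
# truth so recovery can be measured.

#' Study design for the expression generator
#'
#' Defaults encode the exposure-study structure the pipeline targets:
#' multi-dose, multi-duration chemical exposures with a shared control group
#' per (chemical, duration), 3 replicates per group, a DEG fraction that grows
#' with dose (more DEGs at high dose, not larger fold changes), planted log2
#' shifts with half-normal magnitude around `effect_size`, and Gaussian
#' within-group noise.
#'
#' @param n_genes gene-universe size; default 2000.
#' @param chemicals character vector of chemical names.
#' @param dose_levels subset of `c("low", "medium", "high")`.
#' @param durations character labels, e.g. `c("24h", "8d")`.
#' @param test_system one of the three test systems.
#' @param replicates_per_group replicates per treatment/control group
#'   (>= 2); default 3.
#' @param deg_fraction_by_dose named fractions, monotone non-decreasing with
#'   dose; default `c(low = 0.02, medium = 0.05, high = 0.10)`.
#' @param effect_size mean planted |log2 shift|; default 1.5.
#' @param noise_sd within-group standard deviation of log2 intensity;
#'   default 0.3.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   intensities (drawn once per study); defaults 7 and 2.
#' @param gene_ids optional explicit gene IDs (length `n_genes`); default
#'   `g0001...`.
#' @param conserved_genes gene IDs planted as up-regulated DEGs in every
#'   non-control condition (the cross-system conserved signal); default none.
#' @param conserved_shift log2 shift of the conserved genes; default 2.
#' @param unannotated_fraction fraction of genes left without an external
#'   annotation ID; default 0.05.
#' @param seed integer seed.
#' @return a validated `StudyDesign` list.
#' @export
study_design <- function(n_genes = 2000,
                         chemicals = c("chemA", "chemB", "chemC"),
                         dose_levels = c("low", "medium", "high"),
                         durations = c("24h", "8d"),
                         test_system = "rat_in_vivo",
                         replicates_per_group = 3,
                         deg_fraction_by_dose = c(low = 0.02, medium = 0.05,
                                                  high = 0.10),
                         effect_size = 1.5, noise_sd = 0.3,
                         baseline_mean = 7, baseline_sd = 2,
                         gene_ids = NULL,
                         conserved_genes = character(0),
                         conserved_shift = 2,
                         unannotated_fraction = 0.05,
                         seed = 1L) {
  stopifnot(n_genes >= 2, replicates_per_group >= 2,
            all(dose_levels %in% c("low", "medium", "high")),
            test_system %in% TEST_SYSTEMS,
            effect_size >= 0, noise_sd > 0,
            unannotated_fraction >= 0, unannotated_fraction < 1)
  frac <- deg_fraction_by_dose[dose_levels]
  if (anyNA(frac) || any(frac < 0) || any(frac > 1)) {
    stop("deg_fraction_by_dose must name every dose level with a fraction in [0,1]")
  }
  ordered_doses <- intersect(c("low", "medium", "high"), dose_levels)
  if (is.unsorted(deg_fraction_by_dose[ordered_doses])) {
    stop("deg_fraction_by_dose must be non-decreasing with dose")
  }
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
  }
  stopifnot(length(gene_ids) == n_genes, !anyDuplicated(gene_ids),
            all(conserved_genes %in% gene_ids))
  structure(list(n_genes = n_genes, chemicals = chemicals,
                 dose_levels = dose_levels, durations = durations,
                 test_system = test_system,
                 replicates_per_group = replicates_per_group,
                 deg_fraction_by_dose = frac,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 gene_ids = gene_ids, conserved_genes = conserved_genes,
                 conserved_shift = conserved_shift,
                 unannotated_fraction = unannotated_fraction,
                 seed = as.integer(seed)),
            class = "StudyDesign")
}

#' Generate an expression study with planted differential expression
#'
#' Per-gene baselines are drawn once and shared across all conditions. For
#' each non-control condition, a dose-dependent fraction of genes receives a
#' log2 shift of equiprobable sign whose magnitude is half-normal with mean
#' `effect_size`; conserved genes are additionally planted up-regulated in
#' every condition. Replicate values are baseline + shift + N(0, noise_sd).
#' Controls are shared per (chemical, duration).
#'
#' @param design a `StudyDesign` from [study_design()].
#' @return list with `study` (an `ExpressionStudy`), `truth` (data.frame
#'   `(condition, gene, direction, shift)`, planted effects only), and
#'   `annotation` (named vector gene -> external ID, `NA` = unannotated).
#' @export
generate_expression_study <- function(design) {
  stopifnot(inherits(design, "StudyDesign"))
  withr_seed(design$seed, {
    genes <- design$gene_ids
    G <- design$n_genes
    baseline <- rnorm(G, design$baseline_mean, design$baseline_sd)
    names(baseline) <- genes
    # planted |shift| is folded-normal around effect_size (spread = a third of
    # it), so effects vary realistically without a mass of near-zero shifts
    shift_sd <- design$effect_size / 3
    n_unann <- round(design$unannotated_fraction * G)
    annotation <- setNames(paste0("ext:", genes), genes)
    # conserved signal genes stay annotated so filtering cannot drop them
    droppable <- setdiff(genes, design$conserved_genes)
    if (n_unann > 0) {
      annotation[sample(droppable, min(n_unann, length(droppable)))] <- NA
    }
    values <- NULL
    meta <- list()
    truth <- list()
    sample_n <- 0L
    for (chem in design$chemicals) {
      for (dur in design$durations) {
        ctl_group <- paste("ctl", chem, dur, sep = "_")
        ctl_vals <- baseline +
          matrix(rnorm(G * design$replicates_per_group, 0, design$noise_sd),
                 G, design$replicates_per_group)
        ctl_ids <- sprintf("s%04d", sample_n + seq_len(design$replicates_per_group))
        sample_n <- sample_n + design$replicates_per_group
        colnames(ctl_vals) <- ctl_ids
        values <- cbind(values, ctl_vals)
        meta[[length(meta) + 1]] <- data.frame(
          sample_id = ctl_ids, chemical = chem, dose_level = "control",
          duration = dur, test_system = design$test_system,
          replicate = seq_along(ctl_ids), control_group = ctl_group,
          stringsAsFactors = FALSE)
        for (dose in design$dose_levels) {
          cond <- condition_key(chem, dose, dur, design$test_system)
          frac <- design$deg_fraction_by_dose[[dose]]
          n_deg <- round(frac * G)
          shift <- numeric(G)
          names(shift) <- genes
          if (n_deg > 0) {
            idx <- sample.int(G, n_deg)
            signs <- sample(c(-1, 1), n_deg, replace = TRUE)
            shift[idx] <- signs * abs(rnorm(n_deg, design$effect_size, shift_sd))
          }
          if (length(design$conserved_genes) > 0) {
            shift[design$conserved_genes] <- design$conserved_shift
          }
          planted <- which(shift != 0)
          if (length(planted) > 0) {
            truth[[length(truth) + 1]] <- data.frame(
              condition = cond, gene = genes[planted],
              direction = ifelse(shift[planted] > 0, "up", "down"),
              shift = unname(shift[planted]), stringsAsFactors = FALSE)
          }
          trt_vals <- baseline + shift +
            matrix(rnorm(G * design$replicates_per_group, 0, design$noise_sd),
                   G, design$replicates_per_group)
          trt_ids <- sprintf("s%04d", sample_n + seq_len(design$replicates_per_group))
          sample_n <- sample_n + design$replicates_per_group
          colnames(trt_vals) <- trt_ids
          values <- cbind(values, trt_vals)
          meta[[length(meta) + 1]] <- data.frame(
            sample_id = trt_ids, chemical = chem, dose_level = dose,
            duration = dur, test_system = design$test_system,
            replicate = seq_along(trt_ids), control_group = ctl_group,
            stringsAsFactors = FALSE)
        }
      }
    }
    rownames(values) <- genes
    truth <- if (length(truth) > 0) do.call(rbind, truth) else
      data.frame(condition = character(0), gene = character(0),
                 direction = character(0), shift = numeric(0),
                 stringsAsFactors = FALSE)
    list(study = expression_study(values, do.call(rbind, meta)),
         truth = truth, annotation = annotation)
  })
}

#' Generate a toy metabolic model
#'
#' Builds a deterministic, mass-balanced topology that is feasible by
#' construction: `n_exchange` exchangeable metabolites (the first
#' `floor(n_exchange/2)`, at least one, are uptakes with exchange lower bound
#' -10; the rest secrete only), connected through a chain of
#' `n_internal_metabolites` internal metabolites to a hub metabolite, with
#' every other exchangeable metabolite joined to the hub by a reversible
#' conversion. With two or more uptakes every exchangeable metabolite has
#' positive maximum production. Every internal reaction carries a GPR over
#' 1-3 genes drawn from `gene_universe`; exchange reactions have no GPR.
#'
#' @param n_internal_metabolites chain length (>= 1); default 3.
#' @param n_exchange number of exchangeable metabolites (>= 2); default 4.
#' @param gene_universe character vector of gene IDs for GPRs.
#' @param seed integer seed (drives GPR gene assignment).
#' @param max_retries regeneration cap for the feasibility check; default 3.
#' @return a `MetabolicModel`.
#' @export
generate_toy_model <- function(n_internal_metabolites = 3, n_exchange = 4,
                               gene_universe, seed = 1L, max_retries = 3) {
  stopifnot(n_exchange >= 2, n_internal_metabolites >= 1,
            length(gene_universe) >= 3)
  n_uptake <- max(1L, n_exchange %/% 2L)
  for (attempt in seq_len(max_retries)) {
    model <- withr_seed(seed + attempt - 1L, {
      ex_mets <- sprintf("xmet%02d", seq_len(n_exchange))
      int_mets <- sprintf("imet%02d", seq_len(n_internal_metabolites))
      hub <- "hub"
      mets <- data.frame(
        id = c(ex_mets, int_mets, hub),
        name = c(paste("exchangeable metabolite", seq_len(n_exchange)),
                 paste("internal metabolite", seq_len(n_internal_metabolites)),
                 "hub metabolite"),
        exchangeable = c(rep(TRUE, n_exchange),
                         rep(FALSE, n_internal_metabolites + 1)),
        stringsAsFactors = FALSE)
      rxns <- list()
      stoich <- list()
      add_rxn <- function(id, name, lb, ub, gpr, sto) {
        rxns[[length(rxns) + 1]] <<- data.frame(
          id = id, name = name, lb = lb, ub = ub, gpr = gpr,
          stringsAsFactors = FALSE)
        stoich[[id]] <<- sto
      }
      random_gpr <- function() {
        g <- sample(gene_universe, sample(1:3, 1))
        if (length(g) == 1) return(g)
        if (length(g) == 2) return(paste(g[1], sample(c("AND", "OR"), 1), g[2]))
        sprintf("%s AND (%s OR %s)", g[1], g[2], g[3])
      }
      for (i in seq_len(n_exchange)) {
        lb <- if (i <= n_uptake) -10 else 0
        add_rxn(paste0("EX_", ex_mets[i]),
                paste("exchange of", ex_mets[i]), lb, 1000, "",
                setNames(-1, ex_mets[i]))
      }
      chain <- c(ex_mets[1], int_mets, hub)
      for (j in seq_len(length(chain) - 1)) {
        add_rxn(sprintf("R_chain%02d", j),
                paste(chain[j], "to", chain[j + 1]), -1000, 1000,
                random_gpr(), setNames(c(-1, 1), c(chain[j], chain[j + 1])))
      }
      for (i in 2:n_exchange) {
        add_rxn(sprintf("R_conv%02d", i),
                paste(ex_mets[i], "to hub"), -1000, 1000,
                random_gpr(), setNames(c(-1, 1), c(ex_mets[i], hub)))
      }
      rxns <- do.call(rbind, rxns)
      S <- matrix(0, nrow(mets), nrow(rxns),
                  dimnames = list(mets$id, rxns$id))
      for (rid in names(stoich)) S[names(stoich[[rid]]), rid] <- stoich[[rid]]
      metabolic_model(rxns, mets, S)
    })
    producible <- vapply(model$metabolites$id[model$metabolites$exchangeable],
                         function(m) max_production(model, m) > 0, logical(1))
    target <- if (n_uptake >= 2) all(producible) else any(producible)
    if (target) return(model)
    stx_log("TOY_MODEL_RETRY",
            sprintf("attempt %d infeasible, regenerating", attempt),
            level = "WARN")
  }
  stop("could not generate a feasible toy model in ", max_retries, " attempts")
}

#' Generate gene sets, TF-target map, and ortholog table
#'
#' Gene sets of size 10-50 (clamped to the universe) with free overlap; each
#' TF receives 5-50 targets; the ortholog table covers `ortholog_fraction` of
#' the universe, mostly one-to-one with a planted minority of one-to-many
#' human genes. Human IDs are the rat IDs under `human_prefix`.
#'
#' @param gene_universe character vector of (rat) gene IDs.
#' @param n_sets number of gene sets; default 10.
#' @param n_tfs number of transcription factors; default 5.
#' @param seed integer seed.
#' @param set_size_range,targets_range integer length-2 ranges.
#' @param ortholog_fraction fraction of genes with an ortholog; default 0.9.
#' @param one_to_many_fraction fraction of mapped human genes given a second
#'   rat ortholog; default 0.05.
#' @param human_prefix prefix deriving human from rat IDs; default `"h_"`.
#' @return list `(gene_sets, tf_targets, orthologs)` of the loader types.
#' @export
generate_annotations <- function(gene_universe, n_sets = 10, n_tfs = 5,
                                 seed = 1L,
                                 set_size_range = c(10, 50),
                                 targets_range = c(5, 50),
                                 ortholog_fraction = 0.9,
                                 one_to_many_fraction = 0.05,
                                 human_prefix = "h_") {
  stopifnot(length(gene_universe) > 0, n_sets >= 1, n_tfs >= 1)
  withr_seed(seed, {
    G <- length(gene_universe)
    sizes <- pmin(sample(set_size_range[1]:set_size_range[2], n_sets,
                         replace = TRUE), G)
    sets <- lapply(sizes, function(sz) sample(gene_universe, sz))
    names(sets) <- sprintf("P%03d", seq_len(n_sets))
    gene_sets <- structure(sets,
                           description = setNames(
                             sprintf("synthetic pathway %d", seq_len(n_sets)),
                             names(sets)),
                           class = "GeneSetCollection")
    tfs <- sample(gene_universe, n_tfs)
    tf_rows <- do.call(rbind, lapply(tfs, function(tf) {
      n_t <- min(sample(targets_range[1]:targets_range[2], 1), G - 1)
      targets <- sample(setdiff(gene_universe, tf), n_t)
      data.frame(tf = tf, target = targets,
                 mode = sample(c("activation", "repression", "unknown"),
                               n_t, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    class(tf_rows) <- c("TFTargetMap", "data.frame")
    mapped <- sample(gene_universe, round(ortholog_fraction * G))
    ortho <- data.frame(human_gene = paste0(human_prefix, mapped),
                        rat_gene = mapped, stringsAsFactors = FALSE)
    n_multi <- round(one_to_many_fraction * length(mapped))
    if (n_multi > 0 && G > 1) {
      multi_h <- sample(ortho$human_gene, n_multi)
      extra <- data.frame(human_gene = multi_h,
                          rat_gene = sample(gene_universe, n_multi),
                          stringsAsFactors = FALSE)
      ortho <- unique(rbind(ortho, extra))
    }
    rownames(ortho) <- NULL
    class(ortho) <- c("OrthologMap", "data.frame")
    list(gene_sets = gene_sets, tf_targets = tf_rows, orthologs = ortho)
  })
}
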