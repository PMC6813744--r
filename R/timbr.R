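# TIMBR (Transcriptionally Inferred Metabolic Biomarker Response): predicts
# per-condition metabolite increases/decreases from expression changes mapped
# onto a genome-scale metabolic network.
#
# Pipeline per condition: DEG log2 fold changes -> per-reaction fold change
# via GPR rules (AND -> min, OR -> max) -> control/treatment reaction weights
# w = baseline * 2^(+-scale * delta) -> for every exchangeable metabolite, the
# global network demand X = min sum(w |v|) subject to steady state, bounds,
# and producing at least opt_fraction of the metabolite's maximum production
# flux -> relative production score X_raw = (X_control - X_treatment) /
# (X_control + X_treatment) -> z-transform across exchangeable metabolites ->
# increased / unchanged / decreased calls at |X_s| > 0.1.

#' Map gene log2 fold changes onto reactions through GPR rules
#'
#' AND combines operands by signed minimum (a complex is limited by its most
#' depleted subunit), OR by signed maximum (isozymes are dominated by the most
#' induced member). Genes absent from `gene_fc` contribute 0; reactions with
#' an empty GPR get 0.
#'
#' @param model a `MetabolicModel`.
#' @param gene_fc named numeric vector of log2 fold changes (typically
#'   restricted to the condition's DEGs).
#' @return named numeric vector, one fold change per reaction.
#' @export
reaction_log2fc <- function(model, gene_fc) {
  stopifnot(inherits(model, "MetabolicModel"))
  vapply(model$gpr_trees, eval_gpr, numeric(1), values = gene_fc)
}

#' Control and treatment reaction weights
#'
#' `w_treatment = baseline * 2^(-scale * delta)` and
#' `w_control = baseline * 2^(+scale * delta)`: up-regulation makes a reaction
#' cheaper to use in the treatment network and costlier in the control
#' network, and `w_treatment * w_control = baseline^2` for every reaction.
#'
#' @param delta named numeric vector of per-reaction log2 fold changes
#'   (from [reaction_log2fc()]).
#' @param scale positive exponent scale; default 0.5.
#' @param baseline baseline weight for unchanged reactions; default 1.
#' @return data.frame `(reaction, delta, w_control, w_treatment)`.
#' @export
compute_weights <- function(delta, scale = 0.5, baseline = 1.0) {
  stopifnot(scale > 0, baseline > 0)
  data.frame(reaction = names(delta), delta = unname(delta),
             w_control = baseline * 2^(scale * delta),
             w_treatment = baseline * 2^(-scale * delta),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply a named bounds profile to a model
#'
#' Boundary conditions (uptake/secretion rates of the experimental medium)
#' enter as fixed exchange-reaction bounds before any LP is solved.
#'
#' @param model a `MetabolicModel`.
#' @param profile named list: reaction ID -> list with optional `lb`, `ub`.
#' @return the model with updated bounds.
#' @export
apply_bounds_profile <- function(model, profile) {
  for (rid in names(profile)) {
    i <- match(rid, model$reactions$id)
    if (is.na(i)) stop("bounds profile references unknown reaction: ", rid)
    if (!is.null(profile[[rid]]$lb)) model$reactions$lb[i] <- profile[[rid]]$lb
    if (!is.null(profile[[rid]]$ub)) model$reactions$ub[i] <- profile[[rid]]$ub
    if (model$reactions$lb[i] > model$reactions$ub[i]) {
      stop("bounds profile makes lb > ub for reaction: ", rid)
    }
  }
  model
}

#' Exchange reaction producing a metabolite
#'
#' @param model a `MetabolicModel`.
#' @param metabolite metabolite ID.
#' @return list `(reaction, sign)`: `sign * v` is the production (secretion)
#'   flux of the metabolite through its exchange reaction.
#' @keywords internal
exchange_for_metabolite <- function(model, metabolite) {
  ex <- model$exchange_reactions
  touching <- ex[model$S[metabolite, ex] != 0]
  if (length(touching) == 0) {
    stop("metabolite has no exchange reaction: ", metabolite)
  }
  rxn <- touching[1]
  # S[met, ex] = -1 means positive flux exports (produces) the metabolite
  list(reaction = rxn, sign = -sign(model$S[metabolite, rxn]))
}

#' Maximum production flux of a metabolite
#'
#' FBA-style LP: maximize the secretion flux of the metabolite's exchange
#' reaction subject to steady state and bounds. Weights play no role here.
#'
#' @param model a `MetabolicModel`.
#' @param metabolite metabolite ID (must be exchangeable).
#' @return non-negative `v_max`; 0 means the metabolite is unproducible under
#'   the current bounds.
#' @export
max_production <- function(model, metabolite) {
  ex <- exchange_for_metabolite(model, metabolite)
  n <- nrow(model$reactions)
  obj <- numeric(n)
  obj[match(ex$reaction, model$reactions$id)] <- ex$sign
  res <- solve_flux_lp(model$S, model$reactions$lb, model$reactions$ub,
                       obj_net = obj, maximize = TRUE)
  if (res$solved == -1) stop("infeasible model when maximizing production of ",
                             metabolite)
  max(res$value, 0)
}

#' Weighted network demand to produce a metabolite
#'
#' Minimizes the weighted sum of absolute fluxes subject to steady state,
#' bounds, and a required production flux `v_opt = opt_fraction * v_max` for
#' the metabolite. The absolute-value objective is linearized by splitting
#' each reaction into non-negative forward and backward parts carrying the
#' same weight.
#'
#' @param model a `MetabolicModel` (bounds already fixed to the condition's
#'   boundary profile).
#' @param weights numeric vector of positive per-reaction weights, in model
#'   reaction order (the control or the treatment column of
#'   [compute_weights()]).
#' @param metabolite metabolite ID.
#' @param opt_fraction fraction of `v_max` that must be produced; default 0.9.
#' @param v_max optional precomputed [max_production()] value (it is
#'   weight-independent, so one computation serves both the control and the
#'   treatment solve).
#' @return list `(metabolite, X, v_max, v_opt, v)`: `X` is the demand,
#'   `v` the optimal net flux vector.
#' @export
network_demand <- function(model, weights, metabolite, opt_fraction = 0.9,
                           v_max = NULL) {
  stopifnot(opt_fraction > 0, opt_fraction <= 1,
            length(weights) == nrow(model$reactions), all(weights > 0))
  if (is.null(v_max)) v_max <- max_production(model, metabolite)
  if (v_max <= 0) {
    stop("metabolite '", metabolite,
         "' has no positive maximum production under current bounds")
  }
  ex <- exchange_for_metabolite(model, metabolite)
  n <- nrow(model$reactions)
  coef <- numeric(n)
  coef[match(ex$reaction, model$reactions$id)] <- ex$sign
  v_opt <- opt_fraction * v_max
  res <- solve_flux_lp(model$S, model$reactions$lb, model$reactions$ub,
                       obj_abs = weights,
                       extra_ge = list(list(coef = coef, rhs = v_opt)))
  if (res$solved == -1) {
    stop("network demand infeasible for metabolite '", metabolite,
         "' at required production ", signif(v_opt, 6))
  }
  list(metabolite = metabolite, X = res$value, v_max = v_max, v_opt = v_opt,
       v = res$v)
}

#' Relative production score
#'
#' `X_raw = (X_control - X_treatment) / (X_control + X_treatment)`. A positive
#' score means the treatment network produces the metabolite more cheaply than
#' the control network (predicted increase). The degenerate 0/0 case scores 0
#' with a log notice.
#'
#' @param x_control,x_treatment non-negative demands.
#' @return numeric in `[-1, 1]`.
#' @export
production_score <- function(x_control, x_treatment) {
  denom <- x_control + x_treatment
  out <- ifelse(denom > 0, (x_control - x_treatment) / denom, 0)
  if (any(denom <= 0)) {
    stx_log("TIMBR_ZERO_DEMAND",
            sprintf("%d metabolite(s) with zero total demand scored 0",
                    sum(denom <= 0)))
  }
  out
}

#' Z-transform production scores and call changes
#'
#' `X_s = (X_raw - mu) / sigma` with `mu`, `sigma` the mean and population
#' standard deviation across the condition's exchangeable metabolites. Calls:
#' increased if `X_s > cutoff`, decreased if `X_s < -cutoff`, else unchanged
#' (strict inequalities). If `sigma = 0` every call is unchanged, with a log
#' notice.
#'
#' @param raw named numeric vector of `X_raw` scores for one condition.
#' @param cutoff call threshold on `X_s`; default 0.1.
#' @return data.frame `(metabolite, X_raw, X_s, call)`.
#' @export
z_scores_and_call <- function(raw, cutoff = 0.1) {
  stopifnot(length(raw) >= 2)
  mu <- mean(raw)
  sigma <- sqrt(mean((raw - mu)^2))   # population sd
  if (sigma > 0) {
    xs <- (raw - mu) / sigma
    call <- ifelse(xs > cutoff, "increased",
                   ifelse(xs < -cutoff, "decreased", "unchanged"))
  } else {
    stx_log("TIMBR_ZERO_SD", "all raw scores equal; every call is 'unchanged'")
    xs <- rep(0, length(raw))
    call <- rep("unchanged", length(raw))
  }
  data.frame(metabolite = names(raw), X_raw = unname(raw), X_s = unname(xs),
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}

#' TIMBR scores for one condition
#'
#' Runs the whole per-condition chain: GPR mapping, weights, one
#' [max_production()] per metabolite shared by both solves, control and
#' treatment [network_demand()], production scores, z-transform, calls.
#'
#' @param model a `MetabolicModel` with bounds already fixed.
#' @param gene_fc named numeric vector: log2FC of the condition's DEGs.
#' @param opt_fraction required fraction of maximum production; default 0.9.
#' @param scale,baseline weight-transform parameters of [compute_weights()].
#' @param cutoff call threshold on `X_s`; default 0.1.
#' @param metabolites optional metabolite subset (e.g. a lipid-related list);
#'   default all exchangeable metabolites with positive maximum production.
#' @return data.frame `(metabolite, X_control, X_treatment, X_raw, X_s, call)`.
#' @export
timbr_condition <- function(model, gene_fc, opt_fraction = 0.9, scale = 0.5,
                            baseline = 1.0, cutoff = 0.1, metabolites = NULL) {
  delta <- reaction_log2fc(model, gene_fc)
  w <- compute_weights(delta, scale, baseline)
  if (is.null(metabolites)) {
    metabolites <- model$metabolites$id[model$metabolites$exchangeable]
  }
  rows <- lapply(metabolites, function(met) {
    v_max <- max_production(model, met)
    if (v_max <= 0) {
      stx_log("TIMBR_UNPRODUCIBLE",
              sprintf("metabolite '%s' unproducible; skipped", met))
      return(NULL)
    }
    xc <- network_demand(model, w$w_control, met, opt_fraction, v_max)$X
    xt <- network_demand(model, w$w_treatment, met, opt_fraction, v_max)$X
    data.frame(metabolite = met, X_control = xc, X_treatment = xt,
               stringsAsFactors = FALSE)
  })
  demands <- do.call(rbind, rows)
  if (is.null(demands) || nrow(demands) < 2) {
    stop("TIMBR needs at least 2 producible exchangeable metabolites")
  }
  raw <- setNames(production_score(demands$X_control, demands$X_treatment),
                  demands$metabolite)
  scored <- z_scores_and_call(raw, cutoff)
  cbind(demands[, c("metabolite", "X_control", "X_treatment")],
        scored[, c("X_raw", "X_s", "call")])
}

#' TIMBR scores across the conditions of a fold-change matrix
#'
#' @param model a `MetabolicModel` with bounds already fixed.
#' @param fc `FoldChangeMatrix` (genes x condition keys).
#' @param deg_table `DEGTable` restricting which genes' fold changes enter the
#'   weights per condition, or `NULL` to use every gene's fold change
#'   (full-matrix mode).
#' @param ... passed to [timbr_condition()].
#' @return data.frame with a `condition` column stacking per-condition
#'   results.
#' @export
timbr_study <- function(model, fc, deg_table = NULL, ...) {
  conditions <- colnames(fc)
  out <- lapply(conditions, function(cond) {
    gene_fc <- fc[, cond]
    if (!is.null(deg_table)) {
      degs <- deg_table$gene[deg_table$condition == cond]
      gene_fc <- gene_fc[intersect(names(gene_fc), degs)]
    }
    res <- timbr_condition(model, gene_fc, ...)
    cbind(condition = cond, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
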