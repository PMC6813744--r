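# Linear programming layer for flux analyses, built on pracma::linprog
# (dense simplex with a Big-M phase).
#
# Every flux LP is posed over split variables x = (v_plus, v_minus) with
# v = v_plus - v_minus and both parts non-negative, so weighted |v| objectives
# are linear and the solver's x >= 0 convention applies directly. Net-flux
# bounds lb <= v <= ub become cap rows v_plus <= max(ub, 0),
# v_minus <= max(-lb, 0) plus explicit net constraints when lb > 0 or ub < 0
# (caps are passed as inequality rows, not box bounds).

#' Solve a flux LP on a stoichiometric model
#'
#' Minimizes (or maximizes) a linear objective over steady-state fluxes:
#' `S v = 0`, `lb <= v <= ub`, plus optional extra `coef . v >= rhs`
#' constraints.
#'
#' @param S metabolites x reactions stoichiometric matrix.
#' @param lb,ub numeric bound vectors (length = #reactions).
#' @param obj_net numeric vector of objective coefficients on net flux `v`
#'   (use for FBA-style production maximization), or `NULL`.
#' @param obj_abs numeric vector of non-negative weights on `|v|` (use for
#'   weighted flux minimization), or `NULL`. Exactly one of `obj_net`,
#'   `obj_abs` must be given.
#' @param maximize logical; maximize the objective?
#' @param extra_ge optional list of constraints `list(coef = <net-flux
#'   coefficient vector>, rhs = <scalar>)` imposed as `coef . v >= rhs`.
#' @return list `(value, v, solved)`; `v` is the net flux vector and `solved`
#'   is 1 on success, -1 when infeasible.
#' @keywords internal
solve_flux_lp <- function(S, lb, ub, obj_net = NULL, obj_abs = NULL,
                          maximize = FALSE, extra_ge = list()) {
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n, all(lb <= ub))
  if (is.null(obj_net) == is.null(obj_abs)) {
    stop("give exactly one of obj_net, obj_abs")
  }
  cc <- if (!is.null(obj_net)) c(obj_net, -obj_net) else {
    stopifnot(all(obj_abs >= 0))
    c(obj_abs, obj_abs)
  }
  if (maximize) cc <- -cc
  # caps on the split parts, as <= rows
  A <- diag(2 * n)
  b <- c(pmax(ub, 0), pmax(-lb, 0))
  add_le <- function(coef2n, rhs) {
    A <<- rbind(A, coef2n)
    b <<- c(b, rhs)
  }
  for (j in seq_len(n)) {
    if (lb[j] > 0) {        # forced forward flux: -(v_j) <= -lb_j
      e <- numeric(2 * n); e[j] <- -1; e[n + j] <- 1
      add_le(e, -lb[j])
    }
    if (ub[j] < 0) {        # forced reverse flux: v_j <= ub_j < 0
      e <- numeric(2 * n); e[j] <- 1; e[n + j] <- -1
      add_le(e, ub[j])
    }
  }
  for (con in extra_ge) {
    add_le(c(-con$coef, con$coef), -con$rhs)
  }
  Aeq <- cbind(S, -S)
  beq <- rep(0, nrow(S))
  res <- tryCatch(
    pracma::linprog(cc, A = A, b = b, Aeq = Aeq, beq = beq,
                    maxiter = 200 * (2 * n + length(b) + length(beq)),
                    bigM = 1e6),
    error = function(e) list(x = NA, fval = NA, errno = -9,
                             message = conditionMessage(e)))
  if (anyNA(res$x)) {
    return(list(value = NA_real_, v = setNames(rep(NA_real_, n), colnames(S)),
                solved = -1))
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- colnames(S)
  value <- if (maximize) -res$fval else res$fval
  list(value = unname(value), v = v, solved = 1)
}
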