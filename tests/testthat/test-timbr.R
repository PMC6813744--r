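test_that("weight transform follows the reciprocal 2^(+-scale*delta) form", {
  delta <- c(R1 = 0, R2 = 2, R3 = -1)
  w <- compute_weights(delta, scale = 0.5)
  expect_equal(w$w_control, c(1, 2, 2^(-0.5)))
  expect_equal(w$w_treatment, c(1, 0.5, 2^(0.5)))
  # product invariant: w_t * w_c = baseline^2 for every reaction
  expect_equal(w$w_control * w$w_treatment, rep(1, 3))
  w2 <- compute_weights(delta, scale = 1, baseline = 2)
  expect_equal(w2$w_control * w2$w_treatment, rep(4, 3))
})

test_that("reaction fold changes come from GPR evaluation with absent genes at 0", {
  model <- chain_model()
  delta <- reaction_log2fc(model, c(g1 = 1.5))
  expect_equal(unname(delta), c(0, 1.5, 0))
  expect_equal(unname(reaction_log2fc(model, c(other = 3))), c(0, 0, 0))
})

test_that("maximum production solves the chain FBA by hand", {
  model <- chain_model()
  expect_equal(max_production(model, "B"), 10)
  # blocked metabolite: nothing produces A (its exchange only imports)
  expect_equal(max_production(model, "A"), 0)
  # weights play no role in v_max (contract)
  expect_equal(max_production(model, "B"), 10)
})

test_that("network demand equals the hand LP on the chain and routes around costly paths", {
  model <- chain_model()
  res <- network_demand(model, rep(1, 3), "B", opt_fraction = 1)
  expect_equal(res$X, 30)   # three reactions each carrying flux 10
  expect_equal(res$v_max, 10)
  expect_equal(unname(res$v["EX_B"]), 10)
  expect_equal(as.numeric(model$S %*% res$v), c(0, 0), tolerance = 1e-9)
  # parallel paths: all flux goes through the cheap path
  tp <- two_path_model()
  res2 <- network_demand(tp, c(1, 1, 4, 1), "B", opt_fraction = 1)
  expect_equal(unname(res2$v["R2"]), 0)
  expect_equal(res2$X, 30)   # EX_A + R1 + EX_B at flux 10, weight 1 each
  # independent oracle: minimize over the 1-parameter routing split
  split_obj <- function(t) 10 + (1 * t + 4 * (1 - t)) * 10 + 10
  expect_equal(res2$X, min(vapply(seq(0, 1, 1e-3), split_obj, numeric(1))),
               tolerance = 1e-9)
})

test_that("demand is non-decreasing in any single weight", {
  tp <- two_path_model()
  base_w <- c(1, 1, 2, 1)
  X0 <- network_demand(tp, base_w, "B", opt_fraction = 0.9)$X
  for (j in seq_along(base_w)) {
    w <- base_w
    w[j] <- w[j] * 3
    expect_gte(network_demand(tp, w, "B", opt_fraction = 0.9)$X + 1e-9, X0)
  }
})

test_that("infeasible production requirements fail with the metabolite named", {
  model <- chain_model()
  closed <- apply_bounds_profile(model, list(EX_A = list(lb = 0)))
  expect_error(network_demand(closed, rep(1, 3), "B", opt_fraction = 1),
               "B")
  expect_error(apply_bounds_profile(model, list(EX_A = list(lb = 2000))),
               "lb > ub")
  expect_error(apply_bounds_profile(model, list(nope = list(lb = 0))),
               "unknown reaction")
})

test_that("production scores are antisymmetric and handle degenerate demands", {
  expect_equal(production_score(60, 20), 0.5)
  expect_equal(production_score(20, 60), -0.5)
  expect_equal(production_score(5, 5), 0)
  expect_equal(production_score(0, 0), 0)
})

test_that("z-transform uses the population convention with strict call cutoffs", {
  res <- z_scores_and_call(c(m1 = 0.5, m2 = -0.5))
  expect_equal(res$X_s, c(1, -1))
  expect_equal(res$call, c("increased", "decreased"))
  # all-equal scores: sigma = 0, everything unchanged
  res2 <- z_scores_and_call(c(m1 = 0.3, m2 = 0.3, m3 = 0.3))
  expect_true(all(res2$call == "unchanged"))
  # X_s exactly at the cutoff is unchanged (strict inequality)
  res3 <- z_scores_and_call(setNames(c(0.1, -0.1), c("a", "b")), cutoff = 1)
  expect_true(all(res3$call == "unchanged"))   # |X_s| = 1, not > 1
  set.seed(9)
  raw4 <- setNames(rnorm(20), paste0("m", 1:20))
  res4 <- z_scores_and_call(raw4)
  expect_equal(mean(res4$X_s), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(res4$X_s^2)), 1, tolerance = 1e-9)
})

test_that("the weight-null identity makes every call unchanged", {
  genes <- sprintf("g%03d", 1:20)
  model <- generate_toy_model(2, 4, genes, seed = 3)
  res <- timbr_condition(model, setNames(numeric(0), character(0)))
  expect_equal(res$X_control, res$X_treatment)
  expect_true(all(res$X_raw == 0))
  expect_true(all(res$call == "unchanged"))
})

test_that("directional sanity: induced path genes give a positive raw score", {
  genes <- sprintf("g%03d", 1:20)
  model <- generate_toy_model(2, 4, genes, seed = 3)
  # up-regulate every gene: treatment network globally cheaper
  fc <- setNames(rep(2, length(genes)), genes)
  res <- timbr_condition(model, fc)
  expect_true(all(res$X_raw >= 0))
  expect_gt(max(res$X_raw), 0)
  # per-metabolite demands: control above treatment
  expect_true(all(res$X_control >= res$X_treatment))
})
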