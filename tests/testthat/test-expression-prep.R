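test_that("filter_genes applies annotation and variance rules", {
  set.seed(1)
  values <- rbind(matrix(rnorm(3 * 8, mean = 7), 3, 8), rep(5, 8))
  rownames(values) <- paste0("g", 1:4)
  colnames(values) <- paste0("s", 1:8)
  md <- data.frame(sample_id = paste0("s", 1:8), chemical = "chemX",
                   dose_level = rep(c("control", "high"), each = 4),
                   duration = "24h", test_system = "rat_in_vivo",
                   replicate = rep(1:4, 2), control_group = "ctl",
                   stringsAsFactors = FALSE)
  study <- expression_study(values, md)

  # quantile 0 and full annotation: identity
  full_ann <- setNames(paste0("e", 1:4), paste0("g", 1:4))
  out0 <- filter_genes(study, full_ann, variance_quantile = 0)
  expect_equal(rownames(out0$values), paste0("g", 1:4))

  # the constant gene has the lowest variance and is removed at quantile 0.25
  out <- filter_genes(study, full_ann, variance_quantile = 0.25)
  expect_false("g4" %in% rownames(out$values))
  expect_equal(nrow(out$values), 3)

  # unannotated genes are removed
  ann <- full_ann
  ann["g2"] <- NA
  out2 <- filter_genes(study, ann, variance_quantile = 0)
  expect_false("g2" %in% rownames(out2$values))

  # re-filtering with the returned cutoff is the identity
  cutoff <- attr(out, "variance_cutoff")
  out_again <- filter_genes(out, full_ann, variance_cutoff = cutoff)
  expect_equal(rownames(out_again$values), rownames(out$values))

  expect_error(filter_genes(study, setNames(rep(NA, 4), paste0("g", 1:4))),
               "all genes removed")
})

test_that("filtering matches an independent recount of both rules", {
  gen <- generate_expression_study(
    study_design(n_genes = 150, chemicals = "chemA", durations = "24h",
                 seed = 4))
  out <- filter_genes(gen$study, gen$annotation, variance_quantile = 0.25)
  # brute-force recount
  ann_ok <- names(gen$annotation)[!is.na(gen$annotation)]
  vars <- apply(gen$study$values, 1, var)
  cutoff <- quantile(vars[ann_ok], 0.25)
  expected <- ann_ok[vars[ann_ok] >= cutoff]
  expect_setequal(rownames(out$values), expected)
})

test_that("replicate averaging is the per-group arithmetic mean", {
  study <- tiny_study()
  gm <- average_replicates(study)
  expect_equal(unname(gm[, "control:ctl_chemX_24h"]), c(1.5, 2.5, 3.5))
  expect_equal(unname(gm[, "chemX|high|24h|rat_in_vivo"]), c(6, 5, 4))
  # single-replicate groups pass through unchanged
  one <- expression_study(study$values[, c("s1", "s3"), drop = FALSE],
                          study$metadata[c(1, 3), ])
  gm1 <- average_replicates(one)
  expect_equal(unname(gm1[, "control:ctl_chemX_24h"]),
               unname(study$values[, "s1"]))
  # order invariance: permuting samples leaves group means unchanged
  perm <- c("s3", "s1", "s4", "s2")
  study_p <- expression_study(study$values[, perm],
                              study$metadata[match(perm, study$metadata$sample_id), ])
  expect_equal(average_replicates(study_p)[, colnames(gm)], gm[, colnames(gm)],
               ignore_attr = TRUE)
})

test_that("log ratios are treatment minus control and antisymmetric", {
  study <- tiny_study()
  fc <- compute_log_ratios(average_replicates(study))
  expect_equal(unname(fc[, 1]), c(4.5, 2.5, 0.5))
  # treatment == control gives an all-zero column
  gm <- average_replicates(study)
  gm[, "chemX|high|24h|rat_in_vivo"] <- gm[, "control:ctl_chemX_24h"]
  expect_equal(unname(compute_log_ratios(gm)[, 1]), c(0, 0, 0))
  # swapping treatment/control labels flips the sign
  swapped <- study$metadata
  swapped$dose_level <- c("high", "high", "control", "control")
  fc_swap <- compute_log_ratios(average_replicates(
    expression_study(study$values, swapped)))
  expect_equal(unname(fc_swap[, 1]), -unname(fc[, 1]))
  expect_error(compute_log_ratios(unclass(gm)[, 1, drop = FALSE],
                                  c(x = "missing")), "missing")
})

test_that("planted log2FC is recovered within noise on synthetic data", {
  d <- study_design(n_genes = 300, chemicals = "chemA", durations = "24h",
                    effect_size = 1.5, noise_sd = 0.3, seed = 8)
  gen <- generate_expression_study(d)
  fc <- compute_log_ratios(average_replicates(gen$study))
  cond <- "chemA|high|24h|rat_in_vivo"
  tr <- gen$truth[gen$truth$condition == cond, ]
  recovered <- fc[tr$gene, cond]
  tol <- 3 * d$noise_sd / sqrt(d$replicates_per_group)
  expect_true(all(abs(recovered - tr$shift) < 3 * tol))
  expect_lt(mean(abs(recovered - tr$shift)), tol)
})

test_that("fold-change discretization uses a closed none-band", {
  x <- matrix(c(0.61, -0.61, 0.6, -0.6, 0, 2), 2, 3)
  d <- discretize_fc(x)
  expect_equal(as.vector(d), c("up", "down", "none", "none", "none", "up"))
  # ternary counts match a brute-force recount on random data
  set.seed(2)
  y <- matrix(rnorm(200, sd = 1), 20, 10)
  dy <- discretize_fc(y, cutoff = 0.6)
  expect_equal(sum(dy == "up"), sum(y > 0.6))
  expect_equal(sum(dy == "down"), sum(y < -0.6))
  expect_equal(sum(dy == "none"), sum(abs(y) <= 0.6))
  expect_error(discretize_fc(y, cutoff = 0), "cutoff > 0")
})
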