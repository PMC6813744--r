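test_that("pairwise fold changes form all treatment x control pairs", {
  study <- tiny_study()
  fc <- pairwise_fold_changes(study, "chemX|high|24h|rat_in_vivo")
  expect_equal(ncol(fc), 4)   # 2 treatment x 2 control
  expect_equal(unname(fc[, "s3_vs_s1"]),
               unname(study$values[, "s3"] - study$values[, "s1"]))
  # column means average to the group-mean log2FC
  gm_fc <- compute_log_ratios(average_replicates(study))
  expect_equal(rowMeans(fc), gm_fc[, 1], ignore_attr = TRUE)
})

test_that("rank product reproduces hand arithmetic and tie rules", {
  # 3 genes, 2 comparisons with up-ranks (1,2), (2,1), (3,3)
  fc <- matrix(c(5, 4, 1,
                 4, 5, 1), nrow = 3,
               dimnames = list(c("a", "b", "c"), NULL))
  rp <- rank_product(fc, "up")
  expect_equal(rp$rp, c(sqrt(2), sqrt(2), 3))
  # a gene ranked first everywhere has rp = 1
  fc2 <- matrix(c(9, 1, 2, 8, 0, 3), nrow = 3,
                dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(rank_product(fc2, "up")$rp[1], 1)
  # an all-tied column contributes rank (G+1)/2 to every gene
  fc3 <- cbind(c(3, 2, 1), c(7, 7, 7))
  rownames(fc3) <- c("a", "b", "c")
  rp3 <- rank_product(fc3, "up")
  expect_equal(rp3$rp, sqrt(c(1, 2, 3) * 2))
})

test_that("rank product is invariant to monotone column transforms and symmetric under sign flip", {
  set.seed(3)
  fc <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(paste0("g", 1:50), NULL))
  rp <- rank_product(fc, "up")
  fc_t <- cbind(exp(fc[, 1]), fc[, 2]^3, 10 * fc[, 3] + 2, atan(fc[, 4]))
  rownames(fc_t) <- rownames(fc)
  expect_equal(rank_product(fc_t, "up")$rp, rp$rp)
  # negating all fold changes swaps the up and down tables exactly
  expect_equal(rank_product(-fc, "down")$rp, rp$rp)
  expect_equal(rank_product(-fc, "up")$rp, rank_product(fc, "down")$rp)
})

test_that("pfp estimation is seed-deterministic and monotone along rank", {
  set.seed(4)
  fc <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(paste0("g", 1:40), NULL))
  r1 <- estimate_pfp(fc, "up", n_permutations = 200, seed = 11)
  r2 <- estimate_pfp(fc, "up", n_permutations = 200, seed = 11)
  expect_identical(r1$pfp, r2$pfp)
  ord <- order(r1$rank_position)
  expect_true(all(diff(r1$pfp[ord]) >= 0))
  expect_true(all(r1$pfp >= 0 & r1$pfp <= 1))
  expect_error(estimate_pfp(fc, "up", 100), "seed")
})

test_that("DEG calling is strict, conflict-free, and nested in the cutoff", {
  set.seed(5)
  signal <- c(rnorm(5, mean = 4, sd = 0.2), rnorm(195, sd = 0.2))
  fc <- matrix(rep(signal, 3) + rnorm(600, sd = 0.2), 200, 3,
               dimnames = list(paste0("g", 1:200), NULL))
  up <- estimate_pfp(fc, "up", 300, seed = 6)
  down <- estimate_pfp(fc, "down", 300, seed = 7)
  degs <- call_degs(up, down, 0.05, condition = "c|high|24h|rat_in_vivo")
  expect_true(all(paste0("g", 1:5) %in% degs$gene[degs$direction == "up"]))
  expect_false(any(duplicated(degs$gene)))
  # lowering the cutoff never adds calls
  stricter <- call_degs(up, down, 0.01)
  expect_true(all(paste0(stricter$gene, stricter$direction) %in%
                    paste0(degs$gene, degs$direction)))
  # empty passing set is a valid empty table
  null_up <- up
  null_up$pfp <- 1
  null_down <- down
  null_down$pfp <- 1
  expect_equal(nrow(call_degs(null_up, null_down)), 0)
})

test_that("Monte-Carlo pfp matches the enumeration oracle at small G", {
  # G = 6, k = 2, continuous values with planted signal so ranks are exact
  # permutations and the top pfp values are below the clip
  set.seed(8)
  fc <- matrix(c(8, 4, rnorm(4)), 6, 2,
               dimnames = list(paste0("g", 1:6), NULL)) +
    matrix(rnorm(12, sd = 0.1), 6, 2)
  mc <- estimate_pfp(fc, "up", n_permutations = 20000, seed = 13)
  oracle <- pfp_enumeration_oracle_k2(mc$rp)
  expect_true(any(oracle < 0.99))
  # Monte-Carlo standard error of E is < G/sqrt(B); 3 SE margin on pfp
  expect_true(all(abs(mc$pfp - oracle) <= 3 * 6 / sqrt(20000) + 1e-9))
})
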