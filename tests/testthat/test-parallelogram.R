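test_that("frequency selection uses the inclusive 5% convention", {
  # 20 conditions, item in exactly 1: 1/20 = 0.05 >= 0.05, frequent
  items20 <- c(list(cond1 = "geneA"), setNames(rep(list(character(0)), 19),
                                               paste0("cond", 2:20)))
  expect_true("geneA" %in% frequent_items(items20, 0.05))
  # 205 conditions, item in 10: 10/205 < 0.05, not frequent
  items205 <- c(setNames(rep(list("geneB"), 10), paste0("c", 1:10)),
                setNames(rep(list(character(0)), 195), paste0("c", 11:205)))
  expect_false("geneB" %in% frequent_items(items205, 0.05))
  # threshold 0 returns the union of all items
  mix <- list(a = c("x", "y"), b = "z")
  expect_setequal(frequent_items(mix, 0), c("x", "y", "z"))
  # monotone: raising the threshold never adds items
  set.seed(10)
  rand <- lapply(1:30, function(i) sample(letters, sample(1:10, 1)))
  names(rand) <- paste0("c", 1:30)
  f_lo <- frequent_items(rand, 0.05)
  f_hi <- frequent_items(rand, 0.20)
  expect_true(all(f_hi %in% f_lo))
})

test_that("ortholog translation expands one-to-many and counts unmapped genes", {
  ortho <- data.frame(human_gene = c("h1", "h2", "h2"),
                      rat_gene = c("r1", "r2", "r3"),
                      stringsAsFactors = FALSE)
  out <- map_orthologs(c("h1", "h2", "h9"), ortho)
  expect_setequal(as.character(out), c("r1", "r2", "r3"))
  expect_equal(attr(out, "n_unmapped"), 1)
  # one-to-one table preserves cardinality
  one <- map_orthologs("h1", ortho)
  expect_length(one, 1)
  # drop-ambiguous mode discards the one-to-many gene
  strict <- map_orthologs(c("h1", "h2"), ortho, drop_ambiguous = TRUE)
  expect_setequal(as.character(strict), "r1")
})

test_that("three-way overlap computes all Venn regions by set algebra", {
  rep <- three_way_overlap(c("a", "b", "c"), c("b", "c", "d"), c("c", "e"),
                           labels = c("A", "B", "C"))
  expect_equal(rep$triple, "c")
  expect_equal(unname(rep$regions[["A&B"]]), 1)   # b
  expect_equal(unname(rep$regions[["A"]]), 1)     # a
  expect_equal(unname(rep$regions[["C"]]), 1)     # e
  expect_equal(sum(rep$regions), rep$union_size)
  # identical sets concentrate everything in the centre
  same <- three_way_overlap(letters[1:4], letters[1:4], letters[1:4])
  expect_setequal(same$triple, letters[1:4])
  expect_equal(unname(same$regions[7]), 4)
  expect_equal(sum(same$regions[1:6]), 0)
  # region counts match brute-force membership tabulation
  set.seed(11)
  sa <- sample(letters, 12); sb <- sample(letters, 10); sc <- sample(letters, 8)
  rep2 <- three_way_overlap(sa, sb, sc, labels = c("A", "B", "C"))
  uni <- union(union(sa, sb), sc)
  brute <- table(paste0(as.integer(uni %in% sa), as.integer(uni %in% sb),
                        as.integer(uni %in% sc)))
  expect_equal(unname(rep2$regions[["A&B&C"]]),
               unname(as.integer(brute["111"])) %||% 0L)
  expect_equal(sum(rep2$regions), length(uni))
  expect_setequal(rep2$triple, intersect(intersect(sa, sb), sc))
})

test_that("score clustering recovers planted blocks and is stable to row permutation", {
  set.seed(12)
  block1 <- matrix(rnorm(5 * 8, mean = 3), 5, 8)
  block2 <- matrix(rnorm(6 * 8, mean = -3), 6, 8)
  scores <- rbind(block1, block2)
  rownames(scores) <- paste0("m", 1:11)
  colnames(scores) <- paste0("c", 1:8)
  cl <- cluster_scores(scores, k_metabolite = 2, k_condition = 1)
  groups <- split(names(cl$metabolite_clusters), cl$metabolite_clusters)
  expect_setequal(groups[[1]], paste0("m", 1:5))
  expect_setequal(groups[[2]], paste0("m", 6:11))
  expect_equal(unique(cl$condition_clusters), 1)
  # permuting rows permutes labels consistently (same partition)
  perm <- sample(nrow(scores))
  cl_p <- cluster_scores(scores[perm, ], k_metabolite = 2, k_condition = 1)
  part1 <- unname(lapply(split(names(cl$metabolite_clusters),
                               cl$metabolite_clusters), sort))
  part2 <- unname(lapply(split(names(cl_p$metabolite_clusters),
                               cl_p$metabolite_clusters), sort))
  expect_setequal(part1, part2)
  expect_error(cluster_scores(scores, k_metabolite = 50), "exceeds")
})

test_that("dose composition reports integer percentages per cluster", {
  keys <- c(condition_key("ch1", "high", "24h", "rat_in_vivo"),
            condition_key("ch1", "medium", "24h", "rat_in_vivo"),
            condition_key("ch1", "low", "24h", "rat_in_vivo"),
            condition_key("ch2", "low", "24h", "rat_in_vivo"),
            condition_key("ch3", "high", "24h", "rat_in_vivo"))
  clusters <- setNames(c(1, 1, 1, 1, 2), keys)
  comp <- dose_composition(clusters)
  c1 <- comp[comp$cluster == 1, ]
  expect_equal(c1$pct[c1$dose_level == "high"], 25)
  expect_equal(c1$pct[c1$dose_level == "medium"], 25)
  expect_equal(c1$pct[c1$dose_level == "low"], 50)
  # single-condition cluster is 100% its dose
  expect_equal(comp$pct[comp$cluster == 2], 100)
  # percentages sum to 100 up to rounding
  sums <- tapply(comp$pct, comp$cluster, sum)
  expect_true(all(abs(sums - 100) <= 2))
})

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
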