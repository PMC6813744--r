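test_that("hypergeometric p matches the closed-form tail sum", {
  universe <- paste0("g", 1:10)
  collection <- list(S1 = paste0("g", 1:5))
  degs <- paste0("g", 1:4)   # all 4 DEGs inside the 5-gene set
  res <- hypergeom_enrich(degs, universe, collection)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(res$n_hit, 4)
  expect_equal(sort(res$hit_genes[[1]]), sort(degs))
  # independent summation oracle
  expect_equal(res$p_value, hypergeom_tail_oracle(4, 5, 10, 4),
               tolerance = 1e-12)
})

test_that("degenerate DEG sets behave correctly", {
  universe <- paste0("g", 1:10)
  collection <- list(S1 = paste0("g", 1:5), ALL = universe)
  res_empty <- hypergeom_enrich(character(0), universe, collection)
  expect_equal(res_empty$p_value, c(1, 1))
  expect_false(any(res_empty$significant))
  # a set equal to the universe always has n_hit = n_deg and p = 1
  res <- hypergeom_enrich(paste0("g", 1:3), universe, collection)
  expect_equal(res$n_hit[res$set_id == "ALL"], 3)
  expect_equal(res$p_value[res$set_id == "ALL"], 1)
  expect_error(hypergeom_enrich("not_there", universe, collection),
               "not in universe")
})

test_that("hypergeometric p matches exhaustive draw enumeration on small universes", {
  # enumerate every possible DEG draw and count configurations with >= q hits
  for (cfg in list(c(n = 10, m = 4, d = 3), c(n = 12, m = 5, d = 4),
                   c(n = 8, m = 3, d = 5))) {
    universe <- paste0("g", seq_len(cfg["n"]))
    set_genes <- paste0("g", seq_len(cfg["m"]))
    draws <- combn(cfg["n"], cfg["d"])
    for (q in 1:min(cfg["m"], cfg["d"])) {
      exhaustive <- mean(apply(draws, 2, function(ix) {
        sum(universe[ix] %in% set_genes) >= q
      }))
      degs <- c(set_genes[seq_len(q)],
                setdiff(universe, set_genes)[seq_len(cfg["d"] - q)])
      res <- hypergeom_enrich(degs, universe, list(S = set_genes))
      expect_equal(res$p_value, exhaustive, tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment reproduces the step-up definition independently", {
  set.seed(6)
  universe <- paste0("g", 1:40)
  collection <- lapply(1:6, function(i) sample(universe, 8))
  names(collection) <- paste0("S", 1:6)
  res <- hypergeom_enrich(sample(universe, 10), universe, collection)
  p <- res$p_value
  n <- length(p)
  ord <- order(p, decreasing = TRUE)
  expected <- pmin(1, cummin(n / (n:1) * p[ord]))[order(ord)]
  expect_equal(res$p_adjusted, expected)
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("adding an in-pathway DEG never increases the p-value", {
  universe <- paste0("g", 1:30)
  set_genes <- paste0("g", 1:10)
  collection <- list(S = set_genes)
  degs <- c("g1", "g2", "g20", "g21")
  p0 <- hypergeom_enrich(degs, universe, collection)$p_value
  p1 <- hypergeom_enrich(c(degs, "g3"), universe, collection)$p_value
  expect_lte(p1, p0)
})

test_that("the reporting filter keeps significant results with more than two mapped DEGs", {
  res <- data.frame(condition = "c", set_id = c("a", "b", "c"),
                    n_hit = c(2, 3, 50),
                    significant = c(TRUE, TRUE, FALSE))
  kept <- filter_reported(res)
  expect_equal(kept$set_id, "b")
})

test_that("the chemical-pathway network links chemicals to any-condition enrichments", {
  res <- data.frame(
    condition = c("chemA|low|24h|rat_in_vivo", "chemA|high|24h|rat_in_vivo",
                  "chemB|high|24h|rat_in_vivo", "chemB|high|24h|rat_in_vivo"),
    set_id = c("P1", "P1", "P1", "P2"),
    n_hit = c(3, 4, 5, 3),
    significant = c(TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  edges <- chemical_pathway_network(res)
  expect_equal(nrow(edges), 3)   # chemA-P1, chemB-P1, chemB-P2
  expect_false(edges$unique[edges$set_id == "P1" & edges$chemical == "chemA"])
  expect_true(edges$unique[edges$set_id == "P2"])
  # edge count equals a brute-force recount over the result table
  kept <- filter_reported(res)
  brute <- unique(data.frame(
    chemical = parse_condition_key(kept$condition)$chemical,
    set_id = kept$set_id))
  expect_equal(nrow(edges), nrow(brute))
})
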