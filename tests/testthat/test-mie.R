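make_tf_map <- function(tf, targets) {
  df <- data.frame(tf = tf, target = targets, mode = "unknown",
                   stringsAsFactors = FALSE)
  class(df) <- c("TFTargetMap", "data.frame")
  df
}

test_that("target mapping intersects with the universe and reports unmapped MIEs", {
  universe <- paste0("g", 1:100)
  tf_map <- make_tf_map("tf1", c(paste0("g", 1:15), paste0("x", 1:5)))
  mapped <- map_targets(tf_map, c("tf1", "tf2"), universe)
  expect_length(mapped$tf1, 15)   # 20 targets, 15 in universe
  expect_length(mapped$tf2, 0)
  expect_equal(attr(mapped, "unmapped"), "tf2")
  # brute-force set intersection recount
  expect_setequal(mapped$tf1,
                  intersect(tf_map$target[tf_map$tf == "tf1"], universe))
})

test_that("activation percentages follow the integer display convention", {
  universe <- paste0("g", 1:200)
  tf_map <- rbind(make_tf_map("tfA", paste0("g", 1:15)),
                  make_tf_map("tfB", paste0("g", 16:28)),   # 13 targets
                  make_tf_map("tfC", paste0("g", 29:48)))   # 20 targets
  mapped <- map_targets(tf_map, c("tfA", "tfB", "tfC"), universe)
  # chemical with 4 of 15, 5 of 13, and 1 of 20 DE targets
  degs <- data.frame(
    condition = "chem1|high|24h|rat_in_vivo",
    gene = c(paste0("g", 1:4), paste0("g", 16:20), "g29"),
    stringsAsFactors = FALSE)
  tab <- score_mie_activation(degs, mapped)
  expect_equal(tab$pct[tab$mie == "tfA"], 27)   # 4/15 = 26.67
  expect_equal(tab$pct[tab$mie == "tfB"], 38)   # 5/13 = 38.46
  expect_equal(tab$pct[tab$mie == "tfC"], 5)    # 1/20 = 5
  expect_true(tab$flagged[tab$mie == "tfA"])    # 26.67 > 20
  expect_true(tab$flagged[tab$mie == "tfB"])
  expect_false(tab$flagged[tab$mie == "tfC"])
  # 4 of 13 rounds to 31 and is flagged
  degs2 <- data.frame(condition = "chem2|high|24h|rat_in_vivo",
                      gene = paste0("g", 16:19), stringsAsFactors = FALSE)
  tab2 <- score_mie_activation(degs2, mapped)
  expect_equal(tab2$pct[tab2$mie == "tfB"], 31)
  expect_true(tab2$flagged[tab2$mie == "tfB"])
  # zero DE targets: 0%, not flagged
  expect_equal(tab2$pct[tab2$mie == "tfA"], 0)
  expect_false(tab2$flagged[tab2$mie == "tfA"])
})

test_that("the flag threshold is evaluated on the unrounded percentage", {
  universe <- paste0("g", 1:100)
  tf_map <- make_tf_map("tf1", paste0("g", 1:25))
  mapped <- map_targets(tf_map, "tf1", universe)
  # 5 of 25 = exactly 20%: not strictly greater, not flagged
  degs <- data.frame(condition = "c|low|24h|rat_in_vivo",
                     gene = paste0("g", 1:5), stringsAsFactors = FALSE)
  tab <- score_mie_activation(degs, mapped)
  expect_equal(tab$pct, 20)
  expect_false(tab$flagged)
})

test_that("only MIEs with more than min_mapped targets are tabulated", {
  universe <- paste0("g", 1:100)
  tf_map <- rbind(make_tf_map("small", paste0("g", 1:10)),
                  make_tf_map("big", paste0("g", 1:11)))
  mapped <- map_targets(tf_map, c("small", "big"), universe)
  degs <- data.frame(condition = "c|low|24h|rat_in_vivo", gene = "g1",
                     stringsAsFactors = FALSE)
  tab <- score_mie_activation(degs, mapped, min_mapped = 10)
  expect_equal(unique(tab$mie), "big")   # exactly 10 mapped is excluded
})

test_that("adding conditions to a chemical never decreases DE target counts", {
  universe <- paste0("g", 1:50)
  tf_map <- make_tf_map("tf1", paste0("g", 1:20))
  mapped <- map_targets(tf_map, "tf1", universe)
  degs1 <- data.frame(condition = "c|low|24h|rat_in_vivo",
                      gene = paste0("g", 1:3), stringsAsFactors = FALSE)
  degs2 <- rbind(degs1,
                 data.frame(condition = "c|high|24h|rat_in_vivo",
                            gene = paste0("g", 2:6), stringsAsFactors = FALSE))
  n1 <- score_mie_activation(degs1, mapped)$n_de
  n2 <- score_mie_activation(degs2, mapped)$n_de
  expect_gte(n2, n1)
  expect_equal(n2, 6)   # union, not sum
})
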