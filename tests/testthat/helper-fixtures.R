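# Shared fixtures, all built in code.

options(steatox.verbose = FALSE)

# 3 genes x 4 samples, one chemical, one dose, matched controls
tiny_study <- function() {
  values <- matrix(c(1, 2, 3,
                     2, 3, 4,
                     5, 5, 5,
                     7, 5, 3), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("s1", "s2", "s3", "s4")))
  metadata <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    chemical = "chemX",
    dose_level = c("control", "control", "high", "high"),
    duration = "24h",
    test_system = "rat_in_vivo",
    replicate = c(1, 2, 1, 2),
    control_group = "ctl_chemX_24h",
    stringsAsFactors = FALSE)
  expression_study(values, metadata)
}

# linear chain: uptake A (lb = -10) -> A-to-B conversion -> secrete B
chain_model <- function() {
  reactions <- data.frame(
    id = c("EX_A", "R1", "EX_B"),
    name = c("uptake A", "A to B", "secrete B"),
    lb = c(-10, 0, 0), ub = c(1000, 1000, 1000),
    gpr = c("", "g1", ""),
    stringsAsFactors = FALSE)
  metabolites <- data.frame(
    id = c("A", "B"), name = c("metabolite A", "metabolite B"),
    exchangeable = c(TRUE, TRUE), stringsAsFactors = FALSE)
  S <- matrix(c(-1, -1, 0,
                0, 1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("EX_A", "R1", "EX_B")))
  metabolic_model(reactions, metabolites, S)
}

# A converts to B through two parallel reactions (for weighted routing tests)
two_path_model <- function() {
  reactions <- data.frame(
    id = c("EX_A", "R1", "R2", "EX_B"),
    name = c("uptake A", "path 1", "path 2", "secrete B"),
    lb = c(-10, 0, 0, 0), ub = c(1000, 1000, 1000, 1000),
    gpr = c("", "g1", "g2", ""),
    stringsAsFactors = FALSE)
  metabolites <- data.frame(
    id = c("A", "B"), name = c("A", "B"),
    exchangeable = c(TRUE, TRUE), stringsAsFactors = FALSE)
  S <- matrix(c(-1, -1, -1, 0,
                0, 1, 1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"),
                              c("EX_A", "R1", "R2", "EX_B")))
  metabolic_model(reactions, metabolites, S)
}

# independent closed-form upper-tail hypergeometric by explicit summation
hypergeom_tail_oracle <- function(n_hit, n_set, n_universe, n_deg) {
  ks <- n_hit:min(n_set, n_deg)
  sum(choose(n_set, ks) * choose(n_universe - n_set, n_deg - ks)) /
    choose(n_universe, n_deg)
}

# exhaustive pfp oracle for k = 2 comparison columns without ties: under
# label permutation a gene's two ranks are marginally uniform on 1..G, so the
# expected count of permuted rank products at or below x is
# G * #{(a, b) : ab <= x^2} / G^2; pfp = E / rank position, then cumulative
# maximum along increasing rp, clipped to [0, 1]
pfp_enumeration_oracle_k2 <- function(rp) {
  G <- length(rp)
  grid <- expand.grid(a = 1:G, b = 1:G)
  prod_grid <- grid$a * grid$b
  e_value <- vapply(rp, function(x) {
    G * sum(prod_grid <= x^2 * (1 + 1e-12)) / G^2
  }, numeric(1))
  pos <- rank(rp, ties.method = "first")
  pfp <- e_value / pos
  ord <- order(pos)
  out <- numeric(G)
  out[ord] <- cummax(pfp[ord])
  pmin(out, 1)
}
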