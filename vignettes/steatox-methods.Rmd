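---
title: "Methods: cross-system toxicogenomic analysis of steatogenic exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-system toxicogenomic analysis of steatogenic exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatox)
stx_set_logging(verbose = FALSE)
```

# The problem

Chemicals that induce liver steatosis (abnormal triglyceride accumulation in
hepatocytes) leave transcriptomic signatures in exposure studies. Public
toxicogenomics repositories profile the same chemicals across three test
systems — rat in vivo, rat in vitro, and human in vitro — at several doses and
durations. The *parallelogram* inference is that molecular responses conserved
across all three systems are the ones most likely to be relevant to human
in vivo exposure, which no ethical experiment can measure directly.

`steatox` implements the full analysis chain on normalized log2 expression
matrices: preprocessing to per-condition log2 fold changes, rank-product
differential expression with a permutation false-prediction estimate,
hypergeometric pathway over-representation, activation scoring of the
molecular initiating events (MIEs) of the steatosis adverse outcome pathway
(ligand-activated transcription factors, read out through their target genes),
metabolite-level predictions from a genome-scale metabolic network (TIMBR),
and the three-way overlap of the per-system frequent genes, pathways, and
metabolites. A synthetic-data module generates every input with planted
ground truth, so the whole pipeline is testable end to end.

The unit of analysis throughout is the *exposure condition*: one
(chemical, dose level, duration, test system) cell, keyed as
`"chemical|dose|duration|system"`.

# Expression preprocessing

The pipeline starts at normalized log2 intensity matrices; probe-level
processing (normalization, detection calls, array QC) is upstream vendor
tooling and out of scope.

**Non-specific filtering.** Genes without an external annotation ID are
removed, standing in for probe sets that cannot be mapped to a gene. Genes of
low variance across all samples are removed next: the threshold is the
`variance_quantile` quantile (default 0.25) of the per-gene variance
distribution. A self-referential quantile rule cannot be literally idempotent
— re-deriving the quantile on an already-filtered matrix shifts the threshold
— so `filter_genes()` computes the threshold once, attaches it to the result
(`variance_cutoff` attribute), and re-filtering with that fixed cutoff is the
identity. An optional minimum-expression floor (disabled by default)
approximates present/absent detection filtering without probe-level data.

**Replicate averaging and log-ratios.** Group means are arithmetic means of
log2 intensities; control pairing is explicit in the metadata
(`control_group`), never inferred, and one control group may serve several
conditions of a chemical/duration (the shared-control pattern of repeated-dose
designs). `log2FC = mean(treatment) − mean(control)`.

**Discretization.** For reporting, fold changes are ternarized at ±0.6 log2
units with a closed `none` band: up means strictly greater than 0.6, down
strictly less than −0.6.

# Rank-product differential expression

For one condition with $n_t$ treatment and $n_c$ control replicates, all
$k = n_t n_c$ pairwise log2 differences are formed (the standard two-class
rank-product construction). Within each comparison, genes are ranked by
extremity in the tested direction (rank 1 = most extreme, average ranks on
ties) and the rank product is the geometric mean rank
$RP_g = (\prod_{i=1}^k r_{gi})^{1/k}$. Because only ranks enter, the statistic
is invariant to monotone transformations of each comparison.

Significance is a permutation *percentage of false prediction* (pfp): each
permutation shuffles gene labels independently within every comparison column,
and the expected count $E(g)$ of permuted rank products at or below $RP_g$,
divided by the rank position of $g$, estimates the false-prediction
proportion. pfp values are monotonized by cumulative maximum along increasing
$RP$ (so the DEG set is nested in the cutoff) and clipped to $[0,1]$. DEGs are
genes with pfp strictly below 0.05 in either direction; a gene passing both
directions (possible only under pathological ties) keeps the direction with
the smaller rank product.

Defaults: 1000 permutations, mandatory explicit seed. At small problem sizes
($G = 8$, $k = 2$) the permutation marginals are uniform, giving the exact
enumeration oracle used in the tests:
$E(g) = G \cdot \#\{(a,b): ab \le RP_g^2\}/G^2$.

# Pathway over-representation

Per condition, the DEG set is tested against each gene set with the one-sided
upper-tail hypergeometric test, using the *post-filter gene list of the test
system* as the universe (the genes the study could actually have called), and
Benjamini–Hochberg adjustment across the sets tested for that condition.
Adjusted p below 0.05 is significant; whether the original analyses adjusted
is not documented, so the adjusted default is the conservative choice and is
config-exposed. A pathway is *reported* for a condition when it is significant
and has more than two mapped DEGs. The chemical–pathway network links a
chemical to every pathway reported in at least one of its conditions;
pathways of degree one are marked `unique`.

# MIE activation scoring

The steatosis adverse outcome pathway lists ligand-activated transcription
factors as molecular initiating events. Their activation is read out from
their regulatory targets: for each chemical, the DEG set is the union over all
of its exposure conditions (any dose or duration, either direction), and each
MIE cell counts the differentially expressed mapped targets. Both up- and
down-regulated targets count — the table measures *modulation* of the regulon,
not mode-consistent activation; the regulation-mode column is retained for
future use. Only MIEs with strictly more than 10 targets mapped into the
analyzable universe are tabulated; percentages are displayed as integers
(rounded half away from zero) and cells are flagged when the *unrounded*
percentage exceeds 20%.

# TIMBR metabolite predictions

TIMBR scores how cheaply a metabolic network can produce each exchangeable
metabolite under control versus treatment expression. Per condition:

1. **GPR mapping.** DEG log2 fold changes map onto reactions through
   gene-protein-reaction rules: AND combines by signed minimum (a complex is
   limited by its most depleted subunit), OR by signed maximum (isozymes are
   dominated by the most induced member); non-DEG genes contribute 0.
2. **Weights.** $w_{treatment} = 2^{-s\Delta}$, $w_{control} = 2^{+s\Delta}$
   with scale $s = 0.5$: up-regulated reactions become cheap in the treatment
   network and costly in control, and $w_t w_c = 1$. The exact transform used
   by the original algorithm is published elsewhere; this reciprocal
   exponential form matches its qualitative description and is the single
   most consequential free choice in the module — it is config-exposed and
   deliberately prominent.
3. **Demand.** For each metabolite, the maximum production flux $v_{max}$ is
   an FBA LP (weight-independent, computed once and shared by both solves).
   The network demand is
   $X = \min \sum_j w_j |v_j|$ subject to $S v = 0$, bounds, and a required
   production flux $v_x \ge f \cdot v_{max}$ with `opt_fraction` $f = 0.9$
   (the source describes "an optimal fraction" without a value). The
   absolute-value objective is linearized by splitting each reaction into
   non-negative forward/backward parts with equal weight. Boundary conditions
   (medium uptake/secretion rates) enter as a named bounds profile fixed on
   the exchange reactions before solving.
4. **Scores and calls.** $X_{raw} = (X_{control} - X_{treatment}) /
   (X_{control} + X_{treatment})$, implemented exactly as printed (a positive
   score means production got cheaper under treatment, a predicted increase);
   the degenerate 0/0 case scores 0 with a log notice. $X_s$ z-transforms
   $X_{raw}$ across the condition's exchangeable metabolites using the
   population standard deviation, so per condition the scores have mean 0 and
   population sd 1 exactly; all-equal raw scores (σ = 0) call everything
   unchanged. Calls use strict cutoffs: increased if $X_s > 0.1$, decreased if
   $X_s < -0.1$.

Degenerate optima are acceptable: only the demand value is contract-bearing,
not the flux vector. A lipid-focused analysis is a metabolite subset filter
applied after scoring.

The LPs are solved with `pracma::linprog` over the split variables, with the
variable caps supplied as inequality rows. These are dense toy-scale problems
(tens of variables); genome-scale reconstructions would need a sparse
industrial solver, which is a stated limitation.

# Parallelogram analysis

Per test system, an item (gene, reported pathway, or called metabolite) is
*frequent* when it appears in at least 5% of that system's exposure
conditions, inclusive — one condition of twenty qualifies; each system uses
its own condition count as denominator. Human gene sets are translated to rat
IDs through the ortholog table before comparison, expanding one-to-many
mappings (a `drop_ambiguous` mode discards them instead); pathway and
metabolite IDs are shared across systems and need no translation. The
three-way overlap reports all seven exclusive Venn regions and the
triple-intersection members.

TIMBR score matrices are clustered on both axes with agglomerative
hierarchical clustering, Ward linkage on Euclidean distances, cut at 3
clusters per axis — the method is not documented in the source analyses; Ward
was chosen for determinism and compact clusters, and both k values are
config-exposed. Condition-cluster dose composition is reported as integer
percentages.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:

* per-gene baseline log2 intensities drawn once per study
  (N(7, 2) by default), shared by all conditions, mimicking gene-specific
  expression levels on a fixed platform;
* per-condition planted DEGs: a dose-dependent *fraction* of genes
  (2%/5%/10% at low/medium/high by default) receives a log2 shift of
  equiprobable sign — dose acts on the DEG count, not on effect size,
  matching the observation that higher doses yield more DEGs;
* shift magnitudes are folded-normal *around* the design effect size
  (sd = a third of it), giving a realistic effect-size spread without rank
  ties and without a mass of sub-noise effects;
* replicate noise is i.i.d. Gaussian (sd 0.3 by default) around
  baseline + shift; controls are shared per (chemical, duration);
* an optional conserved gene list is planted up-regulated in *every*
  condition of every system — the cross-system signal the parallelogram
  analysis must recover — and the pipeline additionally plants one gene set
  built around those genes, the conserved-pathway analogue;
* the toy metabolic model is a deterministic mass-balanced topology
  (uptakes → chain → hub → other exchangeables, reversible conversions) that
  is feasible by construction, with seeded 1–3-gene GPRs over the synthetic
  universe; with at least two uptakes every exchangeable metabolite has
  positive maximum production;
* annotations: gene sets of size 10–50, TFs with 5–50 targets, an ortholog
  table covering 90% of genes, mostly one-to-one with a planted minority of
  one-to-many pairs (human IDs are prefixed rat IDs).

What it does **not** emulate: probe-level artifacts, batch and array outlier
effects, correlated gene modules, heavy-tailed noise, dose-dependent effect
sizes, or realistic metabolic network scale. Passing tests therefore
demonstrate the statistical machinery is correct under its own assumptions,
not that the pipeline is robust to all real-data pathologies.

All generators are pure functions of (design, seed); identical seeds give
bit-identical outputs.

# Pipeline, sizes, and determinism

`run_pipeline()` executes simulate → prep → deg → enrich → mie → timbr →
overlap from one YAML configuration (unknown keys rejected), writing
plain-text files per stage and caching each stage on a content hash of its
inputs and parameters; unchanged stages are skipped. The default synthetic
study uses 300 genes, 3 chemicals × 3 doses × 2 durations × 3 replicates per
system (18 conditions per system), 12 + 1 gene sets, 6 TFs, and a 6-exchange
toy model — sizes chosen so a full run completes in well under a minute on
one CPU while every code path is exercised; all thresholds stay at their
analysis defaults.

```{r, eval = FALSE}
cfg <- read_pipeline_config(NULL, out_dir = "steatox_out", seed = 1)
res <- run_pipeline(cfg)
res$overlaps$genes$triple
```

# Known limitations

* The rank-product pfp is a Monte-Carlo estimate; at 1000 permutations its
  resolution near the 0.05 cutoff is limited, and the permutation null
  treats genes as exchangeable within comparisons.
* The TIMBR weight transform and optimal fraction are explicit stand-ins for
  values published outside the analyzed source; conclusions that depend on
  their precise values should be checked over a range.
* The LP layer targets toy models; genome-scale reconstructions are out of
  scope.
* Enrichment assumes the gene-set collection and the expression platform
  share an ID space; no topology-aware pathway scoring is attempted.
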