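---
title: "Core hub gene discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core hub gene discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwashub)
```

# The procedure and its assumptions

`gwashub` chains two complementary sources of evidence about disease
genes. The genetic stage assumes a biallelic, population-based
case/control design: under the null, each SNP's two alleles are equally
frequent in cases and controls, and genotypes within each group follow
Hardy–Weinberg (HW) proportions. The association statistic is the allelic
chi-square on the 2×2 allele-by-phenotype table (1 df, no continuity
correction) with the allelic odds ratio as effect size — the classic
single-marker test for unrelated samples. No covariates, relatedness
correction or population-structure adjustment is attempted; samples are
assumed exchangeable within groups.

The network stage assumes that disease genes aggregate in the
protein–protein interaction (PPI) network: genes passing a deliberately
*loose* association screen (p < 0.01 rather than genome-wide 5×10⁻⁸) are
projected onto the PPI graph, and network topology — degree for hubs,
local density for modules — is used as the second filter. The PPI graph is
treated as a simple undirected graph; edge confidence scores are only used
as an optional pre-filter, never as weights.

# Stage-by-stage conventions

## Quality control

A SNP is kept when all of the following hold (first failed criterion is
reported per excluded SNP, in this order):

| filter        | default   | computed on        |
|---------------|-----------|--------------------|
| HW exact fit  | p ≥ 5×10⁻⁷| controls only      |
| missingness   | ≤ 5%      | all samples        |
| minor allele frequency | ≥ 5% | all samples, pooled |
| quality score | off       | optional user column |

HW equilibrium is tested in controls only: under a true association,
cases are *expected* to deviate from HW proportions, so including them
would discard real signals. The test is the asymptotic 1-df genotype
chi-square against p², 2pq, q² at the observed allele frequency (not the
exact test): it matches the formula-level definition and admits a
closed-form oracle. Monomorphic SNPs get χ² = 0, p = 1. The fixed 5×10⁻⁷
threshold is used as given (it is already a multiplicity-adjusted
convention); no further correction is applied.

The fourth QC criterion in the source procedure ("odds ratio R² > 0.8")
does not correspond to any standard single-SNP statistic we can identify.
It is surfaced as an *optional* per-SNP quality/imputation-info score
(`quality_min`, default off) rather than guessed at; the flag is
documented and the filter is inert unless both a threshold and a score
vector are supplied.

## Allele orientation

At load time every SNP is oriented so that the *minor* allele over all
non-missing calls (cases and controls pooled) is the alt allele; genotype
codes count alt alleles. Ties are broken toward the lexicographically
larger allele, and a monomorphic SNP gets the placeholder alt "N". This
makes the odds-ratio direction deterministic and matches the pooled
definition used by the MAF filter. The synthetic generator emits datasets
already in this orientation, which is what makes the PED/MAP write→read
round trip exact.

## Screening and mapping

The risk screen keeps QC-passed SNPs with p strictly below 0.01. Mapping
is strand-agnostic and interval-based, on 1-based inclusive gene
coordinates: a SNP inside one or more genes maps to *all* containing genes
(containment is evidence for every overlapped gene); otherwise it maps to
the single nearest gene whose nearer endpoint is within 5000 bp, ties
broken by lexicographic gene id; farther SNPs are dropped. With
`flank_bp = 0` the rule degenerates to pure containment. Gene-level
(not transcript-level) intervals are used throughout.

## Network metrics

The risk-gene network is the induced subgraph of the edge list on the risk
genes, after removing self-loops and duplicate/reversed edges; genes left
without any partner are dropped (they carry no topological information).
Conventions that matter when comparing numbers across tools:

* **Clustering coefficient** CCᵢ = 2nᵢ/(kᵢ(kᵢ−1)); nodes with degree < 2
  contribute 0, and the network value is the unweighted mean over *all*
  nodes.
* **Betweenness** is summed over *ordered* pairs (s, t), unnormalized —
  exactly twice the common unordered convention for undirected graphs
  (the test suite cross-checks `2 × igraph::betweenness`).
* **Characteristic path length** averages over connected unordered pairs
  only, so disconnected networks still yield a finite value.
* **Topological coefficient** follows the NetworkAnalyzer definition:
  TC(v) = mean over nodes j sharing ≥ 1 neighbor with v of
  (|N(v)∩N(j)| + [v∼j]) / k_v, with 0 for degree < 2.
* **Degree-distribution slope** is the least-squares fit of log₁₀(count)
  on log₁₀(degree); it is reported as `NA` when fewer than two distinct
  positive degrees exist, rather than extrapolated.

Hub genes are nodes with degree *strictly* greater than the threshold
(default 17).

## Module detection and core hubs

Module detection is MCODE-style: each node is weighted by
k_max × density of the highest k-core of the subgraph induced by its
closed neighborhood; clusters grow breadth-first from the highest-weight
unclaimed seed, admitting neighbors whose weight is at least
(1 − node_score_cutoff) × seed weight; grown clusters must contain a
2-core, then haircut (iterative removal of singly-connected members)
applies; fluff is available but off by default. Parameters default to the
familiar interactive-tool defaults (degree cutoff 2, node score cutoff
0.2, k-core 2, haircut on, fluff off, max depth 100) since the procedure
we reimplement names the tool without printing parameters. The cluster
score is density × size. By default clustering runs on the hub-induced
subgraph; `mcode_scope = "network"` runs it on the full risk-gene network
instead (see *Scale choices* below).

**Core hub = strict maximum.** A cluster's core hub is its member with the
strictly highest vertex weight; when two or more members tie exactly, no
core hub is designated and the tied set is reported. This convention has a
sharp consequence worth stating: *a module that is a perfect clique can
never designate a core hub*. Every member of a clique contains the whole
clique in its closed neighborhood, so all members receive the identical
weight k_max × 1 and the maximum is never strict. This is not a numerical
accident but a structural property of the weight function, and it shapes
the synthetic-data design below. More generally, weights are small
rationals (a core order times a density), so exact ties between members of
dense symmetric regions are common, not exotic.

## Enrichment

Over-representation uses the one-sided hypergeometric upper tail
P(X ≥ k), Benjamini–Hochberg FDR across all tested terms, a raw-p cutoff
of 0.01 (an FDR cutoff is available as an alternative via `fdr_max`,
since tools differ on which scale the 0.01 applies), ranking by ascending
FDR (most significant first), and a top-10 report by default. The default
universe is the union of all genes annotated anywhere in the supplied
collection; this choice changes every p-value, so it is exposed as an
argument. Multi-set overlap counting supports 2–4 named sets, reporting
the cardinality of every subset intersection.

# The synthetic-data generator

The generator emulates the statistical structure of a case/control GWAS
plus PPI study at desk scale, with full ground truth:

* **Genotypes.** Per SNP, a control allele frequency is drawn uniformly
  from `maf_range`; genotypes are drawn from HW proportions within each
  group. Causal SNPs use `causal_maf` (default 0.3) in controls and, in
  cases, the frequency solving odds_case = OR × odds_control (for
  f = 0.3, OR = 2 this gives f_case = 6/13). This allele-frequency-shift
  model is exactly the alternative the allelic test targets, so power is
  analytically predictable. Calls are masked missing independently at
  `missing_rate` (default 1%).
* **Gene map.** Genes of fixed length (20 kb) tile each chromosome with a
  fixed 12 kb intergenic gap — large enough that all three mapping strata
  (inside, within 5 kb, beyond 5 kb) exist by construction; each SNP's
  stratum, gene and distance are recorded as truth. Causal SNPs are placed
  inside distinct genes.
* **PPI background.** A preferential-attachment graph (each new node
  attaches to `attachment_edges = 2` existing nodes proportionally to
  degree) over node ids drawn from the gene universe, so the
  induced-subgraph step is genuinely exercised. Planted modules occupy
  genes hit by causal SNPs.
* **Annotation sets.** One term engineered to overlap the causal-gene
  query at a recorded (N, K, n, k), plus uniformly sampled background
  terms.

Default sizes (1000/1000 samples, 5000 SNPs, 50 causal at OR 2, 600
genes, 300 PPI nodes) are the package's chosen desk-scale study
conditions: large enough for the screen to be calibrated (the null p < 0.01
rate is binomially indistinguishable from 1%) and for planted effects at
OR 2 to be recovered with near-certain power, small enough that the whole
pipeline runs in seconds. The calibration test uses 10 000 SNPs.

**What the generator does not emulate:** linkage disequilibrium (SNPs are
independent, so SNP-level sensitivity translates directly to gene-level
recovery — real GWAS hits arrive in LD blocks), population stratification,
genotyping batch effects, realistic human gene geometry, and the
confidence-score structure of curated PPI databases (scores are uniform
noise). Passing tests therefore demonstrate the *procedure's* correctness
and calibration under its own model, not robustness to real-data
pathologies.

## Planted modules: why two styles

Each planted module is either **random** — the edges inside the chosen
member set are rewired to a requested density (density 1 plants a clique),
background edges left intact — or **hub-and-spoke**, a deterministic
structure: one apex adjacent to every spoke, the spokes forming a
circulant ring C_m(1, 3) (each spoke tied to its neighbors at offsets 1
and 3). The default spec plants one 8-clique and one 21-member
hub-and-spoke module (60 internal edges, density 0.286 — close to the
published partial modules this emulates).

The reason for the structured style is the strict-maximum rule analyzed
above. A clique ties by necessity; randomly rewired partial modules tie
*frequently*, because member weights are coarse rationals. Design probing
showed that with random partial modules the in-module core hub appears in
only roughly half to two-thirds of seeds — an unacceptable coin flip for a
deterministic recovery check. The hub-and-spoke geometry instead pins the
weights analytically: the module is a 5-core of density 2/7, giving the
apex weight 5 × 6/(m+1) = 10/7 (for m = 20), while each spoke's closed
neighborhood (itself, four non-adjacent spokes, the apex) is a 2-core of
density 3/5, giving weight 1.2. The apex is the unique maximum, and
1.2 ≥ 0.8 × 10/7, so the default MCODE expansion admits every spoke:
recovery of the module *and* of its core hub is deterministic across
seeds. To keep these weights exact, the hub-and-spoke module replaces its
members' background edges entirely (one bridge from the apex reconnects it)
— unlike random modules, which only rewire internal edges. The two planted
modules thus jointly exercise both designation outcomes: the clique module
must report *no* core hub (tie), the structured module must report its
apex.

# Scale choices

The original procedure selects hubs at degree > 17 from a ~1000-node,
~7.5-mean-degree network and clusters the 112-hub subgraph. A desk-scale
synthetic network (a few dozen risk-gene nodes, mean degree ~5) simply has
no degree-18 nodes, so the end-to-end synthetic runs lower the hub
threshold and run module detection on the full risk-gene network — the
`mcode_scope = "network"` switch exists precisely so both the published
configuration and the desk-scale configuration are expressible. The
defaults remain the published constants (p < 0.01, HW 5×10⁻⁷, missingness
5%, MAF 5%, 5 kb, degree > 17), so a config containing only file paths
reproduces the published procedure.

Problem sizes used by the test suite were chosen once: 10 000 SNPs ×
2000 samples for null calibration, the default 5000 × 2000 spec for
power/recovery and the end-to-end run, 200 random graphs on ≤ 7 nodes for
brute-force oracle equivalence, and ≤ 300-node backgrounds for module
recovery.

# Numerical and degenerate-input conventions

* Degenerate 2×2 tables (a zero marginal) give χ² = 0, p = 1; the odds
  ratio adds 0.5 to every cell only when some cell is zero.
* `cluster_score` requires ≥ 2 nodes; singleton "clusters" score 0 in the
  report and designate themselves as core hub only through the explicit
  singleton rule.
* Seed order in module detection is descending weight with ties broken by
  node id; cluster report order is descending score, ties by smallest
  member id — all orderings are deterministic and seed-free.
* The master seed drives per-generator substreams, so each synthetic input
  can be regenerated independently of the others.
* Written tables format numbers to six significant digits; re-reading
  reproduces values to that precision, and repeated runs are
  byte-identical.

# Known limitations

* Single-marker association only: no logistic regression, covariates,
  imputation or genomic control.
* The PED/MAP reader handles the PLINK *text* dialect only (no binary
  BED/BIM/FAM), by design.
* The enrichment module ships no annotation databases; users supply GMT
  files, and published term-level results are database-version dependent.
* Betweenness and path censuses are exact but pure-R; networks beyond a
  few thousand nodes would want a compiled implementation.
* The tie ⇒ no-core-hub rule is a documented convention, not an empirical
  fact about the original analysis, whose tie handling is not recoverable
  from the published description.
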