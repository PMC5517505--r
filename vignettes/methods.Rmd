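---
title: "Methods: replicate-free screening of an ischemia/reperfusion time course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate-free screening of an ischemia/reperfusion time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogdrscreen)
library(dplyr)
```

## The design this package targets

Oxygen-glucose deprivation followed by reperfusion (OGD/R) is the standard
in-vitro model of ischemic stroke and restored blood flow. A typical
transcriptome screen of this kind sequences **one RNA-seq library per
condition** — a normoxic control, an OGD library, and several reperfusion
time points — and asks which genes respond, which biological processes and
pathways those genes concentrate in, how the responding genes co-vary, and
which small set of "key" genes is worth taking into wet-lab validation.

With a single library per condition there is no way to estimate
within-condition biological variance, so the whole analysis chain has to be
built from statistics that remain valid (and honest about their
assumptions) without replicates. `ogdrscreen` implements that chain
end-to-end, together with a simulator that plants known structure so every
stage can be validated against ground truth.

## Quantification: RPKM

Expression is quantified as reads per kilobase of transcript per million
mapped reads,

$$\mathrm{RPKM}_{gs} = \frac{10^9\, C_{gs}}{N_s\, L_g},$$

with $C_{gs}$ the read count of gene $g$ in library $s$, $N_s$ the
library's total mapped reads, and $L_g$ the gene length in bp. The totals
$N_s$ are supplied in a sidecar table rather than recomputed from column
sums, because reads also map outside the quantified gene set.

## Differential expression between two single libraries

A gene is called differentially expressed between a treatment and a
reference library when it passes two gates:

* **fold change** — $|\log_2(\mathrm{RPKM}_{trt}/\mathrm{RPKM}_{ref})| \ge 1$
  (at least two-fold). Each RPKM is floored at 0.01 before the ratio so a
  gene that drops to zero reads keeps a finite, large ratio; the floor is
  recorded in the run manifest.
* **significance** — Benjamini–Hochberg FDR $\le 10^{-3}$, computed across
  all testable genes of the comparison.

The per-gene p-value is the exact Poisson-ratio (Audic–Claverie style)
conditional test, the standard replicate-free choice: conditional on the
count $x$ observed in the first library, the count in the second follows

$$p(y \mid x) \;=\; \Big(\tfrac{n_2}{n_1}\Big)^{y}\,
  \frac{(x+y)!}{x!\,y!\,\big(1+\tfrac{n_2}{n_1}\big)^{x+y+1}},$$

a negative binomial in $y$, and the two-sided p-value is
$2\min\{P(Y\le y),\,P(Y\ge y)\}$ capped at 1. Tails are summed directly in
log space on whichever side is smaller, so p-values keep full relative
accuracy down to the underflow limit. Genes with zero counts in both
libraries are untestable and are excluded from the test and from the BH
denominator.

Two numerical properties of this statistic are worth knowing:

* It depends on the library depths only through their ratio $n_2/n_1$.
* Because it conditions on the *first* library's count, it is only
  asymptotically exchange-symmetric: swapping $(x, n_1)$ with $(y, n_2)$
  changes the p-value by an $O(1/\sqrt{\text{count}})$ relative amount.
  The package always conditions on the reference library, so results are
  well-defined and deterministic.

The test models sequencing (Poisson) noise only. That is the correct error
model for technical library-to-library comparison, and the only estimable
one in this design; it cannot speak to biological replication, which is
why downstream validation (qPCR, in-vivo models) remains essential in
practice.

## Gene-set over-representation

Enrichment of a DEG list in GO-term or KEGG-pathway style gene sets uses
the upper-tail hypergeometric probability

$$P(X \ge m), \qquad X \sim \mathrm{Hypergeom}(N, M, n),$$

where $N$ counts universe genes, $M$ of them annotated to the term, $n$
DEGs in the universe, and $m$ DEGs annotated to the term. Following the
GO::TermFinder convention, the universe is the intersection of the genes
quantified (testable) in the comparison with the genes annotated to at
least one term of the namespace; gene sets are taken exactly as supplied
in the GMT file — no ontology-graph propagation of annotations to ancestor
terms is performed, which keeps the tool annotation-file-free but means GO
inputs should already be propagated if that behaviour is wanted.

Both a Bonferroni column ($\min(1, p\,T)$ over the $T$ terms of the
namespace) and a BH FDR column are reported; the significance gate is
$p_{\mathrm{fdr}} \le 0.05$ (boundary inclusive), configurable. Namespaces
are corrected independently, mirroring separate GO and KEGG analyses.
Terms with $m = 0$ are tested ($p = 1$) and kept in the table so the
output enumerates the namespace completely.

## Co-expression network, degree, and k-cores

Gene profiles are $\log_2(\mathrm{RPKM}+1)$ across all libraries of the
experiment. Every unordered pair of screened genes with

$$|r| \ge 0.9 \quad\text{and}\quad p \le 0.05$$

becomes an edge, where $r$ is the Pearson correlation and $p$ its
two-sided t-test p-value ($t = r\sqrt{(L-2)/(1-r^2)}$ on $L-2$ df). With
only five conditions the t-test alone is weak, hence the additional
absolute-correlation floor — the common co-expression convention. Both
gates are configurable; negative correlations form edges (the sign is kept
as an edge attribute). Profiles that are exactly collinear are snapped to
$r = \pm 1$, $p = 0$, avoiding floating-point rounding below 1.

Node importance uses **degree centrality** (the number of incident edges)
and the **k-core decomposition**: a node's core number is the largest $k$
such that it survives in a subgraph where every node keeps at least $k$
neighbours. Core numbers are computed by iterative minimum-degree peeling
with a deterministic lexicographic tie-break (core numbers themselves are
independent of tie-breaking; the tie-break only fixes the removal order).
Gene ranking sorts by core number, then degree, then gene id.

## The three-criteria key-gene screen

For each comparison, every DEG receives three boolean flags:

1. **magnitude** — $|\log_2 \text{ratio}| > 1.5$, strict inequality, so a
   ratio of exactly 1.5 fails;
2. **pathway** — membership in at least one significantly enriched term of
   the comparison (either namespace);
3. **mechanism** — membership in a curated list of genes with known
   pathologic roles (calcium overload, oxygen-radical production, and the
   like).

`strict` mode selects genes passing all enabled criteria; `any_two`
requires the (always mandatory) magnitude flag plus at least one of the
other two. Both modes exist because conjunctive phrasing and curated
panels are both defensible readings of how such shortlists are assembled
in practice; `strict` is the default. When no mechanism list is supplied,
criterion 3 is disabled and reported as `NA`. Network degree and core
number annotate the report and order it, but are deliberately not a gate —
no defensible numeric centrality cutoff exists for 5-sample networks.

## The synthetic-data generator

`simulate_counts()` draws, per gene: a length (log-normal, floored at
200 bp so RPKM denominators never degenerate), a baseline expected RPKM
(log-normal, median 10, $\sigma_{\log} = 1.2$ — a realistic bulk RNA-seq
spread), and a gamma rate factor with variance equal to `dispersion`.
Counts in each library are Poisson around the length- and depth-scaled
rate, so each count is marginally negative binomial with the configured
overdispersion while library-to-library noise is purely Poisson.

This factorization is a deliberate model choice: it encodes a design in
which every condition is a single library prepared from the same culture
batch, so the only condition-to-condition noise is sequencing noise — the
exact sampling regime the Poisson-ratio test assumes. What the generator
therefore does *not* emulate is between-culture biological variability;
passing recovery tests on these data show the chain is correct under its
own assumptions, not that single-library designs are robust to biological
replication noise (they are not, which is precisely why the test has no
way to model it).

Planted structure:

* **DE genes** — expected expression multiplied by $2^{\mathrm{lfc}}$ in
  every non-reference condition, $|\mathrm{lfc}|$ uniform in a configured
  range, 90% up-regulated by default, matching the strongly up-dominated
  acute OGD response (on the order of 950 up vs 80 down). DE genes and
  module genes are disjoint so truth labels stay clean.
* **Modules** — each module shares a latent per-condition profile; gene
  $g$ in module $k$ receives the log2-space offset
  $\sigma\big(\sqrt{\rho}\,f_k + \sqrt{1-\rho}\,\varepsilon_g\big)$ with
  $\sigma = 2$, giving pairwise latent correlation $\rho$
  (`module_correlation`). Sequencing noise dilutes the realized profile
  correlation slightly (about 0.92–0.93 at $\rho = 0.95$ and default
  depth). The default five conditions are too few to measure correlation,
  so correlation-recovery experiments use an extended-profile mode (simply
  `n_conditions = 24`); the default design mirrors the five-condition
  experiment.
* **Enriched gene sets** — a configured number of sets draw 80% (default)
  of their members from planted DE genes; the remaining sets sample
  uniformly. Set sizes are uniform in `gene_set_size_range`; namespaces
  alternate GO/KEGG so both enrichment tables are exercised.

All randomness flows through one integer seed: identical configurations
give bit-identical data, truth, and downstream outputs.

### Problem sizes used in the shipped experiments

The recovery experiments run at 2000 genes, depth $5\times10^6$, 100
planted DE genes at $|\mathrm{lfc}| \in [2,4]$, dispersion 0.05 — sizes at
which one run takes about a second and the statistical conclusions
(sensitivity $\ge 0.9$, essentially no false calls, clean enrichment
recovery, purely intra-module edges) are stable across seeds. Module
recovery uses 24 conditions and three 20-gene modules at $\rho = 0.95$.

## Numerical and degenerate-input choices

* AC tails: direct log-space summation on the smaller side; geometric
  remainder bound decides truncation of the upper tail; the cap at 1 is
  applied after doubling the smaller tail.
* Hypergeometric tails: evaluated by the exact distribution function;
  validated exhaustively against draw enumeration for $N \le 30$.
* BH: step-up over the testable genes only.
* Constant expression profiles: excluded from correlation (undefined), the
  genes stay in the network as isolated, core-0 nodes, with a message.
* Double-zero count genes: untestable, excluded from testing and from the
  BH denominator.
* Report tables: tab-separated, fixed column order, floats at 6
  significant digits, UTF-8.

## Pipeline orchestration

`pipeline_config()` + `run_pipeline()` chain the stages for every
configured comparison (default: OGD vs control, then each reperfusion time
point vs OGD) and write, per comparison, the full DEG table, the
enrichment table, GraphML + edge-list network exports, and the key-gene
table, plus a JSON manifest recording package version, thresholds, seed,
and per-stage record counts. The manifest contains no timestamps, so two
runs on identical inputs are byte-identical — which is also how the test
suite checks determinism. Each stage reads and writes only the documented
plain-text formats, so any stage can be re-run from on-disk intermediates.

## Known limitations

* No biological-replicate variance model anywhere — by design, and
  inherited honestly from the single-library design itself.
* Fold changes computed on floored RPKM are conservative for genes near
  the floor.
* Gene sets are used exactly as supplied; no GO ancestry propagation.
* The co-expression thresholds ($|r| \ge 0.9$, $p \le 0.05$) are
  conventions, not estimates; with 5 samples the edge set is sensitive to
  single-condition outliers.
* The Poisson-ratio test is anticonservative if counts are overdispersed
  *between* the two libraries being compared (e.g. true biological
  replicates treated as re-sequencings); it is exact only for shared-rate,
  Poisson-sampled libraries.
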