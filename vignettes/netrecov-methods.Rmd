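---
title: "Disease-network recovery analysis: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-network recovery analysis: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrecov)
```

## The problem

A common design in network pharmacology pairs a three-group expression study
— a healthy control arm (*Sham*), a disease-model arm (*Model*, e.g. mice
after pressure-overload surgery), and a drug-treated arm (*Treated*) — with a
curated disease-gene set and a protein–protein interaction (PPI) database.
The questions are: which disease genes are central to the disease network,
and for which of them does the drug move expression back toward the healthy
state?

`netrecov` implements that analysis end to end:

1. **Disease network.** Intersect the disease-gene set with the genes
   actually measured; induce the PPI subgraph (edges above a confidence
   cutoff) on the intersection; drop genes with no interaction partner.
2. **NTRA node prioritization.** Aggregate topology and transcriptome ranks
   into one priority per node.
3. **Recovery scoring.** Quantify, per gene, how far treatment moved
   expression back toward Sham (RL) and turn that into a bounded efficiency
   score (EoR).
4. **Key genes and enrichment.** Keep the top NTRA fraction with EoR > 0 and
   test the resulting list for pathway over-representation.

## NTRA rank aggregation

For each network node we take four attributes: betweenness $B$ and degree
$D$ (computed on the unweighted network), and the disease contrast's fold
change $F$ and p-value $P$ (Model vs Sham). With $R(\cdot)$ the ranking
operator (rank 1 = most important; ties get the average of the covered
positions):

$$\mathrm{Rank}_T = R(\mathrm{Rank}_B + \mathrm{Rank}_D), \qquad
  \mathrm{Rank}_R = R(\mathrm{Rank}_F + \mathrm{Rank}_P),$$
$$\mathrm{Rank} = R(\mathrm{Rank}_T + \mathrm{Rank}_R).$$

Conventions we fixed where prose descriptions of such schemes are commonly
ambiguous:

* **Smaller rank number = more crucial gene**, at every level. "Top 50%"
  therefore means final rank $\le \lceil 0.5\,n \rceil$.
* **$\mathrm{Rank}_F$ ranks the fold-change magnitude** $|\log_2 FC|$, since
  both induced and repressed genes matter in a disease network. Signed
  ranking is available via `rank_fc_magnitude = FALSE`.
* Ranking a monotone transform of an attribute changes nothing: the scheme
  is scale-free in every component, and improving any single component can
  only improve (never worsen) the final rank. Both properties are asserted
  in the test suite.

Betweenness is normalized by $(n-1)(n-2)/2$; because only ranks enter NTRA,
normalization affects exported reports, not priorities. STRING confidence
scores act solely as an edge-inclusion filter (default `min_score = 400`,
medium confidence); topology is computed unweighted, matching the defaults
of the common network-analyzer tooling.

## Recovery level and efficiency of recovery

For a gene with disease change $\Delta_{dis} = \log_2 FC(\mathrm{Sham/Model})$
and treatment change $\Delta_{trt} = \log_2 FC(\mathrm{Treated/Model})$:

$$RL = \frac{\Delta_{trt}}{\Delta_{dis}}, \qquad
  EoR = 100\% - \lvert 100\% - RL \rvert.$$

$RL = 1$ means treatment moved the gene exactly back to its Sham level;
$RL = 0$ no movement; $RL < 0$ movement away from Sham; $RL > 2$ an
overshoot past Sham by more than the original displacement. $EoR$ peaks at
100% at $RL = 1$, is symmetric about it, and is negative (retained, not
floored) when there is no recovery effect.

Two deliberate choices:

* **RL is a ratio of log2 fold changes by default.** On the log scale,
  "moved back to Sham" is exactly $RL = 1$ for up- and down-regulated genes
  alike; the linear fold-change ratio (available via `scale = "linear"`)
  treats the two directions asymmetrically.
* **Perturbation guard.** $RL$ divides by the disease effect, so genes with
  $|\Delta_{dis}| < \varepsilon$ (default $\varepsilon = 0.1$) are excluded
  from recovery scoring with reason `"not perturbed"` rather than scored on
  a near-zero denominator. Recovery is a property of imbalanced genes.

Key genes are the intersection of the top NTRA fraction (default 0.5) with
$EoR > 0$; the genes scored by NTRA (network nodes with DE measurements)
form the universe for the hypergeometric over-representation test, since
that is the population the key-gene list is drawn from — any larger universe
would inflate significance. BH correction is applied within each collection.

## The differential-expression stand-in

The DE stage is intentionally simple: counts-per-million normalization, a
pseudocounted log2 ratio of group means, and Welch's unequal-variance t-test
on $\log_2(\mathrm{CPM} + c)$ with $c = 0.5$. It is a stand-in, not a
contribution: the pipeline accepts externally produced DE tables
(`read_de_table()` understands any gene / log2FC-or-FC / p table), so output
from a negative-binomial framework such as DESeq2 can be dropped in
unchanged. Genes with zero counts in every sample of both groups of a
contrast have no defined fold change and are excluded with a recorded
reason. DEG thresholds ($|\log_2 FC| \ge 1$, $p < 0.05$) are exposed as
parameters and used for reporting only — no stage filters on them.

One consequence of CPM normalization worth knowing: when perturbed genes
carry a noticeable fraction of the library, their shift changes every
sample's total and biases all fold changes by a common offset (the classic
composition effect that median-of-ratios normalization is designed to
avoid). The estimator-consistency test therefore uses a study where
perturbed genes are a small mass fraction of the library, which is also the
realistic bulk RNA-seq regime.

## The synthetic-study generator

`generate_study()` plants known structure so every downstream stage can be
checked against ground truth:

* Baseline means $\mu_g$ are log-normal (`base_mean_log_mu = log(100)`,
  `base_mean_log_sigma = 1.2`), spanning the few-counts to
  thousands-of-counts range typical of bulk RNA-seq.
* A fraction of the disease genes (default 0.6) is perturbed:
  Model mean $= \mu_g 2^{\lambda_g}$ with $|\lambda_g| \sim U(1, 3)$ and
  random sign.
* A fraction of the perturbed genes (default 0.6) is recovered on the log2
  scale: Treated log2-mean $=$ Model log2-mean $- r_g \lambda_g$ with
  $r_g \sim U(0.5, 1)$, so the planted $r_g$ maps monotonically onto the
  downstream RL ($r = 1$ ⇒ full return to Sham, $RL = 1$).
* Counts are negative binomial with variance $\mu + \phi\mu^2$
  (`nb_dispersion` $= \phi = 0.1$, the usual RNA-seq parameterization;
  $\phi = 0$ gives Poisson), under per-sample log-normal size factors with
  median 1 so depth is not confounded with group.
* The PPI graph grows by preferential attachment (a path seed of $m+1$
  nodes, then $m$ distinct degree-weighted attachments per new node, giving
  $m(n-m)$ edges), with integer confidence scores uniform in [400, 1000]
  and an optional fraction of deliberately isolated genes. The default
  $m = 25$ gives a ~2000-gene universe about 49,000 edges — the density of
  a medium-confidence STRING export. With a sparse graph the induced
  disease subgraph would shed most of its nodes as isolated, which is not
  what real PPI exports do.
* Default `n_per_group = 3` mirrors the small animal cohorts such studies
  sequence; every size is configurable.

One RNG stream, seeded once, is consumed in a fixed order (baseline means →
effect sizes → gene assignments → PPI edges → counts), so identical configs
are bit-identical — the pipeline's determinism test hashes every output file
across two runs.

What the generator does **not** emulate: batch effects, paired designs,
gene–gene expression correlation, length/GC biases, or read-level noise.
Passing tests on synthetic data therefore demonstrate that the statistics
recover planted structure under the stated noise model, not that any
particular biological claim holds on real data.

## Numerical and edge-case conventions

* Welch's test with zero variance in both groups: $p = 1$ if the means are
  equal, else 0.
* Hypergeometric p-values are upper tails $P(X \ge k)$; an empty overlap
  gives $p = 1$.
* Betweenness on graphs with $\le 2$ nodes is 0 (the normalization is
  undefined); disconnected graphs count paths within components.
* `summarize_recovery()` reports the share of high-recovery genes among
  recovered genes as `NA` (undefined), not 0, when nothing is recovered.
* Ties in any rank component take average ranks; the top-fraction cut uses
  the ceiling convention.

## Problem sizes used in the checks

The test suite validates estimator consistency at `n_per_group = 200` on a
1000-gene universe, parameter recovery at `n_per_group = 50` on a 500-gene
universe (100 perturbed disease genes, 50 recovered with $r \in [0.8, 1]$,
and 150 unperturbed in-network disease genes as background), and oracle
equivalence of betweenness (brute-force path enumeration, graphs up to 12
nodes) and of the hypergeometric tail (exhaustive enumeration, universes up
to 25). These sizes make the full suite run in well under a minute while
leaving the asserted effects far from their decision boundaries.

## A worked example

```{r demo, eval = FALSE}
res <- demo_run(seed = 1)
res$report$funnel
```

The funnel counts report, in order: measured genes, disease genes, their
intersection, isolated genes dropped, network nodes and edges, NTRA-scored
genes, recovery-scored and excluded genes, genes with a recovery trend
(EoR > 0), high-recovery genes (EoR > 80%), the percentage of the latter
among the former, and the final key-gene count. The run report
(`report.json`) also echoes every assumption-bearing parameter — the PPI
score cutoff, the DE stand-in, the RL scale, the perturbation guard and the
enrichment universe — so a reader can audit what a given run did.

## Known limitations

* The DE stand-in has no dispersion shrinkage; at `n_per_group = 3` its
  p-values are noisy, which mainly perturbs $\mathrm{Rank}_P$.
* The perturbation guard $\varepsilon$ substitutes for whatever
  significance filter an original analysis might apply before recovery
  scoring; results for weakly perturbed genes depend on it, and it is
  surfaced in the run report.
* Identifier matching is exact and case-sensitive by design; alias or
  ortholog mapping is out of scope and would silently change results.
* ORA uses plain hypergeometric tails; no proprietary pathway scores or
  clustering of redundant sets.
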