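---
title: "Methods: compositional neural gas analysis of AAP communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional neural gas analysis of AAP communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compng)
```

## The analysis problem

Aerobic anoxygenic phototrophs (AAPs) are photoheterotrophic bacterioplankton
that supplement organic-carbon metabolism with light energy captured by
bacteriochlorophyll-*a* reaction centers. Their community composition is
profiled by metabarcoding of the *pufM* gene (the M subunit of the reaction
center), yielding an ASV count table, while group-specific absolute
abundances come from infrared epifluorescence microscopy combined with FISH
(FISH-IR) using probes for Alphaproteobacteria (ALF968), Gammaproteobacteria
(GAM42a) and the *Roseobacter* clade (ROS537).

`compng` implements the quantitative pipeline connecting these data streams:
compositional (CLR/Aitchison) treatment of the ASV table, neural gas
clustering of samples into best-matching units (BMUs) linked to averaged
environmental factors, repeated-rarefaction alpha diversity, one-way
permutation tests, and the concordance between FISH-IR counts and
metabarcoding "pseudoabundances".

## Compositional treatment

Amplicon counts are compositions: only relative information is meaningful.
The pipeline therefore works in centered log-ratio (CLR) coordinates,

$$\mathrm{clr}(x)_j = \ln x_j - \frac{1}{p}\sum_{k=1}^{p} \ln x_k,$$

and sample dissimilarity is the Aitchison distance, i.e. Euclidean distance
between CLR rows.

Before transformation, features are filtered (keep an ASV iff it has at
least 2 reads in at least 5% of samples) and then samples with library size
below 2000 reads are removed — taxa first, then samples, and a test pins
this order, because the sample filter sees row sums computed after feature
removal. The prevalence threshold uses the ceiling of
`min_prevalence * n_samples`, and counts exactly equal to `min_count`
qualify. The literal phrasing of prevalence-filter rules is notoriously
ambiguous ("occurring less than 2 times in at least 5% of samples were
excluded"); `compng` implements the standard keep-rule (≥ 2 reads in ≥ 5% of
samples), which is the common reading in amplicon practice, and documents
the choice rather than hiding it.

Zeros are replaced by a pseudo-count δ equal to **half the smallest nonzero
relative abundance of the whole matrix** — a single δ for every cell. A
per-sample δ is available by flag, but the global δ is the default because a
common replacement value preserves perturbation invariance across samples:
multiplying every sample by the same positive vector leaves all pairwise
Aitchison distances unchanged (a property the test suite asserts to 1e-9).
δ is computed from the table that is actually transformed, i.e. after
filtering and (where applicable) after agglomeration. Rows are *not*
re-closed after zero replacement: CLR centering absorbs the closure
constant, so re-closure would only shift each row by a constant that the
centering removes anyway. This is documented because re-closing first
changes values slightly and implementations differ.

Agglomeration to order or genus level sums raw counts over lineages
(conserving per-sample totals exactly, in integer arithmetic) and is always
performed **before** the CLR transform, never after: mean CLR values of an
agglomerated taxon are not the CLR of summed counts.

## Neural gas

The clustering engine is a from-scratch neural gas: an online, rank-based
vector quantizer that is robust to outliers because *every* codebook unit
moves toward each presented sample, with a weight decaying exponentially in
the unit's distance rank. For presented sample $x$ at presentation $t$:

$$w_i \leftarrow w_i + \varepsilon(t)\, e^{-r_i/\lambda(t)}\,(x - w_i),$$

where $r_i \in \{0, \dots, K-1\}$ is unit $i$'s rank by Euclidean distance
to $x$ (ties to the lower unit index), and both schedules anneal
exponentially on the presentation clock $t = 1 \dots t_{\max}$,
$t_{\max} = \text{epochs} \times n$:

$$\varepsilon(t) = \varepsilon_i(\varepsilon_f/\varepsilon_i)^{t/t_{\max}},
\qquad
\lambda(t) = \lambda_i(\lambda_f/\lambda_i)^{t/t_{\max}}.$$

Defaults are $K = 5$ units, 1000 epochs, initial step size
$\varepsilon_i = 0.5$ and initial decay constant $\lambda_i = 4.5$ — the
settings used for BMU analysis of CLR-transformed *pufM* data. Only the
initial values of the two schedules are conventionally reported; the
annealing endpoints are design choices here, set to
$\varepsilon_f = 0.005$ and $\lambda_f = 0.01$, typical neural gas endpoints
that make late training nearly winner-only (and both are exposed in
`ng_config()`). Counting $t$ in presentations rather than epochs keeps the
schedules smooth for small $n$. In the limit
$\lambda_i = \lambda_f \to 0$ the algorithm reduces exactly to online
k-means updating only the winner; the test suite checks element-wise
agreement with an independent online k-means oracle to 1e-8.

Initialization uses $K$ distinct data rows chosen by the seeded generator
(not random Gaussians): since every update is a convex combination with
weight $0 < \varepsilon e^{-r/\lambda} \le 1$, the codebook then provably
stays inside the axis-aligned bounding box of the data, which is asserted
after every training run. Units are never reseeded mid-training; an empty
unit is simply reported. After assignment (nearest unit, ties to the lower
index), `relabel_units()` renumbers units by decreasing membership so
reports are comparable across runs. A unit together with its member samples
is one "BMU" (characteristic distribution); per-unit profiles report
unweighted arithmetic means of environmental variables over member samples
(no read-depth weighting), skipping missing measurements and recording the
count of contributing samples — whether published BMU averages include
incompletely measured samples is usually unstated, so the non-missing-only
convention is made explicit here.

Exact numeric replication of codebooks produced by other neural gas
implementations is not attempted: toolboxes differ in how "step size" and
"decay constant" are clocked and annealed. `compng` implements the
algorithm family with the stated hyperparameters and validates it by
parameter recovery: on five planted Gaussian clusters at separation 8× the
within-cluster spread (100 samples, 20 features), the median adjusted Rand
index against truth over 20 seeds is ≥ 0.95, and at separation 0 it is
≤ 0.1.

## Diversity

Alpha diversity (observed ASVs, Shannon $H' = -\sum p \ln p$ in nats,
Pielou $J' = H'/\ln S$) is computed on the *unagglomerated* ASV table under
repeated rarefaction: each sample is subsampled without replacement
(multivariate hypergeometric) to 2000 reads, 100 times by default, and means
and standard deviations across repeats are reported. Without-replacement
subsampling is the default because it matches "random subsample of reads";
the natural logarithm is fixed for $H'$ (and stated, since $J'$ is
base-free but $H'$ is not). $J'$ is undefined for a single observed feature
and returned as missing with a warning. Although rarefaction is sometimes
described as "to the smallest library size", the explicit threshold of 2000
reads is used as the default depth, consistent with the sample filter.

## Permutation tests

`permanova_oneway()` implements Anderson's one-way pseudo-F directly from
the distance matrix,

$$SS_T = \frac{1}{N}\sum_{i<j} d_{ij}^2,\qquad
SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2,\qquad
F = \frac{(SS_T - SS_W)/(a-1)}{SS_W/(N-a)},$$

with significance from seeded label permutations using
$p = (b+1)/(m+1)$ — never zero, minimum $1/(m+1)$. When the number of
distinct relabelings is ≤ 10,000 the full enumeration is used automatically
and $p$ is exact. `permdisp()` embeds the distance matrix by principal
coordinates, computes deviations from group centroids with the standard
correction for negative eigenvalues
($z_i = \sqrt{\max(0, d^2_{\text{real}} - d^2_{\text{imag}})}$), and
permutes the deviations' labels around a one-way ANOVA F. Both are
cross-checked in the tests against `vegan::adonis2()` and
`vegan::betadisper()` respectively, which serve as independent oracles, not
as the implementation.

Only one-way designs are implemented. Nested multi-factor PERMANOVA designs
with conditional (Type II) sums of squares and random factors are out of
scope; users test one factor at a time (e.g. season), which reproduces the
usual pairwise follow-ups in spirit.

## FISH-IR concordance

The metabarcoding pseudoabundance of a probe group is its relative abundance
times the total AAP absolute abundance over 100 (cells/mL). The FISH side of
the correlation is, by default, on the same absolute scale
(`fish_pct * AAP_abs / 100`): the ×AAP/100 conversion in the pseudoabundance
definition only makes sense if the two sides share the cells/mL scale. A
`fish_scale = "percent"` option correlates raw percentages instead.
Group-to-taxon mapping is configuration; the defaults map GAM42a and ALF968
to the two proteobacterial classes and ROS537 to the order Rhodobacterales,
since essentially all alphaproteobacterial *pufM* reads in marine surveys
belong to that order — an interpretation, flagged as such.

Spearman's rho uses average ranks; its two-sided p-value is exact by full
enumeration of orderings for $n \le 9$ and uses the t approximation
otherwise, with the method recorded in the result.

## The synthetic-data generator

`generate_dataset()` emulates the *post-denoising* data structure a one-year
marine AAP survey produces — it is the test bed for every downstream stage,
not a read-level simulator (no FASTQ, no sequence content, no chimera or
error models). Its defaults are the study-scale conditions: 81 samples, 661
ASVs nested in 86 genera, 8 orders and 2 classes; log-normal read depths
with median ≈ 58,000 and a hard floor of 2000; 5 planted clusters;
AAP absolute abundances log-normal with mean 1.43e4 cells/mL (cv ≈ 0.53).

Compositions follow a logistic-normal model: each cluster has a center in
CLR space (a shared baseline log-abundance profile, sd 2, plus
cluster-specific Gaussian offsets with sd `effect_sd = 1` CLR units), each
sample adds within-cluster Gaussian noise (`within_cluster_sd = 0.6` per
coordinate) and is inverted through the softmax to a composition, from which
integer counts are drawn multinomially. The Gaussian-in-CLR choice is
deliberate: the downstream analysis operates in CLR space, so effect sizes
have direct geometric meaning there. The effect and noise scales were fixed
once to give the clearly separated five-cluster structure the BMU analysis
presumes; real communities' overdispersion is unknown, so
`within_cluster_sd` is a free knob, not an estimate.

Cluster labels are iid-uniform by default, to exercise unbalanced-unit
handling; a `balanced` override shuffles near-equal blocks. Note that with
81 samples and 5 clusters, iid labels land within ±30% of perfect balance
only with probability around one half — balance is a distributional
property, and the tests check it pooled over seeds rather than on a single
draw. Environmental variables are Gaussian around cluster-specific means
(five contrasting water masses, from nutrient-enriched/low-salinity to
warm/saline/oligotrophic), with DIN generated as NO3 + NO2 + NH4 for
consistency rather than independently. FISH-like fractions equal the true
class-level (and Rhodobacterales) compositions in percent plus Gaussian
noise (`fish_noise_sd`, default 5 percentage points), clipped to [0, 100] —
so the concordance stage has a tunable true correlation. All randomness
derives from the single config seed; identical configs give identical
datasets.

What the generator does *not* emulate — taxon-specific environmental
responses (environment covaries with cluster identity, not with individual
taxa), sequencing error, primer bias, spatial/temporal autocorrelation of
stations and months — bounds what passing tests show about real data: they
validate the algebra, the algorithms and their calibration under the
assumed data structure, not ecological conclusions.

## Numerical choices and degenerate inputs

- CLR rows sum to zero to < 1e-9; all-zero rows are rejected with a pointer
  to `filter_samples()`.
- Distance matrices must be symmetric to 1e-8; PCoA eigenvalues within
  `max|λ| * 1e-8` of zero are treated as null axes.
- Ties: nearest-unit ties go to the lowest unit index; relabelling ties keep
  the original order; Spearman uses average ranks.
- Empty units are reported (n = 0, missing mean) in profiles, never dropped.
- Permutation p-values are never zero by construction.
- `run_pipeline()` writes only plain TSV/JSON/YAML; `config.yaml` stores
  doubles at 17 significant digits so a replay from the written
  configuration is byte-identical, which a test asserts end-to-end.

## Problem sizes used by the test suite

The suite validates closed forms on toy vectors, oracle agreement on small
enumerable designs (all two-group datasets up to 8 samples for PERMANOVA;
n ≤ 9 for exact Spearman), parameter recovery on 100 × 20 planted-cluster
data over 20 seeds, and the full pipeline at study scale (81 × 661, three
ranks, 1000 epochs, 100 rarefactions, 9999 permutations) — sizes chosen so
the whole suite runs in a couple of minutes on one CPU while still
exercising every code path at the scale the method targets.

## Known limitations

- Only CLR is offered; ALR/ILR variants are out of scope.
- No automatic selection of the number of units, no topology edges (growing
  neural gas) and no SOM grid.
- One-way permutation tests only; no Type II conditional sums of squares or
  random-factor variance components.
- The FISH probe-to-taxon mapping is an interpretation supplied as
  configuration, and FISH probe specificity/coverage issues (e.g. ALF968
  undercounting) are outside the model: the generator's FISH noise is
  unbiased Gaussian.
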