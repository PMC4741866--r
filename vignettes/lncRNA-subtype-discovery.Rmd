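---
title: "Discovering lncRNA expression subtypes: models and methods"
author: "lncSubtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering lncRNA expression subtypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncSubtypes)
```

# Overview

`lncSubtypes` implements a complete workflow for discovering molecular tumor
subgroups from long non-coding RNA (lncRNA) expression in bulk RNA-seq
cohorts, and for characterizing those subgroups against mutations, copy
number, clinical covariates, survival, and a second cohort's subtype
structure. The canonical application is an endometrioid endometrial
carcinoma cohort of roughly 190 tumors in which about 2,000 lncRNAs pass
the expression filter and three subgroups emerge; every default in the
package mirrors that setting.

The stages, each exposed as ordinary functions and orchestrated by
`run_all()`:

1. **Masked quantification** — union-exon gene lengths with mRNA/lncRNA
   cross-class masking, FPKM, low-expression filter.
2. **Normalization** — median-of-ratios size factors, a dispersion-mean
   trend, and a closed-form variance-stabilizing transform (VST).
3. **Differential expression** — a negative-binomial Wald test with
   Benjamini–Hochberg correction and one-vs-rest subgroup signatures.
4. **Subgroup discovery** — resampled consensus hierarchical clustering
   with BIC selection of the cluster number.
5. **Cross-cohort mapping** — Pearson similarity of z-scored
   log~2~(FPKM + 0.5) profiles over shared signature genes.
6. **Association testing** — contingency tests, per-gene alteration scans,
   Kaplan–Meier/log-rank survival, lncRNA–neighbor correlation.

A synthetic-cohort generator (`simulate_cohort()`) produces data with the
exact statistical structure the analysis assumes, so the whole pipeline is
testable without access to any controlled-access tumor data.

# Quantification model

RNA-seq libraries prepared with non-strand-specific protocols cannot assign
a fragment that falls in a genomic region shared by an mRNA and an lncRNA
to either gene. Union-mode counting therefore discards such fragments, and
the corresponding bases must leave the length denominator too. For gene $g$
with merged (union) exon set $E_g$ and $M_g$ the merged exons of all genes
of the *other* class (coding vs lncRNA) on the same chromosome, the masked
length is $\ell_g = |E_g \setminus M_g|$ and

$$\mathrm{FPKM}_{gs} = \frac{10^9 \, c_{gs}}{\ell_g \, N_s},$$

with $c_{gs}$ the fragment count and $N_s$ the per-sample column sum of the
count table. Genes of the same class never mask each other, and a gene
whose exons are entirely covered by the other class has $\ell_g = 0$: it is
unquantifiable, dropped with a warning, and listed in the pipeline report.

Two deliberate conventions:

* **Strand is ignored while masking** (matching non-strand-specific
  libraries); `stranded = TRUE` restricts masking to same-strand overlaps.
* **Library size is the column sum over the genes present in the count
  table.** An external library-size vector can be supplied through
  `compute_fpkm(..., lib_size = )` when totals from the full annotation
  are preferred.

Internally all genomic intervals are `GRanges` (1-based, closed — the
native Bioconductor convention), so GTF import/export through `rtracklayer`
involves no coordinate shifting. The standalone `merge_intervals()` helper
for plain numeric intervals documents and uses half-open `[start, end)`
coordinates; the two conventions never mix.

The **expression filter** keeps genes with FPKM $\ge$ 1 in at least 10% of
samples (`ceiling(0.10 * n)` samples; both the threshold and fraction are
`pipeline_config()` fields). The inclusive threshold and ceiling rule are
asserted by boundary tests at exactly 10% and just below.

# Normalization and the variance-stabilizing transform

Size factors are classical median-of-ratios: for sample $s$,
$\hat{f}_s = \mathrm{median}_g \; c_{gs} / (\prod_t c_{gt})^{1/n}$, where
genes with a zero geometric mean (any zero count) are skipped. No rescaling
to unit geometric mean is applied, so two samples with proportional counts
get factors $(1/\sqrt{2}, \sqrt{2})$ rather than $(1, 2)$ — the convention
the downstream tests pin down. On synthetic cohorts the estimates track the
true library-depth multipliers to well under 5% relative error.

Counts are modeled as negative binomial with $\mathrm{Var} = \mu + \alpha
\mu^2$. Per-gene method-of-moments dispersions
$\hat\alpha_g = \max(0, (s^2_g - \bar\mu_g)/\bar\mu_g^2)$ are regressed on
$1/\bar\mu_g$ by iteratively reweighted least squares (Huber weights, at
most 20 iterations, relative tolerance $10^{-8}$; both configurable),
yielding the trend $\alpha(\mu) = a_1/\mu + a_0$ with coefficients clamped
non-negative. $a_0$ is the squared biological coefficient of variation;
$a_1$ captures the extra spread of weakly expressed genes.

The VST integrates $1/\sqrt{\mathrm{Var}(\mu)}$ for the trend-implied
variance $\mathrm{Var}(\mu) = b\mu + a_0\mu^2$, $b = 1 + a_1$:

$$\mathrm{vst}(q) = \frac{2\,\mathrm{asinh}\!\sqrt{a_0 q / b} -
  \log(4 a_0 / b)}{\log 2}.$$

The scaling and additive constant make $\mathrm{vst}(q) \to \log_2 q$ for
large $q$; the transform is strictly increasing and finite at 0. By the
delta method the transformed standard deviation is $\approx
\sqrt{a_0}/\log 2$ regardless of $\mu$, which the tests verify empirically:
the ratio of median per-gene standard deviations between the top and bottom
expression tertiles stays at or below 2 after the VST while exceeding 4 on
normalized counts. When the fitted trend is degenerate ($a_0 = 0$, i.e.
Poisson-or-less data) the transform falls back to $\log_2(q + 1)$ with a
message.

# Differential expression

`nb_two_group_test()` is a Wald test of equal NB means on the normalized
scale. The per-gene dispersion is the *maximum* of the pooled within-group
method-of-moments estimate and the trend value at the gene's mean — a
conservative choice that protects against genes whose scatter exceeds the
trend. The statistic is the difference of log group means with delta-method
standard error $\sqrt{v_A/(n_A m_A^2) + v_B/(n_B m_B^2)}$,
$v = m + \alpha m^2$, referred to a $t$ distribution with $n_A + n_B - 2$
degrees of freedom. A pseudo-mean of 0.5 guards the logarithms at zero —
the same +0.5 constant used for log fold changes
($\log_2\frac{m_B + 0.5}{m_A + 0.5}$) and for the cross-cohort
$\log_2(\mathrm{FPKM} + 0.5)$ transform, so one offset convention runs
through the whole package. The operative contract is calibration, which the
acceptance suite checks directly: on a 10,000-gene NB null with 30 vs 30
samples the rejection rate at $p < 0.05$ must land in $[0.03, 0.07]$.
A gene with identical counts everywhere is an exact null ($p = 1$,
fold change 0).

Subgroup signatures are one-vs-rest applications of this test with the
joint thresholds fold change $\ge$ 2 and BH-adjusted $p < 0.05$ (both
`pipeline_config()` fields). BH adjustment itself is delegated to
`stats::p.adjust` behind input validation, and is property-tested against a
literal step-up implementation.

# Consensus clustering and the number of clusters

Each of `n_runs` (default 500; the validation suites use 100 for speed)
resampled runs draws 80% of samples and 80% of features without
replacement, computes the Pearson correlation distance $d = 1 - r$ between
samples, builds a Ward tree and cuts it. Ward linkage on this
non-Euclidean distance uses the Lance–Williams `ward.D` update applied to
the dissimilarities as given — stated explicitly because `ward.D`/`ward.D2`
conventions differ between implementations.

**Per-k consensus matrices.** Each run's tree is cut at *every* candidate
k in `k_range` (default 2–6), and co-clustering indicators are accumulated
separately per k. The consensus value of a pair at a given k is the number
of runs in which the pair co-clustered divided by the number of runs in
which both samples were drawn (Monti-style normalization; dividing by the
total run count instead is available via `denominator = "runs"`, which
counts never-co-sampled runs as disagreement). This per-k design is
deliberate: a single consensus matrix built from deep cuts retains genuine
sub-block structure (stable sub-splits of true clusters recur across
resamples because the underlying data are fixed), which makes *any*
likelihood-based model-selection criterion improve monotonically with k —
we verified this empirically for both soft-EM and hard-assignment spherical
Gaussian fits, on clustered and on structureless data alike. Building the
k-cluster consensus from k-cluster cuts makes each matrix reflect only the
stability of a k-way partition, and model selection becomes well behaved.

**Final partition.** For each k, samples are clustered hierarchically on
that k's consensus matrix — by Euclidean distance between consensus rows
(default) or with $1 -$ consensus as the dissimilarity
(`final_input = "dissimilarity"`) — and the tree is cut into exactly k
clusters. Row-space Euclidean is the default because it uses both the
similarity values and a Euclidean metric, and it lets two samples be
recognized as similar through their shared co-clustering profile even when
they were rarely co-sampled together.

**BIC.** For each k, a k-component spherical Gaussian mixture with one
shared variance is fitted to the rows of that k's consensus matrix by
seeded k-means with 10 restarts; the classification log-likelihood gives
$\mathrm{BIC}(k) = -2\log L + (kd + k)\log n$ and the chosen k minimizes
it. The shared variance is floored at $10^{-6}$ so that a perfectly stable
(exactly binary) consensus matrix keeps a finite likelihood; the floor is
far below the Monte-Carlo noise of a consensus entry at any realistic run
count. A k whose fit fails (fewer distinct rows than centers) is flagged
`NA` and excluded. On the synthetic study cohort this procedure selects
k = 3 and recovers the planted labels with adjusted Rand index $\ge$ 0.9
(acceptance suite, ten seeded replicates); on a single structureless blob
it settles at the bottom of `k_range`.

Partition agreement uses the Hubert–Arabie adjusted Rand index, implemented
from the contingency-table formula and cross-checked against both a
pair-counting oracle and `mclust::adjustedRandIndex`. The degenerate case
(both partitions trivial) returns 1 by convention.

# Cross-cohort similarity

Genes significantly overexpressed (up-signature at FDR 0.05) in at least
one subgroup of *each* cohort form the shared panel. Within each cohort
separately, $\log_2(\mathrm{FPKM} + 0.5)$ values of panel genes are
z-scored per gene; the cohort-by-cohort sample correlation matrix is then
condensed to a subgroup-level concordance table (mean correlation over all
sample pairs), and each subgroup of cohort A is matched to the cohort-B
subgroup maximizing it. Matching assumes a shared gene-id namespace.
Because the published record does not state the test behind cross-cohort
match p-values, `subgroup_match_test()` uses a seeded label-permutation
test (default 10,000 permutations) with a p-value floor of
$1/(n_{\mathrm{perm}} + 1)$ — permutation p-values cannot reach the
astronomically small magnitudes a parametric test would print, and the
floor makes that explicit.

# Association tests

* **Contingency tests** are Pearson chi-square without continuity
  correction when all expected counts are $\ge$ 5; otherwise Fisher's
  exact test (2×2) or a seeded Monte-Carlo chi-square ($10^5$ draws) for
  larger sparse tables. Grade and stage are treated as unordered
  categories. Reported percentages are rounded half away from zero to one
  decimal, the convention of the pipeline's text reports.
* **Alteration scans** run the contingency test per gene on binary
  mutation (or gain/loss) indicators with BH adjustment across genes. A
  gene altered in every sample is a degenerate table and reports $p = 1$.
* **Survival** uses the product-limit estimator and the k-group log-rank
  statistic with $k - 1$ degrees of freedom via the `survival` package.
* **Neighbor correlation**: each lncRNA is assigned the coding gene with
  the smallest gene-body gap on the same chromosome (0 when overlapping),
  ties broken by TSS-to-TSS distance and then lexicographic id, with a
  1 Mb cap beyond which the lncRNA is left unassigned — a conventional
  cis-neighborhood definition that avoids spurious distal pairings.
  Correlations are Pearson on $\log_2(\mathrm{FPKM} + 0.5)$, classified
  *positive* above 0.33 and *negative* below $-0.33$ with strict
  inequalities, so a correlation exactly at a threshold stays neutral.

# The synthetic-cohort generator

`simulation_config()` defines the generative model; its defaults *are* the
study conditions and are not tuned per analysis:

| Parameter | Default | Meaning |
|---|---|---|
| `n_samples` | 191 | cohort size |
| `subgroup_proportions` | 77/62/52 ÷ 191 | planted subgroup sizes |
| `n_lnc`, `n_coding` | 2000, 2000 | genes per class |
| `n_signature_per_subgroup` | 50 | signature lncRNAs per subgroup |
| `log2_effect` | 2 | signature shift (log2 units; 4-fold) |
| `nb_dispersion` | 0.1 | NB dispersion $\alpha$ |
| `baseline_log2_mean_range` | [3, 9] | per-gene baseline log2 mean count |
| `depth_factor_range` | [0.5, 2] | per-sample depth multipliers |
| `overlap_fraction` | 0.1 | lncRNAs overlapping a coding exon |
| `censor_rate` | 0.7 | expected censoring fraction |

Counts are NB with mean
$\mathrm{depth}_s \cdot \mathrm{base}_g \cdot 2^{\mathrm{effect}}$; the
effect applies when the gene is a signature of the sample's subgroup.
Mutations are Bernoulli with per-gene per-subgroup rates whose defaults
plant a CTNNB1-like gene at 24.7% / 69.3% / 15.4% across the three
subgroups, plus TP53-like and trithorax-like enrichment in subgroup 1 and
uniform 10% background genes. Copy-number calls in $\{-2..2\}$ follow
analogous gain/loss rate tables. Grade and stage are drawn conditionally on
the subgroup (higher grade/stage in subgroup 1); survival is exponential
with per-subgroup hazard multipliers (1.5 / 1.0 / 0.7 around a median
follow-up scale of about 2,000 days) under independent exponential
censoring calibrated to the target censoring fraction.

Gene geometry is one virtual chromosome with genes laid out left to right
(1–4 exons of 100–1,000 bp, intronic gaps of 200–2,000 bp, intergenic gaps
of 3,000–10,000 bp). Overlaps are planted by moving the first exon of a
chosen lncRNA into the first exon of its nearest coding gene — the
simplest geometry that exercises masking, chosen deliberately over
realistic gene architecture. All randomness flows from one root seed
through a fixed eight-slot seed table (annotation, counts, mutations, CNA,
clinical), so any stage can be regenerated independently and every output
is a pure function of the configuration.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real tumor data: GC/length biases and other
technical covariates, batch structure, correlated gene modules beyond the
planted signatures, cis-regulatory correlation between lncRNAs and their
neighbors, isoform-level effects, subclonal mutations, and segment-level
copy number. Results on synthetic cohorts validate the *statistical
machinery*, not biological discovery.

# Problem sizes used for validation

The test and acceptance suites run the full study geometry — 191 samples,
2,000 lncRNAs (with 500 coding genes for masking and neighbor assignment),
100 consensus runs, ten seeded replicates for cluster-number selection —
and a 10,000-gene null for test calibration. Unit tests use a 60-sample,
600-gene cohort with proportionally scaled subgroups. These sizes were
chosen as the smallest at which the asserted properties are stable across
seeds.

# Known limitations

* The Wald NB test has no dispersion shrinkage and is conservative by
  construction (max of moments and trend); it is calibrated for cohorts of
  tens of samples per group, not for n of 3.
* BIC on consensus rows compares fits across per-k matrices, which is a
  heuristic rather than a single-likelihood comparison; it is validated
  empirically, and both the consensus matrices and the full BIC curve are
  returned so users can inspect stability directly.
* The cross-cohort permutation test measures exceedance of mean
  correlation under label exchange, not any parametric null.
* Multi-factor designs, covariate adjustment, Cox regression, and
  transcript-level quantification are out of scope.
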