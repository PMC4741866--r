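# lncSubtypes

Tumor cohorts can be partitioned into clinically meaningful molecular
subgroups from the expression of long non-coding RNAs (lncRNAs) alone.
`lncSubtypes` packages that analysis end to end for bulk RNA-seq cohorts —
written for computational biologists who have a gene-level count matrix, a
GTF annotation that distinguishes coding genes from lncRNAs, and optional
mutation / copy-number / clinical tables, and who want a reproducible,
seedable pipeline from raw counts to annotated subgroups.

## What it computes

**Masked quantification.** With non-strand-specific libraries, fragments in
regions shared by an mRNA and an lncRNA are discarded by union-mode
counting, so shared bases must also leave the length denominator:

    FPKM[g,s] = 1e9 * count[g,s] / (masked_length[g] * total_fragments[s])

where `masked_length` is the union-exon length minus bases overlapped by
the other gene class. Genes are kept when FPKM ≥ 1 in ≥ 10% of samples.

**Normalization.** Median-of-ratios size factors (genes with a zero
geometric mean skipped), a robust dispersion-mean trend
`alpha(mu) = a1/mu + a0` for negative-binomial counts
(`Var = mu + alpha mu^2`), and the closed-form variance-stabilizing
transform

    vst(q) = (2 asinh(sqrt(a0 q / b)) - log(4 a0 / b)) / log 2,  b = 1 + a1

which converges to `log2(q)` for large counts and makes per-gene standard
deviation approximately constant across the expression range.

**Subgroup discovery.** Consensus clustering: many resampled runs (80% of
samples, 80% of features), Pearson correlation distance with Ward linkage,
per-candidate-k consensus matrices of co-clustering frequencies, a final
Ward tree per k, and the number of clusters chosen by the BIC of a
spherical Gaussian mixture fitted to consensus rows. Subgroup signatures
come from one-vs-rest negative-binomial Wald tests (fold change ≥ 2,
BH-adjusted p < 0.05).

**Characterization.** Cross-cohort similarity (per-cohort z-scores of
`log2(FPKM + 0.5)` over shared signature genes, subgroup-level concordance
and best-match assignment), chi-square/Fisher contingency tests against
clinical variables, per-gene mutation and copy-number scans with BH
correction, Kaplan–Meier / log-rank survival, and lncRNA–nearest-coding-
neighbor expression correlation classified at |r| > 0.33.

A synthetic-cohort generator reproduces the statistical structure of a
~190-sample endometrial-carcinoma-like cohort (three subgroups of 77/62/52
samples, ~2,000 expressed lncRNAs, subgroup-enriched mutations, 
subgroup-dependent survival), so everything is testable offline.

## Worked example

```r
library(lncSubtypes)

cfg    <- simulation_config(n_coding = 500, seed = 7)  # 191 samples, 3 subgroups
cohort <- simulate_cohort(cfg)

fpkm      <- compute_fpkm(cohort$counts, cohort$annotation)
expressed <- low_expression_filter(fpkm)                     # FPKM >= 1 in >= 10%
lnc       <- intersect(expressed, cohort$annotation$genes$gene_id[
                 cohort$annotation$genes$gene_class == "lncRNA"])

counts <- cohort$counts[expressed, ]
sf     <- estimate_size_factors(counts)
trend  <- fit_dispersion_trend(counts, sf)
vst    <- variance_stabilizing_transform(counts, sf, trend)

cc <- consensus_cluster(vst[lnc, ], consensus_config(n_runs = 100, seed = 7))
cc
adjusted_rand_index(cc$labels, cohort$true_labels)

scan <- per_gene_alteration_scan(cc$labels, cohort$mutations, seed = 7)
head(scan[order(scan$q), c("gene", "p", "q", "pct_1", "pct_2", "pct_3")], 3)
km_logrank(cohort$clinical$time, cohort$clinical$event, cc$labels)
```

Output:

```
consensus_result: 191 samples; 100 runs; chosen k = 3
BIC by k: 2=-176674.7, 3=-397035.0, 4=-198118.0, 5=-156375.1, 6=-140239.8
[1] 1
    gene            p            q pct_1 pct_2 pct_3
  CTNNB1 1.199554e-09 2.639020e-08  22.1  66.1  15.4
   KDM6A 1.999980e-05 2.199978e-04  22.1   0.0   1.9
 BGMUT10 1.489690e-04 1.092439e-03   6.5  11.3  32.7
log-rank: chisq = 6.406, df = 2, p = 0.0406
```

Reading it: of 2,492 genes passing the filter, 1,992 are lncRNAs; BIC
selects three clusters (its minimum at k = 3), the recovered labels match
the planted subgroups exactly (adjusted Rand index 1), the planted
CTNNB1-like mutation is the top subgroup-associated gene — mutated in
66.1% of the second subgroup versus 22.1% / 15.4% elsewhere — and survival
differs across subgroups (log-rank p = 0.04).

The same stages run from files:

```sh
Rscript inst/cli/lncsubtypes.R simulate --outdir cohort/ --seed 7
Rscript inst/cli/lncsubtypes.R run-all --annotation cohort/annotation.gtf \
    --counts cohort/counts.tsv --clinical cohort/clinical.tsv \
    --mutations cohort/mutations.tsv --cna cohort/cna.tsv \
    --outdir results/ --seed 7
```

(After installation the CLI script lives at
`system.file("cli", "lncsubtypes.R", package = "lncSubtypes")`.)
`run_all()` stamps every output with the configuration hash and seed;
rerunning an identical configuration reproduces byte-identical files.

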