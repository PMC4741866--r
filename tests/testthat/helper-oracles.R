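# Independent reference implementations used as oracles. These deliberately
# use the most literal formulation available (per-base sets, per-pair loops)
# and stay independent of the package's code paths.

# literal step-up Benjamini-Hochberg
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# masked length by explicit per-base set algebra (1-based closed exons)
masked_length_oracle <- function(gene_exons, other_class_exons) {
  mine <- unique(unlist(apply(gene_exons, 1, function(r) r[1]:r[2],
                              simplify = FALSE)))
  if (is.null(other_class_exons) || nrow(other_class_exons) == 0) {
    return(length(mine))
  }
  theirs <- unique(unlist(apply(other_class_exons, 1, function(r) r[1]:r[2],
                                simplify = FALSE)))
  length(setdiff(mine, theirs))
}

# ARI by brute-force pair counting over all sample pairs
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  np <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / np
  maximum <- ((n11 + n10) + (n11 + n01)) / 2
  if (maximum == expected) return(1)
  (n11 - expected) / (maximum - expected)
}

# chi-square statistic from the textbook expected-count formula
chisq_oracle <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# a tiny annotation built by hand: one lncRNA overlapping a coding exon by
# 200 bp, one clean lncRNA, one lncRNA fully inside a coding exon
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("LNC_A", "LNC_B", "LNC_C", "COD_A", "COD_B"),
    gene_name = c("lncA", "lncB", "lncC", "codA", "codB"),
    gene_class = c("lncRNA", "lncRNA", "lncRNA", "coding", "coding"),
    chrom = "chr1",
    strand = c("+", "-", "+", "+", "-"),
    stringsAsFactors = FALSE)
  exons <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(
      start = c(1, 5001, 10100, 801, 10001),
      end = c(1000, 5400, 10150, 1200, 10400)),
    strand = c("+", "-", "+", "+", "-"),
    gene_id = c("LNC_A", "LNC_B", "LNC_C", "COD_A", "COD_B"))
  gene_annotation(genes, exons)
}
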