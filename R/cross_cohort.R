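#' Signature genes shared between two cohorts
#'
#' Genes significantly overexpressed (the `up` set at adjusted p below
#' `fdr`) in at least one subgroup of cohort A AND at least one subgroup of
#' cohort B. Both cohorts must be quantified on a shared gene-id namespace.
#'
#' @param sig_a,sig_b [subgroup_signatures()] results for the two cohorts.
#' @param fdr FDR threshold re-applied to the stored tables (default 0.05).
#' @return Character vector of shared up-regulated gene ids.
#' @export
shared_signature_genes <- function(sig_a, sig_b, fdr = 0.05) {
  stopifnot(inherits(sig_a, "subgroup_signatures"),
            inherits(sig_b, "subgroup_signatures"))
  up_union <- function(sig) {
    unique(unlist(lapply(sig, function(s) {
      s$table$gene[s$table$call == "up" & s$table$adj_p < fdr]
    })))
  }
  ua <- up_union(sig_a)
  ub <- up_union(sig_b)
  shared <- intersect(ua, ub)
  if (length(shared) == 0L) {
    stop("no shared overexpressed genes at FDR ", fdr,
         " (cohort A: ", length(ua), " up, cohort B: ", length(ub), " up)")
  }
  shared
}

#' Per-cohort z-scores of log2(FPKM + 0.5)
#'
#' Selects `genes` from the FPKM matrix, takes log2(FPKM + 0.5) and
#' standardizes each gene across the cohort's samples (mean 0, sd 1).
#' Genes with zero variance are dropped with a warning. Cohorts are always
#' standardized separately before cross-cohort correlation.
#'
#' @param expr FPKM matrix (`scale_tag = "fpkm"`).
#' @param genes Gene ids to retain (must exist in `expr`).
#' @return Gene x sample z-score matrix.
#' @export
zscore_log2_fpkm <- function(expr, genes) {
  if (!identical(expr_scale(expr), "fpkm")) {
    stop("zscore_log2_fpkm requires an FPKM-scale matrix")
  }
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0L) {
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(absent), collapse = ", "))
  }
  lg <- log2(expr[genes, , drop = FALSE] + 0.5)
  sds <- apply(lg, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped from z-scoring")
    lg <- lg[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (lg - rowMeans(lg)) / sds
}

#' Cross-cohort sample similarity and subgroup matching
#'
#' Pearson correlation between every cohort-A sample and every cohort-B
#' sample over a shared gene panel (both matrices z-scored per cohort with
#' [zscore_log2_fpkm()]). When subgroup labels are supplied, the
#' subgroup-level concordance is the mean correlation over all sample pairs
#' of a subgroup pair, and each cohort-A subgroup is matched to the
#' cohort-B subgroup maximizing it.
#'
#' @param z_a,z_b Gene x sample z-score matrices with identical gene rows.
#' @param labels_a,labels_b Optional per-sample subgroup labels.
#' @return Object of class `cohort_similarity`: list with `shared_genes`,
#'   `corr` (A-samples x B-samples), and (when labels are given)
#'   `subgroup_concordance` and `best_match`.
#' @export
cohort_correlation <- function(z_a, z_b, labels_a = NULL, labels_b = NULL) {
  stopifnot(is.matrix(z_a), is.matrix(z_b))
  if (!identical(rownames(z_a), rownames(z_b))) {
    stop("cohorts must share an identical, identically ordered gene panel")
  }
  if (nrow(z_a) < 3L) stop("need at least 3 shared genes")
  corr <- stats::cor(z_a, z_b)
  out <- list(shared_genes = rownames(z_a), corr = corr,
              subgroup_concordance = NULL, best_match = NULL)
  if (!is.null(labels_a) && !is.null(labels_b)) {
    la <- as.factor(labels_a)
    lb <- as.factor(labels_b)
    stopifnot(length(la) == ncol(z_a), length(lb) == ncol(z_b))
    conc <- matrix(NA_real_, nlevels(la), nlevels(lb),
                   dimnames = list(levels(la), levels(lb)))
    for (u in levels(la)) {
      for (v in levels(lb)) {
        conc[u, v] <- mean(corr[la == u, lb == v, drop = FALSE])
      }
    }
    out$subgroup_concordance <- conc
    out$best_match <- stats::setNames(
      colnames(conc)[apply(conc, 1, which.max)], rownames(conc))
  }
  structure(out, class = "cohort_similarity")
}

#' @export
print.cohort_similarity <- function(x, ...) {
  cat("cohort_similarity over", length(x$shared_genes), "shared genes;",
      nrow(x$corr), "x", ncol(x$corr), "samples\n")
  if (!is.null(x$subgroup_concordance)) {
    print(round(x$subgroup_concordance, 3))
  }
  invisible(x)
}

#' Permutation test for a subgroup match
#'
#' Tests whether the mean correlation between cohort-A subgroup `subgroup_a`
#' and cohort-B subgroup `subgroup_b` exceeds what random cohort-B label
#' assignments produce. The cohort-B labels are permuted across cohort-B
#' samples; the p-value has a floor of 1 / (n_perm + 1).
#'
#' @param similarity A [cohort_correlation()] result computed with labels.
#' @param subgroup_a,subgroup_b Subgroup levels to test.
#' @param labels_a,labels_b The per-sample labels used for the similarity.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutations.
#' @return List with `observed`, `p`, `n_perm`.
#' @export
subgroup_match_test <- function(similarity, subgroup_a, subgroup_b,
                                labels_a, labels_b, n_perm = 10000,
                                seed = 1L) {
  stopifnot(inherits(similarity, "cohort_similarity"))
  la <- as.factor(labels_a)
  lb <- as.factor(labels_b)
  corr_u <- similarity$corr[la == subgroup_a, , drop = FALSE]
  observed <- mean(corr_u[, lb == subgroup_b, drop = FALSE])
  set.seed(seed)
  n_b <- sum(lb == subgroup_b)
  col_means <- colMeans(corr_u)
  perm <- replicate(n_perm, mean(col_means[sample.int(length(col_means), n_b)]))
  p <- (1 + sum(perm >= observed)) / (n_perm + 1)
  list(observed = observed, p = p, n_perm = n_perm)
}
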