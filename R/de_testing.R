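#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1 and monotone in the
#' p-value ranks.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p))) {
    stop("p-values must be finite numbers")
  }
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial two-group differential expression test
#'
#' Wald test of equal NB means across two groups on the size-factor
#' normalized scale. The per-gene dispersion is the maximum of the pooled
#' within-group method-of-moments estimate and the fitted trend value at the
#' gene's mean (a conservative choice). The test statistic is the difference
#' of log group means with delta-method standard error
#' \eqn{\sqrt{v_A / (n_A m_A^2) + v_B / (n_B m_B^2)}}, \eqn{v = m + \alpha m^2},
#' referred to a t distribution with \eqn{n_A + n_B - 2} degrees of freedom;
#' a pseudo-mean of 0.5 guards the log at zero. Fold changes are
#' `log2((mean_B + 0.5) / (mean_A + 0.5))`, so `up` means higher in the
#' second group level.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Two-level factor (or coercible) over the samples; the
#'   second level is the "B" group of the fold change.
#' @param sf Size factors for `counts`.
#' @param trend A [fit_dispersion_trend()] result.
#' @param alpha Significance level for the `call` column.
#' @param fc_threshold Fold-change threshold for the `call` column.
#' @return data.frame of class `de_result` with columns `gene`, `mean_A`,
#'   `mean_B`, `log2_fc`, `p`, `adj_p`, `call` (`up`/`down`/`ns`).
#' @export
nb_two_group_test <- function(counts, groups, sf, trend,
                              alpha = 0.05, fc_threshold = 2) {
  stopifnot(is.matrix(counts))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 samples")
  }
  if (length(groups) != ncol(counts)) {
    stop("groups and count matrix have mismatched samples")
  }
  norm <- normalize_counts(counts, sf)
  a_idx <- groups == levels(groups)[1]
  nA <- sum(a_idx); nB <- sum(!a_idx)
  A <- norm[, a_idx, drop = FALSE]
  B <- norm[, !a_idx, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1L)
  vB <- rowSums((B - mB)^2) / (nB - 1L)
  mu <- (nA * mA + nB * mB) / (nA + nB)
  v_within <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
  alpha_mom <- ifelse(mu > 0, pmax(0, (v_within - mu) / mu^2), 0)
  disp <- pmax(alpha_mom, trend_dispersion(trend, mu))

  eps <- 0.5
  l <- log(mB + eps) - log(mA + eps)
  varA <- (mA + disp * mA^2)
  varB <- (mB + disp * mB^2)
  se2 <- varA / (nA * (mA + eps)^2) + varB / (nB * (mB + eps)^2)
  tstat <- ifelse(se2 > 0, l / sqrt(se2), 0)
  p <- 2 * stats::pt(-abs(tstat), df = nA + nB - 2L)
  p[mA == mB] <- 1  # exact null, including all-zero genes
  log2_fc <- log2((mB + eps) / (mA + eps))
  adj_p <- bh_adjust(p)
  call <- rep("ns", length(p))
  call[adj_p < alpha & log2_fc >= log2(fc_threshold)] <- "up"
  call[adj_p < alpha & log2_fc <= -log2(fc_threshold)] <- "down"
  out <- data.frame(gene = rownames(counts), mean_A = mA, mean_B = mB,
                    log2_fc = log2_fc, p = p, adj_p = adj_p, call = call,
                    row.names = rownames(counts), stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' One-vs-rest subgroup expression signatures
#'
#' For every subgroup, runs [nb_two_group_test()] of that subgroup against
#' all remaining samples and reports the genes passing the joint
#' fold-change / adjusted-p thresholds: `up` genes with FC >= `fc_threshold`
#' and adj_p < `alpha`, `down` genes with FC <= 1 / `fc_threshold`.
#'
#' @param counts Gene x sample count matrix.
#' @param labels Subgroup labeling of the samples (>= 2 levels, each with
#'   >= 2 samples).
#' @param sf Size factors.
#' @param trend A [fit_dispersion_trend()] result.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Named list of class `subgroup_signatures`; per subgroup a list
#'   with `table` (the [nb_two_group_test()] result), `up` and `down` gene
#'   id vectors.
#' @export
subgroup_signatures <- function(counts, labels, sf, trend,
                                fc_threshold = 2, alpha = 0.05) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 subgroups")
  small <- names(which(table(labels) < 2L))
  if (length(small) > 0L) {
    stop("subgroup(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  }
  out <- lapply(levels(labels), function(L) {
    grp <- factor(ifelse(labels == L, "subgroup", "rest"),
                  levels = c("rest", "subgroup"))
    tab <- nb_two_group_test(counts, grp, sf, trend,
                             alpha = alpha, fc_threshold = fc_threshold)
    list(table = tab,
         up = tab$gene[tab$call == "up"],
         down = tab$gene[tab$call == "down"])
  })
  names(out) <- levels(labels)
  class(out) <- "subgroup_signatures"
  out
}

#' @export
print.subgroup_signatures <- function(x, ...) {
  for (L in names(x)) {
    cat(sprintf("%s: %d up, %d down\n", L, length(x[[L]]$up),
                length(x[[L]]$down)))
  }
  invisible(x)
}
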