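#' Pearson correlation distance between samples
#'
#' d(i, j) = 1 - r(x_i, x_j) over the feature rows; 0 for perfectly
#' correlated samples, 2 for anti-correlated ones.
#'
#' @param X Feature x sample numeric matrix (>= 2 features).
#' @return Symmetric sample x sample distance matrix with zero diagonal.
#' @export
pearson_distance <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- if (!is.null(colnames(X))) colnames(X)[sds == 0] else which(sds == 0)
    stop("zero-variance sample(s): ", paste(bad, collapse = ", "))
  }
  d <- 1 - stats::cor(X)
  d[d < 0] <- 0  # guard rounding below 0
  diag(d) <- 0
  d
}

#' Configuration for resampled consensus clustering
#'
#' @param n_runs Number of resampled clustering runs (default 500).
#' @param sample_fraction Fraction of samples drawn per run (default 0.8).
#' @param feature_fraction Fraction of features drawn per run (default 0.8).
#' @param k_range Candidate cluster numbers (default 2:6). Each run's tree
#'   is cut at every candidate k, giving one consensus matrix per k.
#' @param final_input How the final tree is built from a consensus matrix:
#'   `"rows"` (Euclidean distance between consensus-matrix rows, default) or
#'   `"dissimilarity"` (1 - consensus as the distance).
#' @param denominator Normalize co-clustering counts by times co-sampled
#'   (`"cosampled"`, default) or by the total number of runs (`"runs"`).
#' @param seed Seed; run r uses `seed + r`.
#' @return List of class `consensus_config`.
#' @export
consensus_config <- function(n_runs = 500, sample_fraction = 0.8,
                             feature_fraction = 0.8, k_range = 2:6,
                             final_input = c("rows", "dissimilarity"),
                             denominator = c("cosampled", "runs"),
                             seed = 1L) {
  final_input <- match.arg(final_input)
  denominator <- match.arg(denominator)
  if (sample_fraction <= 0 || sample_fraction > 1 ||
      feature_fraction <= 0 || feature_fraction > 1) {
    stop("sample_fraction and feature_fraction must lie in (0, 1]")
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L) stop("k_range minimum must be >= 2")
  structure(list(n_runs = as.integer(n_runs),
                 sample_fraction = sample_fraction,
                 feature_fraction = feature_fraction,
                 k_range = k_range,
                 final_input = final_input, denominator = denominator,
                 seed = as.integer(seed)),
            class = "consensus_config")
}

#' One resampled hierarchical-clustering run
#'
#' Draws `sample_fraction` of the samples and `feature_fraction` of the
#' features without replacement, clusters the subsample with Pearson
#' correlation distance and Ward linkage (the Lance-Williams `ward.D`
#' update on the given dissimilarities), and cuts the tree into exactly `k`
#' clusters.
#'
#' @param X Feature x sample matrix.
#' @param k Number of clusters to cut; a vector of k values cuts the same
#'   tree at each (the subsample is drawn once).
#' @param sample_fraction,feature_fraction Resampling fractions in (0, 1\].
#' @param run_seed Seed for this run's subsampling.
#' @return List with `samples` (drawn sample names) and `labels` (named
#'   cluster labels; a matrix with one column per k when `k` is a vector).
#' @export
run_once <- function(X, k, sample_fraction = 0.8, feature_fraction = 0.8,
                     run_seed = 1L) {
  n <- ncol(X)
  ns <- floor(sample_fraction * n)
  if (ns < max(k)) stop("too few samples drawn (", ns, ") for k = ", max(k))
  set.seed(run_seed)
  samp <- sort(sample.int(n, ns))
  feat <- sort(sample.int(nrow(X), max(2L, floor(feature_fraction * nrow(X)))))
  d <- pearson_distance(X[feat, samp, drop = FALSE])
  tree <- stats::hclust(stats::as.dist(d), method = "ward.D")
  labels <- stats::cutree(tree, k)
  ids <- colnames(X)[samp]
  if (is.matrix(labels)) rownames(labels) <- ids else names(labels) <- ids
  list(samples = ids, labels = labels)
}

#' Resampled consensus clustering with BIC model selection
#'
#' Runs [run_once()] `n_runs` times, cutting each run's tree at every k in
#' `k_range`. For each k, the consensus value of a sample pair is the
#' fraction of runs in which the pair was clustered together among the runs
#' in which both samples were drawn (pairs never co-sampled are imputed 0
#' with a warning). Per k, a final partition comes from hierarchical
#' clustering of that k's consensus matrix (Euclidean distance between
#' consensus rows by default, Ward linkage) cut at k; the number of
#' clusters is chosen by the minimum BIC of a spherical Gaussian mixture
#' fitted to the consensus rows ([select_k_bic()]).
#'
#' @param X Feature x sample matrix (filtered, variance-stabilized
#'   expression; >= 3 * max(k_range) samples).
#' @param cfg A [consensus_config()].
#' @return Object of class `consensus_result`: list with `consensus` (the
#'   chosen k's matrix), `consensus_by_k`, `cosample_counts`,
#'   `labels_by_k`, `bic_by_k`, `chosen_k`, `labels` (labels at
#'   `chosen_k`), `tree` (final tree at `chosen_k`) and `config`.
#' @export
consensus_cluster <- function(X, cfg = consensus_config()) {
  stopifnot(is.matrix(X), inherits(cfg, "consensus_config"))
  n <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("S%03d", seq_len(n))
  if (n < 3L * max(cfg$k_range)) {
    stop("need at least 3 * max(k_range) = ", 3L * max(cfg$k_range),
         " samples, got ", n)
  }
  if (cfg$n_runs < 10L) {
    warning("n_runs < 10 gives a very noisy consensus matrix")
  }
  ks <- cfg$k_range
  nm <- colnames(X)
  together <- lapply(ks, function(k) matrix(0L, n, n, dimnames = list(nm, nm)))
  names(together) <- as.character(ks)
  cosampled <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (r in seq_len(cfg$n_runs)) {
    run <- run_once(X, ks, cfg$sample_fraction, cfg$feature_fraction,
                    run_seed = cfg$seed + r)
    idx <- match(run$samples, nm)
    lab <- run$labels
    if (!is.matrix(lab)) lab <- matrix(lab, ncol = 1L)
    for (j in seq_along(ks)) {
      conn <- outer(lab[, j], lab[, j], "==")
      kk <- as.character(ks[j])
      together[[kk]][idx, idx] <- together[[kk]][idx, idx] + conn
    }
    cosampled[idx, idx] <- cosampled[idx, idx] + 1L
  }
  never <- cosampled == 0
  frac_never <- (sum(never) - sum(diag(never))) / max(1, n * (n - 1L))
  if (frac_never > 0.01) {
    stop(sprintf("%.1f%% of sample pairs were never co-sampled; increase n_runs",
                 100 * frac_never))
  }
  if (any(never[upper.tri(never)])) {
    warning(sum(never[upper.tri(never)]),
            " sample pair(s) never co-sampled; consensus imputed as 0")
  }
  denom <- if (cfg$denominator == "cosampled") cosampled else
    matrix(cfg$n_runs, n, n)
  consensus_by_k <- lapply(together, function(tg) {
    cm <- ifelse(denom > 0, tg / denom, 0)
    diag(cm) <- ifelse(diag(cosampled) > 0, 1, 0)
    dimnames(cm) <- list(nm, nm)
    cm
  })

  final_tree <- function(cm) {
    d <- if (cfg$final_input == "rows") stats::dist(cm) else
      stats::as.dist(1 - cm)
    stats::hclust(d, method = "ward.D")
  }
  labels_by_k <- lapply(as.character(ks), function(kk) {
    stats::cutree(final_tree(consensus_by_k[[kk]]), as.integer(kk))
  })
  names(labels_by_k) <- as.character(ks)
  sel <- select_k_bic(consensus_by_k, ks, seed = cfg$seed)
  kk <- as.character(sel$chosen_k)
  structure(list(consensus = consensus_by_k[[kk]],
                 consensus_by_k = consensus_by_k,
                 cosample_counts = cosampled,
                 labels_by_k = labels_by_k, bic_by_k = sel$bic_by_k,
                 chosen_k = sel$chosen_k,
                 labels = labels_by_k[[kk]],
                 tree = final_tree(consensus_by_k[[kk]]), config = cfg),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result:", ncol(x$consensus), "samples;",
      x$config$n_runs, "runs; chosen k =", x$chosen_k, "\n")
  cat("BIC by k:", paste(sprintf("%s=%.1f", names(x$bic_by_k), x$bic_by_k),
                         collapse = ", "), "\n")
  invisible(x)
}

# Classification BIC of a k-component spherical Gaussian mixture with a
# shared variance, fitted by seeded kmeans restarts. The variance is floored
# at 1e-6 so that an exactly binary consensus matrix (perfectly stable
# clustering) keeps a finite likelihood.
spherical_gmm_bic <- function(rows, k, seed = 1L, nstart = 10L) {
  n <- nrow(rows)
  d <- ncol(rows)
  set.seed(seed)
  km <- stats::kmeans(rows, centers = k, nstart = nstart, iter.max = 100L)
  s2 <- max(km$tot.withinss / (n * d), 1e-6)
  prop <- km$size / n
  loglik <- sum(km$size * log(prop)) - n * d / 2 * (log(2 * pi * s2) + 1)
  n_par <- k * d + (k - 1) + 1
  -2 * loglik + n_par * log(n)
}

#' Choose the cluster number by BIC on consensus rows
#'
#' For every candidate k, fits a spherical shared-variance Gaussian mixture
#' with k components to the rows of the corresponding consensus matrix
#' (seeded k-means restarts, classification likelihood) and reports
#' BIC = -2 log L + n_params log(n); the chosen k minimizes BIC. A k whose
#' fit fails (e.g. fewer distinct rows than centers) is flagged `NA` and
#' excluded from the choice.
#'
#' @param consensus Either a single sample x sample consensus matrix, or a
#'   list of per-k consensus matrices named by k (as produced by
#'   [consensus_cluster()]).
#' @param k_range Candidate cluster numbers.
#' @param seed Seed for the k-means restarts.
#' @return List with `bic_by_k` (named numeric, NA where the fit failed)
#'   and `chosen_k`.
#' @export
select_k_bic <- function(consensus, k_range, seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  get_rows <- function(k) {
    if (is.list(consensus)) consensus[[as.character(k)]] else consensus
  }
  if (max(k_range) >= nrow(get_rows(k_range[1]))) {
    stop("k_range must stay below the sample count")
  }
  bic <- stats::setNames(rep(NA_real_, length(k_range)), as.character(k_range))
  for (k in k_range) {
    rows <- get_rows(k)
    if (is.null(rows)) next
    val <- tryCatch(spherical_gmm_bic(rows, k, seed = seed),
                    error = function(e) NA_real_)
    bic[as.character(k)] <- val
  }
  if (all(is.na(bic))) stop("mixture fit failed for every k in k_range")
  chosen <- as.integer(names(bic)[which.min(bic)])
  list(bic_by_k = bic, chosen_k = chosen)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement computed from the contingency
#' table: 1 for identical partitions (up to label permutation), expectation
#' 0 for independent random labelings.
#'
#' @param a,b Equal-length label vectors (>= 2 samples).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) < 2L) stop("need at least 2 samples")
  tab <- table(a, b)
  n <- length(a)
  c2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(c2(tab))
  sum_a <- sum(c2(rowSums(tab)))
  sum_b <- sum(c2(colSums(tab)))
  expected <- sum_a * sum_b / c2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) {
    # both partitions trivial (single cluster each, or all singletons in
    # both): identical by construction
    return(1)
  }
  (sum_ij - expected) / (maximum - expected)
}
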