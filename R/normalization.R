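#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of the ratio
#' between that sample's count and the gene's geometric mean across samples;
#' genes whose geometric mean is zero (any zero count) are skipped. This is
#' the classical median-of-ratios estimator of effective library size.
#'
#' @param counts Gene x sample count matrix.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop("no gene has a positive geometric mean; filter the count matrix ",
         "or supply deeper data")
  }
  sf <- apply(counts, 2, function(col) {
    exp(stats::median(log(col[use]) - log_geo[use]))
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("non-positive size factor estimated; too many zero counts")
  }
  sf
}

#' Divide counts by size factors
#'
#' @param counts Gene x sample count matrix.
#' @param sf Size factors from [estimate_size_factors()] (names must match
#'   the count-matrix samples).
#' @return Normalized matrix (`scale_tag = "normalized"`).
#' @export
normalize_counts <- function(counts, sf) {
  stopifnot(is.matrix(counts))
  if (length(sf) != ncol(counts)) {
    stop("size factors and count matrix have mismatched samples")
  }
  if (!is.null(names(sf)) && !is.null(colnames(counts)) &&
      !identical(names(sf), colnames(counts))) {
    stop("size-factor names do not match count-matrix samples")
  }
  expression_matrix(sweep(counts, 2, sf, "/"), "normalized")
}

#' Fit the dispersion-mean trend dispersion(mu) = a1 / mu + a0
#'
#' Per-gene method-of-moments dispersions alpha_g = max(0, (var_g - mu_g) /
#' mu_g^2) on normalized counts are regressed on 1 / mu_g by iteratively
#' reweighted least squares with Huber weights; coefficients are clamped to
#' be non-negative. The `a0` asymptote is the biological coefficient of
#' variation squared; `a1` absorbs the Poisson-like extra dispersion of
#' weakly expressed genes.
#'
#' @param counts Gene x sample count matrix (>= 2 samples).
#' @param sf Size factors.
#' @param max_iter Iteration cap for the robust fit.
#' @param tol Relative convergence tolerance on the coefficients.
#' @return Object of class `dispersion_trend`: list with `a0`, `a1`,
#'   `n_genes`, `sigma` (robust residual scale), `iterations`, `converged`.
#' @export
fit_dispersion_trend <- function(counts, sf, max_iter = 20, tol = 1e-8) {
  stopifnot(is.matrix(counts))
  if (ncol(counts) < 2L) stop("dispersion trend needs >= 2 samples")
  norm <- normalize_counts(counts, sf)
  mu <- rowMeans(norm)
  v <- rowSums((norm - mu)^2) / (ncol(norm) - 1L)
  use <- mu > 0
  if (sum(use) < 10L) {
    stop("fewer than 10 genes with positive mean; cannot fit dispersion trend")
  }
  alpha <- pmax(0, (v[use] - mu[use]) / mu[use]^2)
  X <- cbind(a0 = 1, a1 = 1 / mu[use])
  w <- rep(1, length(alpha))
  beta <- c(0, 0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.wfit(X, alpha, w)
    new_beta <- fit$coefficients
    r <- alpha - X %*% new_beta
    s <- stats::mad(r)
    if (s <= 0) s <- stats::sd(r)
    if (s <= 0) s <- 1e-12
    w <- pmin(1, 1.345 * s / pmax(abs(r), 1e-300))  # Huber weights
    if (max(abs(new_beta - beta)) <= tol * max(abs(new_beta), 1)) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
  }
  beta <- pmax(beta, 0)
  structure(list(a0 = unname(beta[1]), a1 = unname(beta[2]),
                 n_genes = sum(use), sigma = stats::mad(alpha - X %*% beta),
                 iterations = it, converged = converged),
            class = "dispersion_trend")
}

#' @export
print.dispersion_trend <- function(x, ...) {
  cat(sprintf("dispersion trend: alpha(mu) = %.4g / mu + %.4g (%d genes)\n",
              x$a1, x$a0, x$n_genes))
  invisible(x)
}

#' Evaluate the fitted dispersion trend at given means
#'
#' @param trend A [fit_dispersion_trend()] result.
#' @param mu Vector of normalized means.
#' @return Trend dispersions `a1 / mu + a0`.
#' @export
trend_dispersion <- function(trend, mu) {
  stopifnot(inherits(trend, "dispersion_trend"))
  ifelse(mu > 0, trend$a1 / mu + trend$a0, Inf)
}

#' Variance-stabilizing transform for NB counts
#'
#' Applies the closed-form transform implied by the fitted mean-variance
#' relation Var(mu) = (1 + a1) mu + a0 mu^2:
#' \deqn{vst(q) = (2 \, \mathrm{asinh}(\sqrt{a_0 q / b}) - \log(4 a_0 / b)) / \log 2,
#'   \quad b = 1 + a_1,}
#' the integral of \eqn{1/\sqrt{Var(\mu)}} scaled and shifted so that
#' vst(q) -> log2(q) for large q. The transform is strictly increasing,
#' defined at zero, and makes the per-gene standard deviation approximately
#' constant across the expression range. When the trend is degenerate
#' (a0 = a1 = 0, i.e. Poisson-or-less data) it falls back to
#' log2(normalized count + 1) with a message.
#'
#' @param counts Gene x sample count matrix.
#' @param sf Size factors.
#' @param trend A [fit_dispersion_trend()] result.
#' @return Transformed matrix (`scale_tag = "vst"`).
#' @export
variance_stabilizing_transform <- function(counts, sf, trend) {
  stopifnot(inherits(trend, "dispersion_trend"))
  q <- normalize_counts(counts, sf)
  if (trend$a0 <= 0) {
    message("degenerate dispersion trend (a0 = 0); using log2(count + 1)")
    return(expression_matrix(log2(q + 1), "vst"))
  }
  b <- 1 + trend$a1
  out <- (2 * asinh(sqrt(trend$a0 * q / b)) - log(4 * trend$a0 / b)) / log(2)
  expression_matrix(out, "vst")
}
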