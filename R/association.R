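#' Round half away from zero
#'
#' Report-style rounding (0.05 -> 0.1) as used for printed percentages,
#' rather than the round-half-even rule of [round()].
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Nearest coding neighbors of lncRNAs
#'
#' Assigns every lncRNA the coding gene minimizing the gene-body gap
#' distance on the same chromosome (0 when the bodies overlap), with ties
#' broken by the smaller TSS-to-TSS distance and then by lexicographic gene
#' id. lncRNAs farther than `max_distance` from any coding gene (or on a
#' chromosome without one) are reported unassigned (`NA` neighbor).
#'
#' @param annotation A [gene_annotation()] object.
#' @param max_distance Maximum gene-body gap in bp (default 1 Mb).
#' @return data.frame with columns `lnc_id`, `neighbor_id`, `distance`.
#' @export
nearest_coding_neighbors <- function(annotation, max_distance = 1e6) {
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  tss <- ifelse(g$strand == "-", g$end, g$start)
  bodies <- GenomicRanges::GRanges(g$chrom,
                                   IRanges::IRanges(g$start, g$end))
  lnc <- which(g$gene_class == "lncRNA")
  coding <- which(g$gene_class == "coding")
  out <- data.frame(lnc_id = g$gene_id[lnc],
                    neighbor_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  if (length(coding) == 0L) return(out)
  for (i in seq_along(lnc)) {
    li <- lnc[i]
    same_chr <- coding[g$chrom[coding] == g$chrom[li]]
    if (length(same_chr) == 0L) next
    dist <- GenomicRanges::distance(bodies[li], bodies[same_chr],
                                    ignore.strand = TRUE)
    dmin <- min(dist)
    if (is.na(dmin) || dmin > max_distance) next
    cand <- same_chr[dist == dmin]
    if (length(cand) > 1L) {
      tssd <- abs(tss[cand] - tss[li])
      cand <- cand[tssd == min(tssd)]
      if (length(cand) > 1L) cand <- cand[order(g$gene_id[cand])][1L]
    }
    out$neighbor_id[i] <- g$gene_id[cand[1L]]
    out$distance[i] <- dmin
  }
  out
}

#' Nearest coding neighbor of one lncRNA
#'
#' @param lnc_id lncRNA gene id present in `annotation`.
#' @inheritParams nearest_coding_neighbors
#' @return One-row data.frame (`lnc_id`, `neighbor_id`, `distance`).
#' @export
nearest_coding_neighbor <- function(lnc_id, annotation, max_distance = 1e6) {
  nn <- nearest_coding_neighbors(annotation, max_distance)
  row <- nn[nn$lnc_id == lnc_id, ]
  if (nrow(row) == 0L) stop("lncRNA not found in annotation: ", lnc_id)
  row
}

#' lncRNA-neighbor expression correlations
#'
#' Pearson correlation of log2(FPKM + 0.5) across samples for each
#' lncRNA/neighbor pair, classified as `positive` (r > `pos_threshold`),
#' `negative` (r < `neg_threshold`) or `neutral` (strict inequalities, so a
#' correlation exactly at a threshold is neutral). Pairs with a
#' zero-variance member are flagged `excluded` with class `NA`.
#'
#' @param expr FPKM matrix (`scale_tag = "fpkm"`).
#' @param pairs data.frame with columns `lnc_id`, `neighbor_id` (and
#'   optionally `distance`), e.g. from [nearest_coding_neighbors()].
#' @param pos_threshold Positive threshold (default 0.33).
#' @param neg_threshold Negative threshold (default `-pos_threshold`).
#' @return data.frame with `lnc_id`, `neighbor_id`, `distance`, `r`,
#'   `class`, `excluded`.
#' @export
neighbor_correlations <- function(expr, pairs, pos_threshold = 0.33,
                                  neg_threshold = -pos_threshold) {
  if (!identical(expr_scale(expr), "fpkm")) {
    stop("neighbor_correlations requires an FPKM-scale matrix")
  }
  pairs <- pairs[!is.na(pairs$neighbor_id), , drop = FALSE]
  absent <- setdiff(c(pairs$lnc_id, pairs$neighbor_id), rownames(expr))
  if (length(absent) > 0L) {
    stop("pair gene(s) absent from expression matrix: ",
         paste(utils::head(absent), collapse = ", "))
  }
  lg <- log2(expr + 0.5)
  r <- rep(NA_real_, nrow(pairs))
  excluded <- rep(FALSE, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- lg[pairs$lnc_id[i], ]
    y <- lg[pairs$neighbor_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      excluded[i] <- TRUE
      next
    }
    r[i] <- stats::cor(x, y)
  }
  cls <- ifelse(is.na(r), NA_character_,
                ifelse(r > pos_threshold, "positive",
                       ifelse(r < neg_threshold, "negative", "neutral")))
  data.frame(lnc_id = pairs$lnc_id, neighbor_id = pairs$neighbor_id,
             distance = if ("distance" %in% names(pairs)) pairs$distance
                        else NA_real_,
             r = r, class = cls, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Subgroup x categorical-variable contingency test
#'
#' Pearson chi-square without continuity correction when all expected cell
#' counts are at least 5; otherwise Fisher's exact test for 2 x 2 tables or
#' a seeded Monte-Carlo chi-square for larger tables. Reports per-subgroup
#' percentages of each variable level (rounded half away from zero to one
#' decimal). Degenerate tables (fewer than two observed levels on either
#' axis) return p = 1.
#'
#' @param labels Per-sample subgroup labels.
#' @param variable Per-sample categorical variable (same length).
#' @param monte_carlo_B Monte-Carlo replicates for sparse r x c tables.
#' @param seed Seed for the Monte-Carlo p-value.
#' @return Object of class `contingency_test`: list with `table`,
#'   `statistic`, `df`, `p`, `method`, `percentages`.
#' @export
subgroup_contingency_test <- function(labels, variable,
                                      monte_carlo_B = 1e5, seed = 1L) {
  if (length(labels) != length(variable)) {
    stop("labels and variable must have equal length")
  }
  la <- factor(labels)
  va <- factor(variable)
  empty <- c(levels(la)[tabulate(la, nlevels(la)) == 0],
             levels(va)[tabulate(va, nlevels(va)) == 0])
  if (length(empty) > 0L) {
    warning("empty level(s) dropped: ", paste(empty, collapse = ", "))
    la <- droplevels(la)
    va <- droplevels(va)
  }
  tab <- table(la, va, dnn = c("subgroup", "variable"))
  pct <- round_half_up(100 * prop.table(tab, margin = 1), 1)
  if (nlevels(la) < 2L || nlevels(va) < 2L) {
    return(structure(list(table = tab, statistic = 0, df = 0L, p = 1,
                          method = "chi-square", percentages = pct),
                     class = "contingency_test"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  statistic <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  if (all(expected >= 5)) {
    ct <- stats::chisq.test(tab, correct = FALSE)
    res <- list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                p = ct$p.value, method = "chi-square")
  } else if (nrow(tab) == 2L && ncol(tab) == 2L) {
    ft <- stats::fisher.test(tab)
    res <- list(statistic = statistic, df = df, p = ft$p.value,
                method = "fisher")
  } else {
    set.seed(seed)
    ct <- stats::chisq.test(tab, simulate.p.value = TRUE, B = monte_carlo_B)
    res <- list(statistic = unname(ct$statistic), df = df, p = ct$p.value,
                method = "chi-square (Monte Carlo)")
  }
  structure(c(list(table = tab), res, list(percentages = pct)),
            class = "contingency_test")
}

#' @export
print.contingency_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.3g\n", x$method,
              x$statistic, x$df, x$p))
  print(x$percentages)
  invisible(x)
}

#' Per-gene alteration enrichment scan across subgroups
#'
#' Runs [subgroup_contingency_test()] for every gene of a binary sample x
#' gene alteration table (mutations, gains or losses), adjusts p-values
#' across genes by Benjamini-Hochberg, and reports per-subgroup alteration
#' percentages.
#'
#' @param labels Per-sample subgroup labels (aligned to the table rows).
#' @param alterations Binary sample x gene matrix.
#' @param monte_carlo_B,seed Passed to [subgroup_contingency_test()].
#' @return data.frame with one row per gene: `gene`, `statistic`, `df`,
#'   `p`, `q`, `method`, and one `pct_<subgroup>` column per subgroup.
#' @export
per_gene_alteration_scan <- function(labels, alterations,
                                     monte_carlo_B = 1e5, seed = 1L) {
  stopifnot(is.matrix(alterations) || is.data.frame(alterations))
  alterations <- as.matrix(alterations)
  la <- factor(labels)
  genes <- colnames(alterations)
  rows <- lapply(genes, function(g) {
    altered <- factor(as.integer(alterations[, g] != 0), levels = c(0L, 1L))
    res <- suppressWarnings(
      subgroup_contingency_test(la, droplevels(altered),
                                monte_carlo_B = monte_carlo_B, seed = seed))
    pct <- vapply(levels(la), function(L) {
      round_half_up(100 * mean(alterations[la == L, g] != 0), 1)
    }, numeric(1))
    c(list(gene = g, statistic = res$statistic, df = res$df, p = res$p,
           method = res$method), as.list(stats::setNames(pct, paste0("pct_", levels(la)))))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  out$q <- bh_adjust(out$p)
  out[, c("gene", "statistic", "df", "p", "q", "method",
          paste0("pct_", levels(la)))]
}

#' Kaplan-Meier curves and log-rank test across subgroups
#'
#' Product-limit survival estimate per subgroup with the k-group log-rank
#' statistic (df = k - 1). Subgroups without any follow-up time are
#' excluded with a warning.
#'
#' @param time Follow-up times (days).
#' @param event Event indicators (1 = event, 0 = censored).
#' @param labels Per-sample subgroup labels.
#' @return Object of class `km_logrank`: list with `fit` (a
#'   [survival::survfit] object), `n` per group, `chisq`, `df`, `p`.
#' @export
km_logrank <- function(time, event, labels) {
  stopifnot(length(time) == length(event), length(time) == length(labels))
  if (sum(event) < 1) stop("need at least one event")
  la <- factor(labels)
  keep_groups <- levels(la)[vapply(levels(la), function(L) {
    any(time[la == L] > 0)
  }, logical(1))]
  if (length(keep_groups) < nlevels(la)) {
    warning("group(s) without follow-up excluded: ",
            paste(setdiff(levels(la), keep_groups), collapse = ", "))
  }
  keep <- la %in% keep_groups
  la <- droplevels(la[keep])
  if (nlevels(la) < 2L) stop("need at least two groups with follow-up")
  df <- data.frame(time = time[keep], event = event[keep], group = la)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- nlevels(la)
  p <- stats::pchisq(sd$chisq, df = k - 1L, lower.tail = FALSE)
  structure(list(fit = fit, n = table(la), chisq = unname(sd$chisq),
                 df = k - 1L, p = p),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.4g, df = %d, p = %.3g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}
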