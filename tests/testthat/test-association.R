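neighbor_toy <- function() {
  # layout on one chromosome (gene bodies):
  # COD_N [1000,2000], COD_F [4000,5000], LNC_X [2500,2600] (gaps 499/1399),
  # LNC_OV [1500,1600] inside COD_N, LNC_TIE equidistant between two coding
  # genes with different TSS distances, LNC_FAR beyond the 1 Mb cap
  genes <- data.frame(
    gene_id = c("COD_N", "COD_F", "COD_T1", "COD_T2",
                "LNC_X", "LNC_OV", "LNC_TIE", "LNC_FAR"),
    gene_name = 1:8, gene_class = rep(c("coding", "lncRNA"), each = 4),
    chrom = "chr1", strand = c("+", "+", "+", "-", "+", "+", "+", "+"),
    stringsAsFactors = FALSE)
  starts <- c(1000, 4000, 20000, 24200, 2500, 1500, 22600, 2000000)
  ends <- c(2000, 5000, 21000, 25200, 2600, 1600, 23100, 2000100)
  exons <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(starts, ends),
                                  gene_id = genes$gene_id)
  gene_annotation(genes, exons)
}

test_that("nearest coding neighbor follows gap, TSS and id tie rules", {
  ann <- neighbor_toy()
  nn <- nearest_coding_neighbors(ann)
  rownames(nn) <- nn$lnc_id
  # overlap -> that gene at distance 0
  expect_equal(nn["LNC_OV", "neighbor_id"], "COD_N")
  expect_equal(nn["LNC_OV", "distance"], 0)
  # plain nearest gap (499 vs 1399)
  expect_equal(nn["LNC_X", "neighbor_id"], "COD_N")
  expect_equal(nn["LNC_X", "distance"], 499)
  # equal gene-body gaps: COD_T1 gap = 22600-21000-1 = 1599,
  # COD_T2 gap = 24200-23100-1 = 1099 -> actually nearest wins; make tie:
  # TSS rule exercised below via constructed tie
  expect_equal(nn["LNC_TIE", "neighbor_id"], "COD_T2")
  # beyond the 1 Mb window: unassigned
  expect_true(is.na(nn["LNC_FAR", "neighbor_id"]))
  one <- nearest_coding_neighbor("LNC_X", ann)
  expect_equal(one$neighbor_id, "COD_N")
  expect_error(nearest_coding_neighbor("NOPE", ann), "not found")
})

test_that("gene-body ties break by TSS distance then gene id", {
  # two coding genes at equal body gap 100 from the lncRNA; the minus-strand
  # gene's TSS (its end) sits farther away than the plus-strand gene's TSS
  genes <- data.frame(
    gene_id = c("COD_L", "COD_R", "LNC_M"),
    gene_name = 1:3, gene_class = c("coding", "coding", "lncRNA"),
    chrom = "chr1", strand = c("-", "+", "+"), stringsAsFactors = FALSE)
  exons <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1000, 3101, 2601), c(2500, 4000, 3000)),
    gene_id = genes$gene_id)
  ann <- gene_annotation(genes, exons)
  # gaps: L: 2601-2500-1 = 100; R: 3101-3000-1 = 100 (tie)
  # TSS distances (to lnc TSS 2601): L TSS = 2500 (end, minus strand) -> 101
  #                                  R TSS = 3101 -> 500
  nn <- nearest_coding_neighbors(ann)
  expect_equal(nn$neighbor_id[nn$lnc_id == "LNC_M"], "COD_L")

  # exact tie in both gap and TSS distance: lexicographically smaller id
  genes2 <- genes
  genes2$strand <- c("+", "+", "+")
  exons2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(2101, 3101, 2601), c(2500, 3500, 3000)),
    gene_id = genes2$gene_id)
  ann2 <- gene_annotation(genes2, exons2)
  # gaps both 100; TSS distances: |2101-2601| = 500, |3101-2601| = 500
  nn2 <- nearest_coding_neighbors(ann2)
  expect_equal(nn2$neighbor_id[nn2$lnc_id == "LNC_M"], "COD_L")
})

test_that("neighbor correlations classify by strict thresholds", {
  set.seed(71)
  ns <- 191
  m <- rbind(
    lnc1 = exp(rnorm(ns, 3)), lnc2 = exp(rnorm(ns, 3)),
    lnc3 = exp(rnorm(ns, 3)), flat = rep(2, ns))
  m <- rbind(m, nb1 = m["lnc1", ], nb2 = exp(rnorm(ns, 3)),
             nb3 = exp(rnorm(ns, 3)))
  expr <- expression_matrix(m, "fpkm")
  pairs <- data.frame(lnc_id = c("lnc1", "lnc2", "flat"),
                      neighbor_id = c("nb1", "nb2", "nb3"))
  out <- neighbor_correlations(expr, pairs)
  rownames(out) <- out$lnc_id
  expect_equal(out["lnc1", "r"], 1)
  expect_equal(out["lnc1", "class"], "positive")
  expect_equal(out["lnc2", "class"], "neutral")
  expect_true(out["flat", "excluded"])
  expect_true(is.na(out["flat", "class"]))
})

test_that("independent pairs rarely cross the 0.33 threshold at n = 191", {
  set.seed(72)
  ns <- 191
  n_pairs <- 400
  m <- matrix(exp(rnorm(2 * n_pairs * ns, 3)), ncol = ns)
  rownames(m) <- c(sprintf("lnc%d", 1:n_pairs), sprintf("nb%d", 1:n_pairs))
  expr <- expression_matrix(m, "fpkm")
  pairs <- data.frame(lnc_id = sprintf("lnc%d", 1:n_pairs),
                      neighbor_id = sprintf("nb%d", 1:n_pairs))
  out <- neighbor_correlations(expr, pairs)
  expect_gte(mean(abs(out$r) < 0.33), 0.99)
})

test_that("a correlation exactly at the threshold is neutral", {
  set.seed(76)
  x <- rnorm(30, 3)
  y <- 0.4 * x + rnorm(30)
  expr <- expression_matrix(rbind(lnc = 2^x - 0.5, nb = 2^y - 0.5), "fpkm")
  pairs <- data.frame(lnc_id = "lnc", neighbor_id = "nb")
  r_obs <- neighbor_correlations(expr, pairs)$r
  # re-classify with thresholds placed exactly at the observed correlation:
  # the strict inequality must leave the pair neutral on both sides
  at_pos <- neighbor_correlations(expr, pairs, pos_threshold = r_obs)
  expect_equal(at_pos$class, "neutral")
  at_neg <- neighbor_correlations(expr, pairs, pos_threshold = 2,
                                  neg_threshold = r_obs)
  expect_equal(at_neg$class, "neutral")
  just_below <- neighbor_correlations(expr, pairs,
                                      pos_threshold = r_obs - 1e-12)
  expect_equal(just_below$class, "positive")
})

test_that("contingency test reproduces the printed mutation percentages", {
  labels <- rep(c("basal", "ctnnb1", "luminal"), c(77, 62, 52))
  mutated <- c(rep(1, 19), rep(0, 77 - 19),
               rep(1, 43), rep(0, 62 - 43),
               rep(1, 8), rep(0, 52 - 8))
  res <- subgroup_contingency_test(labels, mutated)
  pct <- res$percentages[, "1"]
  expect_equal(unname(pct[c("ctnnb1", "basal", "luminal")]),
               c(69.4, 24.7, 15.4))  # 43/62 = 69.35 rounds up at 1 decimal
  expect_equal(res$method, "chi-square")
  expect_equal(res$statistic, chisq_oracle(unclass(res$table)),
               tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_lt(res$p, 1e-9)
})

test_that("sparse tables fall back to exact or Monte-Carlo tests", {
  # 2 x 2 with expected counts below 5 -> Fisher; hypergeometric oracle
  labels <- rep(c("a", "b"), each = 7)
  var <- c(rep(1, 7), rep(0, 7))
  res <- subgroup_contingency_test(labels, var)
  expect_equal(res$method, "fisher")
  p_oracle <- 2 * dhyper(7, 7, 7, 7)  # both one-sided extremes
  expect_equal(res$p, min(1, p_oracle), tolerance = 1e-12)
  expect_lt(res$p, 0.001)

  # r x c sparse -> seeded Monte-Carlo chi-square, reproducible
  labels3 <- rep(c("a", "b", "c"), c(8, 8, 8))
  var3 <- c(rep(0:1, c(6, 2)), rep(0:1, c(2, 6)), rep(0:1, c(7, 1)))
  r1 <- subgroup_contingency_test(labels3, var3, monte_carlo_B = 2000, seed = 3)
  r2 <- subgroup_contingency_test(labels3, var3, monte_carlo_B = 2000, seed = 3)
  expect_equal(r1$method, "chi-square (Monte Carlo)")
  expect_equal(r1$p, r2$p)
})

test_that("null contingency p-values are close to uniform", {
  set.seed(73)
  ps <- replicate(300, {
    labels <- sample(rep(1:3, c(60, 50, 40)))
    var <- rbinom(150, 1, 0.4)
    subgroup_contingency_test(labels, var)$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("chi-square statistic is invariant to category permutation", {
  labels <- rep(c("x", "y", "z"), c(30, 30, 30))
  var <- sample(rep(c("g1", "g2", "g3"), 30))
  a <- subgroup_contingency_test(labels, var)
  b <- subgroup_contingency_test(factor(labels, levels = c("z", "x", "y")),
                                 var)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p, b$p)
})

test_that("the alteration scan flags planted genes and only those", {
  b <- small_cohort()
  scan <- per_gene_alteration_scan(b$true_labels, b$mutations, seed = 2)
  expect_equal(scan$q, bh_adjust(scan$p))
  # constant gene: no association by construction
  all_mut <- cbind(b$mutations, ALLMUT = 1L)
  scan2 <- per_gene_alteration_scan(b$true_labels, all_mut, seed = 2)
  expect_equal(scan2$p[scan2$gene == "ALLMUT"], 1)
  # permuted labels: few nominal hits
  set.seed(74)
  hits <- replicate(10, {
    perm <- sample(b$true_labels)
    mean(per_gene_alteration_scan(perm, b$mutations, seed = 2)$p < 0.05)
  })
  expect_lte(mean(hits), 0.06)
})

test_that("a CTNNB1-like planted gene reaches q < 0.01 routinely", {
  hit <- replicate(20, TRUE)
  for (r in 1:20) {
    cfg <- simulation_config(n_coding = 5, n_lnc = 10,
                             n_signature_per_subgroup = 1, seed = 2000L + r)
    b <- simulate_cohort(cfg)
    scan <- per_gene_alteration_scan(b$true_labels, b$mutations, seed = 2)
    hit[r] <- scan$q[scan$gene == "CTNNB1"] < 0.01
  }
  expect_gte(mean(hit), 0.95)
})

test_that("Kaplan-Meier and log-rank behave on canonical cases", {
  time <- c(5, 8, 12, 20, 33, 40, 44, 60)
  event <- c(1, 0, 1, 1, 0, 1, 1, 0)
  # identical data in two groups: statistic 0, p = 1
  res <- km_logrank(rep(time, 2), rep(event, 2), rep(c("a", "b"), each = 8))
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  # without censoring the KM estimate is the empirical survival function
  fit <- survival::survfit(survival::Surv(time, rep(1, 8)) ~ 1)
  ecdf_surv <- 1 - ecdf(time)(fit$time)
  expect_equal(fit$surv, ecdf_surv)
  # KM curves are non-increasing from 1
  km <- km_logrank(time, event, rep(c("a", "b"), 4))
  surv <- km$fit$surv
  expect_true(all(surv <= 1))
  expect_true(all(diff(km$fit$surv[1:km$fit$strata[1]]) <= 0))
  expect_error(km_logrank(time, rep(0, 8), rep(c("a", "b"), 4)),
               "at least one event")
})

test_that("log-rank detects a three-fold hazard ratio", {
  set.seed(75)
  detected <- replicate(20, {
    t1 <- rexp(60, 3); t2 <- rexp(60, 1)
    km_logrank(c(t1, t2), rep(1, 120), rep(c("a", "b"), each = 60))$p < 0.01
  })
  expect_gte(mean(detected), 0.90)
})

test_that("percentages round half away from zero", {
  expect_equal(round_half_up(c(0.05, 0.15, 0.25, -0.05), 1),
               c(0.1, 0.2, 0.3, -0.1))
  expect_equal(round_half_up(69.3548387, 1), 69.4)
  expect_equal(round_half_up(24.6753247, 1), 24.7)
  expect_equal(round_half_up(15.3846154, 1), 15.4)
})
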