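blob_matrix <- function(n_per = c(12, 12, 12), n_feat = 60, sep = 10,
                        seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(length(n_per) * n_feat), ncol = length(n_per)) * sep
  X <- do.call(cbind, lapply(seq_along(n_per), function(g) {
    centers[, g] + matrix(rnorm(n_feat * n_per[g]), nrow = n_feat)
  }))
  colnames(X) <- sprintf("S%02d", seq_len(ncol(X)))
  rownames(X) <- sprintf("f%02d", seq_len(n_feat))
  attr(X, "truth") <- rep(seq_along(n_per), n_per)
  X
}

test_that("pearson distance follows the correlation identities", {
  set.seed(51)
  X <- matrix(rnorm(100 * 20), nrow = 100,
              dimnames = list(NULL, sprintf("s%d", 1:20)))
  X[, 2] <- 2 * X[, 1] + 3   # affine image: distance 0
  X[, 3] <- -X[, 1]          # anti-correlated: distance 2
  d <- pearson_distance(X)
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 2)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 2))
  # brute-force formula oracle
  for (pair in list(c(4, 5), c(6, 17), c(11, 12))) {
    i <- pair[1]; j <- pair[2]
    r <- sum(scale(X[, i]) * scale(X[, j])) / (nrow(X) - 1)
    expect_equal(d[i, j], 1 - r, tolerance = 1e-12)
  }
  Xz <- X
  Xz[, 5] <- 7
  expect_error(pearson_distance(Xz), "s5")
})

test_that("a single run is deterministic and recovers separated blobs", {
  X <- blob_matrix(n_per = c(10, 10), sep = 10, seed = 52)
  full <- run_once(X, 2, sample_fraction = 1, feature_fraction = 1,
                   run_seed = 1)
  expect_identical(full$labels,
                   run_once(X, 2, 1, 1, run_seed = 99)$labels)
  expect_equal(adjusted_rand_index(full$labels, attr(X, "truth")), 1)

  sub <- run_once(X, 2, 0.8, 0.8, run_seed = 5)
  expect_identical(sub, run_once(X, 2, 0.8, 0.8, run_seed = 5))
  expect_length(sub$samples, floor(0.8 * 20))
  expect_false(identical(sub$samples,
                         run_once(X, 2, 0.8, 0.8, run_seed = 6)$samples))
  # vector k cuts one tree at every k
  multi <- run_once(X, c(2, 3), 1, 1, run_seed = 1)
  expect_equal(dim(multi$labels), c(20, 2))
  expect_equal(unname(multi$labels[, 1]), unname(full$labels))

  expect_error(run_once(X, 19, 0.5, 1, run_seed = 1), "too few samples")
})

test_that("consensus matrices are well-formed and degenerate cleanly", {
  X <- blob_matrix(n_per = c(10, 9, 8), sep = 8, seed = 53)
  cc <- consensus_cluster(X, consensus_config(n_runs = 60, k_range = 2:4,
                                              seed = 3))
  for (cm in cc$consensus_by_k) {
    expect_equal(cm, t(cm))
    expect_true(all(cm >= 0 & cm <= 1))
    expect_true(all(diag(cm) == 1))
  }
  expect_equal(cc$chosen_k, 3)
  expect_equal(adjusted_rand_index(cc$labels, attr(X, "truth")), 1)

  # identical samples: every co-sampled pair has consensus 1
  Xc <- matrix(rnorm(40), nrow = 20, ncol = 12)
  Xc <- Xc[, rep(1, 12)] + 0  # all columns identical
  Xc <- Xc + matrix(rnorm(20 * 12, sd = 1e-6), 20)  # break exact ties only
  colnames(Xc) <- sprintf("c%d", 1:12)
  rownames(Xc) <- sprintf("f%d", 1:20)
  cc2 <- consensus_cluster(Xc, consensus_config(n_runs = 30, k_range = 2:3,
                                                seed = 4))
  off <- cc2$consensus_by_k[["2"]][upper.tri(cc2$consensus)]
  # with k forced above 1 some split must occur, but co-clustering of
  # indistinguishable samples stays unstable rather than structured:
  # no pair is systematically separated across every run
  expect_true(mean(off) > 0.2)
})

test_that("sample order does not change the discovered partition", {
  X <- blob_matrix(n_per = c(10, 9, 8), sep = 8, seed = 54)
  cfg <- consensus_config(n_runs = 60, k_range = 2:4, seed = 9)
  cc1 <- consensus_cluster(X, cfg)
  perm <- sample(ncol(X))
  cc2 <- consensus_cluster(X[, perm], cfg)
  expect_equal(adjusted_rand_index(cc1$labels[colnames(X)[perm]],
                                   cc2$labels), 1)
  expect_equal(cc1$chosen_k, cc2$chosen_k)
})

test_that("destroying the structure flattens within-cluster consensus", {
  X <- blob_matrix(n_per = c(10, 9, 8), sep = 8, seed = 55)
  truth <- attr(X, "truth")
  cfg <- consensus_config(n_runs = 60, k_range = 2:4, seed = 10)
  cc <- consensus_cluster(X, cfg)
  Xp <- t(apply(X, 1, sample))  # permute each feature independently
  colnames(Xp) <- colnames(X)
  ccp <- consensus_cluster(Xp, cfg)
  within <- function(cm) {
    vals <- c()
    for (g in unique(truth)) {
      idx <- which(truth == g)
      block <- cm[idx, idx]
      vals <- c(vals, block[upper.tri(block)])
    }
    mean(vals)
  }
  expect_gt(within(cc$consensus_by_k[["3"]]), 0.95)
  expect_lt(within(ccp$consensus_by_k[["3"]]), 0.6)
})

test_that("more runs reduce the Monte-Carlo noise of consensus entries", {
  # structureless data: co-clustering of any pair is genuinely stochastic
  X <- blob_matrix(n_per = c(8, 8), n_feat = 40, sep = 0, seed = 56)
  ent <- function(n_runs, seed) {
    cc <- consensus_cluster(X, consensus_config(n_runs = n_runs,
                                                k_range = 2:3, seed = seed))
    cc$consensus_by_k[["2"]][upper.tri(cc$consensus)]
  }
  few <- sapply(1:6, function(s) ent(15, 100 + s))
  many <- sapply(1:6, function(s) ent(120, 200 + s))
  sd_few <- mean(apply(few, 1, sd))
  sd_many <- mean(apply(many, 1, sd))
  expect_lt(sd_many, sd_few)
})

test_that("BIC selects the planted cluster number", {
  X3 <- blob_matrix(n_per = c(12, 11, 10), sep = 8, seed = 57)
  cc3 <- consensus_cluster(X3, consensus_config(n_runs = 80, k_range = 2:6,
                                                seed = 11))
  expect_equal(cc3$chosen_k, 3)

  # single blob: BIC settles at the k_range minimum
  X1 <- blob_matrix(n_per = c(24), sep = 0, seed = 58)
  cc1 <- consensus_cluster(X1, consensus_config(n_runs = 80, k_range = 2:6,
                                                seed = 12))
  expect_equal(cc1$chosen_k, 2)
  expect_identical(names(cc1$bic_by_k), as.character(2:6))
})

test_that("adjusted Rand index matches the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1, 1), c(1, 1, 2, 2)), 0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 3), c(1, 2, 2, 3, 3)),
               ari_pair_oracle(c(1, 1, 2, 2, 3), c(1, 2, 2, 3, 3)))
  set.seed(59)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_pair_oracle(a, b))
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(60)
  for (rep in 1:10) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:5, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unname(mclust::adjustedRandIndex(a, b)))
  }
})
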