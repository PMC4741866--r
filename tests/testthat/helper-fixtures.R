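# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .fixture_cache)) {
    assign(name, builder(), .fixture_cache)
  }
  get(name, .fixture_cache)
}

small_config <- function(...) {
  defaults <- list(n_samples = 60, n_coding = 200, n_lnc = 400,
                   subgroup_proportions = c(24, 20, 16) / 60,
                   n_signature_per_subgroup = 25, seed = 101L)
  args <- utils::modifyList(defaults, list(...))
  if (!("n_signature_per_subgroup" %in% names(list(...)))) {
    args$n_signature_per_subgroup <- min(25L, args$n_lnc %/% 3L)
  }
  do.call(simulation_config, args)
}

# 60-sample cohort with clear planted structure, reused across test files
small_cohort <- function() {
  cached("small_cohort", function() simulate_cohort(small_config()))
}

# normalization products for the small cohort
small_norm <- function() {
  cached("small_norm", function() {
    b <- small_cohort()
    fpkm <- suppressWarnings(compute_fpkm(b$counts, b$annotation))
    keep <- low_expression_filter(fpkm)
    counts <- b$counts[keep, ]
    sf <- estimate_size_factors(counts)
    trend <- fit_dispersion_trend(counts, sf)
    list(bundle = b, fpkm = fpkm, expressed = keep, counts = counts,
         sf = sf, trend = trend,
         vst = variance_stabilizing_transform(counts, sf, trend))
  })
}

# paired cohorts sharing planted subgroup axes: one double-size cohort is
# simulated and split into two halves with independent samples, so subgroup
# g of cohort A shares its signature genes with subgroup g of cohort B
paired_cohorts <- function(seed = 301L) {
  cfg <- small_config(n_samples = 120,
                      subgroup_proportions = c(48, 40, 32) / 120,
                      seed = seed)
  big <- simulate_cohort(cfg)
  in_a <- unlist(lapply(split(seq_len(120), big$true_labels),
                        function(idx) idx[seq_along(idx) %% 2 == 1]))
  take <- function(cols) {
    out <- big
    out$counts <- big$counts[, cols, drop = FALSE]
    out$true_labels <- big$true_labels[cols]
    out$clinical <- big$clinical[cols, ]
    out$mutations <- big$mutations[cols, , drop = FALSE]
    out$cna <- big$cna[cols, , drop = FALSE]
    out
  }
  list(a = take(sort(in_a)), b = take(sort(setdiff(seq_len(120), in_a))))
}
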