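#' Default per-subgroup mutation rates
#'
#' A small somatic-mutation panel with planted subgroup enrichment mirroring
#' patterns reported in endometrioid endometrial carcinoma: a CTNNB1-like
#' gene strongly enriched in one subgroup (rates 24.7% / 69.3% / 15.4%),
#' trithorax-like and TP53-like genes enriched in the basal-like subgroup,
#' plus background genes mutated uniformly at 10%.
#'
#' @param n_subgroups Number of subgroups (planted rates are defined for 3;
#'   other values get a uniform 10% panel).
#' @param n_background Number of unassociated background genes.
#' @return Matrix of per-subgroup mutation probabilities, genes in rows.
#' @export
default_mutation_rates <- function(n_subgroups = 3, n_background = 15) {
  bg <- matrix(0.1, nrow = n_background, ncol = n_subgroups,
               dimnames = list(sprintf("BGMUT%02d", seq_len(n_background)), NULL))
  if (n_subgroups != 3) {
    colnames(bg) <- sprintf("subgroup%d", seq_len(n_subgroups))
    return(bg)
  }
  planted <- rbind(
    CTNNB1 = c(0.247, 0.693, 0.154),
    PTEN   = c(0.55, 0.80, 0.55),
    KRAS   = c(0.22, 0.08, 0.22),
    TP53   = c(0.35, 0.08, 0.08),
    MLL2   = c(0.26, 0.08, 0.08),
    MLL3   = c(0.234, 0.07, 0.07),
    KDM6A  = c(0.18, 0.05, 0.05))
  out <- rbind(planted, bg)
  colnames(out) <- sprintf("subgroup%d", 1:3)
  out
}

#' Default per-subgroup copy-number alteration rates
#'
#' Gain and loss probabilities per gene per subgroup; the basal-like subgroup
#' carries enriched gains (SOX2/FGF12/TP63-like) and deletions
#' (PTEN/STK11/CDKN2A/RB1-like), and one gene is gain-enriched in the
#' CTNNB1-like subgroup.
#'
#' @inheritParams default_mutation_rates
#' @return List with `gain` and `loss` probability matrices (genes x
#'   subgroups).
#' @export
default_cna_rates <- function(n_subgroups = 3, n_background = 10) {
  bg_names <- sprintf("BGCNA%02d", seq_len(n_background))
  bg <- matrix(0.05, nrow = n_background, ncol = n_subgroups,
               dimnames = list(bg_names, NULL))
  if (n_subgroups != 3) {
    gain <- bg; loss <- bg
    colnames(gain) <- colnames(loss) <- sprintf("subgroup%d", seq_len(n_subgroups))
    return(list(gain = gain, loss = loss))
  }
  gain <- rbind(
    SOX2  = c(0.35, 0.08, 0.08),
    FGF12 = c(0.30, 0.08, 0.08),
    TP63  = c(0.30, 0.08, 0.08),
    FGF8  = c(0.08, 0.35, 0.08),
    bg)
  loss <- rbind(
    SOX2 = c(0.02, 0.02, 0.02), FGF12 = c(0.02, 0.02, 0.02),
    TP63 = c(0.02, 0.02, 0.02), FGF8 = c(0.02, 0.02, 0.02),
    matrix(0.05, nrow = n_background, ncol = 3, dimnames = list(bg_names, NULL)),
    PTEN   = c(0.40, 0.10, 0.10),
    STK11  = c(0.30, 0.08, 0.08),
    CDKN2A = c(0.30, 0.08, 0.08),
    RB1    = c(0.25, 0.08, 0.08))
  gain <- rbind(gain,
                PTEN = c(0.02, 0.02, 0.02), STK11 = c(0.02, 0.02, 0.02),
                CDKN2A = c(0.02, 0.02, 0.02), RB1 = c(0.02, 0.02, 0.02))
  gain <- gain[rownames(loss), ]
  colnames(gain) <- colnames(loss) <- sprintf("subgroup%d", 1:3)
  list(gain = gain, loss = loss)
}

#' Simulation configuration for synthetic cohorts
#'
#' Defines the generative model used throughout the test-bed: a cohort of
#' `n_samples` tumors split into `n_subgroups` molecular subgroups, gene
#' counts drawn from a negative binomial with mean-dispersion
#' parameterization (Var = mu + alpha mu^2), per-subgroup lncRNA signature
#' genes shifted by `log2_effect`, per-sample sequencing-depth multipliers,
#' mRNA/lncRNA exon overlaps at a configurable rate, subgroup-dependent
#' mutation/copy-number/clinical distributions and exponential survival with
#' per-subgroup hazard multipliers.
#'
#' Defaults mirror a 191-sample endometrioid endometrial carcinoma cohort
#' with subgroups of 77/62/52 samples and ~2,000 expressed lncRNAs.
#'
#' @param n_samples Number of tumor samples.
#' @param n_coding,n_lnc Number of coding genes / lncRNAs.
#' @param n_subgroups Number of planted subgroups.
#' @param subgroup_proportions Probability simplex over subgroups.
#' @param n_signature_per_subgroup Signature lncRNAs per subgroup.
#' @param log2_effect Signature shift in log2 units (>= 0).
#' @param nb_dispersion Negative-binomial dispersion alpha (> 0).
#' @param baseline_log2_mean_range Range of per-gene baseline log2 mean counts.
#' @param depth_factor_range Range of per-sample library-size multipliers.
#' @param overlap_fraction Fraction of lncRNAs with an exon overlapping a
#'   coding exon.
#' @param mutation_rates Genes x subgroups mutation probability matrix.
#' @param cna_rates List of `gain`/`loss` probability matrices.
#' @param grade_probs Subgroups x 3 matrix of tumor-grade probabilities.
#' @param stage_probs Subgroups x 4 matrix of FIGO-stage probabilities.
#' @param survival_hazards Per-subgroup hazard multipliers.
#' @param baseline_hazard Baseline exponential hazard (events per day).
#' @param censor_rate Expected fraction of censored samples.
#' @param seed Root seed; all stage-level randomness derives from it.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 191,
                              n_coding = 2000,
                              n_lnc = 2000,
                              n_subgroups = 3,
                              subgroup_proportions = c(77, 62, 52) / 191,
                              n_signature_per_subgroup = 50,
                              log2_effect = 2,
                              nb_dispersion = 0.1,
                              baseline_log2_mean_range = c(3, 9),
                              depth_factor_range = c(0.5, 2),
                              overlap_fraction = 0.1,
                              mutation_rates = default_mutation_rates(n_subgroups),
                              cna_rates = default_cna_rates(n_subgroups),
                              grade_probs = NULL,
                              stage_probs = NULL,
                              survival_hazards = c(1.5, 1.0, 0.7),
                              baseline_hazard = 1 / 2000,
                              censor_rate = 0.7,
                              seed = 1L) {
  if (is.null(grade_probs)) {
    grade_probs <- matrix(rep(c(0.45, 0.35, 0.20), n_subgroups),
                          nrow = n_subgroups, byrow = TRUE)
    grade_probs[1, ] <- c(0.15, 0.35, 0.50)  # subgroup 1: higher grade
  }
  if (is.null(stage_probs)) {
    stage_probs <- matrix(rep(c(0.75, 0.12, 0.09, 0.04), n_subgroups),
                          nrow = n_subgroups, byrow = TRUE)
    stage_probs[1, ] <- c(0.55, 0.17, 0.18, 0.10)
  }
  if (length(survival_hazards) != n_subgroups) {
    survival_hazards <- rep_len(survival_hazards, n_subgroups)
  }
  cfg <- structure(list(
    n_samples = as.integer(n_samples), n_coding = as.integer(n_coding),
    n_lnc = as.integer(n_lnc), n_subgroups = as.integer(n_subgroups),
    subgroup_proportions = subgroup_proportions,
    n_signature_per_subgroup = as.integer(n_signature_per_subgroup),
    log2_effect = log2_effect, nb_dispersion = nb_dispersion,
    baseline_log2_mean_range = baseline_log2_mean_range,
    depth_factor_range = depth_factor_range,
    overlap_fraction = overlap_fraction,
    mutation_rates = mutation_rates, cna_rates = cna_rates,
    grade_probs = grade_probs, stage_probs = stage_probs,
    survival_hazards = survival_hazards, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, seed = as.integer(seed)),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  err <- function(field, why) {
    stop("invalid simulation_config field '", field, "': ", why, call. = FALSE)
  }
  for (f in c("n_samples", "n_coding", "n_lnc", "n_subgroups",
              "n_signature_per_subgroup")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      err(f, "must be a count >= 1")
    }
  }
  p <- cfg$subgroup_proportions
  if (length(p) != cfg$n_subgroups || any(p <= 0) ||
      abs(sum(p) - 1) > 1e-8) {
    err("subgroup_proportions",
        "must be a positive vector of length n_subgroups summing to 1")
  }
  if (cfg$n_signature_per_subgroup * cfg$n_subgroups > cfg$n_lnc) {
    err("n_signature_per_subgroup",
        "n_signature_per_subgroup * n_subgroups must be <= n_lnc")
  }
  if (cfg$log2_effect < 0) err("log2_effect", "must be >= 0")
  if (cfg$nb_dispersion <= 0) err("nb_dispersion", "must be > 0")
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction > 1) {
    err("overlap_fraction", "must be in [0, 1]")
  }
  if (length(cfg$depth_factor_range) != 2L || any(cfg$depth_factor_range <= 0) ||
      diff(cfg$depth_factor_range) < 0) {
    err("depth_factor_range", "must be a positive non-decreasing interval")
  }
  if (diff(cfg$baseline_log2_mean_range) < 0) {
    err("baseline_log2_mean_range", "must be a non-decreasing interval")
  }
  if (any(cfg$mutation_rates < 0) || any(cfg$mutation_rates > 1) ||
      ncol(cfg$mutation_rates) != cfg$n_subgroups) {
    err("mutation_rates",
        "must be probabilities with one column per subgroup")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    err("censor_rate", "must be in [0, 1)")
  }
  if (any(cfg$survival_hazards <= 0)) {
    err("survival_hazards", "must be positive multipliers")
  }
  invisible(cfg)
}

# One root seed feeds an 8-slot seed table; each generation stage consumes its
# own slot so stages can be regenerated independently of one another.
stage_seed <- function(seed, stage) {
  stages <- c(annotation = 1L, counts = 2L, mutations = 3L, cna = 4L,
              clinical = 5L, spare1 = 6L, spare2 = 7L, spare3 = 8L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 8L)[stages[[stage]]]
}

#' Simulate a gene annotation on a virtual chromosome
#'
#' Genes (coding and lncRNA, randomly interleaved) are laid out left to right
#' on one virtual chromosome with intergenic gaps, each with 1-4 exons.
#' A fraction `overlap_fraction` of lncRNAs then has its first exon moved
#' into the first exon of the nearest coding gene, creating the mRNA/lncRNA
#' exon overlaps that union-mode masking must handle.
#'
#' @param cfg A [simulation_config()].
#' @return A [gene_annotation()] object with `cfg$n_coding + cfg$n_lnc` genes.
#' @export
simulate_annotation <- function(cfg) {
  validate_simulation_config(cfg)
  set.seed(stage_seed(cfg$seed, "annotation"))
  n_genes <- cfg$n_coding + cfg$n_lnc
  cls <- sample(rep(c("coding", "lncRNA"), c(cfg$n_coding, cfg$n_lnc)))
  ids <- character(n_genes)
  ids[cls == "coding"] <- sprintf("CG%05d", seq_len(cfg$n_coding))
  ids[cls == "lncRNA"] <- sprintf("LNC%05d", seq_len(cfg$n_lnc))

  exon_start <- vector("list", n_genes)
  exon_end <- vector("list", n_genes)
  pos <- 1L
  for (i in seq_len(n_genes)) {
    n_ex <- sample(1:4, 1L)
    lens <- sample(100:1000, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1L) sample(200:2000, n_ex - 1L, replace = TRUE) else integer(0)
    starts <- pos + cumsum(c(0L, lens[-n_ex] + gaps))
    exon_start[[i]] <- starts
    exon_end[[i]] <- starts + lens - 1L
    pos <- max(exon_end[[i]]) + sample(3000:10000, 1L)
  }

  n_overlap <- round(cfg$overlap_fraction * cfg$n_lnc)
  if (n_overlap > 0L) {
    lnc_idx <- which(cls == "lncRNA")
    coding_idx <- which(cls == "coding")
    if (length(coding_idx) == 0L) {
      stop("invalid simulation_config field 'overlap_fraction': ",
           "requires at least one coding gene")
    }
    chosen <- sort(sample(lnc_idx, n_overlap))
    for (i in chosen) {
      j <- coding_idx[which.min(abs(coding_idx - i))]
      cs <- exon_start[[j]][1L]
      ce <- exon_end[[j]][1L]
      len <- exon_end[[i]][1L] - exon_start[[i]][1L] + 1L
      # anchor inside the coding exon; extension to the right stays within
      # the coding gene's span or its own intergenic gap
      new_start <- cs + max(0L, (ce - cs) %/% 2L)
      exon_start[[i]][1L] <- new_start
      exon_end[[i]][1L] <- new_start + len - 1L
    }
  }

  genes <- data.frame(gene_id = ids,
                      gene_name = ids,
                      gene_class = cls,
                      chrom = "chrV",
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  exons <- GenomicRanges::GRanges(
    seqnames = "chrV",
    ranges = IRanges::IRanges(start = unlist(exon_start), end = unlist(exon_end)),
    strand = rep(ifelse(genes$strand == ".", "*", genes$strand),
                 lengths(exon_start)),
    gene_id = rep(ids, lengths(exon_start)))
  gene_annotation(genes, exons)
}

subgroup_sizes <- function(cfg) {
  sizes <- diff(round(cumsum(c(0, cfg$subgroup_proportions)) * cfg$n_samples))
  sizes[cfg$n_subgroups] <- cfg$n_samples - sum(sizes[-cfg$n_subgroups])
  as.integer(sizes)
}

#' Simulate a full cohort with planted subgroup structure
#'
#' Draws gene counts from NB(mean = depth_s * base_g * 2^(log2_effect *
#' I(gene is a signature of the sample's subgroup)), Var = mu + alpha mu^2),
#' Bernoulli mutations and copy-number calls with per-subgroup rates,
#' subgroup-conditional grade/stage, and exponential survival with
#' independent exponential censoring calibrated to `censor_rate`.
#'
#' @param cfg A [simulation_config()].
#' @return Object of class `cohort_bundle`: list with `annotation`, `counts`
#'   (genes x samples integer matrix), `clinical`, `mutations`, `cna`,
#'   `true_labels`, `signature_genes` (list per subgroup), `depth_factors`,
#'   and `config`.
#' @export
simulate_cohort <- function(cfg) {
  validate_simulation_config(cfg)
  annotation <- simulate_annotation(cfg)
  ids <- annotation$genes$gene_id
  lnc_ids <- ids[annotation$genes$gene_class == "lncRNA"]
  n_genes <- length(ids)
  sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))
  sizes <- subgroup_sizes(cfg)
  true_labels <- stats::setNames(rep(seq_len(cfg$n_subgroups), sizes), sample_ids)

  set.seed(stage_seed(cfg$seed, "counts"))
  base <- 2^stats::runif(n_genes, cfg$baseline_log2_mean_range[1],
                         cfg$baseline_log2_mean_range[2])
  names(base) <- ids
  depth <- stats::runif(cfg$n_samples, cfg$depth_factor_range[1],
                        cfg$depth_factor_range[2])
  names(depth) <- sample_ids
  sig <- sample(lnc_ids, cfg$n_signature_per_subgroup * cfg$n_subgroups)
  signature_genes <- split(sig, rep(seq_len(cfg$n_subgroups),
                                    each = cfg$n_signature_per_subgroup))
  names(signature_genes) <- sprintf("subgroup%d", seq_len(cfg$n_subgroups))

  effect <- matrix(0, nrow = n_genes, ncol = cfg$n_subgroups,
                   dimnames = list(ids, NULL))
  for (g in seq_len(cfg$n_subgroups)) {
    effect[signature_genes[[g]], g] <- cfg$log2_effect
  }
  mu <- (base * 2^effect[, true_labels]) *
    rep(depth, each = n_genes)
  counts <- matrix(stats::rnbinom(n_genes * cfg$n_samples, mu = mu,
                                  size = 1 / cfg$nb_dispersion),
                   nrow = n_genes, dimnames = list(ids, sample_ids))

  set.seed(stage_seed(cfg$seed, "mutations"))
  mut_rates <- cfg$mutation_rates
  mutations <- matrix(0L, nrow = cfg$n_samples, ncol = nrow(mut_rates),
                      dimnames = list(sample_ids, rownames(mut_rates)))
  for (g in seq_len(nrow(mut_rates))) {
    mutations[, g] <- stats::rbinom(cfg$n_samples, 1L,
                                    mut_rates[g, true_labels])
  }

  set.seed(stage_seed(cfg$seed, "cna"))
  gain <- cfg$cna_rates$gain
  loss <- cfg$cna_rates$loss
  cna <- matrix(0L, nrow = cfg$n_samples, ncol = nrow(gain),
                dimnames = list(sample_ids, rownames(gain)))
  for (g in seq_len(nrow(gain))) {
    pg <- gain[g, true_labels]
    pl <- loss[g, true_labels]
    u <- stats::runif(cfg$n_samples)
    amp <- sample(c(1L, 2L), cfg$n_samples, replace = TRUE, prob = c(0.7, 0.3))
    del <- sample(c(-1L, -2L), cfg$n_samples, replace = TRUE, prob = c(0.7, 0.3))
    cna[, g] <- ifelse(u < pg, amp, ifelse(u < pg + pl, del, 0L))
  }

  set.seed(stage_seed(cfg$seed, "clinical"))
  grade <- integer(cfg$n_samples)
  stage <- character(cfg$n_samples)
  stage_levels <- c("I", "II", "III", "IV")
  for (g in seq_len(cfg$n_subgroups)) {
    in_g <- which(true_labels == g)
    grade[in_g] <- sample(1:3, length(in_g), replace = TRUE,
                          prob = cfg$grade_probs[g, ])
    stage[in_g] <- sample(stage_levels, length(in_g), replace = TRUE,
                          prob = cfg$stage_probs[g, ])
  }
  haz <- cfg$baseline_hazard * cfg$survival_hazards[true_labels]
  event_time <- stats::rexp(cfg$n_samples, rate = haz)
  # exponential censoring with P(censored) ~= censor_rate at the mean hazard
  cens_rate <- cfg$baseline_hazard * mean(cfg$survival_hazards) *
    cfg$censor_rate / (1 - cfg$censor_rate)
  cens_time <- if (cens_rate > 0) stats::rexp(cfg$n_samples, rate = cens_rate)
               else rep(Inf, cfg$n_samples)
  clinical <- data.frame(
    sample_id = sample_ids,
    grade = grade,
    stage = factor(stage, levels = stage_levels),
    time = ceiling(pmin(event_time, cens_time)),
    event = as.integer(event_time <= cens_time),
    row.names = sample_ids, stringsAsFactors = FALSE)

  structure(list(annotation = annotation, counts = counts,
                 clinical = clinical, mutations = mutations, cna = cna,
                 true_labels = true_labels,
                 signature_genes = signature_genes,
                 depth_factors = depth, config = cfg),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", ncol(x$counts), "samples x", nrow(x$counts),
      "genes;", x$config$n_subgroups, "planted subgroups\n")
  invisible(x)
}

#' Write a cohort bundle to plain-text files
#'
#' Writes `annotation.gtf`, `counts.tsv`, `clinical.tsv`, `mutations.tsv`,
#' `cna.tsv` and `truth.tsv` into `outdir`.
#'
#' @param bundle A [simulate_cohort()] result.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_annotation_gtf(bundle$annotation, file.path(outdir, "annotation.gtf"))
  write_matrix_tsv(bundle$counts, file.path(outdir, "counts.tsv"), "gene_id")
  utils::write.table(bundle$clinical, file.path(outdir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(bundle$mutations, file.path(outdir, "mutations.tsv"), "sample_id")
  write_matrix_tsv(bundle$cna, file.path(outdir, "cna.tsv"), "sample_id")
  utils::write.table(
    data.frame(sample_id = names(bundle$true_labels),
               subgroup = unname(bundle$true_labels)),
    file.path(outdir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a gene x sample count matrix from TSV
#'
#' First column is the gene identifier; remaining columns are integer counts
#' per sample.
#'
#' @param path TSV path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyNA(m) || any(m < 0)) {
    stop("count matrix must contain non-negative values without NAs: ", path)
  }
  storage.mode(m) <- "integer"
  m
}

#' Read a sample x gene indicator/call matrix from TSV
#'
#' @param path TSV path whose first column is the sample identifier.
#' @return Numeric matrix with sample rownames.
#' @export
read_sample_gene_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
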