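#' Pipeline configuration
#'
#' Houses every tunable threshold of the pipeline with the analysis
#' defaults: FPKM >= 1 in >= 10% of samples for the expression filter,
#' FDR 0.05 and fold change 2 for signatures, r > 0.33 for neighbor-gene
#' correlation, and the consensus-clustering settings of
#' [consensus_config()].
#'
#' @param annotation,counts,clinical,mutations,cna Input file paths (GTF /
#'   TSV); any may be `NULL` when [run_all()] is given an in-memory cohort.
#' @param fpkm_threshold,min_fraction Expression-filter settings.
#' @param de_fdr,fc_threshold Signature thresholds.
#' @param neighbor_r_threshold Neighbor-correlation threshold.
#' @param cluster_input `"vst"` (default) or `"log2fpkm"` as consensus input.
#' @param consensus A [consensus_config()].
#' @param stranded Stranded masking for quantification.
#' @param seed Pipeline seed (propagated to the consensus runs and seeded
#'   Monte-Carlo tests).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation = NULL, counts = NULL, clinical = NULL,
                            mutations = NULL, cna = NULL,
                            fpkm_threshold = 1, min_fraction = 0.10,
                            de_fdr = 0.05, fc_threshold = 2,
                            neighbor_r_threshold = 0.33,
                            cluster_input = c("vst", "log2fpkm"),
                            consensus = consensus_config(),
                            stranded = FALSE, seed = 1L) {
  cluster_input <- match.arg(cluster_input)
  if (fpkm_threshold <= 0 || min_fraction <= 0 || de_fdr <= 0 ||
      fc_threshold <= 0 || neighbor_r_threshold <= 0) {
    stop("pipeline thresholds must be positive")
  }
  consensus$seed <- as.integer(seed)
  structure(list(annotation = annotation, counts = counts,
                 clinical = clinical, mutations = mutations, cna = cna,
                 fpkm_threshold = fpkm_threshold, min_fraction = min_fraction,
                 de_fdr = de_fdr, fc_threshold = fc_threshold,
                 neighbor_r_threshold = neighbor_r_threshold,
                 cluster_input = cluster_input, consensus = consensus,
                 stranded = stranded, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep the defaults of
#' [pipeline_config()]. The `consensus` block maps onto
#' [consensus_config()].
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cons_args <- raw$consensus
  raw$consensus <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg_args <- raw
  if (!is.null(cons_args)) {
    bad <- setdiff(names(cons_args), names(formals(consensus_config)))
    if (length(bad) > 0L) {
      stop("unknown consensus configuration key(s): ",
           paste(bad, collapse = ", "))
    }
    cfg_args$consensus <- do.call(consensus_config, cons_args)
  }
  do.call(pipeline_config, cfg_args)
}

load_cohort_inputs <- function(config) {
  need <- c("annotation", "counts")
  missing <- need[vapply(need, function(f) is.null(config[[f]]), logical(1))]
  if (length(missing) > 0L) {
    stop("configuration error: missing input path(s): ",
         paste(missing, collapse = ", "))
  }
  for (f in c("annotation", "counts", "clinical", "mutations", "cna")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("configuration error: input file not found for '", f, "': ",
           config[[f]])
    }
  }
  bundle <- list(annotation = read_annotation_gtf(config$annotation),
                 counts = read_count_matrix(config$counts),
                 clinical = NULL, mutations = NULL, cna = NULL,
                 true_labels = NULL)
  if (!is.null(config$clinical)) {
    cl <- utils::read.delim(config$clinical, stringsAsFactors = FALSE)
    rownames(cl) <- cl$sample_id
    bundle$clinical <- cl
  }
  if (!is.null(config$mutations)) {
    bundle$mutations <- read_sample_gene_matrix(config$mutations)
  }
  if (!is.null(config$cna)) {
    bundle$cna <- read_sample_gene_matrix(config$cna)
  }
  class(bundle) <- "cohort_bundle"
  bundle
}

fmt_num <- function(x) {
  # 6 significant digits for byte-identical reruns
  ifelse(is.na(x), "NA", formatC(signif(as.numeric(x), 6), format = "g",
                                 digits = 6))
}

write_stamped_tsv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full subgroup-discovery pipeline
#'
#' Executes quantification (masked FPKM), expression filtering,
#' normalization and variance stabilization, consensus clustering of the
#' filtered lncRNAs, per-subgroup signatures, and (when the inputs are
#' available) mutation/CNA scans, clinical contingency tests, survival
#' analysis and lncRNA-neighbor correlations. All outputs are TSV/JSON
#' files stamped with the configuration hash and seed; rerunning with an
#' identical configuration reproduces byte-identical files.
#'
#' @param config A [pipeline_config()]. Ignored input paths when `cohort`
#'   is supplied directly.
#' @param outdir Output directory.
#' @param cohort Optional in-memory `cohort_bundle` (e.g. from
#'   [simulate_cohort()]); otherwise inputs are read from the config paths.
#' @return Invisibly, a list with the in-memory stage results (`fpkm`,
#'   `expressed`, `size_factors`, `trend`, `clustering`, `signatures`,
#'   `associations`, `summary`).
#' @export
run_all <- function(config, outdir, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config)
  stamp <- sprintf("lncSubtypes config_hash=%s seed=%d", cfg_hash, config$seed)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      report <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(report, file.path(outdir, "error.json"),
                           auto_unbox = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  if (is.null(cohort)) cohort <- stage("load", load_cohort_inputs(config))

  fpkm <- stage("quantify", compute_fpkm(cohort$counts, cohort$annotation,
                                         stranded = config$stranded))
  expressed <- stage("filter", low_expression_filter(
    fpkm, threshold = config$fpkm_threshold,
    min_fraction = config$min_fraction))
  lnc_ids <- cohort$annotation$genes$gene_id[
    cohort$annotation$genes$gene_class == "lncRNA"]
  expressed_lnc <- intersect(expressed, lnc_ids)

  norm <- stage("normalize", {
    keep <- intersect(expressed, rownames(cohort$counts))
    counts_f <- cohort$counts[keep, , drop = FALSE]
    sf <- estimate_size_factors(counts_f)
    trend <- fit_dispersion_trend(counts_f, sf)
    vst <- variance_stabilizing_transform(counts_f, sf, trend)
    list(counts = counts_f, sf = sf, trend = trend, vst = vst)
  })

  clustering <- stage("cluster", {
    X <- if (config$cluster_input == "vst") {
      norm$vst[intersect(expressed_lnc, rownames(norm$vst)), , drop = FALSE]
    } else {
      log2(fpkm[intersect(expressed_lnc, rownames(fpkm)), , drop = FALSE] + 0.5)
    }
    consensus_cluster(X, config$consensus)
  })
  labels <- clustering$labels

  signatures <- stage("signatures", subgroup_signatures(
    norm$counts, labels, norm$sf, norm$trend,
    fc_threshold = config$fc_threshold, alpha = config$de_fdr))

  associations <- stage("associate", {
    out <- list()
    if (!is.null(cohort$mutations)) {
      out$mutations <- per_gene_alteration_scan(
        labels[rownames(cohort$mutations)], cohort$mutations,
        seed = config$seed)
    }
    if (!is.null(cohort$cna)) {
      gains <- (cohort$cna > 0) * 1L
      losses <- (cohort$cna < 0) * 1L
      out$cna_gain <- per_gene_alteration_scan(
        labels[rownames(cohort$cna)], gains, seed = config$seed)
      out$cna_loss <- per_gene_alteration_scan(
        labels[rownames(cohort$cna)], losses, seed = config$seed)
    }
    if (!is.null(cohort$clinical)) {
      cl <- cohort$clinical[names(labels), ]
      out$grade <- subgroup_contingency_test(labels, cl$grade,
                                             seed = config$seed)
      out$stage <- subgroup_contingency_test(labels, cl$stage,
                                             seed = config$seed)
      if (all(c("time", "event") %in% names(cl))) {
        out$survival <- km_logrank(cl$time, cl$event, labels)
      }
    }
    pairs <- nearest_coding_neighbors(cohort$annotation)
    pairs <- pairs[pairs$lnc_id %in% expressed_lnc &
                     pairs$neighbor_id %in% rownames(fpkm), , drop = FALSE]
    if (nrow(pairs) > 0L) {
      out$neighbors <- neighbor_correlations(
        fpkm, pairs, pos_threshold = config$neighbor_r_threshold)
    }
    out
  })

  stage("write", {
    write_stamped_tsv(
      data.frame(sample_id = names(norm$sf), size_factor = norm$sf),
      file.path(outdir, "size_factors.tsv"), stamp)
    write_stamped_tsv(data.frame(gene_id = expressed),
                      file.path(outdir, "expressed_genes.tsv"), stamp)
    write_stamped_tsv(
      data.frame(gene_id = attr(fpkm, "unquantifiable")),
      file.path(outdir, "unquantifiable_genes.tsv"), stamp)
    write_stamped_tsv(
      data.frame(sample_id = names(labels), subgroup = unname(labels)),
      file.path(outdir, "cluster_labels.tsv"), stamp)
    write_stamped_tsv(
      data.frame(k = as.integer(names(clustering$bic_by_k)),
                 bic = unname(clustering$bic_by_k)),
      file.path(outdir, "bic.tsv"), stamp)
    for (L in names(signatures)) {
      write_stamped_tsv(signatures[[L]]$table,
                        file.path(outdir, sprintf("signatures_%s.tsv", L)),
                        stamp)
    }
    if (!is.null(associations$mutations)) {
      write_stamped_tsv(associations$mutations,
                        file.path(outdir, "mutation_scan.tsv"), stamp)
    }
    if (!is.null(associations$cna_gain)) {
      write_stamped_tsv(associations$cna_gain,
                        file.path(outdir, "cna_gain_scan.tsv"), stamp)
      write_stamped_tsv(associations$cna_loss,
                        file.path(outdir, "cna_loss_scan.tsv"), stamp)
    }
    if (!is.null(associations$neighbors)) {
      write_stamped_tsv(associations$neighbors,
                        file.path(outdir, "neighbor_correlations.tsv"), stamp)
    }
    TRUE
  })

  summary <- list(
    package_version = as.character(utils::packageVersion("lncSubtypes")),
    config_hash = cfg_hash, seed = config$seed,
    n_samples = ncol(cohort$counts), n_genes = nrow(cohort$counts),
    n_expressed = length(expressed), n_expressed_lnc = length(expressed_lnc),
    chosen_k = clustering$chosen_k,
    bic_by_k = as.list(clustering$bic_by_k),
    subgroup_sizes = as.list(table(labels)),
    clinical_tests = if (!is.null(associations$grade)) list(
      grade_p = associations$grade$p, stage_p = associations$stage$p,
      logrank_p = if (!is.null(associations$survival))
        associations$survival$p else NULL) else NULL,
    ari_vs_truth = if (!is.null(cohort$true_labels))
      adjusted_rand_index(labels, cohort$true_labels[names(labels)]) else NULL)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  # wall times vary between runs, so they live outside the deterministic set
  jsonlite::write_json(list(config_hash = cfg_hash, stage_seconds = timings),
                       file.path(outdir, "run_log.json"), auto_unbox = TRUE)

  invisible(list(fpkm = fpkm, expressed = expressed,
                 expressed_lnc = expressed_lnc,
                 size_factors = norm$sf, trend = norm$trend, vst = norm$vst,
                 clustering = clustering, signatures = signatures,
                 associations = associations, summary = summary))
}
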