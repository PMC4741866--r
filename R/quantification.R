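#' Tag and query the scale of an expression matrix
#'
#' Expression matrices are plain numeric matrices carrying a `scale_tag`
#' attribute (`"fpkm"`, `"log2fpkm"`, `"vst"` or `"normalized"`) so that
#' downstream stages can enforce their input contracts.
#'
#' @param x Numeric matrix.
#' @param scale One of `"fpkm"`, `"log2fpkm"`, `"vst"`, `"normalized"`.
#' @return `x` with the `scale_tag` attribute set.
#' @export
expression_matrix <- function(x, scale) {
  scale <- match.arg(scale, c("fpkm", "log2fpkm", "vst", "normalized"))
  attr(x, "scale_tag") <- scale
  x
}

#' @rdname expression_matrix
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale_tag")
  if (is.null(s)) NA_character_ else s
}

#' FPKM with masked union-exon gene lengths
#'
#' fpkm\[g, s\] = counts\[g, s\] * 1e9 / (masked_length\[g\] *
#' total_fragments\[s\]), where the gene length is the union-exon length
#' after removing bases shared between coding and lncRNA annotations
#' ([masked_lengths()]) and the library size is the per-sample column sum of
#' the count matrix (or an externally supplied vector). Genes whose masked
#' length is zero cannot be quantified and are dropped with a warning.
#'
#' @param counts Gene x sample integer count matrix.
#' @param annotation A [gene_annotation()] covering the count-matrix genes.
#' @param stranded Passed to [masked_lengths()].
#' @param lib_size Optional named per-sample library sizes; defaults to
#'   column sums of `counts`.
#' @return FPKM matrix (`scale_tag = "fpkm"`) over the quantifiable genes,
#'   with dropped gene ids in attribute `unquantifiable`.
#' @export
compute_fpkm <- function(counts, annotation, stranded = FALSE, lib_size = NULL) {
  stopifnot(is.matrix(counts), inherits(annotation, "gene_annotation"))
  absent <- setdiff(rownames(counts), annotation$genes$gene_id)
  if (length(absent) > 0L) {
    stop("count matrix genes missing from annotation: ",
         paste(utils::head(absent), collapse = ", "))
  }
  if (is.null(lib_size)) {
    lib_size <- colSums(counts)
  } else {
    lib_size <- lib_size[colnames(counts)]
  }
  zero_lib <- colnames(counts)[!is.finite(lib_size) | lib_size <= 0]
  if (length(zero_lib) > 0L) {
    stop("sample(s) with zero total fragments: ",
         paste(zero_lib, collapse = ", "))
  }
  ml <- masked_lengths(annotation, stranded = stranded)
  len <- ml[rownames(counts), "masked_length"]
  drop <- rownames(counts)[len <= 0]
  if (length(drop) > 0L) {
    warning(length(drop), " gene(s) with masked length 0 dropped from FPKM: ",
            paste(utils::head(drop), collapse = ", "))
  }
  keep <- len > 0
  fpkm <- counts[keep, , drop = FALSE] * 1e9 /
    outer(len[keep], lib_size)
  dimnames(fpkm) <- list(rownames(counts)[keep], colnames(counts))
  out <- expression_matrix(fpkm, "fpkm")
  attr(out, "unquantifiable") <- drop
  out
}

#' Low-expression filter on FPKM
#'
#' Keeps genes with FPKM at or above `threshold` in at least
#' `ceiling(min_fraction * n_samples)` samples (defaults: FPKM >= 1 in at
#' least 10% of samples).
#'
#' @param expr FPKM matrix from [compute_fpkm()].
#' @param threshold FPKM threshold (inclusive).
#' @param min_fraction Minimum fraction of samples at or above `threshold`.
#' @return Character vector of retained gene ids.
#' @export
low_expression_filter <- function(expr, threshold = 1, min_fraction = 0.10) {
  if (!identical(expr_scale(expr), "fpkm")) {
    stop("low_expression_filter requires an FPKM-scale matrix (scale_tag 'fpkm')")
  }
  need <- ceiling(min_fraction * ncol(expr))
  rownames(expr)[rowSums(expr >= threshold) >= need]
}
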