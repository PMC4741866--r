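#' Construct a gene annotation object
#'
#' Bundles a per-gene table with the exon intervals of every gene. Exons are
#' stored as a [GenomicRanges::GRanges] (1-based, closed intervals, the
#' Bioconductor convention) carrying a `gene_id` metadata column; the gene
#' table holds one row per gene with its class (`coding` or `lncRNA`), strand
#' and gene-body span derived from the exons.
#'
#' @param genes data.frame with columns `gene_id`, `gene_name`, `gene_class`
#'   (values `"coding"` or `"lncRNA"`), `chrom`, `strand` (`"+"`, `"-"` or
#'   `"."`).
#' @param exons [GenomicRanges::GRanges] of exon intervals with a `gene_id`
#'   metadata column; every `gene_id` must appear in `genes` and every gene
#'   must have at least one exon. Exons of one gene may overlap each other.
#' @return An object of class `gene_annotation`: a list with elements `genes`
#'   (the gene table, gene-body `start`/`end` recomputed from the exons) and
#'   `exons`.
#' @export
gene_annotation <- function(genes, exons) {
  required <- c("gene_id", "gene_name", "gene_class", "chrom", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in gene table")
  }
  bad_class <- setdiff(unique(genes$gene_class), c("coding", "lncRNA"))
  if (length(bad_class) > 0L) {
    stop("gene_class must be 'coding' or 'lncRNA'; found: ",
         paste(bad_class, collapse = ", "))
  }
  if (!methods::is(exons, "GRanges") || is.null(exons$gene_id)) {
    stop("exons must be a GRanges with a gene_id metadata column")
  }
  orphan <- setdiff(unique(exons$gene_id), genes$gene_id)
  if (length(orphan) > 0L) {
    stop("exons reference unknown gene_id: ", paste(utils::head(orphan), collapse = ", "))
  }
  no_exon <- setdiff(genes$gene_id, unique(exons$gene_id))
  if (length(no_exon) > 0L) {
    stop("gene(s) without exons: ", paste(utils::head(no_exon), collapse = ", "))
  }
  span_start <- tapply(GenomicRanges::start(exons), exons$gene_id, min)
  span_end <- tapply(GenomicRanges::end(exons), exons$gene_id, max)
  genes$start <- as.integer(span_start[genes$gene_id])
  genes$end <- as.integer(span_end[genes$gene_id])
  rownames(genes) <- genes$gene_id
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  tab <- table(x$genes$gene_class)
  cat("gene_annotation:", nrow(x$genes), "genes (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "),", length(x$exons), "exons\n")
  invisible(x)
}

#' Merge numeric intervals into a disjoint sorted union
#'
#' Operates on half-open `[start, end)` intervals; abutting intervals are
#' merged because their union as point sets is contiguous.
#'
#' @param intervals A two-column matrix/data.frame of `start`, `end`, or a
#'   list of length-2 numeric vectors. Must satisfy `start < end` row-wise.
#' @return A two-column integer matrix (`start`, `end`) of disjoint, sorted
#'   intervals covering exactly the union of the inputs.
#' @export
merge_intervals <- function(intervals) {
  if (is.list(intervals) && !is.data.frame(intervals)) {
    intervals <- do.call(rbind, lapply(intervals, function(x) x[1:2]))
  }
  if (is.null(intervals) || length(intervals) == 0L || nrow(intervals) == 0L) {
    out <- matrix(integer(0), ncol = 2)
    colnames(out) <- c("start", "end")
    return(out)
  }
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2L || !is.numeric(intervals) || anyNA(intervals)) {
    stop("intervals must be numeric start/end pairs without missing values")
  }
  if (any(intervals[, 1L] >= intervals[, 2L])) {
    stop("malformed interval: start must be < end")
  }
  # half-open [s, e) -> 1-based closed [s + 1, e]
  ir <- IRanges::reduce(IRanges::IRanges(start = intervals[, 1L] + 1L,
                                         end = intervals[, 2L]))
  out <- cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  out
}

#' Union-exon gene lengths with cross-class overlap masking
#'
#' For every gene, computes the merged (union-exon) length and the masked
#' length: the merged exonic bases minus any base shared with a gene of the
#' OTHER class (coding vs lncRNA) on the same chromosome. Genes of the same
#' class never mask each other. This mirrors union-mode counting of
#' non-strand-specific libraries, where fragments in mRNA/lncRNA shared
#' regions are discarded, so the corresponding bases must also leave the
#' FPKM length denominator.
#'
#' @param annotation A [gene_annotation()] object.
#' @param stranded If `FALSE` (default, matching non-strand-specific
#'   protocols) masking ignores strand; if `TRUE` only same-strand overlaps
#'   mask.
#' @return data.frame with columns `gene_id`, `gene_class`, `merged_length`,
#'   `masked_length`, and `quantifiable` (`FALSE` when masking removed every
#'   exonic base).
#' @export
masked_lengths <- function(annotation, stranded = FALSE) {
  stopifnot(inherits(annotation, "gene_annotation"))
  ex <- annotation$exons
  cls <- annotation$genes[ex$gene_id, "gene_class"]
  per_gene <- GenomicRanges::reduce(S4Vectors::split(ex, ex$gene_id),
                                    ignore.strand = !stranded)
  merged_len <- sum(IRanges::width(per_gene))

  flat <- unlist(per_gene, use.names = FALSE)
  flat$gene_id <- rep(names(per_gene), S4Vectors::elementNROWS(per_gene))
  flat_cls <- annotation$genes[flat$gene_id, "gene_class"]

  overlap_bp <- stats::setNames(numeric(length(per_gene)), names(per_gene))
  for (this in c("coding", "lncRNA")) {
    other <- setdiff(c("coding", "lncRNA"), this)
    mask <- GenomicRanges::reduce(ex[cls == other], ignore.strand = !stranded)
    mine <- flat[flat_cls == this]
    if (length(mine) == 0L || length(mask) == 0L) next
    hits <- GenomicRanges::findOverlaps(mine, mask, ignore.strand = !stranded)
    if (length(hits) == 0L) next
    ov <- IRanges::width(GenomicRanges::pintersect(
      mine[S4Vectors::queryHits(hits)], mask[S4Vectors::subjectHits(hits)],
      ignore.strand = !stranded))
    bp <- tapply(ov, mine$gene_id[S4Vectors::queryHits(hits)], sum)
    overlap_bp[names(bp)] <- overlap_bp[names(bp)] + bp
  }
  ids <- annotation$genes$gene_id
  merged <- as.numeric(merged_len[ids])
  masked <- merged - as.numeric(overlap_bp[ids])
  data.frame(gene_id = ids,
             gene_class = annotation$genes$gene_class,
             merged_length = merged,
             masked_length = masked,
             quantifiable = masked > 0,
             row.names = ids)
}

#' Masked exonic length of a single gene
#'
#' @param gene_id Gene identifier present in `annotation`.
#' @inheritParams masked_lengths
#' @return Masked length in base pairs (see [masked_lengths()]).
#' @export
masked_exonic_length <- function(gene_id, annotation, stranded = FALSE) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (!gene_id %in% annotation$genes$gene_id) {
    stop("gene not found in annotation: ", gene_id)
  }
  ml <- masked_lengths(annotation, stranded = stranded)
  ml[gene_id, "masked_length"]
}

gene_type_to_class <- function(gene_type) {
  ifelse(gene_type %in% c("protein_coding", "coding"), "coding", "lncRNA")
}

#' Read a gene annotation from GTF
#'
#' Imports exon records (1-based inclusive coordinates per the GTF standard)
#' and classifies genes as coding when `gene_type` (or `gene_biotype`) is
#' `protein_coding`, and as lncRNA otherwise.
#'
#' @param path Path to a GTF file with `gene_id` and `gene_type` attributes.
#' @return A [gene_annotation()] object.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!is.null(gr$type)) gr <- gr[gr$type == "exon"]
  if (is.null(gr$gene_id)) stop("GTF lacks gene_id attribute: ", path)
  gtype <- gr$gene_type
  if (is.null(gtype)) gtype <- gr$gene_biotype
  if (is.null(gtype)) stop("GTF lacks gene_type/gene_biotype attribute: ", path)
  gname <- if (is.null(gr$gene_name)) gr$gene_id else gr$gene_name
  first <- !duplicated(gr$gene_id)
  genes <- data.frame(gene_id = gr$gene_id[first],
                      gene_name = gname[first],
                      gene_class = gene_type_to_class(gtype[first]),
                      chrom = as.character(GenomicRanges::seqnames(gr))[first],
                      strand = as.character(GenomicRanges::strand(gr))[first],
                      stringsAsFactors = FALSE)
  genes$strand[genes$strand == "*"] <- "."
  exons <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    gene_id = gr$gene_id)
  gene_annotation(genes, exons)
}

#' Write a gene annotation to GTF
#'
#' Emits one `exon` record per exon with `gene_id`, `gene_name` and
#' `gene_type` attributes (1-based inclusive coordinates).
#'
#' @param annotation A [gene_annotation()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  ex <- annotation$exons
  g <- annotation$genes[ex$gene_id, ]
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(ex),
    ranges = IRanges::ranges(ex),
    strand = ifelse(g$strand == ".", "*", g$strand))
  out$source <- "lncSubtypes"
  out$type <- "exon"
  out$gene_id <- g$gene_id
  out$gene_name <- g$gene_name
  out$gene_type <- ifelse(g$gene_class == "coding", "protein_coding", "lincRNA")
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}
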