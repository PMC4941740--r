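FEATURE_VOCAB <- c("CDS", "5UTR", "3UTR", "exon", "gene")

# precedence used when a position is covered by several feature classes
FEATURE_PRECEDENCE <- c("CDS", "5UTR", "3UTR", "exon", "gene")

#' Load gene/feature intervals from BED or GFF3
#'
#' Reads gene annotation into a uniform interval table used for point
#' classification of SNPs. BED input is 0-based half-open with the feature
#' class (CDS, 5UTR, 3UTR, exon, gene) in column 7 and the gene id in column
#' 4; GFF3 input is 1-based inclusive (parsed with rtracklayer) with types
#' CDS / five_prime_UTR / three_prime_UTR / exon / gene and the gene id taken
#' from the `gene_id` attribute, falling back to `ID`. Both are converted to
#' the same internal 1-based inclusive representation, so equivalent BED and
#' GFF3 lines produce identical intervals. Overlapping intervals are
#' permitted. Intervals whose feature is outside the vocabulary are skipped
#' with a warning.
#'
#' @param path annotation file path.
#' @param format "auto" (default, by file extension), "bed" or "gff3".
#' @param normalize if TRUE (default), chromosome names lose a "chr" prefix.
#' @return object of class `gene_annotation`: list with `intervals`, a
#'   data.table (gene_id, chrom, start, end, feature; 1-based inclusive), and
#'   `gr`, the same as a GRanges with mcols gene_id/feature.
#' @export
load_annotation <- function(path, format = c("auto", "bed", "gff3"),
                            normalize = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("gff", "gff3")) "gff3"
              else if (ext == "bed") "bed"
              else stopf("cannot infer annotation format from extension '%s'", ext)
  }
  iv <- if (format == "bed") read_bed_features(path) else read_gff3_features(path)
  if (normalize && nrow(iv)) iv[, "chrom" := normalize_chrom(iv$chrom)]
  gene_annotation(iv)
}

gene_annotation <- function(intervals) {
  intervals <- data.table::as.data.table(intervals)
  if (nrow(intervals) == 0L) {
    intervals <- data.table::data.table(gene_id = character(), chrom = character(),
                                        start = integer(), end = integer(),
                                        feature = character())
  }
  if (nrow(intervals) && any(intervals$start > intervals$end))
    stopf("annotation: interval with start > end")
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end),
    gene_id = intervals$gene_id, feature = intervals$feature
  )
  structure(list(intervals = intervals, gr = gr), class = "gene_annotation")
}

# BED dialect: chrom start end name [score strand feature]; 0-based half-open
read_bed_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)
  out <- vector("list", sum(keep))
  n_skipped <- 0L; j <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 1L) f <- strsplit(lines[i], "[ \t]+")[[1L]]
    if (length(f) < 4L)
      stopf("malformed BED line %d in %s: need >= 4 fields", i, path)
    s <- suppressWarnings(as.integer(f[2L])); e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e) || s < 0L || e <= s)
      stopf("malformed BED line %d in %s: bad interval [%s, %s)", i, path, f[2L], f[3L])
    feat <- if (length(f) >= 7L && nzchar(f[7L])) f[7L] else "gene"
    if (!feat %in% FEATURE_VOCAB) { n_skipped <- n_skipped + 1L; next }
    j <- j + 1L
    out[[j]] <- data.table::data.table(gene_id = f[4L], chrom = f[1L],
                                       start = s + 1L, end = e, feature = feat)
  }
  if (n_skipped > 0L)
    warnf("%d BED interval(s) with unknown feature class skipped", n_skipped)
  if (j == 0L) return(data.table::data.table())
  data.table::rbindlist(out[seq_len(j)])
}

read_gff3_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  map <- c(CDS = "CDS", five_prime_UTR = "5UTR", three_prime_UTR = "3UTR",
           exon = "exon", gene = "gene")
  known <- type %in% names(map)
  if (any(!known))
    warnf("%d GFF3 record(s) with unknown feature type skipped", sum(!known))
  gr <- gr[known]
  if (length(gr) == 0L) return(data.table::data.table())
  ids <- gr$gene_id %||% rep(NA_character_, length(gr))
  if (anyNA(ids) && !is.null(gr$ID)) ids[is.na(ids)] <- gr$ID[is.na(ids)]
  if (anyNA(ids)) stopf("GFF3 record(s) lacking both gene_id and ID attributes")
  data.table::data.table(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    feature = unname(map[type[known]])
  )
}

#' Annotate variants with region class and gene ids
#'
#' Assigns each variant position exactly one region class by feature
#' precedence CDS > 5'UTR > 3'UTR > exon > gene body > intergenic; a position
#' inside a gene body but no exonic feature is classed "intronic". Gene ids
#' are all genes whose intervals of the winning class contain the position;
#' intergenic positions get none.
#'
#' @param keys character vector of variant keys, a [callset], or a data.frame
#'   with chrom/pos columns.
#' @param annotation a `gene_annotation` from [load_annotation()].
#' @return data.table with columns `key`, `chrom`, `pos`, `region` (one of
#'   CDS, 5UTR, 3UTR, exon, intronic, intergenic) and `genes` (list column of
#'   character vectors).
#' @export
annotate_variants <- function(keys, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  tab <- if (inherits(keys, "callset")) keys$records
         else if (is.character(keys)) parse_variant_keys(keys)
         else data.table::as.data.table(keys)
  key <- if (is.character(keys)) keys else variant_keys(tab)
  n <- nrow(tab)
  out <- data.table::data.table(chrom = tab$chrom, pos = tab$pos,
                                region = rep("intergenic", n),
                                genes = rep(list(character()), n))
  data.table::set(out, j = "key", value = key)
  data.table::setcolorder(out, c("key", "chrom", "pos", "region", "genes"))
  if (n == 0L || length(annotation$gr) == 0L) return(out)

  qgr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$pos, tab$pos))
  unassigned <- rep(TRUE, n)
  for (feat in FEATURE_PRECEDENCE) {
    if (!any(unassigned)) break
    sub <- annotation$gr[annotation$gr$feature == feat]
    if (length(sub) == 0L) next
    hits <- GenomicRanges::findOverlaps(qgr, sub, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    take <- unassigned[qh]
    if (!any(take)) next
    qh <- qh[take]
    genes_hit <- split(sub$gene_id[S4Vectors::subjectHits(hits)[take]], qh)
    idx <- as.integer(names(genes_hit))
    region_label <- if (feat == "gene") "intronic" else feat
    data.table::set(out, i = idx, j = "region", value = region_label)
    data.table::set(out, i = idx, j = "genes",
                    value = lapply(genes_hit, function(g) sort(unique(g))))
    unassigned[idx] <- FALSE
  }
  out
}

#' Annotate a single variant
#'
#' @param key a single variant key "chrom:pos:ref:alt".
#' @param annotation a `gene_annotation`.
#' @return list with `region` and `genes`.
#' @export
annotate_variant <- function(key, annotation) {
  stopifnot(length(key) == 1L)
  a <- annotate_variants(key, annotation)
  list(region = a$region[[1L]], genes = a$genes[[1L]])
}

#' Candidate genes hit by a variant set
#'
#' Maps each variant to its region class and collects the union of gene ids
#' over all non-intergenic assignments, with the number of supporting SNPs
#' per gene.
#'
#' @inheritParams annotate_variants
#' @return data.table with columns `gene_id` and `n_snps`, sorted by
#'   decreasing support then gene id.
#' @export
candidate_genes <- function(keys, annotation) {
  ann <- annotate_variants(keys, annotation)
  hit <- ann[ann$region != "intergenic" & lengths(ann$genes) > 0L]
  if (nrow(hit) == 0L)
    return(data.table::data.table(gene_id = character(), n_snps = integer()))
  g <- unlist(hit$genes, use.names = FALSE)
  tab <- table(g)
  out <- data.table::data.table(gene_id = names(tab), n_snps = as.integer(tab))
  out[order(-out$n_snps, out$gene_id)]
}

#' Partition a reference gene list against two candidate-gene sets
#'
#' Splits a reference list (e.g. QTL candidate genes for a trait) into four
#' disjoint parts: genes hit by both groups' candidates, by one group only,
#' or by neither.
#'
#' @param genes_high,genes_low candidate gene id vectors (or the data.tables
#'   from [candidate_genes()]).
#' @param reference character vector of reference gene ids; duplicates are
#'   removed with a warning.
#' @param reference_name label for reports.
#' @param ignore_case if TRUE, match ids case-insensitively (ids reported in
#'   the reference's casing).
#' @return object of class `gene_set_partition`: list with `reference_name`,
#'   `common`, `high_only`, `low_only`, `absent`, `total_overlap`.
#' @export
partition_reference <- function(genes_high, genes_low, reference,
                                reference_name = "reference",
                                ignore_case = FALSE) {
  if (is.data.frame(genes_high)) genes_high <- genes_high$gene_id
  if (is.data.frame(genes_low)) genes_low <- genes_low$gene_id
  reference <- as.character(reference)
  if (anyDuplicated(if (ignore_case) toupper(reference) else reference)) {
    warnf("duplicate ids in reference list removed")
    reference <- reference[!duplicated(if (ignore_case) toupper(reference) else reference)]
  }
  fold <- if (ignore_case) toupper else identity
  in_high <- fold(reference) %in% fold(genes_high)
  in_low <- fold(reference) %in% fold(genes_low)
  res <- structure(list(
    reference_name = reference_name,
    common = reference[in_high & in_low],
    high_only = reference[in_high & !in_low],
    low_only = reference[!in_high & in_low],
    absent = reference[!in_high & !in_low]
  ), class = "gene_set_partition")
  res$total_overlap <- length(res$common) + length(res$high_only) + length(res$low_only)
  stopifnot(res$total_overlap + length(res$absent) == length(reference))
  res
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat(sprintf("<gene_set_partition> %s: common=%d high_only=%d low_only=%d absent=%d (overlap %d/%d)\n",
              x$reference_name, length(x$common), length(x$high_only),
              length(x$low_only), length(x$absent), x$total_overlap,
              x$total_overlap + length(x$absent)))
  invisible(x)
}
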