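#' Load a differential-expression table
#'
#' Reads a TSV with columns gene_id, logfc, pvalue and keeps the significant
#' rows (pvalue < alpha). Duplicate gene ids collapse to the record with the
#' smallest p-value; rows with logfc exactly 0 carry no direction and are
#' dropped with a warning. Direction is derived from the sign of logfc in the
#' table's stated contrast.
#'
#' @param path TSV file path, or a data.frame with the same columns.
#' @param alpha significance threshold on the raw p-value (default 0.01).
#' @return data.table with columns `gene_id`, `logfc`, `pvalue`, `direction`
#'   ("up"/"down").
#' @export
load_deg <- function(path, alpha = 0.01) {
  dt <- if (is.data.frame(path)) data.table::as.data.table(path)
        else data.table::fread(path, sep = "\t")
  need <- c("gene_id", "logfc", "pvalue")
  names(dt) <- tolower(names(dt))
  miss <- setdiff(need, names(dt))
  if (length(miss)) stopf("DEG table lacks column(s): %s", paste(miss, collapse = ", "))
  dt <- dt[order(dt$pvalue)][!duplicated(gene_id)]
  dt <- dt[dt$pvalue < alpha]
  if (any(dt$logfc == 0)) {
    warnf("load_deg: %d record(s) with logfc = 0 dropped (no direction)", sum(dt$logfc == 0))
    dt <- dt[dt$logfc != 0]
  }
  dt[, "direction" := ifelse(dt$logfc > 0, "up", "down")]
  dt[, c("gene_id", "logfc", "pvalue", "direction"), with = FALSE]
}

#' Overlap DEG with SNP candidate-gene categories
#'
#' Cross-references a differential-expression gene list with the three
#' disjoint SNP candidate-gene categories (low-specific, high-specific,
#' common) and quantifies each overlap with an upper-tail hypergeometric test
#' against an explicit gene universe. Because the categories are disjoint,
#' each DEG lands in at most one.
#'
#' @param degs data.table from [load_deg()].
#' @param genes_low,genes_high,genes_common character vectors (or
#'   [candidate_genes()] tables) of the three categories; must be pairwise
#'   disjoint.
#' @param universe character vector of background gene ids (non-empty).
#' @return object of class `overlap_report`: list with `n_deg`, `n_up`,
#'   `n_down`, `categories` (data.table: category, overlap, up, down, p),
#'   `total_overlap`, `overlap_fraction` (percent of DEG hit by any category,
#'   half-up 1 decimal).
#' @export
overlap_deg <- function(degs, genes_low, genes_high, genes_common, universe) {
  if (is.data.frame(genes_low)) genes_low <- genes_low$gene_id
  if (is.data.frame(genes_high)) genes_high <- genes_high$gene_id
  if (is.data.frame(genes_common)) genes_common <- genes_common$gene_id
  sets <- list(low_specific = unique(as.character(genes_low)),
               high_specific = unique(as.character(genes_high)),
               common = unique(as.character(genes_common)))
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(sets[[i]], sets[[j]])) > 0L)
      stopf("overlap_deg: categories '%s' and '%s' are not disjoint",
            names(sets)[i], names(sets)[j])
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stopf("overlap_deg: empty universe")

  n_deg <- nrow(degs)
  n_up <- sum(degs$direction == "up")
  n_down <- sum(degs$direction == "down")
  deg_in_universe <- intersect(degs$gene_id, universe)

  cat_rows <- lapply(names(sets), function(nm) {
    hit <- degs[degs$gene_id %in% sets[[nm]]]
    K <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(hit$gene_id, universe))
    data.table::data.table(
      category = nm, overlap = nrow(hit),
      up = sum(hit$direction == "up"), down = sum(hit$direction == "down"),
      p = hypergeom_upper(length(universe), K, length(deg_in_universe), k)
    )
  })
  categories <- data.table::rbindlist(cat_rows)
  total <- sum(categories$overlap)
  stopifnot(total == length(unique(
    degs$gene_id[degs$gene_id %in% unlist(sets, use.names = FALSE)])))
  structure(list(
    n_deg = n_deg, n_up = n_up, n_down = n_down,
    categories = categories, total_overlap = total,
    overlap_fraction = if (n_deg == 0L) NA_real_
                       else round_half_up(100 * total / n_deg, 1L)
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> DEG=%d (up %d / down %d); overlapping=%d (%.1f%%)\n",
              x$n_deg, x$n_up, x$n_down, x$total_overlap, x$overlap_fraction))
  print(x$categories)
  invisible(x)
}
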