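#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` marked items when drawing `n` items
#' without replacement from a universe of `N` containing `K` marked items:
#' P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n). Computed via
#' [stats::phyper()] which works in log space and is stable for large N.
#'
#' @param N universe size.
#' @param K marked (term) items in the universe.
#' @param n drawn (query) items.
#' @param k observed overlap.
#' @return the upper-tail probability in (0, 1].
#' @export
#' @examples
#' hypergeom_upper(10, 4, 3, 3)  # 4/120
hypergeom_upper <- function(N, K, n, k) {
  if (length(N) != 1L || length(K) != 1L || length(n) != 1L || length(k) != 1L)
    stopf("hypergeom_upper expects scalar arguments")
  if (N < 0 || K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n))
    stopf("hypergeom_upper: bounds violated (N=%s K=%s n=%s k=%s)", N, K, n, k)
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up procedure: sort the m p-values ascending, multiply
#' the i-th by m/i, enforce monotonicity by a cumulative minimum from the
#' largest rank down, cap at 1, and return in the input order.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stopf("bh_adjust: p-values must lie in (0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  scaled <- pvalues[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(scaled))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Hypergeometric over-representation test of a query gene set
#'
#' Tests each named gene set (pathway, GO term, DEG list, ...) for
#' over-representation in the query via the upper-tail hypergeometric test
#' against an explicit gene universe, with Benjamini-Hochberg correction
#' across terms. The universe matters: p-values shift with the background, so
#' it is a required argument rather than a hidden default.
#'
#' @param query character vector of query gene ids; ids outside the universe
#'   are dropped with a warning.
#' @param terms named list of character vectors (term -> gene ids); each term
#'   is intersected with the universe.
#' @param universe character vector of background gene ids (non-empty).
#' @param alpha adjusted-p significance threshold (default 0.01).
#' @return data.table with one row per term: `term`, `N`, `K`, `n`, `k`, `p`,
#'   `p_adj`, `significant`, sorted by `p_adj` then `p`.
#' @export
enrich <- function(query, terms, universe, alpha = 0.01) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stopf("enrich: empty universe")
  if (is.null(names(terms)) || any(!nzchar(names(terms))))
    stopf("enrich: terms must be a named list")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warnf("enrich: %d query gene(s) outside the universe dropped", length(outside))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(as.character(terms[[tm]])), universe)
    K <- length(tg)
    k <- length(intersect(tg, query))
    data.table::data.table(term = tm, N = N, K = K, n = n, k = k,
                           p = hypergeom_upper(N, K, n, k))
  })
  res <- data.table::rbindlist(rows)
  res[, "p_adj" := bh_adjust(res$p)]
  res[, "significant" := res$p_adj < alpha]
  res[order(res$p_adj, res$p, res$term)]
}

#' Read gene sets from a GMT or two-column TSV file
#'
#' GMT: one term per line, tab-separated as term, description, gene ids.
#' TSV: two columns, term and gene id, one pair per line.
#'
#' @param path file path.
#' @param format "auto" (by extension), "gmt" or "tsv".
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("gene-set file not found: %s", path)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "gmt") "gmt" else "tsv"
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L) stopf("malformed GMT line: %s", substr(l, 1, 60))
      unique(f[-(1:2)])
    })
    names(out) <- vapply(lines, function(l)
      strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1), USE.NAMES = FALSE)
    out
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            col.names = c("term", "gene_id"))
    split(dt$gene_id, dt$term)
  }
}

#' Read a one-id-per-line gene list
#'
#' @param path file path; blank lines and `#` comments ignored.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("gene list not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
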