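#' k-of-n reproducibility consensus over caller callsets
#'
#' Implements the MultiCom selection rule: a SNP is retained when it is
#' reported by at least `min_support` of the supplied callers. With three
#' callers and the default `min_support = 2` this keeps every call reproduced
#' by at least two tools; `min_support = 1` yields the union and
#' `min_support = n` the strict intersection. Calls reported by exactly one
#' caller ("tool-specific" or non-reproducible calls) are extracted per
#' caller, as they behave like false positives in transition/transversion and
#' region-composition diagnostics.
#'
#' @param callsets list of [callset] objects: same group label, distinct
#'   caller labels, at least two callsets.
#' @param min_support minimum number of supporting callers (default 2).
#' @param allele_aware if FALSE, calls match on (chrom, pos) only, so two
#'   callers reporting different alternate alleles at a site agree.
#' @return an object of class `consensus_result`: a list with `group`, `k`,
#'   `callers`, `per_tool_total` (named integer), `pairwise` (named integer of
#'   full pairwise intersection sizes, names "a&b"), `intersect_all` (count in
#'   every caller; for three callers the triple-overlap), `shared` (character
#'   vector of variant keys with support >= k), `tool_specific` (named list of
#'   key vectors unique to each caller), and `support` (named integer vector,
#'   key -> number of supporting callers).
#' @export
#' @examples
#' a <- callset("samtools", "high", data.frame(chrom = "1", pos = 1:3,
#'        ref = "A", alt = "G", qual = 40, depth = 10L))
#' b <- callset("varscan", "high", data.frame(chrom = "1", pos = 2:4,
#'        ref = "A", alt = "G", qual = 40, depth = 10L))
#' multicom(list(a, b), min_support = 2)
multicom <- function(callsets, min_support = 2L, allele_aware = TRUE) {
  keysets <- check_consensus_input(callsets, allele_aware)
  n <- length(keysets)
  if (min_support < 1L || min_support > n)
    stopf("min_support must be in 1..%d, got %s", n, min_support)

  all_keys <- unique(unlist(keysets, use.names = FALSE))
  member <- vapply(keysets, function(k) all_keys %in% k, logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L)
  support <- as.integer(rowSums(member))
  names(support) <- all_keys

  callers <- names(keysets)
  per_tool_total <- vapply(keysets, length, integer(1))

  pairs <- utils::combn(callers, 2L, simplify = FALSE)
  pairwise <- vapply(pairs, function(p) {
    sum(member[, match(p[1L], callers)] & member[, match(p[2L], callers)])
  }, integer(1))
  names(pairwise) <- vapply(pairs, paste, character(1), collapse = "&")

  tool_specific <- lapply(seq_len(n), function(j) {
    all_keys[member[, j] & support == 1L]
  })
  names(tool_specific) <- callers

  structure(list(
    group = callsets[[1L]]$group,
    k = as.integer(min_support),
    callers = callers,
    per_tool_total = per_tool_total,
    pairwise = pairwise,
    intersect_all = sum(support == n),
    shared = all_keys[support >= min_support],
    tool_specific = tool_specific,
    support = support
  ), class = "consensus_result")
}

check_consensus_input <- function(callsets, allele_aware = TRUE) {
  if (!is.list(callsets) || length(callsets) < 2L)
    stopf("need at least 2 callsets")
  if (!all(vapply(callsets, inherits, logical(1), "callset")))
    stopf("all inputs must be callset objects")
  groups <- vapply(callsets, `[[`, character(1), "group")
  if (length(unique(groups)) != 1L)
    stopf("mixed group labels: %s", paste(unique(groups), collapse = ", "))
  callers <- vapply(callsets, `[[`, character(1), "caller")
  if (anyDuplicated(callers))
    stopf("duplicate caller labels: %s", paste(callers[duplicated(callers)], collapse = ", "))
  keysets <- lapply(callsets, variant_keys, allele_aware = allele_aware)
  if (!allele_aware) keysets <- lapply(keysets, unique)
  names(keysets) <- callers
  keysets
}

#' Histogram of caller support levels
#'
#' Counts, for each support level 1..n, how many distinct variants were called
#' by exactly that many callers. The counts sum to the size of the union of
#' all callsets.
#'
#' @inheritParams multicom
#' @return named integer vector over support levels "1".."n".
#' @export
support_histogram <- function(callsets, allele_aware = TRUE) {
  keysets <- check_consensus_input(callsets, allele_aware)
  n <- length(keysets)
  tab <- table(factor(table(unlist(lapply(keysets, unique), use.names = FALSE)),
                      levels = seq_len(n)))
  out <- as.integer(tab)
  names(out) <- as.character(seq_len(n))
  out
}

#' Relative discovery gain of the consensus set over each caller
#'
#' For each caller c, gain = (|shared| - total_c) / total_c: the relative
#' increase in retained calls from pooling evidence across callers instead of
#' trusting one tool. May be negative when a caller out-calls the consensus.
#'
#' @param result a `consensus_result` from [multicom()].
#' @return named numeric vector of relative gains; a caller with zero calls
#'   yields NA with a warning.
#' @export
discovery_gain <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  tot <- result$per_tool_total
  if (any(tot == 0L)) warnf("caller(s) with zero calls: gain undefined (NA)")
  gain <- ifelse(tot == 0L, NA_real_, (length(result$shared) - tot) / tot)
  names(gain) <- names(tot)
  gain
}

#' Exclusive Venn region counts for a three-caller consensus
#'
#' @param result a `consensus_result` built from exactly three callsets.
#' @return named integer vector of the 7 exclusive regions, e.g. "a_only",
#'   "a&b_only", "all".
#' @export
venn_regions <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  if (length(result$callers) != 3L) stopf("venn_regions requires exactly 3 callers")
  cl <- result$callers
  only <- vapply(result$tool_specific, length, integer(1))
  triple <- result$intersect_all
  pair_only <- result$pairwise - triple
  out <- c(only, pair_only, all = triple)
  names(out) <- c(paste0(cl, "_only"), paste0(names(result$pairwise), "_only"), "all")
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> group=%s k=%d callers=%s\n", x$group, x$k,
              paste(x$callers, collapse = ",")))
  cat(sprintf("  per-tool totals: %s\n",
              paste(sprintf("%s=%d", names(x$per_tool_total), x$per_tool_total),
                    collapse = " ")))
  cat(sprintf("  shared (support >= %d): %d\n", x$k, length(x$shared)))
  cat(sprintf("  tool-specific: %s\n",
              paste(sprintf("%s=%d", names(x$tool_specific),
                            lengths(x$tool_specific)), collapse = " ")))
  invisible(x)
}
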