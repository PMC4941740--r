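#' Partition two groups' consensus SNP sets into specific and common calls
#'
#' Given the consensus (MultiCom) SNP sets of two contrasted groups, derives
#' the group-specific sets by plain set difference — a SNP is "specific" for a
#' group when it is absent from the other group's consensus set, whether never
#' called there or called but sub-threshold — and the common set by
#' intersection. Percentages express each specific set relative to its group's
#' full consensus set, rounded half-up to one decimal.
#'
#' @param mc_high,mc_low character vectors of variant keys (or
#'   `consensus_result` objects, whose `shared` sets are used), both under the
#'   same variant-identity convention.
#' @return object of class `group_partition`: list with `specific_high`,
#'   `specific_low`, `common` (disjoint key vectors), `pct_specific_high`,
#'   `pct_specific_low` (NA when the group's consensus set is empty).
#' @export
#' @examples
#' p <- partition_groups(c("1:1:A:G", "1:2:A:G"), c("1:2:A:G", "1:3:A:G"))
#' p$pct_specific_high  # 50
partition_groups <- function(mc_high, mc_low) {
  if (inherits(mc_high, "consensus_result")) mc_high <- mc_high$shared
  if (inherits(mc_low, "consensus_result")) mc_low <- mc_low$shared
  mc_high <- unique(as.character(mc_high))
  mc_low <- unique(as.character(mc_low))
  common <- intersect(mc_high, mc_low)
  specific_high <- setdiff(mc_high, mc_low)
  specific_low <- setdiff(mc_low, mc_high)
  pct <- function(spec, total) {
    if (total == 0L) NA_real_ else round_half_up(100 * spec / total, 1L)
  }
  structure(list(
    specific_high = specific_high,
    specific_low = specific_low,
    common = common,
    pct_specific_high = pct(length(specific_high), length(mc_high)),
    pct_specific_low = pct(length(specific_low), length(mc_low))
  ), class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf(
    "<group_partition> high-specific=%d (%.1f%%) low-specific=%d (%.1f%%) common=%d\n",
    length(x$specific_high), x$pct_specific_high,
    length(x$specific_low), x$pct_specific_low, length(x$common)))
  invisible(x)
}
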