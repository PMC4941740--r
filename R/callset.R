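#' Construct a callset
#'
#' A callset is one variant caller's filtered SNP set for one sample group.
#' Records are biallelic SNPs identified by (chrom, pos, ref, alt) with the
#' caller's reported quality (QUAL) and read depth (DP). Depth may be NA when
#' a record carried neither INFO/DP nor any per-sample DP; such records fail
#' any depth filter.
#'
#' @param caller non-empty caller label, e.g. "samtools".
#' @param group non-empty group label, e.g. "high".
#' @param records a data.frame with columns chrom (character), pos (integer,
#'   1-based), ref, alt (single upper-case bases, ref != alt), qual
#'   (non-negative numeric), depth (non-negative integer or NA).
#' @return an object of class `callset`.
#' @export
#' @examples
#' callset("samtools", "high",
#'         data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
#'                    qual = 40, depth = 10L))
callset <- function(caller, group, records = empty_records()) {
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L) records <- empty_records()
  obj <- structure(
    list(caller = caller, group = group, records = records),
    class = "callset"
  )
  validate_callset(obj)
}

empty_records <- function() {
  data.table::data.table(
    chrom = character(), pos = integer(),
    ref = character(), alt = character(),
    qual = numeric(), depth = integer()
  )
}

validate_callset <- function(x) {
  if (!nzchar(x$caller)) stopf("callset: caller label must be non-empty")
  if (!nzchar(x$group)) stopf("callset: group label must be non-empty")
  r <- x$records
  need <- c("chrom", "pos", "ref", "alt", "qual", "depth")
  miss <- setdiff(need, names(r))
  if (length(miss)) stopf("callset records lack column(s): %s", paste(miss, collapse = ", "))
  if (nrow(r)) {
    if (any(!r$ref %in% VALID_BASES) || any(!r$alt %in% VALID_BASES))
      stopf("callset: ref/alt must be single bases A/C/G/T")
    if (any(r$ref == r$alt)) stopf("callset: ref must differ from alt")
    if (any(r$pos < 1L)) stopf("callset: positions are 1-based (pos >= 1)")
    if (any(r$qual < 0, na.rm = TRUE)) stopf("callset: qual must be non-negative")
    if (any(r$depth < 0L, na.rm = TRUE)) stopf("callset: depth must be non-negative")
    k <- variant_key(r$chrom, r$pos, r$ref, r$alt)
    if (anyDuplicated(k)) stopf("callset: duplicate variant key(s), e.g. %s", k[duplicated(k)][1L])
  }
  x
}

#' Variant keys of a callset or key-set object
#'
#' @param x a `callset`, or a data.frame with chrom/pos/ref/alt columns, or a
#'   character vector already in key form.
#' @param allele_aware if FALSE, identity is (chrom, pos) only.
#' @return character vector of canonical variant keys.
#' @export
variant_keys <- function(x, allele_aware = TRUE) {
  if (is.character(x)) return(x)
  r <- if (inherits(x, "callset")) x$records else data.table::as.data.table(x)
  if (nrow(r) == 0L) return(character())
  variant_key(r$chrom, r$pos, r$ref, r$alt, allele_aware = allele_aware)
}

#' Parse canonical variant keys back to a table
#'
#' Inverse of [variant_keys()] for allele-aware keys "chrom:pos:ref:alt".
#'
#' @param keys character vector of keys.
#' @return data.table with columns chrom, pos, ref, alt.
#' @export
parse_variant_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()))
  }
  parts <- data.table::tstrsplit(keys, ":", fixed = TRUE)
  if (length(parts) != 4L) stopf("keys are not in chrom:pos:ref:alt form")
  data.table::data.table(chrom = parts[[1L]], pos = as.integer(parts[[2L]]),
                         ref = parts[[3L]], alt = parts[[4L]])
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset> caller=%s group=%s records=%d\n",
              x$caller, x$group, nrow(x$records)))
  invisible(x)
}

#' @export
length.callset <- function(x) nrow(x$records)
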