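#' Round half away from zero
#'
#' Fixed-precision rounding where ties go up (1.25 -> 1.3 at one decimal),
#' matching how percentages are conventionally printed in reports, unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(21.25, 1)  # 21.3
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix (case-insensitive) so callsets produced
#' against references with different chromosome-naming dialects can be
#' intersected.
#'
#' @param chrom character vector of chromosome names.
#' @return normalized character vector.
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

VALID_BASES <- c("A", "C", "G", "T")

# canonical string identity of a biallelic SNP; `allele_aware = FALSE` drops
# the allele part so two callers reporting different alts at one site match
variant_key <- function(chrom, pos, ref, alt, allele_aware = TRUE) {
  if (allele_aware) {
    paste(chrom, pos, ref, alt, sep = ":")
  } else {
    paste(chrom, pos, sep = ":")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
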