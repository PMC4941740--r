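#' Read a VCF file into a callset
#'
#' Parses a VCF v4.x text file (plain or gzip/bgzip compressed) and returns
#' the biallelic SNP records. Multi-allelic records are split into one record
#' per alternate allele; alleles that are not simple single-base substitutions
#' (indels, MNPs, symbolic alleles, spanning deletions) are dropped and
#' counted. Read depth is taken from INFO/DP; when absent it falls back to the
#' sum of per-sample FORMAT/DP values (the pooled-calling interpretation).
#' Records with neither are kept with `depth = NA`, which fails any depth
#' filter downstream.
#'
#' Duplicate keys (e.g. the same site emitted once per sample in per-sample
#' VCFs) are collapsed to the record with the highest QUAL, ties broken by
#' depth; the number collapsed is reported in the `io_stats` attribute.
#'
#' @param path path to a VCF file.
#' @param caller caller label for the resulting callset; defaults to the file
#'   name without extension.
#' @param group group label; default "ungrouped".
#' @param sample_pooling if TRUE (default), per-sample DP values are summed
#'   when INFO/DP is missing.
#' @param normalize if TRUE (default), chromosome names are normalized by
#'   stripping a leading "chr".
#' @return a [callset] with attribute `io_stats`: a list with
#'   `n_dropped_nonsnp`, `n_missing_depth` and `n_collapsed_duplicates`.
#' @export
read_vcf <- function(path, caller = NULL, group = "ungrouped",
                     sample_pooling = TRUE, normalize = TRUE) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  caller <- caller %||% sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(path))
  con <- file(path, "rt")  # file() transparently decompresses gzip/bgzip
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  is_meta <- startsWith(lines, "#")
  body_idx <- which(!is_meta & nzchar(lines))

  chrom <- character(0); pos <- integer(0); ref <- character(0)
  alt <- character(0); qual <- numeric(0); depth <- integer(0)
  n_nonsnp <- 0L; n_missing_dp <- 0L

  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      stopf("malformed VCF line %d in %s: expected >= 8 tab-separated fields, got %d",
            i, path, length(f))
    p <- suppressWarnings(as.integer(f[2L]))
    if (is.na(p) || p < 1L)
      stopf("malformed VCF line %d in %s: POS '%s' is not a positive integer", i, path, f[2L])
    q <- if (f[6L] == ".") NA_real_ else suppressWarnings(as.numeric(f[6L]))
    if (!is.na(f[6L]) && f[6L] != "." && is.na(q))
      stopf("malformed VCF line %d in %s: QUAL '%s' is not numeric", i, path, f[6L])

    dp <- parse_info_dp(f[8L])
    if (is.na(dp) && sample_pooling && length(f) >= 10L) {
      dp <- sum_format_dp(f[9L], f[10:length(f)])
    }

    r <- toupper(f[4L])
    alts <- toupper(strsplit(f[5L], ",", fixed = TRUE)[[1L]])
    for (a in alts) {
      if (nchar(r) == 1L && nchar(a) == 1L && r %in% VALID_BASES &&
          a %in% VALID_BASES && a != r) {
        chrom <- c(chrom, f[1L]); pos <- c(pos, p); ref <- c(ref, r)
        alt <- c(alt, a); qual <- c(qual, q); depth <- c(depth, dp)
        if (is.na(dp)) n_missing_dp <- n_missing_dp + 1L
      } else {
        n_nonsnp <- n_nonsnp + 1L
      }
    }
  }

  rec <- data.table::data.table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                                qual = qual, depth = depth)
  if (normalize && nrow(rec)) rec[, "chrom" := normalize_chrom(rec$chrom)]

  n_dup <- 0L
  if (nrow(rec)) {
    key <- variant_key(rec$chrom, rec$pos, rec$ref, rec$alt)
    if (anyDuplicated(key)) {
      ord <- order(key, -replace(rec$qual, is.na(rec$qual), -1),
                   -replace(rec$depth, is.na(rec$depth), -1L))
      rec <- rec[ord][!duplicated(sort(key))]
      n_dup <- length(key) - nrow(rec)
    }
  }

  cs <- callset(caller = caller, group = group, records = rec)
  attr(cs, "io_stats") <- list(n_dropped_nonsnp = n_nonsnp,
                               n_missing_depth = n_missing_dp,
                               n_collapsed_duplicates = n_dup)
  cs
}

parse_info_dp <- function(info) {
  if (info == "." || !nzchar(info)) return(NA_integer_)
  m <- regmatches(info, regexpr("(?:^|;)DP=([0-9]+)", info))
  if (length(m) == 0L) return(NA_integer_)
  as.integer(sub(".*DP=", "", m))
}

sum_format_dp <- function(format, samples) {
  keys <- strsplit(format, ":", fixed = TRUE)[[1L]]
  j <- match("DP", keys)
  if (is.na(j)) return(NA_integer_)
  vals <- vapply(samples, function(s) {
    v <- strsplit(s, ":", fixed = TRUE)[[1L]]
    if (length(v) < j || v[j] %in% c(".", "")) NA_integer_
    else suppressWarnings(as.integer(v[j]))
  }, integer(1), USE.NAMES = FALSE)
  if (all(is.na(vals))) NA_integer_ else sum(vals, na.rm = TRUE)
}

#' Filter a callset on depth and quality thresholds
#'
#' Keeps records with `depth >= min_depth` and `qual >= min_qual` (both
#' inclusive). Records with missing depth or quality fail the corresponding
#' criterion. The input callset is not modified.
#'
#' @param cs a [callset].
#' @param min_depth minimum read depth (default 5).
#' @param min_qual minimum phred-scaled quality (default 30).
#' @return the filtered [callset], with attribute `filter_report`: a list with
#'   `n_input`, `n_kept`, `removed_depth`, `removed_qual` (records failing each
#'   criterion, counted independently).
#' @export
filter_callset <- function(cs, min_depth = 5L, min_qual = 30) {
  stopifnot(inherits(cs, "callset"))
  if (min_depth < 0 || min_qual < 0) stopf("filter thresholds must be non-negative")
  r <- cs$records
  ok_dp <- !is.na(r$depth) & r$depth >= min_depth
  ok_q <- !is.na(r$qual) & r$qual >= min_qual
  if (min_depth == 0) ok_dp <- ok_dp | is.na(r$depth) | r$depth >= 0   # 0 threshold keeps all
  if (min_qual == 0) ok_q <- ok_q | is.na(r$qual) | r$qual >= 0
  out <- callset(cs$caller, cs$group, r[ok_dp & ok_q])
  attr(out, "filter_report") <- list(
    n_input = nrow(r), n_kept = sum(ok_dp & ok_q),
    removed_depth = sum(!ok_dp), removed_qual = sum(!ok_q)
  )
  out
}

#' Write a callset to a minimal VCF v4.2 file
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO columns with depth carried in
#' INFO/DP, records sorted by (chrom, pos, alt). `read_vcf(write_vcf(cs))`
#' reproduces the callset's key/qual/depth content exactly.
#'
#' @param cs a [callset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path) {
  stopifnot(inherits(cs, "callset"))
  r <- data.table::copy(cs$records)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=multicom (caller=%s group=%s)", cs$caller, cs$group),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth at site">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (nrow(r)) {
    r <- r[order(r$chrom, r$pos, r$alt)]
    info <- ifelse(is.na(r$depth), ".", paste0("DP=", r$depth))
    qual <- ifelse(is.na(r$qual), ".", vapply(r$qual, format_qual, character(1)))
    body <- paste(r$chrom, r$pos, ".", r$ref, r$alt, qual, "PASS", info, sep = "\t")
  }
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write VCF to %s", path)
  invisible(path)
}

# full-precision decimal so the read/write round trip is exact
format_qual <- function(q) {
  if (q == floor(q) && abs(q) < 1e15) sprintf("%d", as.integer(q))
  else format(q, digits = 17, scientific = FALSE, trim = TRUE)
}
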