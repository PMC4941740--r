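test_that("read_vcf maps fields, splits multi-allelics and drops non-SNPs", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(c(
    "chr1\t100\t.\tA\tG\t40\t.\tDP=10",
    "chr1\t200\t.\tA\tG,T\t40\t.\tDP=10",
    "chr1\t300\t.\tAT\tA\t40\t.\tDP=10",
    "chr1\t400\t.\tC\t<DEL>\t40\t.\tDP=10"
  ), p)
  cs <- read_vcf(p, caller = "samtools", group = "high")

  expect_s3_class(cs, "callset")
  expect_equal(length(cs), 3L)
  expect_setequal(variant_keys(cs), c("1:100:A:G", "1:200:A:G", "1:200:A:T"))
  expect_equal(cs$records$qual, rep(40, 3))
  expect_equal(cs$records$depth, rep(10L, 3))
  expect_equal(attr(cs, "io_stats")$n_dropped_nonsnp, 2L)
})

test_that("read_vcf splitting preserves total alternate-allele count", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(c(
    "1\t10\t.\tA\tC,G,T\t50\t.\tDP=8",
    "1\t20\t.\tG\tA,T\t50\t.\tDP=8",
    "2\t10\t.\tT\tC\t50\t.\tDP=8"
  ), p)
  cs <- read_vcf(p)
  expect_equal(length(cs) + attr(cs, "io_stats")$n_dropped_nonsnp, 6L)
  expect_equal(length(cs), 6L)
})

test_that("read_vcf falls back to summed per-sample DP and flags missing DP", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\t.\tA\tG\t40\t.\t.\tGT:DP\t0/1:6\t1/1:7",
    "1\t200\t.\tC\tT\t40\t.\t.\tGT\t0/1\t1/1"
  ), p)
  cs <- read_vcf(p)
  rec <- cs$records[base::order(cs$records$pos), ]
  expect_equal(rec$depth, c(13L, NA_integer_))
  expect_equal(attr(cs, "io_stats")$n_missing_depth, 1L)
  # the depth-missing record fails the depth criterion
  kept <- filter_callset(cs, min_depth = 5, min_qual = 30)
  expect_equal(variant_keys(kept), "1:100:A:G")
})

test_that("read_vcf errors name the file and line", {
  expect_error(read_vcf(file.path(tempdir(), "absent.vcf")), "not found")
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(c("1\t100\t.\tA\tG\t40\t.\tDP=10", "1\tnope\tbroken"), p)
  expect_error(read_vcf(p), "line 5")
})

test_that("filter_callset applies inclusive thresholds and reports removals", {
  uni <- make_universe(3)
  cs <- callset("c", "g", data.frame(uni, qual = c(30, 99, 29),
                                     depth = c(5L, 4L, 99L)))
  out <- filter_callset(cs, min_depth = 5, min_qual = 30)
  expect_equal(variant_keys(out), variant_keys(cs)[1])
  rep <- attr(out, "filter_report")
  expect_equal(rep$removed_depth, 1L)
  expect_equal(rep$removed_qual, 1L)

  expect_equal(length(filter_callset(callset("c", "g"), 5, 30)), 0L)
  # zero thresholds are the identity
  expect_equal(filter_callset(cs, 0, 0)$records, cs$records)
  # idempotence
  expect_equal(filter_callset(out, 5, 30)$records, out$records)
})

test_that("write_vcf/read_vcf round-trips exactly and sorts records", {
  set.seed(402)
  for (i in 1:20) {
    n <- sample(0:40, 1)
    uni <- make_universe(200, chrom = sample(c("1", "2", "X"), 1))
    rows <- sample(200, n)
    rec <- uni[rows, , drop = FALSE]
    rec$qual <- round(stats::runif(n, 0, 99), 1)
    rec$depth <- sample(0:99, n, replace = TRUE)
    if (n > 0) rec$depth[sample(n, 1)] <- NA_integer_
    cs <- callset("x", "g", rec)
    p <- tempfile(fileext = ".vcf")
    write_vcf(cs, p)
    back <- read_vcf(p, caller = "x", group = "g")
    o1 <- cs$records[base::order(cs$records$chrom, cs$records$pos,
                                 cs$records$alt), ]
    expect_equal(back$records, o1, ignore_attr = TRUE)
    unlink(p)
  }
  # empty callset -> header-only VCF
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(callset("x", "g"), p)
  expect_true(all(startsWith(readLines(p), "#")))
  expect_equal(length(read_vcf(p)), 0L)
})

test_that("read_vcf agrees with the VariantAnnotation reader on a standard file", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    "##contig=<ID=1,length=1000000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t101\t.\tA\tG\t55.5\tPASS\tDP=12",
    "1\t202\t.\tC\tT\t60\tPASS\tDP=9",
    "1\t303\t.\tG\tC\t33\tPASS\tDP=20"
  ), p)
  mine <- read_vcf(p)

  vcf <- VariantAnnotation::readVcf(p)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref_keys <- paste(as.character(GenomicRanges::seqnames(rr)),
                    GenomicRanges::start(rr),
                    as.character(rr$REF),
                    vapply(rr$ALT, function(a) as.character(a[[1]]), character(1)),
                    sep = ":")
  expect_setequal(variant_keys(mine), ref_keys)
  ord <- match(ref_keys, variant_keys(mine))
  expect_equal(mine$records$qual[ord], unname(rr$QUAL))
  expect_equal(mine$records$depth[ord], unname(VariantAnnotation::info(vcf)$DP))
})

test_that("duplicate sites collapse to the best-supported record", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(c(
    "1\t100\t.\tA\tG\t40\t.\tDP=10",
    "1\t100\t.\tA\tG\t70\t.\tDP=4"
  ), p)
  cs <- read_vcf(p)
  expect_equal(length(cs), 1L)
  expect_equal(cs$records$qual, 70)
  expect_equal(attr(cs, "io_stats")$n_collapsed_duplicates, 1L)
})

test_that("callset validation rejects malformed records", {
  expect_error(callset("", "g"), "caller")
  expect_error(callset("c", "g", data.frame(chrom = "1", pos = 1L, ref = "A",
                                            alt = "A", qual = 1, depth = 1L)),
               "differ")
  expect_error(callset("c", "g", data.frame(chrom = "1", pos = 0L, ref = "A",
                                            alt = "G", qual = 1, depth = 1L)),
               "1-based")
  expect_error(callset("c", "g", data.frame(chrom = c("1", "1"), pos = c(1L, 1L),
                                            ref = "A", alt = "G", qual = 1,
                                            depth = 1L)),
               "duplicate")
})
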