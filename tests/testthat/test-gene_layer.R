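test_that("BED and GFF3 dialects load to identical internal intervals", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tGENE1\t.\t+\tCDS",
               "chr1\t50\t300\tGENE1\t.\t+\tgene"), bed)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t101\t200\t.\t+\t.\tID=cds1;gene_id=GENE1",
               "chr1\tsrc\tgene\t51\t300\t.\t+\t.\tID=g1;gene_id=GENE1"), gff)
  a <- load_annotation(bed)
  b <- load_annotation(gff)
  setkeyless <- function(x) as.data.frame(x$intervals[base::order(x$intervals$start), ])
  expect_equal(setkeyless(a), setkeyless(b), ignore_attr = TRUE)
  # BED 0-based half-open -> 1-based inclusive 101..200
  cds <- a$intervals[a$intervals$feature == "CDS", ]
  expect_equal(cds$start, 101L)
  expect_equal(cds$end, 200L)
})

test_that("annotation loading errors and warnings follow the contract", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100", p)
  expect_error(load_annotation(p), "line 1")
  writeLines("chr1\t200\t100\tG1", p)
  expect_error(load_annotation(p), "line 1")
  writeLines(c("chr1\t100\t200\tG1\t.\t+\tCDS",
               "chr1\t100\t200\tG1\t.\t+\tpromoter"), p)
  expect_warning(ann <- load_annotation(p), "unknown feature")
  expect_equal(nrow(ann$intervals), 1L)

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_equal(nrow(load_annotation(empty)$intervals), 0L)
})

test_that("annotate_variant applies the precedence rule", {
  ann <- tiny_annotation()
  expect_equal(annotate_variant("1:200:A:G", ann),
               list(region = "CDS", genes = "GENE1"))
  expect_equal(annotate_variant("1:300:A:G", ann),
               list(region = "intronic", genes = "GENE1"))
  # GENE1 CDS (401..500) wins over GENE2 3'UTR (451..520) at 460
  expect_equal(annotate_variant("1:460:A:G", ann),
               list(region = "CDS", genes = "GENE1"))
  # GENE2 3'UTR wins over gene bodies at 510
  expect_equal(annotate_variant("1:510:A:G", ann),
               list(region = "3UTR", genes = "GENE2"))
  expect_equal(annotate_variant("1:9999:A:G", ann),
               list(region = "intergenic", genes = character()))
})

test_that("annotate_variants agrees with a naive all-interval scan on random positions", {
  set.seed(55)
  ann <- tiny_annotation()
  pos <- sample(1000, 120)
  keys <- sprintf("1:%d:A:G", pos)
  got <- annotate_variants(keys, ann)
  for (i in seq_along(pos)) {
    want <- oracle_annotate("1", pos[i], ann$intervals)
    expect_equal(got$region[i], want$region)
    expect_equal(got$genes[[i]], want$genes)
  }
})

test_that("candidate_genes unions non-intergenic hits with support counts", {
  ann <- tiny_annotation()
  keys <- c("1:160:A:G", "1:170:C:T", "1:420:G:A",  # 3 in GENE1
            "1:510:A:C",                            # 1 in GENE2
            "1:50:A:G", "1:2000:C:A")               # 2 intergenic
  g <- candidate_genes(keys, ann)
  expect_equal(g$gene_id, c("GENE1", "GENE2"))
  expect_equal(g$n_snps, c(3L, 1L))

  none <- candidate_genes(c("1:50:A:G", "2:1:C:A"), ann)
  expect_equal(nrow(none), 0L)

  # monotone: adding SNPs never removes genes
  g2 <- candidate_genes(c(keys, "1:700:A:G"), ann)
  expect_true(all(g$gene_id %in% g2$gene_id))
})

test_that("partition_reference reproduces the published overlap totals", {
  # milk-yield shape: common 26, low-only 17, high-only 8, reference 74
  ref <- sprintf("R%02d", 1:74)
  high <- c(ref[1:26], ref[44:51], "X1")
  low <- c(ref[1:26], ref[27:43], "X2")
  p <- partition_reference(high, low, ref, reference_name = "milk-yield")
  expect_length(p$common, 26L)
  expect_length(p$low_only, 17L)
  expect_length(p$high_only, 8L)
  expect_equal(p$total_overlap, 51L)
  expect_length(p$absent, 23L)

  # milk-fat shape: common 30, low-only 24, high-only 15, reference 91
  ref2 <- sprintf("F%02d", 1:91)
  p2 <- partition_reference(c(ref2[1:30], ref2[55:69]),
                            c(ref2[1:30], ref2[31:54]), ref2)
  expect_equal(p2$total_overlap, 69L)

  p3 <- partition_reference(c("A", "B"), c("C"), c("Z1", "Z2"))
  expect_equal(p3$total_overlap, 0L)
  expect_length(p3$absent, 2L)
})

test_that("partition_reference handles duplicates and case folding", {
  expect_warning(p <- partition_reference("g1", "g2", c("G1", "G1", "G2"),
                                          ignore_case = TRUE),
                 "duplicate")
  expect_equal(p$total_overlap, 2L)
  expect_setequal(p$high_only, "G1")
  p2 <- partition_reference("g1", character(), c("G1"))
  expect_equal(p2$total_overlap, 0L)  # case-sensitive by default
})
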