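# shared fixture builders and independent oracles

# a universe of distinct SNPs (consistent ref/alt per position) that several
# callsets can sample from, so keys coincide across callers
make_universe <- function(n, chrom = "1") {
  ref <- c("A", "C", "G", "T")[(seq_len(n) %% 4L) + 1L]
  # alternate transition / transversion partners so ts and tv both occur
  transition <- c(A = "G", C = "T", G = "A", T = "C")[ref]
  transversion <- c(A = "C", C = "A", G = "T", T = "G")[ref]
  alt <- ifelse(seq_len(n) %% 2L == 0L, transition, transversion)
  data.frame(chrom = chrom, pos = seq_len(n), ref = ref, alt = unname(alt),
             stringsAsFactors = FALSE)
}

sample_callset <- function(universe, rows, caller = "c", group = "g",
                           qual = 50, depth = 10L) {
  rec <- universe[rows, , drop = FALSE]
  rec$qual <- qual
  rec$depth <- depth
  callset(caller, group, rec)
}

# callsets over integer-labelled keys (1 -> pos 1, ...), as in the worked
# examples: A={1,2,3} etc.
int_callsets <- function(sets, group = "g") {
  uni <- make_universe(max(unlist(sets)))
  lapply(seq_along(sets), function(i) {
    sample_callset(uni, sets[[i]], caller = names(sets)[i] %||% paste0("c", i),
                   group = group)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force consensus oracle: per-key membership counting, no set algebra
oracle_support <- function(keysets) {
  all_keys <- unique(unlist(keysets, use.names = FALSE))
  supp <- vapply(all_keys, function(k) {
    sum(vapply(keysets, function(s) k %in% s, logical(1)))
  }, integer(1))
  names(supp) <- all_keys
  supp
}

# exhaustive hypergeometric upper tail: enumerate every C(N, n) draw
oracle_hyper_enum <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k == 0L))
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(draws <= K, nrow = n))
  mean(hits >= k)
}

# tiny two-gene annotation used across gene-layer tests:
#   GENE1 on chrom 1: body 101..600, 5'UTR 101..150, CDS 151..250,
#                     CDS 401..500, 3'UTR 551..600 (introns elsewhere)
#   GENE2 on chrom 1: body 451..900 (overlaps GENE1), 3'UTR 451..520
tiny_annotation <- function() {
  gene_ann <- data.frame(
    gene_id = c("GENE1", "GENE1", "GENE1", "GENE1", "GENE1", "GENE2", "GENE2"),
    chrom = "1",
    start = c(101L, 101L, 151L, 401L, 551L, 451L, 451L),
    end = c(600L, 150L, 250L, 500L, 600L, 900L, 520L),
    feature = c("gene", "5UTR", "CDS", "CDS", "3UTR", "gene", "3UTR"),
    stringsAsFactors = FALSE
  )
  multicom:::gene_annotation(gene_ann)
}

# naive per-position annotation oracle: scan all intervals, apply precedence
oracle_annotate <- function(chrom, pos, intervals) {
  prec <- c("CDS", "5UTR", "3UTR", "exon", "gene")
  hit <- intervals[intervals$chrom == chrom & intervals$start <= pos &
                     intervals$end >= pos, , drop = FALSE]
  if (nrow(hit) == 0L) return(list(region = "intergenic", genes = character()))
  for (f in prec) {
    sub <- hit[hit$feature == f, , drop = FALSE]
    if (nrow(sub) > 0L) {
      return(list(region = if (f == "gene") "intronic" else f,
                  genes = sort(unique(sub$gene_id))))
    }
  }
}

# small, fast simulation world for pipeline-level tests; ... overrides any
# default, including caller_fp_rate
small_sim_config <- function(seed = 11L, ...) {
  args <- list(genome = data.frame(chrom = c("1", "2"), length = c(2e6, 2e6)),
               n_true_high = 160L, n_true_low = 240L, n_common_true = 600L,
               n_genes = 80L, caller_fp_rate = 40, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

vcf_header_minimal <- c(
  "##fileformat=VCFv4.2",
  '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
)

write_vcf_text <- function(body, path, header = vcf_header_minimal) {
  writeLines(c(header, body), path)
  path
}
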