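#' Simulation configuration
#'
#' Describes the synthetic world the callset simulator emulates: a small
#' multi-chromosome genome with gene models, two contrasted sample groups
#' sharing a large common pool of true SNPs plus group-specific ones, and
#' three imperfect callers. True variants carry the transition/transversion
#' signature of clean exome-target callsets (ts/tv ~ 2.6) and sit mostly in
#' genic sequence; false positives are caller-independent, lower-ts/tv
#' (~1.8), and placed into intergenic sequence at twice the true rate —
#' the error structure that makes k-of-n consensus selection effective.
#'
#' @param genome data.frame with columns chrom, length (bp).
#' @param n_true_high,n_true_low,n_common_true counts of group-specific and
#'   shared true variants.
#' @param tstv_true,tstv_fp target ts/tv ratios of true and false calls.
#' @param callers caller labels.
#' @param caller_sensitivity per-caller detection probability for a true
#'   variant (scalar or named vector; default 0.95).
#' @param caller_fp_rate per-caller expected false-positive count per group
#'   (Poisson mean); default 5% of the average per-group truth size.
#' @param fp_intergenic_multiplier relative intergenic placement rate of
#'   false positives vs true variants (default 2).
#' @param p_intergenic_true probability a true variant is intergenic
#'   (default 0.3).
#' @param n_genes,exons_per_gene annotation shape.
#' @param subthreshold_fraction fraction of emitted calls given QUAL or DP
#'   below the standard thresholds (30 / 5), to exercise filtering.
#' @param fp_correlation probability that a caller's false positive is drawn
#'   from a shared per-group FP pool instead of independently; 0 (default)
#'   gives fully independent errors, higher values defeat the consensus.
#' @param seed integer master seed; all randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome = data.frame(chrom = as.character(1:5),
                                           length = rep(10e6, 5)),
                       n_true_high = 1600L, n_true_low = 2400L,
                       n_common_true = 6000L,
                       tstv_true = 2.6, tstv_fp = 1.8,
                       callers = c("samtools", "freebayes", "varscan"),
                       caller_sensitivity = 0.95,
                       caller_fp_rate = NULL,
                       fp_intergenic_multiplier = 2,
                       p_intergenic_true = 0.3,
                       n_genes = 500L, exons_per_gene = 5L,
                       subthreshold_fraction = 0.05,
                       fp_correlation = 0,
                       seed = 1L) {
  sens <- expand_caller_param(caller_sensitivity, callers, "caller_sensitivity")
  if (is.null(caller_fp_rate)) {
    caller_fp_rate <- 0.05 * (n_common_true + (n_true_high + n_true_low) / 2)
  }
  fp <- expand_caller_param(caller_fp_rate, callers, "caller_fp_rate")
  cfg <- structure(list(
    genome = data.table::as.data.table(genome),
    n_true_high = as.integer(n_true_high), n_true_low = as.integer(n_true_low),
    n_common_true = as.integer(n_common_true),
    tstv_true = tstv_true, tstv_fp = tstv_fp,
    callers = callers, caller_sensitivity = sens, caller_fp_rate = fp,
    fp_intergenic_multiplier = fp_intergenic_multiplier,
    p_intergenic_true = p_intergenic_true,
    n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
    subthreshold_fraction = subthreshold_fraction,
    fp_correlation = fp_correlation,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

expand_caller_param <- function(x, callers, what) {
  if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, length(callers)), callers)
  if (is.null(names(x)) || !setequal(names(x), callers))
    stopf("%s must be a scalar or a vector named by caller", what)
  x[callers]
}

validate_sim_config <- function(cfg) {
  if (any(cfg$caller_sensitivity < 0 | cfg$caller_sensitivity > 1))
    stopf("caller_sensitivity must lie in [0, 1]")
  if (any(cfg$caller_fp_rate < 0)) stopf("caller_fp_rate must be non-negative")
  if (cfg$tstv_true <= 0 || cfg$tstv_fp <= 0) stopf("ts/tv targets must be positive")
  if (cfg$n_true_high < 0 || cfg$n_true_low < 0 || cfg$n_common_true < 0)
    stopf("variant counts must be non-negative")
  if (cfg$p_intergenic_true < 0 || cfg$p_intergenic_true > 1 ||
      cfg$subthreshold_fraction < 0 || cfg$subthreshold_fraction > 1 ||
      cfg$fp_correlation < 0 || cfg$fp_correlation > 1)
    stopf("probabilities must lie in [0, 1]")
  cfg
}

# deterministic sub-stream seeds: one master seed, split by labelled context
split_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Simulate the true variant sets and gene annotation
#'
#' Builds a deterministic gene layout (5'UTR, CDS exons with introns, 3'UTR
#' per gene) on the configured genome, then draws the disjoint high-specific,
#' low-specific and common true SNP sets: each variant is intergenic with
#' probability `p_intergenic_true`, substitution types are drawn so the
#' expected transition fraction is tstv_true/(1 + tstv_true), and all
#' positions are distinct. Deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `truth` (data.tables `high_specific`, `low_specific`,
#'   `common` with chrom/pos/ref/alt/key), `annotation` (a `gene_annotation`),
#'   `gene_lists` (candidate-gene id vectors per truth set plus `universe`,
#'   all genes), and `config`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(split_seed(cfg$seed, "truth"))
  annotation <- build_sim_annotation(cfg)
  genes <- annotation$intervals[annotation$intervals$feature == "gene"]

  n_total <- cfg$n_true_high + cfg$n_true_low + cfg$n_common_true
  genic_bp <- sum(genes$end - genes$start + 1)
  if (n_total > 0.5 * sum(cfg$genome$length))
    stopf("genome too small for %d requested variants", n_total)
  if (n_total > 0L && genic_bp == 0L && cfg$p_intergenic_true < 1)
    stopf("annotation has no genes but genic variant placement was requested")

  pos_tab <- draw_positions(n_total, cfg$p_intergenic_true, genes, cfg$genome)
  subst <- draw_substitutions(n_total, cfg$tstv_true)
  tab <- data.table::data.table(chrom = pos_tab$chrom, pos = pos_tab$pos,
                                ref = subst$ref, alt = subst$alt)
  tab[, "key" := variant_keys(tab)]

  idx <- sample.int(n_total)  # random assignment to the three truth sets
  take <- function(k, off) tab[idx[seq_len(k) + off]]
  truth <- list(
    common = take(cfg$n_common_true, 0L),
    high_specific = take(cfg$n_true_high, cfg$n_common_true),
    low_specific = take(cfg$n_true_low, cfg$n_common_true + cfg$n_true_high)
  )

  gene_lists <- lapply(truth, function(t) {
    if (nrow(t) == 0L) character() else candidate_genes(t$key, annotation)$gene_id
  })
  gene_lists$universe <- sort(unique(genes$gene_id))

  list(truth = truth, annotation = annotation, gene_lists = gene_lists,
       config = cfg)
}

# regular gene layout with per-gene jitter: 5'UTR, exons_per_gene CDS exons
# separated by introns, 3'UTR; gene-body interval spans the lot
build_sim_annotation <- function(cfg, utr_len = 200L, exon_len = 300L,
                                 intron_len = 1000L) {
  if (cfg$n_genes == 0L) return(gene_annotation(data.table::data.table()))
  n_chrom <- nrow(cfg$genome)
  body_len <- 2L * utr_len + cfg$exons_per_gene * exon_len +
    (cfg$exons_per_gene - 1L) * intron_len
  chrom_of <- rep(seq_len(n_chrom), length.out = cfg$n_genes)
  rows <- vector("list", cfg$n_genes)
  per_chrom <- tabulate(chrom_of, n_chrom)
  slot_in_chrom <- stats::ave(seq_len(cfg$n_genes), chrom_of, FUN = seq_along)
  for (g in seq_len(cfg$n_genes)) {
    ci <- chrom_of[g]
    chrom <- cfg$genome$chrom[ci]
    pitch <- floor(cfg$genome$length[ci] / (per_chrom[ci] + 1L))
    if (pitch <= body_len + 2L)
      stopf("genome too small for %d genes of span %d bp", cfg$n_genes, body_len)
    jitter <- sample.int(max(1L, pitch - body_len - 1L), 1L)
    start <- (slot_in_chrom[g] - 1L) * pitch + jitter
    gid <- sprintf("GENE%04d", g)
    feats <- list(data.table::data.table(gene_id = gid, chrom = chrom,
                                         start = start, end = start + body_len - 1L,
                                         feature = "gene"))
    cur <- start
    feats <- c(feats, list(data.table::data.table(gene_id = gid, chrom = chrom,
                                                  start = cur, end = cur + utr_len - 1L,
                                                  feature = "5UTR")))
    cur <- cur + utr_len
    for (e in seq_len(cfg$exons_per_gene)) {
      feats <- c(feats, list(data.table::data.table(gene_id = gid, chrom = chrom,
                                                    start = cur, end = cur + exon_len - 1L,
                                                    feature = "CDS")))
      cur <- cur + exon_len + if (e < cfg$exons_per_gene) intron_len else 0L
    }
    feats <- c(feats, list(data.table::data.table(gene_id = gid, chrom = chrom,
                                                  start = cur, end = cur + utr_len - 1L,
                                                  feature = "3UTR")))
    rows[[g]] <- data.table::rbindlist(feats)
  }
  gene_annotation(data.table::rbindlist(rows))
}

# distinct (chrom, pos) draws with an exact genic/intergenic split: the class
# of each variant is drawn first, then positions are generated class-wise
# (genic: uniform within a length-weighted random gene body; intergenic:
# rejection-sampled genome positions outside every gene body), so rejection
# never biases the class mix
draw_positions <- function(n, p_intergenic, genes, genome) {
  if (n == 0L) return(data.table::data.table(chrom = character(), pos = integer()))
  if (nrow(genes) == 0L) p_intergenic <- 1
  n_int <- stats::rbinom(1L, n, p_intergenic)
  n_gen <- n - n_int
  out <- data.table::data.table(chrom = character(), pos = integer(),
                                genic = logical())
  repeat {
    got_gen <- sum(out$genic); got_int <- nrow(out) - got_gen
    if (got_gen >= n_gen && got_int >= n_int) break
    add <- list()
    if (got_gen < n_gen)
      add <- c(add, list(cbind(draw_genic(n_gen - got_gen, genes), genic = TRUE)))
    if (got_int < n_int)
      add <- c(add, list(cbind(draw_intergenic(n_int - got_int, genes, genome),
                               genic = FALSE)))
    out <- unique(data.table::rbindlist(list(out, data.table::rbindlist(add))),
                  by = c("chrom", "pos"))
  }
  out <- data.table::rbindlist(list(out[out$genic][seq_len(n_gen)],
                                    out[!out$genic][seq_len(n_int)]))
  out[sample.int(n), c("chrom", "pos"), with = FALSE]
}

draw_genic <- function(k, genes) {
  if (k == 0L) return(data.table::data.table(chrom = character(), pos = integer()))
  gi <- sample.int(nrow(genes), k, replace = TRUE,
                   prob = genes$end - genes$start + 1)
  data.table::data.table(
    chrom = genes$chrom[gi],
    pos = as.integer(genes$start[gi] +
                       floor(stats::runif(k) * (genes$end[gi] - genes$start[gi] + 1))))
}

draw_intergenic <- function(k, genes, genome) {
  out <- data.table::data.table(chrom = character(), pos = integer())
  if (k == 0L) return(out)
  glen <- genome$length
  ggr <- if (nrow(genes)) GenomicRanges::GRanges(genes$chrom,
                                                 IRanges::IRanges(genes$start, genes$end))
  while (nrow(out) < k) {
    m <- (k - nrow(out)) * 2L + 10L
    ci <- sample.int(length(glen), m, replace = TRUE, prob = glen)
    pos <- 1L + as.integer(floor(stats::runif(m) * glen[ci]))
    chrom <- genome$chrom[ci]
    if (!is.null(ggr)) {
      pgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
      keep <- GenomicRanges::countOverlaps(pgr, ggr) == 0L
      chrom <- chrom[keep]; pos <- pos[keep]
    }
    out <- data.table::rbindlist(list(out, data.table::data.table(chrom = chrom,
                                                                  pos = pos)))
  }
  out[seq_len(k)]
}

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

draw_substitutions <- function(n, tstv) {
  ref <- sample(VALID_BASES, n, replace = TRUE)
  is_ts <- stats::runif(n) < tstv / (1 + tstv)
  alt <- character(n)
  alt[is_ts] <- TRANSITION_PARTNER[ref[is_ts]]
  if (any(!is_ts)) {
    tv_ref <- ref[!is_ts]
    pick <- stats::runif(length(tv_ref)) < 0.5
    other <- ifelse(tv_ref %in% c("A", "G"),
                    ifelse(pick, "C", "T"), ifelse(pick, "A", "G"))
    alt[!is_ts] <- other
  }
  list(ref = ref, alt = unname(alt))
}

#' Simulate one caller's callset for one group
#'
#' Each true variant of the group is detected independently with the caller's
#' sensitivity; false positives are drawn per caller (Poisson count) with the
#' configured FP ts/tv mix and the intergenic placement bias, independent
#' across callers unless `fp_correlation > 0`. Detected calls get QUAL
#' uniform in [30, 100) and DP in 5..60; a `subthreshold_fraction` of calls
#' instead get QUAL below 30 or DP below 5 so threshold filtering has work
#' to do.
#'
#' @param truth result of [simulate_truth()].
#' @param caller caller label (must be in the config).
#' @param group "high" or "low".
#' @param cfg the [sim_config()] (defaults to the one inside `truth`).
#' @return a [callset].
#' @export
simulate_caller <- function(truth, caller, group, cfg = truth$config) {
  if (!caller %in% cfg$callers) stopf("unknown caller label '%s'", caller)
  if (!group %in% c("high", "low")) stopf("group must be 'high' or 'low'")
  set.seed(split_seed(cfg$seed, "caller", caller, group))

  gt <- group_truth(truth, group)
  detected <- gt[stats::runif(nrow(gt)) < cfg$caller_sensitivity[[caller]]]

  fp <- simulate_fp(truth, caller, group, cfg)
  rec <- data.table::rbindlist(list(
    detected[, c("chrom", "pos", "ref", "alt"), with = FALSE], fp))
  rec <- rec[!duplicated(variant_key(rec$chrom, rec$pos, rec$ref, rec$alt))]

  n <- nrow(rec)
  qual <- round(stats::runif(n, 30, 100), 1)
  depth <- sample(5:60, n, replace = TRUE)
  low <- stats::runif(n) < cfg$subthreshold_fraction
  if (any(low)) {
    which_crit <- stats::runif(sum(low)) < 0.5
    li <- which(low)
    qual[li[which_crit]] <- round(stats::runif(sum(which_crit), 0, 29.9), 1)
    depth[li[!which_crit]] <- sample(0:4, sum(!which_crit), replace = TRUE)
  }
  rec[, "qual" := qual]
  rec[, "depth" := as.integer(depth)]
  callset(caller, group, rec)
}

group_truth <- function(truth, group) {
  spec <- if (group == "high") truth$truth$high_specific else truth$truth$low_specific
  data.table::rbindlist(list(truth$truth$common, spec))
}

simulate_fp <- function(truth, caller, group, cfg) {
  n_fp <- stats::rpois(1L, cfg$caller_fp_rate[[caller]])
  if (n_fp == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()))
  q_fp <- min(1, cfg$fp_intergenic_multiplier * cfg$p_intergenic_true)
  genes <- truth$annotation$intervals[truth$annotation$intervals$feature == "gene"]

  n_shared <- stats::rbinom(1L, n_fp, cfg$fp_correlation)
  own <- draw_fp_records(n_fp - n_shared, q_fp, genes, cfg)
  shared <- if (n_shared > 0L) {
    # shared-FP pool: same stream for every caller of the group
    seed_keep <- get(".Random.seed", envir = globalenv())
    set.seed(split_seed(cfg$seed, "fp_pool", group))
    pool <- draw_fp_records(max(50L, n_shared), q_fp, genes, cfg)
    assign(".Random.seed", seed_keep, envir = globalenv())
    pool[seq_len(n_shared)]
  } else own[0L]
  fp <- data.table::rbindlist(list(own, shared))

  truth_keys <- unlist(lapply(truth$truth, `[[`, "key"), use.names = FALSE)
  fp[!variant_key(fp$chrom, fp$pos, fp$ref, fp$alt) %in% truth_keys]
}

draw_fp_records <- function(n, q_fp, genes, cfg) {
  if (n == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()))
  pos_tab <- draw_positions(n, q_fp, genes, cfg$genome)
  subst <- draw_substitutions(n, cfg$tstv_fp)
  data.table::data.table(chrom = pos_tab$chrom, pos = pos_tab$pos,
                         ref = subst$ref, alt = subst$alt)
}

#' Simulate a differential-expression table
#'
#' Draws `n_deg` significant DEG rows: each gene comes from the candidate
#' pool with probability `frac_candidate` and uniformly from the universe
#' otherwise (so `frac_candidate = 0` is the uniform null), with balanced
#' log-fold-change signs and p-values below `alpha`; `n_null` background
#' genes are appended with p-values above `alpha`.
#'
#' @param universe character vector of all gene ids.
#' @param candidates character vector of SNP candidate gene ids.
#' @param cfg a [sim_config()] (used for the seed).
#' @param n_deg number of significant rows.
#' @param frac_candidate probability a DEG gene is candidate-drawn.
#' @param n_null number of non-significant filler rows.
#' @param alpha significance boundary (default 0.01).
#' @return data.table with columns gene_id, logfc, pvalue.
#' @export
simulate_deg <- function(universe, candidates, cfg, n_deg = 200L,
                         frac_candidate = 0.55, n_null = 200L, alpha = 0.01) {
  set.seed(split_seed(cfg$seed, "deg"))
  universe <- unique(as.character(universe))
  candidates <- intersect(unique(as.character(candidates)), universe)
  if (n_deg + n_null > length(universe))
    stopf("requested %d DEG + %d null rows exceed universe of %d genes",
          n_deg, n_null, length(universe))
  if (frac_candidate > 0 && length(candidates) == 0L)
    stopf("no candidate genes available for candidate-enriched draws")

  chosen <- character(0)
  while (length(chosen) < n_deg) {
    need <- n_deg - length(chosen)
    from_cand <- stats::runif(need) < frac_candidate
    draw <- character(need)
    if (any(from_cand)) draw[from_cand] <- sample(candidates, sum(from_cand), replace = TRUE)
    if (any(!from_cand)) draw[!from_cand] <- sample(universe, sum(!from_cand), replace = TRUE)
    chosen <- unique(c(chosen, draw))
  }
  chosen <- chosen[seq_len(n_deg)]

  sign <- sample(rep(c(1, -1), length.out = n_deg))
  deg <- data.table::data.table(
    gene_id = chosen,
    logfc = sign * stats::runif(n_deg, 0.5, 3),
    pvalue = stats::runif(n_deg, 1e-8, alpha * 0.999)
  )
  null_genes <- sample(setdiff(universe, chosen), n_null)
  null <- data.table::data.table(
    gene_id = null_genes,
    logfc = stats::runif(n_null, -0.5, 0.5),
    pvalue = stats::runif(n_null, alpha * 1.1, 1)
  )
  out <- data.table::rbindlist(list(deg, null))
  out[order(out$pvalue)]
}

#' Simulate a complete two-group, multi-caller dataset
#'
#' Convenience wrapper: truth + per-caller callsets for both groups + a DEG
#' table whose candidate pool is the union of both groups' truth-derived
#' candidate genes.
#'
#' @param cfg a [sim_config()].
#' @param deg_frac_candidate passed to [simulate_deg()].
#' @param n_deg,n_null DEG table shape; by default each is 15% of the gene
#'   universe, so the table scales with the simulated annotation.
#' @return list with `truth`, `callsets` (list `high` / `low`, each a list of
#'   [callset]s by caller), `deg`, `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(), deg_frac_candidate = 0.55,
                             n_deg = NULL, n_null = NULL) {
  truth <- simulate_truth(cfg)
  callsets <- lapply(stats::setNames(c("high", "low"), c("high", "low")),
                     function(gr) {
    lapply(stats::setNames(cfg$callers, cfg$callers),
           function(cl) simulate_caller(truth, cl, gr, cfg))
  })
  cand <- unique(c(truth$gene_lists$high_specific, truth$gene_lists$low_specific,
                   truth$gene_lists$common))
  n_universe <- length(truth$gene_lists$universe)
  n_deg <- n_deg %||% max(10L, as.integer(0.15 * n_universe))
  n_null <- n_null %||% max(10L, as.integer(0.15 * n_universe))
  deg <- simulate_deg(truth$gene_lists$universe, cand, cfg,
                      n_deg = n_deg, frac_candidate = deg_frac_candidate,
                      n_null = n_null)
  list(truth = truth, callsets = callsets, deg = deg, config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits per-caller per-group VCFs, the annotation as GFF3, gene lists, the
#' DEG TSV and a truth manifest.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (gr in names(sim$callsets)) {
    for (cl in names(sim$callsets[[gr]])) {
      p <- file.path(dir, sprintf("%s_%s.vcf", gr, cl))
      write_vcf(sim$callsets[[gr]][[cl]], p)
      paths[[sprintf("vcf_%s_%s", gr, cl)]] <- p
    }
  }
  paths$annotation <- file.path(dir, "annotation.gff3")
  write_gff3(sim$truth$annotation, paths$annotation)
  for (nm in names(sim$truth$gene_lists)) {
    p <- file.path(dir, sprintf("genes_%s.txt", nm))
    writeLines(sim$truth$gene_lists[[nm]], p)
    paths[[sprintf("genes_%s", nm)]] <- p
  }
  paths$deg <- file.path(dir, "deg.tsv")
  data.table::fwrite(sim$deg, paths$deg, sep = "\t")
  manifest <- data.table::rbindlist(lapply(names(sim$truth$truth), function(nm) {
    t <- sim$truth$truth[[nm]]
    if (nrow(t) == 0L) return(NULL)
    data.table::data.table(set = nm, t[, c("chrom", "pos", "ref", "alt"), with = FALSE])
  }))
  paths$truth_manifest <- file.path(dir, "truth.tsv")
  data.table::fwrite(manifest, paths$truth_manifest, sep = "\t")
  invisible(paths)
}

#' Write gene annotation as GFF3
#'
#' @param annotation a `gene_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  iv <- annotation$intervals
  type <- c(gene = "gene", CDS = "CDS", `5UTR` = "five_prime_UTR",
            `3UTR` = "three_prime_UTR", exon = "exon")[iv$feature]
  lines <- c("##gff-version 3",
             if (nrow(iv)) paste(iv$chrom, "multicom_sim", type, iv$start, iv$end,
                                 ".", "+", ".",
                                 sprintf("ID=%s_%s_%d;gene_id=%s", iv$gene_id,
                                         iv$feature, seq_len(nrow(iv)), iv$gene_id),
                                 sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
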