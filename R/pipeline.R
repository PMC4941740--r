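#' Build a bare callset from variant keys
#'
#' Used when writing derived key sets (consensus, group-specific) back to
#' VCF: QUAL and DP are unknown at the set level and are emitted as missing.
#'
#' @param keys character vector of canonical keys.
#' @param caller,group labels for the resulting [callset].
#' @return a [callset] with NA qual/depth.
#' @export
keyset_to_callset <- function(keys, caller = "set", group = "all") {
  tab <- parse_variant_keys(keys)
  tab[, "qual" := NA_real_]
  tab[, "depth" := NA_integer_]
  callset(caller, group, tab)
}

#' Default pipeline configuration
#'
#' Thresholds default to the standard values: depth >= 5, quality >= 30,
#' consensus support >= 2 of 3 callers, and 0.01 significance for both
#' enrichment and DEG selection.
#'
#' @param vcfs list with elements `high` and `low`, each a named character
#'   vector caller -> VCF path.
#' @param annotation path to BED/GFF3 gene annotation.
#' @param out_dir output directory.
#' @param qtl_lists named character vector of reference gene-list paths
#'   (optional).
#' @param deg path to a DEG TSV (optional).
#' @param run_metrics path to a run-metrics TSV (optional).
#' @param universe path to a universe gene list; default: all annotation
#'   genes.
#' @param min_depth,min_qual,min_support,enrichment_alpha,deg_alpha
#'   thresholds.
#' @param seed integer seed recorded in the summary.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(vcfs, annotation, out_dir,
                            qtl_lists = NULL, deg = NULL, run_metrics = NULL,
                            universe = NULL,
                            min_depth = 5L, min_qual = 30, min_support = 2L,
                            enrichment_alpha = 0.01, deg_alpha = 0.01,
                            seed = 1L) {
  structure(list(vcfs = vcfs, annotation = annotation, out_dir = out_dir,
                 qtl_lists = qtl_lists, deg = deg, run_metrics = run_metrics,
                 universe = universe,
                 min_depth = min_depth, min_qual = min_qual,
                 min_support = min_support,
                 enrichment_alpha = enrichment_alpha, deg_alpha = deg_alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full candidate-discovery pipeline
#'
#' Executes filter -> consensus (per group) -> ts/tv QC -> group partition ->
#' gene annotation -> QTL-list partition -> DEG overlap -> run-metric
#' summary, writing per-stage artifacts (VCFs, TSVs) and a machine-readable
#' `summary.json` under the configured output directory. Stages whose inputs
#' are not configured (QTL lists, DEG, run metrics) are skipped and recorded
#' as such. Any stage failure raises an error naming the stage; artifacts of
#' completed stages are retained.
#'
#' @param cfg a [pipeline_config()].
#' @return the summary list, invisibly; also written as JSON.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(config = cfg[setdiff(names(cfg), "vcfs")],
                  vcfs = cfg$vcfs, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  annotation <- stage("genes", load_annotation(cfg$annotation))

  groups <- list()
  for (gr in c("high", "low")) {
    paths <- cfg$vcfs[[gr]]
    if (is.null(paths) || length(paths) < 2L)
      stopf("pipeline stage 'filter' failed: need >= 2 caller VCFs for group '%s'", gr)
    filtered <- stage("filter", lapply(seq_along(paths), function(i) {
      cs <- read_vcf(paths[[i]], caller = names(paths)[i] %||% NULL, group = gr)
      filter_callset(cs, cfg$min_depth, cfg$min_qual)
    }))
    cons <- stage("consensus", multicom(filtered, cfg$min_support))
    qc <- stage("tstv", consensus_tstv_qc(cons, annotation, gr))
    write_vcf(keyset_to_callset(cons$shared, "multicom", gr),
              file.path(cfg$out_dir, sprintf("%s_shared.vcf", gr)))
    groups[[gr]] <- list(consensus = cons, qc = qc)
    summary$stages[[paste0("consensus_", gr)]] <- list(
      per_tool_total = as.list(cons$per_tool_total),
      shared = length(cons$shared),
      tool_specific = lapply(cons$tool_specific, length),
      discovery_gain = as.list(round(discovery_gain(cons), 4)),
      tstv = qc)
  }

  part <- stage("groupdiff", partition_groups(groups$high$consensus,
                                              groups$low$consensus))
  for (nm in c("specific_high", "specific_low", "common")) {
    write_vcf(keyset_to_callset(part[[nm]], nm),
              file.path(cfg$out_dir, sprintf("%s.vcf", nm)))
  }
  summary$stages$group_partition <- list(
    n_specific_high = length(part$specific_high),
    n_specific_low = length(part$specific_low),
    n_common = length(part$common),
    pct_specific_high = part$pct_specific_high,
    pct_specific_low = part$pct_specific_low)

  genes <- stage("genes", list(
    high = candidate_genes(part$specific_high, annotation),
    low = candidate_genes(part$specific_low, annotation),
    common = candidate_genes(part$common, annotation)))
  # keep the three gene categories disjoint, mirroring the SNP-set partition:
  # a gene hit by both groups' specific SNPs moves to the common category
  both <- intersect(genes$high$gene_id, genes$low$gene_id)
  common_set <- union(genes$common$gene_id, both)
  gsets <- list(high = setdiff(genes$high$gene_id, common_set),
                low = setdiff(genes$low$gene_id, common_set),
                common = common_set)
  for (nm in names(gsets)) {
    writeLines(sort(gsets[[nm]]), file.path(cfg$out_dir, sprintf("genes_%s.txt", nm)))
  }
  summary$stages$candidate_genes <- lapply(gsets, length)

  universe <- if (!is.null(cfg[["universe"]])) read_gene_list(cfg[["universe"]])
              else unique(annotation$intervals$gene_id)

  if (!is.null(cfg[["qtl_lists"]])) {
    qtl <- stage("qtl_partition", lapply(names(cfg[["qtl_lists"]]), function(nm) {
      ref <- read_gene_list(cfg[["qtl_lists"]][[nm]])
      p <- partition_reference(genes$high$gene_id, genes$low$gene_id, ref,
                               reference_name = nm)
      list(reference = nm, reference_size = p$total_overlap + length(p$absent),
           common = length(p$common), high_only = length(p$high_only),
           low_only = length(p$low_only), absent = length(p$absent),
           total_overlap = p$total_overlap)
    }))
    summary$stages$qtl_partition <- qtl
  } else summary$stages$qtl_partition <- "skipped (no reference lists)"

  if (!is.null(cfg[["deg"]])) {
    degs <- stage("deg_overlap", load_deg(cfg[["deg"]], alpha = cfg$deg_alpha))
    rep <- stage("deg_overlap",
                 overlap_deg(degs, gsets$low, gsets$high, gsets$common, universe))
    summary$stages$deg_overlap <- list(
      n_deg = rep$n_deg, n_up = rep$n_up, n_down = rep$n_down,
      total_overlap = rep$total_overlap,
      overlap_fraction = rep$overlap_fraction,
      categories = as.data.frame(rep$categories))
  } else summary$stages$deg_overlap <- "skipped (no DEG table)"

  if (!is.null(cfg[["run_metrics"]])) {
    summary$stages$run_summary <- as.list(
      stage("summarize", summarize_runs(read_run_metrics(cfg[["run_metrics"]]))))
  } else summary$stages$run_summary <- "skipped (no run metrics)"

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(summary)
}

consensus_tstv_qc <- function(cons, annotation, group) {
  shared_r <- tstv_ratio(cons$shared, label = "shared", group = group)
  spec <- lapply(names(cons$tool_specific), function(cl) {
    keys <- cons$tool_specific[[cl]]
    if (length(keys) == 0L) return(NULL)
    r <- tstv_ratio(keys, label = paste0(cl, "-specific"), group = group)
    comp <- region_composition(keys, annotation, label = r$label, group = group)
    list(label = r$label, ts = r$ts, tv = r$tv, ratio = r$ratio,
         intergenic_fraction = comp$intergenic_fraction)
  })
  shared_comp <- region_composition(cons$shared, annotation,
                                    label = "shared", group = group)
  list(shared = list(ts = shared_r$ts, tv = shared_r$tv, ratio = shared_r$ratio,
                     intergenic_fraction = shared_comp$intergenic_fraction),
       tool_specific = Filter(Negate(is.null), spec))
}
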