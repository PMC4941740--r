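test_that("simulate_truth is deterministic and honors its seed", {
  cfg <- small_sim_config(seed = 5L)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_equal(t1$truth, t2$truth)
  expect_equal(t1$annotation$intervals, t2$annotation$intervals)
  t3 <- simulate_truth(small_sim_config(seed = 6L))
  expect_false(identical(t1$truth$common$key, t3$truth$common$key))
})

test_that("truth sets are disjoint, sized as configured, with valid SNPs", {
  cfg <- small_sim_config(seed = 7L)
  tr <- simulate_truth(cfg)
  expect_equal(nrow(tr$truth$high_specific), 160L)
  expect_equal(nrow(tr$truth$low_specific), 240L)
  expect_equal(nrow(tr$truth$common), 600L)
  keys <- c(tr$truth$high_specific$key, tr$truth$low_specific$key,
            tr$truth$common$key)
  expect_false(anyDuplicated(keys) > 0)
  all_t <- data.table::rbindlist(tr$truth)
  expect_true(all(all_t$ref != all_t$alt))
  expect_true(all(all_t$ref %in% c("A", "C", "G", "T")))

  zero <- small_sim_config(seed = 7L)
  zero$n_true_high <- 0L
  expect_equal(nrow(simulate_truth(zero)$truth$high_specific), 0L)
})

test_that("true ts/tv lands within 3 SE of the configured 2.6 at n = 50,000", {
  cfg <- sim_config(n_true_high = 0L, n_true_low = 0L, n_common_true = 50000L,
                    n_genes = 200L, seed = 13L)
  tr <- simulate_truth(cfg)
  r <- tstv_ratio(tr$truth$common$key)
  p_target <- 2.6 / 3.6
  se <- sqrt(p_target * (1 - p_target) / 50000)
  p_obs <- r$ts / r$n
  expect_lt(abs(p_obs - p_target), 3 * se)
})

test_that("simulate_caller edge cases: perfect, blind, unknown", {
  cfg <- small_sim_config(seed = 9L, caller_sensitivity = 1, caller_fp_rate = 0,
                          subthreshold_fraction = 0)
  tr <- simulate_truth(cfg)
  cs <- simulate_caller(tr, "samtools", "high")
  expect_setequal(variant_keys(cs),
                  c(tr$truth$common$key, tr$truth$high_specific$key))
  expect_true(all(cs$records$qual >= 30 & cs$records$depth >= 5))

  blind <- small_sim_config(seed = 9L, caller_sensitivity = 0, caller_fp_rate = 0)
  trb <- simulate_truth(blind)
  expect_equal(length(simulate_caller(trb, "samtools", "high")), 0L)

  expect_error(simulate_caller(tr, "gatk", "high"), "unknown caller")
  expect_error(simulate_caller(tr, "samtools", "mid"), "group")
})

test_that("false positives carry the configured ts/tv and intergenic bias", {
  cfg <- small_sim_config(seed = 15L, caller_sensitivity = 0,
                          caller_fp_rate = 4000)
  tr <- simulate_truth(cfg)
  fp_cs <- simulate_caller(tr, "varscan", "high")  # pure FP callset
  r <- tstv_ratio(fp_cs)
  p_fp <- 1.8 / 2.8
  se <- sqrt(p_fp * (1 - p_fp) / length(fp_cs))
  expect_lt(abs(r$ts / r$n - p_fp), 3 * se)

  comp <- region_composition(variant_keys(fp_cs), tr$annotation)
  # q_fp = 2 x 0.3 = 0.6 by default
  se_q <- sqrt(0.6 * 0.4 / length(fp_cs))
  expect_lt(abs(comp$intergenic_fraction - 0.6), 3 * se_q)
})

test_that("subthreshold fraction exercises the depth/quality filter", {
  cfg <- small_sim_config(seed = 17L, subthreshold_fraction = 0.3)
  tr <- simulate_truth(cfg)
  cs <- simulate_caller(tr, "freebayes", "low")
  kept <- filter_callset(cs)
  frac_removed <- 1 - length(kept) / length(cs)
  expect_gt(frac_removed, 0.2)
  expect_lt(frac_removed, 0.4)
})

test_that("simulate_deg controls the candidate share of DEG", {
  cfg <- small_sim_config(seed = 19L)
  universe <- sprintf("GENE%04d", 1:80)
  candidates <- universe[1:20]

  # enrichment fraction 1 with candidates covering the draw: full overlap
  full <- simulate_deg(universe, candidates, cfg, n_deg = 15, n_null = 10,
                       frac_candidate = 1)
  deg_full <- load_deg(full)
  expect_equal(nrow(deg_full), 15L)
  expect_true(all(deg_full$gene_id %in% candidates))

  # enrichment fraction 0: uniform draw, overlap near the candidate share
  reps <- 40
  fracs <- vapply(seq_len(reps), function(i) {
    cfg_i <- small_sim_config(seed = 1000L + i)
    d <- load_deg(simulate_deg(universe, candidates, cfg_i, n_deg = 20,
                               n_null = 5, frac_candidate = 0))
    mean(d$gene_id %in% candidates)
  }, numeric(1))
  share <- length(candidates) / length(universe)
  se <- sqrt(share * (1 - share) / (reps * 20))
  expect_lt(abs(mean(fracs) - share), 4 * se)

  # determinism: same seed, byte-identical table
  expect_equal(simulate_deg(universe, candidates, cfg, n_deg = 15, n_null = 10),
               simulate_deg(universe, candidates, cfg, n_deg = 15, n_null = 10))
  expect_error(simulate_deg(universe[1:5], candidates[1:2], cfg,
                            n_deg = 10, n_null = 10),
               "exceed")
})

test_that("independent errors make the consensus beat every single caller", {
  sim <- simulate_dataset(small_sim_config(seed = 23L))
  truth_high <- c(sim$truth$truth$common$key, sim$truth$truth$high_specific$key)
  filtered <- lapply(sim$callsets$high, filter_callset)
  res <- multicom(filtered, 2)
  prec_mc <- mean(res$shared %in% truth_high)
  prec_single <- vapply(filtered, function(cs)
    mean(variant_keys(cs) %in% truth_high), numeric(1))
  expect_true(all(prec_mc > prec_single))
})

test_that("correlated false positives defeat the consensus filter", {
  mk <- function(rho) {
    cfg <- small_sim_config(seed = 29L, fp_correlation = rho,
                            caller_fp_rate = 120)
    tr <- simulate_truth(cfg)
    truth_high <- c(tr$truth$common$key, tr$truth$high_specific$key)
    css <- lapply(stats::setNames(cfg$callers, cfg$callers),
                  function(cl) simulate_caller(tr, cl, "high", cfg))
    res <- multicom(css, 2)
    mean(res$shared %in% truth_high)
  }
  expect_gt(mk(0), mk(1))  # shared FP pool leaks through the 2-of-3 rule
})

test_that("write_simulation emits a complete, readable file set", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(small_sim_config(seed = 31L), n_deg = 30, n_null = 30)
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(unlist(paths))))
  # VCF round trip
  back <- read_vcf(paths$vcf_high_samtools, caller = "samtools", group = "high")
  expect_equal(sort(variant_keys(back)),
               sort(variant_keys(sim$callsets$high$samtools)))
  # GFF3 round trip through the rtracklayer reader
  ann <- load_annotation(paths$annotation)
  sort_iv <- function(x) {
    as.data.frame(x[base::order(x$chrom, x$start, x$feature, x$end), ])
  }
  expect_equal(sort_iv(ann$intervals),
               sort_iv(sim$truth$annotation$intervals), ignore_attr = TRUE)
  deg <- load_deg(paths$deg)
  expect_gt(nrow(deg), 0L)
})
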