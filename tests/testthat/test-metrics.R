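stats_fixture <- function(...) {
  args <- utils::modifyList(list(
    total_raw_reads = 1e6, merged_filtered_reads = 1e4,
    mapped_pre_dedup = 50, unique_mapped = 40,
    avg_mapped_read_length = 50, library_molecules = 1e6,
    mg_input = 50, extract_ul_total = 100, extract_ul_used = 20,
    target_genome_length = 1e4), list(...))
  do.call(library_stats, args)
}

test_that("recovery metric formulas match hand arithmetic", {
  tol <- 1e-9
  s <- stats_fixture(mapped_pre_dedup = 50, merged_filtered_reads = 1e4)
  expect_equal(prop_mammoth_dna(s), 0.005, tolerance = tol)

  expect_equal(enrichment_factor(0.5, 0.001), 500, tolerance = tol)

  s <- stats_fixture(library_molecules = 1e6, unique_mapped = 100,
                     mapped_pre_dedup = 100,
                     merged_filtered_reads = 1e4, mg_input = 50)
  expect_equal(informative_per_mg(s), 200, tolerance = tol)

  # molecules 1e6, prop 0.01, len 50, genome 1e4, 100/20 uL, 50 mg
  s <- stats_fixture(library_molecules = 1e6, mapped_pre_dedup = 100,
                     merged_filtered_reads = 1e4,
                     avg_mapped_read_length = 50,
                     target_genome_length = 1e4, extract_ul_total = 100,
                     extract_ul_used = 20, mg_input = 50)
  expect_equal(coverage_per_50mg(s), 250, tolerance = tol)

  s <- stats_fixture(unique_mapped = 1000, avg_mapped_read_length = 50,
                     total_raw_reads = 1e6, mg_input = 10,
                     mapped_pre_dedup = 1000)
  expect_equal(cost_effectiveness(s), 5000, tolerance = tol)

  s <- stats_fixture(unique_mapped = 1000, mapped_pre_dedup = 1000,
                     avg_mapped_read_length = 50,
                     target_genome_length = 1e4)
  expect_equal(mean_coverage(s), 5, tolerance = tol)
})

test_that("metrics vanish with their numerators and scale as ratios", {
  z <- stats_fixture(mapped_pre_dedup = 0, unique_mapped = 0)
  expect_equal(prop_mammoth_dna(z), 0)
  expect_equal(informative_per_mg(z), 0)
  expect_equal(coverage_per_50mg(z), 0)
  expect_equal(cost_effectiveness(z), 0)
  expect_equal(mean_coverage(z), 0)

  s1 <- stats_fixture(mg_input = 25)
  s2 <- stats_fixture(mg_input = 50)
  expect_equal(informative_per_mg(s1), 2 * informative_per_mg(s2))

  s3 <- stats_fixture(extract_ul_total = 200)
  expect_equal(coverage_per_50mg(s3), 2 * coverage_per_50mg(stats_fixture()))

  # doubling unique and raw together leaves cost-effectiveness unchanged
  s4 <- stats_fixture(unique_mapped = 80, mapped_pre_dedup = 100,
                      total_raw_reads = 2e6)
  s5 <- stats_fixture(unique_mapped = 40, mapped_pre_dedup = 100,
                      total_raw_reads = 1e6)
  expect_equal(cost_effectiveness(s4), cost_effectiveness(s5))

  expect_equal(enrichment_factor(0.3, 0.3), 1)
})

test_that("undefined metric states propagate as NA, never silent zero", {
  s <- stats_fixture(merged_filtered_reads = 0, mapped_pre_dedup = 0,
                     unique_mapped = 0)
  expect_true(is.na(prop_mammoth_dna(s)))
  expect_true(is.na(informative_per_mg(s)))
  expect_true(is.na(coverage_per_50mg(s)))
  expect_true(is.na(enrichment_factor(0.5, 0)))
  ms <- metric_set(s)
  expect_true(is.na(ms$prop_mammoth_dna))
  expect_false(identical(ms$prop_mammoth_dna, 0))
})

test_that("library_stats enforces its invariants", {
  expect_error(stats_fixture(unique_mapped = 100, mapped_pre_dedup = 50),
               "exceed")
  expect_error(stats_fixture(extract_ul_used = 200), "exceed")
  expect_error(stats_fixture(target_genome_length = 0), "positive")
  expect_error(stats_fixture(total_raw_reads = -1), "non-negative")
})

test_that("formula mean coverage agrees with pileup mean depth", {
  ref <- small_reference()
  cfg <- simulation_config(endogenous_fraction = 1, mito_fraction = 1,
                           duplicate_fraction = 0, damage_5p_ct_rate = 0,
                           n_haplotype_variants = 0, seed = 12)
  lib <- simulate_library(ref, cfg, 1000)
  pu <- build_pileup(lib$reads, ref$mito, ref_label = "mito")
  formula_cov <- mean_coverage(lib$stats)
  # agreement up to integer rounding of fragment lengths in the simulator
  expect_equal(mean(pu$depth), formula_cov, tolerance = 0.02)
})

test_that("enrichment factor recovers the configured capture multiplier", {
  ref <- small_reference()
  base <- list(endogenous_fraction = 0.5, mito_fraction = 0.001,
               duplicate_fraction = 0)
  shot_cfg <- do.call(simulation_config, c(base, seed = 61))
  cap_cfg <- do.call(simulation_config,
                     c(base, capture_on_target_multiplier = 400, seed = 62))
  n <- 4e5
  shot <- simulate_library(ref, shot_cfg, n)
  cap <- simulate_library(ref, cap_cfg, n)
  mito_prop <- function(lib) {
    sum(lib$reads$ref_label == "mito" & !lib$reads$duplicate_flag) /
      lib$stats$merged_filtered_reads
  }
  est <- enrichment_factor(mito_prop(cap), mito_prop(shot))
  # shotgun on-target counts are small, so allow generous sampling error
  expect_gt(est, 200)
  expect_lt(est, 800)
})

test_that("compute_metrics maps a manifest to one row per library", {
  manifest <- data.frame(sample_id = c("a", "b"),
                         total_raw_reads = c(1e6, 1e6),
                         merged_filtered_reads = c(1e4, 0),
                         mapped_pre_dedup = c(50, 0),
                         unique_mapped = c(40, 0),
                         avg_mapped_read_length = c(50, 0),
                         library_molecules = 1e6, mg_input = 50,
                         extract_ul_total = 100, extract_ul_used = 20,
                         target_genome_length = 1e4)
  out <- compute_metrics(manifest)
  expect_equal(nrow(out), 2)
  expect_equal(out$prop_mammoth_dna[1], 0.005)
  expect_true(is.na(out$prop_mammoth_dna[2]))
})
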