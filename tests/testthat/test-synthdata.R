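test_that("reference simulation honors lengths, alphabet and seeds", {
  ref <- simulate_reference_set(10000, 50000, seed = 1)
  expect_equal(nchar(ref$mito), 10000)
  expect_equal(nchar(ref$nuclear$chrX), 50000)
  expect_equal(nchar(ref$nuclear$chr8), 50000)
  expect_true(ref$circular)
  expect_true(all(strsplit(ref$mito, "")[[1]] %in% c("A", "C", "G", "T")))

  ref2 <- simulate_reference_set(10000, 50000, seed = 1)
  expect_identical(ref, ref2)
  ref3 <- simulate_reference_set(10000, 50000, seed = 2)
  expect_false(identical(ref$mito, ref3$mito))

  expect_error(simulate_reference_set(500, 50000, seed = 1), "1000")
  expect_error(simulate_reference_set(10000, 50000, seed = 1,
                                      chr8_length = 30000), "20%")
})

test_that("library simulation recovers the configured endogenous fraction", {
  ref <- small_reference()
  f <- 0.2
  cfg <- simulation_config(endogenous_fraction = f, duplicate_fraction = 0,
                           seed = 11)
  lib <- simulate_library(ref, cfg, 2e4)
  prop <- lib$stats$mapped_pre_dedup / lib$stats$merged_filtered_reads
  se <- sqrt(f * (1 - f) / lib$stats$merged_filtered_reads)
  expect_lt(abs(prop - f), 3 * se)
  # with no duplicates, the formula-level proportion matches too
  expect_equal(prop_mammoth_dna(lib$stats), prop)
})

test_that("zero endogenous fraction yields an empty alignment table", {
  ref <- small_reference()
  cfg <- simulation_config(endogenous_fraction = 0, seed = 3)
  lib <- simulate_library(ref, cfg, 5000)
  expect_equal(nrow(lib$reads), 0)
  expect_equal(lib$stats$mapped_pre_dedup, 0)
  expect_equal(lib$stats$unique_mapped, 0)
})

test_that("library statistics respect the count ordering invariant", {
  ref <- small_reference()
  for (f in c(0.01, 0.5, 1)) {
    cfg <- simulation_config(endogenous_fraction = f, seed = 5)
    s <- simulate_library(ref, cfg, 5000)$stats
    expect_lte(s$unique_mapped, s$mapped_pre_dedup)
    expect_lte(s$mapped_pre_dedup, s$merged_filtered_reads)
    expect_lte(s$merged_filtered_reads, s$total_raw_reads)
  }
})

test_that("simulation is bit-reproducible for a fixed seed", {
  ref <- small_reference()
  cfg <- simulation_config(endogenous_fraction = 0.3, seed = 99)
  a <- simulate_library(ref, cfg, 3000)
  b <- simulate_library(ref, cfg, 3000)
  expect_identical(a, b)
})

test_that("X dosage drives the chrX:chr8 count ratio by sex", {
  ref <- small_reference()
  for (sex in c("M", "F")) {
    cfg <- simulation_config(true_sex = sex, endogenous_fraction = 0.9,
                             mito_fraction = 0, duplicate_fraction = 0,
                             seed = if (sex == "M") 21 else 22)
    lib <- simulate_library(ref, cfg, 1.2e5)
    n <- count_xy_reads(lib$reads)
    expected <- if (sex == "M") 0.5 else 1
    # binomial SE on the ratio via the delta method
    se <- (n[["n_x"]] / n[["n_8"]]) * sqrt(1 / n[["n_x"]] + 1 / n[["n_8"]])
    expect_lt(abs(n[["n_x"]] / n[["n_8"]] - expected), 3 * se)
  }
})

test_that("injected terminal damage is recovered by the profiler", {
  ref <- small_reference()
  cfg <- simulation_config(endogenous_fraction = 1, mito_fraction = 1,
                           duplicate_fraction = 0,
                           damage_5p_ct_rate = c(0.3, 0),
                           n_haplotype_variants = 0, seed = 31)
  lib <- simulate_library(ref, cfg, 2e4)
  dp <- damage_profile(lib$reads, ref$mito, 4)
  se1 <- sqrt(0.3 * 0.7 / dp$ct_5p_n[1])
  expect_lt(abs(dp$ct_5p[1] - 0.3), 3 * se1)
  expect_lt(abs(dp$ga_3p[1] - 0.3), 3 * sqrt(0.3 * 0.7 / dp$ga_3p_n[1]))
  expect_equal(dp$ct_5p[2:4], rep(0, 3))
  expect_equal(dp$ga_3p[2:4], rep(0, 3))
})

test_that("config validation rejects out-of-range damage and fractions", {
  expect_error(simulation_config(endogenous_fraction = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(damage_5p_ct_rate = c(0.05, 0.2)),
               "maximum")
  expect_error(simulation_config(fragment_length_mean = 20), ">= 30")
  expect_error(simulation_config(capture_on_target_multiplier = 0.5), ">= 1")
})

test_that("paired substrate simulation applies fold and length shift", {
  ref <- small_reference()
  base <- simulation_config(endogenous_fraction = 0.01,
                            duplicate_fraction = 0)

  # null case: no fold, no shift -> paired differences center on zero
  null_pairs <- simulate_paired_substrates(ref, base, 1, 0, n_pairs = 6,
                                           n_reads = 2e4, seed = 41)
  dprop <- vapply(null_pairs, function(p) {
    prop_mammoth_dna(p$cementum$stats) - prop_mammoth_dna(p$dentin$stats)
  }, numeric(1))
  expect_lt(abs(mean(dprop)), 3 * sd(dprop) / sqrt(length(dprop)))

  pairs <- simulate_paired_substrates(ref, base, 30, 10, n_pairs = 4,
                                      n_reads = 4e4, seed = 42)
  # emitted truth: cementum endogenous fraction = 30x dentin
  folds <- vapply(pairs, function(p) {
    p$cementum$truth$true_endogenous_fraction /
      p$dentin$truth$true_endogenous_fraction
  }, numeric(1))
  expect_equal(folds, rep(30, 4))
  # measured mapped-length difference ~ +10 bp
  dlen <- vapply(pairs, function(p) {
    p$cementum$stats$avg_mapped_read_length -
      p$dentin$stats$avg_mapped_read_length
  }, numeric(1))
  expect_lt(abs(mean(dlen) - 10), 2.5)
  # measured proportion fold across pairs ~ 30
  mfold <- vapply(pairs, function(p) {
    prop_mammoth_dna(p$cementum$stats) / prop_mammoth_dna(p$dentin$stats)
  }, numeric(1))
  expect_lt(abs(mean(mfold) - 30), 6)

  expect_error(simulate_paired_substrates(ref, base, 0, 0, 2), "fold")
})
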