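#' Pipeline run configuration
#'
#' Assembles the knobs of a full demonstration run: simulator geometry,
#' cohort sizes, and the processing thresholds (2-bp terminal trim,
#' depth-3 / strict-majority consensus, >90% completeness filter, >100
#' read sexing floor). The configuration round-trips losslessly through
#' YAML via [write_run_config()] / [read_run_config()].
#'
#' @param seed Master seed; all per-sample seeds derive from it.
#' @param mito_length,chr_length Reference lengths (bp).
#' @param n_pairs Dentin/cementum specimen pairs to simulate.
#' @param pair_fold,pair_length_shift Cementum endogenous fold change and
#'   fragment-length shift (bp).
#' @param n_sex_samples Libraries simulated for sexing (alternating M/F).
#' @param n_capture_samples mtDNA-capture libraries for consensus calling.
#' @param n_reads_pair,n_reads_sex,n_reads_capture Raw reads per library
#'   in each arm.
#' @param endogenous_dentin Baseline dentin endogenous fraction.
#' @param endogenous_sex,endogenous_capture Endogenous fractions of the
#'   sexing and capture arms.
#' @param capture_multiplier On-target fold increase of the capture arm.
#' @param trim_bp,min_depth,majority,completeness_threshold,sex_min_reads
#'   Processing thresholds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       mito_length = 10000,
                       chr_length = 50000,
                       n_pairs = 4,
                       pair_fold = 30,
                       pair_length_shift = 10,
                       n_sex_samples = 8,
                       n_capture_samples = 3,
                       n_reads_pair = 20000,
                       n_reads_sex = 20000,
                       n_reads_capture = 40000,
                       endogenous_dentin = 0.01,
                       endogenous_sex = 0.05,
                       endogenous_capture = 0.10,
                       capture_multiplier = 500,
                       trim_bp = 2,
                       min_depth = 3,
                       majority = 0.5,
                       completeness_threshold = 90,
                       sex_min_reads = 100) {
  cfg <- as.list(environment())
  stopifnot(cfg$trim_bp >= 0, cfg$min_depth > 0, cfg$majority > 0,
            cfg$completeness_threshold > 0, cfg$sex_min_reads > 0)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full simulated analysis pipeline
#'
#' Orchestrates simulate -> trim/dedup/pileup -> metrics -> consensus ->
#' sexing -> stats and writes all artifacts into `outdir`: the library
#' manifest and metrics tables, consensus FASTA, sex-call table, a
#' statistics report (paired substrate tests across the five recovery
#' metrics, fold differences in both estimators, and the cohort sex-ratio
#' binomial test), and a provenance record (seed, config hash, package
#' version) sufficient to reproduce the run. Outputs are byte-identical
#' across runs with the same configuration.
#'
#' @param cfg A [run_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages (logged to stderr).
#' @return Invisibly, a list with the in-memory results (`manifest`,
#'   `metrics`, `consensus`, `passing`, `sex_calls`, `paired_tests`,
#'   `sex_test`, `files`).
#' @export
run_pipeline <- function(cfg, outdir, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[tuskDNA] ", sprintf(...))

  say("simulating references (seed %d)", cfg$seed)
  ref <- simulate_reference_set(cfg$mito_length, cfg$chr_length,
                                seed = cfg$seed)

  # --- substrate-comparison arm -------------------------------------------
  say("simulating %d dentin/cementum pairs", cfg$n_pairs)
  base_cfg <- simulation_config(endogenous_fraction = cfg$endogenous_dentin)
  pairs <- simulate_paired_substrates(ref, base_cfg, cfg$pair_fold,
                                      cfg$pair_length_shift, cfg$n_pairs,
                                      n_reads = cfg$n_reads_pair,
                                      seed = child_seed(cfg$seed, 1L))
  pair_libs <- unlist(lapply(pairs, function(p) list(p$dentin, p$cementum)),
                      recursive = FALSE)

  # --- sexing arm ----------------------------------------------------------
  say("simulating %d libraries for sexing", cfg$n_sex_samples)
  sex_libs <- lapply(seq_len(cfg$n_sex_samples), function(i) {
    sc <- simulation_config(
      true_sex = if (i %% 2 == 1) "M" else "F",
      endogenous_fraction = cfg$endogenous_sex,
      seed = child_seed(cfg$seed, 100L + i))
    simulate_library(ref, sc, cfg$n_reads_sex, sprintf("SEX%03d", i))
  })

  # --- capture/consensus arm ----------------------------------------------
  say("simulating %d mtDNA-capture libraries", cfg$n_capture_samples)
  cap_libs <- lapply(seq_len(cfg$n_capture_samples), function(i) {
    sc <- simulation_config(
      endogenous_fraction = cfg$endogenous_capture,
      capture_on_target_multiplier = cfg$capture_multiplier,
      seed = child_seed(cfg$seed, 200L + i))
    simulate_library(ref, sc, cfg$n_reads_capture, sprintf("CAP%03d", i))
  })

  libs <- c(pair_libs, sex_libs, cap_libs)
  manifest <- do.call(rbind, lapply(libs, function(l) {
    cbind(data.frame(sample_id = l$truth$sample_id,
                     material = l$truth$substrate,
                     true_sex = l$truth$true_sex,
                     true_endogenous_fraction = l$truth$true_endogenous_fraction),
          as.data.frame(unclass(l$stats)))
  }))

  say("computing recovery metrics")
  metrics <- compute_metrics(manifest)

  say("calling consensus sequences")
  consensus <- lapply(cap_libs, function(l) {
    reads <- l$reads[l$reads$ref_label == "mito", , drop = FALSE]
    reads <- deduplicate(trim_terminal(reads, cfg$trim_bp), "position")
    call_consensus(build_pileup(reads, l$truth$true_mito_haplotype),
                   min_depth = cfg$min_depth, majority = cfg$majority)
  })
  names(consensus) <- vapply(cap_libs, function(l) l$truth$sample_id,
                             character(1))
  passing <- completeness_filter(consensus, cfg$completeness_threshold)

  say("sexing %d libraries", length(sex_libs))
  sex_calls <- do.call(rbind, lapply(sex_libs, function(l) {
    reads <- deduplicate(l$reads, "position")
    n <- count_xy_reads(reads)
    sc <- sex_ratio_call(n[["n_x"]], n[["n_8"]],
                         nchar(ref$nuclear$chrX), nchar(ref$nuclear$chr8),
                         min_reads = cfg$sex_min_reads)
    data.frame(sample_id = l$truth$sample_id, true_sex = l$truth$true_sex,
               n_x = sc$n_x, n_8 = sc$n_8, ratio = sc$ratio, se = sc$se,
               call = sc$call)
  }))

  say("running substrate and sex-ratio statistics")
  dentin_stats <- lapply(pairs, function(p) p$dentin$stats)
  cementum_stats <- lapply(pairs, function(p) p$cementum$stats)
  metric_fns <- list(
    informative_per_mg = informative_per_mg,
    prop_mammoth_dna = prop_mammoth_dna,
    avg_length = function(s) s$avg_mapped_read_length,
    coverage_per_50mg = coverage_per_50mg,
    cost_effectiveness = cost_effectiveness
  )
  paired_tests <- do.call(rbind, lapply(names(metric_fns), function(m) {
    a <- vapply(dentin_stats, metric_fns[[m]], numeric(1))
    b <- vapply(cementum_stats, metric_fns[[m]], numeric(1))
    # the paired t needs at least two specimens
    tt <- if (length(a) >= 2 && !anyNA(a) && !anyNA(b)) paired_t(a, b)
          else NULL
    fd <- fold_difference(a, b)
    data.frame(metric = m,
               t = if (is.null(tt)) NA_real_ else tt$statistic,
               p_value = if (is.null(tt)) NA_real_ else tt$p_value,
               shapiro_p = if (is.null(tt) || is.null(tt$shapiro)) NA_real_
                           else tt$shapiro$p_value,
               fold_mean_of_ratios = fd[["mean_of_ratios"]],
               fold_ratio_of_means = fd[["ratio_of_means"]])
  }))
  n_m <- sum(sex_calls$call == "male")
  n_f <- sum(sex_calls$call == "female")
  sex_test <- if (n_m + n_f > 0) binomial_two_tailed(n_m, n_m + n_f) else NULL

  files <- c(
    manifest = file.path(outdir, "manifest.tsv"),
    metrics = file.path(outdir, "metrics.tsv"),
    consensus = file.path(outdir, "consensus.fasta"),
    sex = file.path(outdir, "sex_calls.tsv"),
    stats = file.path(outdir, "stats_report.tsv"),
    config = file.path(outdir, "config.yaml"),
    provenance = file.path(outdir, "provenance.json")
  )
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(manifest, files[["manifest"]])
  write_tsv(render_undefined(metrics), files[["metrics"]])
  write_consensus_fasta(consensus, files[["consensus"]])
  write_tsv(sex_calls, files[["sex"]])
  report <- render_undefined(paired_tests)
  write_tsv(report, files[["stats"]])
  write_run_config(cfg, files[["config"]])
  prov <- list(
    package = "tuskDNA",
    version = as.character(utils::packageVersion("tuskDNA")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(files[["config"]])),
    n_libraries = nrow(manifest),
    consensus_passing = as.list(passing),
    sex_ratio_p = if (is.null(sex_test)) NULL else sex_test$p_value
  )
  jsonlite::write_json(prov, files[["provenance"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: %d libraries, %d/%d consensus passing, sex ratio %d:%d",
      nrow(manifest), length(passing), length(consensus), n_m, n_f)

  invisible(list(manifest = manifest, metrics = metrics,
                 consensus = consensus, passing = passing,
                 sex_calls = sex_calls, paired_tests = paired_tests,
                 sex_test = sex_test, files = files))
}

# render NA metric cells as the literal "undefined", as in sample reports
render_undefined <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && anyNA(df[[j]])) {
      x <- as.character(df[[j]])
      x[is.na(df[[j]])] <- "undefined"
      df[[j]] <- x
    }
  }
  df
}

#' Load the packaged 29-library ivory screening table
#'
#' A 29-row table of mammoth-ivory sequencing libraries from 25 specimens:
#' completeness, mean mitogenome coverage, genetic sex where assignable,
#' shotgun endogenous DNA percentage and mtDNA capture enrichment factor
#' (the literal `"undefined"` where the shotgun proportion was zero).
#'
#' @return Data frame with columns `lab_id`, `context`, `material`,
#'   `completeness_pct`, `mean_coverage`, `sex`, `endogenous_pct`,
#'   `enrichment_factor`.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_ivory.tsv", package = "tuskDNA")
  if (path == "") stop("packaged screening table not found", call. = FALSE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character")
}

#' Analyze the packaged screening table
#'
#' Recomputes the headline numbers of the ivory screening study from the
#' packaged fixtures: the completeness filter (samples above the
#' completeness threshold and the specimen percentage they represent),
#' cohort sex ratios, the two-tailed binomial tests of each ratio against
#' 1:1, and the Fisher tests comparing ratios between materials and
#' between archaeological periods. Specimens whose archaeological context
#' carries a direct-date flag (`*`) are assigned to the Gravettian.
#'
#' @param completeness_threshold Percent breadth required (exclusive;
#'   default 90).
#' @return A list of class `table1_summary`.
#' @export
analyze_table1 <- function(completeness_threshold = 90) {
  tab <- load_table1()
  counts_path <- system.file("extdata", "ivory_bone_sex_counts.tsv",
                             package = "tuskDNA")
  if (counts_path == "") stop("packaged sex-count table not found",
                              call. = FALSE)
  sex_counts <- utils::read.table(counts_path, sep = "\t", header = TRUE)

  completeness <- stats::setNames(as.numeric(tab$completeness_pct),
                                  tab$lab_id)
  passing <- completeness_filter(completeness, completeness_threshold)
  specimens <- unique(sub("\\..*$", "", tab$lab_id))
  passing_specimens <- unique(sub("\\..*$", "", passing))
  pct_specimens <- 100 * length(passing_specimens) / length(specimens)

  ivory <- sex_counts[sex_counts$material == "ivory", ]
  bone <- sex_counts[sex_counts$material == "bone", ]
  # cross-check the ivory counts against the table itself
  tallied <- c(males = sum(tab$sex == "M"), females = sum(tab$sex == "F"))
  if (tallied[["males"]] != ivory$males ||
      tallied[["females"]] != ivory$females) {
    warning("ivory sex counts disagree with the screening table")
  }
  n_m <- ivory$males + bone$males
  n_f <- ivory$females + bone$females

  binom_combined <- binomial_two_tailed(n_m, n_m + n_f)
  binom_ivory <- binomial_two_tailed(ivory$males, ivory$males + ivory$females)
  binom_bone <- binomial_two_tailed(bone$males, bone$males + bone$females)
  fisher_material <- fisher_two_sided(contingency_table(
    ivory$males, ivory$females, bone$males, bone$females))

  period <- ifelse(grepl("Magdalenian\\*", tab$context), "Gravettian",
            ifelse(grepl("Aurignacian", tab$context), "Aurignacian",
            ifelse(grepl("Gravettian", tab$context), "Gravettian",
                   "Magdalenian")))
  sexed <- tab$sex %in% c("M", "F")
  per <- table(factor(period[sexed], c("Aurignacian", "Gravettian")),
               factor(tab$sex[sexed], c("M", "F")))
  fisher_period <- fisher_two_sided(matrix(as.integer(per), 2))

  structure(list(
    passing = passing,
    n_pass = length(passing),
    n_specimens = length(specimens),
    pct_specimens = pct_specimens,
    sex_counts = data.frame(
      material = c("ivory", "bone", "combined"),
      males = c(ivory$males, bone$males, n_m),
      females = c(ivory$females, bone$females, n_f)),
    binom_combined = binom_combined,
    binom_ivory = binom_ivory,
    binom_bone = binom_bone,
    fisher_material = fisher_material,
    period_table = per,
    fisher_period = fisher_period
  ), class = "table1_summary")
}

#' @export
print.table1_summary <- function(x, ...) {
  cat(sprintf("Screening-table analysis\n"))
  cat(sprintf("  mitogenomes above threshold: %d (%.0f%% of %d specimens)\n",
              x$n_pass, x$pct_specimens, x$n_specimens))
  sc <- x$sex_counts
  for (i in seq_len(nrow(sc))) {
    cat(sprintf("  %s sex ratio %d:%d males:females\n", sc$material[i],
                sc$males[i], sc$females[i]))
  }
  cat(sprintf("  binomial vs 1:1 -- combined p = %.2f, ivory p = %.2f, bone p = %.2f\n",
              round_half_up(x$binom_combined$p_value),
              round_half_up(x$binom_ivory$p_value),
              round_half_up(x$binom_bone$p_value)))
  cat(sprintf("  Fisher ivory vs bone p = %.2f; by period p = %.2f\n",
              round_half_up(x$fisher_material$p_value),
              round_half_up(x$fisher_period$p_value)))
  invisible(x)
}
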