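#' Simulate a reference set for ancient-ivory analyses
#'
#' Generates a uniform-random circular mitochondrial reference plus two
#' nuclear chromosomes, `chrX` and `chr8`. Chromosome 8 stands in for an
#' autosome of similar size to the X, the standard choice when the nuclear
#' reference derives from a female individual and carries no Y.
#'
#' @param mito_length Length of the mitochondrial reference in bp (>= 1000).
#' @param chr_length Length of each nuclear chromosome in bp (>= 1000).
#'   `chrX` and `chr8` are drawn at this same length; supply
#'   `chr8_length` to make them differ (must stay within 20% of
#'   `chr_length`).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param chr8_length Optional separate length for chr8.
#' @return An object of class `reference_set`: a list with `mito`
#'   (character DNA string), `circular` (TRUE), and `nuclear` (named list
#'   with `chrX`, `chr8`).
#' @examples
#' ref <- simulate_reference_set(2000, 5000, seed = 1)
#' nchar(ref$mito)
#' @export
simulate_reference_set <- function(mito_length, chr_length, seed,
                                   chr8_length = chr_length) {
  if (!is.numeric(mito_length) || mito_length < 1000 ||
      !is.numeric(chr_length) || chr_length < 1000 || chr8_length < 1000) {
    stop("reference lengths must be numeric and >= 1000 bp", call. = FALSE)
  }
  if (abs(chr8_length - chr_length) > 0.2 * max(chr_length, chr8_length)) {
    stop("chr8 length must be within 20% of chrX length", call. = FALSE)
  }
  withr_seed(seed, {
    ref <- structure(list(
      mito = random_dna(mito_length),
      circular = TRUE,
      nuclear = list(
        chrX = random_dna(chr_length),
        chr8 = random_dna(chr8_length)
      )
    ), class = "reference_set")
    ref
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set\n")
  cat(sprintf("  mito: %d bp (circular)\n", nchar(x$mito)))
  for (nm in names(x$nuclear)) {
    cat(sprintf("  %s: %d bp\n", nm, nchar(x$nuclear[[nm]])))
  }
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG
# stream; seed = NULL uses the current stream.
withr_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic per-sample child seed
#'
#' Maps one master seed and a sample index to a reproducible child seed,
#' so that batches of simulated libraries are independent yet fully
#' determined by the master seed.
#'
#' @param master Integer master seed.
#' @param index Sample index (integer).
#' @return An integer seed.
#' @export
child_seed <- function(master, index) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(index)) %% 2147483587)
}

#' Per-sample simulation configuration
#'
#' Bundles the knobs of the ancient-ivory library simulator. Defaults
#' emulate a partial-UDG 75-cycle single-end screening library: short
#' lognormal fragments, terminal C-to-T deamination concentrated on the
#' first two molecule positions, a few percent endogenous DNA, and a small
#' baseline mtDNA share that capture enrichment can multiply.
#'
#' @param substrate `"dentin"` or `"cementum"`.
#' @param true_sex `"M"` or `"F"`; males carry one X-chromosome copy,
#'   females two, against two copies of chromosome 8.
#' @param endogenous_fraction Probability that a sequenced read is
#'   endogenous (maps to the target genome); in `[0, 1]`.
#' @param fragment_length_mean,fragment_length_sd Mean and sd (bp) of the
#'   lognormal fragment-length distribution, truncated to
#'   `[min_length, max_length]`. Mean must be >= 30 bp.
#' @param min_length,max_length Truncation bounds for fragment length (bp).
#' @param damage_5p_ct_rate Per-position C-to-T deamination probabilities
#'   from the 5' terminus (mirrored as G-to-A from the 3' terminus);
#'   position 1 must be the maximum (partial-UDG shape).
#' @param library_molecules qPCR-style count of unique molecules in the
#'   pre-amplification 40 uL library.
#' @param capture_on_target_multiplier Fold increase of the mtDNA read
#'   share under in-solution capture (>= 1; 1 = shotgun).
#' @param mito_fraction Baseline (shotgun) fraction of endogenous reads
#'   that are mitochondrial.
#' @param duplicate_fraction Fraction of mapped reads that are PCR
#'   duplicates of another read.
#' @param mg_input Sample input mass (mg).
#' @param extract_ul_total,extract_ul_used Total and used extract volume
#'   (uL); used must not exceed total.
#' @param n_haplotype_variants Number of random substitutions injected into
#'   the sample's true mitochondrial haplotype.
#' @param seed Optional per-sample seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(substrate = "dentin",
                              true_sex = "F",
                              endogenous_fraction = 0.02,
                              fragment_length_mean = 55,
                              fragment_length_sd = 15,
                              min_length = 30,
                              max_length = 150,
                              damage_5p_ct_rate = c(0.10, 0.03),
                              library_molecules = 1e6,
                              capture_on_target_multiplier = 1,
                              mito_fraction = 0.001,
                              duplicate_fraction = 0.10,
                              mg_input = 50,
                              extract_ul_total = 100,
                              extract_ul_used = 25,
                              n_haplotype_variants = 5,
                              seed = NULL) {
  substrate <- match.arg(substrate, c("dentin", "cementum"))
  true_sex <- match.arg(true_sex, c("M", "F"))
  if (endogenous_fraction < 0 || endogenous_fraction > 1) {
    stop("endogenous_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(damage_5p_ct_rate < 0) || any(damage_5p_ct_rate > 1)) {
    stop("damage rates must lie in [0, 1]", call. = FALSE)
  }
  if (length(damage_5p_ct_rate) > 1 &&
      damage_5p_ct_rate[1] < max(damage_5p_ct_rate[-1])) {
    stop("terminal (position 1) damage rate must be the maximum", call. = FALSE)
  }
  if (fragment_length_mean < 30) {
    stop("fragment_length_mean must be >= 30 bp", call. = FALSE)
  }
  if (capture_on_target_multiplier < 1) {
    stop("capture_on_target_multiplier must be >= 1", call. = FALSE)
  }
  if (extract_ul_used > extract_ul_total) {
    stop("extract_ul_used must not exceed extract_ul_total", call. = FALSE)
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate one ancient-ivory sequencing library
#'
#' Draws `n_reads` sequencing reads. Each read is endogenous with
#' probability `cfg$endogenous_fraction`; endogenous reads are placed on
#' the mitochondrial haplotype or on the nuclear chromosomes, with chrX
#' sampled at half the per-base rate of chr8 in males and at the same rate
#' in females. Terminal C-to-T (and mirrored 3' G-to-A) deamination is
#' injected per `cfg$damage_5p_ct_rate`, and a configurable fraction of
#' mapped reads is emitted as flagged PCR duplicates. Non-endogenous
#' (microbial) reads are accounted for in the library statistics only and
#' carry no alignment.
#'
#' @param ref A `reference_set`.
#' @param cfg A `simulation_config`.
#' @param n_reads Total raw reads to simulate (> 0).
#' @param sample_id Sample label used in read ids and the truth record.
#' @return A list of class `simulated_library` with elements
#'   `reads` (a `read_alignments` data frame), `truth` (class
#'   `sample_truth`: sample id, substrate, sex, true haplotype, true
#'   endogenous fraction), and `stats` (a [library_stats()] record whose
#'   mapped counts cover all references).
#' @export
simulate_library <- function(ref, cfg, n_reads, sample_id = "SIM001") {
  stopifnot(inherits(ref, "reference_set"), inherits(cfg, "simulation_config"))
  if (!is.numeric(n_reads) || n_reads <= 0) {
    stop("n_reads must be positive", call. = FALSE)
  }
  if (cfg$endogenous_fraction < 0 || cfg$endogenous_fraction > 1) {
    stop("endogenous_fraction must lie in [0, 1]", call. = FALSE)
  }
  withr_seed(cfg$seed, simulate_library_impl(ref, cfg, n_reads, sample_id))
}

simulate_library_impl <- function(ref, cfg, n_reads, sample_id) {
  n_reads <- as.integer(n_reads)
  # survive adapter merging + quality/length filtering
  merged <- stats::rbinom(1L, n_reads, 0.95)
  # mapped (pre-dedup) endogenous reads; a fraction of these are PCR
  # duplicates of another mapped read
  n_mapped <- stats::rbinom(1L, merged, cfg$endogenous_fraction)
  n_dup <- if (n_mapped > 1) stats::rbinom(1L, n_mapped, cfg$duplicate_fraction)
           else 0L
  n_dup <- max(0L, min(n_dup, n_mapped - 1L))
  n_endog <- n_mapped - n_dup  # unique molecules

  haplotype <- inject_variants(ref$mito, cfg$n_haplotype_variants)

  # allocate endogenous reads: mito (capture-boosted) vs nuclear chrX/chr8,
  # nuclear split proportional to length x copy number
  p_mito <- min(1, cfg$mito_fraction * cfg$capture_on_target_multiplier)
  x_copies <- if (cfg$true_sex == "M") 1 else 2
  len_x <- nchar(ref$nuclear$chrX)
  len_8 <- nchar(ref$nuclear$chr8)
  w <- c(len_x * x_copies, len_8 * 2)
  p_ref <- c(p_mito, (1 - p_mito) * w / sum(w))
  origin <- if (n_endog > 0) {
    sample(c("mito", "chrX", "chr8"), n_endog, replace = TRUE, prob = p_ref)
  } else character(0)

  lens <- rlnorm_truncated(n_endog, cfg$fragment_length_mean,
                           cfg$fragment_length_sd, cfg$min_length,
                           cfg$max_length)
  ref_len <- c(mito = nchar(haplotype), chrX = len_x, chr8 = len_8)
  lens <- pmin(lens, ref_len[origin] - 1L)
  start <- floor(stats::runif(n_endog) * (ref_len[origin] - lens + 1))
  end <- start + lens
  strand <- sample(c("+", "-"), n_endog, replace = TRUE)
  seqs <- character(n_endog)
  for (lab in unique(origin)) {
    i <- origin == lab
    src <- if (lab == "mito") haplotype else ref$nuclear[[lab]]
    seqs[i] <- substring(src, start[i] + 1, end[i])
  }
  seqs <- inject_damage(seqs, strand, cfg$damage_5p_ct_rate)

  reads <- data.frame(
    read_id = if (n_endog > 0) sprintf("%s_r%06d", sample_id, seq_len(n_endog))
              else character(0),
    ref_label = unname(origin),
    start = as.integer(start),
    end = as.integer(end),
    strand = strand,
    sequence = seqs,
    duplicate_flag = rep(FALSE, n_endog),
    stringsAsFactors = FALSE
  )

  # emit the PCR duplicates as flagged copies of existing placements
  if (n_dup > 0) {
    dup <- reads[sample.int(n_endog, n_dup, replace = TRUE), , drop = FALSE]
    dup$read_id <- sprintf("%s_d%06d", sample_id, seq_len(n_dup))
    dup$duplicate_flag <- TRUE
    reads <- rbind(reads, dup)
    rownames(reads) <- NULL
  }
  reads <- as_read_alignments(reads)

  stats <- library_stats(
    total_raw_reads = n_reads,
    merged_filtered_reads = merged,
    mapped_pre_dedup = nrow(reads),
    unique_mapped = n_endog,
    avg_mapped_read_length = if (n_endog > 0) mean(lens) else 0,
    library_molecules = cfg$library_molecules,
    mg_input = cfg$mg_input,
    extract_ul_total = cfg$extract_ul_total,
    extract_ul_used = cfg$extract_ul_used,
    target_genome_length = nchar(ref$mito)
  )

  truth <- structure(list(
    sample_id = sample_id,
    substrate = cfg$substrate,
    true_sex = cfg$true_sex,
    true_mito_haplotype = haplotype,
    true_endogenous_fraction = cfg$endogenous_fraction
  ), class = "sample_truth")

  structure(list(reads = reads, truth = truth, stats = stats),
            class = "simulated_library")
}

# substitute n random positions of a DNA string with a different base
inject_variants <- function(seq, n) {
  if (n <= 0) return(seq)
  len <- nchar(seq)
  pos <- sample.int(len, min(n, len))
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    cur <- substring(seq, p, p)
    substring(seq, p, p) <- sample(setdiff(bases, cur), 1)
  }
  seq
}

# lognormal with given arithmetic mean/sd, truncated by resampling
rlnorm_truncated <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(integer(0))
  s2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - s2 / 2
  x <- stats::rlnorm(n, mu, sqrt(s2))
  bad <- which(x < lo | x > hi)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    x[bad] <- stats::rlnorm(length(bad), mu, sqrt(s2))
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1
  }
  x <- pmin(pmax(x, lo), hi)
  as.integer(round(x))
}

# Terminal deamination in molecule (read) orientation, projected onto the
# stored reference-orientation sequence. The 5' C>T channel of a plus read
# and the mirrored 3' G>A channel of a minus read both land as C>T at the
# LEFT end of the aligned segment; symmetrically the right end always
# takes G>A. With one shared rate vector for both channels, injection is
# therefore strand-independent in reference orientation.
inject_damage <- function(seqs, strand, rates) {
  n <- length(seqs)
  if (n == 0 || length(rates) == 0 || all(rates == 0)) return(seqs)
  lens <- nchar(seqs)
  for (j in seq_along(rates)) {
    r <- rates[j]
    if (r <= 0) next
    ok <- lens >= 2 * j  # keep the two channels on distinct positions
    # left end, offset j: C>T
    b <- substring(seqs, j, j)
    hit <- ok & b == "C" & stats::runif(n) < r
    if (any(hit)) {
      tmp <- seqs[hit]
      substring(tmp, j, j) <- "T"
      seqs[hit] <- tmp
    }
    # right end, offset j: G>A
    p <- lens - j + 1
    b <- substring(seqs, p, p)
    hit <- ok & b == "G" & stats::runif(n) < r
    if (any(hit)) {
      tmp <- seqs[hit]
      substring(tmp, p[hit], p[hit]) <- "A"
      seqs[hit] <- tmp
    }
  }
  seqs
}

#' Simulate paired dentin/cementum libraries from the same specimens
#'
#' Emulates sampling both tusk tissues from each of `n_pairs` specimens:
#' the cementum member of each pair has its endogenous fraction multiplied
#' by `cementum_endog_fold` (capped at 1) and its mean fragment length
#' shifted by `cementum_length_shift` bp, mirroring the empirical pattern
#' that tusk cementum preserves more, and slightly longer, endogenous DNA
#' than dentin.
#'
#' @param ref A `reference_set`.
#' @param base_cfg Baseline `simulation_config` describing the dentin
#'   member (its `endogenous_fraction` is the per-pair dentin mean).
#' @param cementum_endog_fold Fold change of the endogenous fraction in
#'   cementum (> 0).
#' @param cementum_length_shift Additive shift of mean fragment length in
#'   cementum (bp).
#' @param n_pairs Number of specimens (>= 1).
#' @param n_reads Raw reads per library.
#' @param seed Master seed; per-library child seeds are derived from it.
#' @param pair_cv Lognormal coefficient of variation of the dentin
#'   endogenous fraction across specimens.
#' @return A list of class `paired_libraries`; each element is a list with
#'   `dentin` and `cementum` [simulate_library()] results.
#' @export
simulate_paired_substrates <- function(ref, base_cfg, cementum_endog_fold,
                                       cementum_length_shift, n_pairs,
                                       n_reads = 5e4, seed = 1,
                                       pair_cv = 0.5) {
  stopifnot(inherits(ref, "reference_set"),
            inherits(base_cfg, "simulation_config"))
  if (cementum_endog_fold <= 0) stop("fold must be > 0", call. = FALSE)
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  dentin_f <- withr_seed(seed, {
    s2 <- log(1 + pair_cv^2)
    stats::rlnorm(n_pairs, log(base_cfg$endogenous_fraction) - s2 / 2, sqrt(s2))
  })
  dentin_f <- pmin(dentin_f, 1)
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    cfg_d <- base_cfg
    cfg_d$substrate <- "dentin"
    cfg_d$endogenous_fraction <- dentin_f[i]
    cfg_d$seed <- child_seed(seed, 2L * i)
    cfg_c <- cfg_d
    cfg_c$substrate <- "cementum"
    cfg_c$endogenous_fraction <- min(1, dentin_f[i] * cementum_endog_fold)
    cfg_c$fragment_length_mean <- cfg_d$fragment_length_mean +
      cementum_length_shift
    cfg_c$seed <- child_seed(seed, 2L * i + 1L)
    pairs[[i]] <- list(
      dentin = simulate_library(ref, cfg_d, n_reads,
                                sprintf("PAIR%02d.D", i)),
      cementum = simulate_library(ref, cfg_c, n_reads,
                                  sprintf("PAIR%02d.C", i))
    )
  }
  structure(pairs, class = "paired_libraries")
}
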