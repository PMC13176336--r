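# Shared in-code fixtures and independent oracles.

# hand-built read table
make_reads <- function(start, end, sequence, ref_label = "mito",
                       strand = "+", duplicate_flag = FALSE) {
  n <- length(start)
  as_read_alignments(data.frame(
    read_id = sprintf("r%03d", seq_len(n)),
    ref_label = rep_len(ref_label, n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(strand, n),
    sequence = sequence,
    duplicate_flag = rep_len(duplicate_flag, n),
    stringsAsFactors = FALSE
  ))
}

# error-free reads tiling a reference at roughly `fold` coverage
tile_reads <- function(ref, fold, read_len = 50, seed = 1) {
  len <- nchar(ref)
  n <- ceiling(fold * len / read_len)
  withr::with_seed(seed, {
    start <- sample.int(len - read_len + 1, n, replace = TRUE) - 1L
    make_reads(start, start + read_len,
               substring(ref, start + 1, start + read_len),
               strand = sample(c("+", "-"), n, replace = TRUE))
  })
}

# brute-force per-site tally, the slow oracle for build_pileup
oracle_pileup <- function(reads, ref) {
  len <- nchar(ref)
  counts <- matrix(0L, len, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(reads))) {
    bases <- strsplit(reads$sequence[i], "")[[1]]
    for (k in seq_along(bases)) {
      p <- reads$start[i] + k
      b <- bases[k]
      if (b %in% colnames(counts)) counts[p, b] <- counts[p, b] + 1L
    }
  }
  data.frame(position = seq_len(len) - 1L, counts, depth = rowSums(counts))
}

# independent minlike oracles built from the combinatorial definitions
oracle_binom_p <- function(k, n, p0 = 0.5) {
  pr <- vapply(0:n, function(i) {
    exp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0))
  }, numeric(1))
  if (p0 == 0) pr <- c(1, rep(0, n))
  if (p0 == 1) pr <- c(rep(0, n), 1)
  min(1, sum(pr[pr <= pr[k + 1] * (1 + 1e-7)]))
}

oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); N <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  ptab <- function(a) {
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
          lfactorial(N) - lfactorial(a) - lfactorial(r1 - a) -
          lfactorial(c1 - a) - lfactorial(N - r1 - c1 + a))
  }
  support <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- vapply(support, ptab, numeric(1))
  min(1, sum(pr[pr <= ptab(tab[1, 1]) * (1 + 1e-7)]))
}

small_reference <- function(seed = 7) {
  simulate_reference_set(2000, 5000, seed = seed)
}
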