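#' Call a mitogenome consensus from a pileup
#'
#' Applies the majority rule used for low-coverage ancient mitogenomes: a
#' site is called to its majority base only when it is covered by at least
#' `min_depth` non-duplicated reads and the majority base frequency
#' strictly exceeds `majority`; every other site becomes `N`. Ties at
#' exactly 50% therefore always yield `N` — there is no random
#' tie-breaking. Completeness (breadth of coverage) is the percentage of
#' non-N sites.
#'
#' @param pileup A `pileup` data frame from [build_pileup()] covering
#'   every reference position.
#' @param min_depth Minimum depth of non-duplicated reads (default 3).
#' @param majority Frequency the majority base must strictly exceed
#'   (default 0.5).
#' @return A list of class `consensus_result`: `sequence` (string over
#'   `A,C,G,T,N`), `completeness` (percent), `mean_coverage` (mean pileup
#'   depth, fold) and `n_sites_called`.
#' @export
call_consensus <- function(pileup, min_depth = 3, majority = 0.5) {
  needed <- c("position", "A", "C", "G", "T", "depth")
  if (!all(needed %in% names(pileup))) {
    stop("malformed pileup: need columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  counts <- as.matrix(pileup[, c("A", "C", "G", "T")])
  depth <- pileup$depth
  top <- max.col(counts, ties.method = "first")
  top_count <- counts[cbind(seq_len(nrow(counts)), top)]
  # a strict majority is unique, so the first-max column is the call
  called <- depth >= min_depth & top_count > majority * depth
  base <- rep("N", nrow(counts))
  base[called] <- c("A", "C", "G", "T")[top[called]]
  structure(list(
    sequence = paste(base, collapse = ""),
    completeness = 100 * sum(called) / nrow(counts),
    mean_coverage = mean(depth),
    n_sites_called = sum(called)
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "Consensus: %d bp, %.2f%% complete (%d called), mean coverage %.2fx\n",
    nchar(x$sequence), x$completeness, x$n_sites_called, x$mean_coverage))
  invisible(x)
}

#' Filter consensus sequences by completeness
#'
#' Retains samples whose breadth of coverage strictly exceeds `threshold`
#' percent. The strict boundary keeps samples sitting just above 90%
#' while excluding anything at or below it, the convention used when
#' selecting near-complete ancient mitogenomes for downstream alignment.
#'
#' @param completeness Either a named numeric vector of completeness
#'   percentages or a named list of `consensus_result` objects.
#' @param threshold Completeness threshold in percent (default 90).
#' @return Character vector of passing sample names.
#' @export
completeness_filter <- function(completeness, threshold = 90) {
  if (is.list(completeness) && !is.data.frame(completeness)) {
    completeness <- vapply(completeness, function(x) x$completeness,
                           numeric(1))
  }
  names(completeness)[completeness > threshold]
}

#' Reconstruct a simulated sample and score it against its truth
#'
#' Runs the standard processing chain (terminal trim, deduplication,
#' pileup, consensus) on a simulated library and scores the consensus
#' against the sample's true mitochondrial haplotype. Accuracy is the
#' fraction of called (non-N) sites matching the truth.
#'
#' @param sim A `simulated_library` from [simulate_library()].
#' @param ref The `reference_set` the sample was simulated from.
#' @param trim_bp Terminal bases to trim (default 2).
#' @param min_depth,majority Consensus-rule parameters.
#' @return List with `consensus` (a `consensus_result`), `accuracy`
#'   (fraction in `[0, 1]`, `NA` when nothing was called), and
#'   `n_scored` (number of called sites).
#' @export
reconstruct_and_score <- function(sim, ref, trim_bp = 2, min_depth = 3,
                                  majority = 0.5) {
  reads <- sim$reads[sim$reads$ref_label == "mito", , drop = FALSE]
  reads <- deduplicate(trim_terminal(reads, trim_bp), mode = "position")
  pu <- build_pileup(reads, sim$truth$true_mito_haplotype)
  cons <- call_consensus(pu, min_depth = min_depth, majority = majority)
  called <- strsplit(cons$sequence, "", fixed = TRUE)[[1]]
  truth <- strsplit(sim$truth$true_mito_haplotype, "", fixed = TRUE)[[1]]
  idx <- called != "N"
  acc <- if (any(idx)) mean(called[idx] == truth[idx]) else NA_real_
  list(consensus = cons, accuracy = acc, n_scored = sum(idx))
}

#' Write consensus sequences to FASTA
#'
#' Headers carry the sample id, completeness and mean coverage.
#'
#' @param results Named list of `consensus_result` objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(results, path) {
  seqs <- vapply(results, function(x) x$sequence, character(1))
  names(seqs) <- vapply(names(results), function(nm) {
    x <- results[[nm]]
    sprintf("%s completeness=%.2f mean_coverage=%.2f", nm,
            x$completeness, x$mean_coverage)
  }, character(1))
  write_fasta(seqs, path)
}
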