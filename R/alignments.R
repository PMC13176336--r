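#' Read-alignment tables
#'
#' The package represents aligned reads as a plain data frame of class
#' `read_alignments` with one row per read placement and columns
#' `read_id`, `ref_label`, `start` (0-based), `end` (half-open), `strand`
#' (`+`/`-`), `sequence` (aligned bases in reference orientation) and
#' `duplicate_flag`. Coordinates are 0-based, half-open throughout;
#' human-facing reports convert to 1-based inclusive.
#'
#' @param df A data frame with the columns above.
#' @return `df` validated and classed as `read_alignments`.
#' @export
as_read_alignments <- function(df) {
  needed <- c("read_id", "ref_label", "start", "end", "strand", "sequence",
              "duplicate_flag")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("missing alignment columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) > 0) {
    if (any(df$end - df$start != nchar(df$sequence)) ||
        any(df$end <= df$start)) {
      stop("end - start must equal sequence length and be positive",
           call. = FALSE)
    }
    if (!all(df$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'", call. = FALSE)
    }
  }
  class(df) <- unique(c("read_alignments", class(df)))
  df
}

#' Trim bases from both molecule termini
#'
#' Shortens every read by `n_bp` at each end, the standard guard against
#' residual terminal deamination in partial-UDG libraries (2 bp by
#' default downstream). Trimming is symmetric in molecule orientation, so
#' it projects onto reference coordinates as `start + n_bp`,
#' `end - n_bp` for either strand. Reads left with no bases
#' (length <= `2 * n_bp`) are dropped.
#'
#' @param reads A `read_alignments` table.
#' @param n_bp Non-negative number of bases to remove at each end.
#' @return The trimmed `read_alignments` table.
#' @export
trim_terminal <- function(reads, n_bp = 2) {
  if (!is.numeric(n_bp) || n_bp < 0) {
    stop("n_bp must be non-negative", call. = FALSE)
  }
  n_bp <- as.integer(n_bp)
  if (n_bp == 0 || nrow(reads) == 0) return(reads)
  keep <- (reads$end - reads$start) > 2L * n_bp
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) > 0) {
    len <- reads$end - reads$start
    reads$sequence <- substring(reads$sequence, n_bp + 1L, len - n_bp)
    reads$start <- reads$start + n_bp
    reads$end <- reads$end - n_bp
  }
  rownames(reads) <- NULL
  reads
}

#' Remove duplicate read placements
#'
#' In `"position"` mode at most one read is retained per
#' (`ref_label`, `start`, `end`, `strand`) placement key; in `"flag"` mode
#' reads with `duplicate_flag = TRUE` are dropped. Idempotent in both
#' modes.
#'
#' @param reads A `read_alignments` table.
#' @param mode `"position"` (default) or `"flag"`.
#' @return Deduplicated `read_alignments`.
#' @export
deduplicate <- function(reads, mode = c("position", "flag")) {
  mode <- match.arg(mode)
  if (nrow(reads) == 0) return(reads)
  keep <- if (mode == "flag") {
    !reads$duplicate_flag
  } else {
    !duplicated(paste(reads$ref_label, reads$start, reads$end, reads$strand,
                      sep = "\r"))
  }
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a per-site pileup over one reference
#'
#' Tallies A/C/G/T counts at every reference position from the supplied
#' reads (expected to be trimmed and deduplicated already). Positions
#' without coverage carry depth 0.
#'
#' @param reads A `read_alignments` table; all rows must share one
#'   `ref_label` unless `ref_label` is given to subset.
#' @param ref Reference sequence (character string) the reads align to.
#' @param ref_label Optional label to select reads for one reference.
#' @return A data frame of class `pileup` with columns `position`
#'   (0-based), `A`, `C`, `G`, `T`, `depth`, one row per reference
#'   position.
#' @export
build_pileup <- function(reads, ref, ref_label = NULL) {
  len <- nchar(ref)
  if (!is.null(ref_label)) {
    reads <- reads[reads$ref_label == ref_label, , drop = FALSE]
  } else if (nrow(reads) > 0 && length(unique(reads$ref_label)) > 1) {
    stop("reads span multiple references; supply ref_label", call. = FALSE)
  }
  if (nrow(reads) > 0 && (min(reads$start) < 0 || max(reads$end) > len)) {
    stop("read coordinates fall outside the reference", call. = FALSE)
  }
  counts <- matrix(0L, nrow = len, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  if (nrow(reads) > 0) {
    rl <- reads$end - reads$start
    pos <- sequence(rl, from = reads$start + 1L)  # 1-based site index
    base <- unlist(strsplit(reads$sequence, "", fixed = TRUE), use.names = FALSE)
    bi <- match(base, c("A", "C", "G", "T"))
    ok <- !is.na(bi)
    tab <- tabulate((pos[ok] - 1L) * 4L + bi[ok], nbins = len * 4L)
    counts <- matrix(tab, nrow = len, ncol = 4, byrow = TRUE,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
  }
  out <- data.frame(position = seq_len(len) - 1L, counts,
                    depth = rowSums(counts))
  class(out) <- c("pileup", class(out))
  out
}

#' Profile terminal deamination damage
#'
#' Computes, from untrimmed reads, the C-to-T mismatch frequency at each
#' position from the 5' molecule terminus and the G-to-A frequency from
#' the 3' terminus — the canonical diagnostic plot for ancient DNA. A
#' partial-UDG library shows elevated rates only at the first one or two
#' positions. Frequencies are mismatch events over reference-base
#' opportunities; positions without opportunities are reported as `NA`.
#'
#' @param reads Untrimmed `read_alignments` on a single reference.
#' @param ref Reference sequence string.
#' @param n_positions Number of terminal positions to profile.
#' @return A list of class `damage_profile` with numeric vectors
#'   `ct_5p`, `ga_3p` (frequencies) and `ct_5p_n`, `ga_3p_n`
#'   (opportunity counts).
#' @export
damage_profile <- function(reads, ref, n_positions = 10) {
  n_positions <- as.integer(n_positions)
  ct_ev <- ct_op <- ga_ev <- ga_op <- integer(n_positions)
  if (nrow(reads) > 0) {
    lens <- reads$end - reads$start
    for (j in seq_len(n_positions)) {
      ok <- lens >= j
      if (!any(ok)) break
      # 5' terminus: left end of plus reads, right end of minus reads
      p5 <- ifelse(reads$strand == "+", reads$start + j,
                   reads$end - j + 1L)  # 1-based ref coordinate
      # 3' terminus: the opposite end
      p3 <- ifelse(reads$strand == "+", reads$end - j + 1L,
                   reads$start + j)
      rb5 <- substring(ref, p5, p5)
      rb3 <- substring(ref, p3, p3)
      off5 <- ifelse(reads$strand == "+", j, lens - j + 1L)
      off3 <- ifelse(reads$strand == "+", lens - j + 1L, j)
      ob5 <- substring(reads$sequence, off5, off5)
      ob3 <- substring(reads$sequence, off3, off3)
      # read-space C>T at 5' == ref C>T (+) or ref G>A (-)
      opp5 <- ok & ((reads$strand == "+" & rb5 == "C") |
                    (reads$strand == "-" & rb5 == "G"))
      ev5 <- opp5 & ((reads$strand == "+" & ob5 == "T") |
                     (reads$strand == "-" & ob5 == "A"))
      # read-space G>A at 3' == ref G>A (+) or ref C>T (-)
      opp3 <- ok & ((reads$strand == "+" & rb3 == "G") |
                    (reads$strand == "-" & rb3 == "C"))
      ev3 <- opp3 & ((reads$strand == "+" & ob3 == "A") |
                     (reads$strand == "-" & ob3 == "T"))
      ct_op[j] <- sum(opp5); ct_ev[j] <- sum(ev5)
      ga_op[j] <- sum(opp3); ga_ev[j] <- sum(ev3)
    }
  }
  structure(list(
    ct_5p = ifelse(ct_op > 0, ct_ev / ct_op, NA_real_),
    ga_3p = ifelse(ga_op > 0, ga_ev / ga_op, NA_real_),
    ct_5p_n = ct_op,
    ga_3p_n = ga_op
  ), class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat("Terminal damage profile\n")
  cat("  5' C>T:", paste(sprintf("%.3f", x$ct_5p), collapse = " "), "\n")
  cat("  3' G>A:", paste(sprintf("%.3f", x$ga_3p), collapse = " "), "\n")
  invisible(x)
}

#' Write / read the tab-separated alignment table
#'
#' @param reads A `read_alignments` table.
#' @param path Output TSV path.
#' @return `write_alignments_tsv` returns `path` invisibly;
#'   `read_alignments_tsv` returns a `read_alignments` table.
#' @export
write_alignments_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @export
read_alignments_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(
                            read_id = "character", ref_label = "character",
                            start = "integer", end = "integer",
                            strand = "character", sequence = "character",
                            duplicate_flag = "logical"))
  as_read_alignments(df)
}

#' FASTA helpers
#'
#' Thin wrappers over Biostrings for reading and writing the package's
#' references, haplotypes and consensus sequences as plain-text FASTA.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path FASTA file path.
#' @return `write_fasta` returns `path` invisibly; `read_fasta` a named
#'   character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
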