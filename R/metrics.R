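#' Per-library sequencing statistics
#'
#' Collects every count and volume entering the recovery-metric formulas
#' for one library: raw sequencing effort, reads surviving merging and
#' quality/length filtering, mapped reads before and after duplicate
#' removal, the mean mapped read length, the qPCR molecule count of the
#' pre-amplification 40 uL library, sample input mass and extract volumes,
#' and the target genome length.
#'
#' @param total_raw_reads Raw reads sequenced.
#' @param merged_filtered_reads Reads after merging and quality/length
#'   filtering.
#' @param mapped_pre_dedup Mapped reads before duplicate removal and
#'   quality filtering.
#' @param unique_mapped Mapped reads after duplicate removal and quality
#'   filtering.
#' @param avg_mapped_read_length Mean mapped read length (bp).
#' @param library_molecules qPCR molecule count of the 40 uL library.
#' @param mg_input Sample input (mg).
#' @param extract_ul_total,extract_ul_used Extract volumes (uL).
#' @param target_genome_length Length of the mapping target (bp).
#' @return A list of class `library_stats`.
#' @export
library_stats <- function(total_raw_reads, merged_filtered_reads,
                          mapped_pre_dedup, unique_mapped,
                          avg_mapped_read_length, library_molecules,
                          mg_input, extract_ul_total, extract_ul_used,
                          target_genome_length) {
  s <- as.list(environment())
  counts <- c("total_raw_reads", "merged_filtered_reads", "mapped_pre_dedup",
              "unique_mapped")
  if (any(unlist(s[counts]) < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (unique_mapped > mapped_pre_dedup) {
    stop("unique_mapped cannot exceed mapped_pre_dedup", call. = FALSE)
  }
  if (extract_ul_used > extract_ul_total) {
    stop("extract_ul_used cannot exceed extract_ul_total", call. = FALSE)
  }
  if (target_genome_length <= 0) {
    stop("target_genome_length must be positive", call. = FALSE)
  }
  structure(s, class = "library_stats")
}

# Undefined metric states (zero denominators, Table-1-style "undefined"
# enrichment cells) are carried as NA_real_ and rendered as the literal
# string "undefined" in reports -- never silently coerced to 0.

#' Recovery metrics for one library
#'
#' The six per-library metrics used to judge ancient-DNA recovery from a
#' sampling effort. With `r` the mapped reads before duplicate removal,
#' `m` the reads after merging and filtering, `u` the unique mapped reads,
#' `L` the mean mapped read length, `M` the qPCR molecule count of the
#' 40 uL library, `G` the target genome length, `R` the raw reads and
#' `mg` the sample input:
#' \describe{
#'   \item{`prop_mammoth_dna`}{`r / m`, the proportion of target DNA
#'     recovered.}
#'   \item{`enrichment_factor`}{captured proportion / shotgun proportion;
#'     undefined (`NA`) when the shotgun proportion is 0.}
#'   \item{`informative_per_mg`}{`M * u / (m * mg)`, unique informative
#'     molecules in the library per mg input.}
#'   \item{`coverage_per_50mg`}{`(M * (r/m) * L / G) * (uL_total * 50 /
#'     (uL_used * mg))`, genomic coverage obtainable per 50 mg sampled.}
#'   \item{`cost_effectiveness`}{`u * L / (R * mg) * 1e6`, unique bp per
#'     million raw reads per mg.}
#'   \item{`mean_coverage`}{`mapped * L / G` (fold).}
#' }
#'
#' @param s A [library_stats()] record.
#' @return The metric value, or `NA_real_` when a denominator is zero
#'   (an explicit "undefined" state).
#' @name metrics
NULL

#' @rdname metrics
#' @export
prop_mammoth_dna <- function(s) {
  if (s$merged_filtered_reads <= 0) return(NA_real_)
  s$mapped_pre_dedup / s$merged_filtered_reads
}

#' @rdname metrics
#' @param captured,shotgun On-target proportions with and without mtDNA
#'   capture enrichment.
#' @export
enrichment_factor <- function(captured, shotgun) {
  stopifnot(captured >= 0, captured <= 1, shotgun >= 0, shotgun <= 1)
  if (is.na(shotgun) || shotgun == 0) return(NA_real_)
  captured / shotgun
}

#' @rdname metrics
#' @export
informative_per_mg <- function(s) {
  if (s$merged_filtered_reads <= 0 || s$mg_input <= 0) return(NA_real_)
  s$library_molecules * s$unique_mapped /
    (s$merged_filtered_reads * s$mg_input)
}

#' @rdname metrics
#' @export
coverage_per_50mg <- function(s) {
  prop <- prop_mammoth_dna(s)
  if (is.na(prop) || s$target_genome_length <= 0 || s$mg_input <= 0 ||
      s$extract_ul_used <= 0) {
    return(NA_real_)
  }
  (s$library_molecules * prop * s$avg_mapped_read_length /
     s$target_genome_length) *
    (s$extract_ul_total * 50 / (s$extract_ul_used * s$mg_input))
}

#' @rdname metrics
#' @export
cost_effectiveness <- function(s) {
  if (s$total_raw_reads <= 0 || s$mg_input <= 0) return(NA_real_)
  s$unique_mapped * s$avg_mapped_read_length /
    (s$total_raw_reads * s$mg_input) * 1e6
}

#' @rdname metrics
#' @param mapped_mode Which mapped-read count enters mean coverage:
#'   `"unique"` (after deduplication and filtering, the default, matching
#'   how consensus-supporting coverage is reported) or `"pre_dedup"`.
#' @export
mean_coverage <- function(s, mapped_mode = c("unique", "pre_dedup")) {
  mapped_mode <- match.arg(mapped_mode)
  if (s$target_genome_length <= 0) return(NA_real_)
  mapped <- if (mapped_mode == "unique") s$unique_mapped else s$mapped_pre_dedup
  mapped * s$avg_mapped_read_length / s$target_genome_length
}

#' All recovery metrics as a one-row data frame
#'
#' @param s A [library_stats()] record.
#' @param shotgun_prop Optional shotgun on-target proportion; when given,
#'   the enrichment factor of `s`'s own proportion over it is included.
#' @return One-row data frame with columns `prop_mammoth_dna`,
#'   `enrichment_factor`, `informative_per_mg`, `coverage_per_50mg`,
#'   `cost_effectiveness`, `mean_coverage`, `avg_length`.
#' @export
metric_set <- function(s, shotgun_prop = NA_real_) {
  enr <- if (is.na(shotgun_prop)) NA_real_ else {
    enrichment_factor(prop_mammoth_dna(s), shotgun_prop)
  }
  data.frame(
    prop_mammoth_dna = prop_mammoth_dna(s),
    enrichment_factor = enr,
    informative_per_mg = informative_per_mg(s),
    coverage_per_50mg = coverage_per_50mg(s),
    cost_effectiveness = cost_effectiveness(s),
    mean_coverage = mean_coverage(s),
    avg_length = s$avg_mapped_read_length
  )
}

#' Compute recovery metrics for a manifest of libraries
#'
#' @param manifest Data frame with one row per library carrying the
#'   [library_stats()] fields (and optionally `sample_id`).
#' @return Data frame with one row per library and a column per metric.
#' @export
compute_metrics <- function(manifest) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    s <- library_stats(r$total_raw_reads, r$merged_filtered_reads,
                       r$mapped_pre_dedup, r$unique_mapped,
                       r$avg_mapped_read_length, r$library_molecules,
                       r$mg_input, r$extract_ul_total, r$extract_ul_used,
                       r$target_genome_length)
    metric_set(s)
  })
  out <- do.call(rbind, rows)
  if ("sample_id" %in% names(manifest)) {
    out <- cbind(sample_id = manifest$sample_id, out)
  }
  out
}
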