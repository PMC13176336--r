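#' Count reads on chrX and chr8
#'
#' @param reads A deduplicated `read_alignments` table.
#' @return Named integer vector `c(n_x = ..., n_8 = ...)`.
#' @export
count_xy_reads <- function(reads) {
  c(n_x = sum(reads$ref_label == "chrX"),
    n_8 = sum(reads$ref_label == "chr8"))
}

#' Default sex-assignment zones for the ChrX:Chr8 ratio
#'
#' Males, carrying one X chromosome against two copies of chromosome 8,
#' are expected near a ratio of 0.5; females, carrying two, near 1.
#' The zones are explicit configuration because confidence bands trained
#' on large reference panels are dataset-specific.
#'
#' @return List with numeric `male` and `female` intervals.
#' @export
default_sex_zones <- function() {
  list(male = c(0.35, 0.65), female = c(0.85, 1.15))
}

#' Genetic sex from ChrX and Chr8 read counts
#'
#' Computes the ratio of chrX to chr8 read counts (per-base-normalized by
#' chromosome length when `normalize = TRUE`; with equal lengths this
#' reduces to the plain count ratio), its delta-method standard error
#' `ratio * sqrt(1/n_x + 1/n_8)`, and a categorical call: male when
#' `ratio + 2*se` falls inside the male zone, female when `ratio - 2*se`
#' falls inside the female zone, otherwise unassigned. Samples with 100 or
#' fewer reads on either chromosome are ineligible and always unassigned.
#'
#' @param n_x,n_8 Read counts on chrX and chr8.
#' @param length_x,length_8 Chromosome lengths (bp); only their ratio
#'   matters.
#' @param zones Assignment zones, as from [default_sex_zones()].
#' @param min_reads Eligibility floor on both counts (default 100,
#'   exclusive).
#' @param normalize Length-normalize the ratio (default TRUE).
#' @return A list of class `sex_call`: `n_x`, `n_8`, `ratio`, `se`,
#'   `call` (`"male"`, `"female"` or `"unassigned"`), `eligible`.
#' @export
sex_ratio_call <- function(n_x, n_8, length_x = 1, length_8 = 1,
                           zones = default_sex_zones(), min_reads = 100,
                           normalize = TRUE) {
  stopifnot(n_x >= 0, n_8 >= 0, length_x > 0, length_8 > 0)
  eligible <- n_x > min_reads && n_8 > min_reads
  if (n_8 == 0 || n_x == 0) {
    ratio <- if (n_8 == 0) NA_real_ else 0
    return(structure(list(n_x = n_x, n_8 = n_8, ratio = ratio, se = NA_real_,
                          call = "unassigned", eligible = FALSE),
                     class = "sex_call"))
  }
  ratio <- if (normalize) (n_x / length_x) / (n_8 / length_8) else n_x / n_8
  se <- ratio * sqrt(1 / n_x + 1 / n_8)
  call <- "unassigned"
  if (eligible) {
    hi <- ratio + 2 * se
    lo <- ratio - 2 * se
    if (hi >= zones$male[1] && hi <= zones$male[2]) {
      call <- "male"
    } else if (lo >= zones$female[1] && lo <= zones$female[2]) {
      call <- "female"
    }
  }
  structure(list(n_x = n_x, n_8 = n_8, ratio = ratio, se = se, call = call,
                 eligible = eligible), class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("ChrX:Chr8 = %d:%d, ratio %.3f +/- %.3f -> %s%s\n",
              x$n_x, x$n_8, x$ratio, x$se, x$call,
              if (!x$eligible) " (ineligible: <=100 reads)" else ""))
  invisible(x)
}

#' Tally sex calls per group
#'
#' @param calls List of `sex_call` objects (or character vector of
#'   calls).
#' @param grouping Optional vector of group labels, recycled against
#'   `calls`.
#' @return Data frame with columns `group`, `males`, `females`,
#'   `unassigned`.
#' @export
cohort_sex_summary <- function(calls, grouping = NULL) {
  lab <- if (is.character(calls)) calls else {
    vapply(calls, function(x) x$call, character(1))
  }
  if (is.null(grouping)) grouping <- rep("all", length(lab))
  groups <- unique(grouping)
  out <- do.call(rbind, lapply(groups, function(g) {
    l <- lab[grouping == g]
    data.frame(group = g, males = sum(l == "male"),
               females = sum(l == "female"),
               unassigned = sum(l == "unassigned"))
  }))
  if (is.null(out)) {
    out <- data.frame(group = character(0), males = integer(0),
                      females = integer(0), unassigned = integer(0))
  }
  rownames(out) <- NULL
  out
}
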