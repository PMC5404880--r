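## Condition-specific consensus binding sites from replicate peak calls.
##
## The final site list keeps every candidate region supported by at least
## `min_treatment_support` distinct treatment replicates and discards any
## candidate touched by a peak in any control replicate.  Candidates are the
## merged union of all treatment peaks, which makes "found in a sample"
## well-defined for BED3 input with no summit information.

#' Consensus configuration
#'
#' @param min_treatment_support minimum number of distinct treatment
#'   replicates whose peaks must overlap a candidate region (default 2).
#' @param subtract_any_control drop a candidate that overlaps a peak in any
#'   control replicate (default TRUE).
#' @return a list of class `consensus_config`.
#' @export
consensus_config <- function(min_treatment_support = 2L,
                             subtract_any_control = TRUE) {
  min_treatment_support <- as.integer(min_treatment_support)
  if (is.na(min_treatment_support) || min_treatment_support < 1L)
    stop("min_treatment_support must be an integer >= 1")
  structure(list(min_treatment_support = min_treatment_support,
                 subtract_any_control = isTRUE(subtract_any_control)),
            class = "consensus_config")
}

#' Derive consensus binding sites from replicate peak calls
#'
#' Candidate regions are the merged union of all treatment-replicate peaks.
#' A candidate is retained when (1) it overlaps at least one peak in
#' `min_treatment_support` or more \emph{distinct} treatment replicates and
#' (2) it overlaps no peak in any control replicate.  The returned set is
#' sorted, disjoint, and carries the per-candidate replicate support in its
#' `score` column.
#'
#' @param treatment_reps list of `GRanges`, one per treatment replicate.
#' @param control_reps list of `GRanges`, one per control replicate (may be
#'   empty).
#' @param cfg a [consensus_config()].
#' @return a sorted disjoint `GRanges` with a `score` metadata column giving
#'   the number of supporting treatment replicates.
#' @export
consensus_sites <- function(treatment_reps, control_reps = list(),
                            cfg = consensus_config()) {
  if (!methods::is(cfg, "consensus_config")) stop("cfg must be a consensus_config")
  if (!is.list(treatment_reps) || length(treatment_reps) == 0L)
    stop("treatment_reps must be a non-empty list of GRanges")
  if (cfg$min_treatment_support > length(treatment_reps))
    stop(sprintf("min_treatment_support (%d) exceeds number of treatment replicates (%d)",
                 cfg$min_treatment_support, length(treatment_reps)))
  pooled <- suppressWarnings(do.call(c, unname(treatment_reps)))
  S4Vectors::mcols(pooled) <- NULL
  candidates <- merge_overlapping(pooled)
  if (length(candidates) == 0L) return(candidates)
  support <- Reduce(`+`, lapply(treatment_reps, function(rep)
    as.integer(overlaps_any(candidates, rep))))
  keep <- support >= cfg$min_treatment_support
  if (cfg$subtract_any_control && length(control_reps) > 0L) {
    for (ctl in control_reps) keep <- keep & !overlaps_any(candidates, ctl)
  }
  out <- candidates[keep]
  S4Vectors::mcols(out)$score <- support[keep]
  out
}

#' Fraction of query intervals overlapping a reference set
#'
#' @param query a non-empty `GRanges`.
#' @param reference a `GRanges`.
#' @return the fraction (in `[0, 1]`) of query intervals that overlap at
#'   least one reference interval.
#' @export
overlap_fraction <- function(query, reference) {
  if (length(query) == 0L)
    stop("overlap_fraction is undefined for an empty query set")
  mean(overlaps_any(query, reference))
}

#' Query intervals absent from a reference set
#'
#' @param query,reference `GRanges` objects.
#' @return the subset of `query` overlapping no `reference` interval.
#' @export
novel_sites <- function(query, reference) {
  query[!overlaps_any(query, reference)]
}
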