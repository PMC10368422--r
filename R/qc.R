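#' Fraction of reads in peaks (FRiP) for one sample
#'
#' A fragment counts as "in peaks" iff it overlaps at least 1 bp of at
#' least one peak, and is counted once however many peaks it touches.
#' FRiP is computed against the sample's own peak calls, before any atlas
#' construction, matching the usual QC ordering.
#'
#' @param fragments GRanges of mapped fragments.
#' @param peaks GRanges of the sample's peak calls.
#' @return one-row data.frame: `total_fragments`, `fragments_in_peaks`,
#'   `frip` (NA with an explanatory `note` when there are no fragments).
#' @export
compute_frip <- function(fragments, peaks) {
  total <- length(fragments)
  if (total == 0)
    return(data.frame(total_fragments = 0L, fragments_in_peaks = 0L,
                      frip = NA_real_, note = "no fragments"))
  in_peaks <- if (length(peaks) == 0) 0L else
    sum(IRanges::overlapsAny(fragments, peaks))
  data.frame(total_fragments = total, fragments_in_peaks = in_peaks,
             frip = in_peaks / total, note = "")
}

#' Per-sample QC table for a cohort
#' @param cohort cohort list (`samples`, `metadata`).
#' @return data.frame with one row per sample (`sample_id` plus
#'   [compute_frip()] columns).
#' @export
sample_qc <- function(cohort) {
  rows <- lapply(names(cohort$samples), function(sid) {
    s <- cohort$samples[[sid]]
    cbind(sample_id = sid, compute_frip(s$fragments, s$peaks))
  })
  do.call(rbind, rows)
}

#' Sample quality gate on fragment depth and FRiP
#'
#' A sample passes iff it has at least `min_fragments` mapped fragments
#' AND a FRiP of at least `min_frip`; both comparisons are inclusive.
#' Defaults are the standard gate for this assay: 2 million mapped
#' fragments and FRiP 0.2. Samples with undefined FRiP (no fragments)
#' fail with the recorded reason.
#'
#' @param qc data.frame from [sample_qc()] (or with the same columns).
#' @param min_fragments inclusive minimum fragment count.
#' @param min_frip inclusive minimum FRiP.
#' @return the input with a logical `pass` column and a `reason` column
#'   (empty for passing samples).
#' @export
qc_filter <- function(qc, min_fragments = 2e6, min_frip = 0.2) {
  frip_ok <- !is.na(qc$frip) & qc$frip >= min_frip
  depth_ok <- qc$total_fragments >= min_fragments
  qc$pass <- depth_ok & frip_ok
  qc$reason <- ""
  qc$reason[!depth_ok] <- "low depth"
  qc$reason[depth_ok & !frip_ok] <- "low FRiP"
  qc$reason[is.na(qc$frip)] <- "no fragments"
  qc
}
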