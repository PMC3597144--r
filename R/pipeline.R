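## End-to-end per-sample pipeline: clean -> breakpoints -> anchor -> pair
## constraints, with a structured funnel log.

#' Detect fusion candidates in one sample
#'
#' Convenience wrapper running the whole per-sample pipeline: artifact
#' removal, breakpoint detection, gene anchoring and the constraint funnel.
#' Stage counts are reported to `message()` so that runs leave an auditable
#' funnel trail on stderr.
#'
#' @param segmentation A `segmentation_profile` (see [read_segmentation()]).
#' @param probes A `probe_panel` (see [read_probes()]).
#' @param genes Gene models (see [read_gene_models()]).
#' @param params A [fusion_params()] object; unset fusion length bounds are
#'   derived from the gene collection.
#' @param sample_id Sample label; defaults to the profile's sample id.
#' @param verbose Emit per-stage counts via `message()`.
#' @return Candidate data frame as from [evaluate_candidates()], with the
#'   drop log in attribute `drops` and the anchor table in attribute
#'   `anchored`.
#' @export
detect_sample <- function(segmentation, probes, genes,
                          params = fusion_params(), sample_id = NULL,
                          verbose = TRUE) {
  if (is.null(sample_id)) {
    sample_id <- attr(segmentation, "sample_id")
    if (is.null(sample_id) || is.na(sample_id)) sample_id <- "sample"
  }
  params <- set_length_bounds(params, genes)
  cleaned <- remove_single_probe_segments(segmentation, params)
  bps <- detect_breakpoints(cleaned)
  anchored <- suppressWarnings(anchor_genes(bps, genes, cleaned, params))
  cand <- evaluate_candidates(anchored, probes, params, sample_id)
  if (verbose) {
    drops <- attr(cand, "drops")
    message(sprintf(
      "[%s] segments %d -> %d after cleaning; breakpoints %d; anchors %d; pairs kept %d (dropped: %s)",
      sample_id, nrow(segmentation), nrow(cleaned), nrow(bps), nrow(anchored),
      nrow(cand),
      if (nrow(drops) == 0L) "none" else
        paste(sprintf("%s=%d", names(table(drops$stage)), table(drops$stage)),
              collapse = ", ")))
  }
  attr(cand, "anchored") <- anchored
  cand
}

#' Detect candidates for every sample of a cohort and group them
#'
#' @param dataset A simulated cohort from [simulate_cohort()], or any list
#'   with the same shape (`genes`, `samples` with `segmentation`/`probes`).
#' @param params A [fusion_params()] object.
#' @param verbose Emit per-stage counts.
#' @return Grouped fusion report from [evaluate_all()], with the combined
#'   candidate table in attribute `candidates`.
#' @export
run_cohort <- function(dataset, params = fusion_params(), verbose = TRUE) {
  params <- set_length_bounds(params, dataset$genes)
  cands <- lapply(names(dataset$samples), function(sid) {
    s <- dataset$samples[[sid]]
    detect_sample(s$segmentation, s$probes, dataset$genes, params,
                  sample_id = sid, verbose = verbose)
  })
  combined <- do.call(rbind, lapply(cands, as.data.frame))
  grouped <- evaluate_all(combined, params)
  attr(grouped, "candidates") <- combined
  grouped
}
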