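#' Tunable parameters of the fusion-detection pipeline
#'
#' Single home for every numeric rule applied by the pipeline: the gene
#' anchoring distance, the copy-number tolerance between fusion partners,
#' the crossover window size, the correlation cutoff, the loess span grid,
#' the cross-sample grouping rules and the fusion length bounds.
#'
#' @param max_breakpoint_distance_bp Maximum distance (bp) between a
#'   non-spanning gene end and the nearest breakpoint for the gene to be
#'   anchored. Default 10000.
#' @param cn_tolerance Maximum allowed absolute difference between the total
#'   copy numbers of the two fusion partners. Default 1.
#' @param crossover_probes Number of probes taken from each partner
#'   subsegment to form the crossover window; a subsegment with fewer probes
#'   is ignored. Default 7.
#' @param min_abs_correlation Candidates are kept only if the absolute
#'   Pearson correlation of the smoothed crossover windows exceeds this
#'   value (strict inequality). Default 0.9.
#' @param span_grid_lo,span_grid_hi,span_grid_step Loess span grid in
#'   percent of the data points. Defaults 2, 95, 1.
#' @param group_min_samples Minimum number of samples sharing a gene pair
#'   for a group (and for a reported subgroup). Default 2.
#' @param length_fraction Dendrogram cut height as a fraction of the group's
#'   median fusion length. Default 0.40.
#' @param min_fusion_len_bp,max_fusion_len_bp Inclusive bounds on the fusion
#'   length (sum of both subsegment lengths). Defaults NA: derived from the
#'   shortest and longest gene in the gene collection (see
#'   [read_gene_models()] / [set_length_bounds()]).
#' @param artifact_max_probes Segments of at most this many probes are
#'   treated as segmentation artifacts and removed. Default 1.
#' @param max_pairs_per_sample Guard against combinatorial blow-up in pair
#'   enumeration. Default 1e6.
#' @param cut_mode How the subgroup dendrogram is cut: `"height"` (cut at
#'   `length_fraction * median fusion length`) or `"min-cluster-size"`
#'   (smallest height at which every cluster has at least
#'   `group_min_samples` members). Default `"height"`.
#' @return A list of class `fusion_params`.
#' @export
fusion_params <- function(max_breakpoint_distance_bp = 10000L,
                          cn_tolerance = 1L,
                          crossover_probes = 7L,
                          min_abs_correlation = 0.9,
                          span_grid_lo = 2,
                          span_grid_hi = 95,
                          span_grid_step = 1,
                          group_min_samples = 2L,
                          length_fraction = 0.40,
                          min_fusion_len_bp = NA_integer_,
                          max_fusion_len_bp = NA_integer_,
                          artifact_max_probes = 1L,
                          max_pairs_per_sample = 1e6,
                          cut_mode = c("height", "min-cluster-size")) {
  cut_mode <- match.arg(cut_mode)
  p <- list(
    max_breakpoint_distance_bp = as.integer(max_breakpoint_distance_bp),
    cn_tolerance = as.integer(cn_tolerance),
    crossover_probes = as.integer(crossover_probes),
    min_abs_correlation = as.numeric(min_abs_correlation),
    span_grid_lo = as.numeric(span_grid_lo),
    span_grid_hi = as.numeric(span_grid_hi),
    span_grid_step = as.numeric(span_grid_step),
    group_min_samples = as.integer(group_min_samples),
    length_fraction = as.numeric(length_fraction),
    min_fusion_len_bp = as.integer(min_fusion_len_bp),
    max_fusion_len_bp = as.integer(max_fusion_len_bp),
    artifact_max_probes = as.integer(artifact_max_probes),
    max_pairs_per_sample = as.numeric(max_pairs_per_sample),
    cut_mode = cut_mode
  )
  stopifnot(
    p$max_breakpoint_distance_bp > 0L,
    p$cn_tolerance >= 0L,
    p$crossover_probes > 0L,
    p$min_abs_correlation > 0, p$min_abs_correlation <= 1,
    p$span_grid_lo > 0, p$span_grid_step > 0,
    p$span_grid_lo < p$span_grid_hi,
    p$group_min_samples > 0L,
    p$length_fraction > 0, p$length_fraction < 1,
    p$artifact_max_probes >= 1L,
    p$max_pairs_per_sample > 0
  )
  class(p) <- "fusion_params"
  p
}

#' Derive fusion length bounds from a gene collection
#'
#' The minimal and maximal acceptable fusion lengths are set to the lengths
#' of the shortest and longest gene in the collection, unless the caller
#' already fixed them.
#'
#' @param params A [fusion_params()] object.
#' @param genes A gene model data frame from [read_gene_models()].
#' @return The updated parameter object.
#' @export
set_length_bounds <- function(params, genes) {
  stopifnot(inherits(params, "fusion_params"), nrow(genes) >= 1L)
  len <- genes$end - genes$start + 1L
  if (is.na(params$min_fusion_len_bp)) params$min_fusion_len_bp <- as.integer(min(len))
  if (is.na(params$max_fusion_len_bp)) params$max_fusion_len_bp <- as.integer(max(len))
  params
}

#' @export
print.fusion_params <- function(x, ...) {
  cat("Fusion detection parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, as.character(x[[nm]])))
  invisible(x)
}
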