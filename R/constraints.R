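## Pairing of anchored genes and the per-pair constraints: copy-number
## agreement, read-through orientation, fusion length, and concordance of
## the loess-smoothed probe intensities across the putative junction.

#' Enumerate candidate 5'/3' anchor pairs
#'
#' All ordered (5' anchor, 3' anchor) combinations are formed, across
#' chromosomes as well as within them (translocation-style fusions are
#' allowed). A gene -- or two subsegments of one gene -- is never paired
#' with itself at the same breakpoint, which would merely reconstitute the
#' unbroken gene.
#'
#' @param anchored Anchor table from [anchor_genes()].
#' @param params A [fusion_params()] object.
#' @return A data frame of index pairs `i5`, `i3` into `anchored`.
#' @export
enumerate_pairs <- function(anchored, params = fusion_params()) {
  i5 <- which(anchored$role == "five_prime")
  i3 <- which(anchored$role == "three_prime")
  if (length(i5) == 0L || length(i3) == 0L) {
    return(data.frame(i5 = integer(), i3 = integer()))
  }
  pairs <- expand.grid(i5 = i5, i3 = i3, KEEP.OUT.ATTRS = FALSE)
  same_gene <- anchored$gene_id[pairs$i5] == anchored$gene_id[pairs$i3]
  same_bp <- !is.na(anchored$anchor_pos[pairs$i5]) &
    !is.na(anchored$anchor_pos[pairs$i3]) &
    anchored$chrom[pairs$i5] == anchored$chrom[pairs$i3] &
    anchored$anchor_pos[pairs$i5] == anchored$anchor_pos[pairs$i3]
  ## one subsegment in both roles must not be joined to itself either
  same_sub <- anchored$sub_start[pairs$i5] == anchored$sub_start[pairs$i3] &
    anchored$sub_end[pairs$i5] == anchored$sub_end[pairs$i3]
  pairs <- pairs[!(same_gene & (same_bp | same_sub)), , drop = FALSE]
  if (nrow(pairs) > params$max_pairs_per_sample) {
    warning(sprintf("candidate pairs capped at %g (had %d)",
                    params$max_pairs_per_sample, nrow(pairs)))
    pairs <- pairs[seq_len(params$max_pairs_per_sample), , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Copy-number agreement filter
#'
#' Both partners of a physically joined fusion are replicated together, so
#' their total copy numbers should be close; segmentation uncertainty is
#' allowed for by a tolerance of +/- `cn_tolerance`.
#'
#' @param cn_5p,cn_3p Total copy numbers of the 5' and 3' anchors.
#' @param params A [fusion_params()] object.
#' @return Logical: keep the pair?
#' @export
filter_cn <- function(cn_5p, cn_3p, params = fusion_params()) {
  abs(cn_5p - cn_3p) <= params$cn_tolerance
}

#' Read-through orientation filter
#'
#' The gene end nearest the breakpoint defines the fusion side, and the
#' strand at that end must let transcription read through the junction:
#' the 5' partner contributes its transcriptional 5' portion (junction at
#' its transcript-3'-facing end) and the 3' partner its 3' portion
#' (junction at its transcript-5'-facing end).
#'
#' @param strand_5p,strand_3p Strands (`"+"`/`"-"`) of the two anchors.
#' @param side_5p,side_3p Which edge of each anchored (sub)segment faces
#'   the junction (`"left"` = lower coordinate, `"right"` = higher).
#' @return Logical: keep the pair?
#' @export
filter_orientation <- function(strand_5p, side_5p, strand_3p, side_3p) {
  donates_five_prime(strand_5p, side_5p) &
    donates_three_prime(strand_3p, side_3p)
}

#' Fusion length filter
#'
#' The fusion length is the sum of the two anchored subsegment lengths and
#' must lie (inclusively) between the minimal and maximal acceptable
#' lengths, by default the shortest and longest gene of the collection.
#'
#' @param fusion_len_bp Fusion length in base pairs.
#' @param params A [fusion_params()] object with length bounds set.
#' @return Logical: keep the pair?
#' @export
filter_length <- function(fusion_len_bp, params) {
  if (is.na(params$min_fusion_len_bp) || is.na(params$max_fusion_len_bp)) {
    stop("fusion length bounds are unset; derive them with set_length_bounds()")
  }
  fusion_len_bp >= params$min_fusion_len_bp &
    fusion_len_bp <= params$max_fusion_len_bp
}

## k probes of a subsegment nearest its fusion-side edge, ordered along the
## genome. Returns NULL if fewer than k probes fall inside the subsegment.
side_probes <- function(panel, chrom, sub_start, sub_end, side, k) {
  sub <- panel[panel$chrom == chrom & panel$pos >= sub_start &
                 panel$pos <= sub_end, , drop = FALSE]
  if (nrow(sub) < k) return(NULL)
  sub <- sub[order(sub$pos), , drop = FALSE]
  if (side == "right") utils::tail(sub, k) else utils::head(sub, k)
}

#' Extract the crossover window of a candidate pair
#'
#' The junction neighbourhood is represented by the `crossover_probes`
#' probes of each partner subsegment nearest its fusion-side boundary. The
#' 5' series is ordered toward the junction and the 3' series away from
#' it, so that concatenating them forms one continuous virtual track
#' across the junction. A pair with fewer than `crossover_probes` probes
#' on either side is ignored.
#'
#' @param anchor_5p,anchor_3p Single rows of the anchor table.
#' @param panel A `probe_panel`.
#' @param params A [fusion_params()] object.
#' @return A list with elements `five_prime`, `three_prime` (numeric
#'   intensity vectors of length `crossover_probes`), `probe_ids_5p`,
#'   `probe_ids_3p`; or `NULL` when a side lacks probes.
#' @export
crossover_window <- function(anchor_5p, anchor_3p, panel,
                             params = fusion_params()) {
  k <- params$crossover_probes
  p5 <- side_probes(panel, anchor_5p$chrom, anchor_5p$sub_start,
                    anchor_5p$sub_end, anchor_5p$fusion_side, k)
  p3 <- side_probes(panel, anchor_3p$chrom, anchor_3p$sub_start,
                    anchor_3p$sub_end, anchor_3p$fusion_side, k)
  if (is.null(p5) || is.null(p3)) return(NULL)
  ## toward the junction for the 5' partner ...
  if (anchor_5p$fusion_side == "left") p5 <- p5[rev(seq_len(k)), , drop = FALSE]
  ## ... and away from it for the 3' partner
  if (anchor_3p$fusion_side == "right") p3 <- p3[rev(seq_len(k)), , drop = FALSE]
  list(five_prime = p5$intensity, three_prime = p3$intensity,
       probe_ids_5p = p5$probe_id, probe_ids_3p = p3$probe_id)
}

## Fit a loess smoother on an index grid; warnings from deliberately small
## spans are muffled -- the AICc guard rejects degenerate fits instead.
quiet_loess <- function(y, span) {
  x <- seq_along(y)
  withCallingHandlers(
    stats::loess(y ~ x, span = span, degree = 2, family = "gaussian",
                 control = stats::loess.control(surface = "direct",
                                                statistics = "exact")),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

## AICc of a loess fit: n*log(RSS/n) + n*(n + tr)/(n - tr - 2), the standard
## small-sample criterion for smoother selection, with tr the trace of the
## smoothing operator. Inf marks an infeasible span (saturated or unstable
## fit).
loess_aicc <- function(fit, n) {
  tr <- fit$trace.hat
  rss <- sum(stats::residuals(fit)^2)
  if (!is.finite(tr) || !is.finite(rss)) return(Inf)
  if (n - tr - 2 <= 0) return(Inf)
  n * log(max(rss, 1e-300) / n) + n * (n + tr) / (n - tr - 2)
}

#' Select a loess span by corrected AIC over a percentage grid
#'
#' Candidate spans run from `span_grid_lo` to `span_grid_hi` percent of the
#' data points in steps of `span_grid_step`. For each feasible span the
#' small-sample-corrected Akaike information criterion of the local
#' quadratic fit is evaluated; the smallest span attaining the minimal
#' AICc is returned (ties break toward the smaller span). Spans whose fits
#' saturate (effective degrees of freedom too close to n) or fail are
#' infeasible.
#'
#' @param values Ordered numeric series (at least 4 values).
#' @param params A [fusion_params()] object.
#' @return The selected span, as a percentage of the data points.
#' @export
select_loess_span <- function(values, params = fusion_params()) {
  n <- length(values)
  if (n < 4L) stop("span selection needs at least 4 values")
  grid <- seq(params$span_grid_lo, params$span_grid_hi,
              by = params$span_grid_step)
  aicc <- vapply(grid, function(pct) {
    fit <- tryCatch(quiet_loess(values, pct / 100), error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    loess_aicc(fit, n)
  }, numeric(1))
  if (all(is.infinite(aicc) & aicc > 0)) {
    stop("no feasible loess span on the grid for this series")
  }
  grid[which.min(aicc)]   # which.min returns the first (smallest span) tie
}

#' Loess-smooth a series at a given span
#'
#' Locally weighted quadratic regression (tricube weights) on the
#' observation index, evaluated at each point. Constant and linear series
#' are reproduced exactly.
#'
#' @param values Ordered numeric series.
#' @param span_pct Span as a percentage of the data points.
#' @return Numeric vector of smoothed values, same length.
#' @export
smooth_loess <- function(values, span_pct) {
  fit <- tryCatch(quiet_loess(values, span_pct / 100),
                  error = function(e) {
                    stop(sprintf("loess span %.1f%% infeasible for %d values: %s",
                                 span_pct, length(values), conditionMessage(e)))
                  })
  as.numeric(stats::fitted(fit))
}

#' Pearson correlation of the smoothed crossover series
#'
#' A consistent intensity trend across the junction yields a high absolute
#' correlation between the two smoothed windows; the candidate passes when
#' `|r| > min_abs_correlation` (negative correlations pass too -- the
#' filter is on the magnitude of the trend agreement).
#'
#' @param smoothed_5p,smoothed_3p Smoothed intensity vectors (equal length).
#' @return Pearson correlation, or `NA` when either side has zero variance
#'   (a degenerate window).
#' @export
crossover_correlation <- function(smoothed_5p, smoothed_3p) {
  if (stats::sd(smoothed_5p) == 0 || stats::sd(smoothed_3p) == 0) {
    return(NA_real_)
  }
  stats::cor(smoothed_5p, smoothed_3p, method = "pearson")
}

#' Root-mean-square difference of the smoothed crossover series
#'
#' Measures the distance between the smoothed border intensities of the
#' two partners; a value close to zero indicates a consistent crossover.
#'
#' @param smoothed_5p,smoothed_3p Smoothed intensity vectors (equal length).
#' @return Non-negative RMS difference.
#' @export
crossover_rms <- function(smoothed_5p, smoothed_3p) {
  sqrt(mean((smoothed_5p - smoothed_3p)^2))
}

drop_row <- function(sample_id, gene5, gene3, stage, reason) {
  data.frame(sample = sample_id, gene_5p = gene5, gene_3p = gene3,
             stage = stage, reason = reason, stringsAsFactors = FALSE)
}

#' Evaluate all anchored-gene pairs of one sample
#'
#' Runs the full per-sample constraint funnel: pair enumeration, then the
#' copy-number, orientation and length filters, then crossover-window
#' extraction, AICc span selection on the concatenated 14-probe track,
#' per-side loess smoothing and the correlation filter. Pairs surviving
#' every stage are reported as fusion candidates with their correlation,
#' RMS and span; each dropped pair is recorded with the stage and reason.
#'
#' @param anchored Anchor table from [anchor_genes()].
#' @param panel A `probe_panel` for the same sample.
#' @param params A [fusion_params()] object with length bounds set.
#' @param sample_id Sample label used in the report.
#' @return A candidate data frame (`sample`, `gene_5p`, `gene_3p`,
#'   `start_5p`, `end_5p`, `start_3p`, `end_3p`, `cn_5p`, `cn_3p`,
#'   `correlation`, `rms`, plus `span_pct` and `fusion_len_bp`), with the
#'   drop log in attribute `drops`.
#' @export
evaluate_candidates <- function(anchored, panel, params, sample_id = "sample") {
  pairs <- enumerate_pairs(anchored, params)
  drops <- list()
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    a5 <- anchored[pairs$i5[r], , drop = FALSE]
    a3 <- anchored[pairs$i3[r], , drop = FALSE]
    g5 <- a5$gene_id; g3 <- a3$gene_id
    if (!filter_cn(a5$total_cn, a3$total_cn, params)) {
      drops[[length(drops) + 1L]] <- drop_row(sample_id, g5, g3, "cn",
        sprintf("CN difference %d exceeds tolerance", abs(a5$total_cn - a3$total_cn)))
      next
    }
    if (!filter_orientation(a5$strand, a5$fusion_side, a3$strand, a3$fusion_side)) {
      drops[[length(drops) + 1L]] <- drop_row(sample_id, g5, g3, "orientation",
        "strand/side combination does not read through the junction")
      next
    }
    flen <- (a5$sub_end - a5$sub_start + 1L) + (a3$sub_end - a3$sub_start + 1L)
    if (!filter_length(flen, params)) {
      drops[[length(drops) + 1L]] <- drop_row(sample_id, g5, g3, "length",
        sprintf("fusion length %d outside bounds", flen))
      next
    }
    win <- crossover_window(a5, a3, panel, params)
    if (is.null(win)) {
      drops[[length(drops) + 1L]] <- drop_row(sample_id, g5, g3, "window",
        "fewer probes than the crossover window on one side")
      next
    }
    track <- c(win$five_prime, win$three_prime)
    span <- tryCatch(select_loess_span(track, params), error = function(e) NA_real_)
    if (is.na(span)) {
      drops[[length(drops) + 1L]] <- drop_row(sample_id, g5, g3, "span",
        "no feasible loess span")
      next
    }
    s5 <- smooth_loess(win$five_prime, span)
    s3 <- smooth_loess(win$three_prime, span)
    r_xy <- crossover_correlation(s5, s3)
    if (is.na(r_xy)) {
      drops[[length(drops) + 1L]] <- drop_row(sample_id, g5, g3, "correlation",
        "degenerate window")
      next
    }
    if (abs(r_xy) <= params$min_abs_correlation) {
      drops[[length(drops) + 1L]] <- drop_row(sample_id, g5, g3, "correlation",
        sprintf("|r| = %.4f below threshold", abs(r_xy)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sample_id, gene_5p = g5, gene_3p = g3,
      start_5p = a5$sub_start, end_5p = a5$sub_end,
      start_3p = a3$sub_start, end_3p = a3$sub_end,
      cn_5p = a5$total_cn, cn_3p = a3$total_cn,
      correlation = r_xy, rms = crossover_rms(s5, s3),
      span_pct = span, fusion_len_bp = flen,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else data.frame(
    sample = character(), gene_5p = character(), gene_3p = character(),
    start_5p = integer(), end_5p = integer(), start_3p = integer(),
    end_3p = integer(), cn_5p = integer(), cn_3p = integer(),
    correlation = numeric(), rms = numeric(), span_pct = numeric(),
    fusion_len_bp = integer(), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "drops") <- if (length(drops) > 0L) do.call(rbind, drops) else
    drop_row(character(0), character(0), character(0), character(0), character(0))
  out
}

#' Explain why a specific gene pair is (not) a fusion candidate
#'
#' Replays the constraint funnel for one ordered gene pair, regardless of
#' whether pair enumeration would have produced it: useful to diagnose why
#' a suspected fusion is absent from the report. The first failing stage is
#' returned; `"anchoring"`/`"distance"` when a partner was never anchored,
#' `"orientation"` when the anchored roles cannot form a read-through
#' junction, otherwise one of the funnel stages.
#'
#' @param anchored Anchor table from [anchor_genes()].
#' @param gene_5p,gene_3p Gene ids of the putative 5' and 3' partners.
#' @param genes Gene model table (to distinguish an unanchored gene that
#'   exists from an unknown id).
#' @param panel A `probe_panel`.
#' @param params A [fusion_params()] object with length bounds set.
#' @return A list with `kept` (logical), `stage` (character; `"kept"` when
#'   the pair survives) and `detail`.
#' @export
diagnose_pair <- function(anchored, gene_5p, gene_3p, genes, panel, params) {
  for (gid in c(gene_5p, gene_3p)) {
    if (!gid %in% genes$gene_id) {
      return(list(kept = FALSE, stage = "unknown_gene", detail = gid))
    }
    if (!gid %in% anchored$gene_id) {
      return(list(kept = FALSE, stage = "distance",
                  detail = sprintf("%s not anchored to any breakpoint", gid)))
    }
  }
  a5s <- anchored[anchored$gene_id == gene_5p & anchored$role == "five_prime", , drop = FALSE]
  a3s <- anchored[anchored$gene_id == gene_3p & anchored$role == "three_prime", , drop = FALSE]
  if (nrow(a5s) == 0L || nrow(a3s) == 0L) {
    return(list(kept = FALSE, stage = "orientation",
                detail = "anchored roles cannot form a read-through junction"))
  }
  last <- list(kept = FALSE, stage = "enumeration", detail = "no pairing")
  for (i in seq_len(nrow(a5s))) {
    for (j in seq_len(nrow(a3s))) {
      a5 <- a5s[i, , drop = FALSE]; a3 <- a3s[j, , drop = FALSE]
      if (!filter_cn(a5$total_cn, a3$total_cn, params)) {
        last <- list(kept = FALSE, stage = "cn",
                     detail = sprintf("CN %d vs %d", a5$total_cn, a3$total_cn))
        next
      }
      flen <- (a5$sub_end - a5$sub_start + 1L) + (a3$sub_end - a3$sub_start + 1L)
      if (!filter_length(flen, params)) {
        last <- list(kept = FALSE, stage = "length",
                     detail = sprintf("fusion length %d", flen))
        next
      }
      win <- crossover_window(a5, a3, panel, params)
      if (is.null(win)) {
        last <- list(kept = FALSE, stage = "window",
                     detail = "fewer probes than the crossover window")
        next
      }
      span <- tryCatch(select_loess_span(c(win$five_prime, win$three_prime),
                                         params),
                       error = function(e) NA_real_)
      if (is.na(span)) {
        last <- list(kept = FALSE, stage = "span", detail = "no feasible span")
        next
      }
      s5 <- smooth_loess(win$five_prime, span)
      s3 <- smooth_loess(win$three_prime, span)
      r_xy <- crossover_correlation(s5, s3)
      if (is.na(r_xy)) {
        last <- list(kept = FALSE, stage = "correlation",
                     detail = "degenerate window")
        next
      }
      if (abs(r_xy) <= params$min_abs_correlation) {
        last <- list(kept = FALSE, stage = "correlation",
                     detail = sprintf("|r| = %.4f", abs(r_xy)))
        next
      }
      return(list(kept = TRUE, stage = "kept",
                  detail = sprintf("r = %.4f", r_xy)))
    }
  }
  last
}
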