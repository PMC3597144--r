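## Segmentation cleaning, breakpoint enumeration and gene anchoring.

#' Remove single-probe segmentation artifacts
#'
#' Segments supported by at most `artifact_max_probes` probes cannot be
#' distinguished from experimental or algorithmic artifacts and are
#' removed. The removed run's interval and probe count are absorbed into
#' the flanking segment with equal copy number when both flanks share a CN
#' (the flanks then merge into one segment); otherwise into the left flank.
#' Same-CN neighbours created by removal are merged afterwards, and
#' chromosomes consisting solely of artifacts are dropped.
#'
#' @param profile A `segmentation_profile`.
#' @param params A [fusion_params()] object.
#' @return The cleaned `segmentation_profile`.
#' @export
remove_single_probe_segments <- function(profile, params = fusion_params()) {
  stopifnot(inherits(profile, "segmentation_profile"))
  kmax <- params$artifact_max_probes
  cleaned <- lapply(split(as.data.frame(profile), profile$chrom), function(sub) {
    sub <- sub[order(sub$start), , drop = FALSE]
    ## flag artifacts up front: absorbing one artifact into another must
    ## not launder the receiver into a real segment
    sub$.artifact <- sub$n_probes <= kmax
    if (all(sub$.artifact)) return(sub[0L, , drop = FALSE])
    repeat {
      arte <- which(sub$.artifact)
      if (length(arte) == 0L) break
      i <- arte[1L]
      n <- nrow(sub)
      if (i == 1L) {                       # absorb into right flank
        sub$start[2L] <- sub$start[1L]
        sub$n_probes[2L] <- sub$n_probes[2L] + sub$n_probes[1L]
        sub <- sub[-1L, , drop = FALSE]
      } else if (i == n) {                 # absorb into left flank
        sub$end[n - 1L] <- sub$end[n]
        sub$n_probes[n - 1L] <- sub$n_probes[n - 1L] + sub$n_probes[n]
        sub <- sub[-n, , drop = FALSE]
      } else if (sub$total_cn[i - 1L] == sub$total_cn[i + 1L] &&
                 !sub$.artifact[i + 1L]) {
        ## flanks share CN: fold all three into the left flank
        sub$end[i - 1L] <- sub$end[i + 1L]
        sub$n_probes[i - 1L] <- sub$n_probes[i - 1L] + sub$n_probes[i] +
          sub$n_probes[i + 1L]
        sub <- sub[-c(i, i + 1L), , drop = FALSE]
      } else {                             # flanks differ: left flank takes it
        sub$end[i - 1L] <- sub$end[i]
        sub$n_probes[i - 1L] <- sub$n_probes[i - 1L] + sub$n_probes[i]
        sub <- sub[-i, , drop = FALSE]
      }
    }
    sub$.artifact <- NULL
    sub
  })
  cleaned <- cleaned[vapply(cleaned, nrow, 0L) > 0L]
  if (length(cleaned) == 0L) {
    out <- as.data.frame(profile)[0L, , drop = FALSE]
  } else {
    out <- do.call(rbind, cleaned)
  }
  out <- merge_same_cn(out)
  rownames(out) <- NULL
  structure(out, sample_id = attr(profile, "sample_id"),
            class = c("segmentation_profile", "data.frame"))
}

#' Detect copy-number breakpoints in a segmentation profile
#'
#' A breakpoint is the boundary between two adjacent segments of one
#' chromosome whose total copy numbers differ. After cleaning, every
#' adjacent pair differs, so each chromosome with k segments yields k - 1
#' breakpoints. The boundary position is the floor of the midpoint between
#' the left segment's end and the right segment's start: the true break
#' lies between probes and a deterministic convention is needed for
#' distance computations.
#'
#' @param profile A (cleaned) `segmentation_profile`.
#' @return A data frame with one row per breakpoint: `chrom`, `left_end`,
#'   `right_start`, `boundary_pos`, `cn_left`, `cn_right`.
#' @export
detect_breakpoints <- function(profile) {
  stopifnot(inherits(profile, "segmentation_profile"))
  res <- lapply(split(as.data.frame(profile), profile$chrom), function(sub) {
    sub <- sub[order(sub$start), , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) return(NULL)
    keep <- which(sub$total_cn[-n] != sub$total_cn[-1L])
    if (length(keep) == 0L) return(NULL)
    data.frame(
      chrom = sub$chrom[keep],
      left_end = sub$end[keep],
      right_start = sub$start[keep + 1L],
      boundary_pos = as.integer(floor((sub$end[keep] + sub$start[keep + 1L]) / 2)),
      cn_left = sub$total_cn[keep],
      cn_right = sub$total_cn[keep + 1L],
      stringsAsFactors = FALSE
    )
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L) {
    return(data.frame(chrom = character(), left_end = integer(),
                      right_start = integer(), boundary_pos = integer(),
                      cn_left = integer(), cn_right = integer()))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$boundary_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Does a gene end at this side of a breakpoint donate its transcriptional
## 5' portion?  side = which edge of the anchored (sub)segment faces the
## junction ("left" = lower coordinate).  A gene donates its 5' portion when
## the junction sits at its transcript-3'-facing end: the right edge on the
## forward strand, the left edge on the reverse strand.
donates_five_prime <- function(strand, side) {
  (strand == "+" & side == "right") | (strand == "-" & side == "left")
}
donates_three_prime <- function(strand, side) {
  (strand == "+" & side == "left") | (strand == "-" & side == "right")
}

anchor_row <- function(gene, role, origin, boundary, side, sub_start, sub_end, cn) {
  data.frame(gene_id = gene$gene_id, gene_name = gene$gene_name,
             chrom = gene$chrom, strand = gene$strand,
             role = role, origin = origin,
             anchor_pos = as.integer(boundary), fusion_side = side,
             sub_start = as.integer(sub_start), sub_end = as.integer(sub_end),
             total_cn = as.integer(cn), stringsAsFactors = FALSE)
}

## CN of the cleaned profile segment covering a position (NA if uncovered).
segment_cn_at <- function(profile, chrom, pos) {
  sub <- profile[profile$chrom == chrom, , drop = FALSE]
  hit <- which(sub$start <= pos & sub$end >= pos)
  if (length(hit) == 0L) NA_integer_ else sub$total_cn[hit[1L]]
}

#' Anchor genes to copy-number breakpoints
#'
#' Two cases are handled. A gene spanning one or more breakpoints is split
#' into subsegments at each interior boundary: with two subsegments one
#' becomes the 5' anchor and the other the 3' anchor (by strand and side);
#' with three or more, the most upstream subsegment in transcript
#' orientation is the 5' anchor, the most downstream the 3' anchor, and
#' inner subsegments serve both roles (emitted as two anchor records, one
#' per flanking breakpoint). A gene that does not span a breakpoint is
#' anchored whole when the nearer gene end lies within
#' `max_breakpoint_distance_bp` of a boundary; its role follows from its
#' strand and from which end faces the junction.
#'
#' @param breakpoints Breakpoint table from [detect_breakpoints()].
#' @param genes Gene model data frame from [read_gene_models()].
#' @param profile The cleaned `segmentation_profile` (supplies segment CNs).
#' @param params A [fusion_params()] object.
#' @return A data frame of anchored genes: `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `role` (`five_prime`/`three_prime`), `origin`
#'   (`whole`/`terminal`/`both`), `anchor_pos`, `fusion_side`
#'   (`left`/`right`), `sub_start`, `sub_end`, `total_cn`.
#' @export
anchor_genes <- function(breakpoints, genes, profile, params = fusion_params()) {
  out <- list()
  profile_chroms <- unique(profile$chrom)
  skipped <- setdiff(unique(genes$chrom), profile_chroms)
  if (length(skipped) > 0L) {
    warning(sprintf("genes on chromosome(s) absent from profile skipped: %s",
                    paste(skipped, collapse = ", ")))
  }
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, , drop = FALSE]
    if (!g$chrom %in% profile_chroms) next
    bps <- breakpoints[breakpoints$chrom == g$chrom, , drop = FALSE]
    if (nrow(bps) == 0L) next
    inside <- bps$boundary_pos >= g$start & bps$boundary_pos <= g$end
    if (any(inside)) {
      out[[length(out) + 1L]] <- split_spanning_gene(g, bps[inside, , drop = FALSE],
                                                     profile)
    } else {
      ## whole-gene anchoring to every breakpoint within range
      for (bi in seq_len(nrow(bps))) {
        b <- bps[bi, , drop = FALSE]
        if (b$boundary_pos < g$start) {
          side <- "left"; dist <- g$start - b$boundary_pos; cn <- b$cn_right
        } else {
          side <- "right"; dist <- b$boundary_pos - g$end; cn <- b$cn_left
        }
        if (dist > params$max_breakpoint_distance_bp) next
        role <- if (donates_five_prime(g$strand, side)) "five_prime" else "three_prime"
        out[[length(out) + 1L]] <-
          anchor_row(g, role, "whole", b$boundary_pos, side, g$start, g$end, cn)
      }
    }
  }
  if (length(out) == 0L) {
    return(anchor_row(data.frame(gene_id = character(0), gene_name = character(0),
                                 chrom = character(0), strand = character(0)),
                      character(0), character(0), integer(0), character(0),
                      integer(0), integer(0), integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Split a gene at the interior breakpoints it spans and assign roles.
split_spanning_gene <- function(g, bps, profile) {
  cuts <- sort(bps$boundary_pos)
  starts <- c(g$start, cuts + 1L)
  ends <- c(cuts, g$end)
  k <- length(starts)
  rows <- list()
  ## transcript order: on '+' the leftmost subsegment is the most upstream,
  ## on '-' the rightmost
  upstream_idx <- if (g$strand == "+") 1L else k
  downstream_idx <- if (g$strand == "+") k else 1L
  for (j in seq_len(k)) {
    mid <- floor((starts[j] + ends[j]) / 2)
    cn <- segment_cn_at(profile, g$chrom, mid)
    if (is.na(cn)) next
    left_bp <- if (j > 1L) cuts[j - 1L] else NA_integer_
    right_bp <- if (j < k) cuts[j] else NA_integer_
    if (j == upstream_idx) {
      ## donates the transcript 5' portion; junction at its interior side
      side <- if (g$strand == "+") "right" else "left"
      bp <- if (side == "right") right_bp else left_bp
      rows[[length(rows) + 1L]] <-
        anchor_row(g, "five_prime", "terminal", bp, side, starts[j], ends[j], cn)
    } else if (j == downstream_idx) {
      side <- if (g$strand == "+") "left" else "right"
      bp <- if (side == "right") right_bp else left_bp
      rows[[length(rows) + 1L]] <-
        anchor_row(g, "three_prime", "terminal", bp, side, starts[j], ends[j], cn)
    } else {
      ## inner subsegment: assigned to both groups -> two anchor records.
      ## As a 5' donor its junction is the transcript-3'-side boundary,
      ## as a 3' donor the transcript-5'-side boundary.
      side5 <- if (g$strand == "+") "right" else "left"
      side3 <- if (g$strand == "+") "left" else "right"
      bp5 <- if (side5 == "right") right_bp else left_bp
      bp3 <- if (side3 == "right") right_bp else left_bp
      rows[[length(rows) + 1L]] <-
        anchor_row(g, "five_prime", "both", bp5, side5, starts[j], ends[j], cn)
      rows[[length(rows) + 1L]] <-
        anchor_row(g, "three_prime", "both", bp3, side3, starts[j], ends[j], cn)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}
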