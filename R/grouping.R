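## Cross-sample evaluation: groups of recurrent gene pairs, positional
## conservation, complete-linkage clustering into subgroups.

coord_cols <- c("start_5p", "end_5p", "start_3p", "end_3p")

#' Collect recurrent gene pairs into groups
#'
#' Candidates sharing the same ordered (5' gene, 3' gene) pair in at least
#' `group_min_samples` distinct samples form a group; pairs seen in a
#' single sample are discarded.
#'
#' @param candidates A single data frame of candidates from several samples
#'   (rows carry a `sample` column), or a list of per-sample candidate
#'   data frames.
#' @param params A [fusion_params()] object.
#' @return A named list of groups; each group is the member data frame for
#'   one gene pair, named `"<gene_5p>|<gene_3p>"`.
#' @export
collect_groups <- function(candidates, params = fusion_params()) {
  if (is.data.frame(candidates)) {
    all <- candidates
  } else {
    all <- do.call(rbind, lapply(candidates, as.data.frame))
  }
  if (is.null(all) || nrow(all) == 0L) return(list())
  key <- paste(all$gene_5p, all$gene_3p, sep = "|")
  groups <- split(all, key)
  keep <- vapply(groups, function(g) length(unique(g$sample)), 0L) >=
    params$group_min_samples
  groups <- groups[keep]
  groups <- lapply(groups, function(g) {
    g <- g[order(g$sample), , drop = FALSE]
    rownames(g) <- NULL
    g
  })
  groups[order(names(groups))]
}

#' Positional conservation mask of a group
#'
#' For each of the four fusion coordinates (5' start, 5' end, 3' start,
#' 3' end), tests exact equality across all group members. A group is
#' plausible only when at least two coordinates are conserved -- e.g. the
#' 5'-gene start and the 3'-gene end -- the remaining variability being
#' attributed to breakpoints falling in different introns.
#'
#' @param group A group member data frame (one row per member).
#' @return Named logical vector of length 4 (`TRUE` = conserved), with
#'   attribute `ok` indicating whether at least two positions are
#'   conserved.
#' @export
conserved_positions <- function(group) {
  stopifnot(nrow(group) >= 2L)
  mask <- vapply(coord_cols, function(cc) length(unique(group[[cc]])) == 1L,
                 logical(1))
  attr(mask, "ok") <- sum(mask) >= 2L
  mask
}

#' Euclidean distance matrix over non-conserved coordinates
#'
#' Pairwise Euclidean distances between group members over the
#' non-conserved coordinates only; with every coordinate conserved the
#' matrix is all zero.
#'
#' @param group A group member data frame.
#' @param mask Conservation mask from [conserved_positions()].
#' @return A symmetric numeric matrix with zero diagonal, member rows in
#'   group order.
#' @export
position_distance_matrix <- function(group, mask) {
  n <- nrow(group)
  free <- coord_cols[!mask]
  if (length(free) == 0L) {
    m <- matrix(0, n, n)
  } else {
    coords <- as.matrix(group[, free, drop = FALSE])
    m <- as.matrix(stats::dist(coords, method = "euclidean"))
  }
  dimnames(m) <- list(group$sample, group$sample)
  m
}

#' Median fusion length of a group
#'
#' The fusion length of a member is the sum of its two subsegment lengths;
#' the group median (mean of the middle two for even counts) sets the
#' scale for the clustering cut. All initial members count, including
#' those the clustering later discards.
#'
#' @param group A group member data frame.
#' @return Median fusion length in base pairs.
#' @export
median_fusion_length <- function(group) {
  len <- (group$end_5p - group$start_5p + 1L) +
    (group$end_3p - group$start_3p + 1L)
  stats::median(as.numeric(len))
}

#' Cluster a group into fusion subgroups
#'
#' Complete-linkage hierarchical clustering of the member distance matrix.
#' In `"height"` mode the dendrogram is cut at `length_fraction` times the
#' group's median fusion length -- members farther than that from every
#' cluster end up alone and are discarded; in `"min-cluster-size"` mode the
#' cut is the smallest height at which every cluster has at least
#' `group_min_samples` members. Clusters smaller than `group_min_samples`
#' are labelled `"DISCARDED"`; the rest are numbered 1..k by ascending
#' minimal member coordinates.
#'
#' @param group A group member data frame.
#' @param dmat Distance matrix from [position_distance_matrix()].
#' @param params A [fusion_params()] object.
#' @param median_len Median fusion length (defaults to
#'   [median_fusion_length()] of the group).
#' @return Character vector of subgroup labels (`"1"`, `"2"`, ... or
#'   `"DISCARDED"`), one per member, with attributes `cut_height` and
#'   `merge_heights`.
#' @export
cluster_group <- function(group, dmat, params = fusion_params(),
                          median_len = median_fusion_length(group)) {
  n <- nrow(group)
  stopifnot(n >= 2L, nrow(dmat) == n)
  tree <- stats::hclust(stats::as.dist(dmat), method = "complete")
  if (params$cut_mode == "height") {
    cut_h <- params$length_fraction * median_len
    cl <- stats::cutree(tree, h = cut_h)
  } else {
    heights <- sort(unique(c(0, tree$height)))
    cl <- NULL
    cut_h <- NA_real_
    for (h in heights) {
      cand <- stats::cutree(tree, h = h)
      if (all(table(cand) >= params$group_min_samples)) {
        cl <- cand; cut_h <- h; break
      }
    }
    if (is.null(cl)) {            # single cluster at the top
      cl <- rep(1L, n); cut_h <- max(tree$height)
    }
  }
  sizes <- table(cl)
  labels <- rep(NA_character_, n)
  valid <- as.integer(names(sizes)[sizes >= params$group_min_samples])
  discarded <- setdiff(unique(cl), valid)
  labels[cl %in% discarded] <- "DISCARDED"
  if (length(valid) > 0L) {
    ## deterministic numbering: ascending minimal member coordinates
    key <- t(vapply(valid, function(k) {
      members <- which(cl == k)
      vapply(coord_cols, function(cc) min(group[[cc]][members]), numeric(1))
    }, numeric(4)))
    ord <- do.call(order, as.data.frame(key))
    for (rank in seq_along(ord)) {
      labels[cl == valid[ord[rank]]] <- as.character(rank)
    }
  }
  attr(labels, "cut_height") <- cut_h
  attr(labels, "merge_heights") <- tree$height
  labels
}

#' Run the full cross-sample evaluation
#'
#' Pipeline over all samples' candidates: group collection, conservation
#' test, distance matrix, median fusion length, complete-linkage
#' clustering. Groups failing the two-conserved-positions rule are
#' rejected; members in subgroups smaller than `group_min_samples` are
#' discarded. The result is the grouped fusion report.
#'
#' @param candidates A combined candidate data frame or a list of
#'   per-sample candidate data frames (see [collect_groups()]).
#' @param params A [fusion_params()] object.
#' @return A grouped report data frame: the candidate columns plus `group`
#'   (the `"gene5|gene3"` pair key) and `subgroup` (label or
#'   `"DISCARDED"`). Groups rejected by the conservation rule are absent.
#' @export
evaluate_all <- function(candidates, params = fusion_params()) {
  groups <- collect_groups(candidates, params)
  out <- list()
  for (key in names(groups)) {
    g <- groups[[key]]
    mask <- conserved_positions(g)
    if (!attr(mask, "ok")) next
    dmat <- position_distance_matrix(g, mask)
    labels <- cluster_group(g, dmat, params)
    g$group <- key
    g$subgroup <- as.character(labels)
    out[[length(out) + 1L]] <- g
  }
  if (length(out) == 0L) {
    empty <- data.frame(sample = character(), gene_5p = character(),
                        gene_3p = character(), start_5p = integer(),
                        end_5p = integer(), start_3p = integer(),
                        end_3p = integer(), cn_5p = integer(),
                        cn_3p = integer(), correlation = numeric(),
                        rms = numeric(), group = character(),
                        subgroup = character(), stringsAsFactors = FALSE)
    return(empty)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$group, res$subgroup, res$sample), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export a group's dendrogram as a merge-height table
#'
#' Writes the complete-linkage merge order of a group as TSV (step, the
#' two merged items -- negative numbers are original members, positive
#' numbers earlier merge steps -- and the merge height), convenient for
#' external dendrogram plotting.
#'
#' @param group A group member data frame.
#' @param path Output TSV path.
#' @param params A [fusion_params()] object.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(group, path, params = fusion_params()) {
  mask <- conserved_positions(group)
  dmat <- position_distance_matrix(group, mask)
  tree <- stats::hclust(stats::as.dist(dmat), method = "complete")
  df <- data.frame(step = seq_along(tree$height),
                   item_a = tree$merge[, 1L], item_b = tree$merge[, 2L],
                   height = tree$height)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("# members: ", paste(sprintf("%d=%s", seq_len(nrow(group)), group$sample),
                           collapse = ", "), "\n",
      sep = "", file = path, append = TRUE)
  invisible(path)
}
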