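## Readers and writers for the external formats: segmentation TSV,
## probe TSV, BED6/GTF gene models and the fusion report TSV.
## All TSVs are tab-separated UTF-8 with '#'-prefixed comment lines ignored.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s file %s lacks column(s): %s", what, path,
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Read a per-sample copy-number segmentation profile
#'
#' Parses a segmentation TSV (one sample) with columns `sample`, `chrom`,
#' `start`, `end`, `n_probes`, `total_cn`, emulating the layout of
#' HMM-segmented SNP-array output. Coordinates are 1-based inclusive.
#' Segments are sorted per chromosome, validated for non-overlap, and
#' adjacent segments with equal total copy number are merged (probe counts
#' summed) so that every remaining internal boundary is a copy-number
#' change.
#'
#' @param path Path to the TSV file.
#' @return A `segmentation_profile`: a data frame with the columns above,
#'   plus a `sample_id` attribute.
#' @export
read_segmentation <- function(path) {
  df <- read_tsv_checked(path, c("sample", "chrom", "start", "end",
                                 "n_probes", "total_cn"), "segmentation")
  as_segmentation(df, source = path)
}

#' Build a validated segmentation profile from a data frame
#'
#' @param df Data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `n_probes`, `total_cn`.
#' @param source Label used in error messages.
#' @return A `segmentation_profile` data frame.
#' @export
as_segmentation <- function(df, source = "segmentation") {
  for (col in c("start", "end", "n_probes", "total_cn")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("%s: non-numeric '%s' in row %d", source, col, bad))
    }
    df[[col]] <- as.integer(round(v))
  }
  if (any(df$start > df$end)) {
    bad <- which(df$start > df$end)[1L]
    stop(sprintf("%s: start > end in row %d", source, bad))
  }
  if (any(df$n_probes < 1L)) stop(sprintf("%s: n_probes < 1", source))
  if (any(df$total_cn < 0L)) stop(sprintf("%s: negative total_cn", source))
  sample_id <- unique(df$sample)
  if (length(sample_id) > 1L) {
    stop(sprintf("%s: more than one sample id (%s)", source,
                 paste(sample_id, collapse = ", ")))
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  ## overlap check within chromosome
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] <= sub$end[-nrow(sub)])) {
      stop(sprintf("%s: overlapping segments on %s", source, ch))
    }
  }
  df <- merge_same_cn(df)
  rownames(df) <- NULL
  structure(df, sample_id = if (length(sample_id)) sample_id else NA_character_,
            class = c("segmentation_profile", "data.frame"))
}

## Merge runs of adjacent segments with equal total_cn (probe counts summed).
## Idempotent by construction.
merge_same_cn <- function(df) {
  if (nrow(df) < 2L) return(df)
  out <- lapply(split(df, df$chrom), function(sub) {
    sub <- sub[order(sub$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(sub$total_cn) != 0L))
    merged <- do.call(rbind, lapply(split(sub, grp), function(run) {
      run$end[1L] <- run$end[nrow(run)]
      run$n_probes[1L] <- sum(run$n_probes)
      run[1L, , drop = FALSE]
    }))
    merged
  })
  df2 <- do.call(rbind, out)
  df2 <- df2[order(df2$chrom, df2$start), , drop = FALSE]
  rownames(df2) <- NULL
  df2
}

#' Read a per-sample probe intensity panel
#'
#' Parses a TSV with columns `probe_id`, `chrom`, `pos`, `intensity`
#' (1-based positions). Probes are sorted by (chrom, pos); duplicate
#' positions within a chromosome are rejected.
#'
#' @param path Path to the TSV file.
#' @return A `probe_panel` data frame.
#' @export
read_probes <- function(path) {
  df <- read_tsv_checked(path, c("probe_id", "chrom", "pos", "intensity"),
                         "probe")
  as_probe_panel(df, source = path)
}

#' Build a validated probe panel from a data frame
#'
#' @param df Data frame with columns `probe_id`, `chrom`, `pos`, `intensity`.
#' @param source Label used in error messages.
#' @return A `probe_panel` data frame sorted by (chrom, pos).
#' @export
as_probe_panel <- function(df, source = "probes") {
  pos <- suppressWarnings(as.numeric(df$pos))
  if (anyNA(pos)) stop(sprintf("%s: non-numeric pos", source))
  df$pos <- as.integer(round(pos))
  intensity <- suppressWarnings(as.numeric(df$intensity))
  if (anyNA(intensity)) {
    bad <- which(is.na(intensity))[1L]
    stop(sprintf("%s: non-numeric intensity in row %d", source, bad))
  }
  df$intensity <- intensity
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "pos")])
  if (any(dup)) {
    stop(sprintf("%s: duplicated probe position %s:%d", source,
                 df$chrom[dup][1L], df$pos[dup][1L]))
  }
  rownames(df) <- NULL
  structure(df, class = c("probe_panel", "data.frame"))
}

#' Read gene models from BED6 or GTF
#'
#' BED input (0-based half-open) is converted to the package-internal
#' 1-based inclusive convention; GTF gene records are used as-is. Gene ids
#' must be unique. As a side effect the minimal and maximal gene lengths of
#' the collection are attached as attributes `min_len` / `max_len`; they
#' supply the default fusion length bounds.
#'
#' @param path Path to the annotation file.
#' @param format `"BED"` or `"GTF"`; default guessed from the extension.
#' @return A data frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand`, and attributes `min_len`, `max_len`.
#' @export
read_gene_models <- function(path, format = c("auto", "BED", "GTF")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff")) "GTF" else "BED"
  }
  gr <- if (format == "BED") {
    rtracklayer::import(path, format = "BED")
  } else {
    g <- rtracklayer::import(path, format = "GTF")
    if ("type" %in% names(GenomicRanges::mcols(g))) {
      g <- g[g$type == "gene"]
    }
    g
  }
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  gene_id <- if (format == "BED") df$name else df$gene_id
  gene_name <- if (format == "GTF" && "gene_name" %in% names(df)) {
    df$gene_name
  } else {
    gene_id
  }
  out <- data.frame(
    gene_id = as.character(gene_id),
    gene_name = as.character(gene_name),
    chrom = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = as.character(df$strand),
    stringsAsFactors = FALSE
  )
  if (any(!out$strand %in% c("+", "-"))) {
    stop(sprintf("gene models in %s: strand must be '+' or '-' (got '%s')",
                 path, out$strand[!out$strand %in% c("+", "-")][1L]))
  }
  if (anyNA(out$gene_id) || any(out$gene_id == "")) {
    stop(sprintf("gene models in %s: missing gene id", path))
  }
  if (anyDuplicated(out$gene_id)) {
    stop(sprintf("gene models in %s: duplicated gene_id '%s'", path,
                 out$gene_id[duplicated(out$gene_id)][1L]))
  }
  rownames(out) <- NULL
  len <- out$end - out$start + 1L
  attr(out, "min_len") <- as.integer(min(len))
  attr(out, "max_len") <- as.integer(max(len))
  out
}

report_columns <- c("sample", "gene_5p", "gene_3p",
                    "start_5p", "end_5p", "start_3p", "end_3p",
                    "cn_5p", "cn_3p", "correlation", "rms")
grouped_columns <- c(report_columns, "group", "subgroup")

#' Write a fusion candidate or grouped fusion report
#'
#' Candidate reports carry 11 columns (sample, 5'/3' gene ids, the four
#' subsegment coordinates, both copy numbers, crossover correlation and
#' RMS); grouped reports add `group` and `subgroup`. Rows are written in a
#' deterministic order (sample, gene pair, coordinates) so that the file is
#' reproducible, and re-serializing a parsed report is byte-identical.
#'
#' @param x A candidate or grouped-report data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fusion_report <- function(x, path) {
  grouped <- all(c("group", "subgroup") %in% names(x))
  cols <- if (grouped) grouped_columns else report_columns
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    stop(sprintf("fusion report lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  x <- x[, cols, drop = FALSE]
  if (nrow(x) > 0L) {
    ord <- order(x$sample, x$gene_5p, x$gene_3p,
                 x$start_5p, x$end_5p, x$start_3p, x$end_3p)
    x <- x[ord, , drop = FALSE]
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a fusion report written by [write_fusion_report()]
#'
#' @param path Path to the report TSV.
#' @return A data frame with the candidate (or grouped) report columns.
#' @export
read_fusion_report <- function(path) {
  df <- read_tsv_checked(path, report_columns, "fusion report")
  for (col in c("start_5p", "end_5p", "start_3p", "end_3p", "cn_5p", "cn_3p")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("correlation", "rms")) df[[col]] <- as.numeric(df[[col]])
  if ("subgroup" %in% names(df)) df$subgroup <- as.character(df$subgroup)
  df
}

#' Write a segmentation profile to TSV
#' @param profile A `segmentation_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[, c("sample", "chrom", "start",
                                                "end", "n_probes", "total_cn")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a probe panel to TSV
#' @param panel A `probe_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_probes <- function(panel, path) {
  utils::write.table(as.data.frame(panel)[, c("probe_id", "chrom", "pos",
                                              "intensity")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene models as BED6
#'
#' Converts the internal 1-based inclusive coordinates back to BED's
#' 0-based half-open convention.
#'
#' @param genes Gene model data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom,
                    start = genes$start - 1L,
                    end = genes$end,
                    name = genes$gene_id,
                    score = 0L,
                    strand = genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
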