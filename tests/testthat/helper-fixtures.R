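## Shared fixtures and independent oracles for the test suite.

## --- tiny builders ---------------------------------------------------

make_profile <- function(chrom, start, end, n_probes, cn, sample = "S") {
  as_segmentation(data.frame(sample = sample, chrom = chrom, start = start,
                             end = end, n_probes = n_probes, total_cn = cn,
                             stringsAsFactors = FALSE))
}

make_panel <- function(chrom, pos, intensity,
                       probe_id = sprintf("p%04d", seq_along(pos))) {
  as_probe_panel(data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                            intensity = intensity, stringsAsFactors = FALSE))
}

make_genes <- function(gene_id, chrom, start, end, strand) {
  data.frame(gene_id = gene_id, gene_name = gene_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

make_anchor <- function(gene_id, role, side, sub_start, sub_end, cn,
                        strand = "+", chrom = "chr1", anchor_pos = NA_integer_) {
  data.frame(gene_id = gene_id, gene_name = gene_id, chrom = chrom,
             strand = strand, role = role, origin = "whole",
             anchor_pos = as.integer(anchor_pos), fusion_side = side,
             sub_start = as.integer(sub_start), sub_end = as.integer(sub_end),
             total_cn = as.integer(cn), stringsAsFactors = FALSE)
}

## candidate rows for grouping tests
make_candidate <- function(sample, gene_5p, gene_3p, coords,
                           cn = c(3L, 2L), correlation = 0.99, rms = 0.2) {
  data.frame(sample = sample, gene_5p = gene_5p, gene_3p = gene_3p,
             start_5p = coords[1], end_5p = coords[2],
             start_3p = coords[3], end_3p = coords[4],
             cn_5p = cn[1], cn_3p = cn[2],
             correlation = correlation, rms = rms,
             stringsAsFactors = FALSE)
}

## the worked-example coordinate table shipped with the package
load_cml_group <- function() {
  path <- system.file("extdata", "abl1_bcr_cml_groups.tsv",
                      package = "segfuse")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

## --- independent oracles ---------------------------------------------

## breakpoint count by a direct pairwise scan of CN changes
oracle_breakpoint_count <- function(profile) {
  sum(vapply(split(as.data.frame(profile), profile$chrom), function(sub) {
    sub <- sub[order(sub$start), ]
    if (nrow(sub) < 2L) return(0L)
    sum(sub$total_cn[-1L] != sub$total_cn[-nrow(sub)])
  }, integer(1)))
}

## textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## brute-force complete-linkage agglomeration; returns merge heights and
## the flat clustering at cut height h (ties: smallest member index first)
oracle_complete_linkage_cut <- function(dmat, h) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- max(dmat[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    if (best[1] > h) break
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-best[3]]
  }
  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  labels
}

## partition comparison that ignores label names
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 0))]),
            unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 0))]))
}

## independent AICc over the span grid: trace of the smoothing operator
## computed from the explicit hat matrix (loess is linear in y), RSS from
## the fitted values
oracle_aicc_span <- function(values, params) {
  n <- length(values)
  x <- seq_len(n)
  grid <- seq(params$span_grid_lo, params$span_grid_hi,
              by = params$span_grid_step)
  fit_once <- function(y, span) {
    withCallingHandlers(
      stats::loess(y ~ x, span = span, degree = 2,
                   control = stats::loess.control(surface = "direct",
                                                  statistics = "exact")),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  aicc <- vapply(grid, function(pct) {
    s <- pct / 100
    fitted_vals <- tryCatch(stats::fitted(fit_once(values, s)),
                            error = function(e) NULL)
    if (is.null(fitted_vals)) return(Inf)
    ## hat matrix column by column via unit responses
    tr <- tryCatch({
      sum(vapply(seq_len(n), function(j) {
        e <- numeric(n); e[j] <- 1
        stats::fitted(fit_once(e, s))[j]
      }, numeric(1)))
    }, error = function(e) NaN)
    rss <- sum((values - fitted_vals)^2)
    if (!is.finite(tr) || !is.finite(rss) || n - tr - 2 <= 0) return(Inf)
    n * log(max(rss, 1e-300) / n) + n * (n + tr) / (n - tr - 2)
  }, numeric(1))
  grid[which.min(aicc)]
}

## low-noise cohort with one recurrent compliant fusion and all five
## one-violation controls; shared by several tests
recovery_cohort <- function(seed = 20260927) {
  cfg <- simulation_config(seed = seed, n_samples = 5,
                           base_sd = 0.02, sd_per_cn = 0.01,
                           events = list(fusion_event("F1", carriers = 1:3)))
  simulate_cohort(plant_noncompliant_controls(cfg))
}
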