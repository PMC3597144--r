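## Synthetic cohort generator: copy-number profiles with planted unbalanced
## fusions and single-probe artifacts, probe intensities whose spread grows
## with copy number, gene models, and a truth table. Everything a pipeline
## stage consumes can be produced here, deterministically from a seed.

#' Mean probe intensity for a copy-number state
#'
#' A smooth monotone map from total copy number to the (log-ratio style)
#' intensity scale: `log2((cn + 0.1) / 2)`, so that the diploid state sits
#' near zero, deletions below and amplifications above.
#'
#' @param cn Non-negative integer copy number (vectorised).
#' @return Numeric mean intensity.
#' @export
cn_mean_intensity <- function(cn) {
  log2((cn + 0.1) / 2)
}

#' Describe a planted fusion event
#'
#' Each event occupies its own simulated chromosome carrying one
#' copy-number breakpoint; the 5' partner gene ends shortly upstream of the
#' boundary and the 3' partner starts shortly downstream, so that in
#' carrier samples the pair satisfies the anchoring rule. Control events
#' violating exactly one constraint are declared through `violates`.
#'
#' @param name Event name (also names the simulated chromosome).
#' @param carriers Integer indices of the samples carrying the event.
#' @param cn_5p,cn_3p Total copy numbers of the 5'-side and 3'-side
#'   segments in carriers.
#' @param len_5p,len_3p Gene lengths in bp.
#' @param strand_5p,strand_3p Gene strands.
#' @param gap_5p,gap_3p Distance (bp) from each gene's junction-facing end
#'   to the breakpoint boundary position.
#' @param jitter_bp Per-carrier uniform jitter (bp, rounded to the probe
#'   grid) applied to the breakpoint position.
#' @param compliant Does the event satisfy every pairing constraint by
#'   construction?
#' @param violates For non-compliant controls, the constraint violated:
#'   `"cn"`, `"orientation"`, `"length"`, `"window"` or `"distance"`.
#' @return A `fusion_event` list.
#' @export
fusion_event <- function(name, carriers,
                         cn_5p = 3L, cn_3p = 2L,
                         len_5p = 120000L, len_3p = 90000L,
                         strand_5p = "+", strand_3p = "+",
                         gap_5p = 5000L, gap_3p = 5000L,
                         jitter_bp = 0L,
                         compliant = TRUE, violates = NA_character_) {
  stopifnot(length(carriers) >= 1L, all(carriers >= 1L),
            cn_5p >= 0L, cn_3p >= 0L, len_5p > 0L, len_3p > 0L,
            strand_5p %in% c("+", "-"), strand_3p %in% c("+", "-"),
            gap_5p > 0L, gap_3p > 0L, jitter_bp >= 0L)
  structure(list(name = name, carriers = as.integer(carriers),
                 cn_5p = as.integer(cn_5p), cn_3p = as.integer(cn_3p),
                 len_5p = as.integer(len_5p), len_3p = as.integer(len_3p),
                 strand_5p = strand_5p, strand_3p = strand_3p,
                 gap_5p = as.integer(gap_5p), gap_3p = as.integer(gap_3p),
                 jitter_bp = as.integer(jitter_bp),
                 compliant = isTRUE(compliant), violates = violates),
            class = "fusion_event")
}

#' Configuration of a synthetic cohort
#'
#' @param seed Integer seed; mandatory, every draw derives from it.
#' @param n_samples Number of samples in the cohort.
#' @param probe_spacing_bp Regular probe spacing in bp.
#' @param background_chromosomes Named integer vector of background
#'   chromosome lengths (constant copy number, no breakpoints). They host
#'   the filler genes that define the gene-collection length bounds.
#' @param background_cn Copy number of background chromosomes and of event
#'   chromosomes in non-carrier samples.
#' @param min_gene_len,max_gene_len Lengths of the two bound-setting filler
#'   genes; they become the default fusion length bounds.
#' @param n_background_genes Additional filler genes per background
#'   chromosome with log-uniform lengths between the bounds.
#' @param events List of [fusion_event()] objects.
#' @param artifact_rate Per-eligible-probe probability of a single-probe
#'   copy-number spike in the reported segmentation (the intensities are
#'   untouched: artifacts are segmentation errors).
#' @param base_sd,sd_per_cn Probe intensity standard deviation is
#'   `base_sd + sd_per_cn * cn`: the spread grows with copy number.
#' @param junction_profile_amplitude,junction_profile_probes In carrier
#'   samples the `junction_profile_probes` probes of each partner gene
#'   nearest the junction carry a shared smooth random intensity profile
#'   (a random walk of overall scale `junction_profile_amplitude`, drawn
#'   per event and sample, applied to both sides in pairing order). It
#'   emulates the locally coherent signal of a physically joined,
#'   co-replicated junction that makes the crossover correlation
#'   informative; unrelated junctions get independent profiles.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_samples = 5L,
                              probe_spacing_bp = 1000L,
                              background_chromosomes = c(chrB1 = 2200000L),
                              background_cn = 2L,
                              min_gene_len = 5000L,
                              max_gene_len = 2000000L,
                              n_background_genes = 4L,
                              events = list(fusion_event("F1", carriers = 1:3)),
                              artifact_rate = 0.01,
                              base_sd = 0.05,
                              sd_per_cn = 0.02,
                              junction_profile_amplitude = 0.8,
                              junction_profile_probes = 7L) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("simulation_config(): a seed is mandatory")
  }
  if (n_samples < 1L) stop("simulation_config(): need at least one sample")
  stopifnot(probe_spacing_bp >= 1L, background_cn >= 0L,
            min_gene_len > 0L, max_gene_len >= min_gene_len,
            artifact_rate >= 0, artifact_rate < 1,
            base_sd >= 0, sd_per_cn >= 0,
            junction_profile_amplitude >= 0, junction_profile_probes >= 2L)
  for (ev in events) {
    stopifnot(inherits(ev, "fusion_event"))
    if (any(ev$carriers > n_samples)) {
      stop(sprintf("event %s: carrier index beyond n_samples", ev$name))
    }
  }
  if (anyDuplicated(vapply(events, `[[`, "", "name"))) {
    stop("event names must be unique")
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 probe_spacing_bp = as.integer(probe_spacing_bp),
                 background_chromosomes = background_chromosomes,
                 background_cn = as.integer(background_cn),
                 min_gene_len = as.integer(min_gene_len),
                 max_gene_len = as.integer(max_gene_len),
                 n_background_genes = as.integer(n_background_genes),
                 events = events,
                 artifact_rate = artifact_rate,
                 base_sd = base_sd, sd_per_cn = sd_per_cn,
                 junction_profile_amplitude = junction_profile_amplitude,
                 junction_profile_probes = as.integer(junction_profile_probes)),
            class = "simulation_config")
}

#' Add one-violation negative-control events to a configuration
#'
#' Appends five control events, each violating exactly one pairing
#' constraint while satisfying all others: a copy-number gap of 2, a
#' 3' partner on the wrong strand, a fusion longer than the longest gene,
#' a 3' partner covering only six probes, and a partner 15 kb from the
#' breakpoint. All are marked non-compliant with the violated constraint
#' recorded, and are carried by the first two samples.
#'
#' The control copy numbers are laid out on a lattice (each event's pair
#' at `3k`/`3k - 1`, the CN-gap control at 19/17) so that every
#' cross-event gene pairing differs by at least 2 copies: negative
#' controls then probe exactly one constraint each instead of creating
#' chance cross-event candidates.
#'
#' @param config A [simulation_config()] object.
#' @return The configuration with the control events appended.
#' @export
plant_noncompliant_controls <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  carriers <- seq_len(min(2L, config$n_samples))
  sp <- config$probe_spacing_bp
  controls <- list(
    fusion_event("CTRL_orientation", carriers, cn_5p = 6L, cn_3p = 5L,
                 strand_3p = "-",
                 compliant = FALSE, violates = "orientation"),
    fusion_event("CTRL_length", carriers, cn_5p = 9L, cn_3p = 8L,
                 len_5p = as.integer(config$max_gene_len * 0.75),
                 len_3p = as.integer(config$max_gene_len * 0.75),
                 compliant = FALSE, violates = "length"),
    fusion_event("CTRL_window", carriers, cn_5p = 12L, cn_3p = 11L,
                 len_3p = as.integer(5.5 * sp),
                 compliant = FALSE, violates = "window"),
    fusion_event("CTRL_distance", carriers, cn_5p = 15L, cn_3p = 14L,
                 gap_3p = 15000L,
                 compliant = FALSE, violates = "distance"),
    fusion_event("CTRL_cn", carriers, cn_5p = 19L, cn_3p = 17L,
                 compliant = FALSE, violates = "cn")
  )
  config$events <- c(config$events, controls)
  config
}

## Geometry of one event chromosome, shared by segmentation, probe and
## gene generation. The breakpoint sits on the probe grid; genes flank it.
event_geometry <- function(ev, sp) {
  pre <- max(ev$len_5p + ev$gap_5p + 50L * sp, 60L * sp)
  b_probe <- as.integer(ceiling(pre / sp) * sp)        # last probe of 5' segment
  boundary <- as.integer(b_probe + floor(sp / 2))      # midpoint convention
  g5e <- boundary - ev$gap_5p
  g5s <- g5e - ev$len_5p + 1L
  g3s <- boundary + ev$gap_3p
  g3e <- g3s + ev$len_3p - 1L
  if (g5s < sp) stop(sprintf("event %s: 5' gene extends before the chromosome",
                             ev$name))
  if (g5e >= g3s) stop(sprintf("event %s: fusion genes overlap", ev$name))
  chrom_len <- as.integer(ceiling((g3e + 50L * sp) / sp) * sp)
  list(chrom = paste0("chr_", ev$name), chrom_len = chrom_len,
       b_probe = b_probe, boundary = boundary,
       g5s = g5s, g5e = g5e, g3s = g3s, g3e = g3e)
}

sim_gene_row <- function(gene_id, chrom, start, end, strand) {
  data.frame(gene_id = gene_id, gene_name = gene_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Simulate a synthetic cohort
#'
#' Generates, deterministically from the configured seed: gene models
#' (event partner genes plus background filler genes that set the length
#' bounds), per-sample segmentation profiles (event chromosomes carry one
#' breakpoint in carrier samples, background chromosomes none; single-probe
#' artifact spikes are injected into the reported segmentation at the
#' configured rate), per-sample probe panels (intensity = monotone CN mean
#' + junction ramp in carriers + Gaussian noise with sd growing in CN) and
#' a truth table of the planted events.
#'
#' @param config A [simulation_config()] object.
#' @return A list with elements `genes` (gene model data frame), `samples`
#'   (named list; per sample a list with `segmentation` and `probes`),
#'   `truth` (data frame: sample, gene pair, expected coordinates and CNs,
#'   `compliant`, `violates`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  sp <- config$probe_spacing_bp

  geoms <- lapply(config$events, event_geometry, sp = sp)
  names(geoms) <- vapply(config$events, `[[`, "", "name")

  ## --- gene models (global annotation, identical for every sample) ----
  genes <- list()
  for (i in seq_along(config$events)) {
    ev <- config$events[[i]]; g <- geoms[[i]]
    genes[[length(genes) + 1L]] <-
      sim_gene_row(paste0(ev$name, "_5P"), g$chrom, g$g5s, g$g5e, ev$strand_5p)
    genes[[length(genes) + 1L]] <-
      sim_gene_row(paste0(ev$name, "_3P"), g$chrom, g$g3s, g$g3e, ev$strand_3p)
  }
  bg_names <- names(config$background_chromosomes)
  for (bi in seq_along(config$background_chromosomes)) {
    ch <- bg_names[bi]; L <- config$background_chromosomes[[bi]]
    if (bi == 1L) {
      if (config$max_gene_len + config$min_gene_len + 20L * sp > L) {
        stop("first background chromosome too short for the bound-setting genes")
      }
      genes[[length(genes) + 1L]] <-
        sim_gene_row("BG_MINLEN", ch, sp, sp + config$min_gene_len - 1L, "+")
      genes[[length(genes) + 1L]] <-
        sim_gene_row("BG_MAXLEN", ch, sp + config$min_gene_len + 10L * sp,
                     sp + config$min_gene_len + 10L * sp + config$max_gene_len - 1L,
                     "+")
    }
    if (config$n_background_genes > 0L) {
      len <- round(exp(stats::runif(config$n_background_genes,
                                    log(config$min_gene_len),
                                    log(min(config$max_gene_len, L / 4)))))
      start <- sort(sample.int(max(L - max(len) - 1L, 1L),
                               config$n_background_genes))
      for (k in seq_len(config$n_background_genes)) {
        genes[[length(genes) + 1L]] <-
          sim_gene_row(sprintf("BG_%s_%02d", ch, k), ch, start[k],
                       min(start[k] + len[k] - 1L, L - 1L),
                       if (stats::runif(1) < 0.5) "+" else "-")
      }
    }
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL

  ## --- per-sample data ------------------------------------------------
  all_chroms <- c(vapply(geoms, `[[`, "", "chrom"), bg_names)
  chrom_len <- c(vapply(geoms, function(g) g$chrom_len, 0L),
                 as.integer(config$background_chromosomes))
  names(chrom_len) <- all_chroms

  samples <- list()
  truth <- list()
  for (s in seq_len(config$n_samples)) {
    sid <- sprintf("S%02d", s)
    seg_rows <- list()
    probe_rows <- list()
    for (i in seq_along(config$events)) {
      ev <- config$events[[i]]; g <- geoms[[i]]
      carrier <- s %in% ev$carriers
      jit <- if (carrier && ev$jitter_bp > 0L) {
        as.integer(round(stats::runif(1, -ev$jitter_bp, ev$jitter_bp) / sp) * sp)
      } else 0L
      b_probe <- g$b_probe + jit
      boundary <- g$boundary + jit
      last_probe <- as.integer(floor(g$chrom_len / sp) * sp)
      if (carrier) {
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          sample = sid, chrom = g$chrom,
          start = c(sp, b_probe + sp),
          end = c(b_probe, last_probe),
          n_probes = c(b_probe %/% sp, (last_probe - b_probe) %/% sp),
          total_cn = c(ev$cn_5p, ev$cn_3p), stringsAsFactors = FALSE)
      } else {
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          sample = sid, chrom = g$chrom, start = sp, end = last_probe,
          n_probes = last_probe %/% sp, total_cn = config$background_cn,
          stringsAsFactors = FALSE)
      }
      pos <- seq.int(sp, last_probe, by = sp)
      cn <- if (carrier) ifelse(pos <= b_probe, ev$cn_5p, ev$cn_3p) else
        rep(config$background_cn, length(pos))
      mu <- cn_mean_intensity(cn)
      if (carrier) {
        ## matched junction profile: the kj probes of each partner nearest
        ## the junction share one smooth random profile, paired in the
        ## order the crossover window reads them
        kj <- config$junction_profile_probes
        prof <- cumsum(stats::rnorm(kj))
        prof <- prof - mean(prof)
        psd <- stats::sd(prof)
        if (psd > 0) prof <- prof * config$junction_profile_amplitude / psd
        i5 <- which(pos >= g$g5s & pos <= g$g5e)
        i5 <- i5[order(pos[i5], decreasing = TRUE)]   # nearest junction first
        m5 <- min(kj, length(i5))
        if (m5 > 0L) mu[i5[seq_len(m5)]] <- mu[i5[seq_len(m5)]] +
          prof[kj + 1L - seq_len(m5)]                 # window reads it last
        i3 <- which(pos >= g$g3s & pos <= g$g3e)
        i3 <- i3[order(pos[i3])]                      # nearest junction first
        m3 <- min(kj, length(i3))
        if (m3 > 0L) mu[i3[seq_len(m3)]] <- mu[i3[seq_len(m3)]] + prof[seq_len(m3)]
      }
      intensity <- stats::rnorm(length(pos), mu,
                                config$base_sd + config$sd_per_cn * cn)
      probe_rows[[length(probe_rows) + 1L]] <- data.frame(
        probe_id = sprintf("%s_p%06d", g$chrom, seq_along(pos)),
        chrom = g$chrom, pos = pos, intensity = intensity,
        stringsAsFactors = FALSE)
      if (carrier) {
        truth[[length(truth) + 1L]] <- data.frame(
          sample = sid, gene_5p = paste0(ev$name, "_5P"),
          gene_3p = paste0(ev$name, "_3P"),
          start_5p = g$g5s, end_5p = g$g5e,
          start_3p = g$g3s, end_3p = g$g3e,
          cn_5p = ev$cn_5p, cn_3p = ev$cn_3p,
          boundary_pos = boundary,
          compliant = ev$compliant, violates = ev$violates,
          stringsAsFactors = FALSE)
      }
    }
    for (ch in bg_names) {
      last_probe <- as.integer(floor(chrom_len[[ch]] / sp) * sp)
      pos <- seq.int(sp, last_probe, by = sp)
      cn <- config$background_cn
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        sample = sid, chrom = ch, start = sp, end = last_probe,
        n_probes = length(pos), total_cn = cn, stringsAsFactors = FALSE)
      probe_rows[[length(probe_rows) + 1L]] <- data.frame(
        probe_id = sprintf("%s_p%06d", ch, seq_along(pos)),
        chrom = ch, pos = pos,
        intensity = stats::rnorm(length(pos), cn_mean_intensity(cn),
                                 config$base_sd + config$sd_per_cn * cn),
        stringsAsFactors = FALSE)
    }
    seg <- do.call(rbind, seg_rows)
    if (config$artifact_rate > 0) {
      seg <- inject_artifacts(seg, config$artifact_rate, sp)
    }
    samples[[sid]] <- list(
      segmentation = as_segmentation(seg, source = sid),
      probes = as_probe_panel(do.call(rbind, probe_rows), source = sid)
    )
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(sample = character(), gene_5p = character(),
               gene_3p = character(), start_5p = integer(), end_5p = integer(),
               start_3p = integer(), end_3p = integer(), cn_5p = integer(),
               cn_3p = integer(), boundary_pos = integer(),
               compliant = logical(), violates = character())
  rownames(truth) <- NULL
  list(genes = genes, samples = samples, truth = truth, config = config)
}

## Split segments around randomly chosen interior probes, reporting a
## single-probe CN spike there (the intensities are left untouched).
## Spikes are kept at least three probes apart and away from segment ends.
inject_artifacts <- function(seg, rate, sp) {
  out <- list()
  for (r in seq_len(nrow(seg))) {
    row <- seg[r, , drop = FALSE]
    pos <- seq.int(row$start, row$end, by = sp)
    n <- length(pos)
    if (n < 7L) { out[[length(out) + 1L]] <- row; next }
    eligible <- 3L:(n - 2L)
    hit <- eligible[stats::runif(length(eligible)) < rate]
    if (length(hit) > 1L) hit <- hit[c(TRUE, diff(hit) >= 3L)]
    if (length(hit) == 0L) { out[[length(out) + 1L]] <- row; next }
    bounds <- c(0L, hit, n + 1L)
    for (k in seq_along(hit)) {
      i <- hit[k]
      lo <- bounds[k] + 1L           # first probe index of the host piece
      out[[length(out) + 1L]] <- data.frame(
        sample = row$sample, chrom = row$chrom,
        start = pos[lo], end = pos[i - 1L], n_probes = i - lo,
        total_cn = row$total_cn, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        sample = row$sample, chrom = row$chrom,
        start = pos[i], end = pos[i], n_probes = 1L,
        total_cn = row$total_cn + 2L, stringsAsFactors = FALSE)
    }
    lo <- hit[length(hit)] + 1L
    out[[length(out) + 1L]] <- data.frame(
      sample = row$sample, chrom = row$chrom,
      start = pos[lo], end = pos[n], n_probes = n - lo + 1L,
      total_cn = row$total_cn, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a simulated cohort to a directory
#'
#' Writes `genes.bed`, `truth.tsv` and, per sample, `<id>.segments.tsv`
#' and `<id>.probes.tsv`, in the package's TSV dialects.
#'
#' @param dataset Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_models_bed(dataset$genes, file.path(dir, "genes.bed"))
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (sid in names(dataset$samples)) {
    write_segmentation(dataset$samples[[sid]]$segmentation,
                       file.path(dir, paste0(sid, ".segments.tsv")))
    write_probes(dataset$samples[[sid]]$probes,
                 file.path(dir, paste0(sid, ".probes.tsv")))
  }
  invisible(dir)
}
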