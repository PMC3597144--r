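test_that("single-probe artifacts are absorbed and re-counted into the flanks", {
  prof <- make_profile("chr9", c(1L, 5001L, 5101L), c(5000L, 5100L, 11100L),
                       c(50L, 1L, 60L), c(2L, 5L, 2L))
  cleaned <- remove_single_probe_segments(prof)
  expect_equal(nrow(cleaned), 1L)
  expect_equal(cleaned$total_cn, 2L)
  expect_equal(cleaned$n_probes, 111L)   # all probes, artifact's included
  expect_equal(cleaned$start, 1L)
  expect_equal(cleaned$end, 11100L)
})

test_that("cleaning without artifacts is the identity, and all-singleton chromosomes drop", {
  prof <- make_profile("chr1", c(1L, 1001L), c(1000L, 3000L), c(10L, 20L),
                       c(2L, 3L))
  expect_equal(as.data.frame(remove_single_probe_segments(prof)),
               as.data.frame(prof))

  solo <- make_profile("chr2", c(1L, 101L), c(100L, 200L), c(1L, 1L),
                       c(2L, 3L))
  cleaned <- remove_single_probe_segments(solo)
  expect_equal(nrow(cleaned), 0L)
})

test_that("artifact between unequal flanks goes to the left flank", {
  prof <- make_profile("chr3", c(1L, 1001L, 1101L), c(1000L, 1100L, 3000L),
                       c(10L, 1L, 20L), c(2L, 7L, 3L))
  cleaned <- remove_single_probe_segments(prof)
  expect_equal(nrow(cleaned), 2L)
  expect_equal(cleaned$total_cn, c(2L, 3L))
  expect_equal(cleaned$n_probes, c(11L, 20L))
  expect_equal(cleaned$end[1], 1100L)
})

test_that("breakpoint detection matches a brute-force CN-change scan", {
  expect_equal(nrow(detect_breakpoints(
    make_profile("chr1", 1L, 1000L, 10L, 2L))), 0L)

  prof <- make_profile("chr22", c(1L, 1001L, 2001L), c(1000L, 2000L, 3000L),
                       c(10L, 10L, 10L), c(2L, 3L, 2L))
  bps <- detect_breakpoints(prof)
  expect_equal(nrow(bps), 2L)
  expect_equal(bps$boundary_pos, c(floor((1000 + 1001) / 2),
                                   floor((2000 + 2001) / 2)))

  set.seed(7)
  for (rep in 1:10) {
    n <- 20L
    starts <- cumsum(c(1L, rep(1000L, n - 1L)))
    cn <- sample(0:5, n, replace = TRUE)
    df <- data.frame(sample = "S", chrom = sample(c("c1", "c2"), n, TRUE),
                     start = starts, end = starts + 999L,
                     n_probes = rep(10L, n), total_cn = cn)
    df <- df[order(df$chrom, df$start), ]
    prof <- as_segmentation(df)
    expect_equal(nrow(detect_breakpoints(prof)),
                 oracle_breakpoint_count(prof))
  }
})

test_that("cleaning then detection equals detection on the artifact-free profile", {
  cfg <- simulation_config(seed = 5, n_samples = 2, artifact_rate = 0.05,
                           events = list(fusion_event("F1", carriers = 1:2)))
  cfg0 <- cfg; cfg0$artifact_rate <- 0
  with_art <- simulate_cohort(cfg)
  without <- simulate_cohort(cfg0)
  for (sid in names(with_art$samples)) {
    cleaned <- remove_single_probe_segments(with_art$samples[[sid]]$segmentation)
    expect_equal(as.data.frame(cleaned),
                 as.data.frame(without$samples[[sid]]$segmentation))
  }
})

test_that("whole-gene anchoring honours the distance rule and assigns roles by strand", {
  prof <- make_profile("chr1", c(1000L, 101000L), c(100000L, 200000L),
                       c(100L, 100L), c(3L, 2L))
  bps <- detect_breakpoints(prof)
  boundary <- bps$boundary_pos[1]

  genes <- make_genes(c("UP5K", "FAR15K", "DOWN5K_NEG"), "chr1",
                      c(boundary - 5000L - 20000L + 1L,
                        boundary - 15000L - 20000L + 1L,
                        boundary + 5000L),
                      c(boundary - 5000L,
                        boundary - 15000L,
                        boundary + 5000L + 20000L - 1L),
                      c("+", "+", "-"))
  anch <- anchor_genes(bps, genes, prof, fusion_params())
  expect_true("UP5K" %in% anch$gene_id)
  expect_equal(anch$role[anch$gene_id == "UP5K"], "five_prime")
  expect_false("FAR15K" %in% anch$gene_id)        # 15 kb exceeds the rule
  ## reverse-strand gene downstream of the breakpoint donates its 5' part
  expect_equal(anch$role[anch$gene_id == "DOWN5K_NEG"], "five_prime")
  expect_equal(anch$total_cn[anch$gene_id == "UP5K"], 3L)
  expect_equal(anch$total_cn[anch$gene_id == "DOWN5K_NEG"], 2L)
})

test_that("a gene exactly 10 kb from the boundary is still anchored", {
  prof <- make_profile("chr1", c(1000L, 101000L), c(100000L, 200000L),
                       c(100L, 100L), c(3L, 2L))
  bps <- detect_breakpoints(prof)
  boundary <- bps$boundary_pos[1]
  genes <- make_genes("EXACT10K", "chr1", boundary - 10000L - 5000L + 1L,
                      boundary - 10000L, "+")
  anch <- anchor_genes(bps, genes, prof, fusion_params())
  expect_equal(nrow(anch), 1L)
})

test_that("spanning genes split into subsegments that partition the gene body", {
  prof <- make_profile("chr2", c(1000L, 51000L, 101000L),
                       c(50000L, 100000L, 200000L),
                       c(50L, 50L, 100L), c(2L, 3L, 4L))
  bps <- detect_breakpoints(prof)
  genes <- make_genes("SPAN2", "chr2", 20000L, 150000L, "+")
  anch <- anchor_genes(bps, genes, prof, fusion_params())
  ## 3 subsegments: terminal five_prime, inner both (2 records), terminal three_prime
  expect_equal(sum(anch$origin == "terminal"), 2L)
  expect_equal(sum(anch$origin == "both"), 2L)
  expect_setequal(anch$role[anch$origin == "both"],
                  c("five_prime", "three_prime"))
  segs <- unique(anch[, c("sub_start", "sub_end")])
  segs <- segs[order(segs$sub_start), ]
  expect_equal(segs$sub_start[1], 20000L)
  expect_equal(segs$sub_end[nrow(segs)], 150000L)
  expect_equal(segs$sub_start[-1L], segs$sub_end[-nrow(segs)] + 1L)
  ## each subsegment carries the CN of its covering segment
  expect_equal(sort(unique(anch$total_cn)), c(2L, 3L, 4L))
})

test_that("two-subsegment split assigns one 5' and one 3' role by strand", {
  prof <- make_profile("chr2", c(1000L, 51000L), c(50000L, 100000L),
                       c(50L, 50L), c(2L, 3L))
  bps <- detect_breakpoints(prof)
  fwd <- anchor_genes(bps, make_genes("GF", "chr2", 30000L, 70000L, "+"),
                      prof, fusion_params())
  expect_equal(fwd$role[order(fwd$sub_start)], c("five_prime", "three_prime"))
  rev <- anchor_genes(bps, make_genes("GR", "chr2", 30000L, 70000L, "-"),
                      prof, fusion_params())
  expect_equal(rev$role[order(rev$sub_start)], c("three_prime", "five_prime"))
})

test_that("anchoring roles mirror under strand flip and profile reversal", {
  L <- 300000L
  prof <- make_profile("chr1", c(1000L, 151000L), c(150000L, 299000L),
                       c(150L, 148L), c(2L, 4L))
  bps <- detect_breakpoints(prof)
  set.seed(42)
  for (rep in 1:8) {
    gstart <- sample(2000:280000, 1)
    glen <- sample(3000:15000, 1)
    strand <- sample(c("+", "-"), 1)
    genes <- make_genes("G", "chr1", gstart, min(gstart + glen, L - 1000L),
                        strand)
    a <- anchor_genes(bps, genes, prof, fusion_params())

    ## mirrored world: coordinates x -> L - x, strand flipped
    mprof <- make_profile("chr1", L - c(299000L, 150000L),
                          L - c(151000L, 1000L), c(148L, 150L), c(4L, 2L))
    mgenes <- genes
    mgenes$start <- L - genes$end
    mgenes$end <- L - genes$start
    mgenes$strand <- ifelse(strand == "+", "-", "+")
    mbps <- detect_breakpoints(mprof)
    b <- anchor_genes(mbps, mgenes, mprof, fusion_params())

    expect_equal(nrow(a), nrow(b))
    if (nrow(a) > 0L) {
      expect_setequal(a$role, b$role)   # roles are preserved under mirror+flip
    }
  }
})

test_that("genes on chromosomes absent from the profile are skipped with a warning", {
  prof <- make_profile("chr1", c(1L, 1001L), c(1000L, 2000L), c(10L, 10L),
                       c(2L, 3L))
  bps <- detect_breakpoints(prof)
  genes <- make_genes("GX", "chrZ", 100L, 900L, "+")
  expect_warning(anchor_genes(bps, genes, prof, fusion_params()),
                 "absent from profile")
})
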