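test_that("pair enumeration is the role cartesian product minus self-pairs", {
  anch <- rbind(make_anchor("A", "five_prime", "right", 100L, 200L, 3L, anchor_pos = 250L),
                make_anchor("B", "five_prime", "right", 100L, 200L, 3L, anchor_pos = 250L),
                make_anchor("C", "three_prime", "left", 300L, 400L, 2L, anchor_pos = 250L),
                make_anchor("D", "three_prime", "left", 300L, 400L, 2L, anchor_pos = 250L))
  expect_equal(nrow(enumerate_pairs(anch)), 4L)

  solo <- make_anchor("A", "five_prime", "right", 100L, 200L, 3L)
  expect_equal(nrow(enumerate_pairs(solo)), 0L)

  ## an inner (both-role) subsegment is two records; with one 3' anchor it
  ## pairs once, acting as the 5' partner
  both <- rbind(make_anchor("G", "five_prime", "right", 100L, 200L, 2L, anchor_pos = 250L),
                make_anchor("G", "three_prime", "left", 100L, 200L, 2L, anchor_pos = 50L))
  both$origin <- "both"
  other <- make_anchor("H", "three_prime", "left", 300L, 400L, 2L, anchor_pos = 250L)
  pairs <- enumerate_pairs(rbind(both, other))
  expect_equal(nrow(pairs), 1L)

  ## subsegments of one gene are never re-joined at the breakpoint that
  ## split them
  split_gene <- rbind(
    make_anchor("S", "five_prime", "right", 100L, 249L, 2L, anchor_pos = 249L),
    make_anchor("S", "three_prime", "left", 250L, 400L, 3L, anchor_pos = 249L))
  expect_equal(nrow(enumerate_pairs(split_gene)), 0L)
})

test_that("the CN filter tolerates one copy and rejects larger gaps", {
  p <- fusion_params()
  expect_true(filter_cn(3L, 2L, p))
  expect_true(filter_cn(13L, 12L, p))
  expect_false(filter_cn(2L, 5L, p))
  expect_true(filter_cn(4L, 4L, p))
})

test_that("orientation keeps exactly the read-through strand/side combinations", {
  combos <- expand.grid(strand_5p = c("+", "-"), side_5p = c("left", "right"),
                        strand_3p = c("+", "-"), side_3p = c("left", "right"),
                        stringsAsFactors = FALSE)
  ## read-through rule spelled out independently: the 5' partner's junction
  ## end must be its transcript-3' end, the 3' partner's its transcript-5' end
  expected <- with(combos,
    ((strand_5p == "+" & side_5p == "right") | (strand_5p == "-" & side_5p == "left")) &
    ((strand_3p == "+" & side_3p == "left") | (strand_3p == "-" & side_3p == "right")))
  got <- with(combos, filter_orientation(strand_5p, side_5p, strand_3p, side_3p))
  expect_equal(got, expected)
  expect_equal(sum(got), 4L)
  ## canonical case and a mixed-strand keeper
  expect_true(filter_orientation("+", "right", "+", "left"))
  expect_false(filter_orientation("+", "left", "+", "left"))
  expect_true(filter_orientation("-", "left", "+", "left"))
})

test_that("length bounds are inclusive and must be set", {
  p <- fusion_params(min_fusion_len_bp = 5000L, max_fusion_len_bp = 2000000L)
  expect_true(filter_length(5000L, p))
  expect_true(filter_length(2000000L, p))
  expect_false(filter_length(2000001L, p))
  expect_false(filter_length(4999L, p))
  expect_error(filter_length(100L, fusion_params()), "bounds are unset")

  genes <- make_genes(c("G1", "G2", "G3"), "chr1",
                      c(1L, 100L, 1000L), c(7000L, 80099L, 401000L),
                      c("+", "+", "-"))
  p2 <- set_length_bounds(fusion_params(), genes)
  len <- genes$end - genes$start + 1L
  expect_equal(p2$min_fusion_len_bp, min(len))
  expect_equal(p2$max_fusion_len_bp, max(len))
})

test_that("crossover windows take the k probes nearest the junction, junction-ordered", {
  params <- fusion_params()
  pos5 <- seq(1000L, 20000L, by = 1000L)          # 20 probes
  pos3 <- seq(31000L, 50000L, by = 1000L)
  panel <- make_panel("chr1", c(pos5, pos3), seq_along(c(pos5, pos3)) / 10)
  a5 <- make_anchor("A", "five_prime", "right", 1000L, 20000L, 3L,
                    anchor_pos = 25000L)
  a3 <- make_anchor("B", "three_prime", "left", 31000L, 50000L, 2L,
                    anchor_pos = 25000L)
  win <- crossover_window(a5, a3, panel, params)
  ## brute-force nearest-k by distance to the junction
  d5 <- abs(pos5 - 25000L)
  expect_setequal(win$probe_ids_5p,
                  sprintf("p%04d", order(d5)[1:7]))
  expect_equal(win$five_prime, (14:20) / 10)       # ascending toward junction
  expect_equal(win$three_prime, (21:27) / 10)      # ascending away from it

  ## a six-probe side is ignored
  short3 <- make_anchor("B", "three_prime", "left", 31000L, 36000L, 2L,
                        anchor_pos = 25000L)
  expect_null(crossover_window(a5, short3, panel, params))
})

test_that("crossover windows on right-side 3' anchors read away from the junction", {
  params <- fusion_params()
  pos <- seq(1000L, 20000L, by = 1000L)
  panel <- make_panel("chr1", pos, seq_along(pos))
  a3 <- make_anchor("B", "three_prime", "right", 1000L, 20000L, 2L,
                    anchor_pos = 25000L)
  a5 <- make_anchor("A", "five_prime", "left", 31000L, 50000L, 2L,
                    anchor_pos = 25000L)
  panel2 <- make_panel("chr1", c(pos, seq(31000L, 50000L, by = 1000L)),
                       c(seq_along(pos), rep(0, 20)))
  win <- crossover_window(a5, a3, panel2, params)
  ## 3' side: nearest the junction first, then away (descending position)
  expect_equal(win$three_prime, 20:14)
})

test_that("loess smoothing preserves constants and straight lines", {
  const <- rep(2.5, 14)
  expect_equal(smooth_loess(const, 95), const, tolerance = 1e-8)
  lin <- seq(0, 1, length.out = 14)
  expect_equal(smooth_loess(lin, 60), lin, tolerance = 1e-6)
  expect_equal(smooth_loess(lin, 95), lin, tolerance = 1e-6)
})

test_that("loess at a large span matches an independent local fit closely", {
  set.seed(3)
  y <- sin(seq(0, 3, length.out = 20)) + rnorm(20, 0, 0.05)
  x <- seq_along(y)
  ref <- stats::fitted(stats::loess(y ~ x, span = 0.95, degree = 2,
                                    control = stats::loess.control(surface = "direct")))
  expect_equal(smooth_loess(y, 95), as.numeric(ref), tolerance = 1e-6)
})

test_that("span selection equals an exhaustive grid search with hat-matrix AICc", {
  params <- fusion_params()
  expect_error(select_loess_span(c(1, 2, 3), params), "at least 4")

  set.seed(11)
  for (rep in 1:4) {
    y <- sin(seq(0, 2.5, length.out = 14)) + rnorm(14, 0, 0.1)
    expect_equal(select_loess_span(y, params), oracle_aicc_span(y, params))
  }

  ## an exactly linear series leaves AICc flat: tie breaks to the smallest
  ## feasible span
  lin <- seq(0, 1, length.out = 14)
  s <- select_loess_span(lin, params)
  expect_equal(s, oracle_aicc_span(lin, params))
})

test_that("crossover correlation equals the textbook formula and flags degenerate windows", {
  x <- c(0.1, 0.4, 0.3, 0.8, 0.9, 1.4, 1.2)
  expect_equal(crossover_correlation(x, x), 1)
  expect_equal(crossover_correlation(x, -x), -1)
  y <- c(1.0, 0.7, 0.9, 0.2, 0.5, 0.1, 0.3)
  expect_equal(crossover_correlation(x, y), oracle_pearson(x, y),
               tolerance = 1e-12)
  expect_true(is.na(crossover_correlation(rep(1, 7), y)))
})

test_that("correlation magnitude is invariant under affine rescaling; sign follows slope", {
  set.seed(21)
  for (rep in 1:10) {
    x <- rnorm(7); y <- rnorm(7)
    r0 <- crossover_correlation(x, y)
    a <- runif(1, 0.2, 5); b <- rnorm(1)
    expect_equal(crossover_correlation(a * x + b, y), r0, tolerance = 1e-10)
    expect_equal(crossover_correlation(-a * x + b, y), -r0, tolerance = 1e-10)
    expect_equal(abs(crossover_correlation(-a * x + b, y)), abs(r0),
                 tolerance = 1e-10)
  }
})

test_that("crossover RMS matches the direct formula and its closed forms", {
  x <- c(0.1, 0.4, 0.3, 0.8, 0.9, 1.4, 1.2)
  expect_equal(crossover_rms(x, x), 0)
  expect_equal(crossover_rms(x, x + 0.37), 0.37, tolerance = 1e-12)
  set.seed(5)
  a <- rnorm(7); b <- rnorm(7)
  expect_equal(crossover_rms(a, b), sqrt(sum((a - b)^2) / 7),
               tolerance = 1e-12)
  ## shift invariance
  expect_equal(crossover_rms(a + 2, b + 2), crossover_rms(a, b),
               tolerance = 1e-12)
  ## zero iff identical
  expect_true(crossover_rms(a, b) > 0)
})

test_that("the surviving candidate set is invariant to filter order", {
  ## filters are independent predicates of a pair; applying them in any
  ## order must keep exactly the pairs passing all of them
  params <- fusion_params(min_fusion_len_bp = 100L, max_fusion_len_bp = 500L)
  set.seed(9)
  pairs <- data.frame(
    cn_5p = sample(1:4, 30, TRUE), cn_3p = sample(1:4, 30, TRUE),
    strand_5p = sample(c("+", "-"), 30, TRUE),
    side_5p = sample(c("left", "right"), 30, TRUE),
    strand_3p = sample(c("+", "-"), 30, TRUE),
    side_3p = sample(c("left", "right"), 30, TRUE),
    len = sample(50:600, 30), stringsAsFactors = FALSE)
  preds <- list(
    cn = function(d) filter_cn(d$cn_5p, d$cn_3p, params),
    ori = function(d) filter_orientation(d$strand_5p, d$side_5p,
                                         d$strand_3p, d$side_3p),
    len = function(d) filter_length(d$len, params))
  ref <- which(preds$cn(pairs) & preds$ori(pairs) & preds$len(pairs))
  for (perm in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1), c(3, 1, 2))) {
    keep <- rep(TRUE, nrow(pairs))
    for (k in perm) keep <- keep & preds[[k]](pairs)
    expect_equal(which(keep), ref)
  }
})

test_that("candidate evaluation surfaces drop reasons and keeps compliant pairs", {
  params <- fusion_params(min_fusion_len_bp = 1000L,
                          max_fusion_len_bp = 1000000L)
  pos5 <- seq(1000L, 20000L, by = 1000L)
  pos3 <- seq(31000L, 50000L, by = 1000L)
  ## both windows read the same shape across the junction
  shape <- c(0.0, 0.3, 0.5, 0.4, 0.8, 1.1, 1.6)
  panel <- make_panel("chr1", c(pos5, pos3),
                      c(rep(0.6, 13), shape, shape, rep(0.1, 13)))
  anch <- rbind(
    make_anchor("A", "five_prime", "right", 1000L, 20000L, 3L, anchor_pos = 25000L),
    make_anchor("B", "three_prime", "left", 31000L, 50000L, 2L, anchor_pos = 25000L))
  cand <- evaluate_candidates(anch, panel, params, "S1")
  expect_equal(nrow(cand), 1L)
  expect_true(abs(cand$correlation) > 0.9)

  ## CN gap forces a drop with reason "cn"
  anch2 <- anch; anch2$total_cn[2] <- 6L
  cand2 <- evaluate_candidates(anch2, panel, params, "S1")
  expect_equal(nrow(cand2), 0L)
  expect_equal(attr(cand2, "drops")$stage, "cn")

  ## empty anchor set -> empty output
  cand3 <- evaluate_candidates(anch[0, ], panel, params, "S1")
  expect_equal(nrow(cand3), 0L)
})
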