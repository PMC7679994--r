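test_that("windows pool member cytosines with half-open tile boundaries", {
  ref <- make_records(pos = c(10, 150), n_meth = c(3, 2), n_unmeth = c(7, 8))
  test <- make_records(pos = c(10, 150), n_meth = c(1, 1),
                       n_unmeth = c(9, 9))
  w <- build_windows(ref, test)
  expect_equal(nrow(w), 1L)
  expect_equal(w$start, 1L)
  expect_equal(w$end, 200L)
  expect_equal(w$mC_ref, 5L)
  expect_equal(w$u_ref, 15L)
  expect_equal(w$level_ref, 0.25)

  # position 201 begins the second tile
  ref2 <- make_records(pos = c(200, 201), n_meth = 1, n_unmeth = 1)
  w2 <- build_windows(ref2, ref2)
  expect_equal(w2$start, c(1L, 201L))
})

test_that("per-window totals equal an independent interval-join recount", {
  set.seed(21)
  n <- 2000L
  ref <- make_records(pos = sample.int(20000L, n),
                      context = sample(c("CG", "CHG", "CHH"), n, TRUE),
                      n_meth = rpois(n, 3), n_unmeth = rpois(n, 3))
  test <- copy(ref)[, n_meth := rpois(n, 3)]
  w <- build_windows(ref, test)
  # recount via explicit interval membership, one window at a time
  idx <- sample.int(nrow(w), 50L)
  for (i in idx) {
    members <- ref[pos >= w$start[i] & pos <= w$end[i] &
                     context == w$context[i]]
    expect_equal(w$mC_ref[i], sum(members$n_meth))
    expect_equal(w$u_ref[i], sum(members$n_unmeth))
  }
})

test_that("window coverage filter enforces 16/16/64 in both genotypes", {
  w <- rbind(
    make_window(context = "CHH", mC_ref = 30, u_ref = 33, mC_test = 100,
                u_test = 100),                       # 63 reads in ref: drop
    make_window(context = "CG", mC_ref = 8, u_ref = 8, mC_test = 10,
                u_test = 6),                         # 16 and 16: keep
    make_window(context = "CHG", mC_ref = 0, u_ref = 0, mC_test = 0,
                u_test = 0))                         # empty: drop
  kept <- window_coverage_filter(w)
  expect_equal(kept$context, "CG")
})

test_that("two-sided Fisher p matches fisher.test and full enumeration", {
  # spec'd degenerate and symmetric cases
  expect_equal(fisher_test_2x2(10, 10, 10, 10), 1)
  expect_equal(fisher_test_2x2(0, 10, 0, 10), 1)
  p <- fisher_test_2x2(20, 0, 2, 18)
  expect_equal(p, oracle_fisher_p(20, 0, 2, 18), tolerance = 1e-10)
  expect_equal(p, fisher.test(rbind(c(20, 0), c(2, 18)))$p.value,
               tolerance = 1e-10)

  set.seed(9)
  for (rep in 1:60) {
    tot <- sample(4:80, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    got <- fisher_test_2x2(a, b, c, d)
    expect_equal(got, oracle_fisher_p(a, b, c, d), tolerance = 1e-10)
    expect_equal(got, fisher.test(rbind(c(a, b), c(c, d)))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("test_windows computes delta as test minus reference", {
  w <- make_window(mC_ref = 20, u_ref = 0, mC_test = 2, u_test = 18)
  tw <- test_windows(w)
  expect_equal(tw$delta, -0.9)
  expect_equal(tw$p_value, oracle_fisher_p(20, 0, 2, 18), tolerance = 1e-10)
})

test_that("DMR gates are strict on both adjusted p and per-context delta", {
  # overwhelming significance but |delta| below / above the context gate
  w <- rbind(
    make_window(start = 1, context = "CG", mC_ref = 1000, u_ref = 0,
                mC_test = 550, u_test = 450),   # delta -0.45: not a DMR
    make_window(start = 201, context = "CHG", mC_ref = 1000, u_ref = 0,
                mC_test = 690, u_test = 310),   # delta -0.31: hypo-DMR
    make_window(start = 401, context = "CHH", mC_ref = 500, u_ref = 500,
                mC_test = 500, u_test = 500))   # null window
  d <- call_dmrs(test_windows(w))
  expect_equal(nrow(d), 1L)
  expect_equal(d$context, "CHG")
  expect_equal(d$direction, "hypo")
  expect_equal(d$delta, -0.31)

  # BH consistency on the full adjusted table
  full <- attr(d, "windows")
  expect_true(all(full$p_adj >= full$p_value - 1e-15))
  setorder(full, context, p_value)
  expect_true(all(full[, diff(p_adj) >= -1e-12, by = context]$V1))
})

test_that("swapping reference and test flips direction and keeps p-values", {
  set.seed(31)
  n <- 400L
  ref <- make_records(pos = sample.int(20000L, n), n_meth = rpois(n, 8),
                      n_unmeth = rpois(n, 2))
  test <- copy(ref)[, `:=`(n_meth = rpois(n, 2), n_unmeth = rpois(n, 8))]
  fwd <- call_dmrs(test_windows(window_coverage_filter(
    build_windows(ref, test))))
  rev <- call_dmrs(test_windows(window_coverage_filter(
    build_windows(test, ref))))
  expect_equal(nrow(fwd), nrow(rev))
  setorder(fwd, chrom, start); setorder(rev, chrom, start)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$delta, -rev$delta)
  expect_true(all(fwd$direction != rev$direction))
})

test_that("restoration calls reverted windows and leaves uncovered ones undetermined", {
  set.seed(41)
  # 30 CG cytosines in one tile at depth 50: REF 0.8, TEST 0.1,
  # RESTORED either 0.8 (reverted) or 0.1 (kept)
  mk <- function(level, pos0) {
    depth <- rpois(30, 50)
    m <- rbinom(30, depth, level)
    make_records(pos = pos0 + seq_len(30) * 6, n_meth = m,
                 n_unmeth = depth - m)
  }
  ref <- rbind(mk(0.8, 0), mk(0.8, 200))
  test <- rbind(mk(0.1, 0), mk(0.1, 200))
  restored <- rbind(mk(0.8, 0), mk(0.1, 200))   # tile 1 reverted, tile 2 not
  dmrs <- dmr_scan(ref, test)
  expect_equal(nrow(dmrs), 2L)
  rs <- restoration_analysis(dmrs, test, restored)
  expect_equal(rs[start == 1, restored], TRUE)
  expect_equal(rs[start == 201, restored], FALSE)

  # a restored genotype with no reads there: undetermined
  rs_na <- restoration_analysis(dmrs, test, make_records(pos = 5000,
                                                         n_meth = 5,
                                                         n_unmeth = 5))
  expect_true(all(is.na(rs_na$restored)))

  # identical genotypes produce no DMRs and hence no statuses
  none <- dmr_scan(ref, ref)
  expect_equal(nrow(none), 0L)
  expect_equal(nrow(restoration_analysis(none, ref, ref)), 0L)
})

test_that("DMR overlap fractions count shared tiles per context", {
  d <- function(starts, context = "CG") {
    data.table(chrom = "chr1", start = starts, end = starts + 199L,
               context = context)
  }
  a <- d(seq(1, by = 200, length.out = 10))
  expect_equal(dmr_overlap(a, a)$frac_a, 1)
  b <- d(seq(4001, by = 200, length.out = 10))
  expect_equal(dmr_overlap(a, b)$frac_a, 0)
  # 3 shared tiles out of 10 in each set
  c3 <- rbind(d(c(1, 201, 401)), d(seq(10001, by = 200, length.out = 7)))
  ov <- dmr_overlap(a, c3)
  expect_equal(ov$frac_a, 0.3)
  expect_equal(ov$frac_b, 0.3)
  # same tile, different context: no overlap
  ov2 <- dmr_overlap(a, d(1, context = "CHG"))
  expect_equal(ov2$frac_a, 0)
})
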