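# Windowed differential-methylation testing between two genotypes,
# DMR classification, restoration analysis, cross-comparison overlap.

DMR_DELTA_THRESHOLDS <- c(CG = 0.5, CHG = 0.3, CHH = 0.1)
WINDOW_MIN_READS <- c(CG = 16, CHG = 16, CHH = 64)

#' Pool cytosine counts of two genotypes into fixed windows
#'
#' Tiles each chromosome with non-overlapping windows (default 200 bp,
#' starting at position 1) and pools methylated/unmethylated read counts per
#' (window, context) for both genotypes. The per-genotype window level is
#' `mC / (mC + non-mC)` over the pooled counts.
#'
#' @param ref_records,test_records cytosine `data.table`s for the reference
#'   and test genotypes, normally pre-filtered with [coverage_filter()].
#' @param width window width in bp (default 200).
#' @param contexts contexts to keep (default CG, CHG, CHH).
#' @return `data.table` with `chrom`, `start`, `end`, `context`, pooled
#'   counts `mC_ref`, `u_ref`, `mC_test`, `u_test` and levels `level_ref`,
#'   `level_test` (`NA` where a genotype has no reads in the window). Only
#'   windows containing at least one record are emitted.
#' @export
build_windows <- function(ref_records, test_records, width = 200L,
                          contexts = CONTEXTS) {
  width <- as.integer(width)
  pool <- function(r, suffix) {
    dt <- as.data.table(r)[context %in% contexts]
    agg <- dt[, .(mC = sum(n_meth), u = sum(n_unmeth)),
              by = .(chrom, start = ((pos - 1L) %/% width) * width + 1L,
                     context)]
    setnames(agg, c("mC", "u"), paste0(c("mC_", "u_"), suffix))
    agg
  }
  w <- merge(pool(ref_records, "ref"), pool(test_records, "test"),
             by = c("chrom", "start", "context"), all = TRUE)
  for (col in c("mC_ref", "u_ref", "mC_test", "u_test")) {
    w[is.na(get(col)), (col) := 0L]
  }
  w[, end := start + width - 1L]
  w[, level_ref := ifelse(mC_ref + u_ref > 0L,
                          mC_ref / (mC_ref + u_ref), NA_real_)]
  w[, level_test := ifelse(mC_test + u_test > 0L,
                           mC_test / (mC_test + u_test), NA_real_)]
  setcolorder(w, c("chrom", "start", "end", "context"))
  setorder(w, chrom, start, context)
  w[]
}

#' Window read-coverage filter
#'
#' Keeps a window only when the pooled read total reaches the per-context
#' minimum (defaults 16 for CG, 16 for CHG, 64 for CHH) in *both* genotypes.
#'
#' @param windows output of [build_windows()].
#' @param min_reads named per-context minimum read totals.
#' @return the surviving windows.
#' @export
window_coverage_filter <- function(windows, min_reads = WINDOW_MIN_READS) {
  w <- as.data.table(windows)
  need <- min_reads[w$context]
  w[(mC_ref + u_ref) >= need & (mC_test + u_test) >= need]
}

# Two-sided Fisher exact p for 2x2 tables [[a, b], [c, d]], vectorized over
# tables. Sums all hypergeometric point probabilities not exceeding the
# observed one (with the customary 1 + 1e-7 relative tolerance). A table
# with a zero margin has a single-point support and p = 1.
fisher_test_2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  p <- numeric(n)
  rel <- 1 + 1e-7
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]           # row 1 total
    m2 <- c[i] + d[i]           # row 2 total
    k  <- a[i] + c[i]           # column 1 total
    lo <- max(0L, k - m2)
    hi <- min(k, m1)
    dens <- dhyper(lo:hi, m1, m2, k)
    p[i] <- min(1, sum(dens[dens <= dens[a[i] - lo + 1L] * rel]))
  }
  p
}

#' Test windows for differential methylation
#'
#' Applies a two-sided Fisher exact test to each window's pooled 2x2 count
#' table `[[mC_ref, u_ref], [mC_test, u_test]]` and computes the level
#' difference `delta = level_test - level_ref`.
#'
#' @param windows output of [window_coverage_filter()].
#' @return the windows with `p_value` and `delta` columns added.
#' @export
test_windows <- function(windows) {
  w <- as.data.table(windows)
  w[, p_value := fisher_test_2x2(mC_ref, u_ref, mC_test, u_test)]
  w[, delta := level_test - level_ref]
  w[]
}

#' Call DMRs from tested windows
#'
#' Adjusts Fisher p-values within each context (Benjamini-Hochberg by
#' default) and calls a window a DMR when `p_adj < alpha` *and* the absolute
#' level difference strictly exceeds the context threshold (defaults 0.5 for
#' CG, 0.3 for CHG, 0.1 for CHH). Direction is `hypo` when the test genotype
#' is less methylated than the reference, `hyper` otherwise.
#'
#' @param windows output of [test_windows()].
#' @param alpha adjusted-p significance level (default 0.05, strict `<`).
#' @param thresholds named per-context minimum `|delta|` (strict `>`).
#' @param method multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return `data.table` of DMR calls (subset of windows) with `p_adj` and
#'   `direction` added; the full adjusted window table is attached as
#'   attribute `"windows"`.
#' @export
call_dmrs <- function(windows, alpha = 0.05,
                      thresholds = DMR_DELTA_THRESHOLDS, method = "BH") {
  w <- as.data.table(windows)
  if (!nrow(w)) {
    w[, `:=`(p_adj = numeric(0), direction = character(0))]
    dmrs <- w
    setattr(dmrs, "windows", w)
    return(dmrs)
  }
  w[, p_adj := p.adjust(p_value, method = method), by = context]
  thr <- thresholds[w$context]
  dmrs <- w[!is.na(delta) & p_adj < alpha & abs(delta) > thr]
  dmrs[, direction := ifelse(delta < 0, "hypo", "hyper")]
  setattr(dmrs, "windows", copy(w))
  dmrs[]
}

#' One-call DMR scan between two genotypes
#'
#' Convenience composition: per-cytosine [coverage_filter()] across both
#' genotypes, [build_windows()], [window_coverage_filter()],
#' [test_windows()] and [call_dmrs()].
#'
#' @inheritParams build_windows
#' @inheritParams call_dmrs
#' @param min_site_reads per-cytosine minimum coverage in both genotypes
#'   (default 3).
#' @param min_window_reads per-context window read minimums.
#' @return the [call_dmrs()] result.
#' @export
dmr_scan <- function(ref_records, test_records, width = 200L,
                     contexts = CONTEXTS, min_site_reads = 3L,
                     min_window_reads = WINDOW_MIN_READS, alpha = 0.05,
                     thresholds = DMR_DELTA_THRESHOLDS, method = "BH") {
  filt <- coverage_filter(list(ref = ref_records, test = test_records),
                          min_reads = min_site_reads)
  w <- build_windows(filt$ref, filt$test, width = width, contexts = contexts)
  w <- window_coverage_filter(w, min_reads = min_window_reads)
  w <- test_windows(w)
  call_dmrs(w, alpha = alpha, thresholds = thresholds, method = method)
}

#' Classify DMRs as restored or not in a third genotype
#'
#' For each DMR called between TEST and REF, asks whether the RESTORED
#' genotype has reverted the change: the RESTORED-vs-TEST comparison on the
#' same window must itself be a significant DMR in the opposite direction
#' under the same coverage, significance and effect-size rules. Windows
#' without sufficient coverage in the restored comparison get `restored =
#' NA` and are excluded from restoration-fraction denominators.
#'
#' @param dmrs DMR table from [call_dmrs()] (TEST vs REF).
#' @param test_records,restored_records cytosine tables for the TEST and
#'   RESTORED genotypes (ideally coverage-filtered jointly with REF).
#' @inheritParams dmr_scan
#' @return `dmrs` with `restored` (logical) and `delta_restored`
#'   (`level_restored - level_test`) columns added.
#' @export
restoration_analysis <- function(dmrs, test_records, restored_records,
                                 width = 200L, min_site_reads = 3L,
                                 min_window_reads = WINDOW_MIN_READS,
                                 alpha = 0.05,
                                 thresholds = DMR_DELTA_THRESHOLDS,
                                 method = "BH") {
  d <- as.data.table(dmrs)
  if (!nrow(d)) {
    d[, `:=`(restored = logical(0), delta_restored = numeric(0))]
    return(d[])
  }
  filt <- coverage_filter(list(test = test_records, rest = restored_records),
                          min_reads = min_site_reads)
  w <- build_windows(filt$test, filt$rest, width = width,
                     contexts = unique(d$context))
  w <- w[paste(chrom, start, context) %in%
           d[, paste(chrom, start, context)]]
  w <- window_coverage_filter(w, min_reads = min_window_reads)
  w <- test_windows(w)
  if (nrow(w)) {
    w[, p_adj := p.adjust(p_value, method = method), by = context]
  } else {
    w[, p_adj := numeric(0)]
  }
  key <- c("chrom", "start", "context")
  m <- merge(d[, c(key, "direction"), with = FALSE],
             w[, c(key, "p_adj", "delta"), with = FALSE],
             by = key, all.x = TRUE, sort = FALSE)
  thr <- thresholds[m$context]
  sig <- !is.na(m$p_adj) & m$p_adj < alpha & abs(m$delta) > thr
  opposite <- ifelse(m$direction == "hypo", m$delta > 0, m$delta < 0)
  restored <- ifelse(is.na(m$p_adj), NA, sig & opposite)
  res <- data.table(m[, key, with = FALSE],
                    restored = restored, delta_restored = m$delta)
  out <- merge(d, res, by = key, all.x = TRUE, sort = FALSE)
  setorder(out, chrom, start, context)
  out[]
}

#' Overlap between two DMR sets
#'
#' Two DMRs overlap when they share the same context and at least one base
#' pair. Fractions are reported relative to each set.
#'
#' @param dmrs_a,dmrs_b DMR tables from [call_dmrs()].
#' @return list with `frac_a` (fraction of `dmrs_a` overlapped), `frac_b`,
#'   and `pairs` (`data.table` of overlapping row indices `idx_a`, `idx_b`).
#' @export
dmr_overlap <- function(dmrs_a, dmrs_b) {
  a <- as.data.table(dmrs_a)
  b <- as.data.table(dmrs_b)
  if (!nrow(a) || !nrow(b)) {
    return(list(frac_a = if (nrow(a)) 0 else NaN,
                frac_b = if (nrow(b)) 0 else NaN,
                pairs = data.table(idx_a = integer(0), idx_b = integer(0))))
  }
  keys_a <- paste0(a$chrom, "|", a$context)
  keys_b <- paste0(b$chrom, "|", b$context)
  lev <- union(keys_a, keys_b)
  gra <- GRanges(factor(keys_a, levels = lev), IRanges(a$start, a$end))
  grb <- GRanges(factor(keys_b, levels = lev), IRanges(b$start, b$end))
  ov <- findOverlaps(gra, grb)
  pairs <- data.table(idx_a = queryHits(ov), idx_b = subjectHits(ov))
  list(frac_a = length(unique(pairs$idx_a)) / nrow(a),
       frac_b = length(unique(pairs$idx_b)) / nrow(b),
       pairs = pairs)
}

#' Write DMR calls as BED6+ text
#'
#' Columns: chrom, 0-based start, end, `context:direction`, `-log10(p_adj)`
#' rounded to 3 digits, `.`, then level_ref, level_test, delta, p_value,
#' p_adj.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  d <- as.data.table(dmrs)
  out <- data.table(chrom = d$chrom, start = d$start - 1L, end = d$end,
                    name = paste0(d$context, ":", d$direction),
                    score = round(-log10(pmax(d$p_adj, 1e-300)), 3),
                    strand = ".",
                    level_ref = d$level_ref, level_test = d$level_test,
                    delta = d$delta, p_value = d$p_value, p_adj = d$p_adj)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
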