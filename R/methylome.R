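# Per-cytosine methylcytosine calling and genome-scale summaries.

#' Call methylcytosines with a binomial test against non-conversion
#'
#' Incomplete bisulfite conversion makes a fraction `epsilon` of truly
#' unmethylated cytosines read as methylated, so a cytosine is called a
#' methylcytosine only when its methylated-read count exceeds what that
#' error rate explains: the one-sided upper binomial tail
#' `P(X >= n_meth | X ~ Binomial(n, epsilon))` must fall strictly below
#' `alpha`.
#'
#' @param records cytosine `data.table` (`n_meth`, `n_unmeth`).
#' @param epsilon bisulfite non-conversion rate in (0, 1); default 0.005
#'   (a conversion rate above 99 percent).
#' @param alpha significance level; the call uses a strict `<` (default
#'   `1e-5`).
#' @param min_coverage minimum total reads for a cytosine to be callable
#'   (default 3); below it `p_value` and `is_methylcytosine` are `NA`.
#' @return the input with `p_value` and `is_methylcytosine` columns added.
#' @export
call_methylcytosines <- function(records, epsilon = 0.005, alpha = 1e-5,
                                 min_coverage = 3L) {
  stopifnot(epsilon > 0, epsilon < 1, alpha > 0)
  dt <- as.data.table(records)
  n <- dt$n_meth + dt$n_unmeth
  # P(X >= k) = 1 - P(X <= k - 1); k = 0 gives exactly 1
  p <- pbinom(dt$n_meth - 1L, n, epsilon, lower.tail = FALSE)
  p[n < min_coverage] <- NA_real_
  dt[, p_value := p]
  dt[, is_methylcytosine := p_value < alpha]
  dt[]
}

#' Keep cytosines covered in every genotype
#'
#' A site (chrom, pos, strand) survives only if its total read count is at
#' least `min_reads` in all compared genotypes, so every downstream
#' comparison uses the same cytosines.
#'
#' @param records_list named list of cytosine `data.table`s, one per
#'   genotype.
#' @param min_reads minimum coverage per genotype (default 3).
#' @return list of the same shape with only the surviving sites, each
#'   ordered by (chrom, pos, strand).
#' @export
coverage_filter <- function(records_list, min_reads = 3L) {
  stopifnot(is.list(records_list), length(records_list) >= 1L)
  keys <- lapply(records_list, function(r) {
    dt <- as.data.table(r)
    dt[n_meth + n_unmeth >= min_reads, .(chrom, pos, strand)]
  })
  common <- Reduce(function(a, b) {
    merge(a, b, by = c("chrom", "pos", "strand"))
  }, keys)
  lapply(records_list, function(r) {
    dt <- merge(as.data.table(r), common, by = c("chrom", "pos", "strand"))
    setorder(dt, chrom, pos, strand)
    dt[]
  })
}

#' Pooled methylation level in fixed genome windows
#'
#' Computes the methylation level `sum(mC) / sum(mC + non-mC)` over the
#' covered cytosines of each context in non-overlapping windows tiling each
#' chromosome (default 1 Mb), the per-chromosome summary behind genome-wide
#' methylation landscape plots.
#'
#' @param records cytosine `data.table` with a `context` column.
#' @param seqlengths named integer vector of chromosome lengths.
#' @param width window width in bp (default 1e6).
#' @return `data.table` with `chrom`, `start`, `end` (1-based closed;
#'   the last bin of a chromosome may be partial and is flagged in
#'   `partial`), `context`, `n_covered` and `level` (`NA` when no covered
#'   cytosine falls in the bin).
#' @export
genome_bins <- function(records, seqlengths, width = 1e6L) {
  stopifnot(!is.null(names(seqlengths)))
  width <- as.integer(width)
  dt <- as.data.table(records)
  unknown <- setdiff(unique(dt$chrom), names(seqlengths))
  if (length(unknown)) stop("records on unknown chromosome(s): ",
                            paste(unknown, collapse = ", "))
  # full tiling so empty bins are emitted as undefined
  grid <- rbindlist(lapply(names(seqlengths), function(ch) {
    L <- seqlengths[[ch]]
    s <- seq.int(1L, L, by = width)
    data.table(chrom = ch, start = s, end = pmin(s + width - 1L, L))
  }))
  grid <- grid[rep(seq_len(nrow(grid)), each = length(CONTEXTS))]
  grid[, context := rep(CONTEXTS, length.out = .N)]

  agg <- dt[, .(mC = sum(n_meth), total = sum(n_meth + n_unmeth),
                n_covered = sum(n_meth + n_unmeth > 0L)),
            by = .(chrom, start = ((pos - 1L) %/% width) * width + 1L,
                   context)]
  out <- merge(grid, agg, by = c("chrom", "start", "context"),
               all.x = TRUE, sort = FALSE)
  out[is.na(n_covered), n_covered := 0L]
  out[, level := ifelse(!is.na(total) & total > 0L, mC / total, NA_real_)]
  out[, partial := end - start + 1L < width]
  out[, c("mC", "total") := NULL]
  setorder(out, chrom, start, context)
  out[]
}
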