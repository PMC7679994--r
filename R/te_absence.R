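# Call reference-annotated TEs absent from a query genotype: split and
# discordant read evidence spanning the locus, a depleted-interior depth
# criterion, and confirmation by reference-genotype read coverage.

#' Read a SAM/BAM file into an alignment table
#'
#' Converts SAM to BAM in a temporary directory when needed (via
#' `Rsamtools::asBam`) and extracts the fields the absence-variant caller
#' uses. Reference end positions are computed from the CIGAR.
#'
#' @param path a `.sam` or `.bam` file.
#' @return `data.table` with `qname`, `flag`, `chrom`, `pos`, `end`,
#'   `mapq`, `mrnm`, `mpos`; chromosome lengths from the header are
#'   attached as attribute `"seqlengths"`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "mrnm", "mpos"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  dt <- data.table(qname = x$qname, flag = x$flag,
                   chrom = as.character(x$rname), pos = x$pos,
                   mapq = x$mapq, cigar = x$cigar,
                   mrnm = as.character(x$mrnm), mpos = x$mpos)
  dt <- dt[!is.na(pos)]
  dt[, end := pos +
       GenomicAlignments::cigarWidthAlongReferenceSpace(cigar) - 1L]
  dt[, cigar := NULL]
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  setattr(dt, "seqlengths", hdr)
  dt[]
}

#' Extract split and discordant read evidence
#'
#' A discordant pair has both mates aligned to the same chromosome with
#' more than `min_distance` bp between them (end of the left mate to start
#' of the right); a split read has its primary and supplementary segments
#' separated the same way. The spanned interval of an evidence is the gap
#' between the aligned parts.
#'
#' @param sam alignment table from [read_sam()].
#' @param min_mapq minimum mapping quality; lower records are dropped
#'   (default 20).
#' @param min_distance separation rule in bp (default 2000, strict `>`).
#' @return `data.table` with `read_id`, `kind` (`split`/`discordant`),
#'   `chrom`, `start`, `end` (the spanned gap interval) and `mapq` (the
#'   smaller of the two parts).
#' @export
extract_evidence <- function(sam, min_mapq = 20L, min_distance = 2000L) {
  dt <- as.data.table(sam)[mapq >= min_mapq]
  is_suppl <- bitwAnd(dt$flag, 2048L) > 0L
  is_secondary <- bitwAnd(dt$flag, 256L) > 0L
  mate1 <- bitwAnd(dt$flag, 64L) > 0L

  prim <- dt[!is_suppl & !is_secondary]
  prim_mate1 <- mate1[!is_suppl & !is_secondary]

  # discordant pairs: join the two primary mates of each fragment
  m1 <- prim[prim_mate1, .(qname, chrom, pos, end, mapq)]
  m2 <- prim[!prim_mate1, .(qname, chrom, pos, end, mapq)]
  pairs <- merge(m1, m2, by = "qname", suffixes = c("_1", "_2"))
  pairs <- pairs[chrom_1 == chrom_2]
  pairs[, `:=`(gap_start = pmin(end_1, end_2) + 1L,
               gap_end = pmax(pos_1, pos_2) - 1L)]
  disc <- pairs[gap_end - gap_start + 1L > min_distance,
                .(read_id = qname, kind = "discordant", chrom = chrom_1,
                  start = gap_start, end = gap_end,
                  mapq = pmin(mapq_1, mapq_2))]

  # split reads: join each supplementary segment with its primary
  sup <- dt[is_suppl & !is_secondary]
  sup_mate1 <- mate1[is_suppl & !is_secondary]
  sup[, mate := 2L - as.integer(sup_mate1)]
  pr <- copy(prim)[, mate := 2L - as.integer(prim_mate1)]
  sj <- merge(pr[, .(qname, mate, chrom, pos, end, mapq)],
              sup[, .(qname, mate, chrom, pos, end, mapq)],
              by = c("qname", "mate"), suffixes = c("_p", "_s"))
  sj <- sj[chrom_p == chrom_s]
  sj[, `:=`(gap_start = pmin(end_p, end_s) + 1L,
            gap_end = pmax(pos_p, pos_s) - 1L)]
  spl <- sj[gap_end - gap_start + 1L > min_distance,
            .(read_id = paste0(qname, "/", mate), kind = "split",
              chrom = chrom_p, start = gap_start, end = gap_end,
              mapq = pmin(mapq_p, mapq_s))]

  out <- rbindlist(list(spl, disc))
  if (nrow(out)) setorder(out, chrom, start, end)
  out[]
}

#' Identify candidate absent TEs from spanning evidence
#'
#' For every annotated TE, the span fraction is the covered share of the TE
#' by a single evidence interval (the best one; set `combine = "union"` to
#' use the union of all evidence instead). Candidates require a span
#' fraction of at least `min_span_frac`.
#'
#' @param evidence table from [extract_evidence()].
#' @param tes `GRanges` of TEs with an `id` metadata column.
#' @param min_span_frac minimum spanned fraction (default 0.8, `>=`).
#' @param combine `"best"` (single best evidence interval) or `"union"`.
#' @return `data.table` with one row per TE: `te_id`, `chrom`, `start`,
#'   `end`, `span_frac`, `n_split`, `n_discordant`, the best evidence's
#'   spanned interval (`span_start`, `span_end`) and `candidate`.
#' @export
candidate_tes <- function(evidence, tes, min_span_frac = 0.8,
                          combine = c("best", "union")) {
  combine <- match.arg(combine)
  ev <- as.data.table(evidence)
  out <- data.table(te_id = mcols(tes)$id,
                    chrom = as.character(seqnames(tes)),
                    start = start(tes), end = end(tes),
                    span_frac = 0, n_split = 0L, n_discordant = 0L,
                    span_start = NA_integer_, span_end = NA_integer_)
  if (nrow(ev)) {
    ev_gr <- GRanges(ev$chrom, IRanges(ev$start, ev$end))
    ov <- findOverlaps(ev_gr, tes, ignore.strand = TRUE)
    if (length(ov)) {
      inter <- pintersect(ev_gr[queryHits(ov)],
                          granges(tes)[subjectHits(ov)],
                          ignore.strand = TRUE)
      hits <- data.table(te = subjectHits(ov), ev = queryHits(ov),
                         cov = width(inter),
                         is_start = start(inter), is_end = end(inter),
                         kind = ev$kind[queryHits(ov)])
      kind_n <- hits[, .(n_split = sum(kind == "split"),
                         n_discordant = sum(kind == "discordant")), by = te]
      out[kind_n$te, `:=`(n_split = kind_n$n_split,
                          n_discordant = kind_n$n_discordant)]
      if (combine == "best") {
        best <- hits[order(te, -cov)][!duplicated(te)]
        out[best$te, `:=`(span_frac = best$cov / (end - start + 1L),
                          span_start = best$is_start,
                          span_end = best$is_end)]
      } else {
        uni <- hits[, {
          r <- reduce(IRanges(is_start, is_end))
          .(cov = sum(width(r)), s = min(start(r)), e = max(end(r)))
        }, by = te]
        out[uni$te, `:=`(span_frac = uni$cov / (end - start + 1L),
                         span_start = uni$s, span_end = uni$e)]
      }
    }
  }
  out[, candidate := span_frac >= min_span_frac]
  out[]
}

# Mean per-base depth of an interval from an RleList coverage track.
.mean_depth <- function(cov, chrom, start, end) {
  if (!chrom %in% names(cov)) return(0)
  r <- cov[[chrom]]
  L <- length(r)
  s <- max(1L, start); e <- min(L, end)
  if (e < s) return(0)
  mean(S4Vectors::window(r, s, e))
}

#' Per-base coverage from an alignment table
#'
#' @param sam table from [read_sam()] (uses all mapped primary and
#'   supplementary segments).
#' @param seqlengths named chromosome lengths; defaults to the SAM header
#'   lengths attached by [read_sam()].
#' @return an `RleList` of per-base depths.
#' @export
alignment_coverage <- function(sam, seqlengths = attr(sam, "seqlengths")) {
  dt <- as.data.table(sam)
  dt <- dt[bitwAnd(flag, 256L) == 0L]   # skip secondary alignments
  gr <- GRanges(dt$chrom, IRanges(dt$pos, dt$end))
  if (!is.null(seqlengths)) {
    seqlengths(gr) <- seqlengths[seqlevels(gr)]
  }
  coverage(gr)
}

#' Apply the interior-depth criterion to candidate TEs
#'
#' The interior depth is the mean per-base depth within the spanned region
#' intersected with the TE; the flank depth is the mean over the 2-kb
#' regions either side (truncated at chromosome ends). The criterion passes
#' when interior depth is strictly below `max_ratio` of the flank depth; a
#' zero flank depth fails with an undefined ratio.
#'
#' @param cands table from [candidate_tes()].
#' @param cov coverage `RleList` from [alignment_coverage()].
#' @param flank flank span in bp (default 2000).
#' @param max_ratio maximum interior/flank ratio (default 0.1, strict `<`).
#' @return `cands` with `interior_depth`, `flank_depth`, `depth_ratio` and
#'   `depth_pass` columns added.
#' @export
depth_criterion <- function(cands, cov, flank = 2000L, max_ratio = 0.1) {
  d <- as.data.table(cands)
  n <- nrow(d)
  interior <- numeric(n); flankd <- numeric(n)
  for (i in seq_len(n)) {
    s <- if (is.na(d$span_start[i])) d$start[i] else
      max(d$start[i], d$span_start[i])
    e <- if (is.na(d$span_end[i])) d$end[i] else
      min(d$end[i], d$span_end[i])
    interior[i] <- .mean_depth(cov, d$chrom[i], s, e)
    chrom_len <- length(cov[[d$chrom[i]]])
    left <- c(max(1L, d$start[i] - flank), d$start[i] - 1L)
    right <- c(d$end[i] + 1L, min(chrom_len, d$end[i] + flank))
    sides <- c(
      if (left[2L] >= left[1L])
        sum(S4Vectors::window(cov[[d$chrom[i]]], left[1L], left[2L])),
      if (right[2L] >= right[1L])
        sum(S4Vectors::window(cov[[d$chrom[i]]], right[1L], right[2L])))
    nb <- max(0L, left[2L] - left[1L] + 1L) +
      max(0L, right[2L] - right[1L] + 1L)
    flankd[i] <- if (nb > 0L) sum(sides) / nb else 0
  }
  d[, interior_depth := interior]
  d[, flank_depth := flankd]
  d[, depth_ratio := ifelse(flank_depth > 0, interior_depth / flank_depth,
                            NA_real_)]
  d[, depth_pass := !is.na(depth_ratio) & depth_ratio < max_ratio]
  d[]
}

#' Confirm candidate absences with reference-genotype read coverage
#'
#' A candidate is confirmed when at least `min_frac` of the TE's bases are
#' covered (depth >= 1) by reads of the TE-carrying reference genotype,
#' showing the reference annotation itself is real sequence.
#'
#' @param cands candidate table (with `chrom`, `start`, `end`).
#' @param cov coverage `RleList` (or `GRanges` with a `score` column,
#'   bedgraph-style) of reference-genotype reads.
#' @param min_frac minimum covered fraction (default 0.8, `>=`).
#' @return `cands` with `covered_frac` and `confirmed` columns added.
#' @export
confirm_with_reference_reads <- function(cands, cov, min_frac = 0.8) {
  d <- as.data.table(cands)
  if (is(cov, "GRanges")) {
    sc <- mcols(cov)$score
    if (is.null(sc)) sc <- rep(1L, length(cov))
    cov <- coverage(cov[sc > 0])
  }
  frac <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    ch <- d$chrom[i]
    if (!ch %in% names(cov)) { frac[i] <- 0; next }
    r <- cov[[ch]]
    s <- max(1L, d$start[i]); e <- min(length(r), d$end[i])
    covered <- if (e >= s) sum(S4Vectors::window(r, s, e) >= 1L) else 0L
    frac[i] <- covered / (d$end[i] - d$start[i] + 1L)
  }
  d[, covered_frac := frac]
  d[, confirmed := covered_frac >= min_frac]
  d[]
}

#' End-to-end TE absence-variant calling
#'
#' Composes [extract_evidence()], [candidate_tes()], [depth_criterion()]
#' and, when a reference-genotype coverage track is supplied,
#' [confirm_with_reference_reads()]. A TE is called absent when it is a
#' spanning-evidence candidate, passes the depth criterion, and (if
#' confirmation is requested) is confirmed.
#'
#' @param sam a SAM/BAM path or a table from [read_sam()].
#' @param tes `GRanges` of TEs with an `id` metadata column.
#' @param confirm_coverage optional reference-genotype coverage (`RleList`
#'   or bedgraph-style `GRanges`).
#' @param min_mapq,min_distance,min_span_frac,max_ratio,flank,min_confirm_frac
#'   stage parameters; see the stage functions.
#' @param combine evidence combination rule for [candidate_tes()].
#' @return per-TE `data.table` with all evidence columns and the final
#'   `called` flag.
#' @export
call_te_absence <- function(sam, tes, confirm_coverage = NULL,
                            min_mapq = 20L, min_distance = 2000L,
                            min_span_frac = 0.8, max_ratio = 0.1,
                            flank = 2000L, min_confirm_frac = 0.8,
                            combine = "best") {
  if (is.character(sam)) sam <- read_sam(sam)
  ev <- extract_evidence(sam, min_mapq = min_mapq,
                         min_distance = min_distance)
  cands <- candidate_tes(ev, tes, min_span_frac = min_span_frac,
                         combine = combine)
  cov <- alignment_coverage(sam)
  cands <- depth_criterion(cands, cov, flank = flank,
                           max_ratio = max_ratio)
  if (!is.null(confirm_coverage)) {
    cands <- confirm_with_reference_reads(cands, confirm_coverage,
                                          min_frac = min_confirm_frac)
    cands[, called := candidate & depth_pass & confirmed]
  } else {
    cands[, `:=`(covered_frac = NA_real_, confirmed = NA)]
    cands[, called := candidate & depth_pass]
  }
  setorder(cands, chrom, start)
  cands[]
}
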