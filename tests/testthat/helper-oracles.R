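# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the code paths they check: combinatorial
# enumeration uses choose() directly, never dhyper/phyper/pbinom.

suppressPackageStartupMessages({
  library(data.table)
  library(GenomicRanges)
  library(Biostrings)
})

# Two-sided Fisher exact p for [[a, b], [c, d]] by full enumeration over
# all tables with the observed margins, using binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0L, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  probs <- choose(m1, xs) * choose(m2, k - xs) / choose(m1 + m2, k)
  obs <- probs[xs == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Upper binomial tail P(X >= k | n, p) by direct summation.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  xs <- k:n
  sum(choose(n, xs) * p^xs * (1 - p)^(n - xs))
}

# Upper hypergeometric tail P(X >= k) for a selection of size n from a
# background of size N containing K category members, by enumeration.
oracle_hyper_tail <- function(k, N, K, n) {
  lo <- max(0L, n - (N - K)); hi <- min(n, K)
  xs <- lo:hi
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= k])
}

# String-scan context classification of every cytosine in a sequence,
# position by position (independent of find_cytosines).
oracle_scan_contexts <- function(seq_str) {
  n <- nchar(seq_str)
  ch <- substring(seq_str, seq_len(n), seq_len(n))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  for (i in seq_len(n)) {
    if (ch[i] == "C" && i + 2 <= n) {
      tri <- ch[i:(i + 2)]
      if (all(tri %in% names(comp))) {
        ctx <- if (tri[2] == "G") "CG" else if (tri[3] == "G") "CHG" else "CHH"
        rows[[length(rows) + 1L]] <- data.table(pos = i, strand = "+",
                                                context = ctx)
      }
    }
    if (ch[i] == "G" && i - 2 >= 1) {
      tri <- comp[ch[i:(i - 2)]]
      if (!anyNA(tri)) {
        ctx <- if (tri[2] == "G") "CG" else if (tri[3] == "G") "CHG" else "CHH"
        rows[[length(rows) + 1L]] <- data.table(pos = i, strand = "-",
                                                context = ctx)
      }
    }
  }
  rbindlist(rows)
}

# Minimal cytosine record table.
make_records <- function(chrom = "chr1", pos, strand = "+", context = "CG",
                         n_meth, n_unmeth) {
  data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = context, n_meth = as.integer(n_meth),
             n_unmeth = as.integer(n_unmeth))
}

# A window row shaped like build_windows() output, for direct gate tests.
make_window <- function(chrom = "chr1", start = 1L, width = 200L,
                        context = "CG", mC_ref, u_ref, mC_test, u_test) {
  data.table(chrom = chrom, start = as.integer(start),
             end = as.integer(start + width - 1L), context = context,
             mC_ref = as.integer(mC_ref), u_ref = as.integer(u_ref),
             mC_test = as.integer(mC_test), u_test = as.integer(u_test),
             level_ref = mC_ref / (mC_ref + u_ref),
             level_test = mC_test / (mC_test + u_test))
}

# Hand-built SAM text: header plus records given as a data.frame with
# qname, flag, chrom, pos, cigar, mpos, tlen (seq/qual filled in).
make_sam <- function(records, seqlen = 100000L, chrom = "chr1",
                     read_length = 100L) {
  seq_str <- strrep("A", read_length)
  qual <- strrep("I", read_length)
  lines <- paste(records$qname, records$flag, records$chrom, records$pos,
                 60L, records$cigar, "=", records$mpos, records$tlen,
                 seq_str, qual, sep = "\t")
  c("@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", chrom, "\tLN:", seqlen),
    lines)
}

# A concordant/discordant read pair in the make_sam record format: both
# mates 100M at the given positions.
sam_pair <- function(qname, pos1, pos2, chrom = "chr1",
                     read_length = 100L) {
  span <- pos2 + read_length - pos1
  data.frame(qname = qname, flag = c(97L, 145L), chrom = chrom,
             pos = c(pos1, pos2), cigar = paste0(read_length, "M"),
             mpos = c(pos2, pos1), tlen = c(span, -span),
             stringsAsFactors = FALSE)
}

# TE annotation GRanges.
make_tes <- function(starts, ends, chrom = "chr1", ids = NULL) {
  gr <- GRanges(chrom, IRanges(starts, ends))
  mcols(gr)$id <- if (is.null(ids)) sprintf("te_%04d", seq_along(gr)) else ids
  mcols(gr)$kind <- "TE"
  mcols(gr)$parent <- NA_character_
  gr
}

# Brute-force reciprocal-best oracle: double loop over all query genes.
oracle_reciprocal_best <- function(hits_xy, hits_yx) {
  best_of <- function(h, q) {
    rows <- h[h$qseqid == q, ]
    if (!nrow(rows)) return(NA_character_)
    top <- rows[order(-rows$bitscore, -rows$pident), ]
    if (nrow(top) > 1 && top$bitscore[1] == top$bitscore[2] &&
        top$pident[1] == top$pident[2]) return(NA_character_)
    top$sseqid[1]
  }
  hits_xy <- as.data.frame(hits_xy); hits_yx <- as.data.frame(hits_yx)
  out <- list()
  for (x in unique(hits_xy$qseqid)) {
    y <- best_of(hits_xy, x)
    if (!is.na(y) && identical(best_of(hits_yx, y), x)) {
      out[[length(out) + 1L]] <- data.table(x = x, y = y)
    }
  }
  if (length(out)) setorder(rbindlist(out), x)[] else
    data.table(x = character(0), y = character(0))
}
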