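# Metagene / meta-TE methylation profiles: scaled-body windows with fixed
# flanks, pooled counts across features.

#' Metagene or meta-TE methylation profile
#'
#' Splits each feature body into `n_body` equal-width windows (default 60)
#' and each fixed-length flank into `n_flank` windows (default 20), assigns
#' every covered cytosine of the requested context to a window, and pools
#' methylated/unmethylated counts across features: each window's value is
#' `sum(mC) / sum(mC + non-mC)` over all contributing cytosines.
#' Minus-strand features are orientation-flipped before binning, so window
#' 1 is always the far 5' flank. Features shorter than `n_body` bp are
#' excluded (their windows would be sub-base).
#'
#' @param records cytosine `data.table`.
#' @param features `GRanges` with strand; typically genes or TEs.
#' @param kind `"gene"` or `"TE"`; sets the default flank (2000 bp for
#'   genes, 500 bp for TEs).
#' @param context methylation context to profile (`CG`, `CHG` or `CHH`).
#' @param flank_bp flank span in bp; overrides the `kind` default.
#' @param n_body,n_flank window counts for the body and each flank.
#' @return `data.table` with `window` (1..`n_body + 2 n_flank`), `zone`
#'   (`flank5`, `body`, `flank3`), `n_meth`, `n_total` and `level` (`NA`
#'   where no read covers the window). Attributes `n_features` and
#'   `n_excluded` count used and too-short features.
#' @export
meta_profile <- function(records, features, kind = c("gene", "TE"),
                         context = "CG", flank_bp = NULL, n_body = 60L,
                         n_flank = 20L) {
  kind <- match.arg(kind)
  if (is.null(flank_bp)) flank_bp <- if (kind == "gene") 2000L else 500L
  stopifnot(context %in% CONTEXTS, n_body >= 1L, n_flank >= 1L,
            flank_bp > 0L)
  ctx <- context
  dt <- as.data.table(records)[context == ctx]

  too_short <- width(features) < n_body
  n_excluded <- sum(too_short)
  feats <- features[!too_short]
  n_windows <- n_body + 2L * n_flank

  out <- data.table(window = seq_len(n_windows),
                    zone = rep(c("flank5", "body", "flank3"),
                               c(n_flank, n_body, n_flank)))
  if (!length(feats) || !nrow(dt)) {
    out[, `:=`(n_meth = 0L, n_total = 0L, level = NA_real_)]
    setattr(out, "n_features", length(feats))
    setattr(out, "n_excluded", n_excluded)
    return(out[])
  }

  ext <- GRanges(seqnames(feats),
                 IRanges(pmax(1L, start(feats) - flank_bp),
                         end(feats) + flank_bp))
  cyt <- GRanges(dt$chrom, IRanges(dt$pos, width = 1L))
  ov <- findOverlaps(cyt, ext, ignore.strand = TRUE)
  if (!length(ov)) {
    out[, `:=`(n_meth = 0L, n_total = 0L, level = NA_real_)]
    setattr(out, "n_features", length(feats))
    setattr(out, "n_excluded", n_excluded)
    return(out[])
  }
  qi <- queryHits(ov); si <- subjectHits(ov)
  pos <- dt$pos[qi]
  fs <- start(feats)[si]; fe <- end(feats)[si]
  fw <- fe - fs + 1L
  minus <- as.character(strand(feats))[si] == "-"
  # oriented offset from the far 5' end of the extended region
  u <- ifelse(minus, fe - pos, pos - fs) + flank_bp
  keep <- u >= 0 & u < flank_bp + fw + flank_bp  # 5' flank may be clipped at chrom start
  qi <- qi[keep]; si <- si[keep]; u <- u[keep]; fw <- fw[keep]
  fwin <- flank_bp / n_flank
  body <- u >= flank_bp & u < flank_bp + fw
  win <- integer(length(u))
  win[u < flank_bp] <- floor(u[u < flank_bp] / fwin) + 1L
  win[body] <- n_flank + floor((u[body] - flank_bp) * n_body / fw[body]) + 1L
  after <- u >= flank_bp + fw
  win[after] <- n_flank + n_body +
    floor((u[after] - flank_bp - fw[after]) / fwin) + 1L

  agg <- data.table(window = win, n_meth = dt$n_meth[qi],
                    n_total = dt$n_meth[qi] + dt$n_unmeth[qi])[
                      , .(n_meth = sum(n_meth), n_total = sum(n_total)),
                      by = window]
  out <- merge(out, agg, by = "window", all.x = TRUE, sort = TRUE)
  out[is.na(n_meth), `:=`(n_meth = 0L, n_total = 0L)]
  out[, level := ifelse(n_total > 0L, n_meth / n_total, NA_real_)]
  setattr(out, "n_features", length(feats))
  setattr(out, "n_excluded", n_excluded)
  out[]
}
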