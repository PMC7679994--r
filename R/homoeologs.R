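# Homoeologous dyad and triad identification among subgenomes from
# pairwise CDS alignment hit tables (reciprocal best hits).

BLAST_TAB_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore")

#' Read a 12-column tabular alignment file
#'
#' @param path blast-tab dialect TSV (qseqid, sseqid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' @return `data.table` with those columns.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) != 12L) stop("expected 12 columns, got ", ncol(dt))
  setnames(dt, BLAST_TAB_COLS)
  dt[]
}

#' Write a 12-column tabular alignment file
#'
#' @param hits `data.table` with the blast-tab columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  fwrite(as.data.table(hits)[, BLAST_TAB_COLS, with = FALSE], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Filter alignment hits on e-value, identity and aligned length
#'
#' Keeps a hit only when its e-value is at most `evalue_max`, its percent
#' identity strictly exceeds `identity_min`, and its aligned length
#' strictly exceeds `length_frac_min` of *both* CDS lengths. Multi-HSP
#' query-subject pairs are first reduced to their single best HSP
#' (highest bitscore).
#'
#' @param hits `data.table` with the blast-tab columns.
#' @param lens `data.table`/data.frame with `id` and `len` (CDS lengths of
#'   all query and subject genes).
#' @param evalue_max maximum e-value (default 1e-10).
#' @param identity_min identity gate in percent (default 90, strict `>`).
#' @param length_frac_min length gate as a fraction of each CDS (default
#'   0.6, strict `>`).
#' @return the surviving hits.
#' @export
filter_hits <- function(hits, lens, evalue_max = 1e-10, identity_min = 90,
                        length_frac_min = 0.6) {
  h <- as.data.table(hits)
  if (!nrow(h)) return(h)
  ln <- as.data.table(lens)
  missing_ids <- setdiff(unique(c(h$qseqid, h$sseqid)), ln$id)
  if (length(missing_ids)) {
    stop("no CDS length for: ", paste(head(missing_ids, 5L), collapse = ", "))
  }
  # single best HSP per (query, subject) pair
  h <- h[order(qseqid, sseqid, -bitscore, -pident)]
  h <- h[!duplicated(paste(qseqid, sseqid))]
  h[, qlen := ln[match(h$qseqid, id), len]]
  h[, slen := ln[match(h$sseqid, id), len]]
  out <- h[evalue <= evalue_max & pident > identity_min &
             length > length_frac_min * qlen &
             length > length_frac_min * slen]
  out[, c("qlen", "slen") := NULL]
  out[]
}

# Unique best hit per query: highest bitscore, ties broken by identity; an
# exact tie on both leaves the query without a unique best (dropped).
.best_hits <- function(hits) {
  h <- as.data.table(hits)
  if (!nrow(h)) return(data.table(qseqid = character(0),
                                  sseqid = character(0)))
  h <- h[order(qseqid, -bitscore, -pident, sseqid)]
  first <- h[!duplicated(qseqid)]
  second <- h[duplicated(qseqid)][!duplicated(qseqid)]
  tied <- second[first, on = "qseqid",
                 nomatch = NULL][bitscore == i.bitscore &
                                   pident == i.pident, qseqid]
  first[!qseqid %in% tied, .(qseqid, sseqid)]
}

#' Reciprocal best hits between two subgenomes
#'
#' A dyad is a one-to-one reciprocal pair: gene x's unique best hit is y
#' and gene y's unique best hit is x. Best means highest bitscore, ties
#' broken by percent identity; a query whose top two hits tie on both has
#' no unique best and forms no dyad.
#'
#' @param hits_xy filtered hits with subgenome X genes as queries.
#' @param hits_yx filtered hits with subgenome Y genes as queries.
#' @return `data.table` with columns `x` and `y`, sorted by `x`.
#' @export
reciprocal_best <- function(hits_xy, hits_yx) {
  bx <- .best_hits(hits_xy)
  by <- .best_hits(hits_yx)
  m <- merge(bx, by, by.x = c("qseqid", "sseqid"),
             by.y = c("sseqid", "qseqid"))
  out <- data.table(x = m$qseqid, y = m$sseqid)
  setorder(out, x)
  out[]
}

#' Build homoeolog triads from the three pairwise dyad sets
#'
#' `(a, b, d)` is a triad exactly when `(a, b)`, `(a, d)` and `(b, d)` are
#' dyads in the A-B, A-D and B-D comparisons; one-to-one dyads guarantee a
#' gene occurs in at most one triad.
#'
#' @param dyads_ab,dyads_ad,dyads_bd `data.table`s from
#'   [reciprocal_best()] (columns `x`, `y`).
#' @return `data.table` with columns `A`, `B`, `D`, sorted by `A`.
#' @export
build_triads <- function(dyads_ab, dyads_ad, dyads_bd) {
  ab <- as.data.table(dyads_ab); setnames(ab, c("A", "B"))
  ad <- as.data.table(dyads_ad); setnames(ad, c("A", "D"))
  bd <- as.data.table(dyads_bd); setnames(bd, c("B", "D"))
  tri <- merge(ab, ad, by = "A")
  tri <- merge(tri, bd, by = c("B", "D"))
  setcolorder(tri, c("A", "B", "D"))
  setorder(tri, A)
  tri[]
}

#' Identify homoeolog dyads and triads from six directed hit tables
#'
#' Applies [filter_hits()] to every table, [reciprocal_best()] to each
#' subgenome pair, and [build_triads()].
#'
#' @param hits named list with elements `AB`, `BA`, `AD`, `DA`, `BD`, `DB`
#'   (directed hit tables, as produced by [simulate_cds_hits()]).
#' @param lens CDS length table (`id`, `len`).
#' @inheritParams filter_hits
#' @return list with `dyads` (named list `AB`, `AD`, `BD`) and `triads`.
#' @export
find_homoeologs <- function(hits, lens, evalue_max = 1e-10,
                            identity_min = 90, length_frac_min = 0.6) {
  stopifnot(all(c("AB", "BA", "AD", "DA", "BD", "DB") %in% names(hits)))
  f <- lapply(hits, filter_hits, lens = lens, evalue_max = evalue_max,
              identity_min = identity_min,
              length_frac_min = length_frac_min)
  dyads <- list(AB = reciprocal_best(f$AB, f$BA),
                AD = reciprocal_best(f$AD, f$DA),
                BD = reciprocal_best(f$BD, f$DB))
  list(dyads = dyads, triads = build_triads(dyads$AB, dyads$AD, dyads$BD))
}
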