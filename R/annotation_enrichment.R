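# Assign DMRs to genomic features, TE length classes, promoters and
# homoeolog classes; generic hypergeometric enrichment.

TE_LENGTH_CLASSES <- c("0-1kb", "1-2kb", "2-4kb", "4-8kb", ">8kb")

.dmr_granges <- function(dmrs) {
  d <- as.data.table(dmrs)
  GRanges(d$chrom, IRanges(d$start, d$end))
}

# Drop seqlengths so flanks may extend past annotated chromosome ends
# without out-of-bound warnings (overlaps are unaffected).
.unbounded <- function(gr) {
  out <- gr
  seqlengths(out) <- setNames(rep(NA_integer_, length(seqlevels(out))),
                              seqlevels(out))
  out
}

#' Assign DMRs to genic feature categories
#'
#' Each DMR receives exactly one category by precedence
#' exon > intron > upstream > downstream > intergenic: overlap with an exon
#' wins; then an intron (inferred from exon gaps when absent from the
#' annotation); then the strand-aware `flank`-bp region 5' of the gene
#' start; then the matching region 3' of the gene end; everything else is
#' intergenic.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param features `GRanges` from [read_features()] (genes with exon
#'   structure).
#' @param flank upstream/downstream window in bp (default 2000).
#' @return list with `assignments` (`data.table`: dmr coordinates,
#'   `category`, `feature_id`) and `percentages` (named vector over the
#'   five categories, summing to 100 when any DMR is assigned).
#' @export
assign_dmr_features <- function(dmrs, features, flank = 2000L) {
  d <- as.data.table(dmrs)
  gr <- .dmr_granges(d)
  kind <- mcols(features)$kind
  exons <- features[kind == "exon"]
  introns <- features[kind == "intron"]
  if (!length(introns)) introns <- infer_introns(features)
  genes <- .unbounded(features[kind == "gene"])
  up <- flank(genes, width = flank, start = TRUE)      # strand-aware 5'
  down <- flank(genes, width = flank, start = FALSE)   # strand-aware 3'

  category <- rep("intergenic", nrow(d))
  feature_id <- rep(NA_character_, nrow(d))
  layers <- list(downstream = down, upstream = up, intron = introns,
                 exon = exons)
  ids <- list(downstream = mcols(genes)$id, upstream = mcols(genes)$id,
              intron = mcols(introns)$parent, exon = mcols(exons)$parent)
  # apply lowest precedence first so higher layers overwrite
  for (layer in names(layers)) {
    ov <- findOverlaps(gr, layers[[layer]], ignore.strand = TRUE)
    if (length(ov)) {
      q <- queryHits(ov)
      first <- !duplicated(q)
      category[q[first]] <- layer
      feature_id[q[first]] <- ids[[layer]][subjectHits(ov)[first]]
    }
  }
  assignments <- data.table(d[, .(chrom, start, end, context)],
                            category = category, feature_id = feature_id)
  counts <- table(factor(category, levels = c("exon", "intron", "upstream",
                                              "downstream", "intergenic")))
  pct <- if (nrow(d)) 100 * as.numeric(counts) / nrow(d) else
    rep(NA_real_, 5L)
  names(pct) <- names(counts)
  list(assignments = assignments, percentages = pct)
}

#' Tally TE-overlapping DMRs by TE length class
#'
#' A DMR overlapping an annotated TE is tallied under the length class of
#' that TE; classes are left-closed kb bins 0-1, 1-2, 2-4, 4-8 and >8 kb.
#' DMRs overlapping several TEs count once, under the first by precedence
#' of annotation order.
#'
#' @param dmrs DMR table.
#' @param tes `GRanges` of TEs with an `id` metadata column.
#' @return list with `counts` and `percentages` (of TE-overlapping DMRs)
#'   per length class, and `n_te_dmrs`.
#' @export
assign_te_classes <- function(dmrs, tes) {
  d <- as.data.table(dmrs)
  gr <- .dmr_granges(d)
  ov <- findOverlaps(gr, tes, ignore.strand = TRUE)
  first <- !duplicated(queryHits(ov))
  te_w <- width(tes)[subjectHits(ov)[first]]
  cls <- cut(te_w / 1000, breaks = c(0, 1, 2, 4, 8, Inf), right = FALSE,
             labels = TE_LENGTH_CLASSES)
  counts <- table(factor(cls, levels = TE_LENGTH_CLASSES))
  n <- sum(counts)
  pct <- if (n) 100 * as.numeric(counts) / n else rep(NA_real_, 5L)
  names(pct) <- TE_LENGTH_CLASSES
  list(counts = counts, percentages = pct, n_te_dmrs = n)
}

#' Genes with a DMR in their promoter, per context
#'
#' The promoter is the strand-aware `promoter`-bp region immediately
#' upstream of the gene start. Gene lists are deduplicated.
#'
#' @param dmrs DMR table.
#' @param genes `GRanges` of genes with an `id` metadata column.
#' @param promoter promoter length in bp (default 2000).
#' @return named list, one character vector of gene ids per context present
#'   in `dmrs`.
#' @export
promoter_dmr_genes <- function(dmrs, genes, promoter = 2000L) {
  d <- as.data.table(dmrs)
  prom <- flank(.unbounded(genes), width = promoter, start = TRUE)
  out <- lapply(split(seq_len(nrow(d)), d$context), function(idx) {
    gr <- .dmr_granges(d[idx])
    ov <- findOverlaps(gr, prom, ignore.strand = TRUE)
    sort(unique(mcols(genes)$id[subjectHits(ov)]))
  })
  out
}

#' Classify homoeolog dyads by which member carries a promoter DMR
#'
#' @param gene_list character vector of genes with a promoter DMR (one
#'   context's entry of [promoter_dmr_genes()]).
#' @param dyads `data.table`/data.frame with columns `A` and `B` (one
#'   homoeolog pair per row).
#' @return list with `classes` (`data.table`: A, B, class in
#'   `{A-only, B-only, both}` for dyads with at least one member hit) and
#'   `tallies` (named counts).
#' @export
homoeolog_dmr_classes <- function(gene_list, dyads) {
  dy <- as.data.table(dyads)
  stopifnot(all(c("A", "B") %in% names(dy)))
  a_hit <- dy$A %in% gene_list
  b_hit <- dy$B %in% gene_list
  keep <- a_hit | b_hit
  cls <- ifelse(a_hit & b_hit, "both", ifelse(a_hit, "A-only", "B-only"))
  classes <- data.table(A = dy$A[keep], B = dy$B[keep], class = cls[keep])
  tallies <- table(factor(classes$class,
                          levels = c("A-only", "B-only", "both")))
  list(classes = classes, tallies = tallies)
}

#' Hypergeometric overrepresentation test per category
#'
#' For each category, tests whether the selection contains more members of
#' the category than expected from the background: upper tail
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' background size, `K` the category's background hits, `n` the selection
#' size and `k` the category's selection hits.
#'
#' @param selection character vector of selected ids (must be a subset of
#'   `background`).
#' @param background character vector of all ids.
#' @param categories data.frame with columns `id` and `category` (an id may
#'   carry several categories).
#' @param alpha significance flag level (default 0.05, strict `<`).
#' @return `data.table` with `category`, `k`, `n`, `K`, `N`, `p_value`,
#'   `significant`.
#' @export
hypergeom_enrich <- function(selection, background, categories,
                             alpha = 0.05) {
  selection <- unique(selection)
  background <- unique(background)
  if (!all(selection %in% background)) {
    stop("selection contains ids not in background: ",
         paste(head(setdiff(selection, background), 5L), collapse = ", "))
  }
  cat_dt <- unique(as.data.table(categories)[, .(id, category)])
  cat_dt <- cat_dt[id %in% background]
  N <- length(background)
  n <- length(selection)
  res <- cat_dt[, .(K = .N, k = sum(id %in% selection)), by = category]
  # P(X >= k) = 1 - P(X <= k - 1)
  res[, `:=`(n = n, N = N,
             p_value = phyper(k - 1L, K, N - K, n, lower.tail = FALSE))]
  res[, significant := p_value < alpha]
  setcolorder(res, c("category", "k", "n", "K", "N", "p_value",
                     "significant"))
  res[]
}
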