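# Seeded generators for every input the pipeline consumes, with planted
# ground truth: multi-genotype cytosine reports over a random annotated
# genome, read pairs over TE loci with planted absence variants, and
# three-subgenome CDS hit tables with known triads.

#' Simulation configuration for [simulate_methylomes()]
#'
#' Defaults emulate the study conditions of a polyploid methylome
#' comparison: context baselines CG 0.80 / CHG 0.60 / CHH 0.04, mean
#' cytosine coverage 8.8-fold, bisulfite non-conversion 0.005 (conversion
#' rate above 99 percent). Planted DMR deltas default to 0.6/0.4/0.2 for
#' CG/CHG/CHH, comfortably above the 0.5/0.3/0.1 calling thresholds;
#' direction defaults to hypomethylation in the test genotype for CG and
#' CHG and hypermethylation for CHH (the CHH baseline is too low to lose
#' 0.2).
#'
#' @param seed RNG seed (mandatory; all outputs are deterministic in it).
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes,n_tes annotation density (totals across the genome).
#' @param te_length_range TE length range in bp (log-uniform draw).
#' @param baseline_levels named per-context mean methylation.
#' @param depth_mean mean per-cytosine read coverage (Poisson).
#' @param nonconversion_rate probability an unmethylated cytosine reads as
#'   methylated (bisulfite non-conversion).
#' @param meth_failure_rate probability a methylated cytosine reads as
#'   unmethylated (default 0).
#' @param n_planted_dmrs number of planted DMR tiles (spread over contexts
#'   in rotation).
#' @param effect_sizes named per-context |level change| planted in the test
#'   genotype.
#' @param dmr_direction named per-context direction of the planted change
#'   in the test genotype (`"hypo"` or `"hyper"`).
#' @param dmr_contexts contexts planted DMR tiles rotate over (default all
#'   three); set to a single context for single-context designs.
#' @param restored_fraction fraction of planted DMRs reverted to the
#'   reference level in the restored genotype.
#' @param window_width tile width planted DMRs are aligned to (default 200).
#' @return a validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 1L, chrom_length = 200000L,
                       n_genes = 20L, n_tes = 20L,
                       te_length_range = c(400L, 10000L),
                       baseline_levels = c(CG = 0.80, CHG = 0.60, CHH = 0.04),
                       depth_mean = 8.8, nonconversion_rate = 0.005,
                       meth_failure_rate = 0,
                       n_planted_dmrs = 30L,
                       effect_sizes = c(CG = 0.6, CHG = 0.4, CHH = 0.2),
                       dmr_direction = c(CG = "hypo", CHG = "hypo",
                                         CHH = "hyper"),
                       dmr_contexts = CONTEXTS,
                       restored_fraction = 0.5, window_width = 200L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), n_tes = as.integer(n_tes),
              te_length_range = as.integer(te_length_range),
              baseline_levels = baseline_levels, depth_mean = depth_mean,
              nonconversion_rate = nonconversion_rate,
              meth_failure_rate = meth_failure_rate,
              n_planted_dmrs = as.integer(n_planted_dmrs),
              effect_sizes = effect_sizes, dmr_direction = dmr_direction,
              dmr_contexts = dmr_contexts,
              restored_fraction = restored_fraction,
              window_width = as.integer(window_width))
  stopifnot(cfg$n_chroms >= 1L, cfg$chrom_length >= 1000L,
            all(CONTEXTS %in% names(cfg$baseline_levels)),
            all(cfg$baseline_levels >= 0), all(cfg$baseline_levels <= 1),
            cfg$depth_mean > 0,
            cfg$nonconversion_rate >= 0, cfg$nonconversion_rate <= 1,
            cfg$meth_failure_rate >= 0, cfg$meth_failure_rate <= 1,
            all(CONTEXTS %in% names(cfg$effect_sizes)),
            all(cfg$dmr_direction %in% c("hypo", "hyper")),
            all(cfg$dmr_contexts %in% CONTEXTS),
            cfg$restored_fraction >= 0, cfg$restored_fraction <= 1,
            cfg$window_width >= 50L)
  class(cfg) <- "sim_config"
  cfg
}

.random_genome <- function(n_chroms, chrom_length) {
  seqs <- vapply(seq_len(n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  out <- DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(n_chroms))
  out
}

# Place n_genes gene models (1-4 exons) and n_tes TEs in non-overlapping
# slots across the genome. Returns a GRanges with id/kind/parent mcols.
.random_features <- function(genome, n_genes, n_tes, te_length_range) {
  n_feat <- n_genes + n_tes
  if (n_feat == 0L) {
    out <- GRanges(); mcols(out)$id <- character(0)
    mcols(out)$kind <- character(0); mcols(out)$parent <- character(0)
    return(out)
  }
  lens <- setNames(width(genome), names(genome))
  total <- sum(lens)
  per_chrom <- setNames(pmax(1L, round(n_feat * lens / total)), names(lens))
  # adjust rounding drift
  while (sum(per_chrom) > n_feat) {
    i <- which.max(per_chrom); per_chrom[i] <- per_chrom[i] - 1L
  }
  while (sum(per_chrom) < n_feat) {
    i <- which.max(lens / per_chrom); per_chrom[i] <- per_chrom[i] + 1L
  }
  kinds <- sample(rep(c("gene", "TE"), c(n_genes, n_tes)))
  rows <- list(); gi <- 0L; ti <- 0L; k <- 0L
  for (ch in names(lens)) {
    n_here <- per_chrom[[ch]]
    if (n_here == 0L) next
    slot <- lens[[ch]] %/% n_here
    if (slot < 600L) stop("chromosome ", ch, " too short for ", n_here,
                          " features")
    for (j in seq_len(n_here)) {
      k <- k + 1L
      kind <- kinds[k]
      slot_start <- (j - 1L) * slot + 1L
      strand <- sample(c("+", "-"), 1L)
      if (kind == "TE") {
        ti <- ti + 1L
        w <- round(exp(runif(1, log(te_length_range[1L]),
                             log(min(te_length_range[2L], slot - 200L)))))
        s <- slot_start + sample.int(max(1L, slot - w - 100L), 1L)
        rows[[length(rows) + 1L]] <- data.table(
          chrom = ch, start = s, end = s + w - 1L, strand = strand,
          id = sprintf("te_%04d", ti), kind = "TE", parent = NA_character_)
      } else {
        gi <- gi + 1L
        gid <- sprintf("gene_%04d", gi)
        w <- sample(1200:min(3000L, slot - 300L), 1L)
        s <- slot_start + sample.int(max(1L, slot - w - 100L), 1L)
        n_ex <- sample(1:4, 1L)
        # split gene body into exons separated by introns
        cuts <- sort(sample.int(w - 2L, 2L * (n_ex - 1L))) + c(0L)
        bounds <- c(1L, cuts, w)
        ex_s <- s + bounds[seq(1L, length(bounds), by = 2L)] - 1L
        ex_e <- s + bounds[seq(2L, length(bounds), by = 2L)] - 1L
        rows[[length(rows) + 1L]] <- data.table(
          chrom = ch, start = s, end = s + w - 1L, strand = strand,
          id = gid, kind = "gene", parent = NA_character_)
        rows[[length(rows) + 1L]] <- data.table(
          chrom = ch, start = ex_s, end = ex_e, strand = strand,
          id = sprintf("%s.exon%d", gid, seq_len(n_ex)), kind = "exon",
          parent = gid)
      }
    }
  }
  dt <- rbindlist(rows)
  out <- GRanges(dt$chrom, IRanges(dt$start, dt$end), strand = dt$strand)
  mcols(out)$id <- dt$id
  mcols(out)$kind <- dt$kind
  mcols(out)$parent <- dt$parent
  seqlengths(out) <- lens[seqlevels(out)]
  out
}

#' Simulate a multi-genotype bisulfite methylome with planted DMRs
#'
#' Builds a random annotated genome, assigns every cytosine a true
#' methylation level from its context baseline, plants DMR tiles whose test
#' genotype level is shifted by the configured effect size, reverts a
#' configured fraction of them in the restored genotype, and draws observed
#' counts per genotype: depth `~ Poisson(depth_mean)`, methylated reads
#' `~ Binomial(depth, level * (1 - meth_failure_rate) +
#' nonconversion_rate * (1 - level))`.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `features` (`GRanges`),
#'   `reports` (named list of cytosine `data.table`s for genotypes `REF`,
#'   `TEST`, `RESTORED`) and `truth` (list with `planted_dmrs`:
#'   chrom/start/end/context/direction/delta/restored).
#' @export
simulate_methylomes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome <- .random_genome(config$n_chroms, config$chrom_length)
  features <- .random_features(genome, config$n_genes, config$n_tes,
                               config$te_length_range)
  cyt <- find_cytosines(genome)

  width <- config$window_width
  tiles <- rbindlist(lapply(names(genome), function(ch) {
    n_full <- config$chrom_length %/% width
    data.table(chrom = ch, start = (seq_len(n_full) - 1L) * width + 1L)
  }))
  if (config$n_planted_dmrs > nrow(tiles)) {
    stop("more planted DMRs than available tiles")
  }
  planted <- tiles[sample.int(nrow(tiles), config$n_planted_dmrs)]
  if (nrow(planted)) {
    planted[, end := start + width - 1L]
    planted[, context := rep(config$dmr_contexts, length.out = .N)]
    planted[, direction := config$dmr_direction[context]]
    sign <- ifelse(planted$direction == "hypo", -1, 1)
    base <- config$baseline_levels[planted$context]
    target <- pmin(1, pmax(0, base + sign * config$effect_sizes[planted$context]))
    planted[, delta := target - base]
    n_restored <- round(config$restored_fraction * nrow(planted))
    planted[, restored := FALSE]
    if (n_restored > 0L) {
      planted[sample.int(.N, n_restored), restored := TRUE]
    }
    setorder(planted, chrom, start)
  } else {
    planted <- data.table(chrom = character(0), start = integer(0),
                          end = integer(0), context = character(0),
                          direction = character(0), delta = numeric(0),
                          restored = logical(0))
  }

  lvl_ref <- unname(config$baseline_levels[cyt$context])
  lvl_test <- lvl_ref
  lvl_rest <- lvl_ref
  if (nrow(planted)) {
    cyt[, tile := ((pos - 1L) %/% width) * width + 1L]
    hit <- planted[cyt, on = c(chrom = "chrom", start = "tile",
                               context = "context"), which = FALSE,
                   nomatch = NA, mult = "first"]
    in_dmr <- !is.na(hit$delta)
    lvl_test[in_dmr] <- lvl_ref[in_dmr] + hit$delta[in_dmr]
    # restored genotype keeps the changed level only where the planted DMR
    # was not reverted; elsewhere it matches the reference
    keep_changed <- in_dmr & !hit$restored
    keep_changed[is.na(keep_changed)] <- FALSE
    lvl_rest[keep_changed] <- lvl_test[keep_changed]
    cyt[, tile := NULL]
  }

  draw <- function(lvl) {
    depth <- rpois(length(lvl), config$depth_mean)
    p_obs <- lvl * (1 - config$meth_failure_rate) +
      config$nonconversion_rate * (1 - lvl)
    n_meth <- rbinom(length(lvl), depth, pmin(1, pmax(0, p_obs)))
    data.table(chrom = cyt$chrom, pos = cyt$pos, strand = cyt$strand,
               context = cyt$context, n_meth = n_meth,
               n_unmeth = depth - n_meth)
  }
  reports <- list(REF = draw(lvl_ref), TEST = draw(lvl_test),
                  RESTORED = draw(lvl_rest))
  list(genome = genome, features = features, reports = reports,
       truth = list(planted_dmrs = planted))
}

#' Write features as GFF3
#'
#' @param features `GRanges` with `id`, `kind`, `parent` metadata.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path) {
  gr <- features
  type <- mcols(gr)$kind
  type[type == "TE"] <- "transposable_element"
  out <- granges(gr)
  mcols(out)$source <- "polymeth"
  mcols(out)$type <- type
  mcols(out)$ID <- mcols(gr)$id
  parent <- mcols(gr)$parent
  mcols(out)$Parent <- S4Vectors::List(lapply(parent, function(p)
    if (is.na(p)) character(0) else p))
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

.map_query_to_ref <- function(q, qstarts, ref_starts) {
  i <- findInterval(q, qstarts)
  q - qstarts[i] + ref_starts[i]
}

#' Simulate read pairs over TE loci with planted absence variants
#'
#' Emulates resequencing of a query genotype whose genome lacks some of the
#' reference-annotated TEs: fragments are drawn uniformly from the query
#' genome (the reference with absent TEs deleted) and their reads reported
#' in reference coordinates. Pairs whose mates flank a deleted TE become
#' discordant (mate separation inflated by the TE length); reads crossing a
#' deletion junction align as split reads (primary plus supplementary
#' record); TE interiors receive no coverage.
#'
#' @param genome named `DNAStringSet` (reference).
#' @param tes `GRanges` of TE annotations with an `id` metadata column;
#'   must be non-overlapping.
#' @param absent_te_ids ids of TEs absent from the query genotype.
#' @param depth target fold-coverage of the query genome.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment-length distribution; lengths are
#'   truncated at three standard deviations, as in a size-selected library.
#' @param seed RNG seed.
#' @return character vector of SAM lines (header included); write with
#'   [write_sam()].
#' @export
simulate_read_pairs <- function(genome, tes, absent_te_ids, depth = 20,
                                read_length = 100L, insert_mean = 1500,
                                insert_sd = 150, seed = 1L) {
  stopifnot(is(genome, "DNAStringSet"), is(tes, "GRanges"))
  te_ids <- mcols(tes)$id
  if (!all(absent_te_ids %in% te_ids)) {
    stop("absent_te_ids not in TE annotation: ",
         paste(setdiff(absent_te_ids, te_ids), collapse = ", "))
  }
  if (any(insert_mean >= width(genome))) {
    stop("insert size must be smaller than every chromosome")
  }
  set.seed(seed)
  rl <- as.integer(read_length)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(genome), "\tLN:", width(genome)))
  body <- list()
  frag_id <- 0L
  for (ch in names(genome)) {
    L <- width(genome)[[match(ch, names(genome))]]
    dels <- tes[as.character(seqnames(tes)) == ch &
                  te_ids %in% absent_te_ids]
    dels <- reduce(dels)
    dels <- dels[order(start(dels))]
    # reference segments remaining in the query genome
    if (length(dels)) {
      seg_s <- c(1L, end(dels) + 1L)
      seg_e <- c(start(dels) - 1L, L)
      keep <- seg_e >= seg_s
      seg_s <- seg_s[keep]; seg_e <- seg_e[keep]
    } else {
      seg_s <- 1L; seg_e <- L
    }
    seg_w <- seg_e - seg_s + 1L
    qstarts <- c(1L, cumsum(seg_w)[-length(seg_w)] + 1L)
    Lq <- sum(seg_w)

    n_frags <- round(depth * Lq / (2 * rl))
    if (n_frags == 0L) next
    lo <- max(2L * rl + 10L, round(insert_mean - 3 * insert_sd))
    hi <- round(insert_mean + 3 * insert_sd)
    fl <- pmin(hi, pmax(lo, round(rnorm(n_frags, insert_mean, insert_sd))))
    fl <- pmin(fl, Lq)
    qs <- 1L + floor(runif(n_frags) * (Lq - fl + 1))
    qe <- qs + fl - 1L

    reads <- data.table(
      frag = frag_id + rep(seq_len(n_frags), 2L),
      mate = rep(c(1L, 2L), each = n_frags),
      rs = c(qs, qe - rl + 1L))
    frag_id <- frag_id + n_frags
    reads[, re := rs + rl - 1L]
    reads[, seg1 := findInterval(rs, qstarts)]
    reads[, seg2 := findInterval(re, qstarts)]
    # drop rare fragments with a read crossing more than one junction
    bad <- reads[seg2 - seg1 > 1L, unique(frag)]
    if (length(bad)) reads <- reads[!frag %in% bad]

    reads[, ref1 := rs - qstarts[seg1] + seg_s[seg1]]
    # alignment of each read: one or two segments in reference coords
    reads[, simple := seg1 == seg2]
    simple <- reads$simple
    reads[, a_len := ifelse(simple, rl, qstarts[seg2] - rs)]
    reads[, b_len := rl - a_len]
    reads[, ref2 := ifelse(simple, NA_integer_, seg_s[seg2])]
    # primary alignment position: start of the longer part
    reads[, primary_first := simple | a_len >= b_len]
    reads[, ppos := ifelse(primary_first, ref1, ref2)]
    reads[, pend := ifelse(primary_first, ref1 + a_len - 1L,
                           ref2 + b_len - 1L)]

    # mate's primary position for RNEXT/PNEXT/TLEN
    m1 <- reads[mate == 1L, .(frag, ppos1 = ppos, pend1 = pend)]
    m2 <- reads[mate == 2L, .(frag, ppos2 = ppos, pend2 = pend)]
    mm <- merge(m1, m2, by = "frag")
    reads <- merge(reads, mm, by = "frag")   # re-sorts rows by fragment
    simple <- reads$simple
    reads[, mpos := ifelse(mate == 1L, ppos2, ppos1)]
    reads[, tlen_abs := pmax(pend1, pend2) - pmin(ppos1, ppos2) + 1L]
    reads[, tlen := ifelse(mate == 1L, tlen_abs, -tlen_abs)]
    # ifelse() promotes to double; keep coordinates integral so they never
    # format in scientific notation in the SAM text
    for (col in c("ppos", "pend", "mpos", "tlen", "tlen_abs", "ref1",
                  "ref2", "a_len", "b_len")) {
      reads[, (col) := as.integer(get(col))]
    }

    seq_str <- strrep("A", rl)
    qual_str <- strrep("I", rl)
    qn <- sprintf("frag%07d", reads$frag)
    base_flag <- ifelse(reads$mate == 1L, 97L, 145L)

    cig_primary <- ifelse(simple, paste0(rl, "M"),
                          ifelse(reads$primary_first,
                                 paste0(reads$a_len, "M", reads$b_len, "S"),
                                 paste0(reads$a_len, "S", reads$b_len, "M")))
    lines_primary <- paste(qn, base_flag, ch, reads$ppos, 60L, cig_primary,
                           "=", reads$mpos, reads$tlen, seq_str, qual_str,
                           sep = "\t")
    # supplementary records for split reads
    spl <- reads[!simple]
    lines_suppl <- character(0)
    if (nrow(spl)) {
      spos <- ifelse(spl$primary_first, spl$ref2, spl$ref1)
      cig_s <- ifelse(spl$primary_first,
                      paste0(spl$a_len, "S", spl$b_len, "M"),
                      paste0(spl$a_len, "M", spl$b_len, "S"))
      lines_suppl <- paste(sprintf("frag%07d", spl$frag),
                           ifelse(spl$mate == 1L, 97L, 145L) + 2048L,
                           ch, spos, 60L, cig_s, "=", spl$mpos,
                           ifelse(spl$mate == 1L, spl$tlen_abs,
                                  -spl$tlen_abs),
                           seq_str, qual_str, sep = "\t")
    }
    body[[length(body) + 1L]] <- c(lines_primary, lines_suppl)
  }
  c(header, unlist(body))
}

#' Write SAM lines to a file
#'
#' @param sam character vector from [simulate_read_pairs()].
#' @param path output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path) {
  writeLines(sam, path)
  invisible(path)
}

#' Simulate three-subgenome CDS alignment hit tables with known triads
#'
#' Emits reciprocal tabular alignment hits (12-column blast-tab dialect)
#' for the A-B, A-D and B-D subgenome comparisons. True triads produce
#' unique reciprocal best hits with identity above 90 percent and aligned
#' length above 60 percent of both CDSs. Decoys each violate exactly one
#' criterion: identity in (85, 90), aligned length 40-58 percent,
#' non-reciprocal best hits, or a tied one-to-many best.
#'
#' @param triad_design list with `n_triads` and optionally `decoys`, a
#'   named count vector over `c("identity", "length", "non_reciprocal",
#'   "one_to_many")`.
#' @param seed RNG seed.
#' @return list with `hits` (named list of `data.table`s `AB`, `BA`, `AD`,
#'   `DA`, `BD`, `DB`), `lens` (`data.table` of CDS lengths) and `truth`
#'   (list with `true_triads`).
#' @export
simulate_cds_hits <- function(triad_design = list(n_triads = 50L), seed = 1L) {
  set.seed(seed)
  n <- as.integer(triad_design$n_triads)
  decoys <- c(identity = 0L, length = 0L, non_reciprocal = 0L,
              one_to_many = 0L)
  if (!is.null(triad_design$decoys)) {
    stopifnot(all(names(triad_design$decoys) %in% names(decoys)))
    decoys[names(triad_design$decoys)] <- triad_design$decoys
  }
  gid <- function(sub, i) sprintf("%s%04d", sub, i)

  hit_row <- function(q, s, pident, alen, bitscore, evalue = 1e-50) {
    data.table(qseqid = q, sseqid = s, pident = pident, length = alen,
               mismatch = round(alen * (100 - pident) / 100), gapopen = 0L,
               qstart = 1L, qend = alen, sstart = 1L, send = alen,
               evalue = evalue, bitscore = bitscore)
  }

  hits <- list(AB = list(), BA = list(), AD = list(), DA = list(),
               BD = list(), DB = list())
  lens <- list()
  next_id <- setNames(rep(n, 3L), c("A", "B", "D"))

  if (n > 0L) {
    L <- sample(600:3000, n, replace = TRUE)
    for (sub in c("A", "B", "D")) {
      lens[[length(lens) + 1L]] <- data.table(id = gid(sub, seq_len(n)),
                                              len = L)
    }
    for (pair in list(c("A", "B"), c("A", "D"), c("B", "D"))) {
      alen <- round(runif(n, 0.70, 0.95) * L)
      pid <- runif(n, 92, 99.5)
      bs <- round(1.8 * alen + runif(n, 0, 10), 1)
      fwd <- hit_row(gid(pair[1L], seq_len(n)), gid(pair[2L], seq_len(n)),
                     pid, alen, bs)
      rev <- hit_row(gid(pair[2L], seq_len(n)), gid(pair[1L], seq_len(n)),
                     pid, alen, bs)
      key_f <- paste0(pair[1L], pair[2L]); key_r <- paste0(pair[2L], pair[1L])
      hits[[key_f]][[length(hits[[key_f]]) + 1L]] <- fwd
      hits[[key_r]][[length(hits[[key_r]]) + 1L]] <- rev
    }
  }

  new_gene <- function(sub, len) {
    next_id[[sub]] <<- next_id[[sub]] + 1L
    id <- gid(sub, next_id[[sub]])
    lens[[length(lens) + 1L]] <<- data.table(id = id, len = len)
    id
  }
  add_ab <- function(rows_ab, rows_ba) {
    hits$AB[[length(hits$AB) + 1L]] <<- rows_ab
    hits$BA[[length(hits$BA) + 1L]] <<- rows_ba
  }

  for (k in seq_len(decoys[["identity"]])) {
    L0 <- sample(600:3000, 1L)
    x <- new_gene("A", L0); y <- new_gene("B", L0)
    alen <- round(0.8 * L0); pid <- runif(1, 85, 89.9)
    add_ab(hit_row(x, y, pid, alen, round(1.5 * alen, 1)),
           hit_row(y, x, pid, alen, round(1.5 * alen, 1)))
  }
  for (k in seq_len(decoys[["length"]])) {
    L0 <- sample(600:3000, 1L)
    x <- new_gene("A", L0); y <- new_gene("B", L0)
    alen <- round(runif(1, 0.40, 0.58) * L0)
    add_ab(hit_row(x, y, 95, alen, round(1.8 * alen, 1)),
           hit_row(y, x, 95, alen, round(1.8 * alen, 1)))
  }
  for (k in seq_len(decoys[["non_reciprocal"]])) {
    L0 <- sample(600:3000, 1L)
    x <- new_gene("A", L0); y <- new_gene("B", L0); z <- new_gene("A", L0)
    alen <- round(0.8 * L0)
    # x's best is y, but y's best is z: x forms no dyad
    add_ab(rbindlist(list(hit_row(x, y, 95, alen, 500),
                          hit_row(z, y, 96, alen, 600))),
           rbindlist(list(hit_row(y, x, 95, alen, 500),
                          hit_row(y, z, 96, alen, 600))))
  }
  for (k in seq_len(decoys[["one_to_many"]])) {
    L0 <- sample(600:3000, 1L)
    x <- new_gene("A", L0)
    y1 <- new_gene("B", L0); y2 <- new_gene("B", L0)
    alen <- round(0.8 * L0)
    # exact tie on bitscore and identity: x has no unique best
    add_ab(rbindlist(list(hit_row(x, y1, 95, alen, 500),
                          hit_row(x, y2, 95, alen, 500))),
           rbindlist(list(hit_row(y1, x, 95, alen, 500),
                          hit_row(y2, x, 95, alen, 500))))
  }

  hits <- lapply(hits, function(h) {
    if (length(h)) rbindlist(h) else hit_row(character(0), character(0),
                                             numeric(0), integer(0),
                                             numeric(0))[0L]
  })
  truth <- list(true_triads = if (n > 0L) {
    data.table(A = gid("A", seq_len(n)), B = gid("B", seq_len(n)),
               D = gid("D", seq_len(n)))
  } else {
    data.table(A = character(0), B = character(0), D = character(0))
  })
  list(hits = hits, lens = rbindlist(lens), truth = truth)
}

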