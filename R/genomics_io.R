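# Readers/writers for the formats the pipeline touches, plus the
# SNP-substitution / region-exclusion utility.
#
# Internal conventions: intervals are GRanges (1-based, closed); cytosine
# records are data.tables with columns chrom, pos (1-based), strand (+/-),
# context (CG/CHG/CHH), n_meth, n_unmeth. Conversions to 0-based formats
# (BED) happen only at the format boundary.

CONTEXTS <- c("CG", "CHG", "CHH")

.norm_context <- function(x) {
  x <- toupper(x)
  x[x == "CPG"] <- "CG"
  x
}

#' Read a Bismark-style cytosine report
#'
#' Parses the tab-separated per-cytosine report dialect
#' (`chrom, pos, strand, count_methylated, count_unmethylated, context,
#' trinucleotide`; the trinucleotide column is optional). Positions are
#' 1-based and kept 1-based internally.
#'
#' @param path path to a TSV file.
#' @param assembly optional named `DNAStringSet`; when given, chromosome
#'   names in the file are validated against it.
#' @return a `data.table` with columns `chrom`, `pos`, `strand`, `context`
#'   (one of `CG`, `CHG`, `CHH`; the spelling `CpG` is accepted on input),
#'   `n_meth`, `n_unmeth`, ordered by `(chrom, pos)`.
#' @seealso [write_cytosine_report()]
#' @export
read_cytosine_report <- function(path, assembly = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = c(1, 3, 6)))
  if (ncol(dt) < 6L) stop("cytosine report needs >= 6 columns, got ", ncol(dt))
  dt <- dt[, 1:6]
  setnames(dt, c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context"))
  dt[, pos := as.integer(pos)]
  dt[, n_meth := as.integer(n_meth)]
  dt[, n_unmeth := as.integer(n_unmeth)]
  dt[, context := .norm_context(context)]

  bad <- which(is.na(dt$pos) | dt$pos < 1L |
                 is.na(dt$n_meth) | dt$n_meth < 0L |
                 is.na(dt$n_unmeth) | dt$n_unmeth < 0L |
                 !(dt$strand %in% c("+", "-")) |
                 !(dt$context %in% CONTEXTS))
  if (length(bad)) {
    stop("malformed cytosine report line ", bad[1L], " in ", path,
         " (negative count, bad strand, or unknown context)")
  }
  if (!is.null(assembly)) {
    unknown <- setdiff(unique(dt$chrom), names(assembly))
    if (length(unknown)) {
      stop("unknown chromosome(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  setorder(dt, chrom, pos)
  dt[]
}

#' Write a cytosine report
#'
#' Inverse of [read_cytosine_report()]; emits the 6 mandatory columns.
#'
#' @param records cytosine `data.table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  stopifnot(all(c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                  "context") %in% names(records)))
  out <- as.data.table(records)[
    , .(chrom, pos, strand, n_meth, n_unmeth, context)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Substitute SNPs into an assembly and build the exclusion mask
#'
#' Applies genotype-specific SNPs to the reference sequence so downstream
#' methylation extraction runs against the corrected genome, and merges the
#' Indel/CNV regions into a mask; cytosines falling in masked regions are
#' excluded from analysis (see [drop_masked()]).
#'
#' @param assembly named `DNAStringSet`.
#' @param variants list with `snps` (data.frame: `chrom`, `pos` 1-based,
#'   `ref`, `alt`) and `excluded_regions` (a `GRanges`, or a data.frame with
#'   `chrom`, `start`, `end` in 1-based closed coordinates). Either element
#'   may be `NULL`/empty.
#' @return list with `assembly` (corrected `DNAStringSet`) and `mask`
#'   (reduced `GRanges` of excluded regions).
#' @export
apply_variants <- function(assembly, variants) {
  stopifnot(is(assembly, "DNAStringSet"), !is.null(names(assembly)))
  snps <- variants$snps
  excl <- variants$excluded_regions

  out <- assembly
  if (!is.null(snps) && nrow(snps)) {
    snps <- as.data.table(snps)
    unknown <- setdiff(unique(snps$chrom), names(assembly))
    if (length(unknown)) stop("SNP on unknown chromosome: ",
                              paste(unknown, collapse = ", "))
    for (ch in unique(snps$chrom)) {
      s <- snps[chrom == ch]
      seq <- out[[ch]]
      have <- as.character(Views(seq, start = s$pos, width = 1L))
      mism <- which(have != toupper(s$ref))
      if (length(mism)) {
        stop("SNP ref-base mismatch at ", ch, ":",
             paste(s$pos[mism], collapse = ","),
             " (assembly has ", paste(have[mism], collapse = ","), ")")
      }
      at <- rep(FALSE, length(seq))
      at[s$pos] <- TRUE
      out[[ch]] <- replaceLetterAt(seq, at, toupper(s$alt))
    }
  }

  if (is.null(excl)) {
    mask <- GRanges()
  } else if (is(excl, "GRanges")) {
    mask <- reduce(excl)
  } else if (nrow(as.data.frame(excl))) {
    mask <- reduce(makeGRangesFromDataFrame(as.data.frame(excl)))
  } else {
    mask <- GRanges()
  }
  list(assembly = out, mask = mask)
}

#' Drop cytosine records overlapping an exclusion mask
#'
#' @param records cytosine `data.table`.
#' @param mask `GRanges` of excluded regions.
#' @return the records whose position does not fall inside `mask`.
#' @export
drop_masked <- function(records, mask) {
  if (length(mask) == 0L) return(as.data.table(records))
  gr <- GRanges(records$chrom, IRanges(records$pos, width = 1L))
  hit <- unique(queryHits(findOverlaps(gr, mask)))
  if (!length(hit)) return(as.data.table(records))
  as.data.table(records)[-hit]
}

#' Read gene/TE feature annotations from GFF3 or BED
#'
#' Uses `rtracklayer` for parsing; the result is normalized to a `GRanges`
#' with metadata columns `id`, `kind` (`gene`, `exon`, `CDS`, `TE`, ...)
#' and `parent` (parent gene id for exon/intron/CDS, `NA` otherwise).
#' For BED input `kind` is taken from a `kind=` prefix in the name column
#' (`"TE:te_0001"`), defaulting to `TE`.
#'
#' @param path a `.gff3`/`.gff` or `.bed` file.
#' @param format override format detection (`"gff3"` or `"bed"`).
#' @return `GRanges` of features.
#' @export
read_features <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    id <- as.character(mcols(gr)$ID)
    if (is.null(mcols(gr)$ID)) id <- rep(NA_character_, length(gr))
    nm <- mcols(gr)$Name
    id[is.na(id) & !is.null(nm)] <- as.character(nm)[is.na(id) & !is.null(nm)]
    parent <- rep(NA_character_, length(gr))
    if (!is.null(mcols(gr)$Parent)) {
      p <- mcols(gr)$Parent
      parent <- vapply(as.list(p), function(x)
        if (length(x)) as.character(x[[1L]]) else NA_character_, character(1))
    }
    kind <- as.character(mcols(gr)$type)
    kind[kind %in% c("transposable_element", "repeat_region", "TE")] <- "TE"
    out <- granges(gr)
    mcols(out)$id <- id
    mcols(out)$kind <- kind
    mcols(out)$parent <- parent
  } else {
    nm <- mcols(gr)$name
    if (is.null(nm)) nm <- paste0("feature_", seq_along(gr))
    kind <- rep("TE", length(gr))
    has_kind <- grepl(":", nm, fixed = TRUE)
    kind[has_kind] <- sub(":.*", "", nm[has_kind])
    id <- sub("^[^:]*:", "", nm)
    out <- granges(gr)
    mcols(out)$id <- id
    mcols(out)$kind <- kind
    mcols(out)$parent <- NA_character_
  }
  if (any(width(out) < 1L)) stop("feature with non-positive width in ", path)
  ids <- mcols(out)$id
  dup <- ids[!is.na(ids) & duplicated(ids)]
  if (length(dup)) stop("duplicate feature id(s): ",
                        paste(unique(dup), collapse = ", "))
  out
}

#' Infer introns as gaps between consecutive exons of each gene
#'
#' @param features `GRanges` as returned by [read_features()]; exons must
#'   carry a `parent` gene id.
#' @return `GRanges` of introns with `kind = "intron"` and the parent id.
#' @export
infer_introns <- function(features) {
  ex <- features[mcols(features)$kind == "exon" & !is.na(mcols(features)$parent)]
  if (!length(ex)) {
    out <- GRanges()
    mcols(out)$id <- character(0)
    mcols(out)$kind <- character(0)
    mcols(out)$parent <- character(0)
    return(out)
  }
  dt <- data.table(chrom = as.character(seqnames(ex)),
                   start = start(ex), end = end(ex),
                   strand = as.character(strand(ex)),
                   parent = mcols(ex)$parent)
  setorder(dt, parent, start)
  gaps <- dt[, {
    if (.N < 2L) {
      list(chrom = character(0), start = integer(0), end = integer(0),
           strand = character(0))
    } else {
      s <- end[-.N] + 1L
      e <- start[-1L] - 1L
      keep <- e >= s
      list(chrom = chrom[-.N][keep], start = s[keep], end = e[keep],
           strand = strand[-.N][keep])
    }
  }, by = parent]
  if (!nrow(gaps)) {
    out <- GRanges()
    mcols(out)$id <- character(0)
    mcols(out)$kind <- character(0)
    mcols(out)$parent <- character(0)
    return(out)
  }
  out <- GRanges(gaps$chrom, IRanges(gaps$start, gaps$end),
                 strand = gaps$strand)
  mcols(out)$id <- paste0(gaps$parent, ".intron", seq_len(nrow(gaps)))
  mcols(out)$kind <- "intron"
  mcols(out)$parent <- gaps$parent
  out
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr `GRanges`; the `id` metadata column (if any) becomes the name.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  nm <- mcols(gr)$id
  if (is.null(nm)) nm <- rep(".", length(gr))
  kind <- mcols(gr)$kind
  if (!is.null(kind)) nm <- paste0(kind, ":", nm)
  dt <- data.table(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = nm, score = 0L,
                   strand = ifelse(as.character(strand(gr)) == "*", ".",
                                   as.character(strand(gr))))
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Enumerate every cytosine of an assembly with its strand-local context
#'
#' Scans both strands: a `C` on the plus strand is classified from the two
#' downstream bases (`CG` if followed by G; `CHG` if C-H-G; else `CHH`,
#' H being A, C or T); a `G` on the plus strand is a minus-strand cytosine
#' classified from the reverse complement. Cytosines closer than two bases
#' to the chromosome end, or with `N` in their trinucleotide, are skipped
#' (their context is undefined).
#'
#' @param assembly named `DNAStringSet`.
#' @return `data.table` with `chrom`, `pos` (1-based, position of the C on
#'   its own strand as projected on the plus strand), `strand`, `context`.
#' @export
find_cytosines <- function(assembly) {
  stopifnot(is(assembly, "DNAStringSet"), !is.null(names(assembly)))
  res <- vector("list", length(assembly))
  for (i in seq_along(assembly)) {
    ch <- names(assembly)[i]
    s <- strsplit(as.character(assembly[[i]]), "", fixed = TRUE)[[1L]]
    L <- length(s)
    if (L < 3L) { res[[i]] <- NULL; next }

    # plus strand: C at p, look at p+1, p+2
    p <- which(s == "C")
    p <- p[p <= L - 2L]
    b1 <- s[p + 1L]; b2 <- s[p + 2L]
    ok <- b1 %in% c("A", "C", "G", "T") & b2 %in% c("A", "C", "G", "T")
    p <- p[ok]; b1 <- b1[ok]; b2 <- b2[ok]
    ctx_p <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))

    # minus strand: G at p on plus strand; reverse-complement context reads
    # p-1 (complement must be G -> plus base C) and p-2
    m <- which(s == "G")
    m <- m[m >= 3L]
    c1 <- s[m - 1L]; c2 <- s[m - 2L]
    okm <- c1 %in% c("A", "C", "G", "T") & c2 %in% c("A", "C", "G", "T")
    m <- m[okm]; c1 <- c1[okm]; c2 <- c2[okm]
    ctx_m <- ifelse(c1 == "C", "CG", ifelse(c2 == "C", "CHG", "CHH"))

    res[[i]] <- data.table(
      chrom = ch,
      pos = c(p, m),
      strand = rep(c("+", "-"), c(length(p), length(m))),
      context = c(ctx_p, ctx_m))
  }
  out <- rbindlist(res)
  if (nrow(out)) setorder(out, chrom, pos, strand)
  out[]
}
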