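# A small hand-built annotation: one + strand gene with two exons, one
# - strand gene, and a few TEs of known lengths.
make_annotation <- function() {
  dt <- data.table(
    chrom = "chr1",
    start  = c(1000L, 1000L, 1650L, 9000L, 9000L, 20000L, 30000L, 40000L),
    end    = c(2000L, 1400L, 2000L, 9800L, 9800L, 20999L, 38199L, 40499L),
    strand = c("+", "+", "+", "-", "-", "+", "+", "+"),
    id     = c("g1", "g1.e1", "g1.e2", "g2", "g2.e1", "te1", "te2", "te3"),
    kind   = c("gene", "exon", "exon", "gene", "exon", "TE", "TE", "TE"),
    parent = c(NA, "g1", "g1", NA, "g2", NA, NA, NA))
  gr <- GRanges(dt$chrom, IRanges(dt$start, dt$end), strand = dt$strand)
  mcols(gr)$id <- dt$id; mcols(gr)$kind <- dt$kind
  mcols(gr)$parent <- dt$parent
  gr
}

dmr_at <- function(starts, context = "CG") {
  data.table(chrom = "chr1", start = starts, end = starts + 199L,
             context = context)
}

test_that("DMRs are assigned one category by exon > intron > flank precedence", {
  feats <- make_annotation()
  d <- rbind(dmr_at(1001),    # overlaps exon g1.e1
             dmr_at(1401),    # inside the intron (1401..1649)
             dmr_at(401),     # 5' of + gene g1 (TSS 1000), gap < 2000
             dmr_at(2201),    # 3' of g1 within 2000
             dmr_at(9801),    # - strand gene g2: upstream is right of end
             dmr_at(50001))   # far from everything
  res <- assign_dmr_features(d, feats)
  expect_equal(res$assignments$category,
               c("exon", "intron", "upstream", "downstream", "upstream",
                 "intergenic"))
  expect_equal(sum(res$percentages), 100)
  expect_equal(res$assignments[category == "exon", feature_id], "g1")
})

test_that("feature category counts equal an interval-join recount on random DMRs", {
  feats <- make_annotation()
  set.seed(13)
  starts <- sample.int(60000L, 300L)
  d <- dmr_at(starts)
  res <- assign_dmr_features(d, feats)
  # independent recount with plain arithmetic per DMR
  exons <- feats[mcols(feats)$kind == "exon"]
  introns <- infer_introns(feats)
  genes <- feats[mcols(feats)$kind == "gene"]
  cats <- vapply(seq_len(nrow(d)), function(i) {
    s <- d$start[i]; e <- d$end[i]
    hit <- function(gr) any(start(gr) <= e & end(gr) >= s)
    up <- ifelse(as.character(strand(genes)) == "+",
                 start(genes) - 2000, end(genes) + 1)
    upe <- ifelse(as.character(strand(genes)) == "+",
                  start(genes) - 1, end(genes) + 2000)
    dn <- ifelse(as.character(strand(genes)) == "+",
                 end(genes) + 1, start(genes) - 2000)
    dne <- ifelse(as.character(strand(genes)) == "+",
                  end(genes) + 2000, start(genes) - 1)
    if (hit(exons)) "exon"
    else if (hit(introns)) "intron"
    else if (any(up <= e & upe >= s)) "upstream"
    else if (any(dn <= e & dne >= s)) "downstream"
    else "intergenic"
  }, character(1))
  expect_equal(as.vector(table(res$assignments$category)[
    sort(unique(cats))]), as.vector(table(cats)))
  # order invariance
  res2 <- assign_dmr_features(d[rev(seq_len(nrow(d)))], feats)
  expect_equal(sort(res2$assignments$start), sort(res$assignments$start))
  expect_equal(res2$percentages, res$percentages)
})

test_that("TE length classes are left-closed kb bins", {
  feats <- make_annotation()
  tes <- feats[mcols(feats)$kind == "TE"]   # widths 1000, 8200, 500
  d <- rbind(dmr_at(20001), dmr_at(30001), dmr_at(40001), dmr_at(55001))
  res <- assign_te_classes(d, tes)
  expect_equal(res$n_te_dmrs, 3L)
  expect_equal(as.vector(res$counts[c("1-2kb", ">8kb", "0-1kb")]),
               c(1L, 1L, 1L))
  expect_equal(sum(res$percentages), 100)
})

test_that("promoter gene lists are strand-aware and deduplicated", {
  feats <- make_annotation()
  genes <- feats[mcols(feats)$kind == "gene"]
  # two DMRs in g1's promoter count once; one 2100 bp upstream misses it
  d <- rbind(dmr_at(c(1, 401)), dmr_at(9801), dmr_at(101, context = "CHG"))
  # note: TSS of g1 is 1000 so [1,200] sits 800-999 bp upstream;
  # g2 is - strand with promoter 9801..11800
  pg <- promoter_dmr_genes(d, genes)
  expect_equal(pg$CG, c("g1", "g2"))
  expect_equal(pg$CHG, "g1")
  # 2100 bp past the - strand gene's promoter window: not listed
  d_far <- dmr_at(9800 + 2101)
  expect_length(promoter_dmr_genes(d_far, genes)$CG, 0L)
})

test_that("homoeolog dyads classify as A-only, B-only or both", {
  dyads <- data.table(A = sprintf("a%03d", 1:100), B = sprintf("b%03d", 1:100))
  hit <- c(dyads$A[1:50], dyads$B[1:20], dyads$B[51:60])
  res <- homoeolog_dmr_classes(hit, dyads)
  expect_equal(as.vector(res$tallies[c("both", "A-only", "B-only")]),
               c(20L, 30L, 10L))
  # dyads with neither member hit are not tallied
  expect_equal(nrow(res$classes), 60L)
})

test_that("hypergeometric enrichment equals enumeration and flags at 0.05", {
  cats <- data.frame(id = sprintf("g%02d", 1:20),
                     category = rep(c("X", "Y"), c(5, 15)))
  bg <- cats$id
  # all of X selected among 10: p = C(15,5)/C(20,10)
  sel <- c(cats$id[1:5], cats$id[6:10])
  res <- hypergeom_enrich(sel, bg, cats)
  expect_equal(res[category == "X", p_value],
               oracle_hyper_tail(5, 20, 5, 10), tolerance = 1e-12)
  expect_equal(res[category == "X", p_value],
               choose(15, 5) / choose(20, 10), tolerance = 1e-12)
  expect_true(res[category == "X", significant])

  # selection equal to the whole category universe: p = 1
  res_all <- hypergeom_enrich(bg, bg, cats)
  expect_equal(res_all$p_value, c(1, 1))

  # proportional selection is unremarkable
  sel_prop <- c(cats$id[1], cats$id[6:8])   # 1/4 of X, 1/5 of Y in 4 of 20
  res_p <- hypergeom_enrich(sel_prop, bg, cats)
  expect_false(res_p[category == "X", significant])

  expect_error(hypergeom_enrich(c("g01", "zz"), bg, cats), "background")
})

test_that("enrichment tail agrees with enumeration across random small cases", {
  set.seed(17)
  for (i in 1:40) {
    N <- sample(5:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    ids <- sprintf("id%03d", seq_len(N))
    cats <- data.frame(id = ids[seq_len(K)], category = "C")
    sel <- sample(ids, n)
    res <- hypergeom_enrich(sel, ids, cats)
    k <- sum(sel %in% ids[seq_len(K)])
    if (nrow(res)) {
      expect_equal(res$p_value, oracle_hyper_tail(k, N, K, n),
                   tolerance = 1e-12)
    }
  }
})
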