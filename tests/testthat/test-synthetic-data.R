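test_that("the methylome simulation is deterministic under its seed", {
  cfg <- sim_config(seed = 5, chrom_length = 20000L, n_genes = 3,
                    n_tes = 3, n_planted_dmrs = 5)
  a <- simulate_methylomes(cfg)
  b <- simulate_methylomes(cfg)
  expect_equal(as.character(a$genome), as.character(b$genome))
  expect_equal(as.data.frame(a$reports$TEST), as.data.frame(b$reports$TEST))
  expect_equal(as.data.frame(a$truth$planted_dmrs),
               as.data.frame(b$truth$planted_dmrs))
  c <- simulate_methylomes(sim_config(seed = 6, chrom_length = 20000L,
                                      n_genes = 3, n_tes = 3,
                                      n_planted_dmrs = 5))
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("a null design plants nothing and genotypes share the level field", {
  cfg <- sim_config(seed = 8, chrom_length = 20000L, n_planted_dmrs = 0,
                    n_genes = 2, n_tes = 2, depth_mean = 30)
  sim <- simulate_methylomes(cfg)
  expect_equal(nrow(sim$truth$planted_dmrs), 0L)
  lv <- function(r, ctx) r[context == ctx, sum(n_meth) /
                             sum(n_meth + n_unmeth)]
  for (ctx in c("CG", "CHG", "CHH")) {
    expect_equal(lv(sim$reports$REF, ctx), lv(sim$reports$TEST, ctx),
                 tolerance = 0.02)
  }
})

test_that("observed window levels converge to the planted truth at high depth", {
  cfg <- sim_config(seed = 9, chrom_length = 20000L, depth_mean = 2000,
                    n_planted_dmrs = 6, n_genes = 2, n_tes = 2,
                    nonconversion_rate = 0)
  sim <- simulate_methylomes(cfg)
  truth <- sim$truth$planted_dmrs
  w <- build_windows(sim$reports$REF, sim$reports$TEST)
  m <- merge(w, truth[, .(chrom, start, context, delta)],
             by = c("chrom", "start", "context"))
  expect_equal(nrow(m), 6L)
  base <- c(CG = 0.80, CHG = 0.60, CHH = 0.04)
  expect_true(all(abs(m$level_ref - base[m$context]) <= 0.01))
  expect_true(all(abs(m$level_test - (base[m$context] + m$delta)) <= 0.01))
  # outside planted tiles both genotypes sit at the baseline
  out <- w[!paste(chrom, start, context) %in%
             truth[, paste(chrom, start, context)]]
  expect_true(all(abs(out$level_test - base[out$context]) <= 0.02))
})

test_that("non-conversion inflates unmethylated cytosines by about epsilon", {
  cfg <- sim_config(seed = 10, chrom_length = 50000L, n_planted_dmrs = 0,
                    n_genes = 2, n_tes = 2, depth_mean = 40,
                    baseline_levels = c(CG = 0, CHG = 0, CHH = 0),
                    nonconversion_rate = 0.005)
  sim <- simulate_methylomes(cfg)
  rate <- sim$reports$REF[, sum(n_meth) / sum(n_meth + n_unmeth)]
  expect_equal(rate, 0.005, tolerance = 0.15)
})

test_that("simulated outputs round-trip through the io layer", {
  cfg <- sim_config(seed = 12, chrom_length = 20000L, n_genes = 3,
                    n_tes = 3, n_planted_dmrs = 4)
  sim <- simulate_methylomes(cfg)
  td <- tempfile(); dir.create(td)
  fa <- file.path(td, "g.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  expect_equal(as.character(Biostrings::readDNAStringSet(fa)$chr1),
               as.character(sim$genome$chr1))
  gff <- file.path(td, "f.gff3")
  write_features_gff3(sim$features, gff)
  back <- read_features(gff)
  expect_setequal(mcols(back)$id, mcols(sim$features)$id)
  g1 <- mcols(sim$features)$id[1]
  expect_equal(start(back[mcols(back)$id == g1]),
               start(sim$features[mcols(sim$features)$id == g1]))
  tsv <- file.path(td, "r.tsv")
  write_cytosine_report(sim$reports$REF, tsv)
  rr <- read_cytosine_report(tsv, assembly = sim$genome)
  expect_equal(nrow(rr), nrow(sim$reports$REF))
  # every planted truth tile lies on the window grid of its chromosome
  expect_true(all((sim$truth$planted_dmrs$start - 1L) %% 200L == 0L))
})

test_that("read-pair simulation is deterministic and honors its preconditions", {
  cfg <- sim_config(seed = 14, chrom_length = 30000L, n_tes = 6,
                    n_genes = 2)
  sim <- simulate_methylomes(cfg)
  tes <- sim$features[mcols(sim$features)$kind == "TE"]
  ids <- mcols(tes)$id
  s1 <- simulate_read_pairs(sim$genome, tes, ids[1], depth = 5, seed = 3)
  s2 <- simulate_read_pairs(sim$genome, tes, ids[1], depth = 5, seed = 3)
  expect_identical(s1, s2)
  expect_error(simulate_read_pairs(sim$genome, tes, "nope", depth = 5),
               "nope")
  expect_error(simulate_read_pairs(sim$genome, tes, ids[1], depth = 5,
                                   insert_mean = 40000), "chromosome")
})

test_that("an absent 1-kb TE leaves spanning pairs and an empty interior", {
  set.seed(33)
  # one TE of exactly 1 kb in a 60-kb chromosome
  genome <- DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 60000L, TRUE), collapse = "")))
  tes <- make_tes(starts = 30001L, ends = 31000L, ids = "te1")
  sam <- simulate_read_pairs(genome, tes, "te1", depth = 20, seed = 4)
  recs <- as.data.table(do.call(rbind, strsplit(grep("^@", sam,
                                                     invert = TRUE,
                                                     value = TRUE), "\t")))
  pos <- as.integer(recs$V4)
  cig <- recs$V6
  m <- as.integer(sub("^(\\d+)M.*", "\\1",
                      sub("^\\d+S", "", cig)))
  ends <- pos + m - 1L
  # direct pileup oracle over reference positions
  depth_at <- function(lo, hi) {
    sum(pmax(0L, pmin(ends, hi) - pmax(pos, lo) + 1L)) / (hi - lo + 1L)
  }
  expect_lt(depth_at(30001L, 31000L), 0.1 * depth_at(28001L, 30000L))
  # at least one discordant pair spans the TE
  ev <- extract_evidence(read_sam(write_sam(sam,
                                            tempfile(fileext = ".sam"))))
  spanning <- ev[start <= 30001L & end >= 31000L]
  expect_gte(nrow(spanning), 1L)
})

test_that("CDS hit simulation is deterministic and parses as blast-tab", {
  d1 <- simulate_cds_hits(list(n_triads = 10L), seed = 44)
  d2 <- simulate_cds_hits(list(n_triads = 10L), seed = 44)
  expect_equal(as.data.frame(d1$hits$AB), as.data.frame(d2$hits$AB))
  f <- tempfile(fileext = ".tsv")
  write_blast_tab(d1$hits$AB, f)
  back <- read_blast_tab(f)
  expect_equal(as.data.frame(back), as.data.frame(d1$hits$AB))
})
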