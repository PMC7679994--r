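# Config-driven orchestration of all stages with a one-command synthetic
# end-to-end demo and a machine-readable summary.

#' Build and validate a pipeline configuration
#'
#' The configuration drives [run_pipeline()]. The default runs a fully
#' synthetic demo: a methylome simulation with planted DMRs, a read-pair
#' simulation with planted TE absences, and a CDS-hit simulation with known
#' triads. A YAML file with the same structure can be given instead of
#' arguments.
#'
#' @param path optional YAML file; its entries override nothing else
#'   (mutually exclusive with the other arguments).
#' @param seed master RNG seed for every stage.
#' @param sim named list of [sim_config()] overrides.
#' @param roles genotype roles, named `reference`, `test`, `restored`
#'   (must be distinct names of the simulated reports).
#' @param dmr named list: `width`, `alpha`, `thresholds`, `min_site_reads`,
#'   `min_window_reads`, `method`.
#' @param annotation named list: `flank`, `promoter`.
#' @param bins named list: `width` (genome-bin width).
#' @param te named list: `n_absent`, `depth`, `read_length`, `insert_mean`,
#'   `insert_sd`, `min_mapq`, `min_distance`; set `n_absent = NULL` to skip
#'   the stage.
#' @param homoeologs named list: `n_triads`, `decoys`; `NULL` skips.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, seed = 1L, sim = list(),
                            roles = list(reference = "REF", test = "TEST",
                                         restored = "RESTORED"),
                            dmr = list(), annotation = list(), bins = list(),
                            te = list(), homoeologs = list()) {
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    y <- yaml::read_yaml(path)
    cfg <- pipeline_config(seed = y$seed %null% 1L,
                           sim = y$sim %null% list(),
                           roles = y$roles %null% list(reference = "REF",
                                                       test = "TEST",
                                                       restored = "RESTORED"),
                           dmr = y$dmr %null% list(),
                           annotation = y$annotation %null% list(),
                           bins = y$bins %null% list(),
                           te = y$te %null% list(),
                           homoeologs = y$homoeologs %null% list())
    return(cfg)
  }
  defaults <- list(
    dmr = list(width = 200L, alpha = 0.05,
               thresholds = DMR_DELTA_THRESHOLDS, min_site_reads = 3L,
               min_window_reads = WINDOW_MIN_READS, method = "BH"),
    annotation = list(flank = 2000L, promoter = 2000L),
    bins = list(width = 1e6L),
    te = list(n_absent = 5L, depth = 20, read_length = 100L,
              insert_mean = 1500, insert_sd = 150, min_mapq = 20L,
              min_distance = 2000L),
    homoeologs = list(n_triads = 50L, decoys = NULL))
  merge_over <- function(base, user) {
    for (nm in names(user)) base[[nm]] <- user[[nm]]
    base
  }
  cfg <- list(seed = as.integer(seed), sim = sim, roles = roles,
              dmr = merge_over(defaults$dmr, dmr),
              annotation = merge_over(defaults$annotation, annotation),
              bins = merge_over(defaults$bins, bins),
              te = merge_over(defaults$te, te),
              homoeologs = merge_over(defaults$homoeologs, homoeologs))
  with(cfg, {
    stopifnot(is.list(roles),
              all(c("reference", "test", "restored") %in% names(roles)))
    if (anyDuplicated(unlist(roles[c("reference", "test", "restored")]))) {
      stop("genotype roles must be distinct")
    }
    stopifnot(dmr$width > 0L, dmr$alpha > 0, all(dmr$thresholds > 0),
              annotation$flank > 0L, annotation$promoter > 0L,
              bins$width > 0L)
  })
  class(cfg) <- "pipeline_config"
  cfg
}

`%null%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order — simulate, per-cytosine
#' coverage filter, methylcytosine calls, genome bins, DMR scan (test vs
#' reference), restoration analysis (restored genotype), DMR-vs-DMR
#' overlap, feature/TE/promoter annotation, metagene and meta-TE profiles —
#' plus the independent TE absence-variant and homoeolog stages, writes
#' per-stage outputs and a `summary.json` to `outdir`, and returns the
#' summary. Identical config and seed give an identical summary.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @param outdir output directory (created if needed).
#' @return the summary list, invisibly; side effect: files in `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile()) {
  if (is.character(config)) config <- pipeline_config(path = config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(schema_version = "1.0",
                  seed = config$seed,
                  parameters = list(dmr = config$dmr,
                                    annotation = config$annotation,
                                    bins = config$bins))

  # --- simulate -------------------------------------------------------
  sim_args <- config$sim
  sim_args$seed <- config$seed
  scfg <- do.call(sim_config, sim_args)
  sim <- simulate_methylomes(scfg)
  roles <- config$roles
  stopifnot(all(unlist(roles) %in% names(sim$reports)))
  writeXStringSet(sim$genome, file.path(outdir, "genome.fa"))
  write_features_gff3(sim$features, file.path(outdir, "features.gff3"))
  for (g in names(sim$reports)) {
    write_cytosine_report(sim$reports[[g]],
                          file.path(outdir, paste0(g, ".cytosine.tsv")))
  }
  summary$simulation <- list(
    n_chroms = scfg$n_chroms, chrom_length = scfg$chrom_length,
    n_cytosines = nrow(sim$reports[[1L]]),
    n_planted_dmrs = nrow(sim$truth$planted_dmrs))

  # --- per-cytosine filter and methylcytosine calls -------------------
  filt <- coverage_filter(sim$reports[unlist(roles)],
                          min_reads = config$dmr$min_site_reads)
  names(filt) <- names(roles)
  mc <- call_methylcytosines(filt$test)
  summary$methylome <- list(
    n_sites_covered_all = nrow(filt$reference),
    n_methylcytosines_test = as.integer(
      sum(mc$is_methylcytosine, na.rm = TRUE)))

  seqlens <- setNames(width(sim$genome), names(sim$genome))
  gbins <- genome_bins(filt$test, seqlens, width = config$bins$width)
  fwrite(gbins, file.path(outdir, "bins_test.tsv"), sep = "\t")

  # --- DMR scan -------------------------------------------------------
  w <- build_windows(filt$reference, filt$test, width = config$dmr$width)
  w <- window_coverage_filter(w, min_reads = config$dmr$min_window_reads)
  w <- test_windows(w)
  dmrs <- call_dmrs(w, alpha = config$dmr$alpha,
                    thresholds = config$dmr$thresholds,
                    method = config$dmr$method)
  write_dmr_bed(dmrs, file.path(outdir, "dmrs.bed"))
  summary$dmr <- list(
    n_windows_tested = nrow(w),
    n_dmrs = nrow(dmrs),
    by_context = as.list(table(factor(dmrs$context, levels = CONTEXTS))),
    by_direction = as.list(table(factor(dmrs$direction,
                                        levels = c("hypo", "hyper")))))

  # truth recovery against the planted tiles
  truth <- sim$truth$planted_dmrs
  if (nrow(truth)) {
    called_keys <- dmrs[, paste(chrom, start, context)]
    true_keys <- truth[, paste(chrom, start, context)]
    tp <- sum(called_keys %in% true_keys)
    summary$dmr$truth <- list(
      sensitivity = tp / length(true_keys),
      false_discovery_proportion =
        if (nrow(dmrs)) (nrow(dmrs) - tp) / nrow(dmrs) else 0)
  }

  # --- restoration ----------------------------------------------------
  rest <- restoration_analysis(dmrs, filt$test, filt$restored,
                               width = config$dmr$width,
                               min_site_reads = config$dmr$min_site_reads,
                               min_window_reads = config$dmr$min_window_reads,
                               alpha = config$dmr$alpha,
                               thresholds = config$dmr$thresholds,
                               method = config$dmr$method)
  fwrite(rest, file.path(outdir, "restoration.tsv"), sep = "\t")
  det <- rest[!is.na(restored)]
  summary$restoration <- list(
    n_determined = nrow(det),
    n_restored = as.integer(sum(det$restored)),
    restored_fraction = if (nrow(det)) mean(det$restored) else NA_real_)

  # --- cross-comparison overlap --------------------------------------
  dmrs_rest_ref <- dmr_scan(filt$reference, filt$restored,
                            width = config$dmr$width,
                            alpha = config$dmr$alpha,
                            thresholds = config$dmr$thresholds,
                            method = config$dmr$method)
  ov <- dmr_overlap(dmrs, dmrs_rest_ref)
  summary$overlap <- list(n_dmrs_restored_vs_ref = nrow(dmrs_rest_ref),
                          frac_test_dmrs_shared = ov$frac_a)

  # --- annotation -----------------------------------------------------
  feats <- sim$features
  tes <- feats[mcols(feats)$kind == "TE"]
  genes <- feats[mcols(feats)$kind == "gene"]
  fa <- assign_dmr_features(dmrs, feats, flank = config$annotation$flank)
  fwrite(fa$assignments, file.path(outdir, "dmr_features.tsv"), sep = "\t")
  tc <- assign_te_classes(dmrs, tes)
  pg <- promoter_dmr_genes(dmrs, genes,
                           promoter = config$annotation$promoter)
  summary$annotation <- list(
    feature_percentages = as.list(fa$percentages),
    te_class_percentages = as.list(tc$percentages),
    n_promoter_genes = lapply(pg, length))

  # --- profiles -------------------------------------------------------
  profs <- list()
  for (ctx in CONTEXTS) {
    pgene <- meta_profile(filt$test, genes, kind = "gene", context = ctx)
    pte <- meta_profile(filt$test, tes, kind = "TE", context = ctx)
    pgene[, `:=`(context = ctx, kind = "gene")]
    pte[, `:=`(context = ctx, kind = "TE")]
    profs[[length(profs) + 1L]] <- pgene
    profs[[length(profs) + 1L]] <- pte
  }
  profs <- rbindlist(profs)
  fwrite(profs, file.path(outdir, "profiles.tsv"), sep = "\t")
  summary$profiles <- list(n_windows = max(profs$window))

  # --- TE absence variants -------------------------------------------
  if (!is.null(config$te$n_absent) && length(tes) > 0L) {
    n_absent <- min(config$te$n_absent, length(tes))
    set.seed(config$seed + 1L)
    absent_ids <- sample(mcols(tes)$id, n_absent)
    sam <- simulate_read_pairs(sim$genome, tes, absent_ids,
                               depth = config$te$depth,
                               read_length = config$te$read_length,
                               insert_mean = config$te$insert_mean,
                               insert_sd = config$te$insert_sd,
                               seed = config$seed + 2L)
    sam_path <- file.path(outdir, "query.sam")
    write_sam(sam, sam_path)
    calls <- call_te_absence(sam_path, tes,
                             confirm_coverage = granges(tes),
                             min_mapq = config$te$min_mapq,
                             min_distance = config$te$min_distance)
    fwrite(calls, file.path(outdir, "te_absence.tsv"), sep = "\t")
    called_ids <- calls[called == TRUE, te_id]
    summary$te_absence <- list(
      n_planted = n_absent,
      n_called = length(called_ids),
      recall = if (n_absent) mean(absent_ids %in% called_ids) else NA_real_,
      precision = if (length(called_ids))
        mean(called_ids %in% absent_ids) else NA_real_)
  }

  # --- homoeologs -----------------------------------------------------
  if (!is.null(config$homoeologs$n_triads)) {
    cds <- simulate_cds_hits(list(n_triads = config$homoeologs$n_triads,
                                  decoys = config$homoeologs$decoys),
                             seed = config$seed + 3L)
    hom <- find_homoeologs(cds$hits, cds$lens)
    fwrite(hom$triads, file.path(outdir, "triads.tsv"), sep = "\t")
    summary$homoeologs <- list(
      n_true_triads = nrow(cds$truth$true_triads),
      n_triads = nrow(hom$triads),
      n_dyads = lapply(hom$dyads, nrow))
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
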