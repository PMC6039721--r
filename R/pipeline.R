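# End-to-end orchestration: fixture generation, the full analysis pass and
# a machine-readable summary, all reproducible from one master seed.

#' Parse a flat key/value run configuration file
#'
#' One `key = value` (or `key value`) pair per line; `#` starts a comment.
#' Values are converted to numbers where possible. Unknown keys are an
#' error; omitted keys fall back to the documented defaults of
#' [default_run_config()].
#'
#' @param path config file path.
#' @return named list merged over the defaults.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- default_run_config()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z0-9_.]+)[ =\t]+(.+)$",
                                      lines[i]))[[1]]
    if (length(m) != 3)
      stopf("read_run_config: %s line %d: expected 'key = value'", path, i)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(cfg))
      stopf("read_run_config: %s line %d: unknown key '%s'", path, i, key)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Default pipeline parameters
#'
#' Every analysis stage parameter defaults to the pipeline's canonical
#' value: track bin size 1 bp, enrichment bin size 10 bp, profile bin size
#' 5 bp with a +/-1500 bp window, 5000 bootstrap iterations, effective
#' genome size 2,150,570,000 bp, fragment lengths 200 (TF ChIP) / 250
#' (PolII ChIP), promoter window -2000/+500 bp, 1-RPKM expression filter.
#' The `demo_*` keys size the synthetic dataset.
#'
#' @return named list of defaults.
#' @export
default_run_config <- function() {
  list(seed = 1,
       track_binsize = 1, enrich_binsize = 10,
       profile_binsize = 5, upstream = 1500, downstream = 1500,
       iterations = 5000, alpha = 0.05,
       effective_genome_size = EFFECTIVE_GENOME_SIZE_MM10,
       fragment_length_tf = 200, fragment_length_polii = 250,
       min_rpkm = 1, promoter_up = 2000, promoter_down = 500,
       pseudocount = 0.1,
       demo_chrom_length = 300000, demo_chroms = 2, demo_genes = 40,
       demo_peaks = 25, demo_depth = 30000, demo_replicates = 3,
       demo_enrichment = 8, demo_iterations = 200,
       demo_polii_depth_per_gene = 2000)
}

#' @noRd
config_hash <- function(cfg) {
  stable_hash(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";"))
}

#' Run the full synthetic-data demonstration pipeline
#'
#' Generates a seeded synthetic dataset (genome, genes, peaks; ChIP with
#' matched input, MNase control/treated, PolII control/treated, nascent
#' RNA), writes the fixtures as BED6/GTF/BED, reads them back through the
#' package's own I/O layer, and runs every analysis stage: RPGC coverage
#' with input subtraction, peak-set consensus/blacklist/classification,
#' bootstrap aggregate profiles with an MNase center test, the nascent
#' s.e.m. profile, and traveling-ratio tables with a condition comparison.
#' All outputs land under `outdir` together with `summary.json` (stamped
#' with the config hash and seed). Identical configs produce identical
#' outputs.
#'
#' @param config named list as from [read_run_config()] /
#'   [default_run_config()], or a path to a flat key/value config file.
#' @param outdir run directory (created if needed).
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config = default_run_config(),
                         outdir = tempfile("chromprofiler_run_")) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  defaults <- default_run_config()
  stopifnot(all(names(config) %in% names(defaults)))
  cfg <- utils::modifyList(defaults, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fixdir <- file.path(outdir, "fixtures")
  dir.create(fixdir, showWarnings = FALSE)

  chroms <- stats::setNames(rep(cfg$demo_chrom_length, cfg$demo_chroms),
                            paste0("chrS", seq_len(cfg$demo_chroms)))
  sc <- sim_config(seed = cfg$seed, chrom_lengths = chroms,
                   n_genes = cfg$demo_genes, n_peaks = cfg$demo_peaks,
                   depth = cfg$demo_depth, replicates = cfg$demo_replicates,
                   fragment_length = cfg$fragment_length_tf)

  ## --- simulate and write fixtures -----------------------------------
  gg <- make_genome_and_genes(sc)
  peaks <- make_peaks(sc)
  chip <- simulate_chip(peaks, cfg$demo_enrichment, sc)
  tssgr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gg$genes),
                                  IRanges::IRanges(tss(gg$genes), width = 1),
                                  strand = BiocGenerics::strand(gg$genes),
                                  seqinfo = gg$genome)
  nmap <- nucleosome_array_map(tssgr, n_nucs = 5, spacing = 180,
                               occupancy = 0.7, delta = 0.5)
  mn_ctrl <- simulate_mnase(nmap, "control", sc)
  mn_trt <- simulate_mnase(nmap, "treated", sc)
  ps_ctrl <- pausing_spec(gg$genes$gene_id, d_p = 9, d_b = 3)   # TR 0.75
  ps_trt <- pausing_spec(gg$genes$gene_id, d_p = 3, d_b = 3)    # TR 0.50
  pol_ctrl <- simulate_polii(gg$genes, ps_ctrl, sc,
                             depth_per_gene = cfg$demo_polii_depth_per_gene,
                             library_id = "polii_t0")
  pol_trt <- simulate_polii(gg$genes, ps_trt, sc,
                            depth_per_gene = cfg$demo_polii_depth_per_gene,
                            library_id = "polii_t1")
  nas <- simulate_nascent(gg$genes, config = sc)

  write_gene_gtf(gg$genes, file.path(fixdir, "genes.gtf"))
  write_bed(peaks, file.path(fixdir, "peaks.bed"))
  for (r in seq_along(chip$replicates))
    write_bed(chip$replicates[[r]],
              file.path(fixdir, sprintf("chip_rep%d.bed", r)))
  write_bed(chip$input, file.path(fixdir, "chip_input.bed"))

  ## --- read back through the I/O layer -------------------------------
  genome <- gg$genome
  genes <- read_gtf_genes(file.path(fixdir, "genes.gtf"), genome)
  peaks_in <- read_bed(file.path(fixdir, "peaks.bed"), genome)
  chip_reps <- lapply(seq_along(chip$replicates), function(r)
    fragment_set(read_bed(file.path(fixdir, sprintf("chip_rep%d.bed", r)),
                          genome), sprintf("chip_rep%d", r)))
  chip_input <- fragment_set(read_bed(file.path(fixdir, "chip_input.bed"),
                                      genome), "chip_input")

  ## --- coverage stage -------------------------------------------------
  egs <- genome_size(genome)  # synthetic genome: fully mappable
  rule <- extension_rule("as_is")
  chip_rpgc <- lapply(chip_reps, function(f)
    rpgc_normalize(fragments_to_coverage(f, genome, cfg$enrich_binsize,
                                         rule), egs))
  input_rpgc <- rpgc_normalize(
    fragments_to_coverage(chip_input, genome, cfg$enrich_binsize, rule), egs)
  chip_sub <- subtract_input(chip_rpgc[[1]], input_rpgc)
  write_bedgraph(chip_sub, file.path(outdir, "chip_rep1_subtracted.bedgraph"))

  ## --- peak stage ------------------------------------------------------
  # per-replicate "called" peak sets: jittered copies of the true peaks
  called <- lapply(seq_along(chip_reps), function(r) with_seed(
    stream_seed(cfg$seed, "peakcall", r), {
      keep <- stats::runif(length(peaks_in)) < 0.9
      sh <- round(stats::rnorm(sum(keep), 0, 30))
      GenomicRanges::shift(granges_clean(peaks_in)[keep], sh)
    }))
  cons <- consensus(called, min_support = 2)
  blacklist <- with_seed(stream_seed(cfg$seed, "blacklist"),
    make_peaks(sc, genome, n_peaks = 3, width = 5000))
  cons_bl <- filter_blacklist(cons, blacklist)
  counts <- count_in_intervals(chip_reps[[1]], cons_bl, chip_input)
  utils::write.table(counts, file.path(outdir, "peak_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- aggregate profiles ---------------------------------------------
  profile_for <- function(frag_sets, refs, frag_rule = rule) {
    lapply(seq_along(frag_sets), function(r) {
      tr <- rpgc_normalize(fragments_to_coverage(frag_sets[[r]], genome,
                                                 cfg$track_binsize,
                                                 frag_rule), egs)
      compute_matrix(tr, refs, mode = "tss", upstream = cfg$upstream,
                     downstream = cfg$downstream,
                     binsize = cfg$profile_binsize,
                     replicate_id = sprintf("rep%d", r))
    })
  }
  mats_ctrl <- profile_for(mn_ctrl, tssgr)
  mats_trt <- profile_for(mn_trt, tssgr)
  prof <- bootstrap_ci(mats_trt, iterations = cfg$demo_iterations,
                       alpha = cfg$alpha, seed = cfg$seed)
  write_profile_table(prof, file.path(outdir, "mnase_treated_profile.tsv"))
  ctest <- empirical_pvalue(mats_trt, mats_ctrl,
                            iterations = cfg$demo_iterations,
                            seed = cfg$seed)
  nas_mats <- profile_for(nas, tssgr)
  nas_prof <- sem_profile(nas_mats)
  write_profile_table(nas_prof, file.path(outdir, "nascent_profile.tsv"))

  ## --- traveling ratio -------------------------------------------------
  tr0 <- suppressMessages(tr_table(pol_ctrl[[1]], genes,
                                   min_rpkm = cfg$min_rpkm,
                                   promoter_up = cfg$promoter_up,
                                   promoter_down = cfg$promoter_down))
  tr1 <- suppressMessages(tr_table(pol_trt[[1]], genes,
                                   min_rpkm = cfg$min_rpkm,
                                   promoter_up = cfg$promoter_up,
                                   promoter_down = cfg$promoter_down))
  utils::write.table(tr0, file.path(outdir, "tr_t0.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tr1, file.path(outdir, "tr_t1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cmp <- compare_tr(tr1, tr0)

  summary <- list(
    config_hash = config_hash(cfg), seed = cfg$seed,
    n_genes = length(genes), n_peaks = length(peaks_in),
    n_consensus_peaks = length(cons), n_after_blacklist = length(cons_bl),
    chip_mean_subtracted_in_peaks = mean_track_in(chip_sub, peaks_in),
    chip_mean_subtracted_outside = mean_track_in(chip_sub, peaks_in,
                                                 complement = TRUE),
    mnase_center_observed = ctest$observed, mnase_center_p = ctest$p,
    mean_tr_t0 = mean(tr0$tr), mean_tr_t1 = mean(tr1$tr),
    tr_ks_statistic = cmp$statistic, tr_ks_p = cmp$p)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' @rdname run_pipeline
#' @param seed master seed for the demo run.
#' @export
run_demo <- function(outdir = tempfile("chromprofiler_demo_"), seed = 1) {
  cfg <- default_run_config()
  cfg$seed <- seed
  run_pipeline(cfg, outdir)
}

#' Mean track value inside (or outside) a set of regions
#' @noRd
mean_track_in <- function(track, regions, complement = FALSE) {
  sl <- GenomeInfoDb::seqlengths(track$genome)
  tot <- 0; nb <- 0
  for (ch in names(track$values)) {
    n <- length(track$values[[ch]])
    inpk <- rep(FALSE, n)
    sub <- regions[as.character(GenomeInfoDb::seqnames(regions)) == ch]
    for (i in seq_along(sub)) {
      b0 <- (BiocGenerics::start(sub)[i] - 1) %/% track$binsize + 1
      b1 <- min(n, (BiocGenerics::end(sub)[i] - 1) %/% track$binsize + 1)
      inpk[b0:b1] <- TRUE
    }
    sel <- if (complement) !inpk else inpk
    tot <- tot + sum(track$values[[ch]][sel])
    nb <- nb + sum(sel)
  }
  if (nb == 0) return(NA_real_)
  tot / nb
}

#' Write gene models as a minimal Ensembl-dialect GTF
#'
#' One `gene` record per gene with a `gene_id` attribute (1-based closed
#' coordinates, as GTF requires).
#' @param genes gene models.
#' @param path output path.
#' @export
write_gene_gtf <- function(genes, path) {
  lines <- sprintf(
    "%s\tchromprofiler\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    as.character(GenomeInfoDb::seqnames(genes)),
    BiocGenerics::start(genes), BiocGenerics::end(genes),
    as.character(BiocGenerics::strand(genes)), genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}
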