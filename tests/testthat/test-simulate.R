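test_that("the generator is fully deterministic under a fixed seed", {
  sc <- sim_config(seed = 7, chrom_lengths = c(c1 = 3e5), n_genes = 15,
                   n_peaks = 10, depth = 5000, replicates = 2)
  g1 <- make_genome_and_genes(sc); g2 <- make_genome_and_genes(sc)
  expect_identical(as.data.frame(g1$genes), as.data.frame(g2$genes))
  p1 <- make_peaks(sc); p2 <- make_peaks(sc)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  c1 <- simulate_chip(p1, 5, sc); c2 <- simulate_chip(p2, 5, sc)
  expect_identical(as.data.frame(c1$replicates[[1]]),
                   as.data.frame(c2$replicates[[1]]))
  expect_identical(as.data.frame(c1$input), as.data.frame(c2$input))
  # ... and written fixtures are byte-identical
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(c1$replicates[[2]], f1); write_bed(c2$replicates[[2]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("rng streams are independent across libraries", {
  sc <- sim_config(seed = 7, chrom_lengths = c(c1 = 3e5), n_peaks = 5,
                   depth = 2000, replicates = 1)
  p <- make_peaks(sc)
  a <- simulate_chip(p, 5, sc, library_id = "libA")
  # generating another library in between must not change libA
  invisible(simulate_chip(p, 2, sc, library_id = "libB"))
  a2 <- simulate_chip(p, 5, sc, library_id = "libA")
  expect_identical(as.data.frame(a$replicates[[1]]),
                   as.data.frame(a2$replicates[[1]]))
})

test_that("gene placement yields disjoint genes within the genome", {
  sc <- sim_config(seed = 3, chrom_lengths = c(c1 = 2e6), n_genes = 50)
  gg <- make_genome_and_genes(sc)
  expect_length(gg$genes, 50)
  df <- as.data.frame(gg$genes)
  # brute-force pairwise overlap check
  for (i in seq_len(nrow(df) - 1))
    expect_true(df$start[i + 1] > df$end[i])
  expect_true(all(df$end <= 2e6) && all(df$start >= 1))
  expect_true(all(df$width >= 3000))

  empty <- make_genome_and_genes(sim_config(seed = 3, n_genes = 0))
  expect_length(empty$genes, 0)
  expect_error(make_genome_and_genes(
    sim_config(seed = 3, chrom_lengths = c(c1 = 5e4), n_genes = 20)),
    "too small")
})

test_that("chip enrichment=1 is indistinguishable from input", {
  sc <- sim_config(seed = 11, chrom_lengths = c(c1 = 1e6), n_peaks = 20,
                   depth = 1e4, replicates = 1, dispersion = 0)
  peaks <- make_peaks(sc)
  sim <- simulate_chip(peaks, enrichment = 1, sc)
  pos_chip <- start(fragment_midpoints(sim$replicates[[1]]))
  pos_inp <- start(fragment_midpoints(sim$input))
  ks <- suppressWarnings(stats::ks.test(pos_chip, pos_inp))
  expect_gt(ks$p.value, 0.01)
})

test_that("chip enrichment concentrates coverage in peaks", {
  sc <- sim_config(seed = 13, chrom_lengths = c(c1 = 1e6), n_peaks = 20,
                   depth = 1e5, replicates = 1)
  gm <- genome_model(sc$chrom_lengths)
  peaks <- make_peaks(sc)
  sim <- simulate_chip(peaks, enrichment = 10, sc)
  mids <- fragment_midpoints(sim$replicates[[1]])
  n_in <- sum(overlapsAny(mids, peaks, ignore.strand = TRUE))
  Lpk <- sum(width(peaks)); G <- genome_size(gm)
  dens_in <- n_in / Lpk
  dens_out <- (length(mids) - n_in) / (G - Lpk)
  expect_gt(dens_in / dens_out, 3)
  expect_error(simulate_chip(peaks, 0.5, sc), ">= 1")
  zero <- simulate_chip(peaks, 2, sim_config(seed = 13, depth = 0,
                                             replicates = 1))
  expect_equal(library_size(zero$replicates[[1]]), 0L)
})

test_that("mnase fragments are ~147 bp and centered on dyads", {
  sc <- sim_config(seed = 21, chrom_lengths = c(c1 = 5e5), depth = 1e4,
                   replicates = 1, mnase_background = 0)
  map <- nucleosome_map("c1", dyad = seq(5000, 495000, by = 5000),
                        occupancy = 0.8)
  fr <- simulate_mnase(map, "control", sc)[[1]]
  expect_gt(length(fr), 5000)
  expect_lt(abs(mean(width(fr)) - 147), 2)
  # midpoints cluster at dyads
  d <- abs(start(fragment_midpoints(fr)) - map$dyad[
    findInterval(start(fragment_midpoints(fr)), map$dyad - 2500) ])
  expect_lt(median(d), 50)
})

test_that("mnase occupancy delta raises dyad-local density when treated", {
  sc <- sim_config(seed = 22, chrom_lengths = c(c1 = 5e5), depth = 2e4)
  map <- nucleosome_map("c1", dyad = seq(10000, 490000, by = 10000),
                        occupancy = 0.6, delta = 0.5)
  ctrl <- simulate_mnase(map, "control", sc)
  trt <- simulate_mnase(map, "treated", sc)
  near <- GRanges("c1", IRanges(map$dyad - 60, map$dyad + 60))
  frac_near <- function(fs) {
    m <- fragment_midpoints(fs)
    sum(overlapsAny(m, near)) / length(m)
  }
  for (r in 1:3)
    expect_gt(frac_near(trt[[r]]), frac_near(ctrl[[r]]))
})

test_that("mnase rejects unknown conditions and degenerate maps are empty", {
  sc <- sim_config(seed = 23, chrom_lengths = c(c1 = 1e5), depth = 1000,
                   replicates = 1, mnase_background = 0)
  map <- nucleosome_map("c1", dyad = c(1000, 2000), occupancy = 0)
  expect_error(simulate_mnase(map, "induced", sc))
  expect_equal(library_size(simulate_mnase(map, "control", sc)[[1]]), 0L)
  expect_error(nucleosome_map("c1", dyad = c(100, 200), occupancy = 0.5),
               "147")
  expect_error(nucleosome_map("c1", 100, occupancy = 1.2), "\\[0, 1\\]")
})

test_that("polii fragments split promoter/body by density ratio", {
  sc <- sim_config(seed = 31, chrom_lengths = c(c1 = 1e6), n_genes = 5,
                   replicates = 1, dispersion = 0)
  gg <- make_genome_and_genes(sc)
  spec_all_prom <- pausing_spec(gg$genes$gene_id, d_p = 4, d_b = 0)
  fr <- simulate_polii(gg$genes, spec_all_prom, sc, depth_per_gene = 500)[[1]]
  win <- gene_windows(gg$genes)
  mids <- fragment_midpoints(fr)
  expect_equal(sum(countOverlaps(win$body, mids, ignore.strand = TRUE)), 0)
  expect_equal(sum(countOverlaps(win$promoter, mids, ignore.strand = TRUE)),
               length(fr))
  # missing gene in the spec is an error
  expect_error(simulate_polii(gg$genes,
                              pausing_spec("nope", 1, 1), sc), "no pausing")
})

test_that("equal promoter/body densities give uniform polii coverage", {
  sc <- sim_config(seed = 32, chrom_lengths = c(c1 = 1e6), n_genes = 1,
                   replicates = 1, dispersion = 0,
                   gene_length_range = c(8000, 8000))
  gg <- make_genome_and_genes(sc)
  fr <- simulate_polii(gg$genes, pausing_spec(gg$genes$gene_id, 2, 2), sc,
                       depth_per_gene = 1e4)[[1]]
  win <- gene_windows(gg$genes)
  lo <- min(start(win$promoter), start(win$body))
  hi <- max(end(win$promoter), end(win$body))
  mids <- start(fragment_midpoints(fr))
  cs <- cut(mids, breaks = seq(lo, hi, length.out = 11))
  cont <- table(cs)
  expect_gt(stats::chisq.test(cont)$p.value, 0.01)
})

test_that("nascent reads are stranded and 5'-weighted", {
  sc <- sim_config(seed = 41, chrom_lengths = c(c1 = 1e6), n_genes = 10,
                   replicates = 1, dispersion = 0)
  gg <- make_genome_and_genes(sc)
  fr <- simulate_nascent(gg$genes, config = sc)[[1]]
  # every read carries its gene's strand
  ov <- findOverlaps(fr, gg$genes, ignore.strand = TRUE)
  expect_true(all(as.character(strand(fr))[queryHits(ov)] ==
                    as.character(strand(gg$genes))[subjectHits(ov)]))
  # mean distance from TSS grows as the 5' excess weight shrinks
  mean_dist <- function(w) {
    f <- simulate_nascent(gg$genes, config = sc, five_prime_weight = w,
                          library_id = paste0("nas", w))[[1]]
    ovf <- findOverlaps(f, gg$genes, ignore.strand = TRUE)
    g <- subjectHits(ovf)
    p5 <- ifelse(as.character(strand(f))[queryHits(ovf)] == "-",
                 end(f)[queryHits(ovf)], start(f)[queryHits(ovf)])
    mean(abs(p5 - tss(gg$genes)[g]))
  }
  d <- vapply(c(0.9, 0.5, 0), mean_dist, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("zero 5' excess gives positions uniform along the gene", {
  sc <- sim_config(seed = 42, chrom_lengths = c(c1 = 1e6), n_genes = 1,
                   replicates = 1, dispersion = 0,
                   gene_length_range = c(9000, 9000))
  gg <- make_genome_and_genes(sc)
  fr <- simulate_nascent(gg$genes, config = sc, five_prime_weight = 0,
                         depth_per_gene = 5000)[[1]]
  p5 <- ifelse(as.character(strand(fr)) == "-", end(fr), start(fr))
  x <- abs(p5 - tss(gg$genes)[1])
  cont <- table(cut(x, breaks = seq(0, 9000, length.out = 10)))
  expect_gt(stats::chisq.test(cont)$p.value, 0.01)
})
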