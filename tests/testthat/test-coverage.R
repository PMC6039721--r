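make_track <- function(values, binsize = 10, len = length(values) * binsize,
                       provenance = "raw")
  coverage_track(list(c1 = values), binsize, genome_model(c(c1 = len)),
                 provenance)

test_that("fragment extension follows the 5' end in strand direction", {
  gm <- genome_model(c(c1 = 1000))
  # 0-based [100,150) = 1-based 101..150; extend_to 200 -> 0-based [100,300)
  fr <- fragment_set(GRanges("c1", IRanges(101, 150), strand = "+"), "l", gm)
  tr <- fragments_to_coverage(fr, gm, 10, extension_rule("extend_to", 200))
  expect_equal(tr$values$c1[1], 0)                 # bin [0,10) untouched
  expect_equal(tr$values$c1[11:30], rep(1, 20))    # [100,300) covered
  expect_equal(tr$values$c1[31], 0)
  # minus-strand fragment extends leftward from its 3'-most base
  fm <- fragment_set(GRanges("c1", IRanges(401, 450), strand = "-"), "l", gm)
  trm <- fragments_to_coverage(fm, gm, 10, extension_rule("extend_to", 200))
  expect_equal(trm$values$c1[26:45], rep(1, 20))   # 0-based [250,450)
})

test_that("bin values are mean per-base coverage (half-overlap case)", {
  gm <- genome_model(c(c1 = 200))
  # 0-based [95,105): half in bin [90,100), half in [100,110)
  fr <- fragment_set(GRanges("c1", IRanges(96, 105), strand = "+"), "l", gm)
  tr <- fragments_to_coverage(fr, gm, 10)
  expect_equal(tr$values$c1[10], 0.5)
  expect_equal(tr$values$c1[11], 0.5)
  expect_equal(sum(unlist(tr$values)) * 10, 10)  # total base coverage
})

test_that("binned coverage matches the per-base oracle for all rules", {
  for (trial in 1:12) {
    withr::local_seed(100 + trial)
    gm <- tiny_genome(4000 + sample(500, 1))
    frags <- random_fragments(80, gm)
    binsize <- sample(c(1, 7, 10), 1)
    len <- GenomeInfoDb::seqlengths(gm)[["c1"]]
    for (mode in c("as_is", "extend_to", "center_at")) {
      L <- if (mode == "as_is") NULL else 150
      rule <- if (mode == "as_is") extension_rule("as_is")
              else extension_rule(mode, L)
      tr <- fragments_to_coverage(frags, gm, binsize, rule)
      expect_equal(tr$values$c1, oracle_coverage(frags, len, binsize, mode, L))
    }
  }
})

test_that("coverage is strand-symmetric under genome reflection", {
  withr::local_seed(42)
  gm <- tiny_genome(5000)
  len <- 5000
  frags <- random_fragments(100, gm)
  refl <- GRanges("c1", IRanges(len - end(frags) + 1, len - start(frags) + 1),
                  strand = ifelse(as.character(strand(frags)) == "+", "-", "+"))
  GenomeInfoDb::seqinfo(refl) <- gm
  rule <- extension_rule("extend_to", 120)
  a <- fragments_to_coverage(frags, gm, 1, rule)$values$c1
  b <- fragments_to_coverage(refl, gm, 1, rule)$values$c1
  expect_equal(b, rev(a))
})

test_that("coverage rejects fragments on unknown chromosomes", {
  gm <- genome_model(c(c1 = 1000))
  fr <- GRanges("cX", IRanges(1, 100), strand = "+")
  expect_error(fragments_to_coverage(fr, gm, 10), "unknown chromosome")
})

test_that("RPGC scales a uniform track to 1x", {
  tr <- make_track(rep(4, 10))
  out <- rpgc_normalize(tr, 100)  # effective size = genome length
  expect_equal(out$values$c1, rep(1, 10))
  expect_equal(out$provenance, "rpgc")
})

test_that("RPGC conserves total coverage at the effective genome size", {
  withr::local_seed(5)
  tr <- make_track(runif(50, 0, 7))
  out <- rpgc_normalize(tr, 500)
  expect_equal(track_total_coverage(out), 500, tolerance = 1e-9)
  # mean bin value is 1 when effective size equals genome length
  expect_equal(mean(out$values$c1), 1, tolerance = 1e-9)
})

test_that("RPGC rejects zero tracks and non-raw provenance", {
  expect_error(rpgc_normalize(make_track(numeric(10)), 100), "zero total")
  r <- rpgc_normalize(make_track(rep(1, 10)), 100)
  expect_error(rpgc_normalize(r, 100), "raw")
})

test_that("input subtraction is bin-wise and keeps negatives", {
  chip <- rpgc_normalize(make_track(rep(4, 10)), 100)
  same <- rpgc_normalize(make_track(rep(2, 10)), 100)
  out <- subtract_input(chip, same)
  expect_equal(out$values$c1, rep(0, 10))  # both normalize to 1x
  expect_equal(out$provenance, "input_subtracted")

  chip2 <- coverage_track(list(c1 = rep(2, 10)), 10,
                          genome_model(c(c1 = 100)), "rpgc")
  inp2 <- coverage_track(list(c1 = c(rep(0.5, 5), rep(3, 5))), 10,
                         genome_model(c(c1 = 100)), "rpgc")
  out2 <- subtract_input(chip2, inp2)
  expect_equal(out2$values$c1, c(rep(1.5, 5), rep(-1, 5)))
})

test_that("track arithmetic rejects mismatched geometry and provenance", {
  a <- rpgc_normalize(make_track(rep(1, 10)), 100)
  b <- rpgc_normalize(make_track(rep(1, 20), binsize = 5), 100)
  expect_error(subtract_input(a, b), "bin sizes differ")
  expect_error(subtract_input(make_track(rep(1, 10)), a), "rpgc")
  expect_error(ratio_normalize(a, a, pseudocount = 0), "> 0")
})

test_that("ratio normalization applies the pseudocount formula", {
  gm <- genome_model(c(c1 = 100))
  num <- coverage_track(list(c1 = rep(3, 10)), 10, gm, "rpgc")
  den <- coverage_track(list(c1 = rep(1, 10)), 10, gm, "rpgc")
  expect_equal(ratio_normalize(num, den, 1)$values$c1, rep(2, 10))
  expect_equal(ratio_normalize(num, num, 0.1)$values$c1, rep(1, 10))
})

test_that("track ratio is monotone in the numerator", {
  withr::local_seed(8)
  gm <- genome_model(c(c1 = 500))
  den <- coverage_track(list(c1 = runif(50, 0, 5)), 10, gm, "rpgc")
  v <- runif(50, 0, 5)
  lo <- coverage_track(list(c1 = v), 10, gm, "rpgc")
  hi <- coverage_track(list(c1 = v + runif(50, 0.1, 2)), 10, gm, "rpgc")
  expect_true(all(ratio_normalize(hi, den)$values$c1 >
                    ratio_normalize(lo, den)$values$c1))
})

test_that("subtracted ChIP signal is enriched in peaks for simulated data", {
  sc <- sim_config(seed = 33, chrom_lengths = c(c1 = 2e5), n_peaks = 10,
                   depth = 3e4, replicates = 1)
  gm <- genome_model(sc$chrom_lengths)
  peaks <- make_peaks(sc, gm)
  sim <- simulate_chip(peaks, enrichment = 5, sc)
  egs <- genome_size(gm)
  chip <- rpgc_normalize(fragments_to_coverage(sim$replicates[[1]], gm, 10),
                         egs)
  inp <- rpgc_normalize(fragments_to_coverage(sim$input, gm, 10), egs)
  sub <- subtract_input(chip, inp)
  inbin <- logical(length(sub$values$c1))
  for (i in seq_along(peaks)) {
    b0 <- (start(peaks)[i] - 1) %/% 10 + 1
    b1 <- (end(peaks)[i] - 1) %/% 10 + 1
    inbin[b0:b1] <- TRUE
  }
  expect_gt(mean(sub$values$c1[inbin]), mean(sub$values$c1[!inbin]))
})
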