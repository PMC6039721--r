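const_track <- function(value, len = 20000, binsize = 1)
  coverage_track(list(c1 = rep(value, ceiling(len / binsize))), binsize,
                 genome_model(c(c1 = len)))

point_refs <- function(pos1, strand = "+", len = 20000) {
  gr <- GRanges("c1", IRanges(pos1, width = 1), strand = strand)
  GenomeInfoDb::seqinfo(gr) <- genome_model(c(c1 = len))
  gr
}

pm <- function(values, binsize = 5) {
  up <- ncol(values) * binsize / 2
  structure(list(values = values, binsize = as.integer(binsize),
                 upstream = as.integer(up), downstream = as.integer(up),
                 replicate_id = "r"), class = "ProfileMatrix")
}

test_that("compute_matrix reproduces simple geometries", {
  tr <- const_track(3)
  m <- compute_matrix(tr, point_refs(10000), mode = "tss")
  expect_equal(dim(m$values), c(1, 600))
  expect_true(all(m$values == 3))

  # step track: 0 below 0-based 5000, 1 at and above
  step <- coverage_track(list(c1 = c(rep(0, 5000), rep(1, 15000))), 1,
                         genome_model(c(c1 = 20000)))
  row <- compute_matrix(step, point_refs(5001), mode = "tss")$values[1, ]
  expect_equal(row, c(rep(0, 300), rep(1, 300)))  # step at the center bin
})

test_that("minus-strand rows equal reversed rows of the mirror track", {
  withr::local_seed(61)
  len <- 20000
  v <- runif(len)
  fwd <- coverage_track(list(c1 = v), 1, genome_model(c(c1 = len)))
  rev_tr <- coverage_track(list(c1 = rev(v)), 1, genome_model(c(c1 = len)))
  p <- 7537
  plus_row <- compute_matrix(fwd, point_refs(p), mode = "tss")$values[1, ]
  minus_row <- compute_matrix(rev_tr, point_refs(len - p + 1, "-"),
                              mode = "tss")$values[1, ]
  expect_equal(minus_row, plus_row)
})

test_that("compute_matrix matches the per-base oracle with edge effects", {
  for (trial in 1:10) {
    withr::local_seed(800 + trial)
    len <- 3000
    v <- round(runif(len, 0, 9), 3)
    tr <- coverage_track(list(c1 = v), 1, genome_model(c(c1 = len)))
    # references near the chromosome edges exercise missing-data-as-zero
    refs <- data.frame(point0 = sample(0:(len - 1), 8),
                       strand = sample(c("+", "-"), 8, replace = TRUE))
    gr <- GRanges("c1", IRanges(refs$point0 + 1, width = 1),
                  strand = refs$strand)
    GenomeInfoDb::seqinfo(gr) <- genome_model(c(c1 = len))
    m <- compute_matrix(tr, gr, mode = "tss", upstream = 300,
                        downstream = 300, binsize = 5)
    expect_equal(m$values, oracle_matrix(v, len, refs, 300, 300, 5))
  }
})

test_that("compute_matrix validates inputs", {
  tr <- const_track(1)
  expect_error(compute_matrix(tr, GRanges("cX", IRanges(1, 1))), "unknown")
  expect_error(compute_matrix(tr, point_refs(100), binsize = 7),
               "multiple of binsize")
  tr10 <- coverage_track(list(c1 = rep(1, 2000)), 10,
                         genome_model(c(c1 = 20000)))
  expect_error(compute_matrix(tr10, point_refs(100), binsize = 5),
               "multiple of the track binsize")
})

test_that("row-wise normalization divides by the row mean and drops zeros", {
  m <- pm(rbind(c(2, 4, 6), c(0, 0, 0)), binsize = 2)
  expect_message(out <- rowwise_normalize(m), "dropped 1")
  expect_equal(out$values, matrix(c(0.5, 1, 1.5), nrow = 1))
  expect_equal(attr(out, "dropped"), 1)
  expect_error(rowwise_normalize(pm(matrix(0, 2, 4), 2)), "all locations")

  withr::local_seed(3)
  big <- pm(matrix(rexp(600), 10, 60))
  expect_equal(unname(rowMeans(rowwise_normalize(big)$values)), rep(1, 10))
})

test_that("baseline normalization anchors the flanks at 1", {
  expect_equal(baseline_normalize(rep(4, 600)), rep(1, 600))
  prof <- c(rep(2, 10), rep(6, 580), rep(2, 10))
  out <- baseline_normalize(prof)
  expect_equal(out[300], 3)
  withr::local_seed(4)
  r <- runif(600, 1, 5)
  out2 <- baseline_normalize(r)
  expect_equal(mean(out2[c(1:10, 591:600)]), 1, tolerance = 1e-12)
  expect_error(baseline_normalize(c(rep(0, 10), rep(1, 580), rep(0, 10))),
               "flank mean is zero")
})

test_that("replicate aggregation averages and applies one shared baseline", {
  m <- pm(matrix(c(1, 2, 3, 2, 4, 6), 2, 3, byrow = TRUE), binsize = 2)
  same <- aggregate_replicates(list(m, m, m), normalized = FALSE)
  expect_equal(same$mean, colMeans(m$values))
  consts <- lapply(c(1, 2, 6), function(c_) pm(matrix(c_, 4, 6), 2))
  expect_equal(aggregate_replicates(consts, normalized = FALSE)$mean,
               rep(3, 6))
  expect_equal(aggregate_replicates(consts, normalized = TRUE,
                                    flank_width = 2)$mean, rep(1, 6))
  expect_error(aggregate_replicates(list(m, pm(matrix(1, 2, 4), 2))),
               "mismatched geometry")
})

test_that("bootstrap CIs collapse under zero variance and are reproducible", {
  m <- pm(matrix(5, 30, 6), 2)
  out <- bootstrap_ci(list(m, m), iterations = 50, seed = 9,
                      normalized = FALSE)
  expect_equal(out$ci_low, out$mean)
  expect_equal(out$ci_high, out$mean)

  withr::local_seed(10)
  ms <- lapply(1:3, function(r) pm(matrix(rnorm(300, 10), 50, 6), 2))
  a <- bootstrap_ci(ms, iterations = 200, seed = 4, normalized = FALSE)
  b <- bootstrap_ci(ms, iterations = 200, seed = 4, normalized = FALSE)
  expect_identical(a$ci_low, b$ci_low)
  expect_true(all(a$ci_low <= a$mean & a$mean <= a$ci_high))
})

test_that("the normalized pipeline is invariant to global track scaling", {
  withr::local_seed(12)
  ms <- lapply(1:3, function(r) pm(matrix(rexp(1200, 1 / 10), 20, 60)))
  scaled <- lapply(ms, function(m) { m$values <- m$values * 37.5; m })
  a <- bootstrap_ci(ms, iterations = 100, seed = 2)
  b <- bootstrap_ci(scaled, iterations = 100, seed = 2)
  expect_equal(a$mean, b$mean)
  expect_equal(a$ci_low, b$ci_low)
  expect_equal(a$ci_high, b$ci_high)
})

test_that("bootstrap CI width shrinks like 1/sqrt(locations)", {
  withr::local_seed(13)
  width_at <- function(n) {
    ms <- lapply(1:3, function(r) pm(matrix(rnorm(n * 8, 20, 4), n, 8), 2))
    out <- bootstrap_ci(ms, iterations = 400, seed = 5, normalized = FALSE)
    mean(out$ci_high - out$ci_low)
  }
  ratio <- width_at(50) / width_at(200)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})

test_that("empirical p-values are smoothed, two-sided and bounded below", {
  m <- pm(matrix(5, 30, 6), 2)
  out <- empirical_pvalue(list(m, m), list(m, m), iterations = 99,
                          seed = 1, normalized = FALSE)
  expect_equal(out$p, 1)
  expect_equal(out$observed, 0)
  withr::local_seed(14)
  a <- lapply(1:3, function(r) pm(matrix(rnorm(240, 30, 1), 40, 6), 2))
  b <- lapply(1:3, function(r) pm(matrix(rnorm(240, 10, 1), 40, 6), 2))
  strong <- empirical_pvalue(a, b, iterations = 199, seed = 1,
                             normalized = FALSE)
  expect_equal(strong$p, 2 / 200)  # add-one smoothing floor, two-sided
  expect_gte(strong$p, 1 / 200)
})

test_that("sem profiles implement mean +/- 1.96 s.e.m. without normalization", {
  m1 <- pm(matrix(1, 10, 4), 2); m3 <- pm(matrix(3, 10, 4), 2)
  out <- sem_profile(list(m1, m3))
  expect_equal(out$mean, rep(2, 4))
  expect_equal(out$ci_high - out$mean, rep(1.96, 4))  # two-point sem = 1
  expect_equal(sem_profile(list(m1, m1))$ci_low, rep(1, 4))  # zero width
  expect_error(sem_profile(list(m1)), ">= 2 replicates")

  withr::local_seed(15)
  ms <- lapply(1:4, function(r) pm(matrix(rnorm(80, 7), 10, 8), 2))
  out2 <- sem_profile(ms)
  profs <- sapply(ms, function(m) colMeans(m$values))
  sem <- apply(profs, 1, sd) / 2
  expect_equal((out2$ci_high - out2$mean) / sem, rep(1.96, 8))
})

test_that("profile tables round-trip through their text form", {
  withr::local_seed(16)
  ms <- lapply(1:2, function(r) pm(matrix(rnorm(80, 7), 10, 8), 2))
  out <- sem_profile(ms)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_table(out, f)
  df <- read.delim(f)
  expect_equal(df$mean, out$mean, tolerance = 1e-8)
  expect_equal(df$bin_center_bp, bin_centers(out))
})
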