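# Brute-force oracles and random-instance generators shared by the unit and
# acceptance suites. All oracles work on plain integer vectors / data frames
# (1-based closed coordinates) and are deliberately independent of the
# GRanges-based implementation paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## ---- random instances -------------------------------------------------

random_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 10000,
                             max_width = 300) {
  if (n == 0)
    return(GRanges())
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos - max_width, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  sort(GRanges(factor(chrom, levels = sort(chroms)),
               IRanges(start, width = width)), ignore.strand = TRUE)
}

random_fragments <- function(n, genome, max_width = 200) {
  sl <- GenomeInfoDb::seqlengths(genome)
  chrom <- sample(names(sl), n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(sl[[chrom[i]]] - width[i], 1), integer(1))
  gr <- GRanges(chrom, IRanges(start, width = width),
                strand = sample(c("+", "-"), n, replace = TRUE))
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqinfo(gr) <- genome
  gr
}

random_profile_matrix <- function(n_loc, n_bins, binsize = 5, mu = 10,
                                  sd = 1, replicate_id = "rep1") {
  up <- n_bins * binsize / 2
  structure(list(values = matrix(rnorm(n_loc * n_bins, mu, sd),
                                 nrow = n_loc),
                 binsize = as.integer(binsize), upstream = as.integer(up),
                 downstream = as.integer(up), replicate_id = replicate_id),
            class = "ProfileMatrix")
}

## ---- per-base coverage oracle ----------------------------------------

# Transformation arithmetic restated independently (1-based closed spans):
# extend_to: L bases from the 5' end in strand direction; center_at: L-base
# window whose start is old_start + floor((old_width - L)/2); clipping to
# [1, chrom_length]; per-base counts averaged into bins of `binsize`.
oracle_coverage <- function(frags, chrom_len, binsize, mode = "as_is",
                            L = NULL) {
  counts <- numeric(chrom_len)
  for (i in seq_along(frags)) {
    s <- start(frags)[i]; e <- end(frags)[i]
    st <- as.character(strand(frags))[i]
    if (mode == "extend_to") {
      if (st == "-") { e2 <- e; s2 <- e - L + 1 } else { s2 <- s; e2 <- s + L - 1 }
    } else if (mode == "center_at") {
      s2 <- s + floor((e - s + 1 - L) / 2); e2 <- s2 + L - 1
    } else { s2 <- s; e2 <- e }
    s2 <- max(1, s2); e2 <- min(chrom_len, e2)
    if (s2 <= e2) counts[s2:e2] <- counts[s2:e2] + 1
  }
  nb <- ceiling(chrom_len / binsize)
  vapply(seq_len(nb), function(b) {
    lo <- (b - 1) * binsize + 1; hi <- min(chrom_len, b * binsize)
    mean(counts[lo:hi])
  }, numeric(1))
}

## ---- per-base profile-matrix oracle ----------------------------------

# refs: data.frame(point0 = 0-based reference position, strand); signal:
# per-base vector (base i holds signal of 0-based position i-1). Row bins
# run over transcription-direction offsets -upstream .. downstream-1 from
# the reference base (leftward on the minus strand).
oracle_matrix <- function(signal, chrom_len, refs, upstream, downstream,
                          binsize) {
  nb <- (upstream + downstream) / binsize
  t(vapply(seq_len(nrow(refs)), function(i) {
    p <- refs$point0[i]
    vals <- vapply(seq_len(upstream + downstream), function(k) {
      off <- k - 1 - upstream
      b0 <- if (refs$strand[i] == "-") p - off else p + off
      if (b0 < 0 || b0 >= chrom_len) 0 else signal[b0 + 1]
    }, numeric(1))
    vapply(seq_len(nb), function(b)
      mean(vals[((b - 1) * binsize + 1):(b * binsize)]), numeric(1))
  }, numeric(nb)))
}

## ---- interval-set oracles (per-chromosome integer work) ---------------

gr_to_df <- function(gr) data.frame(chrom = as.character(seqnames(gr)),
                                    start = start(gr), end = end(gr),
                                    stringsAsFactors = FALSE)

df_to_gr <- function(df) {
  if (!nrow(df)) return(GRanges())
  sort(GRanges(factor(df$chrom, levels = sort(unique(df$chrom))),
               IRanges(df$start, df$end)), ignore.strand = TRUE)
}

overlap_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)

# merge overlapping-or-adjacent spans until fixpoint
merge_spans <- function(df) {
  if (!nrow(df)) return(df)
  out <- NULL
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start, d$end), ]
    ms <- d$start[1]; me <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= me + 1) me <- max(me, d$end[i])
      else { out <- rbind(out, data.frame(chrom = ch, start = ms, end = me)); ms <- d$start[i]; me <- d$end[i] }
    }
    out <- rbind(out, data.frame(chrom = ch, start = ms, end = me))
  }
  out[order(out$chrom, out$start), ]
}

oracle_cobound <- function(a, b, min_overlap = 1) {
  da <- gr_to_df(a); db <- gr_to_df(b)
  hulls <- NULL
  for (i in seq_len(nrow(da))) for (j in seq_len(nrow(db))) {
    if (da$chrom[i] != db$chrom[j]) next
    if (overlap_len(da$start[i], da$end[i], db$start[j], db$end[j]) >=
        min_overlap)
      hulls <- rbind(hulls, data.frame(
        chrom = da$chrom[i], start = min(da$start[i], db$start[j]),
        end = max(da$end[i], db$end[j])))
  }
  if (is.null(hulls)) return(GRanges())
  df_to_gr(merge_spans(hulls))
}

oracle_consensus <- function(sets, min_support = 2, max_pos = 20000) {
  # each replicate's peak set is merged within itself first (book-ended or
  # overlapping intervals are one peak), matching the documented semantics
  dfs <- lapply(sets, function(s) {
    d <- gr_to_df(s)
    if (nrow(d)) merge_spans(d) else d
  })
  chroms <- unique(unlist(lapply(dfs, function(d) d$chrom)))
  out <- NULL
  for (ch in chroms) {
    support <- integer(max_pos)
    for (d in dfs) {
      covered <- logical(max_pos)
      dc <- d[d$chrom == ch, ]
      for (i in seq_len(nrow(dc))) covered[dc$start[i]:dc$end[i]] <- TRUE
      support <- support + covered
    }
    corepos <- which(support >= min_support)
    if (!length(corepos)) next
    runs <- split(corepos, cumsum(c(1, diff(corepos) != 1)))
    core <- do.call(rbind, lapply(runs, function(r)
      data.frame(chrom = ch, start = min(r), end = max(r))))
    # extend by union of contributing intervals overlapping any core run
    contrib <- NULL
    for (d in dfs) {
      dc <- d[d$chrom == ch, ]
      for (i in seq_len(nrow(dc)))
        if (any(support[dc$start[i]:dc$end[i]] >= min_support))
          contrib <- rbind(contrib, dc[i, ])
    }
    out <- rbind(out, merge_spans(rbind(core, contrib)))
  }
  if (is.null(out)) return(GRanges())
  df_to_gr(out)
}

oracle_intersect_all <- function(sets) {
  ref <- gr_to_df(sort(sets[[1]], ignore.strand = TRUE))
  keep <- rep(TRUE, nrow(ref))
  for (other in sets[-1]) {
    do <- gr_to_df(other)
    for (i in seq_len(nrow(ref))) {
      hit <- FALSE
      for (j in seq_len(nrow(do)))
        if (ref$chrom[i] == do$chrom[j] &&
            overlap_len(ref$start[i], ref$end[i], do$start[j], do$end[j]) >= 1)
          hit <- TRUE
      keep[i] <- keep[i] && hit
    }
  }
  df_to_gr(ref[keep, , drop = FALSE])
}

oracle_blacklist <- function(peaks, blacklist) {
  dp <- gr_to_df(sort(peaks, ignore.strand = TRUE))
  db <- gr_to_df(blacklist)
  keep <- vapply(seq_len(nrow(dp)), function(i)
    !any(vapply(seq_len(nrow(db)), function(j)
      dp$chrom[i] == db$chrom[j] &&
        overlap_len(dp$start[i], dp$end[i], db$start[j], db$end[j]) >= 1,
      logical(1))), logical(1))
  df_to_gr(dp[keep, , drop = FALSE])
}

oracle_classify_enhancers <- function(me1, me3, ac, p300) {
  d1 <- gr_to_df(sort(me1, ignore.strand = TRUE))
  any_overlap <- function(i, dset) {
    d <- gr_to_df(dset)
    any(vapply(seq_len(nrow(d)), function(j)
      d1$chrom[i] == d$chrom[j] &&
        overlap_len(d1$start[i], d1$end[i], d$start[j], d$end[j]) >= 1,
      logical(1)))
  }
  vapply(seq_len(nrow(d1)), function(i) {
    if (any_overlap(i, me3)) "promoter"
    else if (any_overlap(i, ac) && any_overlap(i, p300)) "active_enhancer"
    else "inactive_enhancer"
  }, character(1))
}

expect_same_regions <- function(x, y) {
  expect_equal(length(x), length(y))
  if (length(x)) {
    expect_equal(as.character(seqnames(x)), as.character(seqnames(y)))
    expect_equal(start(x), start(y))
    expect_equal(end(x), end(y))
  }
}

## ---- misc --------------------------------------------------------------

tiny_genome <- function(len = 10000, chroms = "c1")
  genome_model(stats::setNames(rep(len, length(chroms)), chroms))

# evenly spaced width-1 sites, windows isolated from one another
grid_sites <- function(genome, n, margin = 10000) {
  sl <- GenomeInfoDb::seqlengths(genome)
  per <- ceiling(n / length(sl))
  pos <- lapply(names(sl), function(ch)
    round(seq(margin, sl[[ch]] - margin, length.out = per)))
  gr <- GRanges(factor(rep(names(sl), lengths(pos)), levels = names(sl)),
                IRanges(unlist(pos), width = 1))
  gr <- gr[seq_len(n)]
  GenomeInfoDb::seqinfo(gr) <- genome
  gr
}
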