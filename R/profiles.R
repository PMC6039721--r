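# Reference-point signal matrices and aggregate (metagene) profile
# statistics: per-location and flank-baseline normalization, replicate
# averaging, bootstrap confidence intervals, empirical p-values and the
# unnormalized +/- 1.96 s.e.m. variant used for nascent RNA-seq.

#' Extract a reference-point signal matrix from a coverage track
#'
#' For each reference, signal is averaged into `binsize`-bp bins over the
#' window `[ref - upstream, ref + downstream)` (coordinates in transcription
#' direction: rows of minus-strand references are reversed so that upstream
#' is always leftward). The reference point is the strand-aware start for
#' `mode = "tss"` or the interval midpoint for `mode = "center"`. Bases
#' outside the chromosome contribute 0 (missing data as zero).
#'
#' The window is strand-symmetric: a minus-strand reference covers exactly
#' the mirror image of a plus-strand one, so reflecting the genome and the
#' strands reproduces the same rows.
#'
#' @param track a `CoverageTrack`; the matrix bin size must be a multiple of
#'   the track bin size.
#' @param refs `GRanges` of reference features (points or intervals);
#'   unstranded features are treated as `+`.
#' @param mode `"center"` or `"tss"`.
#' @param upstream,downstream window half-sizes in bp (defaults 1500/1500).
#' @param binsize matrix bin width in bp (default 5).
#' @param replicate_id label carried into replicate aggregation.
#' @return a `ProfileMatrix`: list with `values` (locations x bins matrix),
#'   `binsize`, `upstream`, `downstream`, `replicate_id`.
#' @export
compute_matrix <- function(track, refs, mode = c("center", "tss"),
                           upstream = 1500, downstream = 1500, binsize = 5,
                           replicate_id = "rep1") {
  mode <- match.arg(mode)
  if (!length(refs)) stopf("compute_matrix: no reference features")
  if ((upstream + downstream) %% binsize != 0)
    stopf("compute_matrix: window size must be a multiple of binsize")
  if (binsize %% track$binsize != 0)
    stopf("compute_matrix: matrix binsize must be a multiple of the track binsize (%d)",
          track$binsize)
  sl <- GenomeInfoDb::seqlengths(track$genome)
  chr <- as.character(GenomeInfoDb::seqnames(refs))
  unknown <- setdiff(unique(chr), names(sl))
  if (length(unknown))
    stopf("compute_matrix: reference on unknown chromosome(s): %s",
          paste(unknown, collapse = ", "))
  std <- as.character(BiocGenerics::strand(refs))
  std[std == "*"] <- "+"
  # 0-based reference point
  s0 <- BiocGenerics::start(refs) - 1L
  e0 <- BiocGenerics::end(refs)
  p0 <- switch(mode,
    tss = ifelse(std == "-", e0 - 1L, s0),
    center = floor((s0 + e0) / 2))
  nbins <- (upstream + downstream) %/% binsize
  tb <- track$binsize
  mat <- matrix(0, nrow = length(refs), ncol = nbins)
  base_off <- seq.int(0L, upstream + downstream - 1L)
  for (i in seq_along(refs)) {
    v <- track$values[[chr[i]]]
    len <- sl[[chr[i]]]
    # transcription-direction offsets -upstream .. downstream-1 from the
    # reference base; for minus strands the offsets run leftward
    b <- if (std[i] == "-") p0[i] + upstream - base_off
         else p0[i] - upstream + base_off
    inside <- b >= 0 & b < len
    x <- numeric(length(b))
    x[inside] <- v[b[inside] %/% tb + 1L]
    mat[i, ] <- colMeans(matrix(x, nrow = binsize))
  }
  structure(list(values = mat, binsize = as.integer(binsize),
                 upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 replicate_id = replicate_id),
            class = "ProfileMatrix")
}

#' @export
print.ProfileMatrix <- function(x, ...) {
  cat(sprintf(
    "ProfileMatrix '%s': %d locations x %d bins (%d bp bins, -%d/+%d bp)\n",
    x$replicate_id, nrow(x$values), ncol(x$values), x$binsize, x$upstream,
    x$downstream))
  invisible(x)
}

#' Genomic offsets (bp, window midpoints) of profile bins
#' @param m a `ProfileMatrix` or `AggregateProfile`.
#' @export
bin_centers <- function(m) {
  nbins <- (m$upstream + m$downstream) %/% m$binsize
  -m$upstream + (seq_len(nbins) - 0.5) * m$binsize
}

#' Per-location (row-wise) normalization of a profile matrix
#'
#' Divides each location's signal row by its own mean, removing
#' between-location scale differences before aggregation. Rows with mean 0
#' carry no signal and are dropped; their count is reported via a message
#' and the `"dropped"` attribute.
#'
#' @param m a `ProfileMatrix`.
#' @return a `ProfileMatrix` of the surviving rows, each with mean exactly 1.
#' @export
rowwise_normalize <- function(m) {
  rm_ <- rowMeans(m$values)
  drop <- rm_ == 0
  if (all(drop)) stopf("rowwise_normalize: all locations have zero signal")
  if (any(drop))
    message(sprintf("rowwise_normalize: dropped %d zero-signal location(s)",
                    sum(drop)))
  out <- m
  out$values <- m$values[!drop, , drop = FALSE] / rm_[!drop]
  attr(out, "dropped") <- sum(drop)
  out
}

#' Flank-baseline normalization of an aggregate profile vector
#'
#' Divides a per-bin profile by the mean signal in the outermost
#' `flank_width` bp on each side of the window (with the default
#' 1500 bp window and 50 bp flanks: positions -1500..-1450 and
#' +1450..+1500), yielding enrichment over local baseline; the flank mean
#' of the output is 1.
#'
#' @param profile numeric per-bin vector.
#' @param binsize,upstream,downstream window geometry of the vector.
#' @param flank_width width in bp of each outer flank (default 50; must be
#'   a multiple of `binsize`).
#' @return normalized numeric vector.
#' @export
baseline_normalize <- function(profile, binsize = 5, upstream = 1500,
                               downstream = 1500, flank_width = 50) {
  nbins <- (upstream + downstream) %/% binsize
  if (length(profile) != nbins)
    stopf("baseline_normalize: profile has %d bins, geometry implies %d",
          length(profile), nbins)
  if (flank_width %% binsize != 0)
    stopf("baseline_normalize: flank_width must be a multiple of binsize")
  k <- flank_width %/% binsize
  if (2 * k > nbins) stopf("baseline_normalize: flanks exceed the window")
  fl <- c(seq_len(k), nbins - k + seq_len(k))
  base <- mean(profile[fl])
  if (base == 0) stopf("baseline_normalize: flank mean is zero")
  profile / base
}

#' @noRd
check_geometry_matrices <- function(matrices, what) {
  stopifnot(length(matrices) >= 1)
  g <- vapply(matrices, function(m)
    c(m$binsize, m$upstream, m$downstream, ncol(m$values)), numeric(4))
  if (any(g != g[, 1]))
    stopf("%s: replicate matrices have mismatched geometry", what)
  invisible(TRUE)
}

#' Replicate-averaged profile with a single baseline shared by all
#' replicates: per-replicate column means (of row-normalized rows when
#' `normalized`), averaged, then one flank-baseline division.
#' @noRd
pooled_profile <- function(mats, normalized, flank_width = 50,
                           resample = FALSE) {
  tmpl <- mats[[1]]
  profs <- vapply(mats, function(m) {
    n <- nrow(m$values)
    idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
    colMeans(m$values[idx, , drop = FALSE])
  }, numeric(ncol(tmpl$values)))
  p <- rowMeans(profs)
  if (normalized)
    p <- baseline_normalize(p, tmpl$binsize, tmpl$upstream, tmpl$downstream,
                            flank_width)
  p
}

#' @noRd
new_aggregate_profile <- function(mean, ci_low, ci_high, template,
                                  n_locations, n_replicates, method,
                                  normalization) {
  structure(list(mean = mean, ci_low = ci_low, ci_high = ci_high,
                 binsize = template$binsize, upstream = template$upstream,
                 downstream = template$downstream,
                 n_locations = n_locations, n_replicates = n_replicates,
                 method = method, normalization = normalization),
            class = "AggregateProfile")
}

#' @export
print.AggregateProfile <- function(x, ...) {
  cat(sprintf(
    "AggregateProfile: %d bins, %d location(s), %d replicate(s), method %s, normalization %s\n",
    length(x$mean), x$n_locations, x$n_replicates,
    if (is.null(x$method)) "none" else x$method, x$normalization))
  invisible(x)
}

#' Aggregate replicate profile matrices into a mean profile
#'
#' Per replicate the matrix is row-normalized and column means are taken;
#' the replicate profiles are averaged (unweighted) and the average is
#' divided by its flank mean — one baseline consistent across all
#' replicates — to yield enrichment over baseline (when
#' `normalized = TRUE`; otherwise plain averaged column means).
#'
#' @param matrices list of `ProfileMatrix`, one per biological replicate.
#' @param normalized apply the row-wise + baseline normalization pipeline
#'   (default `TRUE`).
#' @param flank_width baseline flank width in bp (see
#'   [baseline_normalize()]).
#' @return an `AggregateProfile` (mean only; no CI).
#' @export
aggregate_replicates <- function(matrices, normalized = TRUE,
                                 flank_width = 50) {
  check_geometry_matrices(matrices, "aggregate_replicates")
  prep <- lapply(matrices, function(m)
    if (normalized) rowwise_normalize(m) else m)
  new_aggregate_profile(pooled_profile(prep, normalized, flank_width),
                        NULL, NULL, matrices[[1]],
                        n_locations = sum(vapply(matrices, function(m)
                          nrow(m$values), integer(1))),
                        n_replicates = length(matrices), method = NULL,
                        normalization = if (normalized) "rowwise+baseline"
                                        else "none")
}

#' Bootstrap confidence interval for an aggregate profile
#'
#' Locations (matrix rows) are the resampling unit: per iteration, each
#' replicate's locations are resampled with replacement and the
#' normalization procedure (per-location normalization, column means,
#' replicate averaging, shared flank-baseline division) is re-run on the
#' resample. The CI per bin is the empirical `alpha/2` and `1 - alpha/2`
#' percentile over iterations; the reported mean is the non-resampled
#' estimate.
#'
#' @inheritParams aggregate_replicates
#' @param iterations bootstrap iterations (default 5000).
#' @param alpha 1 - confidence level (default 0.05 for a 95% CI).
#' @param seed integer seed for the resampling RNG (global RNG state is
#'   left untouched).
#' @return an `AggregateProfile` with `ci_low`/`ci_high`.
#' @export
bootstrap_ci <- function(matrices, iterations = 5000, alpha = 0.05,
                         seed = 1, normalized = TRUE, flank_width = 50) {
  stopifnot(is_count(iterations), iterations >= 1)
  check_geometry_matrices(matrices, "bootstrap_ci")
  point <- aggregate_replicates(matrices, normalized, flank_width)
  # Row-wise normalization of a resampled row equals the precomputed
  # normalized row (a row's own mean does not depend on the resample), so
  # rows are normalized once; the baseline step is re-run per iteration.
  prep <- lapply(matrices, function(m)
    if (normalized) suppressMessages(rowwise_normalize(m)) else m)
  nb <- ncol(prep[[1]]$values)
  boot <- with_seed(seed, {
    vapply(seq_len(iterations), function(b)
      pooled_profile(prep, normalized, flank_width, resample = TRUE),
      numeric(nb))
  })
  qs <- apply(boot, 1, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  out <- point
  out$ci_low <- qs[1, ]
  out$ci_high <- qs[2, ]
  out$method <- "bootstrap"
  out$iterations <- as.integer(iterations)
  out
}

#' Empirical bootstrap p-value for a profile difference at one position
#'
#' Tests the difference between two conditions (e.g. a time point versus
#' time 0) in aggregate signal at a single bin — by default the central bin,
#' i.e. the reference point. Per iteration both conditions are independently
#' resampled (locations within each replicate) and their aggregate values at
#' the test position recomputed with the normalization re-run; the two-sided
#' empirical p-value of the bootstrap difference distribution is returned
#' with add-one smoothing, so `p >= 1/(iterations+1)`:
#' `p = min(1, 2 * min((1 + #\{d <= 0\}), (1 + #\{d >= 0\})) / (B + 1))`.
#'
#' @param matrices_a,matrices_0 lists of `ProfileMatrix` for the two
#'   conditions (same geometry).
#' @param position bin index to test; `NULL` (default) uses the central bin.
#' @param iterations bootstrap iterations (default 5000).
#' @param seed RNG seed.
#' @inheritParams aggregate_replicates
#' @return list of class `CenterTest`: `position`, `observed` (condition A
#'   minus condition 0 at the position), `p`, `iterations`.
#' @export
empirical_pvalue <- function(matrices_a, matrices_0, position = NULL,
                             iterations = 5000, seed = 1, normalized = TRUE,
                             flank_width = 50) {
  check_geometry_matrices(c(matrices_a, matrices_0), "empirical_pvalue")
  nb <- ncol(matrices_a[[1]]$values)
  if (is.null(position)) position <- nb %/% 2 + 1L
  stopifnot(position >= 1, position <= nb)
  prep <- function(ms) lapply(ms, function(m)
    if (normalized) suppressMessages(rowwise_normalize(m)) else m)
  pa <- prep(matrices_a); p0 <- prep(matrices_0)
  value_at <- function(ms, resample)
    pooled_profile(ms, normalized, flank_width, resample = resample)[position]
  observed <- value_at(pa, FALSE) - value_at(p0, FALSE)
  d <- with_seed(seed, vapply(seq_len(iterations), function(b)
    value_at(pa, TRUE) - value_at(p0, TRUE), numeric(1)))
  B <- iterations
  p <- min(1, 2 * min((1 + sum(d <= 0)) / (B + 1),
                      (1 + sum(d >= 0)) / (B + 1)))
  structure(list(position = as.integer(position), observed = observed,
                 p = p, iterations = as.integer(B)),
            class = "CenterTest")
}

#' @export
print.CenterTest <- function(x, ...) {
  cat(sprintf("CenterTest: bin %d, observed difference %.4g, empirical p = %.4g (B = %d)\n",
              x$position, x$observed, x$p, x$iterations))
  invisible(x)
}

#' Aggregate profile with parametric +/- 1.96 s.e.m. confidence interval
#'
#' The unnormalized variant used for nascent RNA-seq profiles: no
#' per-location or baseline normalization is applied. Each replicate
#' contributes its plain column-mean profile; the CI is
#' `mean +/- 1.96 * sd(replicate profiles)/sqrt(n_replicates)` per bin.
#' Strand selection (e.g. plus-strand-only reporting) is applied upstream
#' when building the matrices.
#'
#' @param matrices list of at least two `ProfileMatrix` replicates.
#' @return an `AggregateProfile` with `method = "sem"`.
#' @export
sem_profile <- function(matrices) {
  check_geometry_matrices(matrices, "sem_profile")
  if (length(matrices) < 2)
    stopf("sem_profile: need >= 2 replicates for a s.e.m.-based interval")
  profs <- vapply(matrices, function(m) colMeans(m$values),
                  numeric(ncol(matrices[[1]]$values)))
  mu <- rowMeans(profs)
  sem <- apply(profs, 1, stats::sd) / sqrt(ncol(profs))
  out <- new_aggregate_profile(mu, mu - 1.96 * sem, mu + 1.96 * sem,
                               matrices[[1]],
                               n_locations = sum(vapply(matrices, function(m)
                                 nrow(m$values), integer(1))),
                               n_replicates = length(matrices),
                               method = "sem", normalization = "none")
  out
}

#' Write an aggregate profile as a tab-delimited table
#'
#' Columns: `bin_center_bp`, `mean` and, when present, `ci_low`, `ci_high`.
#' @param profile an `AggregateProfile`.
#' @param path output path.
#' @export
write_profile_table <- function(profile, path) {
  df <- data.frame(bin_center_bp = bin_centers(profile), mean = profile$mean)
  if (!is.null(profile$ci_low)) {
    df$ci_low <- profile$ci_low
    df$ci_high <- profile$ci_high
  }
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
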