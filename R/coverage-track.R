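#' Binned coverage tracks
#'
#' A `CoverageTrack` stores per-chromosome signal vectors at a fixed bin
#' size. Each bin value is the *mean per-base coverage* within the bin (not a
#' fragment count), so changing the bin size does not change the scale of
#' the track and 1x-coverage semantics are preserved. The last bin of a
#' chromosome may be partial; its value is the mean over the bases it
#' actually covers. The track records its normalization provenance:
#' `raw` -> `rpgc` -> `input_subtracted` / `ratio`. Raw and RPGC tracks are
#' non-negative; input-subtracted tracks may contain negative values.
#'
#' @param values named list (one element per chromosome, in genome order) of
#'   numeric bin-value vectors.
#' @param binsize bin width in bp.
#' @param genome `Seqinfo` coordinate frame; each vector must have
#'   `ceiling(chrom_length / binsize)` elements.
#' @param provenance one of `"raw"`, `"rpgc"`, `"input_subtracted"`,
#'   `"ratio"`.
#' @return object of class `CoverageTrack`.
#' @export
coverage_track <- function(values, binsize, genome,
                           provenance = c("raw", "rpgc",
                                          "input_subtracted", "ratio")) {
  provenance <- match.arg(provenance)
  stopifnot(is.list(values), is_count(binsize), binsize >= 1)
  sl <- GenomeInfoDb::seqlengths(genome)
  if (!identical(sort(names(values)), sort(names(sl))))
    stopf("coverage_track: value list names must match genome chromosomes")
  values <- values[names(sl)]
  for (ch in names(sl)) {
    expected <- ceiling(sl[[ch]] / binsize)
    if (length(values[[ch]]) != expected)
      stopf("coverage_track: %s has %d bins, expected %d",
            ch, length(values[[ch]]), expected)
  }
  if (provenance %in% c("raw", "rpgc") &&
      any(vapply(values, function(v) any(v < 0), logical(1))))
    stopf("coverage_track: %s tracks must be non-negative", provenance)
  structure(list(values = values, binsize = as.integer(binsize),
                 genome = genome, provenance = provenance),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  sl <- GenomeInfoDb::seqlengths(x$genome)
  cat(sprintf("CoverageTrack: %d chromosome(s), binsize %d bp, provenance %s\n",
              length(sl), x$binsize, x$provenance))
  cat(sprintf("  total base coverage: %.6g\n", track_total_coverage(x)))
  invisible(x)
}

#' Widths in bp of the bins of one chromosome (last bin may be partial)
#' @noRd
track_bin_widths <- function(track, chrom) {
  len <- GenomeInfoDb::seqlengths(track$genome)[[chrom]]
  n <- ceiling(len / track$binsize)
  w <- rep(track$binsize, n)
  w[n] <- len - (n - 1) * track$binsize
  w
}

#' Total base coverage of a track
#'
#' Sum over bins of (bin value x bin width); equals the total number of
#' fragment-covered bases for a raw track built by [fragments_to_coverage()].
#' @param track a `CoverageTrack`.
#' @export
track_total_coverage <- function(track) {
  sum(vapply(names(track$values), function(ch)
    sum(track$values[[ch]] * track_bin_widths(track, ch)), numeric(1)))
}

#' @noRd
check_same_geometry <- function(a, b, what) {
  if (a$binsize != b$binsize)
    stopf("%s: bin sizes differ (%d vs %d)", what, a$binsize, b$binsize)
  if (!identical(GenomeInfoDb::seqlengths(a$genome),
                 GenomeInfoDb::seqlengths(b$genome)))
    stopf("%s: tracks are on different genomes", what)
  invisible(TRUE)
}

#' Map a track and return a new CoverageTrack with given provenance
#' @noRd
track_map <- function(track, f, provenance) {
  coverage_track(lapply(track$values, f), track$binsize, track$genome,
                 provenance)
}

#' Map two tracks bin-wise
#' @noRd
track_map2 <- function(a, b, f, provenance) {
  vals <- lapply(names(a$values), function(ch) f(a$values[[ch]], b$values[[ch]]))
  names(vals) <- names(a$values)
  coverage_track(vals, a$binsize, a$genome, provenance)
}
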