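# Fragment libraries -> normalized coverage tracks.

#' Fragment extension rule
#'
#' Controls how each aligned fragment is transformed before coverage is
#' computed:
#' * `as_is` — use the fragment span untouched;
#' * `extend_to` — span `fragment_length` bp from the fragment's 5' end in
#'   the strand direction (read-extension for single-end ChIP data; typical
#'   lengths 200 bp for transcription-factor ChIP, 250 bp for PolII ChIP);
#' * `center_at` — a `fragment_length` bp window centered on the original
#'   fragment midpoint (read-centering).
#'
#' @param mode one of `"as_is"`, `"extend_to"`, `"center_at"`.
#' @param fragment_length target length in bp (required unless `as_is`).
#' @export
extension_rule <- function(mode = c("as_is", "extend_to", "center_at"),
                           fragment_length = NULL) {
  mode <- match.arg(mode)
  if (mode != "as_is") {
    if (is.null(fragment_length) || !is_count(fragment_length) ||
        fragment_length <= 0)
      stopf("extension_rule: fragment_length must be a positive integer for %s",
            mode)
    fragment_length <- as.integer(fragment_length)
  }
  structure(list(mode = mode, fragment_length = fragment_length),
            class = "ExtensionRule")
}

#' @noRd
apply_extension <- function(frags, rule) {
  switch(rule$mode,
    as_is = frags,
    extend_to = GenomicRanges::resize(frags, rule$fragment_length,
                                      fix = "start"),
    center_at = GenomicRanges::resize(frags, rule$fragment_length,
                                      fix = "center"))
}

#' Compute binned coverage from a fragment set
#'
#' Each fragment is transformed per the extension rule, clipped to the
#' chromosome bounds (clipped, not dropped, so depth is preserved near
#' chromosome ends), and counted into per-base coverage; bin values are the
#' mean per-base count over each bin.
#'
#' @param frags fragment `GRanges` (see [fragment_set()]).
#' @param genome `Seqinfo`; fragments on chromosomes absent from it are an
#'   error.
#' @param binsize bin width in bp (default 1, i.e. single-nucleotide
#'   resolution).
#' @param rule an [extension_rule()]; default `as_is`.
#' @return a `CoverageTrack` with provenance `raw`.
#' @export
fragments_to_coverage <- function(frags, genome, binsize = 1,
                                  rule = extension_rule("as_is")) {
  stopifnot(is_count(binsize), binsize >= 1)
  unknown <- setdiff(GenomeInfoDb::seqlevelsInUse(frags),
                     GenomeInfoDb::seqnames(genome))
  if (length(unknown))
    stopf("fragments_to_coverage: fragment on unknown chromosome(s): %s",
          paste(unknown, collapse = ", "))
  frags <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(frags),
                                  IRanges::ranges(frags),
                                  strand = BiocGenerics::strand(frags))
  GenomeInfoDb::seqlevels(frags) <- GenomeInfoDb::seqnames(genome)
  tr <- apply_extension(frags, rule)
  # extension may momentarily run past chromosome ends; clipped right away
  suppressWarnings(GenomeInfoDb::seqinfo(tr) <- genome)
  tr <- GenomicRanges::trim(tr)
  tr <- tr[BiocGenerics::width(tr) > 0]
  cov <- GenomicRanges::coverage(tr)
  sl <- GenomeInfoDb::seqlengths(genome)
  vals <- lapply(names(sl), function(ch) {
    len <- sl[[ch]]
    starts <- seq.int(1L, len, by = binsize)
    ends <- pmin(starts + binsize - 1L, len)
    as.numeric(IRanges::viewMeans(IRanges::Views(cov[[ch]], starts, ends)))
  })
  names(vals) <- names(sl)
  coverage_track(vals, binsize, genome, "raw")
}

#' Scale a raw track to 1x genome coverage (RPGC)
#'
#' Reads-per-genomic-content scaling: values are multiplied by
#' `effective_genome_size / total_base_coverage`, so that the mean per-base
#' coverage over the effective genome equals 1x. When the effective genome
#' size equals the actual genome length, the post-normalization mean bin
#' value is exactly 1.
#'
#' @param track raw `CoverageTrack`.
#' @param effective_genome_size effective (mappable) genome size in bp;
#'   default [EFFECTIVE_GENOME_SIZE_MM10]. For synthetic genomes, pass
#'   [genome_size()] of the genome model.
#' @return `CoverageTrack` with provenance `rpgc`.
#' @export
rpgc_normalize <- function(track,
                           effective_genome_size = EFFECTIVE_GENOME_SIZE_MM10) {
  if (track$provenance != "raw")
    stopf("rpgc_normalize: expected a raw track, got provenance '%s'",
          track$provenance)
  total <- track_total_coverage(track)
  if (total == 0)
    stopf("rpgc_normalize: track has zero total coverage; scale undefined")
  scale <- effective_genome_size / total
  track_map(track, function(v) v * scale, "rpgc")
}

#' Subtract a depth-normalized input track from a ChIP track
#'
#' Both tracks must already be RPGC-normalized (the depth normalization
#' mechanism), share the bin size and genome. The result is the bin-wise
#' difference; negative values are preserved.
#'
#' @param chip,input RPGC `CoverageTrack`s.
#' @return `CoverageTrack` with provenance `input_subtracted`.
#' @export
subtract_input <- function(chip, input) {
  check_same_geometry(chip, input, "subtract_input")
  if (chip$provenance != "rpgc" || input$provenance != "rpgc")
    stopf("subtract_input: both tracks must be rpgc-normalized")
  track_map2(chip, input, `-`, "input_subtracted")
}

#' Bin-wise ratio of two tracks (e.g. a histone mark over an H3 control)
#'
#' Computes `(num + pseudocount) / (den + pseudocount)` bin-wise. The
#' pseudocount (in RPGC units) bounds the ratio where the denominator
#' approaches zero without washing out signal elsewhere.
#'
#' @param num,den RPGC `CoverageTrack`s.
#' @param pseudocount positive real, default 0.1.
#' @return `CoverageTrack` with provenance `ratio`.
#' @export
ratio_normalize <- function(num, den, pseudocount = 0.1) {
  check_same_geometry(num, den, "ratio_normalize")
  if (num$provenance != "rpgc" || den$provenance != "rpgc")
    stopf("ratio_normalize: both tracks must be rpgc-normalized")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stopf("ratio_normalize: pseudocount must be > 0")
  track_map2(num, den,
             function(a, b) (a + pseudocount) / (b + pseudocount), "ratio")
}
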