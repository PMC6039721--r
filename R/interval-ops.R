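# Peak-set algebra and region classification.

#' Co-bound union of two peak sets
#'
#' Defines jointly-bound regions (e.g. NuRD peaks from Mbd3 and Chd4
#' ChIP-seq): for every pair of peaks, one from each set, overlapping by at
#' least `min_overlap` bp, the merged span is emitted; emitted spans that
#' touch are merged transitively. Peaks with no cross-set partner are
#' excluded. Set `cobound = FALSE` for the plain union of both sets instead.
#'
#' @param a,b `GRanges` peak sets.
#' @param min_overlap minimum cross-set overlap in bp (default 1).
#' @param cobound if `FALSE`, return `reduce(c(a, b))` (every peak kept).
#' @return `GRanges` of merged regions, sorted, non-overlapping.
#' @export
cobound_union <- function(a, b, min_overlap = 1, cobound = TRUE) {
  if (!is_count(min_overlap) || min_overlap < 1)
    stopf("cobound_union: min_overlap must be >= 1")
  a <- granges_clean(a); b <- granges_clean(b)
  if (!cobound)
    return(GenomicRanges::sort(GenomicRanges::reduce(c(a, b))))
  ov <- GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap,
                                    ignore.strand = TRUE)
  partnered <- c(a[unique(S4Vectors::queryHits(ov))],
                 b[unique(S4Vectors::subjectHits(ov))])
  GenomicRanges::sort(GenomicRanges::reduce(partnered))
}

#' Consensus peaks across replicates
#'
#' Regions supported by at least `min_support` replicate peak sets: a core
#' base is one covered by intervals from `>= min_support` distinct
#' replicates; cores are merged, then each consensus region is extended to
#' the union of all replicate intervals overlapping its core (so consensus
#' peaks are not fragmented to the bare intersection). Each replicate set
#' is first merged within itself (overlapping or book-ended intervals
#' become one peak), since a peak set is non-overlapping by construction.
#'
#' @param replicate_sets list of `GRanges`, one per replicate.
#' @param min_support minimum number of supporting replicates (default 2).
#' @return `GRanges`, sorted, non-overlapping.
#' @export
consensus <- function(replicate_sets, min_support = 2) {
  stopifnot(is.list(replicate_sets))
  if (min_support > length(replicate_sets))
    stopf("consensus: min_support (%d) exceeds number of replicate sets (%d)",
          min_support, length(replicate_sets))
  sets <- lapply(replicate_sets, function(g)
    GenomicRanges::reduce(granges_clean(g)))
  nonempty <- sets[vapply(sets, length, integer(1)) > 0]
  if (!length(nonempty)) return(GenomicRanges::GRanges())
  chroms <- sort(unique(unlist(lapply(nonempty,
                                      GenomeInfoDb::seqlevelsInUse))))
  span <- vapply(chroms, function(ch) max(unlist(lapply(nonempty, function(g) {
    e <- BiocGenerics::end(g)[as.character(GenomeInfoDb::seqnames(g)) == ch]
    if (length(e)) max(e) else 0L
  }))), numeric(1))
  covs <- lapply(nonempty, function(g) {
    GenomeInfoDb::seqlevels(g) <- chroms
    GenomicRanges::coverage(g, width = span)
  })
  support <- Reduce(`+`, covs)
  core <- methods::as(IRanges::slice(support, lower = min_support,
                                     rangesOnly = TRUE), "GRanges")
  if (!length(core)) return(GenomicRanges::GRanges())
  all_iv <- do.call(c, unname(nonempty))
  contrib <- IRanges::subsetByOverlaps(all_iv, core, ignore.strand = TRUE)
  GenomicRanges::sort(GenomicRanges::reduce(c(core, contrib)))
}

#' Peaks called in all datasets
#'
#' Retains intervals of the first set that are overlapped (by at least 1 bp)
#' by at least one interval in every other set. Used when several published
#' datasets exist for the same mark and only concordant peaks should enter
#' downstream classification.
#'
#' @param sets non-empty list of `GRanges`; the first is the reference set.
#' @return subset of `sets[[1]]`, sorted.
#' @export
intersect_all <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  ref <- GenomicRanges::sort(granges_clean(sets[[1]]), ignore.strand = TRUE)
  keep <- rep(TRUE, length(ref))
  for (other in sets[-1])
    keep <- keep & IRanges::overlapsAny(ref, granges_clean(other),
                                        ignore.strand = TRUE)
  ref[keep]
}

#' Remove peaks overlapping a blacklist
#'
#' Peaks overlapping any blacklist interval by >= 1 bp are removed entirely
#' (no trimming), matching standard ENCODE-blacklist filtering.
#'
#' @param peaks,blacklist `GRanges`.
#' @return filtered `GRanges`, sorted.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  peaks <- GenomicRanges::sort(granges_clean(peaks), ignore.strand = TRUE)
  drop <- IRanges::overlapsAny(peaks, granges_clean(blacklist),
                               ignore.strand = TRUE)
  peaks[!drop]
}

#' Classify H3K4me1 regions into enhancer classes
#'
#' Each H3K4me1-enriched region is labeled:
#' * overlaps H3K4me3 -> `promoter` (excluded from the enhancer classes;
#'   H3K4me3 marks promoter chromatin);
#' * else overlaps both H3K27ac and p300 -> `active_enhancer`;
#' * else -> `inactive_enhancer`.
#'
#' The three labels partition the input, so
#' `active + inactive + promoter-excluded = |h3k4me1|`.
#'
#' @param h3k4me1,h3k4me3,h3k27ac,p300 `GRanges` peak sets.
#' @return `GRanges` of all H3K4me1 regions with a `label` column.
#' @export
classify_enhancers <- function(h3k4me1, h3k4me3, h3k27ac, p300) {
  me1 <- GenomicRanges::sort(granges_clean(h3k4me1), ignore.strand = TRUE)
  has_me3 <- IRanges::overlapsAny(me1, granges_clean(h3k4me3),
                                  ignore.strand = TRUE)
  has_ac <- IRanges::overlapsAny(me1, granges_clean(h3k27ac),
                                 ignore.strand = TRUE)
  has_p300 <- IRanges::overlapsAny(me1, granges_clean(p300),
                                   ignore.strand = TRUE)
  label <- ifelse(has_me3, "promoter",
                  ifelse(has_ac & has_p300, "active_enhancer",
                         "inactive_enhancer"))
  me1$label <- label
  me1
}

#' Classify arbitrary regions against promoters and enhancer classes
#'
#' Each query region gets exactly one label with precedence
#' `promoter > active_enhancer > inactive_enhancer > other`:
#' promoter if it overlaps any strand-aware TSS window
#' (`TSS - promoter_window[1]` to `TSS + promoter_window[2]` in
#' transcription direction), else the highest-precedence enhancer class it
#' overlaps, else `other`. Labels partition the input.
#'
#' @param peaks `GRanges` to classify.
#' @param genes gene models ([gene_models()]).
#' @param enhancers labeled `GRanges` from [classify_enhancers()].
#' @param promoter_window `c(upstream, downstream)` in bp around the TSS;
#'   default `c(2000, 500)`, the same promoter definition used for the
#'   traveling ratio.
#' @return `GRanges` with a `label` column.
#' @export
classify_regions <- function(peaks, genes, enhancers,
                             promoter_window = c(2000, 500)) {
  peaks <- GenomicRanges::sort(granges_clean(peaks), ignore.strand = TRUE)
  prom <- GenomicRanges::trim(GenomicRanges::promoters(
    genes, upstream = promoter_window[1], downstream = promoter_window[2]))
  is_prom <- IRanges::overlapsAny(peaks, prom, ignore.strand = TRUE)
  enh <- enhancers[enhancers$label %in% c("active_enhancer",
                                          "inactive_enhancer")]
  is_active <- IRanges::overlapsAny(
    peaks, enh[enh$label == "active_enhancer"], ignore.strand = TRUE)
  is_inactive <- IRanges::overlapsAny(
    peaks, enh[enh$label == "inactive_enhancer"], ignore.strand = TRUE)
  peaks$label <- ifelse(is_prom, "promoter",
                        ifelse(is_active, "active_enhancer",
                               ifelse(is_inactive, "inactive_enhancer",
                                      "other")))
  peaks
}

#' Count fragments in intervals, with input subtraction
#'
#' A fragment is assigned to an interval iff its midpoint lies inside
#' ([fragment_midpoints()]). When an input (control) library is supplied,
#' the input count is rescaled by the ratio of library sizes and subtracted,
#' flooring at zero:
#' `subtracted = max(0, raw - input_raw * library_size / input_library_size)`.
#'
#' @param frags fragment `GRanges`.
#' @param intervals `GRanges` of regions to count over.
#' @param input optional input fragment `GRanges`.
#' @return `data.frame` with one row per interval: `chrom`, `start`, `end`,
#'   `count` and, with input, `input_count` (rescaled) and
#'   `subtracted_count`.
#' @export
count_in_intervals <- function(frags, intervals, input = NULL) {
  intervals <- granges_clean(intervals)
  raw <- GenomicRanges::countOverlaps(intervals, fragment_midpoints(frags),
                                      ignore.strand = TRUE)
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(intervals)),
    start = BiocGenerics::start(intervals),
    end = BiocGenerics::end(intervals),
    count = as.integer(raw))
  if (!is.null(input)) {
    if (!length(input))
      stopf("count_in_intervals: input library is empty; cannot depth-scale")
    iraw <- GenomicRanges::countOverlaps(intervals, fragment_midpoints(input),
                                         ignore.strand = TRUE)
    scale <- length(frags) / length(input)
    out$input_count <- iraw * scale
    out$subtracted_count <- pmax(0, raw - iraw * scale)
  }
  out
}

#' Drop mcols and normalize seqlevels for set algebra
#' @noRd
granges_clean <- function(gr) {
  stopifnot(methods::is(gr, "GRanges"))
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  GenomicRanges::GRanges(factor(chr, levels = sort(unique(chr))),
                         IRanges::ranges(gr),
                         strand = BiocGenerics::strand(gr))
}
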