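#' Construct a genome model
#'
#' The genome model fixes the coordinate frame for every other object in the
#' pipeline: an ordered set of chromosome names and lengths, represented as a
#' [GenomeInfoDb::Seqinfo] so that all GenomicRanges operations can validate
#' and clip against it.
#'
#' @param chroms character vector of unique chromosome names, or a named
#'   numeric vector of lengths (in which case `lengths` is omitted).
#' @param lengths integer vector of chromosome lengths in bp, all `> 0`.
#' @return A `Seqinfo` object.
#' @examples
#' gm <- genome_model(c(chr1 = 2e6, chr2 = 2e6))
#' @export
genome_model <- function(chroms, lengths = NULL) {
  if (is.null(lengths)) {
    if (is.null(names(chroms)))
      stopf("genome_model: supply lengths or a named numeric vector")
    lengths <- unname(chroms)
    chroms <- names(chroms)
  }
  if (anyDuplicated(chroms)) stopf("genome_model: duplicated chromosome names")
  if (any(lengths <= 0) || any(lengths != floor(lengths)))
    stopf("genome_model: chromosome lengths must be positive integers")
  GenomeInfoDb::Seqinfo(seqnames = as.character(chroms),
                        seqlengths = as.integer(lengths))
}

#' Total genome length in bp
#' @param genome a `Seqinfo` from [genome_model()].
#' @export
genome_size <- function(genome) sum(as.numeric(GenomeInfoDb::seqlengths(genome)))

#' Effective genome size used for 1x (RPGC) normalization, in bp.
#'
#' Default matches the mouse GRCm38 effective genome size used when scaling
#' coverage tracks to uniform 1x mean coverage.
#' @export
EFFECTIVE_GENOME_SIZE_MM10 <- 2150570000

#' Build a fragment set
#'
#' A fragment set is the universal raw input of the pipeline: the aligned
#' sequenced fragments of one library as a `GRanges` (one range per fragment,
#' strand mandatory) carrying its `library_id`. The library size is the
#' fragment count, `length(x)`.
#'
#' @param gr `GRanges` of fragments; strand must be `+` or `-` for every
#'   fragment.
#' @param library_id single string naming the library.
#' @param genome optional `Seqinfo`; when given, fragments are validated
#'   against (and carry) it.
#' @return `GRanges` with `metadata(x)$library_id` set.
#' @export
fragment_set <- function(gr, library_id, genome = NULL) {
  stopifnot(methods::is(gr, "GRanges"), is.character(library_id),
            length(library_id) == 1L)
  if (length(gr) && any(BiocGenerics::strand(gr) == "*"))
    stopf("fragment_set: every fragment needs an explicit strand (+/-)")
  if (!is.null(genome)) {
    bad <- !(as.character(GenomeInfoDb::seqnames(gr)) %in%
               GenomeInfoDb::seqnames(genome))
    if (any(bad))
      stopf("fragment_set: fragments on chromosomes absent from the genome: %s",
            paste(unique(as.character(GenomeInfoDb::seqnames(gr))[bad]),
                  collapse = ", "))
    if (any(BiocGenerics::start(gr) < 1) ||
        any(BiocGenerics::end(gr) >
              GenomeInfoDb::seqlengths(genome)[as.character(
                GenomeInfoDb::seqnames(gr))]))
      stopf("fragment_set: fragment outside chromosome bounds")
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  S4Vectors::metadata(gr)$library_id <- library_id
  gr
}

#' @rdname fragment_set
#' @param x a fragment set.
#' @export
library_id <- function(x) S4Vectors::metadata(x)$library_id

#' @rdname fragment_set
#' @export
library_size <- function(x) length(x)

#' Construct gene models
#'
#' Genes are `GRanges` spans (1-based, closed, as usual for `GRanges`) with a
#' mandatory `gene_id` column and an explicit strand. The transcription start
#' site (TSS) is the strand-aware 5' end; the transcription end site (TES,
#' the polyA addition site) is the strand-aware 3' end. A gene span must be
#' at least 502 bp so that a non-empty gene-body window (TSS+501 bp onwards)
#' exists.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom,start,end,strand vectors defining the spans (1-based closed
#'   coordinates; strand `+` or `-`).
#' @param genome optional `Seqinfo` to validate against.
#' @return `GRanges` with a `gene_id` metadata column.
#' @seealso [tss()], [tes()], [gene_windows()]
#' @export
gene_models <- function(gene_id, chrom, start, end, strand, genome = NULL) {
  if (anyDuplicated(gene_id)) stopf("gene_models: duplicated gene_id")
  if (any(!strand %in% c("+", "-")))
    stopf("gene_models: gene strand must be + or -")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand, gene_id = gene_id)
  if (any(BiocGenerics::width(gr) < 502))
    stopf("gene_models: gene span must be >= 502 bp (body window would be empty)")
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  gr
}

#' Strand-aware transcription start / end positions
#'
#' `tss()` returns the 5' position of each gene, `tes()` the 3' position
#' (polyA addition site), both as 1-based positions on the chromosome.
#' @param genes `GRanges` of gene models.
#' @return integer vector of positions.
#' @export
tss <- function(genes) {
  ifelse(as.character(BiocGenerics::strand(genes)) == "-",
         BiocGenerics::end(genes), BiocGenerics::start(genes))
}

#' @rdname tss
#' @export
tes <- function(genes) {
  ifelse(as.character(BiocGenerics::strand(genes)) == "-",
         BiocGenerics::start(genes), BiocGenerics::end(genes))
}

#' Fragment midpoints as width-1 ranges
#'
#' The midpoint convention used for all interval counting: the midpoint of a
#' fragment occupying 0-based half-open span \[s0, e0) is floor((s0+e0)/2);
#' a fragment is assigned to an interval iff its midpoint lies inside. This
#' makes counts additive across adjacent windows and insensitive to
#' fragment-length edge effects.
#' @param frags fragment `GRanges`.
#' @return `GRanges` of width-1 midpoints (same order and mcols).
#' @export
fragment_midpoints <- function(frags) {
  m0 <- floor((BiocGenerics::start(frags) - 1 + BiocGenerics::end(frags)) / 2)
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(frags),
                         IRanges::IRanges(m0 + 1, width = 1),
                         strand = BiocGenerics::strand(frags))
}
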