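# Readers/writers for the standard interval and track formats. Parsing is
# delegated to rtracklayer; the wrappers add the validation contracts the
# pipeline relies on (line-numbered errors, zero-length rejection, bounds
# checks, bin alignment).

#' Read a BED3/BED6 file of genomic intervals
#'
#' BED coordinates on disk are 0-based half-open; the returned `GRanges`
#' uses the usual 1-based closed convention (conversion is handled by
#' rtracklayer). Intervals are returned sorted by (chrom, start, end).
#' Strand is `*` when the file has no strand column.
#'
#' @param path BED file path.
#' @param genome optional `Seqinfo`; when given, intervals beyond chromosome
#'   bounds (or on unknown chromosomes) raise a validation error.
#' @return sorted `GRanges`; `name` and `score` columns preserved if present.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stopf("read_bed: %s line %d: expected >= 3 tab-separated fields", path, i)
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stopf("read_bed: %s line %d: non-numeric start/end", path, i)
    if (s >= e)
      stopf("read_bed: %s line %d: empty or inverted interval [%s, %s)",
            path, i, f[2], f[3])
  }
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!is.null(genome)) {
    unknown <- setdiff(GenomeInfoDb::seqlevelsInUse(gr),
                       GenomeInfoDb::seqnames(genome))
    if (length(unknown))
      stopf("read_bed: %s: unknown chromosome(s): %s", path,
            paste(unknown, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
    over <- BiocGenerics::end(gr) >
      GenomeInfoDb::seqlengths(genome)[as.character(GenomeInfoDb::seqnames(gr))]
    if (any(over))
      stopf("read_bed: %s: interval beyond chromosome length", path)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  gr
}

#' Write intervals to BED
#'
#' Writes BED6 when the input has any stranded interval or name/score
#' metadata, BED3 otherwise.
#' @param gr `GRanges`.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Keeps gene-level records (`type == "gene"`; if the file carries no gene
#' records, gene spans are taken as the range of each `gene_id`'s records).
#' GTF is 1-based closed on disk, matching the `GRanges` convention used
#' internally. TSS/TES are derived strand-aware ([tss()], [tes()]).
#'
#' @param path GTF file path.
#' @param genome optional `Seqinfo`.
#' @return `GRanges` of gene models with `gene_id`, as from [gene_models()].
#' @export
read_gtf_genes <- function(path, genome = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "GTF"),
                 error = function(e)
                   stopf("read_gtf_genes: %s: parse error: %s", path,
                         conditionMessage(e)))
  if (!length(gr)) stopf("read_gtf_genes: %s: no records", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stopf("read_gtf_genes: %s: record without gene_id attribute", path)
  if (!is.null(gr$type) && any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  else {
    rng <- unlist(range(GenomicRanges::split(gr, gr$gene_id)))
    rng$gene_id <- names(rng)
    names(rng) <- NULL
    gr <- rng
  }
  gene_models(gr$gene_id, as.character(GenomeInfoDb::seqnames(gr)),
              BiocGenerics::start(gr), BiocGenerics::end(gr),
              as.character(BiocGenerics::strand(gr)), genome = genome)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued bins are merged into runs (standard bedGraph
#' run-length form); values are serialized to 6 significant digits. The
#' companion [read_bedgraph()] inverts the operation, so a write/read round
#' trip reproduces the track up to that precision.
#'
#' @param track a `CoverageTrack`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  sl <- GenomeInfoDb::seqlengths(track$genome)
  pieces <- lapply(names(track$values), function(ch) {
    v <- signif(track$values[[ch]], 6)
    r <- rle(v)
    endbin <- cumsum(r$lengths)
    startbin <- c(1L, endbin[-length(endbin)] + 1L)
    starts0 <- (startbin - 1L) * track$binsize
    ends0 <- pmin(endbin * track$binsize, sl[[ch]])
    data.frame(chrom = ch, start0 = starts0, end0 = as.numeric(ends0),
               value = r$values)
  })
  df <- do.call(rbind, pieces)
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start0),
                   as.integer(df$end0), sprintf("%.6g", df$value))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Intervals must be aligned to the requested bin grid (start on a bin
#' boundary; end on a boundary or at the chromosome end) and must not
#' overlap. Bases not covered by any interval get value 0.
#'
#' @param path bedGraph file path.
#' @param binsize bin width in bp of the resulting track.
#' @param genome `Seqinfo` coordinate frame.
#' @param provenance provenance tag to stamp on the track (bedGraph itself
#'   does not record normalization history); defaults to `"raw"`.
#' @return a `CoverageTrack`.
#' @export
read_bedgraph <- function(path, binsize, genome, provenance = "raw") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  unknown <- setdiff(GenomeInfoDb::seqlevelsInUse(gr),
                     GenomeInfoDb::seqnames(genome))
  if (length(unknown))
    stopf("read_bedgraph: %s: unknown chromosome(s): %s", path,
          paste(unknown, collapse = ", "))
  sl <- GenomeInfoDb::seqlengths(genome)
  vals <- lapply(names(sl), function(ch) numeric(ceiling(sl[[ch]] / binsize)))
  names(vals) <- names(sl)
  for (ch in unique(as.character(GenomeInfoDb::seqnames(gr)))) {
    sub <- gr[GenomeInfoDb::seqnames(gr) == ch]
    s0 <- BiocGenerics::start(sub) - 1L
    e0 <- BiocGenerics::end(sub)
    o <- order(s0)
    if (any(e0[o][-length(o)] > s0[o][-1]))
      stopf("read_bedgraph: %s: overlapping intervals on %s", path, ch)
    if (any(e0 > sl[[ch]]))
      stopf("read_bedgraph: %s: interval beyond end of %s", path, ch)
    aligned <- s0 %% binsize == 0 & (e0 %% binsize == 0 | e0 == sl[[ch]])
    if (!all(aligned))
      stopf("read_bedgraph: %s: interval not aligned to %d-bp bins on %s",
            path, binsize, ch)
    for (i in seq_along(sub)) {
      bins <- (s0[i] %/% binsize + 1L):ceiling(e0[i] / binsize)
      vals[[ch]][bins] <- sub$score[i]
    }
  }
  coverage_track(vals, binsize, genome, provenance)
}
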