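# Per-gene RNA polymerase II traveling ratio (pausing statistic).

#' Promoter-proximal and gene-body windows of genes
#'
#' Strand-aware, in transcription direction: the promoter-proximal window
#' spans TSS - `promoter_up` to TSS + `promoter_down` (default -2 kb to
#' +500 bp around the gene start) and the gene body runs from
#' TSS + `promoter_down` + 1 to the gene end (polyA addition site). Windows
#' are clipped to the chromosome when the genes carry sequence lengths; a
#' gene whose body is empty after clipping is flagged unusable.
#'
#' @param genes gene models ([gene_models()]).
#' @param promoter_up,promoter_down promoter window extent in bp (defaults
#'   2000 and 500).
#' @return list with `promoter` and `body` (`GRanges` parallel to `genes`)
#'   and `usable` (logical vector).
#' @export
gene_windows <- function(genes, promoter_up = 2000, promoter_down = 500) {
  bare <- granges_clean(genes)  # windows are built unclipped, clipped below
  promoter <- GenomicRanges::promoters(bare, upstream = promoter_up,
                                       downstream = promoter_down)
  minus <- as.character(BiocGenerics::strand(genes)) == "-"
  bstart <- ifelse(minus, BiocGenerics::start(genes),
                   BiocGenerics::start(genes) + promoter_down)
  bend <- ifelse(minus, BiocGenerics::end(genes) - promoter_down,
                 BiocGenerics::end(genes))
  # genes too short for a body window get an empty range and usable = FALSE
  body <- GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(genes)),
                                 IRanges::IRanges(bstart,
                                                  pmax(bend, bstart - 1L)),
                                 strand = BiocGenerics::strand(genes))
  sl <- GenomeInfoDb::seqlengths(genes)
  if (!all(is.na(sl))) {
    promoter <- clip_to_chrom(promoter, sl)
    body <- clip_to_chrom(body, sl)
  }
  usable <- BiocGenerics::width(body) > 0 & BiocGenerics::width(promoter) > 0
  list(promoter = promoter, body = body, usable = usable)
}

#' @noRd
clip_to_chrom <- function(gr, sl) {
  lens <- sl[as.character(GenomeInfoDb::seqnames(gr))]
  s <- pmax(BiocGenerics::start(gr), 1)
  e <- pmin(BiocGenerics::end(gr), lens)
  # keep ranges representable even when fully clipped out (width 0 -> flag)
  bad <- s > e
  e[bad] <- s[bad] - 1
  GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(gr)),
                         IRanges::IRanges(s, width = pmax(0, e - s + 1)),
                         strand = BiocGenerics::strand(gr))
}

#' Fragment density of a region in RPKM
#'
#' Reads per kilobase of region per million library fragments, with
#' fragments assigned to the region by midpoint:
#' `count / (region_kb * library_size_millions)`.
#'
#' @param frags fragment `GRanges`.
#' @param region single-range `GRanges`.
#' @param library_size library fragment count; defaults to `length(frags)`.
#' @return RPKM value.
#' @export
region_rpkm <- function(frags, region, library_size = length(frags)) {
  stopifnot(length(region) == 1)
  if (BiocGenerics::width(region) <= 0)
    stopf("region_rpkm: zero-length region")
  if (library_size <= 0) stopf("region_rpkm: library size must be positive")
  n <- GenomicRanges::countOverlaps(region, fragment_midpoints(frags),
                                    ignore.strand = TRUE)
  as.numeric(n) / (BiocGenerics::width(region) / 1e3 * library_size / 1e6)
}

#' Traveling ratios for a set of genes
#'
#' For each usable gene, computes the promoter-proximal and gene-body
#' PolII densities (RPKM; [gene_windows()], midpoint assignment) and the
#' traveling ratio. The default definition is the promoter fraction
#' `TR = d_p / (d_p + d_b)`, under which a uniformly covered (unpaused)
#' gene scores 0.5 and a gene with 3x promoter density scores 0.75; higher
#' values indicate promoter-proximal accumulation (pausing). The
#' alternative `"density_ratio"` definition divides the promoter density by
#' the density of the combined promoter+body region.
#'
#' Genes with promoter or body RPKM below `min_rpkm` (default 1) fail the
#' expression filter; by default only passing genes are returned.
#'
#' @param frags PolII S5P fragment `GRanges`.
#' @param genes gene models.
#' @param min_rpkm expression filter threshold in RPKM (default 1).
#' @param promoter_up,promoter_down promoter window (see [gene_windows()]).
#' @param definition `"fraction"` (default) or `"density_ratio"`.
#' @param filter drop non-passing records (default `TRUE`); losses are
#'   reported via a message.
#' @return `data.frame` with one row per gene: `gene_id`,
#'   `promoter_count`, `body_count`, `promoter_rpkm`, `body_rpkm`, `tr`,
#'   `passed_filter`.
#' @export
tr_table <- function(frags, genes, min_rpkm = 1, promoter_up = 2000,
                     promoter_down = 500,
                     definition = c("fraction", "density_ratio"),
                     filter = TRUE) {
  definition <- match.arg(definition)
  win <- gene_windows(genes, promoter_up, promoter_down)
  mids <- fragment_midpoints(frags)
  libsize <- length(frags)
  if (libsize == 0) stopf("tr_table: empty fragment library")
  pc <- GenomicRanges::countOverlaps(win$promoter, mids, ignore.strand = TRUE)
  bc <- GenomicRanges::countOverlaps(win$body, mids, ignore.strand = TRUE)
  wp <- BiocGenerics::width(win$promoter)
  wb <- BiocGenerics::width(win$body)
  rpkm <- function(n, w) ifelse(w > 0, n / (w / 1e3 * libsize / 1e6), NA_real_)
  prpkm <- rpkm(pc, wp)
  brpkm <- rpkm(bc, wb)
  tr <- switch(definition,
    fraction = ifelse(prpkm + brpkm > 0, prpkm / (prpkm + brpkm), NA_real_),
    density_ratio = {
      whole <- (pc + bc) / ((wp + wb) / 1e3 * libsize / 1e6)
      ifelse(whole > 0, prpkm / whole, NA_real_)
    })
  out <- data.frame(gene_id = genes$gene_id,
                    promoter_count = as.integer(pc),
                    body_count = as.integer(bc),
                    promoter_rpkm = prpkm, body_rpkm = brpkm, tr = tr,
                    passed_filter = win$usable & !is.na(tr) &
                      prpkm >= min_rpkm & brpkm >= min_rpkm)
  out <- out[win$usable, , drop = FALSE]
  if (filter) {
    lost <- sum(!out$passed_filter)
    if (lost)
      message(sprintf("tr_table: %d gene(s) below the %g-RPKM filter", lost,
                      min_rpkm))
    out <- out[out$passed_filter, , drop = FALSE]
    if (!nrow(out)) warning("tr_table: no gene passed the expression filter")
  }
  rownames(out) <- NULL
  out
}

#' Traveling ratio of a single gene
#'
#' Convenience wrapper around [tr_table()] for one gene; returns the
#' unfiltered record.
#' @inheritParams tr_table
#' @param gene a single gene model.
#' @export
traveling_ratio <- function(frags, gene, promoter_up = 2000,
                            promoter_down = 500,
                            definition = c("fraction", "density_ratio")) {
  stopifnot(length(gene) == 1)
  tr_table(frags, gene, promoter_up = promoter_up,
           promoter_down = promoter_down, definition = match.arg(definition),
           filter = FALSE)
}

#' Compare traveling-ratio distributions between two conditions
#'
#' Two-sample Kolmogorov-Smirnov test on the per-gene traveling ratios
#' (the canonical distance between the two cumulative distribution
#' functions), with a Mann-Whitney option. The empirical CDFs of both
#' conditions are returned as tabulated curves for plotting.
#'
#' @param table_a,table_0 `data.frame`s from [tr_table()] (condition vs
#'   reference).
#' @param test `"ks"` (default) or `"wilcox"`.
#' @return list of class `TRComparison`: `statistic` (KS D in \[0,1\], or
#'   the Wilcoxon statistic), `p`, `n_a`, `n_0`, `cdf` (data.frame with
#'   `tr`, `cdf_a`, `cdf_0`).
#' @export
compare_tr <- function(table_a, table_0, test = c("ks", "wilcox")) {
  test <- match.arg(test)
  if (!nrow(table_a) || !nrow(table_0))
    stopf("compare_tr: empty traveling-ratio table")
  a <- table_a$tr; b <- table_0$tr
  res <- if (test == "ks")
    suppressWarnings(stats::ks.test(a, b))
  else suppressWarnings(stats::wilcox.test(a, b))
  grid <- sort(unique(c(a, b)))
  structure(list(statistic = unname(res$statistic), p = res$p.value,
                 n_a = length(a), n_0 = length(b),
                 cdf = data.frame(tr = grid,
                                  cdf_a = stats::ecdf(a)(grid),
                                  cdf_0 = stats::ecdf(b)(grid)),
                 test = test),
            class = "TRComparison")
}

#' @export
print.TRComparison <- function(x, ...) {
  cat(sprintf("TRComparison (%s): statistic = %.4g, p = %.4g (n = %d vs %d)\n",
              x$test, x$statistic, x$p, x$n_a, x$n_0))
  invisible(x)
}
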