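# chromprofiler

Quantitative analysis of chromatin time-course sequencing experiments in
R. When a chromatin regulator is induced and ChIP-seq, MNase-seq and
nascent RNA-seq libraries are collected along the time course, the
questions are quantitative: did nucleosome occupancy at transcription
start sites change, did RNA polymerase II redistribute between promoters
and gene bodies, is a profile difference larger than replicate and
sampling noise? chromprofiler implements the analysis stack for those
questions:

* **Coverage normalization** — binned coverage tracks from aligned
  fragments (with 5'-end extension or read centering), RPGC scaling to 1×
  genome coverage, depth-normalized input subtraction, and control-ratio
  (e.g. H3) normalization.
* **Peak-set algebra** — co-bound unions of two factors' peaks, replicate
  consensus, all-dataset intersection, ENCODE-style blacklist filtering,
  enhancer/promoter classification from histone-mark peak sets, and
  input-subtracted counting over peaks.
* **Aggregate (metagene) profiles** — reference-point signal matrices
  (5-bp bins, ±1500 bp), per-location and flank-baseline normalization,
  bootstrap 95% confidence intervals (5000 iterations, locations
  resampled, normalization re-run per iteration), empirical p-values at
  the feature center, and the unnormalized ±1.96 s.e.m. variant for
  nascent RNA.
* **Traveling ratio** — the PolII pausing statistic per gene,

  $$\mathrm{TR} = \frac{d_p}{d_p + d_b},$$

  where $d_p$ is the S5P density (RPKM) in the promoter-proximal window
  (TSS −2 kb..+500 bp) and $d_b$ in the gene body (+501 bp..gene end);
  an unpaused, uniformly covered gene gives TR = 0.5 and three-fold
  promoter accumulation gives TR = 0.75. Genes pass a 1-RPKM filter in
  both windows; condition shifts are tested with a two-sample KS test on
  the TR distributions.
* **Synthetic data** — a seeded generator for genomes, gene models, peak
  sets and fragment libraries (peak-enriched ChIP with matched input,
  positioned-nucleosome MNase with condition-dependent occupancy,
  promoter-paused PolII, 5'-weighted stranded nascent RNA), so the whole
  pipeline runs end to end with no downloads.

Everything is built on Bioconductor containers (`GRanges`, `Seqinfo`) and
standard formats (BED6, GTF, bedGraph) via rtracklayer.

## Worked example

Simulate a PolII S5P library over 30 genes, half strongly paused
(promoter density 9 vs body 3 → true TR 0.75) and half unpaused (3 vs 3 →
true TR 0.5), then recover per-gene traveling ratios and compare the two
groups:

```r
library(chromprofiler)

cfg   <- sim_config(seed = 1, chrom_lengths = c(chrS1 = 5e5),
                    n_genes = 30, replicates = 1)
gg    <- make_genome_and_genes(cfg)
spec  <- pausing_spec(gg$genes$gene_id, d_p = rep(c(9, 3), 15), d_b = 3)
frags <- simulate_polii(gg$genes, spec, cfg)[[1]]
tab   <- tr_table(frags, gg$genes)
head(tab, 4)
#>    gene_id promoter_count body_count promoter_rpkm body_rpkm        tr passed_filter
#> 1 gene0001            682       1468     12461.497  3978.773 0.7579862          TRUE
#> 2 gene0002            351        968      2442.249  2616.674 0.4827606          TRUE
#> 3 gene0003           1170        946      8140.829  2017.360 0.8014055          TRUE
#> 4 gene0004           1137       1593      7911.216  3165.787 0.7142019          TRUE
```

Gene 1 was simulated paused and is recovered near TR 0.75; gene 2 was
simulated unpaused and lands near 0.5 (the spread is binomial sampling
noise at ~2000 fragments per gene). The group comparison separates the
two TR distributions completely:

```r
paused   <- tab[spec$true_tr[match(tab$gene_id, spec$gene_id)] == 0.75, ]
unpaused <- tab[spec$true_tr[match(tab$gene_id, spec$gene_id)] == 0.50, ]
compare_tr(paused, unpaused)
#> TRComparison (ks): statistic = 1, p = 1.289e-08 (n = 15 vs 15)
```

`run_demo(outdir)` runs the full pipeline — fixture generation, BED/GTF
round trips, RPGC + input subtraction, peak consensus and blacklist
filtering, bootstrap MNase profiles with a center test, nascent s.e.m.
profiles, and TR tables for a paused vs unpaused condition — and writes
tables, bedGraph tracks and a `summary.json` into the run directory.

## Documentation

`vignette("chromprofiler-methods")` describes the statistical model of
every stage, all tunable parameters with their defaults, the design
decisions, and what the synthetic generator does and does not emulate.
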