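# marscan

Genome-wide characterization of **matrix attachment regions (MARs)** —
the genomic segments that stay bound to the nuclear matrix after
chromatin extraction and are thought to anchor the bases of chromatin
loops. Given two replicate peak sets from a MAR-DNA sequencing
experiment, a reference genome and a gene annotation, marscan:

* reconciles the replicates into **common peaks** (one interval per
  maximal group of cross-replicate overlaps of ≥ 50 bp; union span
  reported, intersection kept as metadata) and measures replicate
  agreement as the Pearson correlation of 500 bp-windowed tag counts;
* computes MAR interval statistics — size distribution (median,
  fraction under 600 bp), midpoint-to-midpoint **inter-MAR distances**
  per chromosome arm (a chromatin loop-size proxy), and per-arm density
  (kb of DNA per MAR, genes per MAR);
* scans MAR sequences for the classic MAR signatures: the **ATC rule**
  (≥ 20 consecutive A/T/C on one strand with no intervening G), **ORI
  motifs** (ATTA, ATTTA, ATTTTA and reverse complements), AT-rich
  stretches, and a configurable registry of curved-DNA, kinked-DNA,
  topoisomerase II and BUR patterns;
* detects **simple sequence repeats** as maximal perfect tandem tracts
  ≥ 12 bp over the 501 non-redundant unit classes (unit lengths 1–6,
  canonicalized under rotation and reverse complement) and reports
  MAR association and fold enrichment per class;
* associates MARs with **transposable elements** by affine-gap local
  alignment (identity ≥ 90% over ≥ 100 aligned columns, both strands);
* classifies MARs against the annotation (5'UTR / 3'UTR / exon /
  intron / intergenic by midpoint, with precedence), builds
  TSS-relative metaprofiles (±1 kb, 50 bp bins), and quantifies overlap
  with stalled/active Pol II promoters, chromatin-domain boundaries and
  expression tiers of exonic-MAR host genes;
* ships a **synthetic-universe generator** with planted ground truth
  (genome, annotation, MARs with controlled feature content, jittered
  replicate peaks, tags, SSR/TE plantings, expression tiers) so the
  entire pipeline is exercisable and verifiable offline.

See `vignettes/marscan-methods.Rmd` for the model, parameter and design
discussion.

## Worked example

Build a synthetic universe and run the pipeline on the files it writes:

```r
library(marscan)
cfg <- synthetic_config(seed = 42)           # 3 x 300 kb genome, 200 MARs
u   <- generate_universe(cfg, outdir = file.path(tempdir(), "sim"))
rep <- run_pipeline(list(
  rep1 = u$files[["rep1"]], rep2 = u$files[["rep2"]],
  chrom_sizes = u$files[["chrom_sizes"]], genome = u$files[["genome"]],
  gff3 = u$files[["gff3"]], expression = u$files[["expression"]],
  boundaries = u$files[["boundaries"]]
), quiet = TRUE)
print(rep)
#> MAR pipeline report
#>   common peaks: 147 (84.5% of rep1)
#>   MARs: 147, median size 425 bp
#>   context fractions: utr5 0.00, utr3 0.01, exon 0.04, intron 0.02, intergenic 0.93
print(rep$size_stats)
#> MAR set: n = 147, total 0.065 Mb, median size 425 bp
#>   fraction < 600 bp: 0.871
head(rep$features)
#>     feature n_mars_with_feature  frac_mars
#> 1  atc_rule                 138 0.93877551
#> 2 ori_motif                 141 0.95918367
#> 3   at_rich                  78 0.53061224
#> 4    curved                  74 0.50340136
#> 5    kinked                  51 0.34693878
#> 6    topoII                   9 0.06122449
```

Reading the output: 147 of the 200 planted MARs were placed in both
replicates and recovered as common peaks; the median reconciled size
(425 bp) sits slightly above the planted 400 bp median because the
union span inherits the ±25 bp peak jitter; 87% of MARs are shorter
than 600 bp; and the per-feature fractions recover the planted mix
(ATC rule 0.94, ORI 0.95 planting probabilities, measured here over the
147 reconciled peaks). On a real data set, replace the file paths with
your replicate peak BEDs, genome FASTA, GFF3 annotation and auxiliary
BED/TSV inputs — `?run_pipeline` lists every recognized entry.

A command-line wrapper with per-stage subcommands (`reconcile`,
`stats`, `features`, `ssr`, `te`, `context`, `simulate`, `run`) is
installed at `inst/scripts/marscan`.

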