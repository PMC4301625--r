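#' Run the full MAR characterization pipeline
#'
#' Orchestrates the analysis stages in dependency order: replicate
#' reconciliation, MAR interval statistics, genomic-context
#' classification, sequence-feature enrichment, SSR enrichment, TE
#' association, and regulatory-element overlaps. Stages whose inputs
#' are absent from the configuration are skipped; every stage's record
#' counts are logged and the report carries a provenance block
#' (inputs, parameters, file digests, package version).
#'
#' @param config a named list. Recognized input entries (all file
#'   paths unless noted): `rep1`, `rep2` (replicate peak BEDs) OR
#'   `mars` (a reconciled MAR BED); `chrom_sizes` (two-column TSV);
#'   `genome` (FASTA); `gff3` or `gene_table` (annotation); `tags1`,
#'   `tags2` (tag BEDs); `promoters`, `boundaries` (BEDs; promoter
#'   names label stalled/active); `te_fasta`, `te_copies` (TE inputs);
#'   `expression` (TSV gene_id/tier). Parameter entries (with
#'   defaults): `min_overlap` (50), `window` (500), `ssr_min_len`
#'   (12), `min_identity` (0.9), `min_aln_len` (100),
#'   `min_genomic_loci` (100), `tss_flank` (1000), `tss_bin` (50),
#'   `size_thresholds` (600).
#' @param outdir optional directory for per-stage TSV/BED outputs.
#' @param quiet suppress per-stage log messages.
#' @return list of class `mar_report` with one element per executed
#'   stage plus `provenance`.
#' @export
run_pipeline <- function(config, outdir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  p <- function(name, default = NULL) config[[name]] %||% default
  report <- list()
  prov <- list(
    package = "marscan",
    version = as.character(packageVersion("marscan")),
    parameters = list(
      min_overlap = p("min_overlap", 50L),
      window = p("window", 500L),
      ssr_min_len = p("ssr_min_len", 12L),
      min_identity = p("min_identity", 0.90),
      min_aln_len = p("min_aln_len", 100L),
      min_genomic_loci = p("min_genomic_loci", 100L),
      tss_flank = p("tss_flank", 1000L),
      tss_bin = p("tss_bin", 50L),
      size_thresholds = p("size_thresholds", 600L)
    ),
    inputs = list()
  )
  infile <- function(name) {
    f <- p(name)
    if (!is.null(f)) {
      if (!file.exists(f)) {
        stop("configuration error: input '", name, "' does not exist: ", f)
      }
      prov$inputs[[name]] <<- list(path = f,
                                   md5 = unname(tools::md5sum(f)))
    }
    f
  }
  # validate all declared inputs up front, before any computation
  for (nm in c("rep1", "rep2", "mars", "chrom_sizes", "genome", "gff3",
               "gene_table", "tags1", "tags2", "promoters", "boundaries",
               "te_fasta", "te_copies", "expression")) {
    infile(nm)
  }
  if (is.null(p("mars")) && (is.null(p("rep1")) || is.null(p("rep2")))) {
    stop("configuration error: need either 'mars' or both 'rep1' and 'rep2'")
  }

  chrom_sizes <- if (!is.null(p("chrom_sizes")))
    read_chrom_sizes(p("chrom_sizes")) else NULL

  # -- reconcile ------------------------------------------------------------
  if (!is.null(p("rep1")) && !is.null(p("rep2"))) {
    rep1 <- read_bed(p("rep1"))
    rep2 <- read_bed(p("rep2"))
    say("reconcile: %d + %d replicate peaks", nrow(rep1), nrow(rep2))
    mars <- common_peaks(rep1, rep2,
                         min_overlap = prov$parameters$min_overlap)
    n_union <- nrow(unique_intervals(rep1)) + nrow(unique_intervals(rep2)) -
      nrow(mars)
    report$reconciliation <- list(
      n_rep1 = nrow(rep1), n_rep2 = nrow(rep2),
      n_common = nrow(mars),
      frac_of_rep1 = nrow(mars) / nrow(rep1),
      frac_of_rep2 = nrow(mars) / nrow(rep2),
      frac_of_union = nrow(mars) / n_union
    )
    say("reconcile: %d common peaks", nrow(mars))
    if (!is.null(p("tags1")) && !is.null(p("tags2")) &&
        !is.null(chrom_sizes)) {
      report$reconciliation$tag_correlation <- windowed_tag_correlation(
        read_tags(p("tags1")), read_tags(p("tags2")), chrom_sizes,
        window = prov$parameters$window
      )
      say("reconcile: windowed tag correlation %.4f",
          report$reconciliation$tag_correlation)
    }
  } else {
    mars <- read_bed(p("mars"))
    say("input: %d MARs", nrow(mars))
  }
  report$mars <- mars

  # -- interval statistics --------------------------------------------------
  report$size_stats <- size_stats(
    mars, thresholds = prov$parameters$size_thresholds
  )
  report$inter_mar <- inter_mar_distances(mars)
  if (!is.null(chrom_sizes)) {
    gene_counts <- NULL
    if (!is.null(p("gff3")) || !is.null(p("gene_table"))) {
      genes <- if (!is.null(p("gff3"))) read_gff3_genes(p("gff3"))
               else read_gene_table(p("gene_table"))
      gene_counts <- table(genes$genes$chrom)
    }
    report$density <- chromosome_density_table(mars, chrom_sizes,
                                               gene_counts = gene_counts)
  }

  # -- genomic context ------------------------------------------------------
  if (!is.null(p("gff3")) || !is.null(p("gene_table"))) {
    genes <- if (!is.null(p("gff3"))) read_gff3_genes(p("gff3"))
             else read_gene_table(p("gene_table"))
    report$context <- classify_mars(mars, genes)
    report$tss_profile <- tss_profile(
      mars, genes, flank = prov$parameters$tss_flank,
      bin = prov$parameters$tss_bin
    )
    say("context: %s", paste(sprintf("%s %.2f", context_categories,
                                     report$context$fractions),
                             collapse = ", "))
    if (!is.null(p("expression"))) {
      expr <- read.table(p("expression"), sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
      lab <- report$context$labels
      ex <- lab$category == "exon" & !is.na(lab$gene_id)
      exonic <- data.frame(
        mar = sprintf("%s:%d-%d", lab$chrom[ex], lab$start[ex], lab$end[ex]),
        gene_id = lab$gene_id[ex], stringsAsFactors = FALSE
      )
      report$exonic_expression <-
        exonic_expression_association(exonic, expr)
    }
  }

  # -- sequence features ----------------------------------------------------
  if (!is.null(p("genome"))) {
    genome <- read_genome(p("genome"))
    report$features <- feature_enrichment_table(mars, genome)
    say("features: %s",
        paste(sprintf("%s %.2f", report$features$feature,
                      report$features$frac_mars), collapse = ", "))

    # -- SSR enrichment -----------------------------------------------------
    loci <- ssr_loci(genome, min_len = prov$parameters$ssr_min_len)
    report$ssr <- ssr_mar_association(
      loci, mars, genome_bp = sum(Biostrings::width(genome)),
      min_genomic_loci = prov$parameters$min_genomic_loci
    )
    say("ssr: %d genomic loci, %d enriched classes reported",
        nrow(loci), nrow(report$ssr))

    # -- TE association -----------------------------------------------------
    if (!is.null(p("te_fasta"))) {
      te_seqs <- read_genome(p("te_fasta"))
      hits <- te_mar_hits(te_seqs, mar_sequences(mars, genome),
                          min_identity = prov$parameters$min_identity,
                          min_len = prov$parameters$min_aln_len)
      report$te_hits <- hits
      if (!is.null(p("te_copies"))) {
        report$te_summary <- te_summary(
          hits, read_bed(p("te_copies")), mars,
          te_lengths = setNames(Biostrings::width(te_seqs),
                                names(te_seqs))
        )
      }
      say("te: %d hits", nrow(hits))
    }
  }

  # -- regulatory overlaps --------------------------------------------------
  if (!is.null(p("promoters"))) {
    report$polII <- polII_overlap(mars, read_bed(p("promoters")))
  }
  if (!is.null(p("boundaries"))) {
    report$boundaries <- boundary_overlap(mars, read_bed(p("boundaries")))
  }

  report$provenance <- prov
  class(report) <- "mar_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write the per-stage files of a pipeline report
#'
#' @param report a `mar_report` from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  tsv <- function(df, f) {
    write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_bed(report$mars, p("mars.bed"))
  if (!is.null(report$density)) tsv(report$density, "density.tsv")
  if (!is.null(report$features)) tsv(report$features, "features.tsv")
  if (!is.null(report$ssr)) tsv(report$ssr, "ssr_enrichment.tsv")
  if (!is.null(report$te_hits)) tsv(report$te_hits, "te_hits.tsv")
  if (!is.null(report$te_summary)) tsv(report$te_summary, "te_summary.tsv")
  if (!is.null(report$context)) tsv(report$context$labels, "context.tsv")
  if (!is.null(report$polII)) tsv(report$polII, "polII_overlap.tsv")
  summary <- list(
    reconciliation = report$reconciliation,
    size_stats = unclass(report$size_stats)[c("n_mars", "total_bp",
                                              "median_size", "frac_below")],
    inter_mar = report$inter_mar[c("mean", "frac_below")],
    context_fractions = as.list(report$context$fractions),
    boundaries = report$boundaries,
    exonic_expression = report$exonic_expression[c("fraction", "n_used")],
    provenance = report$provenance
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(outdir)
}

#' @export
print.mar_report <- function(x, ...) {
  cat("MAR pipeline report\n")
  if (!is.null(x$reconciliation)) {
    cat(sprintf("  common peaks: %d (%.1f%% of rep1)\n",
                x$reconciliation$n_common,
                100 * x$reconciliation$frac_of_rep1))
  }
  cat(sprintf("  MARs: %d, median size %g bp\n",
              x$size_stats$n_mars, x$size_stats$median_size))
  if (!is.null(x$context)) {
    cat("  context fractions:",
        paste(sprintf("%s %.2f", names(x$context$fractions),
                      x$context$fractions), collapse = ", "), "\n")
  }
  invisible(x)
}
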