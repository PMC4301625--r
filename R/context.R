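#' Build a gene-model table
#'
#' The annotation container used for context classification: a list
#' with `$genes` (one row per gene: `gene_id`, `chrom`, `strand`,
#' `start`, `end`, `tss`) and `$features` (one row per exon/UTR
#' interval: `gene_id`, `type` in \{exon, utr5, utr3\}, `chrom`,
#' `start`, `end`; union over isoforms). Coordinates are 0-based
#' half-open; the TSS is `start` on the plus strand and `end - 1` on
#' the minus strand.
#'
#' @param genes data frame with `gene_id`, `chrom`, `strand`, `start`,
#'   `end`.
#' @param features data frame with `gene_id`, `type`, `chrom`,
#'   `start`, `end` (may be empty).
#' @return list of class `gene_models`.
#' @export
gene_models <- function(genes, features = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)),
            all(genes$strand %in% c("+", "-")))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (is.null(features)) {
    features <- data.frame(gene_id = character(), type = character(),
                           chrom = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(all(features$type %in% c("exon", "utr5", "utr3")))
  structure(list(genes = genes, features = features),
            class = "gene_models")
}

#' Read gene models from GFF3
#'
#' Consumes gene / mRNA / exon / five_prime_UTR / three_prime_UTR
#' records; exons and UTRs of all isoforms are pooled per gene
#' (union-over-isoforms handling). Parent attributes are resolved one
#' level (feature -> mRNA -> gene).
#'
#' @param path GFF3 file path.
#' @return a [gene_models()] object.
#' @export
read_gff3_genes <- function(path) {
  gff <- rtracklayer::import(path)
  typ <- as.character(gff$type)
  ids <- as.character(gff$ID)
  getparent <- function(x) {
    p <- gff$Parent
    vapply(seq_along(p), function(i) {
      v <- p[[i]]
      if (length(v)) as.character(v[[1L]]) else NA_character_
    }, "")
  }
  parent <- getparent(gff)
  is_gene <- typ == "gene"
  genes <- data.frame(
    gene_id = ids[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gff))[is_gene],
    strand = as.character(GenomicRanges::strand(gff))[is_gene],
    start = GenomicRanges::start(gff)[is_gene] - 1L,
    end = GenomicRanges::end(gff)[is_gene],
    stringsAsFactors = FALSE
  )
  # transcript -> gene map
  is_tx <- typ %in% c("mRNA", "transcript")
  tx2gene <- setNames(parent[is_tx], ids[is_tx])
  fmap <- c(exon = "exon", five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  is_feat <- typ %in% names(fmap)
  fparent <- parent[is_feat]
  fg <- ifelse(fparent %in% names(tx2gene), tx2gene[fparent], fparent)
  features <- data.frame(
    gene_id = unname(fg),
    type = unname(fmap[typ[is_feat]]),
    chrom = as.character(GenomicRanges::seqnames(gff))[is_feat],
    start = GenomicRanges::start(gff)[is_feat] - 1L,
    end = GenomicRanges::end(gff)[is_feat],
    stringsAsFactors = FALSE
  )
  features <- unique(features)
  gene_models(genes, features)
}

#' Read gene models from a simplified gene table (TSV)
#'
#' Fallback annotation format: a tab-separated table with header
#' columns `gene_id`, `chrom`, `strand`, `start`, `end`. No exon
#' structure; every gene body counts as a single exon.
#'
#' @param path TSV file path.
#' @return a [gene_models()] object.
#' @export
read_gene_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  gene_models(df, data.frame(
    gene_id = df$gene_id, type = "exon", chrom = df$chrom,
    start = df$start, end = df$end, stringsAsFactors = FALSE
  ))
}

context_categories <- c("utr5", "utr3", "exon", "intron", "intergenic")

#' Classify MARs by genomic context
#'
#' Midpoint-based classification against the annotation: each MAR's
#' midpoint is assigned to exactly one of utr5, utr3, exon, intron or
#' intergenic. When overlapping annotations cover a midpoint the
#' precedence is utr5 > utr3 > exon > intron; a midpoint inside a gene
#' span but in no exon/UTR is intronic; a midpoint in no gene span is
#' intergenic.
#'
#' @param mars an `interval_set`.
#' @param genes a [gene_models()] object.
#' @return list with `labels` (per-MAR data frame: `chrom`, `start`,
#'   `end`, `midpoint`, `category`, `gene_id` of the assigning gene or
#'   NA), `fractions` (named vector over the five categories, summing
#'   to 1), `mean_size` (mean MAR length per category) and
#'   `noncoding_frac` (intergenic+intron, with and without UTRs).
#' @export
classify_mars <- function(mars, genes) {
  stopifnot(inherits(genes, "gene_models"))
  n <- nrow(mars)
  mid <- interval_midpoint(mars$start, mars$end)
  midg <- GenomicRanges::GRanges(mars$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  assign_from <- function(df, ids, cat) {
    if (!nrow(df)) return()
    g <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start + 1L, df$end))
    ov <- GenomicRanges::findOverlaps(midg, g, select = "first")
    hit <- !is.na(ov) & category == "intergenic"
    category[hit] <<- cat
    gene_id[hit] <<- ids[ov[hit]]
  }
  f <- genes$features
  # precedence is enforced by assignment order (first assignment wins)
  assign_from(f[f$type == "utr5", , drop = FALSE],
              f$gene_id[f$type == "utr5"], "utr5")
  assign_from(f[f$type == "utr3", , drop = FALSE],
              f$gene_id[f$type == "utr3"], "utr3")
  assign_from(f[f$type == "exon", , drop = FALSE],
              f$gene_id[f$type == "exon"], "exon")
  assign_from(genes$genes, genes$genes$gene_id, "intron")
  labels <- data.frame(
    chrom = mars$chrom, start = mars$start, end = mars$end,
    midpoint = mid, category = category, gene_id = gene_id,
    stringsAsFactors = FALSE
  )
  fr <- vapply(context_categories, function(k) mean(category == k), 0)
  len <- mars$end - mars$start
  msz <- vapply(context_categories, function(k) {
    if (any(category == k)) mean(len[category == k]) else NA_real_
  }, 0)
  list(
    labels = labels,
    fractions = fr,
    mean_size = msz,
    noncoding_frac = c(
      excluding_utrs = unname(fr["intron"] + fr["intergenic"]),
      including_utrs = unname(fr["intron"] + fr["intergenic"] +
                                fr["utr5"] + fr["utr3"])
    )
  )
}

#' TSS-relative MAR profile
#'
#' Bins the strand-oriented offsets of MAR midpoints around every TSS
#' (downstream positive). In the default "all" mode a midpoint within
#' the flank of several TSSs contributes to each; "nearest" assigns
#' each MAR to its single nearest TSS only.
#'
#' @param mars an `interval_set`.
#' @param genes a [gene_models()] object.
#' @param flank half-width of the profile in bp (default 1000).
#' @param bin bin width in bp (default 50); must divide `2*flank`.
#' @param mode "all" or "nearest".
#' @param density when TRUE, counts are divided by the total count
#'   (per-bin density normalization).
#' @return list of class `tss_profile` with `breaks` (bin edges from
#'   -flank to +flank), `mids`, `counts`, `mode_offset` (midpoint of
#'   the maximal bin) and `n_contributions`.
#' @export
tss_profile <- function(mars, genes, flank = 1000L, bin = 50L,
                        mode = c("all", "nearest"), density = FALSE) {
  mode <- match.arg(mode)
  stopifnot(flank > 0L, (2L * flank) %% bin == 0L)
  g <- genes$genes
  mid <- interval_midpoint(mars$start, mars$end)
  offs <- list()
  for (i in seq_len(nrow(g))) {
    same <- which(mars$chrom == g$chrom[i])
    if (!length(same)) next
    d <- mid[same] - g$tss[i]
    if (g$strand[i] == "-") d <- -d
    offs <- c(offs, list(data.frame(mar = same, off = d)))
  }
  offs <- if (length(offs)) do.call(rbind, offs) else
    data.frame(mar = integer(), off = numeric())
  offs <- offs[abs(offs$off) <= flank, , drop = FALSE]
  if (mode == "nearest" && nrow(offs)) {
    offs <- offs[order(offs$mar, abs(offs$off)), , drop = FALSE]
    offs <- offs[!duplicated(offs$mar), , drop = FALSE]
  }
  breaks <- seq(-flank, flank, by = bin)
  idx <- pmin(pmax(floor((offs$off + flank) / bin) + 1L, 1L),
              length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  mids <- head(breaks, -1L) + bin / 2
  structure(list(
    breaks = breaks, mids = mids,
    counts = if (density && sum(counts) > 0) counts / sum(counts) else counts,
    mode_offset = if (sum(counts) > 0) mids[which.max(counts)] else NA_real_,
    n_contributions = nrow(offs)
  ), class = "tss_profile")
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf("TSS profile: %d contributions, mode at %+g bp\n",
              x$n_contributions, x$mode_offset))
  invisible(x)
}

#' Overlap of labeled Pol II promoter regions with MARs
#'
#' @param mars an `interval_set`.
#' @param promoters an `interval_set` of promoter windows (TSS +/- 300
#'   bp) whose `name` column labels each as e.g. "stalled" or
#'   "active".
#' @return data frame with columns `label`, `n_promoters`,
#'   `n_overlapping`, `frac_overlapping` (>= 1 bp overlap rule).
#' @export
polII_overlap <- function(mars, promoters) {
  labs <- ifelse(is.na(promoters$name), "unlabeled", promoters$name)
  lv <- union(unique(promoters$chrom), unique(mars$chrom))
  ov <- if (nrow(mars)) {
    GenomicRanges::countOverlaps(as_granges(promoters, lv),
                                 as_granges(mars, lv)) > 0L
  } else {
    rep(FALSE, nrow(promoters))
  }
  out <- aggregate(cbind(n_promoters = rep(1L, length(labs)),
                         n_overlapping = as.integer(ov)),
                   by = list(label = labs), FUN = sum)
  out$frac_overlapping <- out$n_overlapping / out$n_promoters
  out
}

#' Symmetric MAR / chromatin-boundary overlap accounting
#'
#' @param mars,boundaries `interval_set`s on the same assembly.
#' @return list with `n_mars_overlapping`, `frac_mars`,
#'   `n_boundaries_overlapping`, `frac_boundaries` (>= 1 bp rule, both
#'   directions).
#' @export
boundary_overlap <- function(mars, boundaries) {
  if (nrow(mars) == 0L || nrow(boundaries) == 0L) {
    return(list(n_mars_overlapping = 0L,
                frac_mars = if (nrow(mars)) 0 else NA_real_,
                n_boundaries_overlapping = 0L,
                frac_boundaries = if (nrow(boundaries)) 0 else NA_real_))
  }
  lv <- union(unique(mars$chrom), unique(boundaries$chrom))
  mg <- as_granges(mars, lv); bg <- as_granges(boundaries, lv)
  m_ov <- sum(GenomicRanges::countOverlaps(mg, bg) > 0L)
  b_ov <- sum(GenomicRanges::countOverlaps(bg, mg) > 0L)
  list(
    n_mars_overlapping = m_ov,
    frac_mars = m_ov / nrow(mars),
    n_boundaries_overlapping = b_ov,
    frac_boundaries = b_ov / nrow(boundaries)
  )
}

#' Expression association of exonic MARs
#'
#' Fraction of exonic MARs whose host gene sits in the moderate or
#' high expression tier. MARs whose gene has no tier are excluded from
#' the denominator and reported with a warning.
#'
#' @param exonic_mars data frame with columns `mar` (id) and `gene_id`.
#' @param expression data frame with columns `gene_id` and `tier`
#'   (one of "low", "moderate", "high").
#' @return list with `fraction`, `n_exonic`, `n_used`, `n_missing`,
#'   `missing` (gene ids without a tier).
#' @export
exonic_expression_association <- function(exonic_mars, expression) {
  stopifnot(all(c("mar", "gene_id") %in% names(exonic_mars)),
            all(c("gene_id", "tier") %in% names(expression)))
  stopifnot(all(expression$tier %in% c("low", "moderate", "high")))
  tier <- expression$tier[match(exonic_mars$gene_id, expression$gene_id)]
  missing <- is.na(tier)
  if (any(missing)) {
    warning(sum(missing), " exonic MAR(s) with no expression tier excluded")
  }
  used <- tier[!missing]
  list(
    fraction = if (length(used)) mean(used %in% c("moderate", "high"))
               else NA_real_,
    n_exonic = nrow(exonic_mars),
    n_used = length(used),
    n_missing = sum(missing),
    missing = unique(exonic_mars$gene_id[missing])
  )
}
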