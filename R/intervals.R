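#' Construct an interval set
#'
#' The universal interval container of the package: a data frame of
#' 0-based half-open genomic intervals (BED convention), sorted by
#' chromosome then start, with an optional `chrom_sizes` attribute.
#' Peaks, MARs, promoters, boundaries and SSR loci are all interval sets.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `start < end`.
#' @param name optional labels (recycled).
#' @param score optional numeric scores (recycled).
#' @param chrom_sizes optional named numeric vector of chromosome
#'   lengths in bp; when given, no interval may extend past its
#'   chromosome end.
#' @return a data frame of class `interval_set` with columns
#'   `chrom`, `start`, `end`, `name`, `score`.
#' @export
#' @examples
#' interval_set(c("2L", "2L"), c(100, 500), c(300, 900))
interval_set <- function(chrom, start, end, name = NA_character_,
                         score = NA_real_, chrom_sizes = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  if (n > 0L) {
    if (anyNA(start) || anyNA(end)) stop("NA coordinates in interval set")
    bad <- which(start < 0L | start >= end)
    if (length(bad)) {
      stop(sprintf(
        "invalid interval (need 0 <= start < end) at record %d: %s:%d-%d",
        bad[1L], chrom[bad[1L]], start[bad[1L]], end[bad[1L]]
      ))
    }
  }
  df <- data.frame(
    chrom = chrom, start = start, end = end,
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(chrom_sizes)) {
    stopifnot(!is.null(names(chrom_sizes)))
    known <- df$chrom %in% names(chrom_sizes)
    if (!all(known)) {
      stop("chromosome missing from chrom_sizes: ",
           paste(unique(df$chrom[!known]), collapse = ", "))
    }
    over <- df$end > chrom_sizes[df$chrom]
    if (any(over)) {
      i <- which(over)[1L]
      stop(sprintf("interval %s:%d-%d extends past chromosome end (%d bp)",
                   df$chrom[i], df$start[i], df$end[i],
                   as.integer(chrom_sizes[df$chrom[i]])))
    }
    attr(df, "chrom_sizes") <- chrom_sizes
  }
  class(df) <- c("interval_set", "data.frame")
  df
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set: %d intervals on %d chromosome(s), %d bp total\n",
              nrow(x), length(unique(x$chrom)), sum(x$end - x$start)))
  NextMethod()
}

#' Coerce to an interval set
#'
#' @param x a data frame with `chrom`, `start`, `end` (and optionally
#'   `name`, `score`) columns, or a `GRanges`.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return an `interval_set`.
#' @export
as_interval_set <- function(x, chrom_sizes = NULL) {
  if (inherits(x, "GRanges")) {
    return(interval_set(
      as.character(GenomicRanges::seqnames(x)),
      GenomicRanges::start(x) - 1L, GenomicRanges::end(x),
      name = if (!is.null(x$name)) x$name else NA_character_,
      score = if (!is.null(x$score)) x$score else NA_real_,
      chrom_sizes = chrom_sizes
    ))
  }
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  interval_set(x$chrom, x$start, x$end,
               name = x$name %||% NA_character_,
               score = x$score %||% NA_real_,
               chrom_sizes = chrom_sizes)
}

# internal: GRanges view of an interval set (1-based closed internally);
# pass the union of chromosome names as `seqlevels` when two sets are
# compared, so findOverlaps never sees disjoint sequence universes
as_granges <- function(x, seqlevels = NULL) {
  sn <- if (is.null(seqlevels)) x$chrom else
    factor(x$chrom, levels = seqlevels)
  GenomicRanges::GRanges(
    seqnames = sn,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Read a BED file as an interval set
#'
#' Accepts BED3+ (tab-separated, 0-based half-open). Columns beyond the
#' sixth are ignored; column 4 becomes `name`, column 5 `score`.
#'
#' @param path path to a BED file.
#' @param chrom_sizes optional named vector of chromosome lengths used
#'   to validate interval bounds.
#' @return an `interval_set`.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(interval_set(character(), integer(), integer(),
                        chrom_sizes = chrom_sizes))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1L]]
    stop(sprintf("malformed BED line %d in %s: fewer than 3 tab-separated fields",
                 bad, path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1L]]
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinates", bad, path))
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    stop(sprintf("invalid interval on BED line %d in %s: start %d >= end %d",
                 idx[bad[1L]], path, start[bad[1L]], end[bad[1L]]))
  }
  nm <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
               NA_character_)
  sc <- suppressWarnings(as.numeric(
    ifelse(nf >= 5L, vapply(fields, function(f) f[min(5L, length(f))], ""),
           NA_character_)
  ))
  interval_set(chrom, start, end, name = nm, score = sc,
               chrom_sizes = chrom_sizes)
}

#' Write an interval set as BED
#'
#' Emits BED3 when neither names nor scores are present, BED6 otherwise
#' (strand written as ".").
#'
#' @param x an `interval_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (all(is.na(x$name)) && all(is.na(x$score))) {
    df <- x[, c("chrom", "start", "end")]
  } else {
    df <- data.frame(x$chrom, x$start, x$end,
                     ifelse(is.na(x$name), ".", x$name),
                     ifelse(is.na(x$score), 0, x$score),
                     ".")
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path path to a tab-separated file with columns
#'   chromosome, length(bp).
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "numeric"))
  setNames(df$size, df$chrom)
}

#' Reconcile two replicate peak sets into common peaks
#'
#' Builds the bipartite overlap graph between the replicates, with an
#' edge wherever a rep1 peak and a rep2 peak share at least
#' `min_overlap` bp, and emits one interval per connected group: the
#' union span of the contributing peaks. The intersection of the group's
#' rep1 span and rep2 span and the per-replicate contributor counts are
#' carried as extra columns. Duplicate identical peaks within a
#' replicate are collapsed before reconciliation.
#'
#' @param rep1,rep2 `interval_set`s of replicate peaks.
#' @param min_overlap minimum cross-replicate overlap in bp (default 50,
#'   the classic reconciliation threshold for MAR peak replicates).
#' @return an `interval_set` of common peaks with additional columns
#'   `n_rep1`, `n_rep2` (contributing peak counts) and
#'   `int_start`, `int_end` (intersection of the rep1 and rep2 group
#'   spans).
#' @export
#' @examples
#' a <- interval_set("2L", 100, 300)
#' b <- interval_set("2L", 240, 500)
#' common_peaks(a, b)  # one peak spanning 100-500
common_peaks <- function(rep1, rep2, min_overlap = 50L) {
  stopifnot(inherits(rep1, "interval_set"), inherits(rep2, "interval_set"),
            min_overlap >= 1L)
  rep1 <- unique_intervals(rep1)
  rep2 <- unique_intervals(rep2)
  empty <- interval_set(character(), integer(), integer())
  empty$n_rep1 <- integer(0); empty$n_rep2 <- integer(0)
  empty$int_start <- integer(0); empty$int_end <- integer(0)
  if (nrow(rep1) == 0L || nrow(rep2) == 0L) return(empty)
  lv <- union(unique(rep1$chrom), unique(rep2$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges(rep1, lv),
                                      as_granges(rep2, lv),
                                      minoverlap = as.integer(min_overlap))
  if (!length(hits)) return(empty)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  # union-find over rep1 nodes (1..n1) and rep2 nodes (n1+1..n1+n2)
  n1 <- nrow(rep1); n2 <- nrow(rep2)
  parent <- seq_len(n1 + n2)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(q)) {
    a <- find(q[k]); b <- find(n1 + s[k])
    if (a != b) parent[b] <- a
  }
  comp1 <- vapply(unique(q), find, 1L)
  used1 <- unique(q); used2 <- unique(s)
  root1 <- vapply(used1, find, 1L)
  root2 <- vapply(n1 + used2, find, 1L)
  roots <- sort(unique(c(root1, root2)))
  out <- lapply(roots, function(r) {
    i1 <- used1[root1 == r]
    i2 <- used2[root2 == r]
    s1 <- min(rep1$start[i1]); e1 <- max(rep1$end[i1])
    s2 <- min(rep2$start[i2]); e2 <- max(rep2$end[i2])
    data.frame(
      chrom = rep1$chrom[i1[1L]],
      start = min(s1, s2), end = max(e1, e2),
      n_rep1 = length(i1), n_rep2 = length(i2),
      int_start = max(s1, s2), int_end = min(e1, e2),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  res <- interval_set(out$chrom, out$start, out$end)
  key <- paste(out$chrom, out$start, out$end)
  m <- match(paste(res$chrom, res$start, res$end), key)
  res$n_rep1 <- out$n_rep1[m]
  res$n_rep2 <- out$n_rep2[m]
  res$int_start <- out$int_start[m]
  res$int_end <- out$int_end[m]
  res
}

# collapse duplicate identical intervals
unique_intervals <- function(x) {
  dup <- duplicated(x[, c("chrom", "start", "end")])
  y <- x[!dup, , drop = FALSE]
  rownames(y) <- NULL
  class(y) <- class(x)
  y
}

#' Read mapped tag positions from a BED-like file
#'
#' Expects at least chrom/start/end columns; strand is taken from
#' column 6 when present, otherwise "+". Only the start coordinate is
#' used downstream (window assignment ignores strand).
#'
#' @param path path to a BED-like file of tag positions.
#' @return data frame with columns `chrom`, `start`, `strand`.
#' @export
read_tags <- function(path) {
  b <- read_bed(path)
  data.frame(chrom = b$chrom, start = b$start,
             strand = rep("+", nrow(b)), stringsAsFactors = FALSE)
}

#' Windowed Pearson correlation of tag counts between replicates
#'
#' Partitions every chromosome into consecutive non-overlapping windows
#' anchored at coordinate 0 (the trailing partial window is included),
#' counts tags per window in each replicate (a tag belongs to the window
#' containing its start; strand is ignored), and returns the Pearson
#' correlation of the two count vectors over all windows genome-wide.
#'
#' @param tags1,tags2 data frames with `chrom` and `start` columns.
#' @param chrom_sizes named vector of chromosome lengths covering every
#'   tag chromosome.
#' @param window window width in bp (default 500).
#' @return Pearson correlation coefficient (length-1 numeric).
#' @export
windowed_tag_correlation <- function(tags1, tags2, chrom_sizes,
                                     window = 500L) {
  stopifnot(window >= 1L, !is.null(names(chrom_sizes)))
  chroms <- unique(c(tags1$chrom, tags2$chrom))
  miss <- setdiff(chroms, names(chrom_sizes))
  if (length(miss)) {
    stop("chrom_sizes does not cover: ", paste(miss, collapse = ", "))
  }
  counts <- function(tags) {
    unlist(lapply(names(chrom_sizes), function(ch) {
      nwin <- ceiling(chrom_sizes[[ch]] / window)
      st <- tags$start[tags$chrom == ch]
      if (any(st < 0 | st >= chrom_sizes[[ch]])) {
        stop("tag start outside chromosome ", ch)
      }
      tabulate(st %/% window + 1L, nbins = nwin)
    }), use.names = FALSE)
  }
  c1 <- counts(tags1)
  c2 <- counts(tags2)
  if (stats::sd(c1) == 0 || stats::sd(c2) == 0) {
    stop("undefined correlation: zero variance in windowed tag counts")
  }
  cor(c1, c2)
}

#' Interval size statistics for a MAR set
#'
#' @param mars a non-empty `interval_set`.
#' @param thresholds sizes (bp) at which to report the fraction of
#'   intervals strictly shorter (default 600, the classic "90% of MARs
#'   under 600 bp" threshold).
#' @param bin histogram bin width in bp.
#' @return list of class `mar_stats` with `n_mars`, `total_bp`,
#'   `median_size`, `size_histogram` (table of bin start -> count) and
#'   `frac_below` (named vector over `thresholds`).
#' @export
size_stats <- function(mars, thresholds = c(600L), bin = 100L) {
  stopifnot(inherits(mars, "interval_set"))
  if (nrow(mars) == 0L) stop("size_stats: empty interval set")
  len <- mars$end - mars$start
  thresholds <- sort(as.integer(thresholds))
  frac_below <- vapply(thresholds, function(t) mean(len < t), 0)
  breaks <- seq(0L, max(len) + bin, by = bin)
  h <- table(cut(len, breaks = breaks, right = FALSE,
                 labels = head(breaks, -1L)))
  structure(list(
    n_mars = nrow(mars),
    total_bp = sum(len),
    median_size = median(len),
    size_histogram = h,
    frac_below = setNames(frac_below, thresholds)
  ), class = "mar_stats")
}

#' @export
print.mar_stats <- function(x, ...) {
  cat(sprintf("MAR set: n = %d, total %.3f Mb, median size %g bp\n",
              x$n_mars, x$total_bp / 1e6, x$median_size))
  for (t in names(x$frac_below)) {
    cat(sprintf("  fraction < %s bp: %.3f\n", t, x$frac_below[[t]]))
  }
  invisible(x)
}

#' Inter-MAR midpoint distances
#'
#' Per chromosome, the distances between midpoints of consecutive MARs
#' in coordinate order; a proxy for chromatin loop size. Midpoint of an
#' interval is `floor((start+end)/2)`. Chromosomes with fewer than two
#' MARs contribute no distances; no distances are taken across
#' chromosome (arm) boundaries.
#'
#' @param mars an `interval_set`.
#' @param threshold distance (bp) for the summary fraction (default
#'   20 kb).
#' @return list with `per_chrom` (named list of distance vectors),
#'   `distances` (pooled), `mean`, and `frac_below` (fraction of
#'   distances strictly below `threshold`).
#' @export
inter_mar_distances <- function(mars, threshold = 20000L) {
  stopifnot(inherits(mars, "interval_set"))
  per <- lapply(split(mars, mars$chrom), function(df) {
    if (nrow(df) < 2L) return(numeric(0))
    diff(interval_midpoint(df$start, df$end))
  })
  all <- unlist(per, use.names = FALSE)
  list(
    per_chrom = per,
    distances = all,
    mean = if (length(all)) mean(all) else NA_real_,
    frac_below = if (length(all)) mean(all < threshold) else NA_real_
  )
}

#' Per-chromosome MAR density table
#'
#' One row per chromosome (arm) with MAR count, kb of DNA per MAR and
#' genes per MAR, plus a genome-wide totals row (chrom = "total").
#' Chromosomes present in `chrom_sizes` but carrying zero MARs get
#' `NA` ratios rather than an error.
#'
#' @param mars an `interval_set`.
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param gene_counts named vector of gene counts per chromosome
#'   (optional; genes_per_mar is NA where missing).
#' @return data frame with columns `chrom`, `size_mb`, `n_genes`,
#'   `n_mars`, `kb_per_mar`, `genes_per_mar`.
#' @export
chromosome_density_table <- function(mars, chrom_sizes, gene_counts = NULL) {
  stopifnot(inherits(mars, "interval_set"), !is.null(names(chrom_sizes)))
  miss <- setdiff(unique(mars$chrom), names(chrom_sizes))
  if (length(miss)) {
    stop("MAR chromosome missing from chrom_sizes: ",
         paste(miss, collapse = ", "))
  }
  chroms <- names(chrom_sizes)
  n_mars <- vapply(chroms, function(ch) sum(mars$chrom == ch), 0L)
  n_genes <- if (is.null(gene_counts)) rep(NA_real_, length(chroms)) else
    as.numeric(gene_counts[chroms])
  size_mb <- as.numeric(chrom_sizes) / 1e6
  rows <- data.frame(
    chrom = chroms, size_mb = size_mb, n_genes = n_genes, n_mars = n_mars,
    kb_per_mar = ifelse(n_mars > 0, size_mb * 1000 / n_mars, NA_real_),
    genes_per_mar = ifelse(n_mars > 0, n_genes / n_mars, NA_real_),
    stringsAsFactors = FALSE
  )
  tot_mars <- sum(n_mars)
  total <- data.frame(
    chrom = "total", size_mb = sum(size_mb),
    n_genes = if (all(is.na(n_genes))) NA_real_ else sum(n_genes, na.rm = TRUE),
    n_mars = tot_mars,
    kb_per_mar = if (tot_mars > 0) sum(size_mb) * 1000 / tot_mars else NA_real_,
    genes_per_mar = if (tot_mars > 0 && !all(is.na(n_genes)))
      sum(n_genes, na.rm = TRUE) / tot_mars else NA_real_,
    stringsAsFactors = FALSE
  )
  out <- rbind(rows, total)
  rownames(out) <- NULL
  out
}

#' Restrict an interval set to euchromatic chromosome arms
#'
#' Heterochromatic and unplaced scaffolds are excluded by chromosome
#' name; the default list is the classic euchromatic arm set of the
#' fly genome assembly.
#'
#' @param x an `interval_set`.
#' @param chroms chromosome names to keep.
#' @return the filtered `interval_set`.
#' @export
filter_euchromatic <- function(x, chroms = c("2L", "2R", "3L", "3R",
                                             "4", "X")) {
  keep <- x$chrom %in% chroms
  y <- x[keep, , drop = FALSE]
  rownames(y) <- NULL
  class(y) <- class(x)
  y
}
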