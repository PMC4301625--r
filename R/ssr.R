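#' Canonical form of an SSR repeat unit
#'
#' The canonical representative of a repeat unit is the
#' lexicographically smallest string among all rotations of the unit
#' and all rotations of its reverse complement. Two tandem repeats
#' belong to the same class exactly when their units share a canonical
#' form (a tract read in either phase or on either strand is the same
#' repeat).
#'
#' @param unit character vector of DNA units (1-6 bp each).
#' @return character vector of canonical units.
#' @export
#' @examples
#' canonical_ssr_unit(c("GA", "TC", "CT"))  # all "AG"
canonical_ssr_unit <- function(unit) {
  vapply(toupper(unit), function(u) {
    k <- nchar(u)
    rot <- function(x) {
      vapply(seq_len(k) - 1L, function(i) {
        paste0(substring(x, i + 1L, k), substring(x, 1L, i))
      }, "")
    }
    min(c(rot(u), rot(revcomp(u))))
  }, "", USE.NAMES = FALSE)
}

is_primitive_unit <- function(unit) {
  vapply(unit, function(u) {
    k <- nchar(u)
    divs <- which(k %% seq_len(k - 1L) == 0L)
    !any(vapply(divs, function(d) {
      strrep(substring(u, 1L, d), k / d) == u
    }, TRUE))
  }, TRUE, USE.NAMES = FALSE)
}

#' Enumerate the non-redundant SSR classes
#'
#' All canonical repeat-unit classes for unit lengths 1..`max_unit`,
#' excluding units that are whole-number repetitions of a shorter unit.
#' For `max_unit = 6` this yields the classic 501 non-redundant
#' microsatellite classes (2, 4, 10, 33, 102 and 350 classes for unit
#' lengths 1-6).
#'
#' @param max_unit maximum unit length in bp (1-6).
#' @return data frame with columns `canonical_unit`, `unit_len`, in
#'   deterministic (unit length, then lexicographic) order.
#' @export
enumerate_ssr_classes <- function(max_unit = 6L) {
  stopifnot(max_unit >= 1L, max_unit <= 6L)
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(max_unit), function(k) {
    units <- do.call(paste0, expand.grid(rep(list(bases), k),
                                         stringsAsFactors = FALSE))
    units <- units[is_primitive_unit(units)]
    sort(unique(canonical_ssr_unit(units)))
  })
  data.frame(
    canonical_unit = unlist(out),
    unit_len = rep(seq_len(max_unit), lengths(out)),
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence for perfect SSR tracts
#'
#' Finds, for every repeat period 1..`max_unit`, the maximal perfect
#' tandem tracts of at least `min_len` bp. A tract is attributed to the
#' canonical class of its repeat unit; tracts whose unit is itself a
#' repetition of a shorter unit are reported only under the shorter
#' period (a poly-A run is an A-class locus, never an AA- or AAA-class
#' one). Tracts of different classes may overlap (a mononucleotide run
#' inside a longer dinucleotide tract is reported only when it itself
#' reaches `min_len`). N matches nothing and breaks every tract.
#' Imperfect (mismatch-containing) repeats are not detected.
#'
#' @param seq character scalar.
#' @param min_len minimum tract length in bp (default 12).
#' @param classes optional character vector of canonical units to
#'   restrict the scan to (default: all classes up to `max_unit`).
#' @param max_unit maximum repeat period (default 6).
#' @return data frame with columns `start`, `end` (0-based half-open),
#'   `canonical_unit`, `unit`, `unit_len`, `n_units`, `length`.
#' @export
#' @examples
#' scan_ssrs(strrep("AG", 6))  # one AG locus of 12 bp
scan_ssrs <- function(seq, min_len = 12L, classes = NULL, max_unit = 6L) {
  s <- normalize_seq(seq)
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  valid <- ch != "N"
  res <- list()
  for (k in seq_len(min(max_unit, max(0L, n - 1L)))) {
    if (n < max(min_len, 2L * k)) next
    eq <- ch[seq_len(n - k)] == ch[seq_len(n - k) + k] &
      valid[seq_len(n - k)] & valid[seq_len(n - k) + k]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (j in runs) {
      tract_start <- begs[j]           # 1-based
      tract_len <- r$lengths[j] + k
      if (tract_len < min_len) next
      if (tract_len < 2L * k) next     # need at least two full units
      unit <- substring(s, tract_start, tract_start + k - 1L)
      if (!is_primitive_unit(unit)) next
      res[[length(res) + 1L]] <- data.frame(
        start = tract_start - 1L,
        end = tract_start - 1L + tract_len,
        canonical_unit = canonical_ssr_unit(unit),
        unit = unit,
        unit_len = k,
        n_units = tract_len %/% k,
        length = tract_len,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      canonical_unit = character(), unit = character(),
                      unit_len = integer(), n_units = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  if (!is.null(classes)) out <- out[out$canonical_unit %in% classes, , drop = FALSE]
  # at most one locus per class per position: on the rare same-class
  # overlap, keep the leftmost (then longest) tract
  out <- out[order(out$canonical_unit, out$start, -out$length), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1L) {
    last_class <- out$canonical_unit[1L]
    last_end <- out$end[1L]
    for (i in 2L:nrow(out)) {
      if (out$canonical_unit[i] != last_class) {
        last_class <- out$canonical_unit[i]
        last_end <- out$end[i]
      } else if (out$start[i] < last_end) {
        keep[i] <- FALSE
      } else {
        last_end <- out$end[i]
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$end, out$canonical_unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a whole genome for SSR loci
#'
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @inheritParams scan_ssrs
#' @return data frame of loci with a leading `chrom` column
#'   (coordinates 0-based half-open on each chromosome).
#' @export
ssr_loci <- function(genome, min_len = 12L, classes = NULL, max_unit = 6L) {
  if (is.character(genome)) genome <- read_genome(genome)
  out <- lapply(names(genome), function(ch) {
    hits <- scan_ssrs(as.character(genome[[ch]]), min_len = min_len,
                      classes = classes, max_unit = max_unit)
    if (nrow(hits)) cbind(chrom = ch, hits, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      canonical_unit = character(), unit = character(),
                      unit_len = integer(), n_units = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' SSR-MAR association and fold enrichment
#'
#' Per SSR class, the number of genomic loci, the number associated
#' with MARs and the fold enrichment of that association over the
#' genomic expectation. A locus is associated with MARs when it
#' overlaps a MAR by at least 1 bp (`mode = "any"`, the default) or
#' when it is fully contained in a MAR (`mode = "contained"`). Fold
#' enrichment is the in-MAR fraction of loci divided by the MAR
#' fraction of the (euchromatic) genome, so uniform random placement
#' gives 1.0.
#'
#' @param loci SSR locus table from [ssr_loci()].
#' @param mars an `interval_set`.
#' @param genome_bp total genome (euchromatic) length in bp.
#' @param min_genomic_loci report only classes with more genomic loci
#'   than this (default 100).
#' @param mode association rule, "any" or "contained".
#' @return data frame with columns `canonical_unit`, `unit_len`,
#'   `n_genomic`, `n_in_mars`, `pct_in_mars`, `fold_enrichment`,
#'   ordered by decreasing `pct_in_mars`.
#' @export
ssr_mar_association <- function(loci, mars, genome_bp,
                                min_genomic_loci = 100L,
                                mode = c("any", "contained")) {
  mode <- match.arg(mode)
  if (genome_bp <= 0) stop("genome_bp must be positive")
  mar_bp <- sum(mars$end - mars$start)
  mar_frac <- mar_bp / genome_bp
  if (nrow(loci) == 0L) {
    return(data.frame(canonical_unit = character(), unit_len = integer(),
                      n_genomic = integer(), n_in_mars = integer(),
                      pct_in_mars = numeric(), fold_enrichment = numeric(),
                      stringsAsFactors = FALSE))
  }
  lv <- union(unique(loci$chrom), unique(mars$chrom))
  lg <- GenomicRanges::GRanges(factor(loci$chrom, levels = lv),
                               IRanges::IRanges(loci$start + 1L, loci$end))
  mg <- as_granges(mars, lv)
  in_mar <- if (mode == "any") {
    GenomicRanges::countOverlaps(lg, mg) > 0L
  } else {
    GenomicRanges::countOverlaps(lg, mg, type = "within") > 0L
  }
  agg <- aggregate(
    cbind(n_genomic = rep(1L, nrow(loci)), n_in_mars = as.integer(in_mar)),
    by = list(canonical_unit = loci$canonical_unit,
              unit_len = loci$unit_len),
    FUN = sum
  )
  agg <- agg[agg$n_genomic > min_genomic_loci, , drop = FALSE]
  agg$pct_in_mars <- 100 * agg$n_in_mars / agg$n_genomic
  agg$fold_enrichment <- (agg$n_in_mars / agg$n_genomic) / mar_frac
  agg <- agg[order(-agg$pct_in_mars, agg$canonical_unit), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "mar_frac") <- mar_frac
  attr(agg, "mode") <- mode
  agg
}
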