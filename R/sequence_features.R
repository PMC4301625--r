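#' Read a genome FASTA
#'
#' @param path FASTA file path.
#' @return a [Biostrings::DNAStringSet] named by the first word of each
#'   header.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract MAR sequences from a genome
#'
#' @param mars an `interval_set`.
#' @param genome a [Biostrings::DNAStringSet] (or path to a FASTA).
#' @return character vector of normalized sequences, one per MAR, named
#'   `chrom:start-end` (or by the MAR `name` column when present).
#' @export
mar_sequences <- function(mars, genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  miss <- setdiff(unique(mars$chrom), names(genome))
  if (length(miss)) stop("chromosome not in genome: ", paste(miss, collapse = ", "))
  bad <- which(mars$end > Biostrings::width(genome)[match(mars$chrom, names(genome))])
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf("MAR outside genome bounds: %s:%d-%d",
                 mars$chrom[i], mars$start[i], mars$end[i]))
  }
  seqs <- vapply(seq_len(nrow(mars)), function(i) {
    as.character(Biostrings::subseq(genome[[mars$chrom[i]]],
                                    start = mars$start[i] + 1L,
                                    end = mars$end[i]))
  }, "")
  seqs <- vapply(seqs, normalize_seq, "", USE.NAMES = FALSE)
  ids <- ifelse(is.na(mars$name) | mars$name == ".",
                sprintf("%s:%d-%d", mars$chrom, mars$start, mars$end),
                mars$name)
  setNames(seqs, ids)
}

empty_hits <- function() {
  data.frame(feature = character(), start = integer(), end = integer(),
             strand = character(), motif = character(),
             stringsAsFactors = FALSE)
}

hit_frame <- function(feature, start, end, strand, motif) {
  data.frame(feature = feature, start = as.integer(start),
             end = as.integer(end), strand = strand, motif = motif,
             stringsAsFactors = FALSE)
}

#' Scan for ATC-rule runs
#'
#' The ATC rule is the classic MAR signature: one strand carries at
#' least `min_run` consecutive bases from \{A,T,C\} with no intervening
#' G. On the plus strand these are maximal runs over \{A,T,C\}; the
#' equivalent signal on the minus strand appears on the scanned strand
#' as maximal runs over \{A,T,G\}. Runs from the two senses are reported
#' separately with strand labels; N breaks every run.
#'
#' @param seq character scalar (normalized with [normalize_seq()]).
#' @param min_run minimum run length in bp (default 20).
#' @return hit data frame (`feature`, `start`, `end`, `strand`,
#'   `motif`), 0-based half-open coordinates on the scanned strand.
#' @export
#' @examples
#' scan_atc_rule(strrep("A", 20))  # one run, reported for both senses
scan_atc_rule <- function(seq, min_run = 20L) {
  s <- normalize_seq(seq)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  one_sense <- function(alphabet, strand) {
    r <- rle(ch %in% alphabet)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(empty_hits())
    hit_frame("atc_rule", starts[keep] - 1L, ends[keep], strand,
              substring(s, starts[keep], ends[keep]))
  }
  rbind(one_sense(c("A", "T", "C"), "+"), one_sense(c("A", "T", "G"), "-"))
}

ORI_MOTIFS <- c("ATTA", "ATTTA", "ATTTTA")

#' Scan for origin-of-replication motifs
#'
#' Reports every occurrence (overlaps included) of the ORI motifs ATTA,
#' ATTTA and ATTTTA on the scanned strand, and of their reverse
#' complements (TAAT, TAAAT, TAAAAT) as minus-strand hits. The `motif`
#' column always carries the plus-strand motif identity.
#'
#' @param seq character scalar.
#' @return hit data frame as in [scan_atc_rule()].
#' @export
scan_ori_motifs <- function(seq) {
  s <- normalize_seq(seq)
  res <- empty_hits()
  for (m in ORI_MOTIFS) {
    p <- find_fixed(s, m)
    if (length(p)) {
      res <- rbind(res, hit_frame("ori_motif", p, p + nchar(m), "+", m))
    }
    rc <- revcomp(m)
    p <- find_fixed(s, rc)
    if (length(p)) {
      res <- rbind(res, hit_frame("ori_motif", p, p + nchar(m), "-", m))
    }
  }
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# all (overlapping) 0-based start positions of fixed-string `pat` in `s`
find_fixed <- function(s, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan for AT-rich regions
#'
#' Flags every position covered by a sliding window of width `window`
#' whose A+T fraction is at least `min_at`, and merges flagged windows
#' into maximal regions. N counts as non-AT.
#'
#' @param seq character scalar.
#' @param window sliding-window width in bp (default 100).
#' @param min_at minimum A+T fraction within a window (default 0.70).
#' @return hit data frame; strand is "+" (the signal is
#'   strand-symmetric).
#' @export
scan_at_rich <- function(seq, window = 100L, min_at = 0.70) {
  s <- normalize_seq(seq)
  n <- nchar(s)
  if (n < window) return(empty_hits())
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  cs <- c(0L, cumsum(ch %in% c("A", "T")))
  starts <- seq_len(n - window + 1L)
  frac <- (cs[starts + window] - cs[starts]) / window
  ok <- frac >= min_at
  if (!any(ok)) return(empty_hits())
  # mark every position covered by a qualifying window, then take the
  # maximal covered regions
  covered <- rep(FALSE, n)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    covered[begs[k]:(ends[k] + window - 1L)] <- TRUE
  }
  r2 <- rle(covered)
  e2 <- cumsum(r2$lengths)
  b2 <- e2 - r2$lengths + 1L
  keep <- which(r2$values)
  hit_frame("at_rich", b2[keep] - 1L, e2[keep], "+", NA_character_)
}

#' Default MAR signal pattern registry
#'
#' Named list of plus-strand IUPAC patterns for the structural MAR
#' signals; the scanner adds the reverse complement of every pattern as
#' the minus-strand sense. The curved- and kinked-DNA and
#' topoisomerase II consensus patterns follow the classic MAR-signal
#' sets used by rule-based MAR predictors; the topo II site is the
#' in-vitro Drosophila consensus. The base-unpairing region (BUR)
#' pattern is a short AT-tract unwinding-element core and carries a
#' caveat: BUR elements are poorly captured by a fixed pattern and were
#' found missing from most experimentally mapped MARs.
#'
#' @return named list of character vectors of IUPAC patterns. Users may
#'   amend or replace entries and pass the result to
#'   [scan_pattern_features()].
#' @export
feature_registry <- function() {
  kink_blocks <- c("TA", "TG", "CA")
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  kinked <- vapply(perms, function(p) {
    paste0(kink_blocks[p[1]], "NNN", kink_blocks[p[2]], "NNN",
           kink_blocks[p[3]])
  }, "")
  list(
    curved = "AAAANNNNNNNAAAANNNNNNNAAAA",
    kinked = unique(kinked),
    topoII = "GTNWAYATTNATNNR",
    bur = "AATATATTT"
  )
}

IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
  H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

iupac_to_regex <- function(pat) {
  ch <- strsplit(toupper(pat), "", fixed = TRUE)[[1]]
  bad <- setdiff(ch, names(IUPAC_REGEX))
  if (length(bad)) stop("unknown IUPAC symbol in pattern: ", bad[1L])
  paste(IUPAC_REGEX[ch], collapse = "")
}

#' Scan for registry-defined structural MAR signals
#'
#' Matches the named feature's IUPAC patterns on both strands
#' (minus-strand hits are matches of the reverse-complemented pattern,
#' reported in plus-strand coordinates). N in the sequence matches no
#' pattern symbol, including N. Overlapping matches are all reported;
#' a palindromic (revcomp-closed) pattern set yields the same interval
#' on both strands.
#'
#' @param seq character scalar.
#' @param feature registry entry name (e.g. "curved", "kinked",
#'   "topoII", "bur").
#' @param registry pattern registry, see [feature_registry()].
#' @return hit data frame as in [scan_atc_rule()].
#' @export
scan_pattern_features <- function(seq, feature,
                                  registry = feature_registry()) {
  if (!feature %in% names(registry)) {
    stop("unknown feature '", feature, "'; registry has: ",
         paste(names(registry), collapse = ", "))
  }
  s <- normalize_seq(seq)
  res <- empty_hits()
  for (pat in registry[[feature]]) {
    w <- nchar(pat)
    p <- find_iupac(s, pat)
    if (length(p)) {
      res <- rbind(res, hit_frame(feature, p, p + w, "+", pat))
    }
    p <- find_iupac(s, revcomp(pat))
    if (length(p)) {
      res <- rbind(res, hit_frame(feature, p, p + w, "-", pat))
    }
  }
  res <- unique(res)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

find_iupac <- function(s, pat) {
  rx <- paste0("(?=", iupac_to_regex(pat), ")")
  m <- gregexpr(rx, s, perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Per-MAR hit counts for every known MAR feature
#'
#' @param mars an `interval_set`.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param registry pattern registry for the structural signals.
#' @param at_window,at_min_at parameters of [scan_at_rich()].
#' @param atc_min_run parameter of [scan_atc_rule()].
#' @return data frame with one row per MAR and one hit-count column per
#'   feature (`atc_rule`, `ori_motif`, `at_rich`, plus every registry
#'   entry).
#' @export
feature_hit_table <- function(mars, genome, registry = feature_registry(),
                              at_window = 100L, at_min_at = 0.70,
                              atc_min_run = 20L) {
  seqs <- mar_sequences(mars, genome)
  features <- c("atc_rule", "ori_motif", "at_rich", names(registry))
  counts <- vapply(seqs, function(s) {
    c(
      atc_rule = nrow(scan_atc_rule(s, min_run = atc_min_run)),
      ori_motif = nrow(scan_ori_motifs(s)),
      at_rich = nrow(scan_at_rich(s, window = at_window, min_at = at_min_at)),
      vapply(names(registry), function(f) {
        nrow(scan_pattern_features(s, f, registry))
      }, 0L)
    )
  }, setNames(integer(length(features)), features))
  out <- data.frame(mar = names(seqs), t(counts), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Feature-enrichment table over a MAR set
#'
#' For each known MAR feature, the number and fraction of MARs that
#' carry at least one hit anywhere in their interval.
#'
#' @inheritParams feature_hit_table
#' @return data frame with columns `feature`, `n_mars_with_feature`,
#'   `frac_mars`; attribute `n_mars` records the denominator. The `bur`
#'   row carries the registry's fixed-pattern caveat (see
#'   [feature_registry()]).
#' @export
feature_enrichment_table <- function(mars, genome,
                                     registry = feature_registry(),
                                     at_window = 100L, at_min_at = 0.70,
                                     atc_min_run = 20L) {
  tab <- feature_hit_table(mars, genome, registry, at_window, at_min_at,
                           atc_min_run)
  feats <- setdiff(names(tab), "mar")
  n <- nrow(tab)
  with_feat <- vapply(feats, function(f) sum(tab[[f]] > 0L), 0L)
  out <- data.frame(
    feature = feats,
    n_mars_with_feature = with_feat,
    frac_mars = if (n > 0) with_feat / n else NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_mars") <- n
  out
}
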