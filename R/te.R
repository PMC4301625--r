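#' Local alignment scoring parameters
#'
#' Defaults emulate legacy blastn-style pairwise alignment: match +1,
#' mismatch -2, affine gap cost `gap_open + L * gap_extend` for a gap
#' of length L (5 and 2 by default).
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (<= 0).
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return list of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = 5,
                         gap_extend = 2) {
  stopifnot(match > 0, mismatch <= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment with affine gaps (via
#' [Biostrings::pairwiseAlignment()]). Identity is the fraction of
#' aligned columns that are matches; gap columns count in the
#' denominator. N scores as a mismatch against everything.
#'
#' @param a,b character scalars (non-empty DNA sequences).
#' @param params an [align_params()] object.
#' @return list with `score`, `identity`, `aln_len` (aligned columns,
#'   gaps included), and 0-based half-open spans `a_start`, `a_end`,
#'   `b_start`, `b_end`. A pair with no positive-scoring alignment
#'   returns `score = 0`, `aln_len = 0` and `NA` spans.
#' @export
local_align <- function(a, b, params = align_params()) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  a <- normalize_seq(a); b <- normalize_seq(b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE
  )
  letters_all <- rownames(mat)
  # N (and any ambiguity) scores as a plain mismatch
  amb <- setdiff(letters_all, c("A", "C", "G", "T"))
  mat[amb, ] <- params$mismatch
  mat[, amb] <- params$mismatch
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(list(score = 0, identity = NA_real_, aln_len = 0L,
                a_start = NA_integer_, a_end = NA_integer_,
                b_start = NA_integer_, b_end = NA_integer_))
  }
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(pa)
  ca <- strsplit(pa, "", fixed = TRUE)[[1]]
  cb <- strsplit(pb, "", fixed = TRUE)[[1]]
  matches <- sum(ca == cb & ca != "-")
  list(
    score = sc,
    identity = matches / cols,
    aln_len = cols,
    a_start = Biostrings::start(Biostrings::pattern(aln)) - 1L,
    a_end = Biostrings::end(Biostrings::pattern(aln)),
    b_start = Biostrings::start(Biostrings::subject(aln)) - 1L,
    b_end = Biostrings::end(Biostrings::subject(aln))
  )
}

#' Align MAR sequences against canonical TE sequences
#'
#' Computes, for every (TE, MAR) pair, the best local alignment of the
#' MAR (both strands) against the TE plus strand, and reports the pairs
#' whose best alignment reaches both the identity and the
#' aligned-length thresholds (the classic 90% identity over a 100 bp
#' segment criterion).
#'
#' @param te_seqs named character vector (or `DNAStringSet`) of
#'   canonical TE sequences.
#' @param mar_seqs named character vector (or `DNAStringSet`) of MAR
#'   sequences.
#' @param min_identity minimum identity fraction (default 0.90,
#'   boundary included).
#' @param min_len minimum aligned columns (default 100).
#' @param params an [align_params()] object.
#' @return data frame with columns `te_id`, `mar_id`, `strand`,
#'   `identity`, `aln_len`, `score`, `te_start`, `te_end`,
#'   `mar_start`, `mar_end` (0-based half-open; MAR span always in
#'   plus-strand MAR coordinates).
#' @export
te_mar_hits <- function(te_seqs, mar_seqs, min_identity = 0.90,
                        min_len = 100L, params = align_params()) {
  te_seqs <- as_named_chars(te_seqs, "te")
  mar_seqs <- as_named_chars(mar_seqs, "mar")
  rows <- list()
  for (te in names(te_seqs)) {
    for (mar in names(mar_seqs)) {
      mlen <- nchar(mar_seqs[[mar]])
      best <- NULL
      for (strand in c("+", "-")) {
        q <- if (strand == "+") mar_seqs[[mar]] else revcomp(mar_seqs[[mar]])
        al <- local_align(te_seqs[[te]], q, params)
        if (is.null(best) || al$score > best$al$score) {
          best <- list(al = al, strand = strand)
        }
      }
      al <- best$al
      if (al$aln_len >= min_len && !is.na(al$identity) &&
          al$identity >= min_identity) {
        ms <- al$b_start; me <- al$b_end
        if (best$strand == "-") {            # map back to plus strand
          tmp <- ms
          ms <- mlen - me
          me <- mlen - tmp
        }
        rows[[length(rows) + 1L]] <- data.frame(
          te_id = te, mar_id = mar, strand = best$strand,
          identity = al$identity, aln_len = al$aln_len, score = al$score,
          te_start = al$a_start, te_end = al$a_end,
          mar_start = ms, mar_end = me,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(te_id = character(), mar_id = character(),
               strand = character(), identity = numeric(),
               aln_len = integer(), score = numeric(),
               te_start = integer(), te_end = integer(),
               mar_start = integer(), mar_end = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

as_named_chars <- function(x, prefix) {
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  if (is.null(names(x))) names(x) <- paste0(prefix, seq_along(x))
  vapply(x, normalize_seq, "", USE.NAMES = TRUE)
}

#' Summarize TE-MAR association per TE family
#'
#' For each TE family, the percentage of its genomic copies that
#' overlap at least one MAR (over all copies, and over full-length
#' copies only -- a copy is full-length when it spans at least
#' `full_frac` of the canonical sequence), the median size of the
#' hit MAR regions, and the annotated TE region containing the modal
#' alignment span.
#'
#' @param hits hit table from [te_mar_hits()].
#' @param te_copies an `interval_set` of genomic TE copies with `name`
#'   = TE id.
#' @param mars an `interval_set`.
#' @param te_annotation optional data frame with columns `te_id`,
#'   `region` (e.g. "3'-UTR", "LTR", "ORF"), `start`, `end` (0-based
#'   half-open TE-local coordinates).
#' @param te_lengths named vector of canonical TE lengths (bp),
#'   required for the full-length copy count.
#' @param full_frac minimum spanned fraction for a full-length copy.
#' @return data frame with one row per TE family: `te_id`, `te_len`,
#'   `n_copies`, `n_copies_in_mars`, `pct_copies_in_mars`,
#'   `n_full_copies`, `pct_full_copies_in_mars`, `mar_size` (median bp
#'   of hit MAR spans), `context`, `context_span`.
#' @export
te_summary <- function(hits, te_copies, mars, te_annotation = NULL,
                       te_lengths = NULL, full_frac = 0.95) {
  te_ids <- unique(c(hits$te_id, te_copies$name))
  te_ids <- te_ids[!is.na(te_ids)]
  lv <- union(unique(te_copies$chrom), unique(mars$chrom))
  mg <- as_granges(mars, lv)
  out <- lapply(te_ids, function(te) {
    cp <- te_copies[!is.na(te_copies$name) & te_copies$name == te, ,
                    drop = FALSE]
    n_cp <- nrow(cp)
    te_len <- if (!is.null(te_lengths) && te %in% names(te_lengths))
      as.integer(te_lengths[[te]]) else NA_integer_
    if (n_cp > 0L) {
      cg <- GenomicRanges::GRanges(factor(cp$chrom, levels = lv),
                                   IRanges::IRanges(cp$start + 1L, cp$end))
      in_mar <- GenomicRanges::countOverlaps(cg, mg) > 0L
      full <- if (!is.na(te_len)) (cp$end - cp$start) >= full_frac * te_len
              else rep(NA, n_cp)
    } else {
      in_mar <- logical(0)
      full <- logical(0)
    }
    h <- hits[hits$te_id == te, , drop = FALSE]
    if (nrow(h)) {
      # modal hit span on the TE: midpoint of the most frequent span
      key <- paste(h$te_start, h$te_end)
      modal <- h[key == names(which.max(table(key)))[1L], , drop = FALSE][1L, ]
      ctx <- NA_character_
      if (!is.null(te_annotation)) {
        ann <- te_annotation[te_annotation$te_id == te, , drop = FALSE]
        mid <- interval_midpoint(modal$te_start, modal$te_end)
        inreg <- ann$start <= mid & mid < ann$end
        if (any(inreg)) ctx <- ann$region[which(inreg)[1L]]
      }
      context_span <- sprintf("%d-%d", modal$te_start, modal$te_end)
      mar_size <- median(h$mar_end - h$mar_start)
    } else {
      ctx <- NA_character_
      context_span <- NA_character_
      mar_size <- NA_real_
    }
    data.frame(
      te_id = te, te_len = te_len, n_copies = n_cp,
      n_copies_in_mars = sum(in_mar),
      pct_copies_in_mars = if (n_cp > 0L) 100 * mean(in_mar) else NA_real_,
      n_full_copies = if (all(is.na(full))) NA_integer_ else sum(full, na.rm = TRUE),
      pct_full_copies_in_mars = if (!all(is.na(full)) && sum(full, na.rm = TRUE) > 0)
        100 * sum(in_mar & full, na.rm = TRUE) / sum(full, na.rm = TRUE)
      else NA_real_,
      mar_size = mar_size, context = ctx, context_span = context_span,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
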