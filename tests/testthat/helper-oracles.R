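# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive quadratic/positional algorithms and share no
# code with the package internals.

rand_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# all-pairs replicate reconciliation: overlap graph + transitive closure
brute_common_peaks <- function(rep1, rep2, min_overlap = 50L) {
  r1 <- unique(as.data.frame(rep1)[, c("chrom", "start", "end")])
  r2 <- unique(as.data.frame(rep2)[, c("chrom", "start", "end")])
  n1 <- nrow(r1); n2 <- nrow(r2)
  if (n1 == 0 || n2 == 0) return(data.frame(chrom = character(),
                                            start = integer(),
                                            end = integer()))
  # adjacency between nodes 1..n1 (rep1) and n1+1..n1+n2 (rep2)
  grp <- seq_len(n1 + n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      if (r1$chrom[i] != r2$chrom[j]) next
      ov <- min(r1$end[i], r2$end[j]) - max(r1$start[i], r2$start[j])
      if (ov >= min_overlap) {
        a <- grp[i]; b <- grp[n1 + j]
        grp[grp == b] <- a
      }
    }
  }
  linked <- c(vapply(seq_len(n1), function(i) any(grp[n1 + seq_len(n2)] == grp[i]), TRUE),
              vapply(seq_len(n2), function(j) any(grp[seq_len(n1)] == grp[n1 + j]), TRUE))
  out <- NULL
  for (g in unique(grp[linked])) {
    members <- which(grp == g & linked)
    i1 <- members[members <= n1]
    i2 <- members[members > n1] - n1
    if (!length(i1) || !length(i2)) next
    out <- rbind(out, data.frame(
      chrom = r1$chrom[i1[1]],
      start = min(r1$start[i1], r2$start[i2]),
      end = max(r1$end[i1], r2$end[i2])
    ))
  }
  if (is.null(out)) return(data.frame(chrom = character(),
                                      start = integer(), end = integer()))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# textbook affine-gap Smith-Waterman, score only (gap of length L costs
# open + L * ext)
sw_reference_score <- function(a, b, match = 1, mismatch = -2,
                               open = 5, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap in A (left)
  F <- matrix(NEG, n + 1, m + 1)   # gap in B (up)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# position-by-position scanners ---------------------------------------------

naive_atc_runs <- function(seq, min_run = 20L) {
  ch <- strsplit(seq, "")[[1]]
  out <- NULL
  for (alpha in list(c("A", "T", "C"), c("A", "T", "G"))) {
    strand <- if (identical(alpha, c("A", "T", "C"))) "+" else "-"
    i <- 1
    while (i <= length(ch)) {
      if (ch[i] %in% alpha) {
        j <- i
        while (j + 1 <= length(ch) && ch[j + 1] %in% alpha) j <- j + 1
        if (j - i + 1 >= min_run) {
          out <- rbind(out, data.frame(start = i - 1L, end = j,
                                       strand = strand))
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  out
}

naive_ori <- function(seq) {
  motifs <- c("ATTA", "ATTTA", "ATTTTA")
  rc <- c("TAAT", "TAAAT", "TAAAAT")
  ch <- strsplit(seq, "")[[1]]
  out <- NULL
  for (k in seq_along(motifs)) {
    for (m in c(motifs[k], rc[k])) {
      w <- nchar(m)
      mm <- strsplit(m, "")[[1]]
      for (i in seq_len(max(0, length(ch) - w + 1))) {
        if (all(ch[i:(i + w - 1)] == mm)) {
          out <- rbind(out, data.frame(
            start = i - 1L, end = i - 1L + w,
            strand = if (m == motifs[k]) "+" else "-", motif = motifs[k]
          ))
        }
      }
    }
  }
  out
}

naive_at_rich <- function(seq, window = 100L, min_at = 0.70) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < window) return(NULL)
  flagged <- rep(FALSE, n)
  for (i in seq_len(n - window + 1)) {
    w <- ch[i:(i + window - 1)]
    if (mean(w %in% c("A", "T")) >= min_at) {
      flagged[i:(i + window - 1)] <- TRUE
    }
  }
  if (!any(flagged)) return(NULL)
  r <- rle(flagged)
  ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = begs[keep] - 1L, end = ends[keep])
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

naive_iupac_positions <- function(seq, pat) {
  ch <- strsplit(seq, "")[[1]]
  pp <- strsplit(pat, "")[[1]]
  w <- length(pp)
  hits <- integer(0)
  for (i in seq_len(max(0, length(ch) - w + 1))) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (!(ch[i + k - 1] %in% IUPAC_SETS[[pp[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

rc_chr <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# independent SSR class enumerator: count orbit-minimal primitive units
brute_ssr_class_count <- function(k) {
  bases <- c("A", "C", "G", "T")
  units <- do.call(paste0, expand.grid(rep(list(bases), k),
                                       stringsAsFactors = FALSE))
  rotations <- function(u) {
    n <- nchar(u)
    vapply(0:(n - 1), function(i) {
      paste0(substring(u, i + 1, n), substring(u, 1, i))
    }, "")
  }
  is_prim <- function(u) {
    n <- nchar(u)
    for (d in seq_len(n - 1)) {
      if (n %% d == 0 && strrep(substring(u, 1, d), n / d) == u) return(FALSE)
    }
    TRUE
  }
  count <- 0
  for (u in units) {
    if (!is_prim(u)) next
    orbit <- c(rotations(u), rotations(rc_chr(u)))
    if (u == min(orbit)) count <- count + 1
  }
  count
}

# brute-force maximal perfect tandem tracts (independent formulation)
naive_ssr_tracts <- function(seq, min_len = 12L, max_unit = 6L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  rotations <- function(u) {
    w <- nchar(u)
    vapply(0:(w - 1), function(i) {
      paste0(substring(u, i + 1, w), substring(u, 1, i))
    }, "")
  }
  canon <- function(u) min(c(rotations(u), rotations(rc_chr(u))))
  is_prim <- function(u) {
    w <- nchar(u)
    for (d in seq_len(w - 1)) {
      if (w %% d == 0 && strrep(substring(u, 1, d), w / d) == u) return(FALSE)
    }
    TRUE
  }
  out <- NULL
  for (k in seq_len(max_unit)) {
    i <- 1
    while (i + k <= n) {
      # leftmost-maximal: not extendable to the left
      if (i > 1 && i + k - 1 <= n && ch[i - 1] == ch[i + k - 1] &&
          ch[i - 1] != "N") { i <- i + 1; next }
      j <- i
      while (j + k <= n && ch[j + k] == ch[j] && ch[j] != "N") j <- j + 1
      tract_len <- (j - i) + k
      if (tract_len >= max(min_len, 2 * k) &&
          !any(ch[i:(i + k - 1)] == "N")) {
        unit <- paste(ch[i:(i + k - 1)], collapse = "")
        if (is_prim(unit)) {
          out <- rbind(out, data.frame(
            start = i - 1L, end = i - 1L + tract_len,
            canonical_unit = canon(unit), unit_len = k
          ))
        }
      }
      i <- if (j > i) j else i + 1
    }
  }
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      canonical_unit = character(),
                                      unit_len = integer()))
  # same-class overlapping tracts: keep leftmost (mirrors documented rule)
  out <- out[order(out$canonical_unit, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    lc <- out$canonical_unit[1]; le <- out$end[1]
    for (i in 2:nrow(out)) {
      if (out$canonical_unit[i] != lc) {
        lc <- out$canonical_unit[i]; le <- out$end[i]
      } else if (out$start[i] < le) keep[i] <- FALSE
      else le <- out$end[i]
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$end, out$canonical_unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shared synthetic universe for closure tests (built once per test run)
.universe_cache <- new.env(parent = emptyenv())
acceptance_universe <- function() {
  if (is.null(.universe_cache$u)) {
    .universe_cache$u <- generate_universe(synthetic_config(seed = 20141125L %% 1000L))
  }
  .universe_cache$u
}

# small fast universe for pipeline/unit tests
small_universe <- function(seed = 7L) {
  key <- paste0("small", seed)
  if (is.null(.universe_cache[[key]])) {
    cfg <- synthetic_config(
      seed = seed, n_chroms = 2L, chrom_len = 150000L, n_genes = 20L,
      n_mars = 60L,
      ssr_plant_list = data.frame(
        unit = c("A", "AG"), n_units = c(12L, 8L),
        n_in_mars = c(10L, 8L), n_background = c(30L, 25L),
        stringsAsFactors = FALSE
      ),
      te_plant_list = list(
        list(te_id = "synLINE1", type = "LINE", length = 1500L,
             fragment = c(1200L, 1407L), region = "3'-UTR",
             n_copies = 5L, n_in_mars = 2L)
      ),
      n_boundaries = 10L
    )
    .universe_cache[[key]] <- generate_universe(cfg)
  }
  .universe_cache[[key]]
}
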