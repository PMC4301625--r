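#' Configuration for the synthetic MAR universe
#'
#' The defaults ARE the stated world the generator emulates: a
#' multi-chromosome euchromatic genome carrying planted MARs whose size
#' distribution matches the experimentally mapped one (log-normal with
#' median 400 bp, ~90% under 600 bp, truncated to 100-3000 bp), two
#' replicate peak sets with a planted 70% mutual-overlap fraction,
#' controllable tag counts, and per-MAR planted sequence features with
#' probabilities mirroring the published enrichment fractions (ATC rule
#' 0.94, ORI motifs 0.95). 90% of MARs are placed outside gene spans.
#'
#' @param seed RNG seed (single global stream; recorded in the truth
#'   set).
#' @param n_chroms,chrom_len number and length (bp) of chromosomes.
#' @param background_gc GC fraction of the genomic background.
#' @param mar_background_at A+T fraction inside MAR background sequence
#'   (kept at 0.5 so that AT-rich windows only exist where planted).
#' @param n_genes,n_mars counts of genes and MARs.
#' @param mar_size_meanlog,mar_size_sdlog log-normal size parameters;
#'   the defaults put the median at 400 bp and ~90% of sizes under
#'   600 bp.
#' @param mar_size_range truncation bounds in bp.
#' @param category_mix placement probabilities over genomic categories;
#'   must sum to 1.
#' @param replicate_overlap fraction of MARs appearing in both
#'   replicate peak sets.
#' @param peak_jitter_sd SD (bp) of the peak boundary jitter (clamped
#'   at +/- 25 bp so reconciliation recall stays exact).
#' @param tags_per_peak mean mapped tags per peak per replicate.
#' @param background_tag_rate background tags per bp per replicate.
#' @param feature_mix per-feature planting probabilities.
#' @param ssr_plant_list data frame of SSR plantings: `unit`,
#'   `n_units`, `n_in_mars`, `n_background`.
#' @param te_plant_list list of TE families; each entry a list with
#'   `te_id`, `type` ("LINE" or "LTR"), `length`, `fragment`
#'   (0-based half-open span of the canonical sequence planted into
#'   MARs), `region` (annotation label of that span), `n_copies`
#'   (genomic copies) and `n_in_mars` (copies placed inside MARs as
#'   fragments).
#' @param n_boundaries number of chromatin-domain boundary intervals.
#' @param stalled_frac fraction of promoters labeled "stalled".
#' @param exonic_high_frac fraction of exonic-MAR host genes assigned
#'   to the moderate/high expression tiers.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 3L,
                             chrom_len = 300000L,
                             background_gc = 0.42,
                             mar_background_at = 0.50,
                             n_genes = 60L,
                             n_mars = 200L,
                             mar_size_meanlog = log(400),
                             mar_size_sdlog = 0.3164,
                             mar_size_range = c(100L, 3000L),
                             category_mix = c(intergenic = 0.90,
                                              intron = 0.04,
                                              exon = 0.04,
                                              utr5 = 0.01,
                                              utr3 = 0.01),
                             replicate_overlap = 0.7,
                             peak_jitter_sd = 20,
                             tags_per_peak = 50,
                             background_tag_rate = 1e-4,
                             feature_mix = c(atc_rule = 0.94,
                                             ori_motif = 0.95,
                                             at_rich = 0.60,
                                             curved = 0.50,
                                             kinked = 0.25,
                                             topoII = 0.05,
                                             bur = 0.05),
                             ssr_plant_list = default_ssr_plants(),
                             te_plant_list = default_te_plants(),
                             n_boundaries = 30L,
                             stalled_frac = 0.3,
                             exonic_high_frac = 0.75) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(category_mix) - 1) < 1e-9,
            all(category_mix >= 0),
            replicate_overlap >= 0, replicate_overlap <= 1,
            all(feature_mix >= 0), all(feature_mix <= 1),
            cfg$mar_size_range[1] >= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

#' @rdname synthetic_config
#' @export
default_ssr_plants <- function() {
  data.frame(
    unit = c("A", "AG", "AC", "AGC", "AAAAAC"),
    n_units = c(12L, 8L, 8L, 5L, 2L),
    n_in_mars = c(40L, 30L, 30L, 20L, 15L),
    n_background = c(120L, 110L, 110L, 105L, 101L),
    stringsAsFactors = FALSE
  )
}

#' @rdname synthetic_config
#' @export
default_te_plants <- function() {
  list(
    list(te_id = "synLINE1", type = "LINE", length = 3000L,
         fragment = c(2500L, 2707L), region = "3'-UTR",
         n_copies = 10L, n_in_mars = 4L),
    list(te_id = "synLTR1", type = "LTR", length = 2000L,
         fragment = c(0L, 126L), region = "LTR",
         n_copies = 6L, n_in_mars = 6L)
  )
}

# ---------------------------------------------------------------------------
# feature planting instances: fixed sequences verified to trigger exactly
# their own scanner and none of the others (see the package vignette for the
# closure argument); PLANT_AT_RICH_UNIT is a 15-mer with one G and one C so
# that concatenation never builds an ATC-rule run, repeated to clear the
# 100 bp AT-rich window.

PLANT_INSTANCES <- list(
  atc_rule = "ACCTTCACTACCATCCTACT",
  ori_motif = "ATTA",
  curved = "AAAACGCGCGCAAAACGCGCGCAAAA",
  kinked = "TACGCTGCGCCA",
  topoII = "GTCAACATTCATCCG",
  bur = "AATATATTT"
)
PLANT_AT_RICH_UNIT <- "ATACTAGTATCATAT"
PLANT_AT_RICH_REPS <- 8L

plant_instance <- function(feature) {
  if (feature == "at_rich") {
    return(strrep(PLANT_AT_RICH_UNIT, PLANT_AT_RICH_REPS))
  }
  inst <- PLANT_INSTANCES[[feature]]
  if (is.null(inst)) stop("no planting instance for feature ", feature)
  inst
}

#' Plant a feature instance into a sequence
#'
#' Overwrites the sequence at `position` (0-based) with a fixed
#' instance of the named feature, chosen so that the corresponding
#' scanner reports a hit there and no other scanner is triggered by
#' the instance itself.
#'
#' @param seq character scalar.
#' @param feature one of "atc_rule", "ori_motif", "at_rich", "curved",
#'   "kinked", "topoII", "bur", or "ssr" (for which `unit` and
#'   `n_units` must be given).
#' @param position 0-based offset at which to plant.
#' @param unit,n_units SSR unit and repeat count (feature = "ssr").
#' @return modified sequence (character scalar).
#' @export
#' @examples
#' s <- plant_feature(strrep("C", 60), "ori_motif", 10)
#' scan_ori_motifs(s)
plant_feature <- function(seq, feature, position, unit = NULL,
                          n_units = NULL) {
  inst <- if (feature == "ssr") {
    stopifnot(!is.null(unit), !is.null(n_units))
    strrep(unit, n_units)
  } else {
    plant_instance(feature)
  }
  w <- nchar(inst)
  if (position < 0L || position + w > nchar(seq)) {
    stop(sprintf("feature '%s' (%d bp) does not fit at offset %d of a %d bp sequence",
                 feature, w, position, nchar(seq)))
  }
  substr(seq, position + 1L, position + w) <- inst
  seq
}

# ---------------------------------------------------------------------------
# internal generator machinery

# random DNA with given AT fraction
random_dna <- function(n, at) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
}

# MAR/TE-safe background: iid letters with forced G/C breakers every 17 bp
# so neither strand sense can carry a 20 bp ATC-rule run
safe_background <- function(n, at) {
  ch <- random_dna(n, at)
  i <- seq_len(n) - 1L
  ch[i %% 17L == 5L] <- "G"
  ch[i %% 17L == 6L] <- "C"
  ch
}

# overlap test against an occupied (start,end) matrix (0-based half-open)
overlaps_any <- function(start, end, occ) {
  if (is.null(occ) || nrow(occ) == 0L) return(FALSE)
  any(start < occ[, 2L] & end > occ[, 1L])
}

scrub_features <- function(s, protected, planted, min_run = 20L,
                           ssr_min_len = 12L, max_iter = 150L) {
  all_feats <- c("atc_rule", "ori_motif", "at_rich", "curved", "kinked",
                 "topoII", "bur")
  to_clean <- setdiff(all_feats, planted)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  fix_pos <- function(hits) {
    # one mutation per offending hit, at an unprotected position
    for (r in seq_len(nrow(hits))) {
      span <- (hits$start[r] + 1L):(hits$end[r])
      free <- span[!protected[span]]
      if (!length(free)) {
        stop("scrub failed: feature hit fully inside protected spans")
      }
      feat <- hits$feature[r]
      if (feat == "atc_rule") {
        # pure-AT runs belong to both senses: break with an adjacent G+C
        # pair; otherwise one breaker suffices
        p <- free[ceiling(length(free) / 2)]
        ch[p] <<- if (hits$strand[r] == "+") "G" else "C"
        q <- free[free != p]
        if (length(q)) {
          ch[q[1L]] <<- if (hits$strand[r] == "+") "C" else "G"
        }
      } else if (feat == "at_rich") {
        idx <- free[ch[free] %in% c("A", "T")]
        if (!length(idx)) idx <- free
        pick <- idx[seq(1L, length(idx), by = 3L)]
        ch[pick] <<- rep(c("G", "C"), length.out = length(pick))
      } else if (feat == "curved") {
        ch[free[min(2L, length(free))]] <<- "C"
      } else if (feat == "kinked") {
        # a naive single-letter rule can complete a new TA/TG/CA block and
        # ping-pong; greedy local descent over G/C candidates instead
        lo <- max(1L, hits$start[r] - 30L)
        hi <- min(length(ch), hits$end[r] + 30L)
        # count only kinked hits intersecting this hit's span: any hit a
        # candidate mutation creates contains the mutated position, hence
        # also intersects the span, so this objective is sound and local
        local_hits <- function(v) {
          h <- scan_pattern_features(paste(v[lo:hi], collapse = ""),
                                     "kinked")
          if (!nrow(h)) return(0L)
          gs <- h$start + lo - 1L   # back to 0-based global
          ge <- h$end + lo - 1L
          sum(gs < hits$end[r] & ge > hits$start[r])
        }
        cur <- local_hits(ch)
        if (cur == 0L) next   # already resolved by an earlier fix this round
        done <- FALSE
        for (p in free) {
          for (letter in setdiff(c("G", "C", "T", "A"), ch[p])) {
            cand <- ch
            cand[p] <- letter
            if (local_hits(cand) < cur) {
              ch[p] <<- letter
              done <- TRUE
              break
            }
          }
          if (done) break
        }
        if (!done) stop("scrub failed: kinked hit is irreducible")
      } else {
        ch[free[1L]] <<- "C"
      }
    }
  }
  for (iter in seq_len(max_iter)) {
    s <- paste(ch, collapse = "")
    dirty <- FALSE
    for (f in to_clean) {
      hits <- switch(f,
        atc_rule = scan_atc_rule(s, min_run = min_run),
        ori_motif = scan_ori_motifs(s),
        at_rich = scan_at_rich(s),
        scan_pattern_features(s, f)
      )
      if (nrow(hits)) {
        dirty <- TRUE
        fix_pos(hits)
        break
      }
    }
    if (!dirty) {
      # unplanted SSR tracts
      tr <- scan_ssrs(s, min_len = ssr_min_len)
      if (nrow(tr)) {
        drop <- vapply(seq_len(nrow(tr)), function(i) {
          span <- (tr$start[i] + 1L):tr$end[i]
          !all(protected[span])      # fully protected tracts are planted
        }, TRUE)
        tr <- tr[drop, , drop = FALSE]
      }
      if (nrow(tr)) {
        for (i in seq_len(nrow(tr))) {
          span <- (tr$start[i] + 1L):tr$end[i]
          free <- span[!protected[span]]
          p <- free[ceiling(length(free) / 2)]
          k <- tr$unit_len[i]
          forbidden <- ch[c(max(1L, p - k), min(length(ch), p + k),
                            max(1L, p - 1L), min(length(ch), p + 1L))]
          repl <- setdiff(c("G", "C", "T", "A"), forbidden)
          ch[p] <- if (length(repl)) repl[1L] else "N"
        }
        dirty <- TRUE
      }
    }
    if (!dirty) return(paste(ch, collapse = ""))
  }
  stop("scrub_features did not converge")
}

# gene-local structure (plus strand, 0-based half-open, gene length 3000):
# exon1 [0,400) (utr5 = [0,200)), intron1, exon2 [1200,1700),
# intron2, exon3 [2500,3000) (utr3 = [2700,3000)); minus strand mirrored
GENE_LEN <- 3000L

gene_segments <- function(strand) {
  segs <- list(
    exon = rbind(c(0L, 400L), c(1200L, 1700L), c(2500L, 3000L)),
    utr5 = rbind(c(0L, 200L)),
    utr3 = rbind(c(2700L, 3000L)),
    coding = rbind(c(1200L, 1700L)),     # exon region clear of both UTRs
    intron = rbind(c(400L, 1200L), c(1700L, 2500L))
  )
  if (strand == "-") {
    segs <- lapply(segs, function(m) {
      m2 <- cbind(GENE_LEN - m[, 2L], GENE_LEN - m[, 1L])
      m2[order(m2[, 1L]), , drop = FALSE]
    })
  }
  segs
}

#' Generate a synthetic MAR universe with planted ground truth
#'
#' Builds a deterministic (per seed) multi-chromosome genome with gene
#' models, planted non-overlapping MARs (sizes, genomic-category mix
#' and per-MAR sequence features as configured), SSR tracts inside and
#' outside MARs, transposable-element canonical sequences with genomic
#' copies and MAR-planted fragments, two jittered replicate peak sets
#' covering a configured fraction of MARs in common, per-replicate tag
#' positions, promoter and boundary interval sets and gene expression
#' tiers. MAR background sequence is scrubbed so that a MAR carries a
#' sequence feature exactly when the generator planted it.
#'
#' @param config a [synthetic_config()].
#' @param outdir optional directory; when given, all standard files
#'   (FASTA/GFF3/BED/TSV and a metadata JSON) are written there.
#' @return a list (the truth set) with elements `config`,
#'   `chrom_sizes`, `genome` (DNAStringSet), `genes` (a
#'   [gene_models()]), `mars` (interval_set, names "mar0001"...),
#'   `mar_truth` (data frame: category, in_both, per-feature planted
#'   flags, TE fragment info), `rep1`, `rep2`, `tags1`, `tags2`,
#'   `ssr_truth`, `te` (list: `seqs`, `types`, `lengths`,
#'   `annotation`, `copies`), `promoters`, `boundaries`, `expression`,
#'   `exonic_mars`, and `files` (paths, when `outdir` was given).
#' @export
generate_universe <- function(config = synthetic_config(), outdir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(as.numeric(config$chrom_len),
                              config$n_chroms), chroms)

  # -- genome background ----------------------------------------------------
  genome_ch <- lapply(chroms, function(ch) {
    random_dna(config$chrom_len, at = 1 - config$background_gc)
  })
  names(genome_ch) <- chroms

  # -- genes: evenly slotted, random offset and strand ----------------------
  ngpc <- ceiling(config$n_genes / config$n_chroms)
  gene_rows <- list()
  gid <- 0L
  for (ch in chroms) {
    slot <- config$chrom_len %/% ngpc
    if (slot < GENE_LEN + 6000L) stop("chromosomes too short for gene slots")
    for (k in seq_len(ngpc)) {
      if (gid >= config$n_genes) break
      gid <- gid + 1L
      off <- (k - 1L) * slot +
        sample(3000L:(slot - GENE_LEN - 3000L), 1L)
      gene_rows[[gid]] <- data.frame(
        gene_id = sprintf("gene%03d", gid), chrom = ch,
        strand = sample(c("+", "-"), 1L),
        start = off, end = off + GENE_LEN, stringsAsFactors = FALSE
      )
    }
  }
  gdf <- do.call(rbind, gene_rows)
  feat_rows <- lapply(seq_len(nrow(gdf)), function(i) {
    segs <- gene_segments(gdf$strand[i])
    do.call(rbind, lapply(c("exon", "utr5", "utr3"), function(t) {
      data.frame(gene_id = gdf$gene_id[i], type = t, chrom = gdf$chrom[i],
                 start = gdf$start[i] + segs[[t]][, 1L],
                 end = gdf$start[i] + segs[[t]][, 2L],
                 stringsAsFactors = FALSE)
    }))
  })
  genes <- gene_models(gdf, do.call(rbind, feat_rows))

  # occupancy ledgers (0-based half-open), per chromosome
  gene_occ <- lapply(chroms, function(ch) {
    g <- gdf[gdf$chrom == ch, , drop = FALSE]
    cbind(g$start - 500L, g$end + 500L)
  })
  names(gene_occ) <- chroms
  mar_occ <- setNames(lapply(chroms, function(ch) {
    matrix(numeric(0), ncol = 2L)
  }), chroms)
  aux_occ <- mar_occ   # SSR background loci, TE copies, boundaries

  # -- MAR placement --------------------------------------------------------
  n <- config$n_mars
  cats <- sample(names(config$category_mix), n, replace = TRUE,
                 prob = config$category_mix)
  sizes <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      s <- round(rlnorm(1, config$mar_size_meanlog, config$mar_size_sdlog))
      if (s >= config$mar_size_range[1] && s <= config$mar_size_range[2]) {
        sizes[i] <- as.integer(s)
        break
      }
    }
  }
  mar_gap <- 200L
  mars_df <- data.frame(chrom = character(n), start = integer(n),
                        end = integer(n), category = cats,
                        gene_id = NA_character_, stringsAsFactors = FALSE)
  genic_cats <- c("intron", "exon", "utr5", "utr3")
  seg_key <- c(intron = "intron", exon = "coding", utr5 = "utr5",
               utr3 = "utr3")
  # one exonic MAR per gene so expression tiers map 1:1
  gene_pool <- sample(gdf$gene_id)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(3000L)) {
      if (cats[i] %in% genic_cats) {
        if (!length(gene_pool)) stop("infeasible placement: out of genes")
        g <- gdf[gdf$gene_id == gene_pool[1L], , drop = FALSE]
        segs <- gene_segments(g$strand)[[seg_key[cats[i]]]]
        seg <- segs[sample(nrow(segs), 1L), ]
        mid <- g$start + seg[1L] + sample(seq_len(seg[2L] - seg[1L] - 20L) +
                                            9L, 1L)
        ch <- g$chrom
      } else {
        ch <- sample(chroms, 1L)
        mid <- sample(1000L:(config$chrom_len - 1000L), 1L)
      }
      st <- mid - sizes[i] %/% 2L
      en <- st + sizes[i]
      if (st < 500L || en > config$chrom_len - 500L) next
      if (overlaps_any(st - mar_gap, en + mar_gap, mar_occ[[ch]])) next
      if (cats[i] == "intergenic" &&
          overlaps_any(st, en, gene_occ[[ch]])) next
      mars_df$chrom[i] <- ch
      mars_df$start[i] <- st
      mars_df$end[i] <- en
      if (cats[i] %in% genic_cats) {
        mars_df$gene_id[i] <- gene_pool[1L]
        gene_pool <- gene_pool[-1L]
      }
      mar_occ[[ch]] <- rbind(mar_occ[[ch]], c(st, en))
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible placement: too many/too large MARs")
  }
  mars_df$name <- sprintf("mar%04d", seq_len(n))

  # -- TE canonical sequences ----------------------------------------------
  te_specs <- config$te_plant_list
  te_seqs <- list()
  for (sp in te_specs) {
    seq_ok <- NULL
    for (attempt in seq_len(10L)) {
      bg <- paste(safe_background(sp$length, at = 0.5), collapse = "")
      seq_ok <- tryCatch(
        scrub_features(bg, protected = rep(FALSE, sp$length),
                       planted = character()),
        error = function(e) NULL
      )
      if (!is.null(seq_ok)) break
    }
    if (is.null(seq_ok)) {
      stop("could not build a scrubbed TE sequence after 10 attempts")
    }
    te_seqs[[sp$te_id]] <- seq_ok
  }

  # -- per-MAR content: TE fragments, SSR tracts, features ------------------
  feature_names <- names(config$feature_mix)
  planted_mat <- matrix(FALSE, nrow = n, ncol = length(feature_names),
                        dimnames = list(mars_df$name, feature_names))
  ssr_truth <- list()
  te_frag_rows <- list()
  te_copy_rows <- list()

  # which MARs get TE fragments / SSR tracts
  frag_assign <- rep(NA_integer_, n)   # index into te_specs
  avail <- order(-sizes)               # biggest MARs first
  ai <- 1L
  for (t in seq_along(te_specs)) {
    need <- te_specs[[t]]$n_in_mars
    fl <- te_specs[[t]]$fragment[2L] - te_specs[[t]]$fragment[1L]
    got <- 0L
    while (got < need && ai <= n) {
      i <- avail[ai]; ai <- ai + 1L
      if (sizes[i] >= fl + 40L && is.na(frag_assign[i])) {
        frag_assign[i] <- t
        got <- got + 1L
      }
    }
    if (got < need) stop("infeasible placement: MARs too small for TE fragments")
  }
  ssr_assign <- vector("list", n)
  for (r in seq_len(nrow(config$ssr_plant_list))) {
    spec <- config$ssr_plant_list[r, ]
    pool <- sample(which(sizes >= nchar(spec$unit) * spec$n_units + 60L))
    cnt <- 0L; j <- 1L
    while (cnt < spec$n_in_mars && j <= length(pool)) {
      i <- pool[j]; j <- j + 1L
      ssr_assign[[i]] <- c(ssr_assign[[i]], r)
      cnt <- cnt + 1L
    }
    if (cnt < spec$n_in_mars) stop("infeasible placement: SSR plants")
  }

  for (i in seq_len(n)) {
    L <- sizes[i]
    ch <- mars_df$chrom[i]
    # feature choices are drawn once per MAR; background and plant
    # positions are redrawn if scrubbing fails to converge
    want_feat <- runif(length(feature_names)) <= unlist(config$feature_mix)
    names(want_feat) <- feature_names
    built <- NULL
    for (attempt in seq_len(10L)) {
      s <- paste(safe_background(L, at = config$mar_background_at),
                 collapse = "")
      protected <- rep(FALSE, L)
      rec <- list(te_frag = NULL, ssr = list(), planted = rep(FALSE,
                                                             length(feature_names)))
      names(rec$planted) <- feature_names
      # free-gap allocator inside the MAR
      alloc <- function(w) {
        free_runs <- rle(!protected)
        ends <- cumsum(free_runs$lengths)
        begs <- ends - free_runs$lengths + 1L
        ok <- which(free_runs$values & free_runs$lengths >= w + 2L)
        if (!length(ok)) return(NA_integer_)
        j <- ok[sample(length(ok), 1L)]
        begs[j] + sample(free_runs$lengths[j] - w - 1L, 1L)   # 1-based
      }
      # TE fragment
      if (!is.na(frag_assign[i])) {
        sp <- te_specs[[frag_assign[i]]]
        frag <- substr(te_seqs[[sp$te_id]], sp$fragment[1L] + 1L,
                       sp$fragment[2L])
        w <- nchar(frag)
        beg <- alloc(w)
        if (is.na(beg)) stop("internal: TE fragment does not fit")
        substr(s, beg, beg + w - 1L) <- frag
        protected[beg:(beg + w - 1L)] <- TRUE
        gstart <- mars_df$start[i] + beg - 1L
        rec$te_frag <- data.frame(
          te_id = sp$te_id, mar = mars_df$name[i],
          te_start = sp$fragment[1L], te_end = sp$fragment[2L],
          chrom = ch, start = gstart, end = gstart + w,
          stringsAsFactors = FALSE
        )
      }
      # SSR tracts
      for (r in ssr_assign[[i]]) {
        spec <- config$ssr_plant_list[r, ]
        tract <- strrep(spec$unit, spec$n_units)
        w <- nchar(tract)
        beg <- alloc(w + 2L)
        if (is.na(beg)) next
        brk <- setdiff(c("G", "C", "T", "A"),
                       strsplit(spec$unit, "")[[1]])[1L]
        substr(s, beg, beg + w + 1L) <- paste0(brk, tract, brk)
        protected[beg:(beg + w + 1L)] <- TRUE
        rec$ssr[[length(rec$ssr) + 1L]] <- data.frame(
          chrom = ch, start = mars_df$start[i] + beg, # tract after brk
          end = mars_df$start[i] + beg + w,
          unit = spec$unit,
          canonical_unit = canonical_ssr_unit(spec$unit),
          in_mar = TRUE, stringsAsFactors = FALSE
        )
      }
      # sequence features
      for (f in feature_names[want_feat]) {
        inst <- plant_instance(f)
        w <- nchar(inst)
        beg <- alloc(w)
        if (is.na(beg)) next
        substr(s, beg, beg + w - 1L) <- inst
        protected[beg:(beg + w - 1L)] <- TRUE
        rec$planted[f] <- TRUE
      }
      s2 <- tryCatch(
        scrub_features(s, protected,
                       planted = feature_names[rec$planted]),
        error = function(e) NULL
      )
      if (!is.null(s2)) {
        built <- list(s = s2, rec = rec)
        break
      }
    }
    if (is.null(built)) {
      stop("could not build a scrubbed MAR sequence after 10 attempts")
    }
    rec <- built$rec
    planted_mat[i, ] <- rec$planted
    if (!is.null(rec$te_frag)) {
      te_frag_rows[[length(te_frag_rows) + 1L]] <- rec$te_frag
      te_copy_rows[[length(te_copy_rows) + 1L]] <- data.frame(
        chrom = rec$te_frag$chrom, start = rec$te_frag$start,
        end = rec$te_frag$end, name = rec$te_frag$te_id,
        stringsAsFactors = FALSE
      )
    }
    for (d in rec$ssr) ssr_truth[[length(ssr_truth) + 1L]] <- d
    genome_ch[[ch]][(mars_df$start[i] + 1L):mars_df$end[i]] <-
      strsplit(built$s, "", fixed = TRUE)[[1]]
  }

  # -- background SSR loci --------------------------------------------------
  for (r in seq_len(nrow(config$ssr_plant_list))) {
    spec <- config$ssr_plant_list[r, ]
    tract <- strrep(spec$unit, spec$n_units)
    w <- nchar(tract) + 2L
    brk <- setdiff(c("G", "C", "T", "A"),
                   strsplit(spec$unit, "")[[1]])[1L]
    for (k in seq_len(spec$n_background)) {
      for (try in seq_len(3000L)) {
        ch <- sample(chroms, 1L)
        st <- sample(1000L:(config$chrom_len - 1000L - w), 1L)
        if (overlaps_any(st, st + w, mar_occ[[ch]])) next
        if (overlaps_any(st, st + w, aux_occ[[ch]])) next
        genome_ch[[ch]][(st + 1L):(st + w)] <-
          strsplit(paste0(brk, tract, brk), "", fixed = TRUE)[[1]]
        aux_occ[[ch]] <- rbind(aux_occ[[ch]], c(st, st + w))
        ssr_truth[[length(ssr_truth) + 1L]] <- data.frame(
          chrom = ch, start = st + 1L, end = st + 1L + nchar(tract),
          unit = spec$unit,
          canonical_unit = canonical_ssr_unit(spec$unit),
          in_mar = FALSE, stringsAsFactors = FALSE
        )
        break
      }
    }
  }
  ssr_truth <- do.call(rbind, ssr_truth)

  # -- full-length TE copies outside MARs -----------------------------------
  for (t in seq_along(te_specs)) {
    sp <- te_specs[[t]]
    n_free <- sp$n_copies - sp$n_in_mars
    if (n_free <= 0L) next
    for (k in seq_len(n_free)) {
      for (try in seq_len(3000L)) {
        ch <- sample(chroms, 1L)
        st <- sample(1000L:(config$chrom_len - 1000L - sp$length), 1L)
        if (overlaps_any(st, st + sp$length, mar_occ[[ch]])) next
        if (overlaps_any(st, st + sp$length, aux_occ[[ch]])) next
        if (overlaps_any(st, st + sp$length, gene_occ[[ch]])) next
        genome_ch[[ch]][(st + 1L):(st + sp$length)] <-
          strsplit(te_seqs[[sp$te_id]], "", fixed = TRUE)[[1]]
        aux_occ[[ch]] <- rbind(aux_occ[[ch]], c(st, st + sp$length))
        te_copy_rows[[length(te_copy_rows) + 1L]] <- data.frame(
          chrom = ch, start = st, end = st + sp$length,
          name = sp$te_id, stringsAsFactors = FALSE
        )
        break
      }
    }
  }
  te_copies_df <- do.call(rbind, te_copy_rows)
  te_copies <- interval_set(te_copies_df$chrom, te_copies_df$start,
                            te_copies_df$end, name = te_copies_df$name)

  # -- replicate peaks ------------------------------------------------------
  in_both <- runif(n) < config$replicate_overlap
  jit <- function(x) {
    as.integer(x + pmax(pmin(round(rnorm(length(x),
                                         sd = config$peak_jitter_sd)),
                             25L), -25L))
  }
  single_rep <- rep_len(c(1L, 2L), n)   # alternate singles between reps
  mk_rep <- function(which_rep) {
    use <- in_both | single_rep == which_rep
    interval_set(mars_df$chrom[use], jit(mars_df$start[use]),
                 jit(mars_df$end[use]), name = mars_df$name[use])
  }
  rep1 <- mk_rep(1L)
  rep2 <- mk_rep(2L)

  # -- tags -----------------------------------------------------------------
  mk_tags <- function(peaks) {
    rows <- lapply(seq_len(nrow(peaks)), function(j) {
      m <- rpois(1L, config$tags_per_peak)
      if (m == 0L) return(NULL)
      data.frame(chrom = peaks$chrom[j],
                 start = as.integer(peaks$start[j] +
                                      floor(runif(m) *
                                              (peaks$end[j] - peaks$start[j]))),
                 strand = sample(c("+", "-"), m, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    bg <- lapply(chroms, function(ch) {
      m <- rpois(1L, config$background_tag_rate * config$chrom_len)
      if (m == 0L) return(NULL)
      data.frame(chrom = ch,
                 start = as.integer(floor(runif(m) * config$chrom_len)),
                 strand = sample(c("+", "-"), m, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, bg))
    out[order(out$chrom, out$start), , drop = FALSE]
  }
  tags1 <- mk_tags(rep1)
  tags2 <- mk_tags(rep2)

  # -- promoters & boundaries ----------------------------------------------
  prom <- interval_set(
    gdf$chrom,
    pmax(genes$genes$tss - 300L, 0L),
    pmin(genes$genes$tss + 301L, config$chrom_len),
    name = ifelse(runif(nrow(gdf)) < config$stalled_frac,
                  "stalled", "active")
  )
  brows <- list()
  for (k in seq_len(config$n_boundaries)) {
    for (try in seq_len(3000L)) {
      ch <- sample(chroms, 1L)
      st <- sample(1000L:(config$chrom_len - 3000L), 1L)
      if (overlaps_any(st, st + 1000L, mar_occ[[ch]])) next
      if (overlaps_any(st, st + 1000L, aux_occ[[ch]])) next
      aux_occ[[ch]] <- rbind(aux_occ[[ch]], c(st, st + 1000L))
      brows[[k]] <- data.frame(chrom = ch, start = st, end = st + 1000L,
                               stringsAsFactors = FALSE)
      break
    }
  }
  brows <- do.call(rbind, brows)
  boundaries <- interval_set(brows$chrom, brows$start, brows$end)

  # -- expression tiers -----------------------------------------------------
  exonic <- which(mars_df$category == "exon")
  exonic_mars <- data.frame(mar = mars_df$name[exonic],
                            gene_id = mars_df$gene_id[exonic],
                            stringsAsFactors = FALSE)
  n_hi <- round(config$exonic_high_frac * nrow(exonic_mars))
  tier <- setNames(sample(c("low", "moderate", "high"), nrow(gdf),
                          replace = TRUE), gdf$gene_id)
  if (nrow(exonic_mars)) {
    hi <- exonic_mars$gene_id[seq_len(n_hi)]
    lo <- setdiff(exonic_mars$gene_id, hi)
    tier[hi] <- rep_len(c("high", "moderate"), length(hi))
    tier[lo] <- "low"
  }
  expression <- data.frame(gene_id = names(tier), tier = unname(tier),
                           stringsAsFactors = FALSE)

  genome <- Biostrings::DNAStringSet(
    vapply(genome_ch, paste, "", collapse = "")
  )
  names(genome) <- chroms

  mars <- interval_set(mars_df$chrom, mars_df$start, mars_df$end,
                       name = mars_df$name, chrom_sizes = chrom_sizes)
  ord <- match(mars$name, mars_df$name)
  mar_truth <- data.frame(
    mar = mars$name,
    category = mars_df$category[ord],
    gene_id = mars_df$gene_id[ord],
    in_both = in_both[ord],
    planted_mat[ord, , drop = FALSE],
    stringsAsFactors = FALSE
  )
  rownames(mar_truth) <- NULL

  te <- list(
    seqs = unlist(te_seqs),
    types = setNames(vapply(te_specs, `[[`, "", "type"),
                     vapply(te_specs, `[[`, "", "te_id")),
    lengths = setNames(vapply(te_specs, function(x) x$length, 0L),
                       vapply(te_specs, `[[`, "", "te_id")),
    annotation = do.call(rbind, lapply(te_specs, function(sp) {
      data.frame(te_id = sp$te_id, region = sp$region,
                 start = sp$fragment[1L], end = sp$fragment[2L],
                 stringsAsFactors = FALSE)
    })),
    copies = te_copies,
    fragments = if (length(te_frag_rows)) do.call(rbind, te_frag_rows)
                else NULL
  )

  truth <- list(
    config = config, chrom_sizes = chrom_sizes, genome = genome,
    genes = genes, mars = mars, mar_truth = mar_truth,
    rep1 = rep1, rep2 = rep2, tags1 = tags1, tags2 = tags2,
    ssr_truth = ssr_truth, te = te, promoters = prom,
    boundaries = boundaries, expression = expression,
    exonic_mars = exonic_mars
  )
  if (!is.null(outdir)) {
    truth$files <- write_universe(truth, outdir)
  }
  truth
}

# write all standard-format files of a universe
write_universe <- function(truth, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  Biostrings::writeXStringSet(truth$genome, p("genome.fa"))
  write_gff3(truth$genes, p("genes.gff3"))
  write_bed(truth$mars, p("mars_truth.bed"))
  write_bed(truth$rep1, p("rep1_peaks.bed"))
  write_bed(truth$rep2, p("rep2_peaks.bed"))
  for (tg in c("tags1", "tags2")) {
    df <- truth[[tg]]
    write.table(
      data.frame(df$chrom, df$start, df$start + 24L, ".", 0, df$strand),
      p(paste0(tg, ".bed")), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  tes <- Biostrings::DNAStringSet(truth$te$seqs)
  Biostrings::writeXStringSet(tes, p("te_canonical.fa"))
  write_bed(truth$te$copies, p("te_copies.bed"))
  write_bed(truth$promoters, p("promoters.bed"))
  write_bed(truth$boundaries, p("boundaries.bed"))
  write.table(truth$expression, p("expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(chrom = names(truth$chrom_sizes),
               size = as.integer(truth$chrom_sizes)),
    p("chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  jsonlite::write_json(
    list(seed = truth$config$seed,
         n_mars = truth$config$n_mars,
         replicate_overlap = truth$config$replicate_overlap,
         package_version = as.character(packageVersion("marscan"))),
    p("metadata.json"), auto_unbox = TRUE
  )
  setNames(
    file.path(outdir, c("genome.fa", "genes.gff3", "mars_truth.bed",
                        "rep1_peaks.bed", "rep2_peaks.bed", "tags1.bed",
                        "tags2.bed", "te_canonical.fa", "te_copies.bed",
                        "promoters.bed", "boundaries.bed", "expression.tsv",
                        "chrom.sizes", "metadata.json")),
    c("genome", "gff3", "mars_truth", "rep1", "rep2", "tags1", "tags2",
      "te_fasta", "te_copies", "promoters", "boundaries", "expression",
      "chrom_sizes", "metadata")
  )
}

# minimal GFF3 writer for gene_models (one mRNA per gene)
write_gff3 <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  g <- genes$genes
  f <- genes$features
  lines <- c("##gff-version 3")
  type_out <- c(exon = "exon", utr5 = "five_prime_UTR",
                utr3 = "three_prime_UTR")
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines,
      sprintf("%s\tmarscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i], gid),
      sprintf("%s\tmarscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i], gid, gid)
    )
    ff <- f[f$gene_id == gid, , drop = FALSE]
    if (nrow(ff)) {
      lines <- c(lines, sprintf(
        "%s\tmarscan\t%s\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
        ff$chrom, type_out[ff$type], ff$start + 1L, ff$end,
        g$strand[i], gid
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
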