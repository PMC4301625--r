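test_that("normalize_seq uppercases and maps non-ACGT to N", {
  expect_equal(normalize_seq("acgtRyn-"), "ACGTNNNN")
})

test_that("scan_atc_rule finds strand-sense runs with N/G breaks", {
  h <- scan_atc_rule(strrep("A", 20))
  # a pure-A run satisfies both senses: one hit per sense
  expect_equal(nrow(h), 2L)
  expect_setequal(h$strand, c("+", "-"))
  expect_equal(unique(h$start), 0L)
  expect_equal(unique(h$end), 20L)
  # G breaks the plus-sense run at 19
  h2 <- scan_atc_rule(paste0(strrep("A", 19), "G"))
  expect_equal(sum(h2$strand == "+"), 0L)
  # ...but the full 20 bp is a minus-sense ({A,T,G}) run
  expect_equal(sum(h2$strand == "-"), 1L)
  # N breaks both senses
  h3 <- scan_atc_rule(paste0(strrep("A", 10), "N", strrep("A", 10)))
  expect_equal(nrow(h3), 0L)
  # custom threshold
  expect_equal(nrow(scan_atc_rule(strrep("T", 10), min_run = 10)), 2L)
})

test_that("scan_atc_rule agrees with a brute-force scan", {
  set.seed(42)
  for (rep in 1:5) {
    s <- rand_dna(2000, at = 0.7)
    got <- scan_atc_rule(s)
    want <- naive_atc_runs(s)
    got <- got[order(got$strand, got$start), c("start", "end", "strand")]
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want$strand, want$start), ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("scan_ori_motifs reports all overlapping occurrences, both strands", {
  h <- scan_ori_motifs("ATTA")
  expect_equal(nrow(h), 1L)
  expect_equal(h$motif, "ATTA")
  expect_equal(h$strand, "+")
  # ATTTA is not an ATTA occurrence
  h2 <- scan_ori_motifs("ATTTA")
  expect_equal(h2$motif, "ATTTA")
  expect_equal(nrow(h2), 1L)
  # reverse complement reported as minus strand, motif keeps + identity
  h3 <- scan_ori_motifs("TAAT")
  expect_equal(h3$strand, "-")
  expect_equal(h3$motif, "ATTA")
  # overlapping occurrences all reported
  h4 <- scan_ori_motifs("ATTATTA")
  expect_equal(sum(h4$motif == "ATTA" & h4$strand == "+"), 2L)
})

test_that("scan_ori_motifs agrees with a brute-force scan", {
  set.seed(43)
  s <- rand_dna(3000, at = 0.65)
  got <- scan_ori_motifs(s)
  want <- naive_ori(s)
  key <- function(d) sort(paste(d$start, d$end, d$strand, d$motif))
  expect_equal(key(got), key(want))
})

test_that("scan_at_rich merges qualifying windows into maximal regions", {
  h <- scan_at_rich(strrep("AT", 60))
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 120L))
  expect_equal(nrow(scan_at_rich(strrep("GC", 60))), 0L)
  # shorter than the window: no hit possible
  expect_equal(nrow(scan_at_rich(strrep("AT", 40))), 0L)
})

test_that("scan_at_rich agrees with a brute-force sliding window", {
  set.seed(44)
  for (at in c(0.4, 0.65)) {
    s <- rand_dna(5000, at = at)
    got <- scan_at_rich(s)
    want <- naive_at_rich(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got[, c("start", "end")],
                   want[, c("start", "end")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("scan_pattern_features matches IUPAC patterns on both strands", {
  # curved: three A4 blocks with 7 bp spacers
  curved <- "AAAACGCGCGCAAAACGCGCGCAAAA"
  h <- scan_pattern_features(curved, "curved")
  expect_equal(sum(h$strand == "+"), 1L)
  expect_equal(h$start[h$strand == "+"], 0L)
  # TTTT version matches as the reverse complement (minus strand)
  h2 <- scan_pattern_features(chartr("ACGT", "TGCA", curved), "curved")
  expect_equal(sum(h2$strand == "-"), 1L)
  # kinked: TA-N3-TG-N3-CA
  h3 <- scan_pattern_features("TACGCTGCGCCA", "kinked")
  expect_true(any(h3$start == 0L & h3$end == 12L))
  expect_error(scan_pattern_features("ACGT", "nosuch"), "unknown feature")
  # N in the subject matches nothing
  expect_equal(nrow(scan_pattern_features("AAAANNNNNNNAAAANNNNNNNAAAA",
                                          "curved")), 0L)
})

test_that("pattern scanner agrees with a position-by-position matcher", {
  set.seed(45)
  reg <- feature_registry()
  s <- paste0(rand_dna(4000, at = 0.62),
              "TACGCTGCGCCA", "GTCAACATTCATCCG",
              rand_dna(500, at = 0.62))
  for (f in names(reg)) {
    got <- scan_pattern_features(s, f, reg)
    want <- NULL
    for (pat in reg[[f]]) {
      p <- naive_iupac_positions(s, pat)
      if (length(p)) want <- rbind(want, data.frame(start = p, strand = "+"))
      p <- naive_iupac_positions(s, rc_chr(pat))
      if (length(p)) want <- rbind(want, data.frame(start = p, strand = "-"))
    }
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- unique(want)
      expect_equal(sort(paste(got$start, got$strand)),
                   sort(paste(want$start, want$strand)),
                   info = f)
    }
  }
})

test_that("scanners are strand-consistent under reverse complement", {
  set.seed(46)
  s <- rand_dna(2000, at = 0.68)
  rc <- revcomp(s)
  L <- nchar(s)
  mirror <- function(h) {
    data.frame(start = L - h$end, end = L - h$start,
               strand = chartr("+-", "-+", h$strand))
  }
  for (scanner in list(scan_ori_motifs,
                       function(x) scan_pattern_features(x, "topoII"),
                       function(x) scan_atc_rule(x, min_run = 10))) {
    a <- scanner(s)
    b <- scanner(rc)
    key <- function(d) sort(paste(d$start, d$end, d$strand))
    expect_equal(key(mirror(b)), key(a[, c("start", "end", "strand")]))
  }
})

test_that("mar_sequences extracts and validates against genome bounds", {
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTAC"))
  m <- interval_set("c1", 2, 6)
  expect_equal(unname(mar_sequences(m, genome)), "GTAC")
  expect_error(mar_sequences(interval_set("c1", 5, 12), genome),
               "outside genome bounds: c1:5-12")
  expect_error(mar_sequences(interval_set("c9", 0, 5), genome),
               "not in genome")
})

test_that("feature_enrichment_table reports per-feature MAR fractions", {
  # poly-A carries the run on both senses; alternating GC carries none on
  # either (a poly-G MAR would still satisfy the rule via its complement
  # strand, which is poly-C)
  genome <- Biostrings::DNAStringSet(c(
    c1 = paste0(strrep("A", 30), strrep("GC", 15))
  ))
  mars <- interval_set(c("c1", "c1"), c(0, 30), c(30, 60))
  tab <- feature_enrichment_table(mars, genome)
  expect_equal(tab$frac_mars[tab$feature == "atc_rule"], 0.5)
  expect_equal(attr(tab, "n_mars"), 2L)
  expect_true(all(tab$frac_mars >= 0 & tab$frac_mars <= 1))
  # hit-count table exposes raw counts
  ht <- feature_hit_table(mars, genome)
  expect_equal(nrow(ht), 2L)
  expect_true(ht$atc_rule[1] > 0L)
  expect_equal(ht$atc_rule[2], 0L)
})
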