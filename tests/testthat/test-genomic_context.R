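# two-gene annotation used across blocks: plus- and minus-strand genes
# with UTR/exon/intron structure
demo_genes <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = c("c1", "c1"),
    strand = c("+", "-"), start = c(1000L, 10000L), end = c(4000L, 13000L)
  )
  features <- data.frame(
    gene_id = c("gA", "gA", "gA", "gA",
                "gB", "gB", "gB", "gB"),
    type = c("exon", "exon", "utr5", "utr3",
             "exon", "exon", "utr5", "utr3"),
    chrom = "c1",
    start = c(1000L, 3000L, 1000L, 3800L,
              10000L, 12000L, 12800L, 10000L),
    end = c(1500L, 4000L, 1200L, 4000L,
            10500L, 13000L, 13000L, 10200L)
  )
  gene_models(genes, features)
}

test_that("gene_models derives the TSS from strand", {
  g <- demo_genes()
  expect_equal(g$genes$tss, c(1000L, 12999L))
  expect_error(gene_models(data.frame(gene_id = "x", chrom = "c",
                                      strand = "?", start = 1, end = 2)))
})

test_that("classify_mars assigns midpoint categories with precedence", {
  g <- demo_genes()
  mars <- interval_set(
    rep("c1", 6),
    c(1050, 3100, 2000, 6000, 12850, 10050),
    c(1150, 3300, 2300, 6400, 12950, 10150)
  )
  cls <- classify_mars(mars, g)
  lab <- cls$labels
  get <- function(s) lab$category[lab$start == s]
  expect_equal(get(1050), "utr5")       # inside exon AND utr5 -> utr5 wins
  expect_equal(get(3100), "exon")       # coding exon
  expect_equal(get(2000), "intron")     # in gene span, outside exons
  expect_equal(get(6000), "intergenic")
  expect_equal(get(12850), "utr5")      # minus-strand 5' UTR at gene end
  expect_equal(get(10050), "utr3")      # utr3 beats the containing exon
  expect_equal(sum(cls$fractions), 1)
  expect_equal(unname(cls$fractions["intergenic"]), 1 / 6)
  # gene attribution travels with the label
  expect_equal(lab$gene_id[lab$start == 3100], "gA")
  expect_true(is.na(lab$gene_id[lab$start == 6000]))
  # mean size per category
  expect_equal(unname(cls$mean_size["intergenic"]), 400)
  # noncoding aggregations with and without UTRs
  expect_equal(unname(cls$noncoding_frac["excluding_utrs"]), 2 / 6)
  expect_equal(unname(cls$noncoding_frac["including_utrs"]), 5 / 6)
})

test_that("tss_profile orients offsets by strand", {
  g <- gene_models(data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                              start = 5000L, end = 8000L))
  m <- interval_set("c1", 5050, 5150)   # midpoint 5100 -> offset +100
  pr <- tss_profile(m, g)
  expect_equal(pr$n_contributions, 1L)
  bin <- findInterval(100, pr$breaks, rightmost.closed = TRUE)
  expect_equal(pr$counts[bin], 1L)
  expect_true(pr$mode_offset >= 100 - 50 && pr$mode_offset <= 150)
  # same geometry on the minus strand: TSS 4999 is end-1 of span 2000-5000
  g2 <- gene_models(data.frame(gene_id = "g2", chrom = "c1", strand = "-",
                               start = 2000L, end = 5000L))
  m2 <- interval_set("c1", 4849, 4949)  # midpoint 4899 -> offset +100
  pr2 <- tss_profile(m2, g2)
  expect_equal(pr2$counts, pr$counts)
  # translation invariance
  g3 <- gene_models(data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                               start = 15000L, end = 18000L))
  m3 <- interval_set("c1", 15050, 15150)
  expect_equal(tss_profile(m3, g3)$counts, pr$counts)
  # a midpoint outside the flank contributes nothing
  far <- interval_set("c1", 8000, 8100)
  expect_equal(tss_profile(far, g)$n_contributions, 0L)
})

test_that("tss_profile multi-TSS and nearest modes", {
  genes <- gene_models(data.frame(
    gene_id = c("g1", "g2"), chrom = "c1", strand = "+",
    start = c(5000L, 5400L), end = c(8000L, 8400L)
  ))
  m <- interval_set("c1", 5150, 5250)   # midpoint 5200: +200 / -200
  expect_equal(tss_profile(m, genes, mode = "all")$n_contributions, 2L)
  nearest <- tss_profile(m, genes, mode = "nearest")
  expect_equal(nearest$n_contributions, 1L)
})

test_that("polII_overlap reports per-label overlap fractions", {
  prom <- interval_set(rep("c1", 10), seq(0, 9000, 1000),
                       seq(0, 9000, 1000) + 601,
                       name = rep(c("stalled", "active"), 5))
  mars <- interval_set(rep("c1", 2), c(100, 1100), c(300, 1300))
  ov <- polII_overlap(mars, prom)
  expect_equal(ov$frac_overlapping[ov$label == "stalled"], 0.2)
  expect_equal(ov$frac_overlapping[ov$label == "active"], 0.2)
  # empty MAR set -> all zero
  ov0 <- polII_overlap(mars[0, ], prom)
  expect_true(all(ov0$frac_overlapping == 0))
})

test_that("boundary_overlap is symmetric and consistent", {
  m <- interval_set(rep("c1", 3), c(0, 1000, 2000), c(100, 1100, 2100))
  b_disjoint <- interval_set("c1", 5000, 5100)
  r <- boundary_overlap(m, b_disjoint)
  expect_equal(r$n_mars_overlapping, 0L)
  expect_equal(r$n_boundaries_overlapping, 0L)
  r2 <- boundary_overlap(m, m)
  expect_equal(r2$n_mars_overlapping, 3L)
  expect_equal(r2$frac_boundaries, 1)
  # zero in one direction implies zero in the other
  expect_equal(r$n_mars_overlapping == 0L, r$n_boundaries_overlapping == 0L)
})

test_that("exonic_expression_association handles tiers and missing genes", {
  em <- data.frame(mar = paste0("m", 1:4), gene_id = paste0("g", 1:4))
  expr <- data.frame(gene_id = paste0("g", 1:4),
                     tier = c("high", "high", "moderate", "low"))
  expect_equal(exonic_expression_association(em, expr)$fraction, 0.75)
  expr$tier <- "low"
  expect_equal(exonic_expression_association(em, expr)$fraction, 0)
  # missing tier excluded from the denominator with a warning
  expr2 <- expr[1:3, ]; expr2$tier <- c("high", "low", "high")
  expect_warning(r <- exonic_expression_association(em, expr2),
                 "no expression tier")
  expect_equal(r$n_used, 3L)
  expect_equal(r$fraction, 2 / 3)
  expect_equal(r$missing, "g4")
  expect_error(exonic_expression_association(
    em, data.frame(gene_id = "g1", tier = "huge")
  ))
})

test_that("GFF3 writer and reader round-trip gene models", {
  u <- small_universe()
  f <- withr::local_tempfile(fileext = ".gff3")
  marscan:::write_gff3(u$genes, f)
  g2 <- read_gff3_genes(f)
  expect_equal(g2$genes[, c("gene_id", "chrom", "strand", "start", "end")],
               u$genes$genes[, c("gene_id", "chrom", "strand", "start",
                                 "end")])
  key <- function(d) sort(paste(d$gene_id, d$type, d$start, d$end))
  expect_equal(key(g2$features), key(u$genes$features))
  expect_equal(g2$genes$tss, u$genes$genes$tss)
})
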