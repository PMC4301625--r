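test_that("interval_set validates coordinates and sorts records", {
  x <- interval_set(c("3R", "2L", "2L"), c(5, 100, 10), c(9, 300, 20))
  expect_s3_class(x, "interval_set")
  expect_equal(x$chrom, c("2L", "2L", "3R"))
  expect_equal(x$start, c(10L, 100L, 5L))
  expect_error(interval_set("2L", 100, 100), "start < end")
  expect_error(interval_set("2L", -1, 50), "start < end")
  expect_error(interval_set("2L", 10, 600, chrom_sizes = c("2L" = 500)),
               "past chromosome end")
  expect_error(interval_set("2L", 10, 50, chrom_sizes = c(X = 500)),
               "missing from chrom_sizes")
})

test_that("read_bed parses BED3/BED6 and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# comment", "2L\t100\t300\tpk1\t7\t+",
               "2R\t0\t50", "X\t5\t9"), f)
  b <- read_bed(f)
  expect_equal(nrow(b), 3L)
  expect_equal(b$name[b$chrom == "2L"], "pk1")
  expect_equal(b$score[b$chrom == "2L"], 7)
  expect_true(all(is.na(b$name[b$chrom != "2L"])))

  writeLines(c("2L\t100\t300", "2L\t100"), f)
  expect_error(read_bed(f), "line 2.*fewer than 3")
  writeLines(c("2L\t100\t300", "2L\t100\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("2L\tx\t300", f)
  expect_error(read_bed(f), "non-numeric")
  expect_error(read_bed(file.path(tempdir(), "nope.bed")), "no such file")
})

test_that("write_bed/read_bed round-trips", {
  x <- interval_set(c("2L", "2L", "X"), c(0, 500, 9), c(100, 900, 10),
                    name = c("a", "b", "c"), score = c(1, 2, 3))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
  expect_equal(y$name, x$name)
})

test_that("common_peaks applies the minimum-overlap rule", {
  a <- interval_set("2L", 100, 300)
  # identity
  expect_equal(common_peaks(a, a)[, c("start", "end")],
               data.frame(start = 100L, end = 300L), ignore_attr = TRUE)
  # 40 bp overlap fails the 50 bp rule
  b40 <- interval_set("2L", 260, 500)
  expect_equal(nrow(common_peaks(a, b40)), 0L)
  # 60 bp overlap passes; union span is reported
  b60 <- interval_set("2L", 240, 500)
  cp <- common_peaks(a, b60)
  expect_equal(cp$start, 100L)
  expect_equal(cp$end, 500L)
  expect_equal(cp$int_start, 240L)   # intersection metadata
  expect_equal(cp$int_end, 300L)
  expect_equal(cp$n_rep1, 1L)
  expect_equal(cp$n_rep2, 1L)
})

test_that("common_peaks groups chains and collapses duplicates", {
  # two rep1 peaks bridged by one rep2 peak -> one union interval
  r1 <- interval_set(c("2L", "2L"), c(0, 300), c(200, 500))
  r2 <- interval_set("2L", 100, 400)
  cp <- common_peaks(r1, r2)
  expect_equal(nrow(cp), 1L)
  expect_equal(c(cp$start, cp$end), c(0L, 500L))
  expect_equal(cp$n_rep1, 2L)
  # duplicate identical peaks count once
  r1d <- interval_set(c("2L", "2L"), c(0, 0), c(200, 200))
  cpd <- common_peaks(r1d, r2)
  expect_equal(cpd$n_rep1, 1L)
})

test_that("common_peaks is symmetric and monotone in min_overlap", {
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    s1 <- sample(0:5000, n1); s2 <- sample(0:5000, n2)
    r1 <- interval_set(rep("c1", n1), s1, s1 + sample(50:400, n1, TRUE))
    r2 <- interval_set(rep("c1", n2), s2, s2 + sample(50:400, n2, TRUE))
    ab <- common_peaks(r1, r2)
    ba <- common_peaks(r2, r1)
    expect_equal(ab[, c("chrom", "start", "end")],
                 ba[, c("chrom", "start", "end")])
    expect_equal(ab$n_rep1, ba$n_rep2)
    # raising the threshold never increases the number of peaks that
    # participate in a common region (note: the number of output GROUPS
    # is not monotone -- a higher threshold can split one chained group
    # into several)
    counts <- vapply(c(1L, 25L, 50L, 100L, 200L), function(mo) {
      cp <- common_peaks(r1, r2, min_overlap = mo)
      sum(cp$n_rep1) + sum(cp$n_rep2)
    }, 0L)
    expect_true(all(diff(counts) <= 0))
    # every output interval contains >= min_overlap bp covered by both
    if (nrow(ab)) {
      expect_true(all(ab$int_end - ab$int_start >= 50L |
                        ab$n_rep1 > 1L | ab$n_rep2 > 1L))
    }
  }
})

test_that("windowed_tag_correlation counts windows genome-wide", {
  sizes <- c(c1 = 2000)
  t1 <- data.frame(chrom = "c1", start = c(10, 600, 700, 1500))
  expect_equal(windowed_tag_correlation(t1, t1, sizes), 1.0)
  # perfectly linear counts
  t2 <- data.frame(chrom = "c1",
                   start = c(10, 600, 700, 1500, 20, 610, 710, 1510))
  expect_equal(windowed_tag_correlation(t1, t2, sizes), 1.0)
  # frozen Pearson value for counts (0,1,2,5) vs (1,1,3,4): direct
  # evaluation of the formula gives 0.9258201 (sxy=9, sxx=14, syy=6.75)
  a <- data.frame(chrom = "c1",
                  start = c(600, 1000, 1100, rep(1600, 5)))
  b <- data.frame(chrom = "c1",
                  start = c(100, 600, rep(1100, 3), rep(1600, 4)))
  expect_equal(windowed_tag_correlation(a, b, sizes),
               9 / sqrt(14 * 6.75), tolerance = 1e-12)
  # order invariance
  expect_equal(windowed_tag_correlation(a[sample(nrow(a)), , drop = FALSE],
                                        b, sizes),
               windowed_tag_correlation(a, b, sizes))
  # zero variance is an error
  u <- data.frame(chrom = "c1", start = c(100, 600, 1100, 1600))
  expect_error(windowed_tag_correlation(u, a, sizes), "zero variance")
  expect_error(windowed_tag_correlation(a, b, c(c2 = 100)), "cover")
})

test_that("size_stats computes median, total and threshold fractions", {
  m <- interval_set(rep("c1", 3), c(0, 1000, 3000), c(100, 1400, 3900))
  st <- size_stats(m, thresholds = c(600))
  expect_equal(st$n_mars, 3L)
  expect_equal(st$total_bp, 100L + 400L + 900L)
  expect_equal(st$median_size, 400)
  expect_equal(unname(st$frac_below["600"]), 2 / 3)
  expect_error(size_stats(interval_set(character(), integer(), integer())),
               "empty")
  # frac_below is non-decreasing in the threshold
  st2 <- size_stats(m, thresholds = c(200, 600, 1000))
  expect_true(all(diff(st2$frac_below) >= 0))
})

test_that("inter_mar_distances uses per-chromosome consecutive midpoints", {
  m <- interval_set(rep("c1", 2), c(900, 4900), c(1100, 5100))
  d <- inter_mar_distances(m)
  expect_equal(d$distances, 4000L)
  # one MAR per chromosome -> no distances
  m1 <- interval_set(c("c1", "c2"), c(0, 0), c(100, 100))
  expect_length(inter_mar_distances(m1)$distances, 0L)
  # no cross-chromosome distances; summary stats
  m2 <- interval_set(c("c1", "c1", "c2", "c2"),
                     c(0, 30000, 0, 10000), c(100, 30100, 100, 10100))
  d2 <- inter_mar_distances(m2)
  expect_equal(sort(d2$distances), c(10000L, 30000L))
  expect_equal(d2$mean, 20000)
  expect_equal(d2$frac_below, 0.5)
  # even-length midpoint rounds down
  expect_equal(
    inter_mar_distances(interval_set(c("c1", "c1"), c(0, 10),
                                     c(3, 14)))$distances,
    11L
  )
})

test_that("chromosome_density_table computes per-arm ratios and totals", {
  m <- interval_set(rep("c1", 50), seq(0, 4900, 100), seq(50, 4950, 100))
  tab <- chromosome_density_table(m, c(c1 = 1e6, c2 = 5e5),
                                  gene_counts = c(c1 = 100, c2 = 10))
  expect_equal(tab$kb_per_mar[tab$chrom == "c1"], 20)
  expect_equal(tab$genes_per_mar[tab$chrom == "c1"], 2)
  # zero-MAR chromosome gets NA ratios, not an error
  expect_true(is.na(tab$kb_per_mar[tab$chrom == "c2"]))
  expect_equal(tab$n_mars[tab$chrom == "total"], 50L)
  expect_error(chromosome_density_table(m, c(c2 = 5e5)), "missing")
})

test_that("density table reproduces the fly euchromatin anchors", {
  # printed per-arm sizes and gene/MAR counts are inputs; the derived
  # kb-per-MAR and genes-per-MAR columns must match the published ratios
  fx <- read.table(
    system.file("extdata", "dmel_chromosome_mar_counts.tsv",
                package = "marscan"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE
  )
  # build a MAR set with the given per-arm counts (positions irrelevant)
  mars <- do.call(rbind, lapply(seq_len(nrow(fx)), function(i) {
    k <- fx$n_mars[i]
    data.frame(chrom = fx$chrom[i], start = seq_len(k) * 100L,
               end = seq_len(k) * 100L + 50L)
  }))
  mars <- as_interval_set(mars)
  sizes <- setNames(fx$size_mb * 1e6, fx$chrom)
  genes <- setNames(fx$n_genes, fx$chrom)
  tab <- chromosome_density_table(mars, sizes, genes)
  expect_equal(tab$kb_per_mar[tab$chrom == "X"], 9.1, tolerance = 0.01)
  expect_equal(tab$genes_per_mar[tab$chrom == "X"], 1.0, tolerance = 0.03)
  expect_equal(tab$n_mars[tab$chrom == "total"], 7353L)
  expect_equal(tab$kb_per_mar[tab$chrom == "total"], 16.4, tolerance = 0.005)
  expect_equal(tab$genes_per_mar[tab$chrom == "total"], 2.1, tolerance = 0.01)
  expect_equal(tab$size_mb[tab$chrom == "total"], 120.2, tolerance = 0.002)
})

test_that("filter_euchromatic drops heterochromatic scaffolds by name", {
  x <- interval_set(c("2L", "X", "2LHet", "U"), c(0, 0, 0, 0),
                    c(10, 10, 10, 10))
  y <- filter_euchromatic(x)
  expect_equal(y$chrom, c("2L", "X"))
  expect_s3_class(y, "interval_set")
})
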