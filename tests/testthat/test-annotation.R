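# Conservation averaging, group comparison, tumor-vs-normal DE, and
# alteration frequencies.

suppressPackageStartupMessages(library(GenomicRanges))

gr <- function(chr, starts, ends, score = NULL) {
  g <- GRanges(chr, IRanges(start = starts, end = ends))
  if (!is.null(score)) g$score <- score
  g
}

test_that("exon conservation averages per base over the exon union", {
  track <- gr("chr1", 1, 1000, score = 0.5)
  expect_equal(exon_conservation(gr("chr1", 101, 200), track), 0.5)

  two_tracks <- gr("chr1", c(1, 501), c(500, 1000), score = c(0.2, 0.8))
  exons <- gr("chr1", c(491, 501), c(500, 510))   # two 10-bp exons
  expect_equal(exon_conservation(exons, two_tracks), 0.5)

  # overlapping exons [1,10] and [6,15]: union is 15 bases, not 20
  per_base <- gr("chr1", 1:15, 1:15, score = c(rep(0.1, 5), rep(0.9, 10)))
  overlapping <- gr("chr1", c(1, 6), c(10, 15))
  expect_equal(exon_conservation(overlapping, per_base),
               (5 * 0.1 + 10 * 0.9) / 15)
  # counting the overlap twice would give (5*0.1 + 5*0.9*... ) over 20 bases
  expect_false(isTRUE(all.equal(exon_conservation(overlapping, per_base),
                                (5 * 0.1 + 15 * 0.9) / 20)))
})

test_that("exon conservation is invariant to exon order and splitting", {
  track <- gr("chr1", 1:100, 1:100, score = seq(0.01, 1, by = 0.01))
  a <- gr("chr1", c(11, 41), c(20, 60))
  b <- gr("chr1", c(41, 11), c(60, 20))
  split3 <- gr("chr1", c(11, 16, 41), c(15, 20, 60))
  expect_equal(exon_conservation(a, track), exon_conservation(b, track))
  expect_equal(exon_conservation(a, track), exon_conservation(split3, track))
})

test_that("missing coverage yields NA (with a warning for absent chromosomes)", {
  track <- gr("chr1", 1, 100, score = 0.5)
  expect_warning(res <- exon_conservation(gr("chr9", 1, 50), track), "chr9")
  expect_true(is.na(res))
  expect_true(is.na(exon_conservation(gr("chr1", 500, 600), track)))
})

test_that("gene models and score tracks round-trip through standard formats", {
  bed <- withr::local_tempfile(fileext = ".bed")
  # BED12: two genes; geneA has exons [0,10) and [20,30) in 0-based
  # half-open coordinates
  writeLines(c(
    paste("chr1", 0, 30, "geneA", 0, "+", 0, 30, 0, 2, "10,10,", "0,20,",
          sep = "\t"),
    paste("chr1", 50, 70, "geneB", 0, "-", 50, 70, 0, 1, "20,", "0,",
          sep = "\t")), bed)
  models <- read_gene_models(bed)
  expect_setequal(names(models), c("geneA", "geneB"))
  expect_equal(sum(width(models[["geneA"]])), 20)

  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t10\t0.2", "chr1\t20\t30\t0.6", "chr1\t50\t70\t1.0"),
             bg)
  track <- read_score_track(bg)
  cons <- conservation_by_gene(models, track)
  expect_equal(unname(cons["geneA"]), (10 * 0.2 + 10 * 0.6) / 20)
  expect_equal(unname(cons["geneB"]), 1.0)

  bad <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t10\t1.7", bad)
  expect_error(read_score_track(bad), "\\[0, 1\\]")
})

test_that("conservation comparison gives the enumerated minimal rank-sum p", {
  a <- seq(0.6, 0.8, length.out = 20)
  b <- seq(0.1, 0.3, length.out = 20)
  res <- conservation_compare(a, b)
  expect_equal(res$p, 2 / choose(40, 20), tolerance = 1e-10)
  expect_equal(res$median_a, median(a))
  same <- conservation_compare(1:9 / 10, 1:9 / 10)
  expect_gt(same$p, 0.9)
  single <- conservation_compare(0.5, 0.7)
  expect_true(single$p > 0 && single$p <= 1)
  expect_error(conservation_compare(numeric(0), b), "empty")
})

test_that("tumor-normal DE recovers planted statuses with strict thresholds", {
  set.seed(71)
  n_per <- 20
  genes <- c(sprintf("up%02d", 1:n_per), sprintf("dn%02d", 1:n_per),
             sprintf("ns%02d", 1:n_per))
  shift <- c(rep(2, n_per), rep(-2, n_per), rep(0, n_per))
  normal <- matrix(rnorm(60 * 10, 6, 0.3), nrow = 60,
                   dimnames = list(genes, sprintf("n%02d", 1:10)))
  tumor <- matrix(rnorm(60 * 10, 6, 0.3) + shift, nrow = 60,
                  dimnames = list(genes, sprintf("t%02d", 1:10)))
  de <- tumor_normal_de(tumor, normal)
  expect_identical(de$status,
                   c(rep("up", n_per), rep("down", n_per), rep("ns", n_per)))

  # |log2FC| exactly 1 stays ns regardless of significance
  t2 <- matrix(rep(c(7, 7.001), 5), nrow = 1,
               dimnames = list("g", sprintf("t%02d", 1:10)))
  n2 <- matrix(rep(c(6, 6.001), 5), nrow = 1,
               dimnames = list("g", sprintf("n%02d", 1:10)))
  de2 <- tumor_normal_de(t2, n2)
  expect_equal(de2$log2fc, 1)
  expect_identical(de2$status, "ns")
  expect_error(tumor_normal_de(tumor[, 1, drop = FALSE], normal), "2 samples")
})

test_that("identical conditions are all non-significant", {
  m <- matrix(rnorm(40, 5, 1), nrow = 4,
              dimnames = list(letters[1:4], sprintf("s%02d", 1:10)))
  colnames(m) <- sprintf("t%02d", 1:10)
  m2 <- m
  colnames(m2) <- sprintf("n%02d", 1:10)
  de <- tumor_normal_de(m, m2)
  expect_true(all(de$status == "ns"))
  expect_true(all(de$log2fc == 0))
})

test_that("SCNA and mutation frequencies match hand counts", {
  cn <- matrix(c(0, 1, -2, 0, 2, 0, 0, -1, 0, 0,
                 rep(0, 10)), nrow = 2, byrow = TRUE,
               dimnames = list(c("gA", "gB"), sprintf("s%02d", 1:10)))
  expect_equal(scna_frequency(cn, "gA"), 0.4)  # amp and del both count
  expect_equal(scna_frequency(cn, "gB"), 0)
  expect_error(scna_frequency(cn, "gC"), "unknown gene")
  summ <- scna_summary(cn)
  expect_equal(summ$freq_amplified[summ$gene_id == "gA"], 0.2)
  expect_equal(summ$freq_deleted[summ$gene_id == "gA"], 0.2)

  mut <- data.frame(
    gene_id = c("gA", "gA", "gA", "gA", "gB"),
    sample_id = c("s01", "s01", "s02", "s03", "s04"),
    class = c("non_silent", "non_silent", "non_silent", "silent",
              "non_silent"),
    stringsAsFactors = FALSE)
  expect_equal(mutation_frequency(mut, "gA", 12), 2 / 12)  # s01 counted once
  expect_equal(mutation_frequency(mut, "gC", 12), 0)
  silent_only <- mut[mut$class == "silent", ]
  expect_equal(mutation_frequency(silent_only, "gA", 12), 0)
  mut3 <- data.frame(gene_id = "g", sample_id = c("a", "b", "c"),
                     class = "non_silent")
  expect_equal(mutation_frequency(mut3, "g", 12), 0.25)
  expect_error(mutation_frequency(mut, "gA", 0), "n_samples")
})
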