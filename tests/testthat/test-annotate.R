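# Region assignment, metagene, source classification, chi-squared and
# GA-richness.

test_that("region assignment follows the half-open boundary rule", {
  model <- make_model("tx1", paste(rep("A", 500), collapse = ""),
                      utr5_end = 100, cds_end = 400)
  expect_equal(assign_region(100, model), "CDS")   # boundary -> downstream
  expect_equal(assign_region(99, model), "5UTR")
  expect_equal(assign_region(400, model), "3UTR")
  expect_equal(assign_region(450, model), "3UTR")
  expect_error(assign_region(500, model), "outside")
  lnc <- make_model("l1", "ACGT", biotype = "lncRNA",
                    utr5_end = NA, cds_end = NA)
  expect_equal(assign_region(2, lnc), "noncoding")
  # totality: every mRNA position maps to exactly one region
  regions <- vapply(0:499, assign_region, character(1), model = model)
  expect_equal(sum(regions == "5UTR"), 100)
  expect_equal(sum(regions == "CDS"), 300)
  expect_equal(sum(regions == "3UTR"), 100)
})

test_that("metagene concentrates, normalizes, and is flat under uniformity", {
  model <- make_model("tx1", paste(rep("A", 1000), collapse = ""),
                      utr5_end = 200, cds_end = 700)
  # all sites at the CDS start: single spike in the first CDS bin
  sites <- data.frame(transcript_id = "tx1", position = rep(200L, 5))
  prof <- metagene(sites, model)
  expect_equal(sum(prof$density), 1, tolerance = 1e-9)
  expect_equal(prof$density[prof$bin == 21], 1)
  # uniform sites on a uniform-length fixture: flat within 3 MC SE
  set.seed(88)
  n <- 6000
  usites <- data.frame(transcript_id = "tx1",
                       position = sample(0:999, n, replace = TRUE))
  uprof <- metagene(usites, model)
  # bin occupancy probability is proportional to region length per bin
  p_bin <- c(rep(200 / 1000 / 20, 20), rep(500 / 1000 / 50, 50),
             rep(300 / 1000 / 30, 30))
  se <- sqrt(p_bin * (1 - p_bin) / n)
  expect_true(all(abs(uprof$density - p_bin) <= 3 * se + 1e-12))
  expect_error(metagene(usites[0, ], model), "no mRNA sites")
})

test_that("lncRNA genomic sources follow the precedence rules", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 1000L, end = 5000L, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", start = c(1000L, 3000L),
                      end = c(1500L, 3500L), stringsAsFactors = FALSE)
  locus <- function(start, end, strand = "+", chrom = "chr1") {
    data.frame(chrom = chrom, strand = strand, start = start, end = end,
               stringsAsFactors = FALSE)
  }
  expect_equal(classify_lncrna_source(locus(1200, 1400), genes, exons),
               "exon_sense_overlapping")
  expect_equal(classify_lncrna_source(locus(2000, 2500), genes, exons),
               "intron_sense_overlapping")
  expect_equal(classify_lncrna_source(locus(1200, 1400, "-"), genes, exons),
               "antisense")
  # opposite strand, no overlap, TSS 500 bp from the gene TSS
  expect_equal(classify_lncrna_source(locus(400, 900, "-"), genes, exons),
               "bidirectional")
  expect_equal(classify_lncrna_source(locus(15000, 16000), genes, exons),
               "intergenic")
  expect_error(classify_lncrna_source(locus(1, 10, NA), genes, exons),
               "strand")
})

test_that("circRNA genomic sources follow the precedence rules", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 1000L, end = 5000L, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", start = c(1000L, 3000L),
                      end = c(1500L, 3500L), stringsAsFactors = FALSE)
  locus <- function(start, end, strand = "+") {
    data.frame(chrom = "chr1", strand = strand, start = start, end = end,
               stringsAsFactors = FALSE)
  }
  expect_equal(classify_circrna_source(locus(1100, 1400), genes, exons),
               "exonic")
  expect_equal(classify_circrna_source(locus(1800, 2500), genes, exons),
               "intronic")
  expect_equal(classify_circrna_source(locus(1400, 1800), genes, exons),
               "sense_overlapping")
  expect_equal(classify_circrna_source(locus(1100, 1400, "-"), genes, exons),
               "antisense")
  expect_equal(classify_circrna_source(locus(9000, 9500), genes, exons),
               "intergenic")
})

test_that("chi-squared homogeneity test matches the textbook formula", {
  out <- chisq_distribution_test(c(10, 20), c(20, 10))
  expect_equal(out$chi2, 20 / 3, tolerance = 1e-9)
  expect_equal(out$df, 1)
  expect_equal(out$p, pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(round(out$p, 5), 0.00982)
  same <- chisq_distribution_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # scaling both rows by 10 multiplies the statistic by 10
  out10 <- chisq_distribution_test(c(100, 200), c(200, 100))
  expect_equal(out10$chi2, 10 * out$chi2, tolerance = 1e-9)
  expect_error(chisq_distribution_test(c(0, 10), c(0, 20)), "expected")
  # random instances against the direct Pearson formula
  set.seed(12)
  for (i in 1:20) {
    a <- rpois(4, 30) + 1; b <- rpois(4, 30) + 1
    tab <- rbind(a, b)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chisq_distribution_test(a, b)$chi2,
                 sum((tab - e)^2 / e), tolerance = 1e-9)
  }
})

test_that("GA-richness flags sequences and shuffles preserve dinucleotides", {
  out <- ga_richness(c("GAGAGAGA", "CTCTCTCT"), n_shuffles = 5, seed = 1)
  expect_true(out$ga_rich[1])
  expect_false(out$ga_rich[2])
  expect_equal(out$fraction, c(1, 0))
  expect_error(ga_richness("ACGN"), "non-ACGT")
  # the shuffle is exactly dinucleotide-preserving
  set.seed(2)
  for (s in c("ACGTACGGTTACGA", "AAAACCCGGGTTT",
              paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""))) {
    sh <- m1ascope:::dinucleotide_shuffle(s)
    expect_equal(sort(names(dinuc_counts(sh))), sort(names(dinuc_counts(s))))
    expect_equal(as.integer(dinuc_counts(sh)[names(dinuc_counts(s))]),
                 as.integer(dinuc_counts(s)))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
  # clustered purines score high against the dinucleotide null
  set.seed(3)
  clustered <- vapply(1:30, function(i) {
    head_p <- sample(c("G", "A", "C", "T"), 40, TRUE,
                     prob = c(0.45, 0.45, 0.05, 0.05))
    tail_p <- sample(c("G", "A", "C", "T"), 60, TRUE,
                     prob = c(0.05, 0.05, 0.45, 0.45))
    paste(c(head_p, tail_p), collapse = "")
  }, character(1))
  z <- ga_richness(clustered, n_shuffles = 30, window = 40, seed = 4)$z
  expect_gt(z, 2)
})

test_that("chromosome tallies match the RNA rollup", {
  models <- rbind(make_model("a", "AAAA", chrom = "chr1"),
                  make_model("b", "CCCC", chrom = "chr1"),
                  make_model("c", "GGGG", chrom = "chr2"))
  rna <- list(Control = data.frame(transcript_id = c("a", "b", "c")),
              Treated = data.frame(transcript_id = "c"))
  tab <- per_chromosome_counts(rna, models)
  expect_equal(tab$Control[tab$chrom == "chr1"], 2L)
  expect_equal(tab$Control[tab$chrom == "chr2"], 1L)
  expect_equal(tab$Treated[tab$chrom == "chr1"], 0L)
  expect_equal(sum(tab$Control), 3L)
  empty <- per_chromosome_counts(list(Control = data.frame(
    transcript_id = character(0))), models)
  expect_equal(sum(empty$Control), 0L)
})
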