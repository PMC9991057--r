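# Synthetic-data generator: determinism, composition, signature contracts.

test_that("degenerate biotype mixture yields only mRNAs with all regions", {
  cfg <- sim_config(n_transcripts = 10, biotype_props = c(mRNA = 1),
                    seed = 1)
  tx <- generate_transcriptome(cfg)
  expect_equal(nrow(tx), 10)
  expect_true(all(tx$biotype == "mRNA"))
  expect_true(all(tx$utr5_end >= 1))
  expect_true(all(tx$cds_end > tx$utr5_end))
  expect_true(all(tx$length > tx$cds_end))
})

test_that("transcriptome generation is deterministic given the seed", {
  cfg <- sim_config(n_transcripts = 30, seed = 99)
  expect_identical(generate_transcriptome(cfg), generate_transcriptome(cfg))
  s1 <- plant_sites(generate_transcriptome(cfg), cfg)
  s2 <- plant_sites(generate_transcriptome(cfg), cfg)
  expect_identical(s1, s2)
})

test_that("biotype apportionment follows largest-remainder rounding", {
  cfg <- sim_config(n_transcripts = 1000,
                    biotype_props = c(mRNA = 0.6, lncRNA = 0.2, circRNA = 0.2),
                    seed = 2)
  tx <- generate_transcriptome(cfg)
  counts <- table(tx$biotype)
  expect_equal(unname(counts[["mRNA"]]), 600)
  expect_equal(unname(counts[["lncRNA"]]), 200)
  expect_equal(unname(counts[["circRNA"]]), 200)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(biotype_props = c(mRNA = 0.5, lncRNA = 0.2)),
               "sum to 1")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(truncation_prob = 1.2), "probability")
  expect_error(simulate_counts(10, dispersion = -1), "dispersion")
})

test_that("site counts reproduce the documented Poisson RNG stream", {
  cfg <- sim_config(n_transcripts = 200, site_rate = 1.5, seed = 77)
  tx <- generate_transcriptome(cfg)
  sites <- suppressWarnings(plant_sites(tx, cfg))
  # independent oracle: re-draw the first Poisson vector of the stream
  set.seed(child_seed(77, "sites"))
  expected <- rpois(nrow(tx), 1.5)
  # planted sites de-duplicate positions within a transcript, and
  # transcripts without an A are skipped, so observed <= drawn
  per_tx <- table(factor(sites$transcript_id, levels = tx$transcript_id))
  expect_true(all(as.integer(per_tx) <= expected))
  expect_gt(sum(per_tx), 0.95 * sum(expected))
})

test_that("all planted sites sit on an A and zero rate plants nothing", {
  cfg <- sim_config(n_transcripts = 50, seed = 3)
  tx <- generate_transcriptome(cfg)
  sites <- plant_sites(tx, cfg)
  base_at <- vapply(seq_len(nrow(sites)), function(i) {
    s <- tx$sequence[tx$transcript_id == sites$transcript_id[i]]
    substr(s, sites$position[i] + 1, sites$position[i] + 1)
  }, character(1))
  expect_true(all(base_at == "A"))
  cfg0 <- sim_config(n_transcripts = 20, site_rate = 0, seed = 3)
  expect_equal(nrow(plant_sites(generate_transcriptome(cfg0), cfg0)), 0)
})

test_that("a transcript without adenosines is skipped with a warning", {
  cfg <- sim_config(n_transcripts = 1, biotype_props = c(lncRNA = 1),
                    site_rate = 5, seed = 8)
  tx <- generate_transcriptome(cfg)
  tx$sequence <- paste(rep("C", tx$length), collapse = "")
  expect_warning(sites <- plant_sites(tx, cfg), "no A nucleotides")
  expect_equal(nrow(sites), 0)
})

test_that("pileups respect conservation and determinism", {
  fx <- standard_fixture(seed = 5, n_transcripts = 15,
                         length_range = list(mRNA = c(400, 800),
                                             lncRNA = c(300, 600),
                                             circRNA = c(300, 500)))
  p <- fx$pileups
  expect_true(all(p$at_mismatch <= p$coverage))
  expect_true(all(p$coverage >= 0))
  p2 <- simulate_merip_pileups(fx$models, fx$sites, fx$config)
  expect_identical(p, p2)
})

test_that("null signatures leave IP and input indistinguishable", {
  cfg <- sim_config(n_transcripts = 12, truncation_prob = 0,
                    mismatch_prob = 0, ip_enrichment = 1,
                    conditions = "Control", seed = 21,
                    length_range = list(mRNA = c(400, 800),
                                        lncRNA = c(300, 600),
                                        circRNA = c(300, 500)))
  tx <- generate_transcriptome(cfg)
  sites <- plant_sites(tx, cfg)
  pile <- simulate_merip_pileups(tx, sites, cfg)
  ip <- pool_pileups(pile, "IP", "untreated")
  inp <- pool_pileups(pile, "input", "untreated")
  # equal means within Monte-Carlo tolerance
  expect_lt(abs(sum(ip$coverage) / sum(inp$coverage) - 1), 0.02)
  # planted mismatches at sites reduce to the background error rate
  site_rate <- mean(vapply(seq_len(nrow(sites)), function(i) {
    sel <- ip$transcript_id == sites$transcript_id[i] &
      ip$pos == sites$position[i]
    ip$at_mismatch[sel] / max(1, ip$coverage[sel])
  }, numeric(1)))
  expect_lt(site_rate, 0.01)
})

test_that("full conversion removes treated mismatch signatures", {
  cfg <- sim_config(n_transcripts = 12, conversion_prob = 1,
                    conditions = "Control", seed = 22,
                    methyl_fraction_range = c(1, 1),
                    length_range = list(mRNA = c(400, 800),
                                        lncRNA = c(300, 600),
                                        circRNA = c(300, 500)))
  tx <- generate_transcriptome(cfg)
  sites <- plant_sites(tx, cfg)
  pile <- simulate_merip_pileups(tx, sites, cfg)
  trt <- pool_pileups(pile, "IP", "treated")
  unt <- pool_pileups(pile, "IP", "untreated")
  rate_at_sites <- function(trk) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(sites))) {
      sel <- trk$transcript_id == sites$transcript_id[i] &
        trk$pos == sites$position[i]
      num <- num + trk$at_mismatch[sel]; den <- den + trk$coverage[sel]
    }
    num / den
  }
  expect_lt(rate_at_sites(trt), 0.005)       # background scale
  expect_gt(rate_at_sites(unt), 0.05)        # full signature
})

test_that("truncation depresses site coverage by about f*t", {
  # isolate truncation: no enrichment, full methylation, t = 0.5
  cfg <- sim_config(n_transcripts = 60, site_rate = 1, depth = 100,
                    ip_enrichment = 1, methyl_fraction_range = c(1, 1),
                    truncation_prob = 0.5, conditions = "Control",
                    replicates = 1, seed = 13,
                    length_range = list(mRNA = c(600, 1000),
                                        lncRNA = c(500, 900),
                                        circRNA = c(400, 800)))
  tx <- generate_transcriptome(cfg)
  sites <- plant_sites(tx, cfg)
  pile <- simulate_merip_pileups(tx, sites, cfg, treatments = "untreated")
  ip <- pool_pileups(pile, "IP", "untreated")
  ratios <- vapply(seq_len(nrow(sites)), function(i) {
    trk <- ip[ip$transcript_id == sites$transcript_id[i], ]
    site_cov <- trk$coverage[trk$pos == sites$position[i]]
    sh_pos <- sites$position[i] + 20          # 3' side, outside the shadow
    sh_cov <- trk$coverage[trk$pos == sh_pos]
    if (!length(site_cov) || !length(sh_cov) || sh_cov == 0) return(NA_real_)
    site_cov / sh_cov
  }, numeric(1))
  expect_equal(mean(ratios, na.rm = TRUE), 0.5, tolerance = 0.05)
})

test_that("signature strength is monotone in t, m and conversion", {
  base <- list(n_transcripts = 25, conditions = "Control", replicates = 2,
               methyl_fraction_range = c(1, 1), seed = 17,
               length_range = list(mRNA = c(500, 900),
                                   lncRNA = c(400, 700),
                                   circRNA = c(300, 600)))
  site_stats <- function(extra) {
    cfg <- do.call(sim_config, c(base, extra))
    tx <- generate_transcriptome(cfg)
    sites <- plant_sites(tx, cfg)
    pile <- simulate_merip_pileups(tx, sites, cfg)
    per_treatment <- lapply(c("untreated", "treated"), function(trt) {
      ip <- pool_pileups(pile, "IP", trt)
      cov_ratio <- c(); mis_rate <- c()
      for (i in seq_len(nrow(sites))) {
        trk <- ip[ip$transcript_id == sites$transcript_id[i], ]
        sc <- trk$coverage[trk$pos == sites$position[i]]
        sh <- trk$coverage[trk$pos == sites$position[i] + 15]
        if (length(sc) && length(sh) && sh > 0) {
          cov_ratio <- c(cov_ratio, sc / sh)
          mis_rate <- c(mis_rate, trk$at_mismatch[trk$pos == sites$position[i]] / max(1, sc))
        }
      }
      c(cov_ratio = mean(cov_ratio), mis_rate = mean(mis_rate))
    })
    names(per_treatment) <- c("untreated", "treated")
    per_treatment
  }
  lo_t <- site_stats(list(truncation_prob = 0.2))
  hi_t <- site_stats(list(truncation_prob = 0.7))
  expect_gt(lo_t$untreated[["cov_ratio"]], hi_t$untreated[["cov_ratio"]])
  lo_m <- site_stats(list(mismatch_prob = 0.05))
  hi_m <- site_stats(list(mismatch_prob = 0.3))
  expect_lt(lo_m$untreated[["mis_rate"]], hi_m$untreated[["mis_rate"]])
  lo_c <- site_stats(list(conversion_prob = 0.2))
  hi_c <- site_stats(list(conversion_prob = 0.95))
  expect_lt(lo_c$treated[["cov_ratio"]], hi_c$treated[["cov_ratio"]])
  expect_gt(lo_c$treated[["mis_rate"]], hi_c$treated[["mis_rate"]])
})

test_that("NB count simulation is calibrated under the null and powered", {
  sim0 <- simulate_counts(2000, n_per_group = 3, dispersion = 0.05, seed = 4)
  de0 <- diff_expression(sim0$counts, sim0$group, kind = "mRNA")
  expect_lte(mean(de0$fdr <= 0.05), 0.01)
  # a strong planted fold change is recovered across seeds
  hits <- vapply(1:50, function(s) {
    fc <- rep(1, 100); fc[1] <- 8
    sim <- simulate_counts(100, n_per_group = 3, dispersion = 0.02,
                           fold_changes = fc, seed = s)
    de <- diff_expression(sim$counts, sim$group, kind = "mRNA")
    de$significant[match("F00001", de$feature_id)]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a zero-depth library is rejected by normalization", {
  sim <- simulate_counts(50, n_per_group = 3, seed = 9)
  sim$counts[, 2] <- 0L
  expect_error(diff_expression(sim$counts, sim$group), "zero total counts")
})

test_that("interaction tables carry the planted structure", {
  tabs <- simulate_interaction_tables(seed = 6)
  hub <- attr(tabs, "hub_lncrna")
  net <- build_lncrna_rbp(unique(tabs$lncrna_rbp$lncrna), tabs$lncrna_rbp,
                          min_evidence = 2)
  deg <- degree_table(net)
  deg_lnc <- deg[deg$type == "lncRNA", ]
  expect_equal(deg_lnc$node[1], hub)
  expect_gte(deg_lnc$degree[1], 10)
  # regulons: signed mode of regulation, no duplicated targets
  expect_true(all(tabs$regulons$mor %in% c(-1, 1)))
  expect_false(anyDuplicated(tabs$regulons[c("tf", "target")]) > 0)
  # table round-trips unchanged through the TSV layer
  tf <- tempfile(fileext = ".tsv")
  write.table(tabs$lncrna_rbp, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_table_schema(tf, c(lncrna = "character", rbp = "character",
                                  evidence = "integer"))
  expect_equal(back$lncrna, tabs$lncrna_rbp$lncrna)
  expect_equal(back$evidence, tabs$lncrna_rbp$evidence)
})
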