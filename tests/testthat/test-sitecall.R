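# The four detection methods and the consensus rule.

test_that("mismatch method calls exactly the binomially significant As", {
  seqs <- paste(rep("A", 200), collapse = "")
  model <- make_model("tx1", seqs)
  cov <- rep(100L, 200)
  mis <- rep(0L, 200); mis[51] <- 30L
  ip <- make_track("tx1", cov, at_mismatch = mis)
  peaks <- data.frame(transcript_id = "tx1", start = 0L, end = 200L)
  out <- detect_mismatch(ip, peaks, model)
  expect_equal(out$position, 50L)
  # exact binomial tail oracle
  p_brute <- sum(dbinom(30:100, 100, 0.001))
  expect_equal(out$p, p_brute, tolerance = 1e-12)
  expect_lt(out$p, 1e-30)
})

test_that("mismatch method respects coverage and rate gates", {
  model <- make_model("tx1", paste(rep("A", 100), collapse = ""))
  peaks <- data.frame(transcript_id = "tx1", start = 0L, end = 100L)
  # zero mismatches: no call
  ip0 <- make_track("tx1", rep(100L, 100))
  expect_equal(nrow(detect_mismatch(ip0, peaks, model)), 0)
  # below min_cov: skipped regardless of the mismatch count
  mis <- rep(0L, 100); mis[11] <- 8L
  low <- make_track("tx1", rep(10L, 100), at_mismatch = mis)
  expect_equal(nrow(detect_mismatch(low, peaks, model, min_cov = 20)), 0)
  expect_error(detect_mismatch(ip0, peaks, model, error_rate = 0),
               "error_rate")
})

test_that("trough method finds the documented dip and ignores flat/ramp", {
  model <- make_model("tx1", "CCCACCC", utr5_end = 1, cds_end = 6)
  peak <- data.frame(transcript_id = "tx1", start = 0L, end = 7L)
  dip <- make_track("tx1", c(10L, 10L, 10L, 3L, 10L, 10L, 10L))
  out <- detect_trough(dip, peak, model, shoulder_halfwidth = 3,
                       min_drop = 0.3, smooth_width = 1)
  expect_equal(out$position, 3L)
  expect_lte(out$depth_ratio, 0.7)
  flat <- make_track("tx1", rep(10L, 7))
  expect_null(detect_trough(flat, peak, model, shoulder_halfwidth = 3,
                            min_drop = 0.3, smooth_width = 1))
  model10 <- make_model("tx2", paste(rep("A", 10), collapse = ""))
  ramp <- make_track("tx2", 1:10)
  peak10 <- data.frame(transcript_id = "tx2", start = 0L, end = 10L)
  expect_null(detect_trough(ramp, peak10, model10, shoulder_halfwidth = 3,
                            min_drop = 0.3, smooth_width = 1))
  # peak shorter than the trough window: skipped quietly
  expect_null(detect_trough(dip, peak, model, shoulder_halfwidth = 50))
})

test_that("a depression without an RT-stop spike is not a trough", {
  model <- make_model("tx1", paste(rep("A", 31), collapse = ""))
  peak <- data.frame(transcript_id = "tx1", start = 0L, end = 31L)
  cov <- rep(20L, 31); cov[16] <- 6L
  # read starts flat: the dip has no truncation signature
  no_spike <- make_track("tx1", cov, read_start = 1L)
  expect_null(detect_trough(no_spike, peak, model, shoulder_halfwidth = 5,
                            min_drop = 0.3, smooth_width = 1))
  # with a spike at the dip the trough is called there
  rs <- rep(1L, 31); rs[16] <- 40L
  spike <- make_track("tx1", cov, read_start = rs)
  out <- detect_trough(spike, peak, model, shoulder_halfwidth = 5,
                       min_drop = 0.3, smooth_width = 1)
  expect_equal(out$position, 15L)
})

test_that("treatment rescue requires vanished signatures under a peak", {
  model <- make_model("tx1", paste(rep("A", 300), collapse = ""))
  peaks_trt <- data.frame(transcript_id = "tx1", start = 0L, end = 300L)
  treated_clean <- make_track("tx1", rep(100L, 300),
                              at_mismatch = rep(0L, 300),
                              treatment = "treated")
  treated_clean$at_mismatch[151] <- 0L
  cand <- data.frame(transcript_id = "tx1", position = 150L,
                     mismatch_rate = 0.30, depth_ratio = NA_real_,
                     stringsAsFactors = FALSE)
  out <- detect_treatment_rescue(cand, treated_clean, peaks_trt, model)
  expect_equal(nrow(out), 1)
  # treated mismatch persists: not rescued
  treated_dirty <- treated_clean
  treated_dirty$at_mismatch[151] <- 30L
  expect_equal(nrow(detect_treatment_rescue(cand, treated_dirty, peaks_trt,
                                            model)), 0)
  # a persisting trough is not rescued
  cov <- rep(100L, 300); cov[141:161] <- 50L
  trough_persists <- make_track("tx1", cov, treatment = "treated")
  cand2 <- data.frame(transcript_id = "tx1", position = 150L,
                      mismatch_rate = NA_real_, depth_ratio = 0.5,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(detect_treatment_rescue(cand2, trough_persists,
                                            peaks_trt, model)), 0)
  # a filled trough is rescued
  filled <- make_track("tx1", rep(100L, 300), treatment = "treated")
  expect_equal(nrow(detect_treatment_rescue(cand2, filled, peaks_trt,
                                            model)), 1)
  # no treated library: method skipped with a warning
  expect_warning(res <- detect_treatment_rescue(cand, NULL, peaks_trt, model),
                 "treatment method skipped")
  expect_null(res)
})

test_that("consensus support follows the at-least-two rule", {
  mk <- function(pos) data.frame(transcript_id = "tx1", position = pos,
                                 stringsAsFactors = FALSE)
  peaks <- data.frame(transcript_id = "tx1", start = 100L, end = 300L,
                      summit = 200L, stringsAsFactors = FALSE)
  # mismatch + trough within tolerance: consensus member
  out <- consensus_sites(list(conventional = NULL, mismatch = mk(150),
                              trough = mk(153), treatment = NULL))
  expect_equal(sum(out$consensus), 1)
  expect_equal(out$n_methods, 2)
  # conventional-only peak: excluded at min_methods = 2
  out <- consensus_sites(list(conventional = peaks, mismatch = NULL,
                              trough = NULL, treatment = NULL))
  expect_equal(sum(out$consensus), 0)
  expect_true(out$peak_level)
  expect_equal(out$position, 200L)   # summit as representative position
  # all four methods at one position
  out <- consensus_sites(list(conventional = peaks, mismatch = mk(200),
                              trough = mk(198), treatment = mk(202)))
  expect_equal(max(out$n_methods), 4)
  expect_true(any(out$consensus))
  # beyond the +/-5 tolerance the calls stay separate
  out <- consensus_sites(list(conventional = NULL, mismatch = mk(150),
                              trough = mk(160), treatment = NULL))
  expect_equal(sum(out$consensus), 0)
  expect_equal(nrow(out), 2)
  expect_error(consensus_sites(list(), min_methods = 5), "min_methods")
})

test_that("consensus sets shrink monotonically in min_methods", {
  fx <- standard_fixture(seed = 53, n_transcripts = 30,
                         length_range = list(mRNA = c(500, 1200),
                                             lncRNA = c(400, 900),
                                             circRNA = c(300, 700)))
  prev <- NULL
  for (mm in 1:4) {
    called <- call_m1a_sites(fx$pileups, fx$models, "Control",
                             min_methods = mm)
    ids <- paste(called$transcript_id[called$consensus],
                 called$position[called$consensus])
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("methylation level matches its closed form", {
  ip <- make_track("tx1", rep(40L, 100))
  inp <- make_track("tx1", rep(40L, 100), library = "input")
  iv <- data.frame(transcript_id = "tx1", start = 10L, end = 60L)
  expect_equal(methylation_level(ip, inp, iv), 0)
  ip4 <- make_track("tx1", rep(40L, 100))
  in1 <- make_track("tx1", rep(10L, 100), library = "input")
  # with equal size factors and psi = 0 the level is exactly log2(4)
  expect_equal(methylation_level(ip4, in1, iv, pseudocount = 0,
                                 size_factors = c(1, 1)), 2)
  expect_error(methylation_level(ip, inp, iv[0, ]), "empty interval")
})

test_that("methylation levels recover the planted enrichment on average", {
  fx <- standard_fixture(seed = 59, n_transcripts = 100, depth = 100,
                         methyl_fraction_range = c(1, 1),
                         truncation_prob = 0)
  ip <- pool_pileups(fx$pileups, "IP", "untreated")
  inp <- pool_pileups(fx$pileups, "input", "untreated")
  iv <- data.frame(transcript_id = fx$sites$transcript_id,
                   start = pmax(0L, fx$sites$position - 50L),
                   end = fx$sites$position + 51L)
  lev <- methylation_level(ip, inp, iv)
  expect_lt(abs(mean(lev) - log2(8)), 0.2)
})

test_that("RNA rollup counts transcripts with consensus sites", {
  sites <- data.frame(transcript_id = c("a", "a", "b", "c"),
                      position = c(1L, 50L, 10L, 20L),
                      consensus = c(TRUE, TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  models <- rbind(make_model("a", "AAAA"), make_model("b", "CCCC"),
                  make_model("c", "GGGG"))
  out <- rollup_rna(sites, models)
  expect_equal(out$transcript_id, c("a", "b"))
  expect_equal(out$n_sites, c(2L, 1L))
})
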