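# The four m1A identification methods and the >=2-method consensus.
#
# conventional: IP/input enrichment peaks (peak-level support, see peakcall).
# mismatch:     A->T misincorporation above the sequencing error rate.
# trough:       coverage depression inside a peak at/adjacent to an A,
#               caused by RT termination at the modified base.
# treatment:    after chemical m1A->m6A conversion the RT signatures vanish
#               while the peak keeps a normal shape.

#' Pool pileup tracks across replicates
#'
#' Sums `coverage`, `at_mismatch` and `read_start` per
#' (transcript, position) for the selected library slice.
#'
#' @param pileups pileup `data.frame`.
#' @param library,treatment,condition optional filters.
#' @return pooled pileup `data.frame` (columns `transcript_id`, `pos`,
#'   `coverage`, `at_mismatch`, `read_start`).
#' @export
pool_pileups <- function(pileups, library = NULL, treatment = NULL,
                         condition = NULL) {
  df <- pileups
  if (!is.null(library)) df <- df[df$library == library, , drop = FALSE]
  if (!is.null(treatment)) df <- df[df$treatment == treatment, , drop = FALSE]
  if (!is.null(condition)) df <- df[df$condition == condition, , drop = FALSE]
  if (!nrow(df)) {
    return(data.frame(transcript_id = character(), pos = integer(),
                      coverage = integer(), at_mismatch = integer(),
                      read_start = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(df$transcript_id, df$pos, sep = "\r")
  agg <- rowsum(cbind(df$coverage, df$at_mismatch, df$read_start), key,
                reorder = TRUE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  res <- data.frame(
    transcript_id = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    coverage = as.integer(agg[, 1]),
    at_mismatch = as.integer(agg[, 2]),
    read_start = as.integer(agg[, 3]),
    stringsAsFactors = FALSE)
  res[order(res$transcript_id, res$pos), , drop = FALSE]
}

# coverage / mismatch / read-start vectors per transcript from a pooled track
track_vectors <- function(track, len) {
  cov <- integer(len); mis <- integer(len); rs <- integer(len)
  cov[track$pos + 1L] <- track$coverage
  mis[track$pos + 1L] <- track$at_mismatch
  if ("read_start" %in% names(track)) rs[track$pos + 1L] <- track$read_start
  list(cov = cov, mis = mis, rs = rs)
}

#' Mismatch method: A->T misincorporation sites inside peaks
#'
#' Every reference `A` inside a peak with pooled IP coverage at least
#' `min_cov` is tested one-sided against the binomial background
#' `error_rate`; p values are BH-adjusted across all tested positions and
#' a site requires adjusted p <= `alpha` and mismatch rate >= `min_rate`.
#'
#' @param ip pooled IP pileup (see [pool_pileups()]).
#' @param peaks peak `data.frame` (`transcript_id`, `start`, `end`).
#' @param models transcript models (for sequences).
#' @param min_cov minimum coverage at a tested position.
#' @param error_rate background A->T error rate.
#' @param alpha BH-adjusted significance cutoff.
#' @param min_rate minimum observed mismatch rate.
#' @return `data.frame`: `transcript_id`, `position`, `coverage`,
#'   `mismatch`, `rate`, `p`, `padj`.
#' @export
detect_mismatch <- function(ip, peaks, models, min_cov = 20,
                            error_rate = 0.001, alpha = 0.05,
                            min_rate = 0.02) {
  if (!is.numeric(error_rate) || error_rate <= 0 || error_rate >= 1) {
    stop("configuration error: error_rate must be in (0,1)", call. = FALSE)
  }
  seqs <- setNames(models$sequence, models$transcript_id)
  lens <- setNames(models$length, models$transcript_id)
  ip_split <- split(ip, ip$transcript_id)
  rows <- list()
  for (tx in unique(peaks$transcript_id)) {
    trk <- ip_split[[tx]]
    if (is.null(trk)) next
    v <- track_vectors(trk, lens[[tx]])
    is_a <- strsplit(seqs[[tx]], "", fixed = TRUE)[[1]] == "A"
    px <- peaks[peaks$transcript_id == tx, , drop = FALSE]
    in_peak <- rep(FALSE, lens[[tx]])
    for (i in seq_len(nrow(px))) {
      in_peak[(px$start[i] + 1L):px$end[i]] <- TRUE
    }
    test_pos <- which(in_peak & is_a & v$cov >= min_cov)
    if (!length(test_pos)) next
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = tx, position = test_pos - 1L,
      coverage = v$cov[test_pos], mismatch = v$mis[test_pos],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), position = integer(),
                      coverage = integer(), mismatch = integer(),
                      rate = numeric(), p = numeric(), padj = numeric(),
                      stringsAsFactors = FALSE))
  }
  tested <- do.call(rbind, rows)
  tested$rate <- tested$mismatch / tested$coverage
  tested$p <- pbinom(tested$mismatch - 1L, tested$coverage, error_rate,
                     lower.tail = FALSE)
  tested$padj <- p.adjust(tested$p, method = "BH")
  res <- tested[tested$padj <= alpha & tested$rate >= min_rate, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Trough method: coverage depression inside one peak
#'
#' Smooths the IP coverage with a centered moving average, finds interior
#' local minima at or adjacent to a reference `A`, and calls a trough when
#' the smoothed depth is at most `(1 - min_drop)` times the lower of the
#' two shoulder maxima (each shoulder searched within
#' `shoulder_halfwidth` nt of the candidate, inside the peak).  The
#' depression must sit in the middle of the peak: both shoulder maxima
#' must reach `min_shoulder_frac` of the peak's smoothed maximum, which
#' rejects incidental dips in the low flanks.  When the read-start track
#' shows a clear RT-stop spike near the chosen minimum (at least
#' `start_spike_fold` times the peak's median start count), the site is
#' snapped to the spike - the truncation start pinpoints the modified
#' base more precisely than the smoothed coverage minimum.  On ties the
#' deepest, then leftmost candidate wins.
#'
#' @param ip pooled IP pileup.
#' @param peak a single-row peak `data.frame`.
#' @param models transcript models.
#' @param shoulder_halfwidth shoulder search half-width (nt).
#' @param min_drop minimum relative depth of the depression.
#' @param smooth_width moving-average width (nt).
#' @param min_shoulder_frac minimum shoulder height relative to the peak
#'   maximum.
#' @param start_spike_fold read-start spike threshold for position
#'   refinement.
#' @return one-row `data.frame` (`transcript_id`, `position`,
#'   `depth_ratio`) or `NULL` when no trough qualifies.
#' @export
detect_trough <- function(ip, peak, models, shoulder_halfwidth = 50,
                          min_drop = 0.3, smooth_width = 5,
                          min_shoulder_frac = 0.5, start_spike_fold = 5) {
  stopifnot(nrow(peak) == 1L)
  if (peak$end - peak$start < 2 * shoulder_halfwidth + 1) {
    m1a_log("debug", "peak shorter than trough window on ",
            peak$transcript_id, "; skipped")
    return(NULL)
  }
  tx <- peak$transcript_id
  mrow <- models[models$transcript_id == tx, , drop = FALSE]
  if (!nrow(mrow)) return(NULL)
  trk <- ip[ip$transcript_id == tx, , drop = FALSE]
  if (!nrow(trk)) return(NULL)
  v <- track_vectors(trk, mrow$length)
  idx <- (peak$start + 1L):peak$end       # 1-based within transcript
  s <- moving_average(v$cov[idx], smooth_width)
  n <- length(s)
  if (n < 3L) return(NULL)
  interior <- 2:(n - 1L)
  is_min <- s[interior] <= s[interior - 1L] & s[interior] <= s[interior + 1L] &
    (s[interior] < s[interior - 1L] | s[interior] < s[interior + 1L])
  cand <- interior[is_min]
  if (!length(cand)) return(NULL)
  bases <- strsplit(mrow$sequence, "", fixed = TRUE)[[1]]
  a_here <- bases[peak$start + cand] == "A"           # candidate itself
  a_adj <- vapply(cand, function(i) {
    any(bases[pmax(1L, peak$start + i - 1L):
                pmin(mrow$length, peak$start + i + 1L)] == "A")
  }, logical(1))
  cand <- cand[a_here | a_adj]
  if (!length(cand)) return(NULL)
  peak_max <- max(s)
  ratio <- vapply(cand, function(i) {
    left <- s[max(1L, i - shoulder_halfwidth):(i - 1L)]
    right <- s[(i + 1L):min(n, i + shoulder_halfwidth)]
    shoulder <- min(max(left), max(right))
    if (shoulder <= 0 || shoulder < min_shoulder_frac * peak_max) return(Inf)
    s[i] / shoulder
  }, numeric(1))
  ok <- which(ratio <= 1 - min_drop)
  if (!length(ok)) return(NULL)
  # an RT-truncation trough must carry an RT-stop spike: when the track
  # has read-start counts, require one near the minimum and take its
  # position (a depression without excess starts is not a truncation
  # signature, e.g. the valley between two nearby enrichment bumps)
  rs_peak <- v$rs[idx]
  have_rs <- any(rs_peak > 0)
  spike_floor <- start_spike_fold * (median(rs_peak) + 1)
  best <- NA_integer_
  for (b in ok[order(ratio[ok], cand[ok])]) {
    i <- cand[b]
    if (!have_rs) { best <- b; break }
    look <- max(1L, i - 4L * smooth_width):min(n, i + 4L * smooth_width)
    if (max(rs_peak[look]) >= spike_floor) { best <- b; break }
  }
  if (is.na(best)) return(NULL)
  i <- cand[best]
  pos0 <- peak$start + i - 1L                         # 0-based candidate
  if (have_rs) {
    look <- max(1L, i - 4L * smooth_width):min(n, i + 4L * smooth_width)
    spike <- look[which.max(rs_peak[look])]
    pos0 <- peak$start + spike - 1L
  }
  # snap to the A: the position itself if A, else nearest adjacent A
  if (bases[pos0 + 1L] != "A") {
    neigh <- c(pos0 - 1L, pos0 + 1L)
    neigh <- neigh[neigh >= 0 & neigh < mrow$length]
    neigh <- neigh[bases[neigh + 1L] == "A"]
    if (length(neigh)) pos0 <- neigh[1]
  }
  data.frame(transcript_id = tx, position = pos0,
             depth_ratio = ratio[best], stringsAsFactors = FALSE)
}

#' Trough method over a peak list
#'
#' @inheritParams detect_trough
#' @param peaks peak `data.frame` (several rows).
#' @return `data.frame` of troughs (possibly empty).
#' @export
detect_trough_all <- function(ip, peaks, models, shoulder_halfwidth = 50,
                              min_drop = 0.3, smooth_width = 5) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    r <- detect_trough(ip, peaks[i, , drop = FALSE], models,
                       shoulder_halfwidth, min_drop, smooth_width)
    if (!is.null(r)) out[[length(out) + 1L]] <- r
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), position = integer(),
                      depth_ratio = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Treatment method: signature rescue after m1A->m6A conversion
#'
#' A candidate site (from the mismatch or trough method) is "rescued" when
#' (i) a treated-library peak still overlaps it, (ii) its treated mismatch
#' rate has dropped to at most `rescue_ratio` times the untreated rate
#' (when a mismatch signature existed), and (iii) its treated trough has
#' filled back to at least `fill_ratio` of the shoulder level (when a
#' trough existed).
#'
#' @param candidates `data.frame` with `transcript_id`, `position`, and
#'   optional `mismatch_rate` / `depth_ratio` columns describing the
#'   untreated signatures (`NA` = signature absent).
#' @param ip_treated pooled treated IP pileup; `NULL` skips the method
#'   with a warning.
#' @param peaks_treated treated-library peaks.
#' @param models transcript models.
#' @param rescue_ratio maximum treated/untreated mismatch-rate ratio.
#' @param fill_ratio minimum treated depth/shoulder ratio.
#' @param shoulder_halfwidth,smooth_width trough geometry (as in
#'   [detect_trough()]).
#' @return the rescued subset of `candidates` (possibly empty), or `NULL`
#'   when no treated library is available.
#' @export
detect_treatment_rescue <- function(candidates, ip_treated, peaks_treated,
                                    models, rescue_ratio = 0.25,
                                    fill_ratio = 0.85,
                                    shoulder_halfwidth = 50,
                                    smooth_width = 5) {
  if (is.null(ip_treated) || !nrow(ip_treated)) {
    warning("no treated library: treatment method skipped", call. = FALSE)
    return(NULL)
  }
  if (!nrow(candidates)) return(candidates)
  lens <- setNames(models$length, models$transcript_id)
  trt_split <- split(ip_treated, ip_treated$transcript_id)
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    tx <- candidates$transcript_id[i]
    pos <- candidates$position[i]
    ptx <- peaks_treated[peaks_treated$transcript_id == tx, , drop = FALSE]
    over <- nrow(ptx) && any(ptx$start <= pos & pos < ptx$end)
    if (!over) next
    trk <- trt_split[[tx]]
    if (is.null(trk)) next
    v <- track_vectors(trk, lens[[tx]])
    ok <- TRUE
    mr <- candidates$mismatch_rate
    if (!is.null(mr) && !is.na(mr[i]) && mr[i] > 0) {
      cov <- v$cov[pos + 1L]
      treated_rate <- if (cov > 0) v$mis[pos + 1L] / cov else 0
      ok <- ok && treated_rate <= rescue_ratio * mr[i]
    }
    dr <- candidates$depth_ratio
    if (ok && !is.null(dr) && !is.na(dr[i])) {
      pk <- ptx[ptx$start <= pos & pos < ptx$end, , drop = FALSE][1, ]
      idx <- (pk$start + 1L):pk$end
      s <- moving_average(v$cov[idx], smooth_width)
      j <- pos - pk$start + 1L
      left <- s[max(1L, j - shoulder_halfwidth):max(1L, j - 1L)]
      right <- s[min(length(s), j + 1L):min(length(s), j + shoulder_halfwidth)]
      shoulder <- min(max(left), max(right))
      ok <- ok && shoulder > 0 && (s[j] / shoulder) >= fill_ratio
    }
    keep[i] <- ok
  }
  res <- candidates[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Consensus over the four detection methods
#'
#' Base-resolution calls (mismatch, trough, treatment) are clustered per
#' transcript with a matching tolerance (single linkage, gap <= `tol` nt);
#' a cluster gains conventional support when its representative position
#' lies inside a conventional peak.  Conventional peaks containing no
#' base-resolution call are kept as peak-level candidates represented by
#' their summit.  The consensus set requires support from at least
#' `min_methods` methods.
#'
#' @param sites_by_method named list with elements `conventional` (peak
#'   `data.frame` with `summit`), and site `data.frame`s `mismatch`,
#'   `trough`, `treatment` (any may be `NULL`).
#' @param min_methods consensus threshold in `[1, 4]`; the published rule
#'   is 2.
#' @param tol site-matching tolerance in nt.
#' @return `data.frame` with `transcript_id`, `position`, logical columns
#'   `conventional`, `mismatch`, `trough`, `treatment`, `n_methods`,
#'   `consensus`, `peak_level`; attribute `"tallies"` holds per-method and
#'   shared/unique counts.
#' @export
consensus_sites <- function(sites_by_method, min_methods = 2, tol = 5) {
  if (min_methods < 1 || min_methods > 4) {
    stop("configuration error: min_methods must be in [1, 4]", call. = FALSE)
  }
  base_methods <- c("mismatch", "trough", "treatment")
  pieces <- list()
  for (m in base_methods) {
    df <- sites_by_method[[m]]
    if (!is.null(df) && nrow(df)) {
      pieces[[m]] <- data.frame(transcript_id = df$transcript_id,
                                position = df$position, method = m,
                                stringsAsFactors = FALSE)
    }
  }
  base <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(transcript_id = character(), position = integer(),
               method = character(), stringsAsFactors = FALSE)
  peaks <- sites_by_method$conventional
  out <- list()
  for (tx in unique(c(base$transcript_id, peaks$transcript_id))) {
    btx <- base[base$transcript_id == tx, , drop = FALSE]
    ptx <- if (!is.null(peaks)) {
      peaks[peaks$transcript_id == tx, , drop = FALSE]
    } else peaks
    covered_peak <- rep(FALSE, if (is.null(ptx)) 0 else nrow(ptx))
    if (nrow(btx)) {
      btx <- btx[order(btx$position), , drop = FALSE]
      grp <- cumsum(c(1, diff(btx$position) > tol))
      for (g in unique(grp)) {
        cl <- btx[grp == g, , drop = FALSE]
        pos <- as.integer(round(median(cl$position)))
        methods <- unique(cl$method)
        conv <- FALSE
        if (!is.null(ptx) && nrow(ptx)) {
          hit <- ptx$start <= pos & pos < ptx$end
          if (any(hit)) {
            conv <- TRUE
            covered_peak[hit] <- TRUE
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = tx, position = pos,
          conventional = conv,
          mismatch = "mismatch" %in% methods,
          trough = "trough" %in% methods,
          treatment = "treatment" %in% methods,
          peak_level = FALSE, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(ptx) && nrow(ptx)) {
      for (i in which(!covered_peak)) {
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = tx,
          position = as.integer(ptx$summit[i]),
          conventional = TRUE, mismatch = FALSE, trough = FALSE,
          treatment = FALSE, peak_level = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(transcript_id = character(), position = integer(),
               conventional = logical(), mismatch = logical(),
               trough = logical(), treatment = logical(),
               peak_level = logical(), stringsAsFactors = FALSE)
  res$n_methods <- rowSums(res[c("conventional", "mismatch", "trough",
                                 "treatment")])
  res$consensus <- res$n_methods >= min_methods
  res <- res[order(res$transcript_id, res$position), , drop = FALSE]
  rownames(res) <- NULL
  tallies <- list(
    per_method = colSums(res[c("conventional", "mismatch", "trough",
                               "treatment")]),
    support_hist = table(factor(res$n_methods, levels = 1:4)),
    consensus = sum(res$consensus))
  attr(res, "tallies") <- tallies
  res
}

#' Roll site calls up to the RNA level
#'
#' @param sites output of [consensus_sites()].
#' @param models transcript models (for biotype).
#' @return `data.frame` of RNAs carrying at least one consensus site, with
#'   `transcript_id`, `biotype`, `n_sites`.
#' @export
rollup_rna <- function(sites, models) {
  keep <- sites[sites$consensus, , drop = FALSE]
  if (!nrow(keep)) {
    return(data.frame(transcript_id = character(), biotype = character(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  }
  tab <- table(keep$transcript_id)
  res <- data.frame(transcript_id = names(tab),
                    n_sites = as.integer(tab), stringsAsFactors = FALSE)
  res$biotype <- models$biotype[match(res$transcript_id, models$transcript_id)]
  res[order(res$transcript_id), c("transcript_id", "biotype", "n_sites")]
}

#' Score recovery of planted sites by a set of calls
#'
#' A planted site counts as recovered when a call lies within `tol` nt of
#' it on the same transcript; a call with no planted site within `tol` is
#' a false positive.
#'
#' @param truth `data.frame` with `transcript_id`, `position`.
#' @param called `data.frame` with `transcript_id`, `position`.
#' @param tol matching tolerance (nt).
#' @return list with `sensitivity`, `fdr`, `n_true`, `n_called`.
#' @export
evaluate_site_recovery <- function(truth, called, tol = 5) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(called$transcript_id == truth$transcript_id[i] &
          abs(called$position - truth$position[i]) <= tol)
  }, logical(1))
  fp <- vapply(seq_len(nrow(called)), function(i) {
    !any(truth$transcript_id == called$transcript_id[i] &
           abs(truth$position - called$position[i]) <= tol)
  }, logical(1))
  list(sensitivity = if (nrow(truth)) mean(hit) else NA_real_,
       fdr = if (nrow(called)) mean(fp) else 0,
       n_true = nrow(truth), n_called = nrow(called))
}

#' Estimate IP/input size factors from background coverage
#'
#' The median of position-wise input/IP coverage ratios; background
#' (non-enriched) positions dominate a transcriptome-wide track, so this
#' equalizes the two libraries outside peaks without letting the
#' enrichment signal itself deflate the methylation levels.
#'
#' @param ip,input pooled pileups on common positions.
#' @return named vector `c(ip = 1, input = r)` scaling input to the IP
#'   background.
#' @export
estimate_size_factors <- function(ip, input) {
  key_ip <- paste(ip$transcript_id, ip$pos)
  key_in <- paste(input$transcript_id, input$pos)
  common <- intersect(key_ip, key_in)
  a <- ip$coverage[match(common, key_ip)]
  b <- input$coverage[match(common, key_in)]
  ok <- a > 0 & b > 0
  r <- if (any(ok)) median(a[ok] / b[ok]) else 1
  c(ip = 1, input = r)
}

#' Normalized log2 IP/input methylation level of an interval
#'
#' `level = log2((sf_ip * mean(IP) + psi) / (sf_in * mean(input) + psi))`.
#' By default the size factors put the input on the IP background scale
#' ([estimate_size_factors()]); pass `size_factors = c(1, 1)` for
#' already-normalized tracks.
#'
#' @param ip,input pooled pileups for one library pair.
#' @param intervals `data.frame` with `transcript_id`, `start`, `end`
#'   (half-open); a site may be given as `position` (then a single base).
#' @param pseudocount stabilizing pseudocount psi.
#' @param size_factors length-2 numeric `(ip, input)` or `NULL` to
#'   estimate from background.
#' @return numeric vector of levels, one per interval row.
#' @export
methylation_level <- function(ip, input, intervals, pseudocount = 1,
                              size_factors = NULL) {
  if (!nrow(intervals)) stop("empty interval set", call. = FALSE)
  if (!all(c("start", "end") %in% names(intervals))) {
    intervals$start <- intervals$position
    intervals$end <- intervals$position + 1L
  }
  if (any(intervals$end <= intervals$start)) {
    stop("empty interval", call. = FALSE)
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(ip, input)
  sf_ip <- size_factors[[1]]
  sf_in <- size_factors[[2]]
  ip_split <- split(ip, ip$transcript_id)
  in_split <- split(input, input$transcript_id)
  vapply(seq_len(nrow(intervals)), function(i) {
    tx <- intervals$transcript_id[i]
    sel <- function(trk) {
      if (is.null(trk)) return(0)
      inwin <- trk$pos >= intervals$start[i] & trk$pos < intervals$end[i]
      if (!any(inwin)) 0 else mean(trk$coverage[inwin])
    }
    log2((sf_ip * sel(ip_split[[tx]]) + pseudocount) /
           (sf_in * sel(in_split[[tx]]) + pseudocount))
  }, numeric(1))
}

#' Run the four methods and consensus for one condition
#'
#' Orchestrates the full site-calling stage on a pileup collection:
#' per-replicate Poisson peak calling on untreated IP vs input,
#' replicate consolidation, pooled mismatch and trough detection,
#' treatment-rescue on the pooled treated libraries, and the >=2-method
#' consensus.
#'
#' @param pileups pileup `data.frame` covering IP+input libraries of one
#'   or more conditions.
#' @param models transcript models.
#' @param condition condition name to analyse.
#' @param min_reps replicate support required for a reproducible peak.
#' @param min_methods consensus threshold.
#' @param window,step,score_threshold peak-caller parameters.
#' @param min_cov,error_rate,alpha,min_rate mismatch-method parameters.
#' @param shoulder_halfwidth,min_drop,smooth_width trough parameters.
#' @param rescue_ratio,fill_ratio treatment-method parameters.
#' @param use_treated set `FALSE` to run the 3-method consensus without a
#'   treated library.
#' @return the [consensus_sites()] `data.frame` (attribute `"tallies"`),
#'   plus attribute `"peaks"` with the reproducible untreated peaks.
#' @export
call_m1a_sites <- function(pileups, models, condition,
                           min_reps = 2, min_methods = 2,
                           window = 100, step = 25, score_threshold = 3,
                           min_cov = 20, error_rate = 0.001, alpha = 0.05,
                           min_rate = 0.02,
                           shoulder_halfwidth = 50, min_drop = 0.3,
                           smooth_width = 5,
                           rescue_ratio = 0.25, fill_ratio = 0.85,
                           use_treated = TRUE) {
  cc <- pileups[pileups$condition == condition, , drop = FALSE]
  if (!nrow(cc)) stop(sprintf("condition '%s' absent from pileups", condition),
                      call. = FALSE)
  reps <- sort(unique(cc$replicate))
  peak_lists <- lapply(reps, function(r) {
    call_peaks(cc[cc$library == "IP" & cc$treatment == "untreated" &
                    cc$replicate == r, , drop = FALSE],
               cc[cc$library == "input" & cc$treatment == "untreated" &
                    cc$replicate == r, , drop = FALSE],
               window = window, step = step,
               score_threshold = score_threshold)
  })
  peaks <- reproducible_peaks(peak_lists, min_reps = min(min_reps, length(reps)))
  # representative summit for peak-level consensus entries
  ip_pool <- pool_pileups(cc, library = "IP", treatment = "untreated")
  lens <- setNames(models$length, models$transcript_id)
  if (nrow(peaks)) {
    ip_split <- split(ip_pool, ip_pool$transcript_id)
    peaks$summit <- vapply(seq_len(nrow(peaks)), function(i) {
      trk <- ip_split[[peaks$transcript_id[i]]]
      v <- track_vectors(trk, lens[[peaks$transcript_id[i]]])
      rng <- (peaks$start[i] + 1L):peaks$end[i]
      peaks$start[i] + which.max(v$cov[rng]) - 1L
    }, integer(1))
  } else {
    peaks$summit <- integer(0)
  }
  mm <- detect_mismatch(ip_pool, peaks, models, min_cov = min_cov,
                        error_rate = error_rate, alpha = alpha,
                        min_rate = min_rate)
  tr <- detect_trough_all(ip_pool, peaks, models,
                          shoulder_halfwidth = shoulder_halfwidth,
                          min_drop = min_drop, smooth_width = smooth_width)
  rescue <- NULL
  if (use_treated && any(cc$treatment == "treated")) {
    cand <- unique(data.frame(
      transcript_id = c(mm$transcript_id, tr$transcript_id),
      position = c(mm$position, tr$position),
      stringsAsFactors = FALSE))
    if (nrow(cand)) {
      cand$mismatch_rate <- mm$rate[match(paste(cand$transcript_id, cand$position),
                                          paste(mm$transcript_id, mm$position))]
      cand$depth_ratio <- tr$depth_ratio[match(paste(cand$transcript_id, cand$position),
                                               paste(tr$transcript_id, tr$position))]
    }
    ip_trt <- pool_pileups(cc, library = "IP", treatment = "treated")
    in_trt <- pool_pileups(cc, library = "input", treatment = "treated")
    trt_peak_lists <- lapply(reps, function(r) {
      call_peaks(cc[cc$library == "IP" & cc$treatment == "treated" &
                      cc$replicate == r, , drop = FALSE],
                 cc[cc$library == "input" & cc$treatment == "treated" &
                      cc$replicate == r, , drop = FALSE],
                 window = window, step = step,
                 score_threshold = score_threshold)
    })
    peaks_trt <- reproducible_peaks(trt_peak_lists,
                                    min_reps = min(min_reps, length(reps)))
    rescue <- detect_treatment_rescue(cand, ip_trt, peaks_trt, models,
                                      rescue_ratio = rescue_ratio,
                                      fill_ratio = fill_ratio,
                                      shoulder_halfwidth = shoulder_halfwidth,
                                      smooth_width = smooth_width)
  } else if (use_treated) {
    warning("no treated library: treatment method skipped", call. = FALSE)
  }
  sites <- consensus_sites(list(conventional = peaks, mismatch = mm,
                                trough = tr, treatment = rescue),
                           min_methods = min_methods)
  attr(sites, "peaks") <- peaks
  sites
}
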