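# Conventional m1A peak calling: IP-vs-input Poisson enrichment on sliding
# windows, thresholded at -10*log10(p) > 3 and merged into peaks.

#' Call enrichment peaks on one or more transcripts
#'
#' For each sliding window the input count is scaled by the library-size
#' ratio to give the Poisson background rate `lambda = max(scaled input,
#' lambda0)`; the window p value is the upper-tail Poisson probability
#' `P(X >= ip_count | lambda)`.  Windows scoring above
#' `-10*log10(p) > score_threshold` are merged when separated by at most
#' `max_gap` nt; the summit is the position of maximum IP coverage inside
#' the merged peak (leftmost on ties).
#'
#' @param ip,input pileup `data.frame`s for the IP and input libraries of
#'   one condition/treatment/replicate (any number of transcripts; the
#'   input track must be non-empty).
#' @param window window width in nt.
#' @param step window step in nt (`window >= step >= 1`).
#' @param score_threshold minimum `-10*log10(p)`; the conventional
#'   threshold is 3.
#' @param max_gap maximal gap (nt) between merged windows; defaults to
#'   `window`.
#' @param lambda0 background pseudo-rate floor.
#' @return a `data.frame` of peaks sorted by (`transcript_id`, `start`):
#'   columns `transcript_id`, `start`, `end` (0-based half-open), `score`
#'   (`-10*log10(p)` of the best window), `p_value`, `fold_enrichment`,
#'   `summit`.
#' @export
call_peaks <- function(ip, input, window = 100, step = 25,
                       score_threshold = 3, max_gap = window, lambda0 = 1) {
  stopifnot(window >= step, step >= 1)
  if (is.null(input) || nrow(input) == 0) {
    stop("input library required: empty input track", call. = FALSE)
  }
  ip_libsize <- sum(ip$coverage)
  input_libsize <- sum(input$coverage)
  if (input_libsize == 0) {
    stop("input library has zero total coverage", call. = FALSE)
  }
  sf <- ip_libsize / input_libsize  # scale input counts to IP depth

  ip_split <- split(ip, ip$transcript_id)
  in_split <- split(input, input$transcript_id)
  out <- list()
  for (tx in names(ip_split)) {
    ipx <- ip_split[[tx]]
    inx <- in_split[[tx]]
    if (is.null(inx)) next
    len <- max(ipx$pos, inx$pos) + 1L
    ip_cov <- integer(len); ip_cov[ipx$pos + 1L] <- ipx$coverage
    in_cov <- integer(len); in_cov[inx$pos + 1L] <- inx$coverage
    if (len < window) next
    starts <- seq(0L, len - window, by = step)
    csum_ip <- cumsum(c(0, ip_cov))
    csum_in <- cumsum(c(0, in_cov))
    ip_win <- csum_ip[starts + window + 1L] - csum_ip[starts + 1L]
    in_win <- csum_in[starts + window + 1L] - csum_in[starts + 1L]
    lambda <- pmax(in_win * sf, lambda0)
    logp <- ppois(ip_win - 1, lambda, lower.tail = FALSE, log.p = TRUE)
    score <- -10 * logp / log(10)
    keep <- which(score > score_threshold)
    if (!length(keep)) next
    ir <- IRanges::reduce(
      IRanges::IRanges(starts[keep] + 1L, starts[keep] + window),
      min.gapwidth = max_gap + 1L)
    for (i in seq_along(ir)) {
      s0 <- IRanges::start(ir)[i] - 1L
      e0 <- IRanges::end(ir)[i]
      inside <- keep[starts[keep] >= s0 & starts[keep] + window <= e0]
      best <- inside[which.max(score[inside])]
      pos_range <- (s0 + 1L):e0
      summit <- s0 + which.max(ip_cov[pos_range]) - 1L
      ip_peak <- sum(ip_cov[pos_range])
      in_peak <- sum(in_cov[pos_range])
      fe <- (ip_peak / ip_libsize) / max(in_peak / input_libsize,
                                         .Machine$double.xmin)
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tx, start = s0, end = e0,
        score = score[best], p_value = exp(logp[best]),
        fold_enrichment = fe, summit = summit,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), score = numeric(), p_value = numeric(),
                      fold_enrichment = numeric(), summit = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$transcript_id, res$start), , drop = FALSE]
}

#' Consolidate peaks across replicates
#'
#' Keeps regions supported by at least `min_reps` replicate peak sets; the
#' coordinates of a reported region are the intersection of the supporting
#' intervals (positions covered by `>= min_reps` replicate peaks).
#'
#' @param peak_lists list of peak `data.frame`s (one per replicate).
#' @param min_reps minimum number of supporting replicates.
#' @return `data.frame` with `transcript_id`, `start`, `end`, `support`
#'   (maximum replicate support inside the region).
#' @export
reproducible_peaks <- function(peak_lists, min_reps = 2) {
  if (min_reps > length(peak_lists)) {
    stop("configuration error: min_reps exceeds number of replicates",
         call. = FALSE)
  }
  all_tx <- unique(unlist(lapply(peak_lists, function(p) p$transcript_id)))
  out <- list()
  for (tx in all_tx) {
    irs <- lapply(peak_lists, function(p) {
      px <- p[p$transcript_id == tx, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(px$start + 1L, px$end))
    })
    len <- max(vapply(irs, function(ir) {
      if (length(ir)) max(IRanges::end(ir)) else 0L
    }, numeric(1)))
    cov <- Reduce(`+`, lapply(irs, IRanges::coverage, width = len))
    sl <- IRanges::slice(cov, lower = min_reps, rangesOnly = TRUE)
    if (!length(sl)) next
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = tx,
      start = IRanges::start(sl) - 1L,
      end = IRanges::end(sl),
      support = vapply(seq_along(sl), function(i) {
        as.integer(max(as.numeric(
          cov[IRanges::start(sl)[i]:IRanges::end(sl)[i]])))
      }, integer(1)),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), support = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$transcript_id, res$start), , drop = FALSE]
}
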