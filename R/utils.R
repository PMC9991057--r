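# Shared internals: seed streams, logging, light numeric helpers.

#' Derive a child seed from a master seed and a stream label
#'
#' All randomness in the package flows through one convention: a 32-bit
#' child seed deterministically derived from the master seed and a short
#' stream label, so independent stages never share an RNG stream.
#'
#' @param seed master seed (integer).
#' @param stream character label of the stream, e.g. `"sites"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # FNV-1a style fold of the label into the seed, kept under 2^31 - 1
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(paste(stream, collapse = ""))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

m1a_log <- function(level, ...) {
  threshold <- getOption("m1ascope.log_level", "info")
  if (log_levels[[level]] >= log_levels[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

#' @noRd
moving_average <- function(x, width) {
  stopifnot(width >= 1L)
  if (width == 1L) return(as.numeric(x))
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, as.numeric(x)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Non-cryptographic content hash for provenance headers (hex string).
# Polynomial rolling hash in 31 bits; the multiplier keeps intermediate
# products below 2^53 so double arithmetic stays exact.
content_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(txt)) {
    h <- ((h + b) * 131) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Adjusted Rand index between two partitions
#'
#' Used to score recovery of planted sample groupings by consensus NMF.
#'
#' @param a,b integer/character vectors of cluster labels, same length.
#' @return the Hubert-Arabie adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sij - expected) / (maxi - expected)
}

# validate a scalar probability
check_prob <- function(x, name, open_left = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1 ||
      (open_left && x == 0)) {
    stop(sprintf("configuration error: '%s' must be a probability in %s",
                 name, if (open_left) "(0,1]" else "[0,1]"), call. = FALSE)
  }
  invisible(x)
}
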