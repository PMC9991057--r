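# Shared fixtures and independent oracles for the test suite.

# a pileup track from an explicit coverage vector
make_track <- function(transcript_id, coverage, at_mismatch = 0,
                       read_start = 0, library = "IP",
                       treatment = "untreated", condition = "Control",
                       replicate = 1L) {
  n <- length(coverage)
  data.frame(transcript_id = transcript_id, pos = 0:(n - 1L),
             coverage = as.integer(coverage),
             at_mismatch = as.integer(rep_len(at_mismatch, n)),
             read_start = as.integer(rep_len(read_start, n)),
             library = library, treatment = treatment,
             condition = condition, replicate = replicate,
             stringsAsFactors = FALSE)
}

# a single-transcript model with an explicit sequence
make_model <- function(transcript_id, sequence, biotype = "mRNA",
                       utr5_end = NA, cds_end = NA, chrom = "chr1",
                       strand = "+") {
  len <- nchar(sequence)
  if (biotype == "mRNA" && is.na(utr5_end)) {
    utr5_end <- max(1L, round(len * 0.2))
    cds_end <- round(len * 0.8)
  }
  data.frame(transcript_id = transcript_id, gene_id = paste0("g_", transcript_id),
             biotype = biotype, chrom = chrom, strand = strand, length = len,
             utr5_end = utr5_end, cds_end = cds_end,
             is_circular = biotype == "circRNA", sequence = sequence,
             stringsAsFactors = FALSE)
}

# ---- independent oracles -------------------------------------------------

# Poisson upper tail P(X >= k) by direct summation of the mass function
poisson_tail_brute <- function(k, lambda) {
  if (k <= 0) return(1)
  hi <- max(k, ceiling(lambda + 12 * sqrt(lambda) + 60))
  sum(dpois(k:hi, lambda))
}

# brute-force peak caller: test every window by direct tail summation,
# then merge qualifying windows with a plain loop
call_peaks_brute <- function(ip_cov, input_cov, sf, window, step,
                             score_threshold = 3, max_gap = window,
                             lambda0 = 1) {
  len <- length(ip_cov)
  if (len < window) return(NULL)
  starts <- seq(0L, len - window, by = step)
  hits <- list()
  for (s in starts) {
    ipc <- sum(ip_cov[(s + 1):(s + window)])
    inc <- sum(input_cov[(s + 1):(s + window)])
    lam <- max(inc * sf, lambda0)
    p <- poisson_tail_brute(ipc, lam)
    if (p > 0 && -10 * log10(p) > score_threshold) {
      hits[[length(hits) + 1L]] <- c(s, s + window)
    } else if (p == 0) {
      hits[[length(hits) + 1L]] <- c(s, s + window)
    }
  }
  if (!length(hits)) return(NULL)
  m <- do.call(rbind, hits)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- merged[[length(merged)]]
    if (m[i, 1] - last[2] <= max_gap) {
      merged[[length(merged)]] <- c(last[1], max(last[2], m[i, 2]))
    } else {
      merged[[length(merged) + 1L]] <- m[i, ]
    }
  }
  do.call(rbind, merged)
}

# Benjamini-Hochberg by the textbook step-up definition
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Fisher exact p (two-sided) by hypergeometric enumeration
fisher_brute <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- cc + d; k <- a + cc
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sample KS statistic by direct ECDF evaluation
ks_D_brute <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  Fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(Fx - Fy))
}

# one-way ANOVA F by direct sums of squares
anova_F_brute <- function(groups) {
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(unlist(groups)) - length(groups)
  (ssb / df1) / (ssw / df2)
}

# dinucleotide count table of a sequence
dinuc_counts <- function(s) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(b) < 2) return(table(character(0)))
  table(paste0(b[-length(b)], b[-1]))
}

# a sites x samples matrix with k planted sample blocks (block-specific
# feature signatures, mild cross-loadings, per-entry noise)
planted_matrix <- function(n_feat = 200, n_samp = 9, k = 3, noise = 0.3,
                           cross = 0.3, seed = 1) {
  set.seed(seed)
  blocks <- sort(rep(1:k, length.out = ceiling(n_samp / k) * k)[seq_len(n_samp)])
  W <- matrix(runif(n_feat * k, 0, 0.3), n_feat, k)
  for (j in 1:k) {
    rows <- seq.int((j - 1) * n_feat / k + 1, j * n_feat / k)
    W[rows, j] <- W[rows, j] + runif(length(rows), 1.5, 3)
  }
  H <- matrix(runif(k * n_samp, 0, cross), k, n_samp)
  for (s in seq_len(n_samp)) H[blocks[s], s] <- 1
  X <- W %*% H + matrix(abs(rnorm(n_feat * n_samp, 0, noise)), n_feat)
  list(X = X, blocks = blocks)
}

# the standard planted-site fixture used by the recovery checks
standard_fixture <- function(seed = 20240915, ...) {
  cfg <- sim_config(seed = seed, conditions = "Control", ...)
  models <- generate_transcriptome(cfg)
  sites <- plant_sites(models, cfg)
  pileups <- simulate_merip_pileups(models, sites, cfg)
  list(config = cfg, models = models, sites = sites, pileups = pileups)
}
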