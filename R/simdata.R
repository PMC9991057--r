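# Synthetic MeRIP-seq study generator.
#
# The simulator works at pileup level (no reads, no alignment): per-position
# coverage, A->T mismatch and read-start counts for every
# {input, IP} x {untreated, treated} x replicate x condition library.
# Planted m1A sites carry the three biochemical signatures the detection
# methods look for: IP enrichment, RT-truncation coverage depression, and
# A->T misincorporation; chemical conversion in "treated" libraries removes
# truncation and misincorporation while reverse transcription stays normal.

#' Simulation configuration
#'
#' Defaults describe a desk-scale MeRIP-seq study of primary neurons under
#' oxygen-glucose deprivation/reoxygenation: three conditions (control plus
#' two reperfusion time points) with three biological replicates each,
#' ~100-nt RNA fragments, and antibody enrichment around planted sites.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param biotype_props named proportions over `mRNA`, `lncRNA`, `circRNA`;
#'   must sum to 1.
#' @param length_range named list of `c(min, max)` transcript lengths (nt)
#'   per biotype.
#' @param site_rate expected planted m1A sites per transcript (Poisson).
#' @param region_weights placement bias of mRNA sites over
#'   `c(utr5, cds, utr3)`; CDS-heavy by default, matching the observed
#'   concentration of m1A peaks in coding sequence.
#' @param depth mean input-library coverage per position at expression
#'   factor 1.
#' @param conditions character vector of condition names.
#' @param replicates biological replicates per condition.
#' @param methyl_fraction_range range of the per-site methylated molecule
#'   fraction f, drawn uniformly.
#' @param truncation_prob probability t that reverse transcription stops at
#'   the modified base of a methylated molecule.
#' @param mismatch_prob probability m of A->T misincorporation in a
#'   methylated, non-truncated read at the site.
#' @param ip_enrichment IP/input enrichment factor e (>= 1) inside the
#'   antibody window around a fully methylated site.
#' @param conversion_prob probability c that the treatment converts a
#'   methylated molecule (losing both truncation and mismatch signatures).
#' @param read_span fragment length (nt); sets the truncation shadow.
#' @param ip_window_halfwidth half-width (nt) of the IP enrichment window.
#' @param error_rate background A->T sequencing error rate per base.
#' @param seed master seed; fixes every downstream draw.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_transcripts = 200,
                       biotype_props = c(mRNA = 0.6, lncRNA = 0.2, circRNA = 0.2),
                       length_range = list(mRNA = c(600, 3000),
                                           lncRNA = c(400, 2000),
                                           circRNA = c(300, 1500)),
                       site_rate = 1.5,
                       region_weights = c(utr5 = 0.25, cds = 0.55, utr3 = 0.20),
                       depth = 30,
                       conditions = c("Control", "OGDR_1.5h", "OGDR_3h"),
                       replicates = 3,
                       methyl_fraction_range = c(0.6, 1),
                       truncation_prob = 0.5,
                       mismatch_prob = 0.15,
                       ip_enrichment = 8,
                       conversion_prob = 0.9,
                       read_span = 100,
                       ip_window_halfwidth = read_span,
                       error_rate = 0.001,
                       seed = 1) {
  if (abs(sum(biotype_props) - 1) > 1e-8) {
    stop("configuration error: biotype_props must sum to 1", call. = FALSE)
  }
  if (!all(names(biotype_props) %in% c("mRNA", "lncRNA", "circRNA"))) {
    stop("configuration error: biotype_props names must be mRNA/lncRNA/circRNA",
         call. = FALSE)
  }
  if (depth <= 0) stop("configuration error: depth must be > 0", call. = FALSE)
  if (site_rate < 0) stop("configuration error: site_rate must be >= 0", call. = FALSE)
  if (ip_enrichment < 1) {
    stop("configuration error: ip_enrichment must be >= 1", call. = FALSE)
  }
  check_prob(truncation_prob, "truncation_prob")
  check_prob(mismatch_prob, "mismatch_prob")
  check_prob(conversion_prob, "conversion_prob")
  check_prob(error_rate, "error_rate")
  stopifnot(length(methyl_fraction_range) == 2L,
            methyl_fraction_range[1] > 0, methyl_fraction_range[2] <= 1,
            methyl_fraction_range[1] <= methyl_fraction_range[2])
  if (abs(sum(region_weights) - 1) > 1e-8) {
    stop("configuration error: region_weights must sum to 1", call. = FALSE)
  }
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              biotype_props = biotype_props,
              length_range = length_range,
              site_rate = site_rate,
              region_weights = region_weights,
              depth = depth,
              conditions = conditions,
              replicates = as.integer(replicates),
              methyl_fraction_range = methyl_fraction_range,
              truncation_prob = truncation_prob,
              mismatch_prob = mismatch_prob,
              ip_enrichment = ip_enrichment,
              conversion_prob = conversion_prob,
              read_span = as.integer(read_span),
              ip_window_halfwidth = as.integer(ip_window_halfwidth),
              error_rate = error_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("MeRIP-seq simulation config:",
      x$n_transcripts, "transcripts,",
      length(x$conditions), "condition(s) x", x$replicates, "replicate(s),",
      "depth", x$depth, "\n")
  cat("  signatures: t =", x$truncation_prob, " m =", x$mismatch_prob,
      " e =", x$ip_enrichment, " conversion c =", x$conversion_prob, "\n")
  invisible(x)
}

# Largest-remainder apportionment of n among proportions p (deterministic).
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic transcriptome
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with one row per transcript: `transcript_id`,
#'   `gene_id`, `biotype`, `chrom`, `strand`, `length`, `utr5_end`,
#'   `cds_end` (half-open bounds in transcript coordinates; `NA` for
#'   non-coding biotypes), `is_circular`, `sequence`.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "transcriptome"))
  props <- config$biotype_props[config$biotype_props > 0]
  counts <- apportion(config$n_transcripts, props)
  biotype <- rep(names(props), counts)
  n <- length(biotype)
  len <- integer(n)
  for (bt in names(props)) {
    idx <- which(biotype == bt)
    rng <- config$length_range[[bt]]
    len[idx] <- as.integer(round(runif(length(idx), rng[1], rng[2])))
  }
  utr5_end <- rep(NA_integer_, n)
  cds_end <- rep(NA_integer_, n)
  is_mrna <- biotype == "mRNA"
  if (any(is_mrna)) {
    u5 <- runif(sum(is_mrna), 0.15, 0.30)
    u3 <- runif(sum(is_mrna), 0.15, 0.30)
    utr5_end[is_mrna] <- pmax(1L, as.integer(round(len[is_mrna] * u5)))
    cds_end[is_mrna] <- pmin(len[is_mrna] - 1L,
                             as.integer(round(len[is_mrna] * (1 - u3))))
    cds_end[is_mrna] <- pmax(cds_end[is_mrna], utr5_end[is_mrna] + 1L)
  }
  seqs <- vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  data.frame(
    transcript_id = sprintf("TX%04d", seq_len(n)),
    gene_id = sprintf("G%04d", seq_len(n)),
    biotype = biotype,
    chrom = sample(paste0("chr", c(1:19, "X")), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    length = len,
    utr5_end = utr5_end,
    cds_end = cds_end,
    is_circular = biotype == "circRNA",
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

#' Plant ground-truth m1A sites on a transcriptome
#'
#' Site counts per transcript are the first Poisson draws of the dedicated
#' `"sites"` RNG stream (rate `site_rate`), so an external audit with the
#' same child seed reproduces them.  Each site sits on an `A` of the sense
#' strand; mRNA sites follow the configured region placement bias.
#'
#' @param transcripts output of [generate_transcriptome()].
#' @param config the same [sim_config()].
#' @return a `data.frame` of sites: `transcript_id`, `position` (0-based),
#'   `methyl_fraction`, `truncation_prob`, `mismatch_prob`,
#'   `ip_enrichment`, plus one `mult_<condition>` multiplier column per
#'   condition (default 1: constitutive sites).
#' @export
plant_sites <- function(transcripts, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "sites"))
  n_sites <- rpois(nrow(transcripts), config$site_rate)
  rows <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    k <- n_sites[i]
    if (k == 0) next
    tx <- transcripts[i, ]
    bases <- strsplit(tx$sequence, "", fixed = TRUE)[[1]]
    a_pos <- which(bases == "A") - 1L  # 0-based
    if (length(a_pos) == 0) {
      warning(sprintf("transcript %s has no A nucleotides; skipping %d site(s)",
                      tx$transcript_id, k), call. = FALSE)
      next
    }
    pos <- integer(k)
    for (j in seq_len(k)) {
      if (tx$biotype == "mRNA") {
        region <- sample(c("utr5", "cds", "utr3"), 1,
                         prob = config$region_weights)
        in_region <- switch(region,
          utr5 = a_pos[a_pos < tx$utr5_end],
          cds  = a_pos[a_pos >= tx$utr5_end & a_pos < tx$cds_end],
          utr3 = a_pos[a_pos >= tx$cds_end])
        pool <- if (length(in_region)) in_region else a_pos
      } else {
        pool <- a_pos
      }
      pos[j] <- pool[sample.int(length(pool), 1)]
    }
    pos <- unique(pos)
    f <- runif(length(pos), config$methyl_fraction_range[1],
               config$methyl_fraction_range[2])
    rows[[i]] <- data.frame(
      transcript_id = tx$transcript_id,
      position = pos,
      methyl_fraction = f,
      truncation_prob = config$truncation_prob,
      mismatch_prob = config$mismatch_prob,
      ip_enrichment = config$ip_enrichment,
      stringsAsFactors = FALSE
    )
  }
  sites <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(sites)) {
    sites <- data.frame(transcript_id = character(), position = integer(),
                        methyl_fraction = numeric(), truncation_prob = numeric(),
                        mismatch_prob = numeric(), ip_enrichment = numeric(),
                        stringsAsFactors = FALSE)
  }
  for (cond in config$conditions) {
    sites[[paste0("mult_", cond)]] <- rep(1, nrow(sites))
  }
  rownames(sites) <- NULL
  sites
}

#' Simulate MeRIP-seq pileup tracks
#'
#' Generative model, per library and transcript position:
#' input coverage ~ Poisson(depth x expression factor); IP coverage gains
#' the site's enrichment factor inside a window around each site; a
#' fraction f·t of methylated molecules truncates at the site, depressing
#' coverage over the upstream read span and adding read starts at the site;
#' of methylated non-truncated molecules covering the site, a fraction m is
#' read as A->T.  In treated libraries a fraction `conversion_prob` of
#' methylated molecules behaves as unmethylated (losing truncation and
#' mismatch while transcription proceeds normally).  Truncation and
#' mismatch apply to input libraries too (the RNA is modified regardless of
#' enrichment); only the IP window enrichment is IP-specific.
#'
#' @param transcripts output of [generate_transcriptome()].
#' @param sites output of [plant_sites()] (may be empty).
#' @param config the same [sim_config()].
#' @param treatments which treatment libraries to emit; default both.
#' @return a pileup `data.frame`: `transcript_id`, `pos` (0-based),
#'   `coverage`, `at_mismatch`, `read_start`, `library`, `treatment`,
#'   `condition`, `replicate`.
#' @export
simulate_merip_pileups <- function(transcripts, sites, config,
                                   treatments = c("untreated", "treated")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth <= 0) stop("configuration error: depth must be > 0", call. = FALSE)
  bad <- !(sites$transcript_id %in% transcripts$transcript_id)
  if (any(bad)) stop("sites refer to unknown transcripts", call. = FALSE)

  set.seed(child_seed(config$seed, "expression"))
  expr <- rlnorm(nrow(transcripts), meanlog = 0, sdlog = 0.5)
  names(expr) <- transcripts$transcript_id

  a_mask <- lapply(strsplit(transcripts$sequence, "", fixed = TRUE),
                   function(b) b == "A")
  names(a_mask) <- transcripts$transcript_id
  site_split <- split(sites, sites$transcript_id)

  span <- config$read_span
  hw <- config$ip_window_halfwidth
  out <- list()
  for (cond in config$conditions) {
    for (rep_i in seq_len(config$replicates)) {
      for (trt in treatments) {
        for (lib in c("input", "IP")) {
          set.seed(child_seed(config$seed,
                              paste("pileup", cond, rep_i, trt, lib, sep = "|")))
          cov_l <- vector("list", nrow(transcripts))
          mis_l <- vector("list", nrow(transcripts))
          rs_l <- vector("list", nrow(transcripts))
          for (i in seq_len(nrow(transcripts))) {
            tx <- transcripts$transcript_id[i]
            len <- transcripts$length[i]
            lam_base <- config$depth * expr[[tx]]
            env <- rep(1, len)
            dep <- rep(1, len)
            mis_rate <- ifelse(a_mask[[tx]], config$error_rate, 0)
            extra_starts <- rep(0, len)
            ss <- site_split[[tx]]
            if (!is.null(ss) && nrow(ss)) {
              mult_col <- paste0("mult_", cond)
              for (s in seq_len(nrow(ss))) {
                p0 <- ss$position[s]
                f_meth <- min(1, ss$methyl_fraction[s] *
                                (if (mult_col %in% names(ss)) ss[[mult_col]][s] else 1))
                # conversion happens after IP, before cDNA synthesis: treated
                # libraries keep antibody enrichment but lose RT signatures
                f_eff <- if (trt == "treated") {
                  f_meth * (1 - config$conversion_prob)
                } else f_meth
                tprob <- ss$truncation_prob[s]
                mprob <- ss$mismatch_prob[s]
                if (lib == "IP") {
                  w0 <- max(0L, p0 - hw); w1 <- min(len - 1L, p0 + hw)
                  e_eff <- 1 + (ss$ip_enrichment[s] - 1) * f_meth
                  idx <- (w0:w1) + 1L
                  env[idx] <- pmax(env[idx], e_eff)
                }
                # truncation shadow: molecules that stop at the site no
                # longer cover positions 5' of it; the fraction of coverage
                # at p that would have spanned the site decays linearly with
                # distance over the read span
                sh0 <- max(0L, p0 - span + 1L)
                idx <- (sh0:p0) + 1L
                frac <- 1 - (p0 - (sh0:p0)) / span
                dep[idx] <- dep[idx] * (1 - f_eff * tprob * frac)
                # mismatch rate among surviving reads at the site
                denom <- 1 - f_eff * tprob
                mis_rate[p0 + 1L] <- min(1, config$error_rate +
                                           f_eff * (1 - tprob) * mprob / denom)
                extra_starts[p0 + 1L] <- extra_starts[p0 + 1L] +
                  lam_base * (if (lib == "IP") max(env[p0 + 1L], 1) else 1) *
                  f_eff * tprob
              }
            }
            lam <- lam_base * env * dep
            cv <- rpois(len, lam)
            mi <- integer(len)
            nz <- which(mis_rate > 0 & cv > 0)
            if (length(nz)) mi[nz] <- rbinom(length(nz), cv[nz], mis_rate[nz])
            rs <- rpois(len, lam / span + extra_starts)
            cov_l[[i]] <- cv; mis_l[[i]] <- mi; rs_l[[i]] <- rs
          }
          out[[length(out) + 1L]] <- data.frame(
            transcript_id = rep(transcripts$transcript_id, transcripts$length),
            pos = unlist(lapply(transcripts$length, function(l) 0:(l - 1L))),
            coverage = unlist(cov_l),
            at_mismatch = unlist(mis_l),
            read_start = unlist(rs_l),
            library = lib,
            treatment = trt,
            condition = cond,
            replicate = rep_i,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate negative-binomial count matrices with known differential labels
#'
#' @param n_features number of features (genes or miRNAs).
#' @param n_per_group replicates per group (two groups, A and B).
#' @param base_mean mean count at expression factor 1.
#' @param dispersion NB dispersion (var = mu + dispersion * mu^2); must be
#'   >= 0.
#' @param fold_changes length-`n_features` vector of true B/A fold changes
#'   (1 = null).
#' @param seed RNG seed.
#' @return list with `counts` (features x samples), `group` factor, and
#'   `true_de` logical vector (`fold_changes != 1`).
#' @export
simulate_counts <- function(n_features, n_per_group = 3, base_mean = 100,
                            dispersion = 0.1, fold_changes = rep(1, n_features),
                            seed = 1) {
  if (dispersion < 0) {
    stop("configuration error: dispersion must be >= 0", call. = FALSE)
  }
  stopifnot(length(fold_changes) == n_features)
  set.seed(child_seed(seed, "counts"))
  mu_base <- base_mean * rlnorm(n_features, 0, 0.5)
  draw <- function(mu) {
    if (dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  cols <- vector("list", 2 * n_per_group)
  for (j in seq_len(n_per_group)) cols[[j]] <- draw(mu_base)
  for (j in seq_len(n_per_group)) {
    cols[[n_per_group + j]] <- draw(mu_base * fold_changes)
  }
  counts <- do.call(cbind, cols)
  colnames(counts) <- c(paste0("A", seq_len(n_per_group)),
                        paste0("B", seq_len(n_per_group)))
  rownames(counts) <- sprintf("F%05d", seq_len(n_features))
  list(counts = counts,
       group = factor(rep(c("A", "B"), each = n_per_group)),
       true_de = fold_changes != 1)
}

#' Simulate interaction tables with planted structure
#'
#' Emits the three input tables the network and TF stages consume:
#' miRNA-target predictions from three "sources" (so the three-database
#' intersection is exercised), a lncRNA-RBP table with CLIP evidence
#' counts, and signed TF regulons with planted activity signs.
#'
#' @param n_mirna,n_mrna,n_lncrna,n_rbp,n_tf pool sizes.
#' @param hub_lncrna_degree degree of the planted hub lncRNA.
#' @param targets_per_tf targets per regulon.
#' @param seed RNG seed.
#' @return list with `mirna_targets` (list of three source tables),
#'   `lncrna_rbp`, `regulons`, and ground-truth attributes `hub_lncrna`
#'   and `tf_truth` (planted activity sign per TF).
#' @export
simulate_interaction_tables <- function(n_mirna = 20, n_mrna = 100,
                                        n_lncrna = 15, n_rbp = 12, n_tf = 6,
                                        hub_lncrna_degree = 10,
                                        targets_per_tf = 10, seed = 1) {
  set.seed(child_seed(seed, "interactions"))
  mirnas <- sprintf("miR-%03d", seq_len(n_mirna))
  mrnas <- sprintf("G%04d", seq_len(n_mrna))
  lncs <- sprintf("LNC%03d", seq_len(n_lncrna))
  rbps <- sprintf("RBP%02d", seq_len(n_rbp))
  tfs <- sprintf("TF%02d", seq_len(n_tf))

  # core miRNA-mRNA pairs present in all three sources, plus per-source noise
  core <- data.frame(
    mirna = sample(mirnas, 40, replace = TRUE),
    target = sample(mrnas, 40, replace = TRUE),
    stringsAsFactors = FALSE
  )
  core <- unique(core)
  mk_source <- function(name) {
    noise <- unique(data.frame(
      mirna = sample(mirnas, 15, replace = TRUE),
      target = sample(mrnas, 15, replace = TRUE),
      stringsAsFactors = FALSE))
    tab <- unique(rbind(core, noise))
    tab$source <- name
    tab
  }
  mirna_targets <- list(targetscan = mk_source("targetscan"),
                        mirdb = mk_source("mirdb"),
                        mirtarbase = mk_source("mirtarbase"))

  hub <- lncs[1]
  lnc_rbp <- data.frame(
    lncrna = c(rep(hub, hub_lncrna_degree),
               sample(lncs[-1], 20, replace = TRUE)),
    rbp = c(sample(rbps, hub_lncrna_degree, replace = FALSE),
            sample(rbps, 20, replace = TRUE)),
    evidence = c(rep(3L, hub_lncrna_degree), sample(1:4, 20, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  lnc_rbp <- lnc_rbp[!duplicated(lnc_rbp[c("lncrna", "rbp")]), ]

  tf_sign <- sample(c(-1, 1), n_tf, replace = TRUE)
  reg <- do.call(rbind, lapply(seq_len(n_tf), function(i) {
    data.frame(tf = tfs[i],
               target = sample(mrnas, targets_per_tf),
               mor = sample(c(-1, 1), targets_per_tf, replace = TRUE,
                            prob = c(0.3, 0.7)),
               weight = 1,
               stringsAsFactors = FALSE)
  }))
  structure(list(mirna_targets = mirna_targets,
                 lncrna_rbp = lnc_rbp,
                 regulons = reg),
            hub_lncrna = hub,
            tf_truth = setNames(tf_sign, tfs))
}
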