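# Differential methylation / expression, distribution comparisons, ANOVA
# and over-representation analysis.  Published thresholds are inclusive:
# methylation |FC| >= 2 with FDR <= 1e-4; expression |FC| >= 2 with
# adjusted p <= 0.05.

#' Apply inclusive fold-change / FDR thresholds to a differential table
#'
#' @param records `data.frame` with `log2fc` and `fdr` columns.
#' @param fc_cut minimum fold change (on the linear scale, applied to
#'   `2^|log2fc|`), inclusive.
#' @param fdr_cut maximum FDR, inclusive.
#' @return `records` with a logical `significant` column and `direction`
#'   (`"up"`/`"down"` by the sign of `log2fc`).
#' @export
significant_records <- function(records, fc_cut = 2, fdr_cut = 1e-4) {
  stopifnot(all(c("log2fc", "fdr") %in% names(records)))
  records$direction <- ifelse(records$log2fc >= 0, "up", "down")
  records$significant <- 2^abs(records$log2fc) >= fc_cut &
    records$fdr <= fdr_cut
  records
}

#' Differential methylation between two conditions
#'
#' Per site, the size-factor-normalized pooled counts (IP and input in
#' each condition, rounded to integers) form a 2x2 table tested by
#' Fisher's exact test; the fold change is the ratio of IP/input
#' enrichments.  BH adjustment across sites; significance uses the
#' inclusive thresholds |FC| >= `fc_cut`, FDR <= `fdr_cut`.
#'
#' @param site_counts `data.frame` with `feature_id`, `ip_a`, `input_a`,
#'   `ip_b`, `input_b` (raw pooled counts over the site interval) and
#'   optionally attribute-free; library sizes are supplied separately.
#' @param libsizes named numeric vector with `ip_a`, `input_a`, `ip_b`,
#'   `input_b` total library counts used for size factors.
#' @param fc_cut,fdr_cut inclusive thresholds (published values 2 and
#'   1e-4).
#' @return `data.frame` of class `diff_records`: `feature_id`, `log2fc`,
#'   `p`, `fdr`, `direction`, `significant`, `kind = "methylation"`.
#' @export
diff_methylation <- function(site_counts, libsizes, fc_cut = 2,
                             fdr_cut = 1e-4) {
  cols <- c("ip_a", "input_a", "ip_b", "input_b")
  stopifnot(all(c("feature_id", cols) %in% names(site_counts)),
            all(cols %in% names(libsizes)))
  geo <- exp(mean(log(libsizes[cols])))
  norm <- site_counts
  for (cc in cols) norm[[cc]] <- round(site_counts[[cc]] * geo / libsizes[[cc]])
  all_zero <- rowSums(norm[cols]) == 0
  if (any(all_zero)) {
    m1a_log("info", sum(all_zero), " site(s) with all-zero counts excluded")
    norm <- norm[!all_zero, , drop = FALSE]
  }
  if (!nrow(norm)) {
    res <- data.frame(feature_id = character(), log2fc = numeric(),
                      p = numeric(), fdr = numeric(), direction = character(),
                      significant = logical(), kind = character(),
                      stringsAsFactors = FALSE)
    class(res) <- c("diff_records", "data.frame")
    return(res)
  }
  p <- vapply(seq_len(nrow(norm)), function(i) {
    tab <- matrix(as.numeric(norm[i, cols]), nrow = 2, byrow = TRUE)
    fisher.test(round(tab))$p.value
  }, numeric(1))
  enr_a <- (norm$ip_a + 0.5) / (norm$input_a + 0.5)
  enr_b <- (norm$ip_b + 0.5) / (norm$input_b + 0.5)
  res <- data.frame(feature_id = norm$feature_id,
                    log2fc = log2(enr_b / enr_a),
                    p = p, fdr = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  res <- significant_records(res, fc_cut = fc_cut, fdr_cut = fdr_cut)
  res$kind <- "methylation"
  class(res) <- c("diff_records", "data.frame")
  res
}

#' Differential expression (mRNA or miRNA) with an NB Wald test
#'
#' Counts are library-size normalized (for miRNA this is the tags-per-
#' million convention, reported in the `tpm_*` columns).  The test is a
#' two-group negative-binomial Wald test: a common method-of-moments
#' dispersion pooled across features, delta-method standard error of the
#' log mean ratio, and a t reference with `n1 + n2 - 2 + prior_df` degrees
#' of freedom (the prior df credits the pooled dispersion estimate).
#' With fewer than 2 replicates in a condition the test falls back to a
#' Poisson exact test with a loud warning.
#'
#' @param counts feature x sample count matrix.
#' @param group two-level factor over columns.
#' @param kind `"mRNA"` or `"miRNA"` (affects reported normalization
#'   units only).
#' @param fc_cut,fdr_cut inclusive thresholds (published values 2 and
#'   0.05).
#' @param prior_df prior degrees of freedom added to the Wald t reference.
#' @return `data.frame` of class `diff_records` with `feature_id`,
#'   `log2fc`, `p`, `fdr`, `direction`, `significant`, `kind`, plus
#'   `mean_a`/`mean_b` (normalized means; TPM for miRNA).
#' @export
diff_expression <- function(counts, group, kind = c("mRNA", "miRNA"),
                            fc_cut = 2, fdr_cut = 0.05, prior_df = 6) {
  kind <- match.arg(kind)
  group <- factor(group)
  stopifnot(nlevels(group) == 2L, ncol(counts) == length(group))
  libs <- colSums(counts)
  if (any(libs == 0)) {
    stop(sprintf("library %s has zero total counts; cannot normalize",
                 colnames(counts)[which(libs == 0)[1]]), call. = FALSE)
  }
  scale_to <- if (kind == "miRNA") 1e6 else mean(libs)
  norm <- sweep(counts, 2, libs, "/") * scale_to
  g1 <- group == levels(group)[1]
  g2 <- group == levels(group)[2]
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  if (n1 < 2 || n2 < 2) {
    warning("fewer than 2 replicates in a condition: falling back to a ",
            "Poisson exact test on pooled counts", call. = FALSE)
    ca <- rowSums(counts[, g1, drop = FALSE])
    cb <- rowSums(counts[, g2, drop = FALSE])
    la <- sum(libs[g1]); lb <- sum(libs[g2])
    p <- vapply(seq_along(ca), function(i) {
      tot <- ca[i] + cb[i]
      if (tot == 0) return(1)
      stats::binom.test(cb[i], tot, p = lb / (la + lb))$p.value
    }, numeric(1))
  } else {
    v1 <- apply(norm[, g1, drop = FALSE], 1, var)
    v2 <- apply(norm[, g2, drop = FALSE], 1, var)
    disp <- ((v1 - m1) / pmax(m1, 1e-8)^2 + (v2 - m2) / pmax(m2, 1e-8)^2) / 2
    alpha <- max(1e-8, median(disp[is.finite(disp)], na.rm = TRUE))
    V1 <- (m1 + alpha * m1^2) / (n1 * pmax(m1, 0.5)^2)
    V2 <- (m2 + alpha * m2^2) / (n2 * pmax(m2, 0.5)^2)
    W <- (log(m2 + 0.5) - log(m1 + 0.5)) / sqrt(V1 + V2)
    p <- 2 * pt(-abs(W), df = n1 + n2 - 2 + prior_df)
  }
  res <- data.frame(feature_id = rownames(counts),
                    log2fc = log2((m2 + 0.5) / (m1 + 0.5)),
                    p = p, fdr = p.adjust(p, "BH"),
                    mean_a = m1, mean_b = m2,
                    stringsAsFactors = FALSE)
  res <- significant_records(res, fc_cut = fc_cut, fdr_cut = fdr_cut)
  res$kind <- if (kind == "miRNA") "expression_miRNA" else "expression_mRNA"
  class(res) <- c("diff_records", "data.frame")
  res
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|`; the p value is exact (by enumeration of
#' the D distribution) when `n * m <= 1e4`, otherwise asymptotic.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("ks_two_sample requires n >= 2 per sample", call. = FALSE)
  }
  kt <- suppressWarnings(ks.test(x, y, exact = length(x) * length(y) <= 1e4))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' One-way analysis of variance
#'
#' Classic equal-variance F test across groups.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(groups) {
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  values <- unlist(groups)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  within_var <- vapply(groups, var, numeric(1))
  if (all(within_var == 0)) {
    stop("zero within-group variance: F statistic undefined", call. = FALSE)
  }
  ot <- oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(ot$statistic), df1 = unname(ot$parameter[1]),
       df2 = unname(ot$parameter[2]), p = unname(ot$p.value))
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p per term, BH q across tested terms, with
#' gene-set size bounds applied before testing.  Published cutoffs: GO
#' p/q 0.005 with set sizes in [2, 500]; KEGG p/q 0.05.
#'
#' @param gene_set character vector of selected genes (subset of
#'   `universe`).
#' @param annotation named list: term -> character vector of genes.
#' @param universe character vector of all genes.
#' @param p_cut,q_cut inclusive cutoffs on p and BH q.
#' @param min_gs,max_gs inclusive term size bounds (genes in universe).
#' @return `data.frame` with `term`, `term_size`, `overlap`, `p`, `q`,
#'   filtered to terms passing both cutoffs, sorted by p.
#' @export
ora <- function(gene_set, annotation, universe, p_cut = 0.005, q_cut = 0.005,
                min_gs = 2, max_gs = 500) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  stopifnot(all(gene_set %in% universe))
  gene_set <- unique(gene_set)
  sizes <- vapply(annotation, function(g) length(intersect(g, universe)),
                  integer(1))
  keep <- sizes >= min_gs & sizes <= max_gs
  terms <- names(annotation)[keep]
  if (!length(terms)) {
    return(data.frame(term = character(), term_size = integer(),
                      overlap = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  N <- length(unique(universe))
  k <- length(gene_set)
  res <- data.frame(term = terms,
                    term_size = sizes[keep],
                    overlap = vapply(annotation[keep], function(g) {
                      length(intersect(intersect(g, universe), gene_set))
                    }, integer(1)),
                    stringsAsFactors = FALSE)
  res$p <- phyper(res$overlap - 1, res$term_size, N - res$term_size, k,
                  lower.tail = FALSE)
  res$q <- p.adjust(res$p, "BH")
  res <- res[res$p <= p_cut & res$q <= q_cut, , drop = FALSE]
  res[order(res$p), , drop = FALSE]
}

#' Extract pooled site counts for differential methylation
#'
#' Sums IP and input coverage over each site interval (site +/- `halfwidth`
#' when only a position is given) for two conditions of a pileup set.
#'
#' @param pileups pileup `data.frame` (untreated libraries are used).
#' @param intervals `data.frame` with `transcript_id` and either
#'   `start`/`end` or `position`.
#' @param cond_a,cond_b condition names.
#' @param halfwidth half-width (nt) around a bare position.
#' @return list with `site_counts` and `libsizes`, ready for
#'   [diff_methylation()].
#' @export
site_counts <- function(pileups, intervals, cond_a, cond_b, halfwidth = 50) {
  if (!all(c("start", "end") %in% names(intervals))) {
    intervals$start <- pmax(0L, intervals$position - halfwidth)
    intervals$end <- intervals$position + halfwidth + 1L
  }
  pools <- list(
    ip_a = pool_pileups(pileups, "IP", "untreated", cond_a),
    input_a = pool_pileups(pileups, "input", "untreated", cond_a),
    ip_b = pool_pileups(pileups, "IP", "untreated", cond_b),
    input_b = pool_pileups(pileups, "input", "untreated", cond_b))
  libsizes <- vapply(pools, function(p) sum(p$coverage), numeric(1))
  splits <- lapply(pools, function(p) split(p, p$transcript_id))
  out <- data.frame(
    feature_id = paste0(intervals$transcript_id, ":", intervals$start, "-",
                        intervals$end),
    stringsAsFactors = FALSE)
  for (nm in names(pools)) {
    out[[nm]] <- vapply(seq_len(nrow(intervals)), function(i) {
      trk <- splits[[nm]][[intervals$transcript_id[i]]]
      if (is.null(trk)) return(0)
      sum(trk$coverage[trk$pos >= intervals$start[i] &
                         trk$pos < intervals$end[i]])
    }, numeric(1))
  }
  list(site_counts = out, libsizes = libsizes)
}
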