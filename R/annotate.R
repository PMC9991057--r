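# Feature assignment, metagene profiles, genomic-source classification,
# chromosome tallies, chi-squared distribution tests and GA-richness.

#' Assign a transcript position to a feature region
#'
#' Half-open boundary convention: a boundary position belongs to the
#' downstream region.  Non-coding biotypes map to `"noncoding"`.
#'
#' @param position 0-based position on the transcript.
#' @param model one-row transcript model.
#' @return one of `"5UTR"`, `"CDS"`, `"3UTR"`, `"noncoding"`.
#' @export
assign_region <- function(position, model) {
  stopifnot(nrow(model) == 1L)
  if (position < 0 || position >= model$length) {
    stop("position outside transcript", call. = FALSE)
  }
  if (model$biotype != "mRNA") return("noncoding")
  if (position < model$utr5_end) "5UTR"
  else if (position < model$cds_end) "CDS"
  else "3UTR"
}

#' Metagene profile of mRNA sites
#'
#' Each site is mapped to its fractional position within its region
#' (5'UTR, CDS or 3'UTR), then to one of `bins["utr5"] + bins["cds"] +
#' bins["utr3"]` global bins; the returned densities sum to 1.
#'
#' @param sites `data.frame` with `transcript_id`, `position`.
#' @param models transcript models.
#' @param bins named integer vector `c(utr5=, cds=, utr3=)`.
#' @return object of class `metagene_profile`: `data.frame` with `bin`,
#'   `region`, `density`.
#' @export
metagene <- function(sites, models, bins = c(utr5 = 20L, cds = 50L, utr3 = 30L)) {
  midx <- match(sites$transcript_id, models$transcript_id)
  mrna <- which(models$biotype[midx] == "mRNA")
  if (!length(mrna)) stop("no mRNA sites for metagene profile", call. = FALSE)
  counts <- numeric(sum(bins))
  for (i in mrna) {
    m <- models[midx[i], ]
    pos <- sites$position[i]
    reg <- assign_region(pos, m)
    bounds <- switch(reg,
                     "5UTR" = c(0L, m$utr5_end, 0L, bins[["utr5"]]),
                     "CDS" = c(m$utr5_end, m$cds_end, bins[["utr5"]], bins[["cds"]]),
                     "3UTR" = c(m$cds_end, m$length,
                                bins[["utr5"]] + bins[["cds"]], bins[["utr3"]]))
    frac <- (pos - bounds[1]) / (bounds[2] - bounds[1])
    b <- bounds[3] + min(bounds[4] - 1L, floor(frac * bounds[4])) + 1L
    counts[b] <- counts[b] + 1
  }
  region <- rep(c("5UTR", "CDS", "3UTR"), bins)
  prof <- data.frame(bin = seq_along(counts), region = region,
                     density = counts / sum(counts))
  class(prof) <- c("metagene_profile", "data.frame")
  prof
}

# locus overlap helpers (genomic, 0-based half-open)
overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
tss_of <- function(strand, start, end) ifelse(strand == "+", start, end)

#' Classify the genomic source of a lncRNA locus
#'
#' Precedence: exon sense-overlapping > intron sense-overlapping >
#' antisense > bidirectional (opposite-strand TSS within 1 kb) >
#' intergenic.
#'
#' @param locus one-row `data.frame` with `chrom`, `strand`, `start`,
#'   `end` (genomic, 0-based half-open).
#' @param genes coding gene loci (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`).
#' @param exons exon table (`gene_id`, `start`, `end`).
#' @param tss_window bidirectional promoter window (bp).
#' @return one of `"exon_sense_overlapping"`, `"intron_sense_overlapping"`,
#'   `"antisense"`, `"bidirectional"`, `"intergenic"`.
#' @export
classify_lncrna_source <- function(locus, genes, exons, tss_window = 1000) {
  if (is.na(locus$strand) || !locus$strand %in% c("+", "-")) {
    stop("missing strand on lncRNA locus", call. = FALSE)
  }
  g <- genes[genes$chrom == locus$chrom, , drop = FALSE]
  if (nrow(g)) {
    hit <- overlaps(locus$start, locus$end, g$start, g$end)
    sense <- hit & g$strand == locus$strand
    anti <- hit & g$strand != locus$strand
    if (any(sense)) {
      ex <- exons[exons$gene_id %in% g$gene_id[sense], , drop = FALSE]
      if (nrow(ex) && any(overlaps(locus$start, locus$end, ex$start, ex$end))) {
        return("exon_sense_overlapping")
      }
      return("intron_sense_overlapping")
    }
    if (any(anti)) return("antisense")
    opp <- g[g$strand != locus$strand, , drop = FALSE]
    if (nrow(opp)) {
      d <- abs(tss_of(locus$strand, locus$start, locus$end) -
                 tss_of(opp$strand, opp$start, opp$end))
      if (any(d <= tss_window)) return("bidirectional")
    }
  }
  "intergenic"
}

#' Classify the genomic source of a circRNA back-splice interval
#'
#' Precedence: exonic (fully inside the exon union of a same-strand gene)
#' > intronic (inside a same-strand gene, no exon overlap) >
#' sense-overlapping (same-strand overlap straddling exon boundaries) >
#' antisense > intergenic.
#'
#' @inheritParams classify_lncrna_source
#' @return one of `"exonic"`, `"intronic"`, `"sense_overlapping"`,
#'   `"antisense"`, `"intergenic"`.
#' @export
classify_circrna_source <- function(locus, genes, exons) {
  if (is.na(locus$strand) || !locus$strand %in% c("+", "-")) {
    stop("missing strand on circRNA locus", call. = FALSE)
  }
  g <- genes[genes$chrom == locus$chrom, , drop = FALSE]
  if (nrow(g)) {
    hit <- overlaps(locus$start, locus$end, g$start, g$end)
    sense <- hit & g$strand == locus$strand
    if (any(sense)) {
      ex <- exons[exons$gene_id %in% g$gene_id[sense], , drop = FALSE]
      if (nrow(ex)) {
        ir <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
        qry <- IRanges::IRanges(locus$start + 1L, locus$end)
        inter <- sum(IRanges::width(IRanges::intersect(qry, ir)))
        if (inter == IRanges::width(qry)) return("exonic")
        if (inter > 0) return("sense_overlapping")
      }
      return("intronic")
    }
    if (any(hit)) return("antisense")
  }
  "intergenic"
}

#' Pearson chi-squared homogeneity test of two count vectors
#'
#' @param counts_a,counts_b same-category count vectors.
#' @return list with `chi2`, `df`, `p`.
#' @export
chisq_distribution_test <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b))
  tab <- rbind(counts_a, counts_b)
  if (identical(as.numeric(counts_a), as.numeric(counts_b))) {
    return(list(chi2 = 0, df = length(counts_a) - 1L, p = 1))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("zero expected cell count; pool sparse categories first",
         call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

# Altschul-Erikson dinucleotide-preserving shuffle: random Eulerian walk
# over the dinucleotide multigraph (last-edge spanning-tree condition).
dinucleotide_shuffle <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (n <= 3) return(seq)
  syms <- unique(b)
  edges <- lapply(setNames(syms, syms), function(s) b[which(b[-n] == s) + 1L])
  last <- b[n]
  repeat {
    # pick a random final edge per vertex (except the terminal vertex);
    # accept when those edges form a tree into the terminal vertex
    final <- vapply(syms, function(s) {
      if (s == last || !length(edges[[s]])) NA_character_
      else sample(edges[[s]], 1)
    }, character(1))
    reach <- function(s) {
      seen <- character(0)
      while (!is.na(s) && !(s %in% seen)) {
        if (s == last) return(TRUE)
        seen <- c(seen, s)
        s <- if (s %in% names(final)) final[[s]] else NA_character_
      }
      FALSE
    }
    ok <- all(vapply(syms[syms != last & vapply(syms, function(s)
      length(edges[[s]]) > 0, logical(1))], reach, logical(1)))
    if (ok) break
  }
  # shuffle the remaining edges, appending the chosen final edge last
  pool <- edges
  for (s in syms) {
    e <- pool[[s]]
    if (s != last && !is.na(final[[s]])) {
      e <- e[-match(final[[s]], e)]
      pool[[s]] <- c(sample(e), final[[s]])
    } else {
      pool[[s]] <- if (length(e) > 1) sample(e) else e
    }
  }
  out <- character(n)
  out[1] <- b[1]
  cur <- b[1]
  for (i in 2:n) {
    nxt <- pool[[cur]][1]
    pool[[cur]] <- pool[[cur]][-1]
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' GA-richness of peak sequences
#'
#' The per-sequence statistic is the maximum {G,A} (purine) fraction over
#' sliding windows of `window` nt (the whole sequence when shorter); a
#' sequence is flagged GA-rich when that fraction reaches
#' `purine_threshold`.  The cohort enrichment z compares the observed mean
#' statistic to its distribution under dinucleotide-preserving shuffles:
#' shuffling preserves base and dinucleotide composition exactly, so the z
#' score measures local clustering of purines rather than composition.
#'
#' @param seqs character vector of peak sequences (ACGT).
#' @param n_shuffles shuffle replicates for the null.
#' @param purine_threshold GA-rich flag threshold.
#' @param window sliding window width (nt).
#' @param seed RNG seed.
#' @return list with `ga_rich` (logical per sequence), `fraction`
#'   (per-sequence statistic), `z` (cohort enrichment), `null_mean`,
#'   `null_sd`.
#' @export
ga_richness <- function(seqs, n_shuffles = 100, purine_threshold = 0.70,
                        window = 50, seed = 1) {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop(sprintf("sequence %d contains non-ACGT symbols", which(bad)[1]),
         call. = FALSE)
  }
  stat <- function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    pur <- as.integer(b %in% c("G", "A"))
    w <- min(window, length(pur))
    cs <- cumsum(c(0L, pur))
    max((cs[(w + 1):(length(pur) + 1)] - cs[1:(length(pur) - w + 1)]) / w)
  }
  obs <- vapply(seqs, stat, numeric(1), USE.NAMES = FALSE)
  set.seed(child_seed(seed, "ga_shuffle"))
  null_means <- vapply(seq_len(n_shuffles), function(i) {
    mean(vapply(seqs, function(s) stat(dinucleotide_shuffle(s)), numeric(1)))
  }, numeric(1))
  nm <- mean(null_means)
  nsd <- sd(null_means)
  list(ga_rich = obs >= purine_threshold,
       fraction = obs,
       z = if (nsd > 0) (mean(obs) - nm) / nsd else NA_real_,
       null_mean = nm, null_sd = nsd)
}

#' Count modified RNAs per chromosome and condition
#'
#' @param rna_lists named list (per condition) of `data.frame`s with
#'   `transcript_id` (e.g. [rollup_rna()] outputs).
#' @param models transcript models (for `chrom`).
#' @return `data.frame` chrom x condition counts of distinct RNAs.
#' @export
per_chromosome_counts <- function(rna_lists, models) {
  conds <- names(rna_lists)
  chroms <- sort(unique(models$chrom))
  out <- data.frame(chrom = chroms, stringsAsFactors = FALSE)
  for (cond in conds) {
    ids <- unique(rna_lists[[cond]]$transcript_id)
    ch <- models$chrom[match(ids, models$transcript_id)]
    out[[cond]] <- as.integer(table(factor(ch, levels = chroms)))
  }
  if (!length(conds)) return(out[0, , drop = FALSE])
  out
}
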