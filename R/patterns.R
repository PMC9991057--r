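# Modification-pattern discovery: Lee-Seung NMF with consensus clustering
# and cophenetic rank selection, permutation-based TF activity, simplified
# pathway scores and regulator-pathway correlation.

#' Non-negative matrix factorization (Lee-Seung, Frobenius loss)
#'
#' Multiplicative updates from a seeded uniform random initialization;
#' the loss is non-increasing and iteration stops at `tol` relative
#' change of the reconstruction error or `max_iter`.
#'
#' @param X non-negative numeric matrix (features x samples).
#' @param k factorization rank, `0 < k < min(dim(X))`.
#' @param max_iter maximum iterations.
#' @param tol relative-change stopping tolerance.
#' @param seed RNG seed for the initialization.
#' @return list with `W` (features x k), `H` (k x samples), `loss`
#'   (trajectory of Frobenius errors), `iterations`.
#' @export
nmf_factorize <- function(X, k, max_iter = 500, tol = 1e-5, seed = 1) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative", call. = FALSE)
  if (k <= 0 || k >= min(dim(X))) {
    stop("k must satisfy 0 < k < min(dim(X))", call. = FALSE)
  }
  set.seed(child_seed(seed, "nmf_init"))
  n <- nrow(X); m <- ncol(X)
  W <- matrix(runif(n * k), n, k)
  H <- matrix(runif(k * m), k, m)
  eps <- .Machine$double.eps
  loss <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H) / (W %*% tcrossprod(H) + eps))
    err <- sqrt(sum((X - W %*% H)^2))
    loss <- c(loss, err)
    if (is.finite(prev) && prev > 0 && abs(prev - err) / prev < tol) break
    prev <- err
  }
  list(W = W, H = H, loss = loss, iterations = length(loss))
}

#' Consensus NMF clustering with cophenetic diagnostics
#'
#' For each rank in `k_range`, runs `n_restarts` seeded factorizations,
#' each on a random feature subsample of `subsample_frac` of the rows
#' (consensus-clustering resampling: a rank that only fits noise gives
#' unstable assignments across subsamples, which is what the cophenetic
#' coefficient is meant to detect).  Each restart assigns samples to the
#' argmax row of `H` (lowest index on ties), the consensus matrix `C` is
#' the mean connectivity over restarts, and the cophenetic coefficient
#' `rho(k)` is the Pearson correlation between `1 - C` distances and the
#' cophenetic distances of their average-linkage dendrogram.  `k = 1` is
#' reported with `rho = 1` by convention.
#'
#' @param X non-negative matrix (features x samples).
#' @param k_range integer vector of ranks to evaluate.
#' @param n_restarts factorization restarts per rank (>= 2).
#' @param seed master seed.
#' @param subsample_frac fraction of features refit per restart; 1
#'   disables resampling.
#' @param ... passed to [nmf_factorize()].
#' @return object of class `nmf_consensus`: list with `rho` (named by k),
#'   `consensus` (list of C matrices), `assignments` (consensus
#'   clustering at each k, from the dendrogram cut), `best_fit` (the
#'   lowest-loss factorization per k, on the full matrix), `k_range`.
#' @export
consensus_cophenetic <- function(X, k_range = 2:6, n_restarts = 30, seed = 1,
                                 subsample_frac = 0.8, ...) {
  if (n_restarts < 2) stop("n_restarts must be >= 2", call. = FALSE)
  stopifnot(subsample_frac > 0, subsample_frac <= 1)
  X <- as.matrix(X)
  m <- ncol(X)
  rho <- setNames(numeric(length(k_range)), k_range)
  consensus <- list(); assignments <- list(); best_fit <- list()
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    if (k == 1) {
      C <- matrix(1, m, m)
      rho[ki] <- 1
      consensus[[as.character(k)]] <- C
      assignments[[as.character(k)]] <- rep(1L, m)
      next
    }
    Csum <- matrix(0, m, m)
    best <- NULL
    n_sub <- max(2L, round(subsample_frac * nrow(X)))
    for (r in seq_len(n_restarts)) {
      rs <- child_seed(seed, paste0("k", k, "r", r))
      rows <- if (n_sub < nrow(X)) {
        set.seed(child_seed(rs, "rows"))
        sample.int(nrow(X), n_sub)
      } else seq_len(nrow(X))
      fit <- nmf_factorize(X[rows, , drop = FALSE], k, seed = rs, ...)
      cl <- apply(fit$H, 2, which.max)   # ties -> lowest index (which.max)
      conn <- outer(cl, cl, `==`) * 1
      Csum <- Csum + conn
    }
    for (r in 1:3) {                     # reference fit on the full matrix
      full <- nmf_factorize(X, k, seed = child_seed(seed,
                                                    paste0("full", k, r)), ...)
      if (is.null(best) || min(full$loss) < min(best$loss)) best <- full
    }
    C <- Csum / n_restarts
    d <- as.dist(1 - C)
    hc <- hclust(d, method = "average")
    coph <- cophenetic(hc)
    rho[ki] <- if (sd(d) == 0 || sd(coph) == 0) 1 else cor(d, coph)
    consensus[[as.character(k)]] <- C
    assignments[[as.character(k)]] <- stats::cutree(hc, k = k)
    best_fit[[as.character(k)]] <- best
  }
  structure(list(rho = rho, consensus = consensus,
                 assignments = assignments, best_fit = best_fit,
                 k_range = k_range),
            class = "nmf_consensus")
}

#' @export
print.nmf_consensus <- function(x, ...) {
  cat("consensus NMF over ranks", paste(x$k_range, collapse = ", "), "\n")
  print(round(x$rho, 4))
  cat("selected rank (largest cophenetic drop):", select_rank(x$rho), "\n")
  invisible(x)
}

#' Select the NMF rank from cophenetic coefficients
#'
#' `rule = "first_decrease"` (default) returns the k at which the
#' coefficient begins to decrease: the last k of the initial
#' non-decreasing stretch, i.e. the value before the first drop larger
#' than `eps`.  `rule = "largest_drop"` returns the k before the largest
#' consecutive decrease; it suits cliff-shaped profiles but overshoots
#' when instability grows steadily with k, which is why it is not the
#' default.  A profile that never decreases returns the smallest rank
#' with a warning.
#'
#' @param rho_by_k named numeric vector (names = ranks, ascending).
#' @param rule selection rule.
#' @param eps decreases at or below this size count as flat.
#' @return the selected rank (integer).
#' @export
select_rank <- function(rho_by_k, rule = c("first_decrease", "largest_drop"),
                        eps = 1e-6) {
  rule <- match.arg(rule)
  if (length(rho_by_k) < 3) {
    stop("need at least 3 evaluated ranks", call. = FALSE)
  }
  ks <- as.integer(names(rho_by_k))
  drops <- rho_by_k[-length(rho_by_k)] - rho_by_k[-1]
  if (all(drops <= eps)) {
    warning("cophenetic profile never decreases; returning smallest rank",
            call. = FALSE)
    return(ks[1])
  }
  if (rule == "largest_drop") {
    ks[which.max(drops)]        # ties -> smallest k (which.max is leftmost)
  } else {
    ks[which(drops > eps)[1]]
  }
}

#' Weighted-mean TF activity with a permutation null
#'
#' `score = sum(mor * weight * stat[targets]) / sum(|weight|)`; the null
#' recomputes the score on `times` random target sets of equal size drawn
#' from all scored genes, giving `norm_score = (score - null mean) / null
#' sd` and a two-sided empirical p with (b+1)/(times+1) smoothing.
#' Regulons with fewer than `minsize` usable targets are skipped.
#'
#' @param stat named numeric vector of per-gene statistics.
#' @param regulons `data.frame` with `tf`, `target`, `mor` (+/-1) and
#'   optional `weight`.
#' @param times permutation count.
#' @param minsize minimum usable targets per regulon.
#' @param seed RNG seed.
#' @return `data.frame` with `tf`, `size`, `score`, `norm_score`, `p`.
#' @export
tf_activity_wmean <- function(stat, regulons, times = 1000, minsize = 5,
                              seed = 1) {
  stopifnot(!is.null(names(stat)), all(is.finite(stat)))
  if (anyDuplicated(regulons[c("tf", "target")])) {
    stop("duplicate targets within a regulon", call. = FALSE)
  }
  if (!"weight" %in% names(regulons)) regulons$weight <- 1
  set.seed(child_seed(seed, "tf_null"))
  genes <- names(stat)
  out <- list()
  for (tf in unique(regulons$tf)) {
    reg <- regulons[regulons$tf == tf, , drop = FALSE]
    reg <- reg[reg$target %in% genes, , drop = FALSE]
    nt <- nrow(reg)
    if (nt < minsize) {
      m1a_log("debug", "regulon ", tf, " below minsize (", nt, "); skipped")
      next
    }
    wsum <- sum(abs(reg$weight))
    score <- sum(reg$mor * reg$weight * stat[reg$target]) / wsum
    null <- vapply(seq_len(times), function(b) {
      idx <- sample.int(length(genes), nt)
      sum(reg$mor * reg$weight * stat[idx]) / wsum
    }, numeric(1))
    nm <- mean(null); nsd <- sd(null)
    norm_score <- if (nsd > 0) (score - nm) / nsd else 0
    p <- (1 + sum(abs(null - nm) >= abs(score - nm))) / (times + 1)
    out[[length(out) + 1L]] <- data.frame(
      tf = tf, size = nt, score = score, norm_score = norm_score, p = p,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(tf = character(), size = integer(), score = numeric(),
                      norm_score = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean z-score pathway activity
#'
#' Each gene is z-scored across samples; a pathway's score per sample is
#' the mean z over its member genes present in the matrix.  Genes with
#' zero variance and sets with no scored members are dropped with a log
#' entry.
#'
#' @param expr genes x samples numeric matrix (rownames = genes).
#' @param gene_sets named list: set -> character vector of genes.
#' @return sets x samples score matrix.
#' @export
pathway_score <- function(expr, gene_sets) {
  sds <- apply(expr, 1, sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    m1a_log("info", sum(flat), " constant-expression gene(s) dropped")
  }
  z <- (expr[!flat, , drop = FALSE] -
          rowMeans(expr[!flat, , drop = FALSE])) / sds[!flat]
  out <- list()
  for (nm in names(gene_sets)) {
    members <- intersect(gene_sets[[nm]], rownames(z))
    if (!length(members)) {
      m1a_log("info", "gene set ", nm, " has no scored members; skipped")
      next
    }
    out[[nm]] <- colMeans(z[members, , drop = FALSE])
  }
  if (!length(out)) {
    return(matrix(numeric(0), 0, ncol(expr),
                  dimnames = list(NULL, colnames(expr))))
  }
  do.call(rbind, out)
}

#' Correlate regulator expression with pathway scores
#'
#' Pearson (default) or Spearman correlation per (regulator, pathway)
#' pair, with BH adjustment across pairs.
#'
#' @param reg_expr regulators x samples matrix.
#' @param scores pathways x samples matrix (same samples).
#' @param method `"pearson"` or `"spearman"`.
#' @return `data.frame` with `regulator`, `pathway`, `r`, `p`, `fdr`.
#' @export
regulator_pathway_correlation <- function(reg_expr, scores,
                                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(reg_expr) < 3) stop("need >= 3 samples", call. = FALSE)
  stopifnot(ncol(reg_expr) == ncol(scores))
  grid <- expand.grid(regulator = rownames(reg_expr),
                      pathway = rownames(scores),
                      stringsAsFactors = FALSE)
  rp <- vapply(seq_len(nrow(grid)), function(i) {
    ct <- suppressWarnings(cor.test(reg_expr[grid$regulator[i], ],
                                    scores[grid$pathway[i], ],
                                    method = method))
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2))
  grid$r <- rp[1, ]
  grid$p <- rp[2, ]
  grid$fdr <- p.adjust(grid$p, "BH")
  grid
}

#' Build the NMF feature matrix from methylation levels
#'
#' Shifts a sites x samples methylation-level matrix to non-negativity by
#' subtracting its minimum (min-shift), the conventional preparation for
#' NMF of signed log-ratio data.
#'
#' @param levels sites x samples numeric matrix.
#' @return non-negative matrix of the same shape.
#' @export
nmf_input_matrix <- function(levels) {
  levels <- as.matrix(levels)
  shift <- min(levels, na.rm = TRUE)
  out <- levels - shift
  out[is.na(out)] <- 0
  out
}
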