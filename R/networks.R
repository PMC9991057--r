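# ceRNA and lncRNA-RBP network assembly, miRNA seed scanning, and
# miRNA-mRNA pair dynamics against m1A peak regions.
#
# Database predictions (TargetScan/miRDB/miRTarBase-style miRNA targets,
# CLIP-supported RBP partners) enter as plain tables, which keeps the
# module fully testable offline.

new_network <- function(edges, nodes) {
  structure(list(edges = edges, nodes = nodes), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges)) print(head(x$edges, 4))
  invisible(x)
}

#' Node degree table of a network
#'
#' @param network an `interaction_network`.
#' @return `data.frame` with `node`, `type`, `degree`, sorted by
#'   decreasing degree.
#' @export
degree_table <- function(network) {
  e <- network$edges
  deg <- table(c(e$source, e$target))
  res <- data.frame(node = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  res$type <- network$nodes$type[match(res$node, network$nodes$node)]
  res[order(-res$degree, res$node), c("node", "type", "degree")]
}

#' Build a ceRNA (circRNA/lncRNA-miRNA-mRNA) network
#'
#' miRNA-mRNA edges must be predicted by all three sources (the
#' three-database intersection); lncRNA-miRNA and circRNA-miRNA edges come
#' from their single source tables.  An edge is kept only when both
#' endpoints belong to the differential sets of the chosen mode.
#'
#' @param diff_sets named list of character vectors: `miRNA`, `mRNA`,
#'   `lncRNA`, `circRNA` (differentially expressed or methylated ids for
#'   the chosen mode; missing/empty sets drop the corresponding edges).
#' @param mirna_target_tables list of exactly three `data.frame`s
#'   (`mirna`, `target`), one per prediction source.
#' @param lncrna_mirna,circrna_mirna optional single-source tables
#'   (`lncrna`/`circrna`, `mirna`).
#' @param mode `"expression"` or `"methylation"` (recorded on the edges).
#' @return an `interaction_network`; empty differential sets yield an
#'   empty network with a warning.
#' @export
build_cerna <- function(diff_sets, mirna_target_tables,
                        lncrna_mirna = NULL, circrna_mirna = NULL,
                        mode = c("expression", "methylation")) {
  mode <- match.arg(mode)
  if (length(mirna_target_tables) != 3) {
    stop("exactly three miRNA-target source tables are required",
         call. = FALSE)
  }
  pair_key <- function(tab) paste(tab$mirna, tab$target, sep = "\r")
  keys <- lapply(mirna_target_tables, pair_key)
  common <- Reduce(intersect, keys)
  mm <- unique(do.call(rbind, lapply(mirna_target_tables, function(t)
    t[c("mirna", "target")])))
  mm <- mm[pair_key(mm) %in% common, , drop = FALSE]
  if (!length(diff_sets$miRNA) ||
      (!length(diff_sets$mRNA) && !length(diff_sets$lncRNA) &&
         !length(diff_sets$circRNA))) {
    warning("empty differential sets: ceRNA network is empty", call. = FALSE)
  }
  edges <- list()
  mm <- mm[mm$mirna %in% diff_sets$miRNA & mm$target %in% diff_sets$mRNA, ,
           drop = FALSE]
  if (nrow(mm)) {
    edges$mm <- data.frame(source = mm$mirna, target = mm$target,
                           type = "miRNA-mRNA",
                           provenance = "three_source_intersection",
                           stringsAsFactors = FALSE)
  }
  add_single <- function(tab, id_col, set, type, prov) {
    if (is.null(tab)) return(NULL)
    t2 <- tab[tab[[id_col]] %in% set & tab$mirna %in% diff_sets$miRNA, ,
              drop = FALSE]
    if (!nrow(t2)) return(NULL)
    data.frame(source = t2[[id_col]], target = t2$mirna, type = type,
               provenance = prov, stringsAsFactors = FALSE)
  }
  edges$lnc <- add_single(lncrna_mirna, "lncrna", diff_sets$lncRNA,
                          "lncRNA-miRNA", "encori")
  edges$circ <- add_single(circrna_mirna, "circrna", diff_sets$circRNA,
                           "circRNA-miRNA", "encori")
  e <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  if (is.null(e)) {
    e <- data.frame(source = character(), target = character(),
                    type = character(), provenance = character(),
                    stringsAsFactors = FALSE)
  }
  e <- e[e$source != e$target, , drop = FALSE]
  e$mode <- rep(mode, nrow(e))
  rownames(e) <- NULL
  node_type <- function(ids, types) {
    if (!length(ids)) return(NULL)
    data.frame(node = ids, type = types, stringsAsFactors = FALSE)
  }
  parts <- list(
    node_type(e$source[e$type == "miRNA-mRNA"], "miRNA"),
    node_type(e$target[e$type == "miRNA-mRNA"], "mRNA"),
    node_type(e$source[e$type == "lncRNA-miRNA"], "lncRNA"),
    node_type(e$target[e$type == "lncRNA-miRNA"], "miRNA"),
    node_type(e$source[e$type == "circRNA-miRNA"], "circRNA"),
    node_type(e$target[e$type == "circRNA-miRNA"], "miRNA"))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  nodes <- if (length(parts)) unique(do.call(rbind, parts)) else
    data.frame(node = character(), type = character(),
               stringsAsFactors = FALSE)
  new_network(e, nodes)
}

#' Build a lncRNA-RBP interaction network
#'
#' Keeps pairs with CLIP evidence >= `min_evidence` (the medium-stringency
#' convention is 2) whose lncRNA is differentially methylated.
#'
#' @param dm_lncrnas character vector of differentially methylated
#'   lncRNAs.
#' @param rbp_table `data.frame` with `lncrna`, `rbp`, `evidence`.
#' @param min_evidence minimum CLIP evidence count (inclusive).
#' @return an `interaction_network` (bipartite lncRNA-RBP).
#' @export
build_lncrna_rbp <- function(dm_lncrnas, rbp_table, min_evidence = 2) {
  if (!"evidence" %in% names(rbp_table)) {
    stop("rbp_table lacks an 'evidence' column", call. = FALSE)
  }
  keep <- rbp_table[rbp_table$evidence >= min_evidence &
                      rbp_table$lncrna %in% dm_lncrnas, , drop = FALSE]
  e <- data.frame(source = keep$lncrna, target = keep$rbp,
                  type = "lncRNA-RBP",
                  provenance = sprintf("clip_evidence>=%d", min_evidence),
                  stringsAsFactors = FALSE)
  rownames(e) <- NULL
  nodes <- unique(rbind(
    data.frame(node = e$source, type = "lncRNA", stringsAsFactors = FALSE),
    data.frame(node = e$target, type = "RBP", stringsAsFactors = FALSE)))
  new_network(e, nodes)
}

#' Scan 3'UTRs for miRNA seed matches
#'
#' Sites are exact reverse-complement matches of the miRNA seed within
#' the 3'UTR, reported as 0-based half-open transcript-local coordinates.
#' Seed definitions: `7mer-m8` = miRNA positions 2-8 (default), `6mer` =
#' 2-7, `8mer` = 1-8.
#'
#' @param mirna_seqs named character vector of mature miRNA sequences
#'   (RNA or DNA alphabet, 5'->3'), each >= 8 nt.
#' @param utr_seqs named character vector of 3'UTR sequences (DNA).
#' @param seed_type seed-match class.
#' @return `data.frame` with `mirna`, `transcript_id`, `start`, `end`.
#' @export
seed_scan <- function(mirna_seqs, utr_seqs,
                      seed_type = c("7mer-m8", "6mer", "8mer")) {
  seed_type <- match.arg(seed_type)
  if (any(nchar(mirna_seqs) < 8)) {
    stop("miRNA shorter than 8 nt", call. = FALSE)
  }
  rng <- switch(seed_type, "7mer-m8" = c(2L, 8L), "6mer" = c(2L, 7L),
                "8mer" = c(1L, 8L))
  out <- list()
  for (mi in names(mirna_seqs)) {
    seed <- substr(gsub("U", "T", toupper(mirna_seqs[[mi]])), rng[1], rng[2])
    site <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seed)))
    for (tx in names(utr_seqs)) {
      m <- gregexpr(site, utr_seqs[[tx]], fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      out[[length(out) + 1L]] <- data.frame(
        mirna = mi, transcript_id = tx,
        start = as.integer(m) - 1L,
        end = as.integer(m) - 1L + nchar(site),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(mirna = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify miRNA-mRNA pair dynamics against m1A peaks per condition
#'
#' A pair is "m1A-overlapped" in a condition when its seed site intersects
#' (half-open) any consensus m1A interval of that condition on the same
#' transcript.
#'
#' @param binding_sites output of [seed_scan()] (`utr_offset` column, if
#'   present, shifts sites into transcript coordinates).
#' @param peaks_by_condition named list (condition -> peak `data.frame`
#'   with `transcript_id`, `start`, `end`).
#' @param conditions conditions to report; default all names of
#'   `peaks_by_condition`.
#' @return `data.frame`: one row per pair with a logical column per
#'   condition and a `status` string such as `"overlapped>free>overlapped"`.
#' @export
pair_dynamics <- function(binding_sites, peaks_by_condition,
                          conditions = names(peaks_by_condition)) {
  missing <- setdiff(conditions, names(peaks_by_condition))
  if (length(missing)) {
    stop(sprintf("condition(s) absent from peaks: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sites <- binding_sites
  if ("utr_offset" %in% names(sites)) {
    sites$start <- sites$start + sites$utr_offset
    sites$end <- sites$end + sites$utr_offset
  }
  res <- unique(sites[c("mirna", "transcript_id", "start", "end")])
  for (cond in conditions) {
    pk <- peaks_by_condition[[cond]]
    res[[cond]] <- vapply(seq_len(nrow(res)), function(i) {
      px <- pk[pk$transcript_id == res$transcript_id[i], , drop = FALSE]
      nrow(px) > 0 && any(px$start < res$end[i] & res$start[i] < px$end)
    }, logical(1))
  }
  res$status <- if (nrow(res)) {
    apply(res[, conditions, drop = FALSE], 1, function(v)
      paste(ifelse(as.logical(v), "overlapped", "free"), collapse = ">"))
  } else character(0)
  rownames(res) <- NULL
  res
}
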