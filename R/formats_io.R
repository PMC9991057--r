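# On-disk formats: pileup TSV, BED6, transcript model tables + FASTA,
# schema-checked result tables, YAML configuration.  All coordinates are
# 0-based half-open internally; writers are deterministic (fixed column
# order, 6 significant digits for floats) and prefix provenance lines with
# '#' so standard parsers skip them.

pileup_cols <- c("transcript_id", "pos", "coverage", "at_mismatch",
                 "read_start", "library", "treatment", "condition", "replicate")

provenance_header <- function(seed = NULL, config = NULL) {
  c(sprintf("# m1ascope %s", as.character(packageVersion("m1ascope"))),
    if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed)),
    if (!is.null(config)) sprintf("# config_hash=%s", content_hash(config)))
}

write_tsv_with_header <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_header <- function(path, colClasses = NA) {
  if (!file.exists(path)) {
    stop(sprintf("missing input file: %s", path), call. = FALSE)
  }
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             colClasses = colClasses)
}

#' Write / read pileup tracks
#'
#' The pileup TSV dialect has columns `transcript_id`, `pos` (0-based),
#' `coverage`, `at_mismatch`, `read_start`, `library`, `treatment`,
#' `condition`, `replicate`.  Reading validates that positions are unique
#' per track and that mismatch counts never exceed coverage.
#'
#' @param tracks pileup `data.frame` (see [simulate_merip_pileups()]).
#' @param path file path.
#' @param seed,config optional provenance recorded in the header.
#' @return `read_pileup` returns the validated, sorted `data.frame`.
#' @export
write_pileup <- function(tracks, path, seed = NULL, config = NULL) {
  stopifnot(all(pileup_cols %in% names(tracks)))
  write_tsv_with_header(tracks[pileup_cols], path, seed, config)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  df <- read_tsv_skip_header(path, colClasses = c(
    transcript_id = "character", pos = "integer", coverage = "integer",
    at_mismatch = "integer", read_start = "integer", library = "character",
    treatment = "character", condition = "character", replicate = "integer"))
  missing <- setdiff(pileup_cols, names(df))
  if (length(missing)) {
    stop(sprintf("pileup file %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(df$at_mismatch > df$coverage)
  if (length(bad)) {
    stop(sprintf("validation error in %s: at_mismatch > coverage at data row %d",
                 path, bad[1]), call. = FALSE)
  }
  key <- interaction(df$transcript_id, df$library, df$treatment,
                     df$condition, df$replicate, drop = TRUE)
  dup <- which(duplicated(paste(key, df$pos)))
  if (length(dup)) {
    stop(sprintf("parse error in %s: duplicate position at data row %d",
                 path, dup[1]), call. = FALSE)
  }
  df[order(df$transcript_id, df$library, df$treatment, df$condition,
           df$replicate, df$pos), , drop = FALSE]
}

#' Write / read BED6 interval files
#'
#' 0-based half-open coordinates; the strand column is honored.  Intervals
#' with `start >= end` are rejected.
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @param path file path.
#' @return `read_bed` returns the validated `data.frame`.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  stopifnot(all(cols %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) {
    stop("validation error: BED interval with start >= end", call. = FALSE)
  }
  write.table(intervals[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("missing input file: %s", path), call. = FALSE)
  }
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BED6 requires 6 columns", call. = FALSE)
  df <- df[, 1:6]
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")
  if (any(df$start >= df$end)) {
    stop("validation error: BED interval with start >= end", call. = FALSE)
  }
  df
}

#' Merge overlapping or bookended intervals
#'
#' @param intervals `data.frame` with `start`, `end` (0-based half-open),
#'   optionally grouped by `chrom`.
#' @return merged intervals sorted by (`chrom`, `start`).
#' @export
merge_intervals <- function(intervals) {
  stopifnot(all(c("start", "end") %in% names(intervals)))
  chrom <- if ("chrom" %in% names(intervals)) intervals$chrom else "*"
  parts <- split(intervals, chrom)
  out <- lapply(names(parts), function(ch) {
    p <- parts[[ch]]
    ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Write / read transcript model tables (with optional FASTA)
#'
#' Model tables are TSV with the columns produced by
#' [generate_transcriptome()]; sequences can live in the table or in a
#' side-car FASTA keyed by `transcript_id`.  Region bounds of mRNAs must
#' partition `[0, length)`.
#'
#' @param models transcript model `data.frame`.
#' @param path TSV path.
#' @param fasta optional FASTA path for sequences.
#' @return `read_models` returns the validated `data.frame`.
#' @export
write_models <- function(models, path, fasta = NULL) {
  df <- models
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(df$sequence)
    names(seqs) <- df$transcript_id
    Biostrings::writeXStringSet(seqs, fasta)
    df$sequence <- NULL
  }
  write_tsv_with_header(df, path)
}

#' @rdname write_models
#' @export
read_models <- function(path, fasta = NULL) {
  df <- read_tsv_skip_header(path)
  if (!is.null(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    df$sequence <- as.character(seqs[df$transcript_id])
  }
  is_mrna <- df$biotype == "mRNA"
  bad <- is_mrna & (is.na(df$utr5_end) | is.na(df$cds_end) |
                      df$utr5_end <= 0 | df$utr5_end >= df$cds_end |
                      df$cds_end >= df$length)
  if (any(bad)) {
    stop(sprintf("validation error: region bounds of %s do not partition [0, length)",
                 df$transcript_id[which(bad)[1]]), call. = FALSE)
  }
  if ("sequence" %in% names(df) && any(nchar(df$sequence) != df$length)) {
    stop("validation error: sequence length != declared length", call. = FALSE)
  }
  df
}

#' Read a result table against a declared schema
#'
#' @param path TSV path.
#' @param schema named character vector mapping required column names to
#'   types (`"character"`, `"integer"`, `"numeric"`, `"logical"`).
#' @return the validated `data.frame`.
#' @export
read_table_schema <- function(path, schema) {
  df <- read_tsv_skip_header(path)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop(sprintf("table %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
                        character = as.character(df[[col]]),
                        integer = as.integer(df[[col]]),
                        numeric = as.numeric(df[[col]]),
                        logical = as.logical(df[[col]]),
                        stop("unknown schema type: ", schema[[col]]))
  }
  df
}

#' Load and validate a pipeline configuration file
#'
#' YAML key/value configuration.  Unknown keys are an error (with a
#' nearest-key suggestion); missing keys take the [sim_config()] defaults
#' and are logged.
#'
#' @param path YAML file; `NULL` for an all-default configuration.
#' @param overrides named list of values overriding the file (CLI flags).
#' @return a [sim_config()] object.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- formals(sim_config)
  known <- names(defaults)
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  user[names(overrides)] <- overrides
  unknown <- setdiff(names(user), known)
  if (length(unknown)) {
    dists <- adist(unknown[1], known)
    hint <- known[which.min(dists)]
    stop(sprintf("unknown config key '%s'; did you mean '%s'?",
                 unknown[1], hint), call. = FALSE)
  }
  for (key in setdiff(known, names(user))) {
    m1a_log("debug", "config: '", key, "' not set, using default")
  }
  # named defaults like biotype_props arrive from YAML as named lists
  for (key in intersect(names(user), c("biotype_props", "region_weights"))) {
    user[[key]] <- unlist(user[[key]])
  }
  if ("length_range" %in% names(user)) {
    user$length_range <- lapply(user$length_range, unlist)
  }
  cfg <- do.call(sim_config, user)
  m1a_log("info", "effective config hash: ", content_hash(unclass(cfg)))
  cfg
}
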