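# End-to-end pipeline driver.  Stages communicate through files in the
# output directory so each stage is independently runnable and testable;
# a JSON manifest records stage order, artifacts, seed and config hash.

#' Demo-scale simulation configuration
#'
#' The full study design (three conditions x three replicates, IP/input,
#' untreated/treated) at a transcriptome size small enough for an
#' interactive end-to-end run.
#'
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
demo_config <- function(seed = 1) {
  sim_config(n_transcripts = 50,
             length_range = list(mRNA = c(500, 1500),
                                 lncRNA = c(400, 1000),
                                 circRNA = c(300, 800)),
             seed = seed)
}

stage_file <- function(outdir, name) file.path(outdir, name)

require_stage_input <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s': missing input file %s (run the producing stage first)",
                 stage, path), call. = FALSE)
  }
  path
}

#' Run the synthetic-study pipeline
#'
#' Stages: `simulate` -> `callpeaks` -> `callsites` -> `annotate` ->
#' `diff` -> `network` -> `patterns` -> `report`.  Rerunning with the
#' same config and seed reproduces every artifact byte for byte.
#'
#' @param config a [sim_config()]; defaults to [demo_config()].
#' @param outdir output directory (created if needed).
#' @param stages subset of stages to run, in order.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = demo_config(), outdir,
                         stages = c("simulate", "callpeaks", "callsites",
                                    "annotate", "diff", "network",
                                    "patterns", "report")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "m1ascope",
                   version = as.character(packageVersion("m1ascope")),
                   seed = config$seed,
                   config_hash = content_hash(unclass(config)),
                   stages = list())
  seed <- config$seed
  mark <- function(stage, outputs) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = stage, outputs = as.list(outputs))
    m1a_log("info", "stage ", stage, " done")
  }
  on.exit(jsonlite::write_json(manifest, stage_file(outdir, "manifest.json"),
                               auto_unbox = TRUE, pretty = TRUE))

  if ("simulate" %in% stages) {
    models <- generate_transcriptome(config)
    sites <- plant_sites(models, config)
    pile <- simulate_merip_pileups(models, sites, config)
    write_models(models, stage_file(outdir, "models.tsv"),
                 fasta = stage_file(outdir, "models.fa"))
    if (nrow(sites)) {
      write_bed(data.frame(chrom = sites$transcript_id,
                           start = sites$position,
                           end = sites$position + 1L,
                           name = paste0(sites$transcript_id, ":",
                                         sites$position),
                           score = round(1000 * sites$methyl_fraction),
                           strand = "+", stringsAsFactors = FALSE),
                stage_file(outdir, "truth_sites.bed"))
    }
    write_pileup(pile, stage_file(outdir, "pileups.tsv"), seed = seed,
                 config = unclass(config))
    mark("simulate", c("models.tsv", "models.fa", "truth_sites.bed",
                       "pileups.tsv"))
  }

  models <- NULL; pile <- NULL
  need_data <- function(stage) {
    if (is.null(models)) {
      models <<- read_models(require_stage_input(
        stage_file(outdir, "models.tsv"), stage),
        fasta = require_stage_input(stage_file(outdir, "models.fa"), stage))
    }
    if (is.null(pile)) {
      pile <<- read_pileup(require_stage_input(
        stage_file(outdir, "pileups.tsv"), stage))
    }
  }

  if ("callpeaks" %in% stages) {
    need_data("callpeaks")
    for (cond in config$conditions) {
      cc <- pile[pile$condition == cond, , drop = FALSE]
      pl <- lapply(sort(unique(cc$replicate)), function(r) {
        call_peaks(cc[cc$library == "IP" & cc$treatment == "untreated" &
                        cc$replicate == r, , drop = FALSE],
                   cc[cc$library == "input" & cc$treatment == "untreated" &
                        cc$replicate == r, , drop = FALSE])
      })
      rp <- reproducible_peaks(pl, min_reps = min(2L, length(pl)))
      write_tsv_with_header(rp, stage_file(outdir,
                                           paste0("peaks_", cond, ".tsv")),
                            seed = seed)
    }
    mark("callpeaks", paste0("peaks_", config$conditions, ".tsv"))
  }

  if ("callsites" %in% stages) {
    need_data("callsites")
    for (cond in config$conditions) {
      sites <- call_m1a_sites(pile, models, cond)
      write_tsv_with_header(sites, stage_file(outdir,
                                              paste0("sites_", cond, ".tsv")),
                            seed = seed)
      rna <- rollup_rna(sites, models)
      write_tsv_with_header(rna, stage_file(outdir,
                                            paste0("rnas_", cond, ".tsv")),
                            seed = seed)
    }
    mark("callsites", paste0("sites_", config$conditions, ".tsv"))
  }

  if ("annotate" %in% stages) {
    need_data("annotate")
    first <- config$conditions[1]
    sites <- read_table_schema(require_stage_input(
      stage_file(outdir, paste0("sites_", first, ".tsv")), "annotate"),
      c(transcript_id = "character", position = "integer",
        consensus = "logical"))
    cons <- sites[sites$consensus, , drop = FALSE]
    ann <- cons
    ann$region <- vapply(seq_len(nrow(cons)), function(i) {
      assign_region(cons$position[i],
                    models[models$transcript_id == cons$transcript_id[i], ,
                           drop = FALSE])
    }, character(1))
    write_tsv_with_header(ann, stage_file(outdir, "annotation.tsv"),
                          seed = seed)
    mrna_sites <- ann[ann$region != "noncoding", , drop = FALSE]
    if (nrow(mrna_sites)) {
      prof <- metagene(mrna_sites, models)
      write_tsv_with_header(as.data.frame(prof),
                            stage_file(outdir, "metagene.tsv"), seed = seed)
    }
    rna_lists <- lapply(config$conditions, function(cond) {
      read_table_schema(stage_file(outdir, paste0("rnas_", cond, ".tsv")),
                        c(transcript_id = "character"))
    })
    names(rna_lists) <- config$conditions
    write_tsv_with_header(per_chromosome_counts(rna_lists, models),
                          stage_file(outdir, "chromosome_counts.tsv"),
                          seed = seed)
    mark("annotate", c("annotation.tsv", "metagene.tsv",
                       "chromosome_counts.tsv"))
  }

  if ("diff" %in% stages) {
    need_data("diff")
    first <- config$conditions[1]
    outs <- character(0)
    for (cond in setdiff(config$conditions, first)) {
      sites <- read_table_schema(require_stage_input(
        stage_file(outdir, paste0("sites_", first, ".tsv")), "diff"),
        c(transcript_id = "character", position = "integer",
          consensus = "logical"))
      cons <- sites[sites$consensus, , drop = FALSE]
      if (!nrow(cons)) next
      sc <- site_counts(pile, cons, first, cond)
      dm <- diff_methylation(sc$site_counts, sc$libsizes)
      fn <- paste0("diff_methylation_", first, "_vs_", cond, ".tsv")
      write_tsv_with_header(as.data.frame(dm), stage_file(outdir, fn),
                            seed = seed)
      outs <- c(outs, fn)
    }
    # companion expression matrix: NB counts with a planted DE fraction
    fc <- rep(1, 200)
    fc[seq_len(20)] <- 4
    de_sim <- simulate_counts(200, n_per_group = config$replicates,
                              fold_changes = fc,
                              seed = child_seed(seed, "pipeline_expr"))
    de <- diff_expression(de_sim$counts, de_sim$group, kind = "mRNA")
    write_tsv_with_header(as.data.frame(de),
                          stage_file(outdir, "diff_expression.tsv"),
                          seed = seed)
    mark("diff", c(outs, "diff_expression.tsv"))
  }

  if ("network" %in% stages) {
    tabs <- simulate_interaction_tables(seed = child_seed(seed, "pipeline_net"))
    # the diff stage must have run; its table anchors stage ordering even
    # though the demo's interaction pools use their own id space
    invisible(read_table_schema(require_stage_input(
      stage_file(outdir, "diff_expression.tsv"), "network"),
      c(feature_id = "character", significant = "logical")))
    diff_sets <- list(
      miRNA = unique(tabs$mirna_targets[[1]]$mirna),
      mRNA = unique(unlist(lapply(tabs$mirna_targets, function(t) t$target))),
      lncRNA = unique(tabs$lncrna_rbp$lncrna), circRNA = character(0))
    net <- build_cerna(diff_sets, tabs$mirna_targets, mode = "expression")
    write_tsv_with_header(net$edges, stage_file(outdir, "cerna_edges.tsv"),
                          seed = seed)
    rbp <- build_lncrna_rbp(diff_sets$lncRNA, tabs$lncrna_rbp)
    write_tsv_with_header(rbp$edges, stage_file(outdir, "rbp_edges.tsv"),
                          seed = seed)
    mark("network", c("cerna_edges.tsv", "rbp_edges.tsv"))
  }

  if ("patterns" %in% stages) {
    need_data("patterns")
    first <- config$conditions[1]
    sites <- read_table_schema(require_stage_input(
      stage_file(outdir, paste0("sites_", first, ".tsv")), "patterns"),
      c(transcript_id = "character", position = "integer",
        consensus = "logical"))
    cons <- sites[sites$consensus, , drop = FALSE]
    if (nrow(cons) >= 10) {
      lv <- methylation_level_matrix(pile, cons, config)
      X <- nmf_input_matrix(lv)
      kmax <- min(5L, ncol(X) - 1L)
      if (kmax >= 4) {
        cn <- consensus_cophenetic(X, k_range = 2:kmax, n_restarts = 10,
                                   seed = child_seed(seed, "pipeline_nmf"))
        coph <- data.frame(k = as.integer(names(cn$rho)), rho = cn$rho)
        write_tsv_with_header(coph, stage_file(outdir, "cophenetic.tsv"),
                              seed = seed)
        ksel <- select_rank(cn$rho)
        best <- cn$best_fit[[as.character(ksel)]]
        w <- as.data.frame(best$W)
        names(w) <- paste0("pattern", seq_len(ncol(w)))
        w <- cbind(data.frame(feature_id = paste0(cons$transcript_id, ":",
                                                  cons$position)), w)
        write_tsv_with_header(w, stage_file(outdir, "nmf_W.tsv"), seed = seed)
        mark("patterns", c("cophenetic.tsv", "nmf_W.tsv"))
      }
    }
  }

  if ("report" %in% stages) {
    first <- config$conditions[1]
    sites_fn <- require_stage_input(
      stage_file(outdir, paste0("sites_", first, ".tsv")), "report")
    summary_rows <- list()
    for (cond in config$conditions) {
      s <- read_table_schema(stage_file(outdir, paste0("sites_", cond, ".tsv")),
                             c(consensus = "logical", conventional = "logical",
                               mismatch = "logical", trough = "logical",
                               treatment = "logical"))
      summary_rows[[cond]] <- data.frame(
        condition = cond,
        conventional = sum(s$conventional), mismatch = sum(s$mismatch),
        trough = sum(s$trough), treatment = sum(s$treatment),
        consensus = sum(s$consensus), stringsAsFactors = FALSE)
    }
    rep_df <- do.call(rbind, summary_rows)
    write_tsv_with_header(rep_df, stage_file(outdir, "report.tsv"),
                          seed = seed)
    md <- c("# m1ascope run report", "",
            sprintf("- seed: %d", seed),
            sprintf("- config hash: %s", manifest$config_hash),
            sprintf("- conditions: %s",
                    paste(config$conditions, collapse = ", ")), "",
            "| condition | conventional | mismatch | trough | treatment | consensus |",
            "|---|---|---|---|---|---|",
            sprintf("| %s | %d | %d | %d | %d | %d |", rep_df$condition,
                    rep_df$conventional, rep_df$mismatch, rep_df$trough,
                    rep_df$treatment, rep_df$consensus))
    writeLines(md, stage_file(outdir, "report.md"))
    mark("report", c("report.tsv", "report.md"))
  }
  invisible(manifest)
}

#' Methylation-level matrix of sites across samples
#'
#' One column per (condition, replicate): the normalized log2 IP/input
#' level of each consensus site, the feature matrix for pattern
#' discovery.
#'
#' @param pileups pileup `data.frame` (untreated libraries used).
#' @param sites `data.frame` with `transcript_id`, `position`.
#' @param config [sim_config()] supplying conditions and replicates.
#' @param halfwidth interval half-width around each site.
#' @return sites x samples numeric matrix with `cond.rep` column names.
#' @export
methylation_level_matrix <- function(pileups, sites, config, halfwidth = 50) {
  intervals <- data.frame(transcript_id = sites$transcript_id,
                          start = pmax(0L, sites$position - halfwidth),
                          end = sites$position + halfwidth + 1L,
                          stringsAsFactors = FALSE)
  cols <- list()
  for (cond in config$conditions) {
    for (r in seq_len(config$replicates)) {
      sel <- pileups$condition == cond & pileups$replicate == r &
        pileups$treatment == "untreated"
      ip <- pileups[sel & pileups$library == "IP", , drop = FALSE]
      inp <- pileups[sel & pileups$library == "input", , drop = FALSE]
      cols[[paste(cond, r, sep = ".")]] <-
        methylation_level(ip, inp, intervals)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- paste0(sites$transcript_id, ":", sites$position)
  mat
}
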