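# Pipeline orchestration: runs the stages (simulate -> ingest -> redundancy
# -> features -> motif-scan -> null-rank -> enrich) in dependency order from
# a single configuration, with every random step seeded from the master
# seed, and writes a manifest of inputs, parameters and per-stage row
# counts.

#' Default pipeline configuration
#'
#' The `test` profile uses desk-scale sizes so a full run completes in well
#' under a minute; the `full` profile mirrors the genome-scale study
#' conditions (set sizes 2594/938, 40000-100000 random motifs) and is meant
#' for long batch runs.
#'
#' @param profile `"test"` or `"full"`.
#' @param outdir Output directory.
#' @param seed Master seed.
#' @return Nested configuration list of class `run_config`.
#' @export
default_config <- function(profile = c("test", "full"), outdir = "alrex_run",
                           seed = 1L) {
  profile <- match.arg(profile)
  synth <- if (profile == "test") {
    list(n_pos = 250L, n_neg = 250L, n_other = 250L)
  } else {
    list(n_pos = 2594L, n_neg = 938L, n_other = 1000L)
  }
  structure(list(
    profile = profile, outdir = outdir, seed = seed,
    stages = c("simulate", "ingest", "redundancy", "features",
               "motif_scan", "null_rank", "enrich"),
    synth = synth,
    region = 99L, pseudocount = 0.5,
    n_null = if (profile == "test") 200L else 100000L,
    fpr_grid = seq(0.1, 0.7, by = 0.1),
    n_resamples = if (profile == "test") 500L else 10000L,
    n_terms = if (profile == "test") 20L else 100L,
    planted_term = list(size = 25L, or = 0.2),
    cluster = list(min_identity = 0.9, min_overlap = 60L)),
    class = "run_config")
}

validate_config <- function(config) {
  if (config$n_null < 100L) stop("n_null below minimum (100)")
  if (config$n_resamples < 100L) stop("n_resamples below minimum (100)")
  if (any(config$fpr_grid <= 0 | config$fpr_grid >= 1))
    stop("fpr_grid values must be in (0,1)")
  bad <- setdiff(config$stages,
                 c("simulate", "ingest", "redundancy", "features",
                   "motif_scan", "null_rank", "enrich"))
  if (length(bad)) stop("unknown stage: ", bad[1])
  invisible(TRUE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order against a synthetic
#' dataset written to and re-read from disk (so the ingest path is exercised
#' end to end), and writes TSV/JSON reports plus a `manifest.json`. Rerunning
#' with the same configuration reproduces every report byte for byte.
#'
#' @param config A [default_config()]-style list.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(profile = config$profile, seed = config$seed,
                   stages = list())
  t0 <- Sys.time()
  env <- new.env(parent = emptyenv())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message("[", name, "] done")
  }

  if ("simulate" %in% config$stages) {
    scfg <- do.call(synthetic_config,
                    c(config$synth, list(seed = derive_seed(config$seed, 1L))))
    env$dataset <- gen_dataset(scfg)
    env$paths <- write_dataset(env$dataset, file.path(outdir, "data"))
    log_stage("simulate", n_records = nrow(env$dataset$records),
              n_planted = if (is.null(env$dataset$truth)) 0L else
                nrow(env$dataset$truth),
              consensus = scfg$motif_consensus)
  }

  if ("ingest" %in% config$stages) {
    if (is.null(env$paths)) stop("ingest: missing upstream artifact (simulate)")
    parsed <- parse_cds_fasta(env$paths[["fasta"]])
    ann <- read_annotation_table(env$paths[["annotation"]])
    sscr <- read_id_list(env$paths[["sscr"]])
    mscr <- read_id_list(env$paths[["mscr"]])
    rec <- build_transcript_records(parsed$records, ann, sscr, mscr)
    filt <- apply_cds_filters(rec)
    rec <- dedup_splice_variants(filt$records,
                                 mode = "identical_leader69",
                                 seed = derive_seed(config$seed, 2L))
    validate_transcript_records(rec)
    env$records <- rec
    .write_tsv(rec[, setdiff(names(rec), "cds")],
               file.path(outdir, "records.tsv"))
    log_stage("ingest", n_parsed = nrow(parsed$records),
              n_rejected = nrow(parsed$rejects),
              filter_report = as.list(filt$report), n_kept = nrow(rec))
  }

  if ("redundancy" %in% config$stages) {
    if (is.null(env$records)) stop("redundancy: missing upstream artifact (ingest)")
    cl <- cluster_first99(env$records,
                          min_identity = config$cluster$min_identity,
                          min_overlap = config$cluster$min_overlap)
    cl <- pick_representatives(cl, seed = derive_seed(config$seed, 3L))
    env$records <- representative_records(env$records, cl)
    write_cluster_report(cl, file.path(outdir, "clusters.tsv"))
    log_stage("redundancy", n_clusters = length(cl),
              n_representatives = nrow(env$records))
  }

  if ("features" %in% config$stages) {
    if (is.null(env$records)) stop("features: missing upstream artifact (ingest)")
    lead <- env$records[env$records$leader_class != "OTHER", , drop = FALSE]
    ft <- codon_feature_table(lead)
    .write_tsv(ft, file.path(outdir, "codon_features.tsv"))
    fv <- function(ids) {
      sel <- lead[lead$transcript_id %in% ids, , drop = FALSE]
      lapply(sel$cds, function(s)
        codon_feature_vector(partition_cds(s)$first69, "first69"))
    }
    g_pos <- fv(lead$transcript_id[!lead$has_5ui])
    g_neg <- fv(lead$transcript_id[lead$has_5ui])
    comps <- lapply(c("adenine_percent", "leu_ile", "arg_lys",
                      "adenine_codon_ratio", "thymine_codon_ratio"),
                    function(f) compare_groups(g_pos, g_neg, feature = f,
                                               seed = derive_seed(config$seed, 4L)))
    names(comps) <- vapply(comps, `[[`, character(1), "feature")
    env$comparisons <- comps
    jsonlite::write_json(
      lapply(comps, function(cm) {
        cm$test <- as.data.frame(cm$test); cm
      }), file.path(outdir, "group_comparisons.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    log_stage("features", n_leader = nrow(lead),
              n_rows = nrow(ft))
  }

  if ("motif_scan" %in% config$stages) {
    if (is.null(env$records)) stop("motif_scan: missing upstream artifact (ingest)")
    lead <- env$records[env$records$leader_class != "OTHER", , drop = FALSE]
    consensus <- if (!is.null(env$dataset))
      env$dataset$config$motif_consensus else "CGSSGC"
    bg <- sequence_background(lead$cds, config$region)
    pssm <- consensus_pssm(consensus, pseudocount = config$pseudocount,
                           background = bg)
    hits <- scan_transcripts(pssm, lead, region = config$region)
    write_hits(hits, file.path(outdir, "hits.tsv"))
    max_by_seq <- tapply(hits$score, factor(hits$transcript_id,
                                            levels = lead$transcript_id), max)
    tstar <- select_threshold_tstar(max_by_seq[!lead$has_5ui],
                                    max_by_seq[lead$has_5ui])
    labels <- stats::setNames(lead$has_5ui, lead$transcript_id)
    occ <- occurrence_stats(hits, labels, tstar$t_star)
    env$pssm <- pssm; env$hits <- hits; env$lead <- lead
    env$tstar <- tstar; env$occurrence <- occ
    jsonlite::write_json(
      list(t_star = tstar$t_star, fisher_p = tstar$fisher_p,
           table = unclass(tstar$table_at_t),
           occurrence = .occurrence_as_list(occ)),
      file.path(outdir, "motif_scan.json"), auto_unbox = TRUE, digits = NA)
    log_stage("motif_scan", n_hits = nrow(hits), t_star = tstar$t_star,
              fisher_p = tstar$fisher_p)
  }

  if ("null_rank" %in% config$stages) {
    if (is.null(env$pssm)) stop("null_rank: missing upstream artifact (motif_scan)")
    lead <- env$lead
    rk <- rank_against_null(env$pssm, lead$cds[!lead$has_5ui],
                            lead$cds[lead$has_5ui],
                            n_null = config$n_null,
                            fpr_grid = config$fpr_grid,
                            seed = derive_seed(config$seed, 5L),
                            region = config$region, keep_null_rocs = TRUE)
    tprime <- select_threshold_tprime(rk$target_roc, rk$null_rocs)
    env$ranking <- rk
    .write_tsv(data.frame(fpr = rk$fpr_grid, target_tpr = rk$target_tpr,
                          null_tpr_median = rk$null_tpr_median,
                          percentile = rk$percentile),
               file.path(outdir, "null_ranking.tsv"))
    jsonlite::write_json(
      list(outperforms_q = rk$outperforms_q, t_prime = as.numeric(tprime),
           n_null = rk$n_null),
      file.path(outdir, "null_ranking.json"), auto_unbox = TRUE, digits = NA)
    log_stage("null_rank", n_null = rk$n_null,
              outperforms_q = rk$outperforms_q,
              t_prime = as.numeric(tprime))
  }

  if ("enrich" %in% config$stages) {
    if (is.null(env$records)) stop("enrich: missing upstream artifact (ingest)")
    rec <- env$records
    ann <- gen_category_annotations(rec, n_terms = config$n_terms,
                                    planted = list(config$planted_term),
                                    seed = derive_seed(config$seed, 6L))
    labels <- stats::setNames(rec$has_5ui, rec$transcript_id)
    rows <- term_enrichment(ann, labels)
    rows <- resampling_adjust(rows, ann, labels,
                              n_resamples = config$n_resamples,
                              seed = derive_seed(config$seed, 7L))
    write_enrichment_report(rows, file.path(outdir, "enrichment.tsv"))
    cmh <- tryCatch(suppressWarnings(length_matched_association(rec)),
                    error = function(e) NULL)
    if (!is.null(cmh))
      jsonlite::write_json(as.data.frame(cmh),
                           file.path(outdir, "length_matched.json"),
                           auto_unbox = TRUE, digits = NA)
    log_stage("enrich", n_terms = length(ann),
              min_p_adj = min(rows$p_adj),
              cmh_p = if (!is.null(cmh)) cmh$p_value else NA)
  }

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$versions <- list(alrexscan = as.character(utils::packageVersion("alrexscan")),
                            r = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

.occurrence_as_list <- function(occ) {
  strip <- function(g) g[setdiff(names(g), "positions")]
  list(threshold = occ$threshold,
       group_5ui_minus = strip(occ$group_5ui_minus),
       group_5ui_plus = strip(occ$group_5ui_plus),
       position_wilcoxon_p = if (!is.null(occ$position_test))
         occ$position_test$p_value else NA)
}
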