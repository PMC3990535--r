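#' Default end-to-end pipeline configuration
#'
#' Per-stage parameter blocks with the calling thresholds locked to their
#' standard values (|mean log2| >= 0.25 and >= 5 probes for retention,
#' +/-1.0 for amplification/deletion, >= 50% cohort frequency for recurrent
#' gain/loss, >= 20% for the focal amplification/deletion tables, p < 0.05
#' for enrichment).
#'
#' @return nested named list of stage parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "cnvseg_run",
    simulate = list(
      n_samples = 20L, n_chrom = 2L, chrom_length_bp = 2509000,
      spacing_bp = 2509, noise_sd = 0.15, gradient = c(0, 0), dye_bias = 0,
      private_cnv_rate = 2, baseline_intensity = 1000, affinity_sd = 1),
    preprocess = list(span = 0.3, degree = 2, n_anchors = 14L,
                      order = "spatial-first", spatial = TRUE),
    segment = list(penalty = "auto", kmax = 20L),
    call = list(min_probes = 5L, min_abs_mean = 0.25,
                gain_threshold = 0.25, amp_threshold = 1.0),
    recurrence = list(threshold_gainloss = 0.5, threshold_ampdel = 0.2),
    annotation = list(features = NULL, mirnas = NULL),
    enrichment = list(terms = NULL, kappa = 0.5, p_cutoff = 0.05),
    qpcr = list(enabled = FALSE, fold = 6.61, control_mean_expression = 0.5174,
                ct_sd = 0.2, n_tumor = 26L, n_control = 14L)
  )
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys (top level or within a stage block) are rejected; missing
#' keys are filled from [default_config()]; frequency thresholds must lie in
#' (0, 1].
#'
#' @param config partial configuration list (or `NULL` for the defaults).
#' @return the completed configuration.
#' @export
validate_config <- function(config = NULL) {
  defaults <- default_config()
  if (is.null(config)) return(defaults)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (blk in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[blk]]) && !is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
      if (length(bad)) {
        stop("unknown keys in config block '", blk, "': ",
             paste(bad, collapse = ", "))
      }
    }
  }
  cfg <- utils::modifyList(defaults, config)
  for (th in c("threshold_gainloss", "threshold_ampdel")) {
    v <- cfg$recurrence[[th]]
    if (!is.numeric(v) || v <= 0 || v > 1) {
      stop("recurrence ", th, " must lie in (0, 1]")
    }
  }
  if (cfg$call$min_probes < 1) stop("call min_probes must be >= 1")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with (a subset of) the [default_config()] blocks.
#' @return validated configuration list.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

#' Run the full aCGH analysis pipeline
#'
#' simulate -> preprocess -> segment -> call -> recurrence (-> annotate ->
#' enrich) (-> qpcr), writing each stage's output under `out_dir` before the
#' next stage starts, plus a machine-readable `summary.json` (per-stage
#' counts, effective parameters, seed and config hash) and a `log.txt`.
#' Identical configuration and seed reproduce byte-identical summaries.
#'
#' @param config a (partial) configuration; see [default_config()].
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return invisibly, a list with the main stage results and the summary.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  info <- function(...) {
    msg <- paste0("INFO ", sprintf(...))
    writeLines(msg, log_con)
    message(msg)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  set.seed(cfg$seed)
  sim_par <- cfg$simulate
  cohort <- run_stage("simulate", {
    layout <- make_layout(n_chrom = sim_par$n_chrom,
                          chrom_length_bp = sim_par$chrom_length_bp,
                          spacing_bp = sim_par$spacing_bp)
    simulate_cohort(n_samples = sim_par$n_samples, layout = layout,
                    private_cnv_rate = sim_par$private_cnv_rate,
                    noise_sd = sim_par$noise_sd, gradient = sim_par$gradient,
                    dye_bias = sim_par$dye_bias,
                    baseline_intensity = sim_par$baseline_intensity,
                    affinity_sd = sim_par$affinity_sd)
  })
  info("simulated %d samples x %d probes", length(cohort$samples),
       nrow(cohort$layout))
  sim_dir <- file.path(cfg$out_dir, "probes")
  dir.create(sim_dir, showWarnings = FALSE)
  for (s in cohort$sample_ids) {
    write_probe_table(cohort$samples[[s]], file.path(sim_dir, paste0(s, ".tsv")))
    write_truth_bed(implant_truth(cohort$layout, cohort$truth[[s]]),
                    file.path(sim_dir, paste0(s, ".truth.bed")))
  }

  penalty <- if (identical(cfg$segment$penalty, "auto")) NULL else cfg$segment$penalty
  calls_list <- list()
  seg_counts <- integer(0)
  call_dir <- file.path(cfg$out_dir, "calls")
  dir.create(call_dir, showWarnings = FALSE)
  for (s in cohort$sample_ids) {
    norm <- run_stage("preprocess", preprocess_sample(
      cohort$samples[[s]], span = cfg$preprocess$span,
      degree = cfg$preprocess$degree, n_anchors = cfg$preprocess$n_anchors,
      order = cfg$preprocess$order, spatial = cfg$preprocess$spatial))
    segs <- run_stage("segment",
                      segment_sample(norm, penalty = penalty,
                                     kmax = cfg$segment$kmax))
    seg_counts[s] <- nrow(segs)
    calls <- run_stage("call", call_sample(
      segs, s, min_probes = cfg$call$min_probes,
      min_abs_mean = cfg$call$min_abs_mean,
      gain_threshold = cfg$call$gain_threshold,
      amp_threshold = cfg$call$amp_threshold))
    write_segments(calls, file.path(call_dir, paste0(s, ".calls.tsv")))
    calls_list[[s]] <- calls
  }
  all_calls <- do.call(rbind, calls_list)
  rownames(all_calls) <- NULL
  info("segmented %d samples (median %d segments); %d calls total",
       length(seg_counts), as.integer(median(seg_counts)), nrow(all_calls))

  regions <- run_stage("recurrence", minimal_common_regions(
    all_calls, n_samples = length(cohort$sample_ids)))
  recur <- recurrent_regions(regions,
                             threshold = cfg$recurrence$threshold_gainloss)
  features <- if (!is.null(cfg$annotation$features)) {
    run_stage("annotate", read_features(cfg$annotation$features))
  } else NULL
  amp_tab <- class_frequency_table(regions, "amplification",
                                   cfg$recurrence$threshold_ampdel, features)
  del_tab <- class_frequency_table(regions, "deletion",
                                   cfg$recurrence$threshold_ampdel, features)
  tab_dir <- file.path(cfg$out_dir, "tables")
  dir.create(tab_dir, showWarnings = FALSE)
  write_segments(regions, file.path(tab_dir, "minimal_common_regions.tsv"))
  write_segments(recur, file.path(tab_dir, "recurrent_gain_loss.tsv"))
  write_segments(amp_tab, file.path(tab_dir, "amplification_ge20.tsv"))
  write_segments(del_tab, file.path(tab_dir, "deletion_ge20.tsv"))
  write_circos_tracks(all_calls, file.path(cfg$out_dir, "circos"))
  info("%d minimal common regions; %d recurrent (gain/loss); %d amp / %d del rows",
       nrow(regions), nrow(recur), nrow(amp_tab), nrow(del_tab))

  enrich <- NULL
  if (!is.null(cfg$enrichment$terms) && !is.null(features)) {
    enrich <- run_stage("enrich", {
      terms <- read_gmt(cfg$enrichment$terms)
      universe <- unique(features$name)
      query <- unique(unlist(strsplit(amp_tab$features, ",")))
      query <- setdiff(query, "")
      if (length(query)) {
        term_enrichment(query, universe, terms)
      } else NULL
    })
    if (!is.null(enrich)) {
      write.table(enrich, file.path(tab_dir, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      info("enrichment over %d terms, %d with p < 0.05", nrow(enrich),
           sum(enrich$p_value < cfg$enrichment$p_cutoff))
    }
  }

  qpcr_res <- NULL
  if (isTRUE(cfg$qpcr$enabled)) {
    qpcr_res <- run_stage("qpcr", {
      tab <- simulate_qpcr(fold = cfg$qpcr$fold,
                           control_mean_expression = cfg$qpcr$control_mean_expression,
                           ct_sd = cfg$qpcr$ct_sd, n_tumor = cfg$qpcr$n_tumor,
                           n_control = cfg$qpcr$n_control)
      qpcr_analyze(tab)
    })
    write.table(qpcr_res$genes, file.path(tab_dir, "qpcr_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    info("qpcr fold %.3f (p = %.4f)", qpcr_res$genes$fold[1], qpcr_res$genes$p[1])
  }

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null", digits = NA)
  cfg_file <- tempfile()
  writeLines(cfg_json, cfg_file)
  summary <- list(
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    n_samples = length(cohort$sample_ids),
    n_probes = nrow(cohort$layout),
    n_segments = unname(seg_counts),
    n_calls = nrow(all_calls),
    n_minimal_common_regions = nrow(regions),
    n_recurrent_gain_loss = nrow(recur),
    n_amplification_rows = nrow(amp_tab),
    n_deletion_rows = nrow(del_tab),
    n_enriched_terms = if (is.null(enrich)) 0L else sum(enrich$p_value < cfg$enrichment$p_cutoff),
    qpcr_fold = if (is.null(qpcr_res)) NULL else qpcr_res$genes$fold[1],
    parameters = cfg
  )
  unlink(cfg_file)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  info("summary written to %s", file.path(cfg$out_dir, "summary.json"))
  invisible(list(cohort = cohort, calls = all_calls, regions = regions,
                 recurrent = recur, amplification_table = amp_tab,
                 deletion_table = del_tab, enrichment = enrich,
                 qpcr = qpcr_res, summary = summary))
}
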