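#' Read / write BIDS-style events tables
#'
#' Tab-separated events with columns `onset`, `duration`, `trial_type`
#' (seconds).
#'
#' @param path file path.
#' @return `read_events`: a [task_design()].
#' @export
read_events <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(tab)) stopf("empty events file: %s", path)
  task_design(tab)
}

#' @rdname read_events
#' @param design a [task_design()] to write.
#' @export
write_events <- function(design, path) {
  utils::write.table(design$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every stage parameter with the analysis defaults: window 8 TR,
#' taper sigma 3 TR, graphical-lasso penalty 0.1, k = 4 states with 150
#' clustering replicates, 5000 permutations, 100 network randomizations,
#' top 20 regional pairs, FDR q = 0.05, behaviour collinearity cut |r| >
#' 0.8 and 95 percent near-zero-variance rule, 0.18 Hz low-pass, mean-FD
#' exclusion above 0.2 mm. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(window_tr = 8L, sigma = 3, lambda = 0.1, stride = 1L,
              k = 4L, replicates = 150L, metric = "cityblock",
              n_perm = 5000L, n_rand = 100L, top_k = 20L,
              fdr_q = 0.05, r_max = 0.8, nzv_prop = 0.95,
              detrend_degree = 3L, despike_z = 3.5, lowpass_hz = 0.18,
              max_mean_fd = 0.2, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$window_tr < 2) stopf("window_tr must be >= 2")
  if (cfg$lambda < 0) stopf("lambda must be >= 0")
  if (cfg$k < 1) stopf("k must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a cohort, post-processes each subject (detrend, task + motion
#' nuisance regression, despike, low-pass), estimates windowed and static
#' FNC, fits states, computes graph metrics per state, group task
#' modulation, regional contrasts, state predictors, and the
#' time-varying/static regression comparison. Outputs are written as CSV
#' with a JSON provenance sidecar; subjects above the mean-FD threshold are
#' excluded and logged.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param synth_cfg a [synthetic_config()] (default: package defaults with
#'   `cfg$seed`).
#' @param design a [task_design()] (default: two-condition block design
#'   covering the session).
#' @return invisible list of stage results; files under `out_dir`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("dynrun"),
                         synth_cfg = NULL, design = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(synth_cfg)) synth_cfg <- synthetic_config(seed = cfg$seed)
  total_s <- synth_cfg$n_timepoints * synth_cfg$tr_seconds
  if (is.null(design)) design <- block_design(total_s = total_s)
  cohort <- simulate_cohort(synth_cfg, design, seed = cfg$seed)

  keep <- which(cohort$covariates$mean_fd <= cfg$max_mean_fd)
  excluded <- setdiff(seq_along(cohort$subjects), keep)
  log_lines <- sprintf("excluded %d subject(s) with mean FD > %g mm",
                       length(excluded), cfg$max_mean_fd)
  subjects <- cohort$subjects[keep]

  tr <- synth_cfg$tr_seconds
  T_ <- synth_cfg$n_timepoints
  task_reg_tr <- t(condition_regressors_tr(design, tr, T_))
  wfnc_list <- vector("list", length(subjects))
  static_list <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    ts <- tryCatch(
      preprocess(subjects[[i]]$ts, task_regressors = task_reg_tr,
                 detrend_degree = cfg$detrend_degree,
                 despike_z = cfg$despike_z, lowpass_hz = cfg$lowpass_hz),
      error = function(e) stopf("stage prep failed for subject %s: %s",
                                subjects[[i]]$ts$subject_id, conditionMessage(e)))
    wfnc_list[[i]] <- compute_windowed_fnc(ts, w = cfg$window_tr,
                                           sigma = cfg$sigma,
                                           lambda = cfg$lambda,
                                           stride = cfg$stride)
    static_list[[i]] <- compute_static_fnc(ts)
  }

  model <- fit_states(wfnc_list, k = cfg$k, n_replicates = cfg$replicates,
                      metric = cfg$metric, seed = cfg$seed)
  metrics <- dwell_and_fraction(model, tr_seconds = tr)
  gm <- lapply(seq_len(cfg$k), function(s)
    graph_metrics(model$centroids[s, ], n_rand = cfg$n_rand,
                  seed = cfg$seed + s))
  reg <- convolve_conditions(design, tr, T_, cfg$window_tr, cfg$stride)
  mod <- group_modulation(model, reg, n_perm = cfg$n_perm, seed = cfg$seed,
                          q = cfg$fdr_q)
  rarr <- pair_condition_correlation(wfnc_list, reg)
  conds <- design$conditions
  contrast <- contrast_t(rarr, conds[1], conds[2], top_k = cfg$top_k,
                         q = cfg$fdr_q)
  preds <- state_predictors(wfnc_list, model, contrast$top_k, static_list)
  behav <- cohort$behaviour[keep, "behaviour", drop = FALSE]
  comp <- compare_regressions(preds, behav)

  write.csv(data.frame(state = seq_len(cfg$k), t(sapply(gm, function(g)
    c(q = g$q, p_pos = g$p_pos, p_neg = g$p_neg, q_norm = g$q_norm)))),
    file.path(out_dir, "graph_metrics.csv"), row.names = FALSE)
  write.csv(mod$table, file.path(out_dir, "modulation.csv"), row.names = FALSE)
  write.csv(comp, file.path(out_dir, "regression_comparison.csv"),
            row.names = FALSE)
  write.csv(cbind(subject = seq_along(subjects), metrics$dwell),
            file.path(out_dir, "dwell_times.csv"), row.names = FALSE)
  utils::write.table(model$centroids, file.path(out_dir, "centroids.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  provenance <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    n_subjects = length(subjects),
    n_excluded = length(excluded),
    package_version = as.character(utils::packageVersion("dynstates")),
    log = log_lines)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, model = model, metrics = metrics,
                 graph_metrics = gm, modulation = mod, contrast = contrast,
                 predictors = preds, comparison = comp, out_dir = out_dir,
                 excluded = excluded))
}
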