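#' Pipeline configuration
#'
#' Bundles everything one analysis run needs: the cohort configuration,
#' which regression models to fit, the output directory (optional; when
#' `NULL` nothing is written), and the master seed.
#'
#' @param cohort a [cohort_config()].
#' @param models names from [latent_effects()] selecting the
#'   cell-level regressions to fit.
#' @param out_dir output directory for the results bundle, or `NULL`.
#' @param seed master seed; overrides the cohort config's seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            models = names(latent_effects()),
                            out_dir = NULL, seed = cohort$seed) {
  cohort$seed <- seed
  structure(list(cohort = cohort, models = models, out_dir = out_dir,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, scores the recognizer channel
#' against the presented sentences, imputes unrecorded sentences,
#' computes per-sentence timing, aggregates to participant x
#' masker-type x SNR cells, fits the stepwise regression models, and
#' computes agreement (examiner vs recognizer ICC) and per-participant
#' correlations between the timing measures and the rank-normalized
#' effort ratings.  With an output directory the bundle is written as
#' CSV/CTM/JSON files; the run is fully determined by the master seed.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally a pre-built [simulate_cohort()] result.
#' @return list of class `pipeline_result` with elements `cohort`,
#'   `scores`, `timing`, `cells`, `fits`, `icc`, `correlations`,
#'   `collinearity`, `srt_summary`, `n_imputed`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  cohort <- cohort %||% simulate_cohort(config$cohort)
  trials <- cohort$trials
  vocab <- matrix_vocabulary()

  # --- scoring ------------------------------------------------------
  asr_raw <- score_trials(trials, cohort$tokens, vocab,
                          status = cohort$outcomes$status)
  imp <- impute_unrecorded(asr_raw, cohort$outcomes$manual_n_correct,
                           paste(trials$listener_id, trials$block_id,
                                 sep = "__"))
  scores <- data.frame(listener_id = trials$listener_id,
                       block_id = trials$block_id,
                       sentence_index = trials$sentence_index,
                       asr_n_correct = imp$scores,
                       manual_n_correct = cohort$outcomes$manual_n_correct,
                       status = cohort$outcomes$status,
                       stringsAsFactors = FALSE)

  # --- timing -------------------------------------------------------
  timing <- timing_table(cohort$tokens, trials)

  # --- aggregation --------------------------------------------------
  cells <- aggregate_cells(trials, scores, cohort$ratings, timing)

  # --- regression models -------------------------------------------
  cell_data <- cells
  cell_data$srle_rank_individual <- cells$srle_mean_rank_individual
  fits <- lapply(config$models, function(m) {
    spec <- latent_effects()[[m]]
    fit_stepwise(cell_data, spec$response, spec$predictors)
  })
  names(fits) <- config$models
  coll <- collinearity_check(
    cell_data[, c("snr_re_srt", "srle_rank_individual", "masker_type",
                  "group")])

  # --- examiner vs recognizer agreement ----------------------------
  manual_filled <- ifelse(is.na(scores$manual_n_correct),
                          scores$asr_n_correct, scores$manual_n_correct)
  cell_f <- interaction(trials$listener_id, trials$masker_type,
                        trials$snr_re_srt, drop = TRUE)
  asr_cell <- tapply(scores$asr_n_correct, cell_f, mean) * 20
  man_cell <- tapply(manual_filled, cell_f, mean) * 20
  icc_scores <- icc_absolute_agreement(as.numeric(man_cell),
                                       as.numeric(asr_cell))
  vrt_man_cell <- tapply(cohort$outcomes$vrt_manual_s, cell_f,
                         function(v) median(v, na.rm = TRUE))
  vrt_asr_cell <- tapply(timing$vrt_s, cell_f,
                         function(v) median(v, na.rm = TRUE))
  icc_vrt <- icc_absolute_agreement(as.numeric(vrt_man_cell),
                                    as.numeric(vrt_asr_cell))

  # --- per-participant correlations --------------------------------
  cor_vrt <- per_participant_pearson(cells$z_logvrt_mean,
                                     cells$srle_mean_rank_individual,
                                     cells$listener_id)
  cor_rsr <- per_participant_pearson(cells$z_rsr_mean,
                                     cells$srle_mean_rank_individual,
                                     cells$listener_id)

  # --- SRT summary --------------------------------------------------
  srt_rows <- lapply(cohort$listeners, function(li) {
    data.frame(listener_id = li$listener_id, group = li$group,
               masker_id = names(li$srt_per_masker),
               srt_db = as.numeric(li$srt_per_masker),
               stringsAsFactors = FALSE)
  })
  srt <- do.call(rbind, srt_rows)
  srt_summary <- aggregate(srt_db ~ group + masker_id, data = srt, FUN = mean)

  result <- structure(list(
    cohort = cohort, scores = scores, timing = timing, cells = cells,
    fits = fits, icc = list(scores = icc_scores, vrt = icc_vrt),
    correlations = list(vrt_vs_srle = cor_vrt, rsr_vs_srle = cor_rsr),
    collinearity = coll, srt_summary = srt_summary,
    n_imputed = imp$n_imputed,
    manifest = list(seed = config$seed, n_trials = nrow(trials),
                    n_cells = nrow(cells),
                    n_complete = sum(cohort$outcomes$status == "complete"),
                    models = config$models,
                    package_version = as.character(
                      utils::packageVersion("vrteffort")))),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_bundle(result, config$out_dir)
  result
}

write_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_table(result$cohort$trials, p("trials.csv"))
  write_table(result$cohort$ratings, p("ratings.csv"))
  write_table(result$scores, p("scores.csv"))
  write_table(result$timing, p("timing.csv"))
  write_table(result$cells, p("aggregate.csv"))
  tok <- result$cohort$tokens
  writeLines(sprintf("%s__%s__%d 1 %.2f %.2f %s", tok$listener_id,
                     tok$block_id, tok$sentence_index, tok$onset_s,
                     tok$duration_s, tok$token),
             p("alignments.ctm"))
  coefs <- do.call(rbind, lapply(names(result$fits), function(m) {
    cbind(model = m, result$fits[[m]]$coefficients)
  }))
  write_table(coefs, p("models.csv"))
  write_table(do.call(rbind, lapply(result$correlations, function(cc)
    cc$per_participant)), p("correlations.csv"))
  write_table(result$srt_summary, p("srt_summary.csv"))
  jsonlite::write_json(
    c(result$manifest,
      list(icc_scores = result$icc$scores$icc, icc_vrt = result$icc$vrt$icc,
           n_imputed = result$n_imputed)),
    p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Human-readable run summary
#'
#' Renders the pipeline result as a markdown-style text report: data
#' volume, SRT summary, examiner-vs-recognizer agreement, one section
#' per regression model, and the per-participant correlation summary.
#'
#' @param result a [run_pipeline()] result.
#' @return character vector of report lines (invisibly printed by
#'   `cat`ing when assigned to a file).
#' @export
pipeline_report <- function(result) {
  required <- c("cells", "fits", "icc", "correlations", "manifest")
  missing <- required[!vapply(required, function(f)
    !is.null(result[[f]]), TRUE)]
  if (length(missing))
    stop_vrt("incomplete results bundle; missing: %s",
             paste(missing, collapse = ", "))
  fmt_fit <- function(name, fit) {
    tab <- fit$coefficients
    c(sprintf("## Model %s (response: %s)", name, fit$response),
      sprintf("- entered: %s",
              if (length(fit$entry_order))
                paste(fit$entry_order, collapse = ", ") else "none"),
      sprintf("- %s: beta = %.3f (SE %.3f, std beta %.3f, CI %.3f..%.3f, p = %.3g)%s",
              tab$predictor, tab$beta, tab$se, tab$std_beta,
              tab$ci_lower, tab$ci_upper, tab$p,
              ifelse(tab$entered, "", " [not entered]")),
      sprintf("- adj. R2 = %.3f, F(%g, %g) = %.2f, Durbin-Watson d = %.2f",
              fit$model$adj_r2, fit$model$df1, fit$model$df2,
              fit$model$f, fit$model$durbin_watson), "")
  }
  lines <- c(
    "# Speech-audiometry response analysis",
    sprintf("- trials: %d (%d complete), aggregate cells: %d, seed: %s",
            result$manifest$n_trials, result$manifest$n_complete,
            result$manifest$n_cells, result$manifest$seed),
    sprintf("- unrecorded sentences imputed: %d", result$n_imputed), "",
    "## Mean SRT per masker and group (dB SNR)",
    sprintf("- %s %s: %.1f", result$srt_summary$group,
            result$srt_summary$masker_id, result$srt_summary$srt_db), "",
    "## Examiner vs recognizer agreement",
    sprintf("- speech-recognition scores: ICC(A,1) = %.3f",
            result$icc$scores$icc),
    sprintf("- VRT: ICC(A,1) = %.3f", result$icc$vrt$icc), "",
    unlist(lapply(names(result$fits), function(m)
      fmt_fit(m, result$fits[[m]]))),
    "## Per-participant correlations with rank-normalized effort",
    sprintf("- z log-VRT: r in %.3f..%.3f (mean %.3f)",
            result$correlations$vrt_vs_srle$summary$min,
            result$correlations$vrt_vs_srle$summary$max,
            result$correlations$vrt_vs_srle$summary$mean),
    sprintf("- z RSR: r in %.3f..%.3f (mean %.3f)",
            result$correlations$rsr_vs_srle$summary$min,
            result$correlations$rsr_vs_srle$summary$max,
            result$correlations$rsr_vs_srle$summary$mean))
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}
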