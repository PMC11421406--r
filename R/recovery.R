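#' Default generating effects for the latent-linear simulator
#'
#' The latent-linear mode draws analysis cells directly from linear
#' models in SNR re SRT, masker type (1 = fluctuating, 2 = stationary),
#' and group (1 = NH, 2 = HI).  The five default models cover the
#' pipeline's response measures — RAU-transformed recognition score
#' regressed on SNR (`rau_on_snr`) or on individually rank-normalized
#' effort (`rau_on_srle`), rank-normalized effort (`srle_on_snr`), and
#' within-participant z-transformed log-VRT (`zlogvrt_on_snr`) and RSR
#' (`zrsr_on_snr`) — with effect sizes and explained variance
#' representative of matrix-test listening-effort studies.  The residual
#' SD of each model is calibrated from its adjusted R-squared on the
#' realized design: `sd^2 = Var(linear predictor) * (1 - R2) / R2`.
#'
#' @return named list of model specifications (`predictors`, `beta`,
#'   `adj_r2`, `center`, and rounding digits per coefficient).
#' @export
latent_effects <- function() {
  list(
    rau_on_snr = list(
      response = "rau_score",
      predictors = c("snr_re_srt", "masker_type", "group"),
      beta = c(snr_re_srt = 3.813, masker_type = 13.390, group = -0.845),
      adj_r2 = 0.719, center = 50,
      digits = c(snr_re_srt = 1, masker_type = 1, group = 1)),
    srle_on_snr = list(
      response = "srle_rank_individual",
      predictors = c("snr_re_srt", "masker_type", "group"),
      beta = c(snr_re_srt = -0.174, masker_type = -0.663, group = 0.070),
      adj_r2 = 0.813, center = 0,
      digits = c(snr_re_srt = 2, masker_type = 2, group = 2)),
    rau_on_srle = list(
      response = "rau_score",
      predictors = c("srle_rank_individual", "masker_type", "group"),
      beta = c(srle_rank_individual = -20.349, masker_type = -0.094,
               group = 0.587),
      adj_r2 = 0.782, center = 50,
      digits = c(srle_rank_individual = 1, masker_type = 1, group = 1)),
    zlogvrt_on_snr = list(
      response = "z_logvrt_mean",
      predictors = c("snr_re_srt", "masker_type", "group"),
      beta = c(snr_re_srt = -0.183, masker_type = -0.679, group = 0.000),
      adj_r2 = 0.798, center = 0,
      digits = c(snr_re_srt = 2, masker_type = 2, group = 2)),
    zrsr_on_snr = list(
      response = "z_rsr_mean",
      predictors = c("snr_re_srt", "masker_type", "group"),
      beta = c(snr_re_srt = 0.157, masker_type = 0.414, group = 0.000),
      adj_r2 = 0.538, center = 0,
      digits = c(snr_re_srt = 2, masker_type = 2, group = 2)))
}

# Cell-level design: one row per listener x masker type x SNR.
cell_design <- function(n_nh = 15L, n_hi = 12L,
                        snr_offsets = c(0, 3, 6, 9, 12)) {
  listeners <- data.frame(
    listener_id = c(sprintf("NH%02d", seq_len(n_nh)),
                    sprintf("HI%02d", seq_len(n_hi))),
    group = rep(c(1L, 2L), c(n_nh, n_hi)), stringsAsFactors = FALSE)
  cells <- expand.grid(listener_id = listeners$listener_id,
                       masker_type = c(1L, 2L), snr_re_srt = snr_offsets,
                       stringsAsFactors = FALSE)
  cells$group <- listeners$group[match(cells$listener_id,
                                       listeners$listener_id)]
  cells[order(cells$listener_id, cells$masker_type, cells$snr_re_srt), ,
        drop = FALSE]
}

#' Simulate analysis cells from a latent linear model
#'
#' Draws the participant x masker-type x SNR aggregate cells (270 with
#' the default 27 listeners) directly from one of the [latent_effects()]
#' models: response = intercept + X beta + Gaussian residual, with the
#' residual SD calibrated from the model's adjusted R-squared on the
#' realized design (or overridden).  For the model with the effort
#' rating as predictor, the rating itself is first generated from the
#' effort-on-SNR model so its correlation structure with SNR and masker
#' type is realistic.
#'
#' @param model a name from [latent_effects()] or a specification list
#'   of the same shape.
#' @param n_nh,n_hi group sizes.
#' @param snr_offsets SNRs re SRT.
#' @param seed RNG seed.
#' @param resid_sd residual SD override; 0 gives the noiseless limit.
#' @return data.frame of cells with the predictors, the response in
#'   column `y`, and the generating truth in attributes `truth` and
#'   `resid_sd`.
#' @export
simulate_latent_cells <- function(model = "rau_on_snr", n_nh = 15L,
                                  n_hi = 12L, snr_offsets = c(0, 3, 6, 9, 12),
                                  seed = 1L, resid_sd = NULL) {
  spec <- if (is.character(model)) {
    all <- latent_effects()
    if (!model %in% names(all))
      stop_vrt("unknown latent model '%s'", model)
    all[[model]]
  } else model
  cells <- cell_design(n_nh, n_hi, snr_offsets)
  with_seed(seed, {
    if ("srle_rank_individual" %in% spec$predictors) {
      b <- latent_effects()$srle_on_snr
      xb <- b$beta[["snr_re_srt"]] * cells$snr_re_srt +
        b$beta[["masker_type"]] * cells$masker_type +
        b$beta[["group"]] * cells$group
      sd_b <- calibrated_sd(xb, b$adj_r2)
      cells$srle_rank_individual <- (xb - mean(xb)) + rnorm(nrow(cells), 0, sd_b)
    }
    x <- as.matrix(cells[, spec$predictors, drop = FALSE])
    lp <- drop(x %*% spec$beta[spec$predictors])
    sd_e <- resid_sd %||% calibrated_sd(lp, spec$adj_r2)
    intercept <- spec$center - mean(lp)
    cells$y <- intercept + lp + rnorm(nrow(cells), 0, sd_e)
  })
  rownames(cells) <- NULL
  attr(cells, "truth") <- spec$beta
  attr(cells, "resid_sd") <- if (is.null(resid_sd))
    calibrated_sd_of(cells, spec) else resid_sd
  cells
}

calibrated_sd <- function(lp, adj_r2) {
  sqrt(var(lp) * (1 - adj_r2) / adj_r2)
}

calibrated_sd_of <- function(cells, spec) {
  x <- as.matrix(cells[, spec$predictors, drop = FALSE])
  calibrated_sd(drop(x %*% spec$beta[spec$predictors]), spec$adj_r2)
}

#' Coefficient-recovery experiment
#'
#' Repeatedly simulates latent-linear cells from a generating model and
#' refits the stepwise regression, returning the recovered coefficient
#' of every candidate per replicate together with the generating truth.
#' Used to verify that the pipeline's regression stage recovers known
#' effects at the design's sample size, and by the acceptance script.
#'
#' @param model model name (see [latent_effects()]).
#' @param n_seeds number of replicates.
#' @param seed master seed (replicate seeds are derived from it).
#' @param n_nh,n_hi,snr_offsets design parameters.
#' @return list with `estimates` (data.frame: seed index x predictor
#'   estimates), `truth`, `median` (named medians), and `digits`.
#' @export
recover_coefficients <- function(model = "rau_on_snr", n_seeds = 100L,
                                 seed = 1L, n_nh = 15L, n_hi = 12L,
                                 snr_offsets = c(0, 3, 6, 9, 12)) {
  spec <- latent_effects()[[model]]
  if (is.null(spec)) stop_vrt("unknown latent model '%s'", model)
  preds <- spec$predictors
  est <- matrix(NA_real_, n_seeds, length(preds),
                dimnames = list(NULL, preds))
  for (s in seq_len(n_seeds)) {
    cells <- simulate_latent_cells(model, n_nh, n_hi, snr_offsets,
                                   seed = derive_seed(seed, 7L, s))
    fit <- fit_stepwise(cells, "y", preds)
    est[s, ] <- fit$coefficients$beta[match(preds,
                                            fit$coefficients$predictor)]
  }
  list(estimates = as.data.frame(est),
       truth = spec$beta[preds],
       median = apply(est, 2L, median),
       digits = spec$digits[preds],
       model = model, n_seeds = n_seeds,
       n_cells = (n_nh + n_hi) * 2L * length(snr_offsets))
}
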