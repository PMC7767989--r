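#' Fit the mixture model and summarize the posterior
#'
#' Runs [run_mcmc()], computes split-Rhat for every parameter, posterior
#' responsibilities and signal/noise labels (strict 0.5 rule), and posterior
#' means.
#'
#' @param dataset A [pet_dataset()].
#' @param config A [mcmc_config()].
#' @return An object of class `pet_fit`: `draws`, `rhat` (full precision),
#'   `rhat_2dp` (rounded to 2 decimals, the reporting convention),
#'   `responsibility`, `labels`, `posterior_means` and `converged`
#'   (all Rhat < 1.05).
#' @export
fit_interactions <- function(dataset, config = mcmc_config()) {
  draws <- run_mcmc(dataset, config)
  rh <- rhat_all(draws)
  resp <- posterior_responsibility(draws, dataset)
  flat <- flatten_draws(draws)
  structure(list(
    draws = draws,
    rhat = rh,
    rhat_2dp = round(rh, 2),
    responsibility = resp,
    labels = classify(resp),
    posterior_means = colMeans(flat),
    converged = all(rh < 1.05),
    dataset_n = nrow(dataset$pairs)), class = "pet_fit")
}

#' @export
print.pet_fit <- function(x, ...) {
  cat(sprintf("<pet_fit> %d pairs, %d signal / %d noise, max Rhat %.3f (%s)\n",
              x$dataset_n, sum(x$labels == "signal"),
              sum(x$labels == "noise"), max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Central credible intervals of the link coefficients and signal offset
#'
#' @param fit A `pet_fit` object.
#' @param level Credible level (default 0.95).
#' @return Data frame with columns `parameter`, `mean`, `lower`, `upper`.
#' @export
credible_intervals <- function(fit, level = 0.95) {
  flat <- flatten_draws(fit$draws)
  keep <- c(paste0("beta", 0:(fit$draws$p - 1)), "C")
  qs <- apply(flat[, keep, drop = FALSE], 2, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2))
  data.frame(parameter = keep,
             mean = colMeans(flat[, keep, drop = FALSE]),
             lower = qs[1, ], upper = qs[2, ], row.names = NULL)
}

#' Significant interactions passing the convergence gate and report filter
#'
#' Emits the signal-labelled pairs with at least `min_count` supporting
#' PETs (the reporting convention for comparing interaction sets). By
#' default the function refuses to emit labels from a fit whose Rhat
#' diagnostics exceed 1.05; set `override_rhat_gate = TRUE` to bypass.
#'
#' @param fit A `pet_fit` object.
#' @param dataset The fitted [pet_dataset()].
#' @param min_count Reporting cut-off on the PET count (default 3).
#' @param override_rhat_gate Emit labels even from a non-converged fit.
#' @return Data frame of significant pairs with responsibilities.
#' @export
significant_interactions <- function(fit, dataset, min_count = 3L,
                                     override_rhat_gate = FALSE) {
  if (min_count < dataset$k)
    stop("`min_count` must be at least the truncation point k")
  if (!fit$converged && !override_rhat_gate)
    stop(sprintf(paste0("convergence gate: max Rhat = %.4f >= 1.05; refusing ",
                        "to emit labels (set override_rhat_gate = TRUE to force)"),
                 max(fit$rhat)))
  keep <- fit$labels == "signal" & dataset$pairs$count >= min_count
  out <- dataset$pairs[keep, c("chrom_a", "start_a", "end_a", "chrom_b",
                               "start_b", "end_b", "pair_id", "count")]
  out$responsibility <- fit$responsibility[keep]
  out[order(out$chrom_a, out$start_a, out$chrom_b, out$start_b), ,
      drop = FALSE]
}
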