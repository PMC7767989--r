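#' Sampler configuration
#'
#' @param chains Number of independent chains (at least 2; default 4, the
#'   usual convergence-diagnostic recommendation).
#' @param warmup Adaptation iterations discarded per chain.
#' @param iter Kept iterations per chain.
#' @param seed Master seed; chain `c` uses `seed * 1009 + c`, so different
#'   master seeds never share chain streams.
#' @param step_beta,step_C Initial random-walk scales (adapted in warmup).
#' @param intercept_only If `TRUE`, all slope coefficients are fixed at 0
#'   and only the intercept is sampled (used for small-instance validation
#'   against numerical integration).
#' @param sample_w1 If `FALSE`, the mixing weights are held fixed at
#'   `w1_fixed` (default: their Beta prior means) instead of being sampled.
#' @param w1_fixed Optional fixed weight vector when `sample_w1 = FALSE`.
#' @return A list of class `pet_mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, warmup = 1000L, iter = 1000L, seed = 1L,
                        step_beta = 0.1, step_C = 0.2,
                        intercept_only = FALSE, sample_w1 = TRUE,
                        w1_fixed = NULL) {
  if (chains < 2L) stop("`chains` must be at least 2")
  if (iter < 4L) stop("`iter` must be at least 4 kept iterations")
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed),
                 step_beta = step_beta, step_C = step_C,
                 intercept_only = isTRUE(intercept_only),
                 sample_w1 = isTRUE(sample_w1), w1_fixed = w1_fixed),
            class = "pet_mcmc_config")
}

#' Sample the mixture-model posterior by MCMC
#'
#' Adaptive Metropolis-within-Gibbs targeting the marginalized posterior of
#' `(beta, C, w1)` (see [log_posterior()]): the coefficient block `beta`
#' moves by multivariate random-walk Metropolis whose scale and proposal
#' covariance are adapted during warmup; `C` moves on the log scale (with
#' the Jacobian correction); each `w1_i` has an exact conjugate Gibbs draw,
#' because a Beta(`mc_i`, `mc_bar`) prior times the two-term mixture
#' likelihood is a two-component Beta mixture with odds
#' `(mc_i / mc_bar) * p1 / p0`.
#'
#' Runs are exactly reproducible: identical dataset, configuration and seed
#' give bit-identical draws.
#'
#' @param dataset A [pet_dataset()].
#' @param config A [mcmc_config()].
#' @return An object of class `pet_draws`: list with `draws` (array
#'   `iter x chains x parameter` with dimnames), `accept` (per-chain
#'   acceptance rates for beta and C), and the configuration.
#' @export
run_mcmc <- function(dataset, config = mcmc_config()) {
  stopifnot(inherits(dataset, "pet_dataset"), inherits(config, "pet_mcmc_config"))
  X <- link_design_matrix(dataset$covariates, dataset$interaction_class)
  Xc <- X
  to_beta <- identity
  y <- dataset$pairs$count
  k <- dataset$k
  n <- length(y)
  p <- ncol(X)
  a_w <- dataset$covariates$mc        # Beta prior shape 1 per pair
  b_w <- dataset$mc_bar               # shape 2, shared
  w_prior_mean <- a_w / (a_w + b_w)
  log_odds_prior <- log(a_w) - log(b_w)  # B(a+1,b)/B(a,b+1) = a/b
  free <- if (config$intercept_only) 1L else seq_len(p)
  sample_w1 <- config$sample_w1

  par_names <- c(paste0("beta", 0:(p - 1)), "C", paste0("w1[", seq_len(n), "]"))
  draws <- array(NA_real_,
                 dim = c(config$iter, config$chains, p + 1L + n),
                 dimnames = list(NULL, paste0("chain", seq_len(config$chains)),
                                 par_names))
  accept <- matrix(0, config$chains, 2,
                   dimnames = list(NULL, c("beta", "C")))

  for (ch in seq_len(config$chains)) {
    set.seed(config$seed * 1009L + ch)
    st <- init_chain(Xc, y, k, a_w, b_w, w_prior_mean, config, free)
    ls_beta <- log(config$step_beta)
    ls_C <- log(config$step_C)
    chol_prop <- NULL                  # proposal covariance factor (warmup)
    hist_beta <- matrix(NA_real_, config$warmup, length(free))
    acc_b <- 0; acc_c <- 0; n_kept <- 0
    total <- config$warmup + config$iter

    for (t in seq_len(total)) {
      adapting <- t <= config$warmup
      # several Metropolis sweeps of (beta, C) per w1 Gibbs draw: the
      # random-walk block mixes slower than the conjugate weights, so it
      # gets proportionally more work
      for (sweep in 1:3) {

      ## -- coefficient block (random-walk Metropolis on gamma) --
      eps <- stats::rnorm(length(free))
      delta <- if (is.null(chol_prop)) exp(ls_beta) * eps
               else exp(ls_beta) * drop(chol_prop %*% eps)
      gamma_p <- st$gamma
      gamma_p[free] <- gamma_p[free] + delta
      lam0_p <- as.vector(exp(Xc %*% gamma_p))
      ll_p <- chain_loglik(y, lam0_p, st$C, st$w1, k)
      la <- sum(ll_p$m) - sum(st$m) +
        sum(stats::dnorm(to_beta(gamma_p), 0, 3, log = TRUE)) -
        sum(stats::dnorm(to_beta(st$gamma), 0, 3, log = TRUE))
      alpha <- if (is.finite(la)) min(1, exp(la)) else 0
      if (stats::runif(1) < alpha) {
        st$gamma <- gamma_p; st$lam0 <- lam0_p
        st$lp0 <- ll_p$lp0; st$lp1 <- ll_p$lp1; st$m <- ll_p$m
        if (!adapting) acc_b <- acc_b + 1
      }
      if (adapting) {
        ls_beta <- ls_beta + t^-0.6 * (alpha - 0.25)
        hist_beta[t, ] <- st$gamma[free]
        if (length(free) > 1L &&
            t %in% floor(config$warmup * c(0.5, 0.75))) {
          span <- max(1L, floor(t / 2)):t   # drop early transient
          S <- stats::cov(hist_beta[span, , drop = FALSE])
          S <- S + diag(1e-8, ncol(S))
          chol_prop <- t(chol(S))
          ls_beta <- log(2.38 / sqrt(length(free)))
        }
      }

      ## -- C (log-scale random-walk Metropolis) --
      logC_p <- log(st$C) + exp(ls_C) * stats::rnorm(1)
      C_p <- exp(logC_p)
      ll_p <- chain_loglik(y, st$lam0, C_p, st$w1, k)
      la <- sum(ll_p$m) - sum(st$m) +
        stats::dnorm(C_p, 0, 3, log = TRUE) -
        stats::dnorm(st$C, 0, 3, log = TRUE) +
        logC_p - log(st$C)             # Jacobian of the log transform
      alpha <- if (is.finite(la)) min(1, exp(la)) else 0
      if (stats::runif(1) < alpha) {
        st$C <- C_p; st$lp1 <- ll_p$lp1; st$m <- ll_p$m
        if (!adapting) acc_c <- acc_c + 1
      }
      if (adapting) ls_C <- ls_C + t^-0.6 * (alpha - 0.44)

      } # end beta/C sweeps

      ## -- w1 (exact conjugate Gibbs) --
      if (sample_w1) {
        q1 <- stats::plogis(st$lp1 - st$lp0 + log_odds_prior)
        zz <- stats::rbinom(n, 1L, q1)
        w1 <- stats::rbeta(n, a_w + zz, b_w + 1 - zz)
        st$w1 <- pmin(pmax(w1, 1e-12), 1 - 1e-12)
        st$m <- logsumexp2(log1p(-st$w1) + st$lp0, log(st$w1) + st$lp1)
      }

      if (!adapting) {
        n_kept <- n_kept + 1L
        draws[n_kept, ch, ] <- c(to_beta(st$gamma), st$C, st$w1)
      }
    }
    accept[ch, ] <- c(acc_b, acc_c) / (3 * config$iter)
  }

  structure(list(draws = draws, accept = accept, config = config,
                 n_params = p + 1L + n, p = p, n = n),
            class = "pet_draws")
}

## component log-pmfs and per-pair marginal mixture log-likelihood
chain_loglik <- function(y, lam0, C, w1, k) {
  lam1 <- lam0 + C
  lp0 <- stats::dpois(y, lam0, log = TRUE)
  lp1 <- stats::dpois(y, lam1, log = TRUE)
  if (k > 0) {
    lp0 <- lp0 - stats::ppois(k - 1, lam0, lower.tail = FALSE, log.p = TRUE)
    lp1 <- lp1 - stats::ppois(k - 1, lam1, lower.tail = FALSE, log.p = TRUE)
  }
  list(lp0 = lp0, lp1 = lp1,
       m = logsumexp2(log1p(-w1) + lp0, log(w1) + lp1))
}

init_chain <- function(Xc, y, k, a_w, b_w, w_prior_mean, config, free) {
  for (attempt in 1:20) {
    gamma <- numeric(ncol(Xc))
    gamma[free] <- stats::rnorm(length(free), 0, 0.1)
    C <- exp(stats::rnorm(1, 0, 0.1))   # near C = 1
    if (config$sample_w1) {
      w1 <- stats::plogis(stats::qlogis(w_prior_mean) +
                            stats::rnorm(length(y), 0, 0.1))
    } else {
      w1 <- if (is.null(config$w1_fixed)) w_prior_mean else config$w1_fixed
    }
    w1 <- pmin(pmax(w1, 1e-12), 1 - 1e-12)
    lam0 <- as.vector(exp(Xc %*% gamma))
    ll <- chain_loglik(y, lam0, C, w1, k)
    if (all(is.finite(ll$m)))
      return(list(gamma = gamma, C = C, w1 = w1, lam0 = lam0,
                  lp0 = ll$lp0, lp1 = ll$lp1, m = ll$m))
  }
  stop("could not find a finite log-posterior initialization after 20 attempts; ",
       "check the dataset for degenerate covariates")
}

#' @export
print.pet_draws <- function(x, ...) {
  cat(sprintf("<pet_draws> %d chains x %d kept iterations, %d parameters (beta: %d, w1: %d)\n",
              x$config$chains, x$config$iter, x$n_params, x$p, x$n))
  cat(sprintf("  mean acceptance: beta %.2f, C %.2f\n",
              mean(x$accept[, "beta"]), mean(x$accept[, "C"])))
  invisible(x)
}

#' Split-chain potential scale reduction (Rhat)
#'
#' Each chain is halved, then the classic between/within variance ratio is
#' computed over the `2 * chains` half-chains. A parameter with zero total
#' variance (e.g. one held fixed) returns exactly 1.
#'
#' @param draws A `pet_draws` object (or an `iter x chains` matrix).
#' @param parameter Parameter name (e.g. `"beta0"`, `"C"`, `"w1[7]"`);
#'   ignored when `draws` is already a matrix.
#' @return Scalar Rhat.
#' @export
compute_rhat <- function(draws, parameter = NULL) {
  m <- if (is.matrix(draws)) draws else {
    if (is.null(parameter)) stop("`parameter` is required")
    draws$draws[, , parameter]
  }
  if (ncol(m) < 2L) stop("Rhat needs at least 2 chains")
  if (nrow(m) < 4L) stop("Rhat needs at least 4 kept iterations per chain")
  half <- floor(nrow(m) / 2)
  split <- cbind(m[seq_len(half), , drop = FALSE],
                 m[(nrow(m) - half + 1):nrow(m), , drop = FALSE])
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0 && B == 0) return(1)
  if (W == 0) return(Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Rhat for every parameter of a fit
#'
#' @param draws A `pet_draws` object.
#' @return Named numeric vector of split-Rhat values.
#' @export
rhat_all <- function(draws) {
  stopifnot(inherits(draws, "pet_draws"))
  vapply(dimnames(draws$draws)[[3]],
         function(pn) compute_rhat(draws$draws[, , pn]),
         numeric(1))
}

#' Posterior probability that each pair is true signal
#'
#' Rao-Blackwellized responsibility: for every kept draw the exact
#' conditional `P(Z_i = 1 | Y, params)` is computed from the two component
#' pmfs and the drawn weight, and the values are averaged over draws.
#'
#' @param draws A `pet_draws` object from [run_mcmc()].
#' @param dataset The [pet_dataset()] that was fitted.
#' @return Numeric vector of probabilities in `[0, 1]`, one per pair.
#' @export
posterior_responsibility <- function(draws, dataset) {
  stopifnot(inherits(draws, "pet_draws"), inherits(dataset, "pet_dataset"))
  X <- link_design_matrix(dataset$covariates, dataset$interaction_class)
  y <- dataset$pairs$count
  k <- dataset$k
  p <- draws$p
  flat <- flatten_draws(draws)
  total <- nrow(flat)
  r_sum <- numeric(length(y))
  chunk <- 250L
  for (s in seq(1L, total, by = chunk)) {
    idx <- s:min(s + chunk - 1L, total)
    r_sum <- r_sum + colSums(responsibility_at(flat[idx, , drop = FALSE],
                                               X, y, k, p))
  }
  unname(r_sum / total)
}

## draws: rows = draws, cols = params; returns draws x pairs matrix of r_i
responsibility_at <- function(flat, X, y, k, p) {
  nd <- nrow(flat)
  beta <- flat[, seq_len(p), drop = FALSE]
  C <- flat[, p + 1L]
  w1 <- flat[, -(seq_len(p + 1L)), drop = FALSE]
  lam0 <- exp(beta %*% t(X))              # draws x pairs
  lam1 <- lam0 + C
  ym <- matrix(y, nd, length(y), byrow = TRUE)
  lp0 <- stats::dpois(ym, lam0, log = TRUE)
  lp1 <- stats::dpois(ym, lam1, log = TRUE)
  if (k > 0) {
    lp0 <- lp0 - stats::ppois(k - 1, lam0, lower.tail = FALSE, log.p = TRUE)
    lp1 <- lp1 - stats::ppois(k - 1, lam1, lower.tail = FALSE, log.p = TRUE)
  }
  stats::plogis(log(w1) - log1p(-w1) + lp1 - lp0)
}

## collapse (iter, chain, param) to (iter*chain, param)
flatten_draws <- function(draws) {
  d <- draws$draws
  matrix(aperm(d, c(1, 2, 3)),
         nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3],
         dimnames = list(NULL, dimnames(d)[[3]]))
}

#' Label pairs as signal or noise
#'
#' A pair is called signal when its posterior responsibility strictly
#' exceeds the threshold (default 0.5); a responsibility exactly at the
#' threshold is noise.
#'
#' @param responsibility Probabilities in `[0, 1]`.
#' @param threshold Decision cut-off in `[0, 1]`.
#' @return Character vector of `"signal"` / `"noise"`.
#' @export
classify <- function(responsibility, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("`threshold` must lie in [0, 1]")
  if (any(responsibility < 0 | responsibility > 1))
    stop("responsibilities must lie in [0, 1]")
  ifelse(responsibility > threshold, "signal", "noise")
}

#' Posterior predictive count replicates
#'
#' For each of `n_rep` randomly selected kept draws, a replicate dataset is
#' simulated from the model at the drawn parameters: a signal indicator per
#' pair, then a truncated-Poisson count at the selected rate. Used for
#' graphical posterior predictive checks against the observed counts.
#'
#' @param draws A `pet_draws` object.
#' @param dataset The fitted [pet_dataset()].
#' @param n_rep Number of replicate vectors.
#' @param seed Optional seed for reproducible replicates.
#' @return Integer matrix `n_rep x n_pairs`; all entries are `>= k`.
#' @export
posterior_predictive <- function(draws, dataset, n_rep = 100L, seed = NULL) {
  stopifnot(n_rep >= 1)
  if (!is.null(seed)) set.seed(seed)
  X <- link_design_matrix(dataset$covariates, dataset$interaction_class)
  y <- dataset$pairs$count
  n <- length(y)
  p <- draws$p
  flat <- flatten_draws(draws)
  pick <- sample.int(nrow(flat), n_rep, replace = n_rep > nrow(flat))
  out <- matrix(NA_integer_, n_rep, n)
  for (r in seq_len(n_rep)) {
    th <- flat[pick[r], ]
    lam0 <- as.vector(exp(X %*% th[seq_len(p)]))
    lam1 <- lam0 + th[p + 1L]
    w1 <- th[-(seq_len(p + 1L))]
    z <- stats::rbinom(n, 1L, w1)
    out[r, ] <- rtpois(n, ifelse(z == 1L, lam1, lam0), dataset$k)
  }
  out
}
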