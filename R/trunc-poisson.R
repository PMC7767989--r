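#' (k-1)-truncated Poisson log probability mass function
#'
#' Log-density of a Poisson random variable conditioned on `y >= k`,
#' renormalized by the upper tail probability `P(Y >= k) = 1 - F(k-1)`.
#' With `k = 0` this is the ordinary Poisson log-pmf; with `k = 2` it is the
#' count model used for ChIA-PET inter-ligation PET frequencies, where
#' singleton pairs are discarded upstream.
#'
#' All computation stays in log space: the tail normalizer uses the Poisson
#' log-survival function, so rates well beyond 50 and counts beyond 500 are
#' handled without overflow.
#'
#' @param y Non-negative integer count(s), each `>= k`.
#' @param lambda Positive Poisson rate(s), recycled against `y`.
#' @param k Truncation point (counts below `k` have zero probability).
#'   Default 2, the usual ChIA-PET cluster cut-off.
#' @param log If `TRUE` (default) return the log-pmf, else the pmf.
#' @return Numeric vector of (log-)probabilities.
#' @examples
#' dtpois(2, lambda = 1, k = 2)           # 0.5 / (e - 2)
#' dtpois(0:5, lambda = 2, k = 0, log = FALSE)  # plain Poisson
#' @export
dtpois <- function(y, lambda, k = 2L, log = TRUE) {
  if (length(k) != 1L || is.na(k) || k < 0 || k != floor(k))
    stop("`k` must be a single non-negative integer")
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("`lambda` must be strictly positive")
  if (any(y < k))
    stop("all `y` must be >= k (support of the truncated distribution)")
  lp <- stats::dpois(y, lambda, log = TRUE)
  if (k > 0)
    lp <- lp - stats::ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  if (log) lp else exp(lp)
}

#' Log-likelihood of one count under the two-component truncated mixture
#'
#' Evaluates `log[(1 - w1) p(y | lambda0, k) + w1 p(y | lambda1, k)]` with
#' both components (k-1)-truncated Poisson, via log-sum-exp. The signal rate
#' must strictly exceed the noise rate (`lambda1 > lambda0`), reflecting the
#' assumption that true interactions produce more PETs than random ligation.
#'
#' @param y Count(s) `>= k`.
#' @param lambda0 Noise rate(s), positive.
#' @param lambda1 Signal rate(s), strictly greater than `lambda0`.
#' @param w1 Signal weight(s) in `[0, 1]`.
#' @param k Truncation point.
#' @return Log-likelihood, vectorized over the longest argument.
#' @export
mixture_loglik_point <- function(y, lambda0, lambda1, w1, k = 2L) {
  if (any(lambda1 <= lambda0))
    stop("rate ordering violated: `lambda1` must be strictly greater than `lambda0`")
  if (any(w1 < 0 | w1 > 1))
    stop("`w1` must lie in [0, 1]")
  lp0 <- dtpois(y, lambda0, k)
  lp1 <- dtpois(y, lambda1, k)
  logsumexp2(log1p(-w1) + lp0, log(w1) + lp1)
}

## pairwise log(exp(a) + exp(b)) without overflow; handles -Inf arguments
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Noise-rate link function
#'
#' Maps the systematic-bias covariates of each anchor pair to its noise rate
#' via a log-linear Poisson regression:
#' `log(lambda0) = b0 + b1 log(enr) + b2 log(gc) + b3 log(map) + b4 log(dis)`
#' for intrachromosomal pairs; interchromosomal pairs drop the distance term
#' (genomic distance is undefined across chromosomes), so `beta` has length 4.
#'
#' Covariates are floored before taking logs (enrichment at 1 count, gc and
#' mappability at 1e-3, distance at 1 bp) so zero values cannot produce an
#' infinite linear predictor.
#'
#' @param beta Coefficient vector: length 5 (intra) or 4 (inter).
#' @param covariates Data frame with columns `enrichment`, `gc`,
#'   `mappability` and, for intrachromosomal data, `distance`.
#' @param interaction_class `"intra"` or `"inter"`.
#' @return Vector of positive noise rates, one per row of `covariates`.
#' @export
link_lambda0 <- function(beta, covariates, interaction_class = c("intra", "inter")) {
  interaction_class <- match.arg(interaction_class)
  X <- link_design_matrix(covariates, interaction_class)
  if (length(beta) != ncol(X))
    stop(sprintf("`beta` must have length %d for %schromosomal data, got %d",
                 ncol(X), interaction_class, length(beta)))
  as.vector(exp(X %*% beta))
}

## design matrix of the link, with the covariate floors applied
link_design_matrix <- function(covariates, interaction_class) {
  stopifnot(all(c("enrichment", "gc", "mappability") %in% names(covariates)))
  X <- cbind(
    intercept   = 1,
    enrichment  = log(pmax(covariates$enrichment, 1)),
    gc          = log(pmax(covariates$gc, 1e-3)),
    mappability = log(pmax(covariates$mappability, 1e-3))
  )
  if (identical(interaction_class, "intra")) {
    if (is.null(covariates$distance) || anyNA(covariates$distance))
      stop("intrachromosomal data require a `distance` covariate for every pair")
    X <- cbind(X, distance = log(pmax(covariates$distance, 1)))
  }
  X
}

#' Joint log-prior density of the mixture model parameters
#'
#' `beta_j ~ N(0, 3^2)` independently; the signal offset `C` has a zero-
#' truncated normal prior, the positive half of `N(0, 3^2)` with doubled
#' density; each mixing weight `w1_i ~ Beta(mc_i, mc_bar)` where `mc_i` is
#' the pair's marginal PET count and `mc_bar` the dataset mean marginal
#' count. Boundary violations (`C <= 0`, `w1` outside the open unit
#' interval) return `-Inf` rather than raising an error, so samplers can
#' treat them as zero-probability proposals.
#'
#' @param params A [model_params()] object.
#' @param dataset A [pet_dataset()] object (supplies `mc_i` and `mc_bar`).
#' @return Scalar log-density (possibly `-Inf`).
#' @export
log_prior <- function(params, dataset) {
  stopifnot(inherits(params, "pet_model_params"), inherits(dataset, "pet_dataset"))
  if (!is.finite(params$C) || params$C <= 0) return(-Inf)
  if (any(params$w1 <= 0 | params$w1 >= 1)) return(-Inf)
  lp_beta <- sum(stats::dnorm(params$beta, 0, 3, log = TRUE))
  lp_C <- log(2) + stats::dnorm(params$C, 0, 3, log = TRUE)
  # Beta(mc_i, mc_bar): shape parameters can reach the thousands for hub
  # anchors, dbeta works in log-gamma space already
  lp_w <- sum(stats::dbeta(params$w1, dataset$covariates$mc, dataset$mc_bar,
                           log = TRUE))
  lp_beta + lp_C + lp_w
}

#' Unnormalized log-posterior with the latent labels marginalized out
#'
#' Sum of [log_prior()] and the per-pair mixture log-likelihoods
#' `log[(1 - w1_i) p(y_i | lambda0_i, k) + w1_i p(y_i | lambda0_i + C, k)]`,
#' with `lambda0_i` from [link_lambda0()]. The latent signal indicator `Z_i`
#' is marginalized analytically; its posterior probability is recovered from
#' the draws by [posterior_responsibility()].
#'
#' @inheritParams log_prior
#' @return Scalar unnormalized log-posterior (possibly `-Inf`).
#' @export
log_posterior <- function(params, dataset) {
  lp <- log_prior(params, dataset)
  if (!is.finite(lp)) return(lp)
  lam0 <- link_lambda0(params$beta, dataset$covariates, dataset$interaction_class)
  lam1 <- lam0 + params$C
  y <- dataset$pairs$count
  # at extreme rates lam0 + C can saturate to lam0 in floating point; the
  # mixture then degenerates to its single shared component
  deg <- lam1 <= lam0
  ll <- numeric(length(y))
  if (any(!deg))
    ll[!deg] <- mixture_loglik_point(y[!deg], lam0[!deg], lam1[!deg],
                                     params$w1[!deg], dataset$k)
  if (any(deg)) ll[deg] <- dtpois(y[deg], lam0[deg], dataset$k)
  lp + sum(ll)
}
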