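# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (no dtpois, no log-sum-exp, no vectorized
# marginal-count logic) so they can arbitrate correctness.

# truncated Poisson pmf normalized by explicit tail summation (never via a
# survival-function identity, which is what the implementation uses)
oracle_tpois <- function(y, lam, k, y_max = max(1000, ceiling(lam * 10 + 50))) {
  dpois(y, lam) / sum(dpois(k:y_max, lam))
}

oracle_tpois_vec <- function(y, lam, k) {
  mapply(oracle_tpois, y = y, lam = lam, MoreArgs = list(k = k))
}

# mixture likelihood without any log-space tricks
oracle_mixture <- function(y, lam0, lam1, w1, k) {
  (1 - w1) * oracle_tpois(y, lam0, k) + w1 * oracle_tpois(y, lam1, k)
}

# per-pair marginal counts by scanning all other pairs for shared anchors
oracle_marginal_counts <- function(pairs) {
  n <- nrow(pairs)
  key <- function(i, side) {
    if (side == "a") paste(pairs$chrom_a[i], pairs$start_a[i], pairs$end_a[i])
    else paste(pairs$chrom_b[i], pairs$start_b[i], pairs$end_b[i])
  }
  mc <- numeric(n)
  for (i in seq_len(n)) {
    for (side in c("a", "b")) {
      ki <- key(i, side)
      for (j in seq_len(n)) {
        if (key(j, "a") == ki || key(j, "b") == ki)
          mc[i] <- mc[i] + pairs$count[j]
      }
    }
    mc[i] <- mc[i] - pairs$count[i]
  }
  mc
}

# random synthetic pair table with anchor sharing, for marginal-count tests
random_pair_table <- function(n, n_anchors = max(4, floor(n * 1.2))) {
  anchors <- data.frame(
    chrom = sample(c("chr1", "chr2"), n_anchors, replace = TRUE),
    start = sample.int(1e6, n_anchors) * 10L)
  anchors$end <- anchors$start + 1000L
  ia <- sample.int(n_anchors, n, replace = TRUE)
  ib <- (ia + sample.int(n_anchors - 1L, n, replace = TRUE) - 1L) %%
    n_anchors + 1L
  pairs <- data.frame(
    chrom_a = anchors$chrom[ia], start_a = anchors$start[ia],
    end_a = anchors$end[ia],
    chrom_b = anchors$chrom[ib], start_b = anchors$start[ib],
    end_b = anchors$end[ib],
    count = sample(2:10, n, replace = TRUE),
    pair_id = sprintf("p%04d", seq_len(n)))
  petmix:::canonicalize_pairs(pairs)
}

# minimal intercept-only dataset: unit covariates make lambda0 = exp(beta0)
intercept_only_dataset <- function(y, k = 2L) {
  n <- length(y)
  step <- 100000L
  pairs <- data.frame(
    chrom_a = "chr1", start_a = seq_len(n) * step,
    end_a = seq_len(n) * step + 1000L,
    chrom_b = "chr1", start_b = seq_len(n) * step + 50000L,
    end_b = seq_len(n) * step + 51000L,
    count = y, pair_id = sprintf("p%03d", seq_len(n)))
  covs <- data.frame(enrichment = 1, gc = 1, mappability = 1,
                     distance = 1, mc = oracle_marginal_counts(pairs))
  pet_dataset(pairs, covs, k = k, interaction_class = "intra")
}

# hand-built single-draw pet_draws object at fixed parameters
manual_draws <- function(beta, C, w1, n_iter = 4L, chains = 2L) {
  p <- length(beta)
  n <- length(w1)
  vals <- c(beta, C, w1)
  a <- array(rep(vals, each = n_iter * chains),
             dim = c(n_iter, chains, p + 1L + n),
             dimnames = list(NULL, paste0("chain", seq_len(chains)),
                             c(paste0("beta", 0:(p - 1)), "C",
                               paste0("w1[", seq_len(n), "]"))))
  structure(list(draws = a,
                 accept = matrix(1, chains, 2,
                                 dimnames = list(NULL, c("beta", "C"))),
                 config = mcmc_config(chains = chains, warmup = 0,
                                      iter = n_iter, seed = 1),
                 n_params = p + 1L + n, p = p, n = n),
            class = "pet_draws")
}

# 2-D grid quadrature over (beta0, C) for the intercept-only model with the
# mixing weights fixed at their prior means; the truncated pmf is normalized
# by an explicit finite sum, not the survival-function identity the sampler
# uses
# the b0 grid must reach far left: at tiny lambda0 the truncated noise
# component concentrates all its mass on y = k, so the posterior keeps a
# long left tail limited only by the prior
quadrature_intercept_only <- function(ds,
                                      b0_grid = seq(-15, 6, length.out = 1051),
                                      C_grid = seq(1e-4, 30, length.out = 1201)) {
  stopifnot(ds$k == 2L)
  y <- ds$pairs$count
  w <- ds$covariates$mc / (ds$covariates$mc + ds$mc_bar)
  lp <- matrix(NA_real_, length(b0_grid), length(C_grid))
  for (i in seq_along(b0_grid)) {
    lam0 <- exp(b0_grid[i]); lam1 <- lam0 + C_grid
    tail0 <- 1 - dpois(0, lam0) - dpois(1, lam0)
    tail1 <- 1 - dpois(0, lam1) - dpois(1, lam1)
    ll <- 0
    for (j in seq_along(y)) {
      p0 <- dpois(y[j], lam0) / tail0
      p1 <- dpois(y[j], lam1) / tail1
      ll <- ll + log((1 - w[j]) * p0 + w[j] * p1)
    }
    lp[i, ] <- dnorm(b0_grid[i], 0, 3, log = TRUE) + log(2) +
      dnorm(C_grid, 0, 3, log = TRUE) + ll
  }
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  list(beta0 = sum(rowSums(post) * b0_grid),
       C = sum(colSums(post) * C_grid))
}

# batch-means Monte Carlo standard error of a draw matrix (iter x chains)
mcse_batch <- function(m, n_batches = 20L) {
  v <- as.vector(m)
  bs <- floor(length(v) / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(v[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
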