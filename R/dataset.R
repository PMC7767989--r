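#' Construct a model-ready interaction dataset
#'
#' Bundles canonicalized interaction pairs with their aligned covariate rows,
#' the truncation point `k`, and the interaction class. All model code
#' (likelihood, priors, MCMC) consumes this container.
#'
#' @param pairs Data frame with columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `count`, `pair_id`. Coordinates are
#'   0-based half-open; anchor A sorts before anchor B.
#' @param covariates Data frame, one row per pair, with columns
#'   `enrichment`, `gc`, `mappability`, `distance` (`NA` allowed only for
#'   interchromosomal data) and `mc` (marginal count).
#' @param k Truncation point; every retained pair must have `count >= k`.
#' @param interaction_class `"intra"` or `"inter"`.
#' @return An object of class `pet_dataset`: a list with elements `pairs`,
#'   `covariates`, `k`, `mc_bar` (mean marginal count) and
#'   `interaction_class`.
#' @export
pet_dataset <- function(pairs, covariates, k = 2L,
                        interaction_class = c("intra", "inter")) {
  interaction_class <- match.arg(interaction_class)
  pairs <- as.data.frame(pairs)
  covariates <- as.data.frame(covariates)
  need_p <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
              "count", "pair_id")
  need_c <- c("enrichment", "gc", "mappability", "distance", "mc")
  if (!all(need_p %in% names(pairs)))
    stop("`pairs` is missing columns: ",
         paste(setdiff(need_p, names(pairs)), collapse = ", "))
  if (!all(need_c %in% names(covariates)))
    stop("`covariates` is missing columns: ",
         paste(setdiff(need_c, names(covariates)), collapse = ", "))
  n <- nrow(pairs)
  if (n < 1L || nrow(covariates) != n)
    stop("`pairs` and `covariates` must have the same positive number of rows")
  if (any(pairs$count < k))
    stop("every pair must have count >= k; filter with assemble_dataset()")
  if (any(covariates$gc < 0 | covariates$gc > 1) ||
      any(covariates$mappability < 0 | covariates$mappability > 1))
    stop("gc and mappability must lie in [0, 1]")
  if (any(covariates$mc < pairs$count))
    stop("marginal count mc_i must be >= the pair count y_i")
  if (interaction_class == "intra") {
    if (anyNA(covariates$distance) || any(covariates$distance <= 0))
      stop("intrachromosomal pairs need a positive distance covariate")
  } else {
    if (!all(is.na(covariates$distance)))
      stop("interchromosomal pairs must not carry a distance covariate")
  }
  structure(
    list(pairs = pairs, covariates = covariates, k = as.integer(k),
         mc_bar = mean(covariates$mc), interaction_class = interaction_class),
    class = "pet_dataset")
}

#' @export
print.pet_dataset <- function(x, ...) {
  cat(sprintf("<pet_dataset> %d %schromosomal pairs, k = %d, mean marginal count %.2f\n",
              nrow(x$pairs), x$interaction_class, x$k, x$mc_bar))
  cat(sprintf("  count range [%d, %d]\n",
              min(x$pairs$count), max(x$pairs$count)))
  invisible(x)
}

#' A point in the mixture-model parameter space
#'
#' @param beta Link coefficients (length 5 intra, 4 inter).
#' @param C Positive signal offset; the signal rate is `lambda0 + C`.
#' @param w1 Per-pair signal weights, each in the open interval (0, 1).
#' @return An object of class `pet_model_params`.
#' @export
model_params <- function(beta, C, w1) {
  if (!length(beta) %in% c(4L, 5L))
    stop("`beta` must have length 5 (intra) or 4 (inter)")
  if (length(C) != 1L || !is.finite(C) || C <= 0)
    stop("`C` must be a single strictly positive number")
  if (any(w1 <= 0 | w1 >= 1))
    stop("all `w1` must lie strictly inside (0, 1)")
  structure(list(beta = as.numeric(beta), C = as.numeric(C),
                 w1 = as.numeric(w1)),
            class = "pet_model_params")
}

#' @export
print.pet_model_params <- function(x, ...) {
  cat("<pet_model_params>\n  beta:", signif(x$beta, 4),
      "\n  C:", signif(x$C, 4),
      "\n  w1: vector of", length(x$w1), "weights, mean",
      signif(mean(x$w1), 4), "\n")
  invisible(x)
}

## order the two anchors of each pair (chrom, then start, then end) so that
## anchor A always sorts first; BEDPE readers and the simulator both route
## through this
canonicalize_pairs <- function(pairs) {
  swap <- (pairs$chrom_b < pairs$chrom_a) |
    (pairs$chrom_b == pairs$chrom_a & pairs$start_b < pairs$start_a) |
    (pairs$chrom_b == pairs$chrom_a & pairs$start_b == pairs$start_a &
       pairs$end_b < pairs$end_a)
  if (any(swap)) {
    a <- pairs[swap, c("chrom_a", "start_a", "end_a")]
    pairs[swap, c("chrom_a", "start_a", "end_a")] <-
      pairs[swap, c("chrom_b", "start_b", "end_b")]
    pairs[swap, c("chrom_b", "start_b", "end_b")] <- a
  }
  pairs
}
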