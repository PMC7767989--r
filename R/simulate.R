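#' Sample from the (k-1)-truncated Poisson distribution
#'
#' Exact inverse-CDF sampling on the renormalized tail: a uniform variate is
#' mapped through `F(k-1) + u (1 - F(k-1))` and inverted with the Poisson
#' quantile function, so no unbounded rejection loop is involved and the
#' draw is a deterministic function of the RNG state.
#'
#' @param n Number of draws.
#' @param lambda Positive rate(s), recycled to length `n`.
#' @param k Truncation point; all draws satisfy `y >= k`.
#' @return Integer vector of counts.
#' @export
rtpois <- function(n, lambda, k = 2L) {
  if (any(lambda <= 0)) stop("`lambda` must be strictly positive")
  lambda <- rep_len(lambda, n)
  u <- stats::runif(n)
  lo <- stats::ppois(k - 1, lambda)
  stats::qpois(lo + u * (1 - lo), lambda)
}

#' Configuration of the synthetic ChIA-PET generator
#'
#' Defaults define the package's reference benchmark: 2000 intrachromosomal
#' pairs generated from the model's own process with
#' `beta = (0.5, 0.4, 0.3, 0.2, -0.3)`, signal offset `C = 4`, truncation
#' `k = 2` and a fixed signal weight of 0.3. Covariates are drawn uniformly
#' in ranges typical of ChIA-PET cluster data: per-anchor self-ligation
#' counts in \[10, 100\], GC in \[0.35, 0.65\], mappability in \[0.6, 1\],
#' anchor span 1 kb, loop spans 5 kb to 1 Mb.
#'
#' @param n_pairs Number of interaction pairs.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @param true_beta Link coefficients used to generate noise rates (length 5
#'   intra, 4 inter).
#' @param true_C Positive signal offset.
#' @param k Truncation point of the count model.
#' @param w1 Signal-weight scheme: a single value in (0, 1) used for every
#'   pair, or a length-2 vector of Beta shape parameters to draw pair
#'   weights from.
#' @param enrichment_range,gc_range,mappability_range,distance_range
#'   Uniform-draw ranges of the per-anchor (enrichment, gc, mappability)
#'   and per-pair (distance, bp) covariates.
#' @param anchor_width Anchor span in bp.
#' @param share_prob Probability that a new pair reuses an existing anchor,
#'   creating the hub anchors that drive marginal counts above `y_i`.
#' @param n_chroms,chrom_length Fixture-genome layout.
#' @param interaction_class `"intra"` or `"inter"`.
#' @return A list of class `pet_sim_config`.
#' @export
simulation_config <- function(n_pairs = 2000L, seed = 1L,
                              true_beta = c(0.5, 0.4, 0.3, 0.2, -0.3),
                              true_C = 4, k = 2L, w1 = 0.3,
                              enrichment_range = c(10L, 100L),
                              gc_range = c(0.35, 0.65),
                              mappability_range = c(0.6, 1),
                              distance_range = c(5e3, 1e6),
                              anchor_width = 1000L,
                              share_prob = 0.15,
                              n_chroms = 4L, chrom_length = 5e6,
                              interaction_class = c("intra", "inter")) {
  interaction_class <- match.arg(interaction_class)
  stopifnot(n_pairs >= 1, true_C > 0, k >= 0,
            gc_range[1] >= 0, gc_range[2] <= 1,
            mappability_range[1] > 0, mappability_range[2] <= 1,
            distance_range[1] >= 1, enrichment_range[1] >= 0)
  if (length(w1) == 1L && (w1 <= 0 || w1 > 1))
    stop("fixed `w1` must lie in (0, 1]")
  p_needed <- if (interaction_class == "intra") 5L else 4L
  if (length(true_beta) != p_needed)
    stop(sprintf("`true_beta` must have length %d for %schromosomal data",
                 p_needed, interaction_class))
  if (interaction_class == "intra" &&
      distance_range[2] + 2 * anchor_width >= chrom_length)
    stop("infeasible ranges: chrom_length too small for the distance range")
  structure(list(
    n_pairs = as.integer(n_pairs), seed = as.integer(seed),
    true_beta = true_beta, true_C = true_C, k = as.integer(k), w1 = w1,
    enrichment_range = enrichment_range, gc_range = gc_range,
    mappability_range = mappability_range, distance_range = distance_range,
    anchor_width = as.integer(anchor_width), share_prob = share_prob,
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    interaction_class = interaction_class), class = "pet_sim_config")
}

#' Generate a synthetic ChIA-PET dataset with known ground truth
#'
#' Anchors are placed on the fixture genome (non-overlapping, with a
#' configurable probability of reusing an existing anchor so that hub
#' anchors arise); per-anchor covariates are drawn uniformly; pair-level
#' covariates use the same combination rules as [assemble_dataset()]; noise
#' rates come from [link_lambda0()] at `true_beta`, signal rates add
#' `true_C`; labels are Bernoulli in the signal weight; counts are exact
#' truncated-Poisson draws; marginal counts are recomputed from the realized
#' pair list, never faked.
#'
#' @param config A [simulation_config()].
#' @return A list of class `pet_synthetic`: `dataset` (a [pet_dataset()]),
#'   `true_labels` (0/1 per pair), `true_params` (a [model_params()]),
#'   `anchors` (fixture anchor table with per-anchor covariates) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "pet_sim_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  wd <- config$anchor_width
  intra <- config$interaction_class == "intra"
  chrom_names <- paste0("chr", seq_len(config$n_chroms))

  # preallocated anchor registry (at most 2 new anchors per pair)
  cap <- 2L * n
  anc_chrom <- integer(cap); anc_start <- integer(cap)
  anc_gc <- numeric(cap); anc_map <- numeric(cap); anc_enr <- integer(cap)
  n_anc <- 0L
  starts_by_chrom <- rep(list(integer(0)), config$n_chroms)
  by_chrom <- rep(list(integer(0)), config$n_chroms)  # anchor indices

  add_anchor <- function(ci, start) {
    n_anc <<- n_anc + 1L
    anc_chrom[n_anc] <<- ci
    anc_start[n_anc] <<- as.integer(start)
    # quantize GC so an emitted fixture sequence can match exactly
    anc_gc[n_anc] <<- round(stats::runif(1, config$gc_range[1],
                                         config$gc_range[2]) * wd) / wd
    anc_map[n_anc] <<- stats::runif(1, config$mappability_range[1],
                                    config$mappability_range[2])
    anc_enr[n_anc] <<- as.integer(round(stats::runif(
      1, config$enrichment_range[1], config$enrichment_range[2])))
    starts_by_chrom[[ci]] <<- c(starts_by_chrom[[ci]], as.integer(start))
    by_chrom[[ci]] <<- c(by_chrom[[ci]], n_anc)
    n_anc
  }
  free_spot <- function(ci, start) {
    s <- starts_by_chrom[[ci]]
    start >= 0 && start + wd <= config$chrom_length &&
      (!length(s) || all(start + wd <= s | start >= s + wd))
  }
  place_new <- function(ci) {
    for (try in 1:200) {
      start <- floor(stats::runif(1, 0, config$chrom_length - wd))
      if (free_spot(ci, start)) return(start)
    }
    stop("infeasible ranges: could not place a non-overlapping anchor")
  }

  idx_a <- integer(n); idx_b <- integer(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:200) {
      ci <- sample.int(config$n_chroms, 1)
      reuse <- stats::runif(1) < config$share_prob && length(by_chrom[[ci]])
      if (reuse) {
        ia <- by_chrom[[ci]][sample.int(length(by_chrom[[ci]]), 1)]
        a_start <- anc_start[ia]
      } else {
        a_start <- place_new(ci)
        ia <- NA_integer_
      }
      if (intra) {
        dis <- stats::runif(1, config$distance_range[1],
                            config$distance_range[2])
        b_start <- as.integer(round(a_start + dis))
        if (!free_spot(ci, b_start)) b_start <- as.integer(round(a_start - dis))
        if (!free_spot(ci, b_start)) next
        cj <- ci
      } else {
        cj <- sample.int(config$n_chroms, 1)
        if (cj == ci) next
        b_start <- place_new(cj)
      }
      if (is.na(ia)) ia <- add_anchor(ci, a_start)
      ib <- add_anchor(cj, b_start)
      idx_a[i] <- ia; idx_b[i] <- ib
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible ranges: could not place pair ", i)
  }

  anchors <- data.frame(
    chrom = chrom_names[anc_chrom[seq_len(n_anc)]],
    start = anc_start[seq_len(n_anc)],
    end = anc_start[seq_len(n_anc)] + wd,
    gc = anc_gc[seq_len(n_anc)], map = anc_map[seq_len(n_anc)],
    enr = anc_enr[seq_len(n_anc)], stringsAsFactors = FALSE)

  pairs <- data.frame(
    chrom_a = anchors$chrom[idx_a], start_a = anchors$start[idx_a],
    end_a = anchors$end[idx_a],
    chrom_b = anchors$chrom[idx_b], start_b = anchors$start[idx_b],
    end_b = anchors$end[idx_b],
    count = NA_integer_, pair_id = sprintf("pair_%05d", seq_len(n)),
    gc_a = anchors$gc[idx_a], gc_b = anchors$gc[idx_b],
    map_a = anchors$map[idx_a], map_b = anchors$map[idx_b],
    enr_a = anchors$enr[idx_a], enr_b = anchors$enr[idx_b],
    stringsAsFactors = FALSE)
  pairs <- canonicalize_pairs(pairs)
  # canonicalization may swap anchor coordinate columns; swap covariates with
  # the same mask so each annotation still describes its own anchor
  swapped <- pairs$start_a != anchors$start[idx_a] |
    pairs$chrom_a != anchors$chrom[idx_a]
  if (any(swapped)) {
    pairs[swapped, c("gc_a", "gc_b")] <- pairs[swapped, c("gc_b", "gc_a")]
    pairs[swapped, c("map_a", "map_b")] <- pairs[swapped, c("map_b", "map_a")]
    pairs[swapped, c("enr_a", "enr_b")] <- pairs[swapped, c("enr_b", "enr_a")]
  }
  pairs$distance <- compute_distance(pairs)

  cov <- data.frame(
    enrichment = pairs$enr_a + pairs$enr_b,
    gc = (pairs$gc_a + pairs$gc_b) / 2,
    mappability = (pairs$map_a + pairs$map_b) / 2,
    distance = pairs$distance)
  lam0 <- link_lambda0(config$true_beta, cov, config$interaction_class)
  lam1 <- lam0 + config$true_C
  w1 <- if (length(config$w1) == 1L) rep(config$w1, n)
        else stats::rbeta(n, config$w1[1], config$w1[2])
  z <- stats::rbinom(n, 1L, w1)
  pairs$count <- rtpois(n, ifelse(z == 1L, lam1, lam0), config$k)

  dataset <- assemble_dataset(pairs, k = config$k,
                              interaction_class = config$interaction_class)
  w1_open <- pmin(pmax(w1, 1e-9), 1 - 1e-9)
  structure(list(
    dataset = dataset, true_labels = z,
    true_params = model_params(config$true_beta, config$true_C, w1_open),
    anchors = anchors, config = config), class = "pet_synthetic")
}

#' Write a synthetic dataset as an on-disk fixture bundle
#'
#' Emits the file set a real analysis would start from: a cluster BEDPE
#' (anchors + inter-ligation counts), a self-ligation BED whose per-anchor
#' overlap counts equal the drawn enrichments, a FASTA genome whose anchor
#' sequences realize the drawn GC fractions exactly (deterministic base
#' patterns, filler `A` elsewhere), and a mappability bedGraph reproducing
#' the drawn scores. Re-annotating the bundle through the covariate module
#' recovers the generated covariates.
#'
#' @param sds A `pet_synthetic` object from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written
#'   (`interactions`, `self_ligation`, `genome`, `mappability`).
#' @export
write_fixture_files <- function(sds, dir) {
  stopifnot(inherits(sds, "pet_synthetic"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    interactions = file.path(dir, "clusters.bedpe"),
    self_ligation = file.path(dir, "self_ligation.bed"),
    genome = file.path(dir, "genome.fa"),
    mappability = file.path(dir, "mappability.bedgraph"))

  p <- sds$dataset$pairs
  data.table::fwrite(
    data.frame(p$chrom_a, p$start_a, p$end_a, p$chrom_b, p$start_b, p$end_b,
               p$pair_id, p$count),
    paths$interactions, sep = "\t", col.names = FALSE)

  anc <- sds$anchors
  # one short self-ligation span per unit of enrichment, inside the anchor;
  # anchors never overlap, so counts round-trip exactly
  reps <- rep.int(seq_len(nrow(anc)), anc$enr)
  sl <- data.frame(chrom = anc$chrom[reps],
                   start = anc$start[reps],
                   end = anc$start[reps] + 10L)
  data.table::fwrite(sl, paths$self_ligation, sep = "\t", col.names = FALSE)

  data.table::fwrite(
    data.frame(anc$chrom, anc$start, anc$end, sprintf("%.10g", anc$map)),
    paths$mappability, sep = "\t", col.names = FALSE)

  chrom_names <- paste0("chr", seq_len(sds$config$n_chroms))
  wd <- sds$config$anchor_width
  seqs <- vapply(chrom_names, function(cn) {
    s <- rep("A", sds$config$chrom_length)
    for (j in which(anc$chrom == cn)) {
      g <- round(anc$gc[j] * wd)
      block <- c(rep(c("G", "C"), length.out = g),
                 rep(c("A", "T"), length.out = wd - g))
      s[(anc$start[j] + 1):(anc$start[j] + wd)] <- block
    }
    paste(s, collapse = "")
  }, character(1))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- chrom_names
  Biostrings::writeXStringSet(dss, paths$genome)
  invisible(paths)
}
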