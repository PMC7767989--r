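test_that("truncated Poisson sampler hits its support and moments", {
  set.seed(10)
  x <- rtpois(2000, 1, k = 2)
  expect_true(all(x >= 2))
  # k = 0: plain Poisson mean
  set.seed(11)
  x0 <- rtpois(1e5, 3, k = 0)
  expect_equal(mean(x0), 3, tolerance = 0.02)
  # k = 2, lam = 1: mean matches numeric pmf summation
  m_oracle <- sum((2:400) * oracle_tpois_vec(2:400, 1, 2))
  set.seed(12)
  x2 <- rtpois(1e5, 1, k = 2)
  expect_equal(mean(x2), m_oracle, tolerance = 0.01)
  # deterministic given the RNG state
  set.seed(13); a <- rtpois(50, 2.5, k = 2)
  set.seed(13); b <- rtpois(50, 2.5, k = 2)
  expect_identical(a, b)
  expect_error(rtpois(5, 0, k = 2), "lambda")
})

test_that("generated datasets are reproducible with known ground truth", {
  cfg <- simulation_config(n_pairs = 150, seed = 5,
                           distance_range = c(5e3, 1e5),
                           chrom_length = 1e6)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$dataset$pairs, b$dataset$pairs)
  expect_identical(a$true_labels, b$true_labels)
  expect_true(all(a$dataset$pairs$count >= cfg$k))
  expect_true(all(a$true_labels %in% 0:1))
  # marginal counts are recomputed from the realized pairs, not faked
  expect_equal(a$dataset$covariates$mc,
               oracle_marginal_counts(a$dataset$pairs))
})

test_that("degenerate and stochastic weight schemes behave as specified", {
  cfg1 <- simulation_config(n_pairs = 80, seed = 6, w1 = 1,
                            distance_range = c(5e3, 1e5),
                            chrom_length = 1e6)
  expect_true(all(generate_dataset(cfg1)$true_labels == 1L))
  cfg3 <- simulation_config(n_pairs = 10000, seed = 7, w1 = 0.3,
                            chrom_length = 5e7)
  frac <- mean(generate_dataset(cfg3)$true_labels)
  # binomial MC error at n = 1e4 is ~0.005
  expect_lt(abs(frac - 0.3), 0.02)
})

test_that("the generated data concentrate likelihood at the true parameters", {
  sds <- generate_dataset(simulation_config(n_pairs = 5000, seed = 8))
  ds <- sds$dataset
  avg_ll <- function(beta) {
    lam0 <- link_lambda0(beta, ds$covariates, "intra")
    mean(mixture_loglik_point(ds$pairs$count, lam0, lam0 + 4,
                              sds$config$w1, k = 2))
  }
  truth <- sds$config$true_beta
  at_truth <- avg_ll(truth)
  # whole-vector shifts of +/-1
  expect_lt(avg_ll(truth + 1), at_truth)
  expect_lt(avg_ll(truth - 1), at_truth)
  # and the strongly identified single coordinates (intercept, enrichment,
  # distance); gc and mappability vary too little over their ranges for a
  # unit shift to rise above Monte-Carlo noise at this n
  for (j in c(1, 2, 5)) {
    for (shift in c(-1, 1)) {
      pert <- truth; pert[j] <- pert[j] + shift
      expect_lt(avg_ll(pert), at_truth)
    }
  }
})

test_that("fixture files round-trip through the annotation module", {
  for (seed in 1:3) {
    cfg <- simulation_config(n_pairs = 60, seed = seed,
                             distance_range = c(2e3, 5e4),
                             chrom_length = 5e5, n_chroms = 2)
    sds <- generate_dataset(cfg)
    dir <- withr::local_tempdir()
    paths <- write_fixture_files(sds, dir)
    pairs <- read_interactions(paths$interactions)
    track <- read_scored_intervals(paths$mappability)
    sl <- read_self_ligation(paths$self_ligation)
    ann <- annotate_pairs(pairs, paths$genome, track, sl)
    rebuilt <- assemble_dataset(ann, k = cfg$k, interaction_class = "intra")
    orig <- sds$dataset
    ord1 <- order(rebuilt$pairs$pair_id)
    ord2 <- order(orig$pairs$pair_id)
    expect_equal(rebuilt$covariates$enrichment[ord1],
                 orig$covariates$enrichment[ord2])
    expect_equal(rebuilt$covariates$gc[ord1], orig$covariates$gc[ord2],
                 tolerance = 1 / cfg$anchor_width)
    expect_equal(rebuilt$covariates$mappability[ord1],
                 orig$covariates$mappability[ord2], tolerance = 1e-6)
    expect_equal(rebuilt$covariates$distance[ord1],
                 orig$covariates$distance[ord2])
    expect_equal(rebuilt$covariates$mc[ord1], orig$covariates$mc[ord2])
  }
})

test_that("extreme GC and zero enrichment are emitted faithfully", {
  cfg <- simulation_config(n_pairs = 10, seed = 9, gc_range = c(1, 1),
                           enrichment_range = c(0, 0),
                           distance_range = c(2e3, 2e4),
                           chrom_length = 2e5, n_chroms = 1)
  sds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(sds, dir)
  genome <- Biostrings::readDNAStringSet(paths$genome)
  anc <- sds$anchors[1, ]
  seq1 <- as.character(Biostrings::subseq(genome[[anc$chrom]],
                                          anc$start + 1, anc$end))
  expect_false(grepl("[AT]", seq1))  # gc = 1 anchor is all G/C
  expect_equal(file.size(paths$self_ligation), 0)  # no self-ligation records
})
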