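#' GC fraction of anchor intervals
#'
#' Fraction of G/C bases over the full anchor width; ambiguous bases (N)
#' count in the denominator only, matching the behaviour of `bedtools nuc`.
#'
#' @param anchors Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genome A named [Biostrings::DNAStringSet] or the path to a FASTA
#'   file.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
compute_gc <- function(anchors, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*$", "", names(genome))
  miss <- setdiff(unique(anchors$chrom), nm)
  if (length(miss))
    stop("chromosome(s) absent from genome: ", paste(miss, collapse = ", "))
  idx <- match(anchors$chrom, nm)
  if (any(anchors$start < 0) ||
      any(anchors$end > Biostrings::width(genome)[idx]))
    stop("anchor interval out of bounds of its chromosome sequence")
  seqs <- Biostrings::subseq(genome[idx], start = anchors$start + 1L,
                             end = anchors$end)
  gc <- Biostrings::letterFrequency(seqs, letters = "GC")
  as.vector(gc) / (anchors$end - anchors$start)
}

#' Mean mappability of anchor intervals
#'
#' Length-weighted mean of the mappability-track scores over each anchor;
#' bases not covered by the track contribute score 0.
#'
#' @param anchors Data frame with columns `chrom`, `start`, `end`.
#' @param track Scored intervals as returned by [read_scored_intervals()]:
#'   a data frame with columns `chrom`, `start`, `end`, `score`,
#'   non-overlapping within each chromosome.
#' @return Numeric vector of mean scores in `[0, 1]`.
#' @export
compute_mappability <- function(anchors, track) {
  out <- numeric(nrow(anchors))
  if (nrow(track) == 0L) return(out)
  gr_a <- anchors_granges(anchors)
  gr_t <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$start + 1L, track$end))
  hits <- GenomicRanges::findOverlaps(gr_a, gr_t)
  if (length(hits)) {
    ov <- IRanges::pintersect(gr_a[S4Vectors::queryHits(hits)],
                              gr_t[S4Vectors::subjectHits(hits)])
    contrib <- GenomicRanges::width(ov) * track$score[S4Vectors::subjectHits(hits)]
    sums <- tapply(contrib, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out / (anchors$end - anchors$start)
}

#' Anchor enrichment from self-ligation PETs
#'
#' Number of self-ligation records overlapping each anchor by at least one
#' base; self-ligation density is the local-enrichment bias proxy.
#'
#' @param anchors Data frame with columns `chrom`, `start`, `end`.
#' @param self_ligation Data frame of self-ligation spans with columns
#'   `chrom`, `start`, `end` (0-based half-open).
#' @return Integer vector of overlap counts.
#' @export
compute_enrichment <- function(anchors, self_ligation) {
  if (is.null(self_ligation) || nrow(self_ligation) == 0L)
    return(integer(nrow(anchors)))
  gr_a <- anchors_granges(anchors)
  gr_s <- GenomicRanges::GRanges(
    self_ligation$chrom,
    IRanges::IRanges(self_ligation$start + 1L, self_ligation$end))
  GenomicRanges::countOverlaps(gr_a, gr_s)
}

anchors_granges <- function(anchors) {
  GenomicRanges::GRanges(anchors$chrom,
                         IRanges::IRanges(anchors$start + 1L, anchors$end))
}

#' Genomic distance between the anchors of each pair
#'
#' Midpoint-to-midpoint distance in bp, floored at 1; `NA` for
#' interchromosomal pairs, for which genomic distance is undefined.
#'
#' @param pairs Canonical pair data frame (see [pet_dataset()]).
#' @return Numeric vector of distances (bp) with `NA` for inter pairs.
#' @export
compute_distance <- function(pairs) {
  mid_a <- (pairs$start_a + pairs$end_a) / 2
  mid_b <- (pairs$start_b + pairs$end_b) / 2
  d <- pmax(abs(mid_b - mid_a), 1)
  d[pairs$chrom_a != pairs$chrom_b] <- NA_real_
  d
}

#' Marginal PET counts per pair
#'
#' For each anchor (identified by exact coordinates) the marginal count is
#' the sum of inter-ligation counts over every pair it participates in. The
#' pair-level marginal count subtracts the shared observation once:
#' `mc_i = mc_A + mc_B - y_i`.
#'
#' @param pairs Canonical pair data frame with a `count` column.
#' @return List with `mc` (per-pair marginal counts), `mc_bar` (their mean)
#'   and `anchor_mc` (named vector of per-anchor marginal counts).
#' @export
compute_marginal_counts <- function(pairs) {
  if (nrow(pairs) == 0L) stop("`pairs` must be nonempty")
  key_a <- paste(pairs$chrom_a, pairs$start_a, pairs$end_a, sep = ":")
  key_b <- paste(pairs$chrom_b, pairs$start_b, pairs$end_b, sep = ":")
  anchor_mc <- tapply(c(pairs$count, pairs$count), c(key_a, key_b), sum)
  mc <- as.numeric(anchor_mc[key_a]) + as.numeric(anchor_mc[key_b]) -
    pairs$count
  list(mc = mc, mc_bar = mean(mc),
       anchor_mc = stats::setNames(as.numeric(anchor_mc), names(anchor_mc)))
}

#' Annotate interaction pairs with per-anchor bias covariates
#'
#' Adds per-anchor GC fraction, mean mappability and self-ligation
#' enrichment columns (`gc_a`, `gc_b`, `map_a`, `map_b`, `enr_a`, `enr_b`)
#' plus the pair distance (`distance`).
#'
#' @param pairs Canonical pair data frame.
#' @param genome FASTA path or `DNAStringSet`.
#' @param mappability_track Scored intervals (see [compute_mappability()]).
#' @param self_ligation Self-ligation span data frame.
#' @return The pair data frame with annotation columns appended.
#' @export
annotate_pairs <- function(pairs, genome, mappability_track, self_ligation) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  a <- data.frame(chrom = pairs$chrom_a, start = pairs$start_a,
                  end = pairs$end_a)
  b <- data.frame(chrom = pairs$chrom_b, start = pairs$start_b,
                  end = pairs$end_b)
  pairs$gc_a <- compute_gc(a, genome)
  pairs$gc_b <- compute_gc(b, genome)
  pairs$map_a <- compute_mappability(a, mappability_track)
  pairs$map_b <- compute_mappability(b, mappability_track)
  pairs$enr_a <- compute_enrichment(a, self_ligation)
  pairs$enr_b <- compute_enrichment(b, self_ligation)
  pairs$distance <- compute_distance(pairs)
  pairs
}

#' Assemble a model-ready dataset from annotated pairs
#'
#' Combines per-anchor covariates to the pair level (arithmetic mean for GC
#' and mappability, which preserves the unit scale; sum for enrichment,
#' since both anchors contribute random-ligation opportunity), computes
#' marginal counts on the supplied pair list, then drops pairs whose count
#' falls below the truncation point `k`.
#'
#' @param pairs Annotated pair data frame (from [annotate_pairs()] or the
#'   simulator).
#' @param k Truncation point; pairs with `count < k` are dropped (default 2).
#' @param interaction_class `"intra"` or `"inter"`.
#' @param combine Named list selecting the anchor-combination rule for
#'   `gc`, `mappability` (`"mean"` or `"max"`) and `enrichment`
#'   (`"sum"` or `"mean"`).
#' @return A [pet_dataset()].
#' @export
assemble_dataset <- function(pairs, k = 2L,
                             interaction_class = c("intra", "inter"),
                             combine = list(gc = "mean", mappability = "mean",
                                            enrichment = "sum")) {
  interaction_class <- match.arg(interaction_class)
  need <- c("gc_a", "gc_b", "map_a", "map_b", "enr_a", "enr_b", "distance")
  if (!all(need %in% names(pairs)))
    stop("pairs are not annotated; run annotate_pairs() first")
  mcs <- compute_marginal_counts(pairs)
  comb2 <- function(x, y, rule)
    switch(rule, mean = (x + y) / 2, sum = x + y, max = pmax(x, y),
           stop("unknown combination rule: ", rule))
  covariates <- data.frame(
    enrichment  = comb2(pairs$enr_a, pairs$enr_b, combine$enrichment),
    gc          = comb2(pairs$gc_a, pairs$gc_b, combine$gc),
    mappability = comb2(pairs$map_a, pairs$map_b, combine$mappability),
    distance    = pairs$distance,
    mc          = mcs$mc)
  keep <- pairs$count >= k
  if (!any(keep))
    stop(sprintf("no pairs with count >= k = %d survive the filter", k))
  pet_dataset(pairs[keep, , drop = FALSE],
              covariates[keep, , drop = FALSE],
              k = k, interaction_class = interaction_class)
}
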