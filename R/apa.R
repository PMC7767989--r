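#' Build a binned contact matrix from paired-end records
#'
#' Each intrachromosomal record on the requested chromosome adds its count
#' at the (bin_a, bin_b) cell and its mirror, with bins assigned by anchor
#' midpoint (`floor(midpoint / bin_size)`). A record whose two ends fall in
#' one bin increments the diagonal once. Interchromosomal records and other
#' chromosomes are ignored.
#'
#' @param pets Data frame of BEDPE-like records (`chrom_a`, `start_a`,
#'   `end_a`, `chrom_b`, `start_b`, `end_b`, optional `count`; missing
#'   `count` means 1 per record, i.e. PET-level input).
#' @param chrom Chromosome to build the matrix for.
#' @param bin_size Bin width in bp (default 5000).
#' @return Object of class `pet_contact_matrix`: sparse symmetric matrix
#'   plus `chrom` and `bin_size`. Bin `b` (0-based) is row/column `b + 1`.
#' @export
build_contact_matrix <- function(pets, chrom, bin_size = 5000L) {
  if (bin_size <= 0) stop("`bin_size` must be positive")
  cnt <- if ("count" %in% names(pets)) pets$count else rep(1L, nrow(pets))
  sel <- pets$chrom_a == chrom & pets$chrom_b == chrom
  pets <- pets[sel, , drop = FALSE]
  cnt <- cnt[sel]
  if (nrow(pets) == 0L) {
    mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0, 0))
    return(structure(list(mat = mat, chrom = chrom,
                          bin_size = as.integer(bin_size), n_bins = 0L),
                     class = "pet_contact_matrix"))
  }
  bin_a <- floor((pets$start_a + pets$end_a) / 2 / bin_size)
  bin_b <- floor((pets$start_b + pets$end_b) / 2 / bin_size)
  lo <- pmin(bin_a, bin_b) + 1L
  hi <- pmax(bin_a, bin_b) + 1L
  n_bins <- max(hi)
  # upper triangle accumulates; symmetrize without doubling the diagonal
  up <- Matrix::sparseMatrix(i = lo, j = hi, x = as.numeric(cnt),
                             dims = c(n_bins, n_bins))
  mat <- up + Matrix::t(up)
  Matrix::diag(mat) <- Matrix::diag(up)
  structure(list(mat = mat, chrom = chrom, bin_size = as.integer(bin_size),
                 n_bins = n_bins),
            class = "pet_contact_matrix")
}

#' @export
print.pet_contact_matrix <- function(x, ...) {
  cat(sprintf("<pet_contact_matrix> %s, %d bins of %d bp, total count %g\n",
              x$chrom, x$n_bins, x$bin_size,
              sum(x$mat) - sum(Matrix::diag(x$mat)) / 2))
  invisible(x)
}

#' Aggregate contact-matrix windows around called loops
#'
#' For every loop with both anchors on the matrix chromosome and anchor-bin
#' separation greater than `2 w` bins (near-diagonal loops are excluded so
#' the diagonal cannot bleed into the window), the `(2w+1) x (2w+1)`
#' submatrix centred on (upstream bin, downstream bin) is extracted and the
#' windows are summed element-wise. Bins beyond the last observed contact
#' are implicit zeros (no contacts were seen there), so only windows that
#' would cross the chromosome start are skipped (and counted).
#'
#' @param cm A `pet_contact_matrix`.
#' @param loops Data frame of loop calls with the BEDPE-like columns of
#'   [build_contact_matrix()].
#' @param w Window half-width in bins (default 10, i.e. a 21 x 21 window).
#' @return Object of class `pet_apa`: `matrix` (dense `(2w+1)^2` window
#'   sum), `w`, `n_loops_used`, `n_loops_skipped`.
#' @export
aggregate_peaks <- function(cm, loops, w = 10L) {
  stopifnot(inherits(cm, "pet_contact_matrix"))
  if (w < 1) stop("`w` must be at least 1 bin")
  sel <- loops$chrom_a == cm$chrom & loops$chrom_b == cm$chrom
  loops <- loops[sel, , drop = FALSE]
  acc <- matrix(0, 2 * w + 1, 2 * w + 1)
  used <- 0L; skipped <- 0L
  if (nrow(loops)) {
    bin_a <- floor((loops$start_a + loops$end_a) / 2 / cm$bin_size)
    bin_b <- floor((loops$start_b + loops$end_b) / 2 / cm$bin_size)
    up <- pmin(bin_a, bin_b) + 1L
    dn <- pmax(bin_a, bin_b) + 1L
    for (i in seq_len(nrow(loops))) {
      if (dn[i] - up[i] <= 2L * w) { skipped <- skipped + 1L; next }
      rows <- (up[i] - w):(up[i] + w)
      cols <- (dn[i] - w):(dn[i] + w)
      if (rows[1] < 1L) { skipped <- skipped + 1L; next }
      vr <- which(rows <= cm$n_bins)
      vc <- which(cols <= cm$n_bins)
      if (length(vr) && length(vc))
        acc[vr, vc] <- acc[vr, vc] +
          as.matrix(cm$mat[rows[vr], cols[vc], drop = FALSE])
      used <- used + 1L
    }
  }
  if (used == 0L)
    stop("no usable loops: all were off-chromosome, near-diagonal, or out of bounds")
  structure(list(matrix = acc, w = as.integer(w), n_loops_used = used,
                 n_loops_skipped = skipped),
            class = "pet_apa")
}

#' @export
print.pet_apa <- function(x, ...) {
  cat(sprintf("<pet_apa> %dx%d window, %d loops aggregated (%d skipped), center %g\n",
              nrow(x$matrix), ncol(x$matrix), x$n_loops_used,
              x$n_loops_skipped, x$matrix[x$w + 1, x$w + 1]))
  invisible(x)
}

#' Peak-to-lower-left enrichment score
#'
#' Ratio of the central pixel of the aggregated window to the mean of the
#' `corner_size x corner_size` block in the lower-left corner (largest row
#' indices, smallest column indices; rows follow the upstream-anchor axis
#' increasing downward). Values above 1 indicate loop enrichment over the
#' local background.
#'
#' @param apa A `pet_apa` object.
#' @param corner_size Edge length of the corner block in bins (default 6).
#' @return Scalar P2LL ratio.
#' @export
p2ll <- function(apa, corner_size = 6L) {
  stopifnot(inherits(apa, "pet_apa"))
  sz <- nrow(apa$matrix)
  if (corner_size >= sz) stop("`corner_size` must be smaller than the window")
  center <- apa$matrix[apa$w + 1L, apa$w + 1L]
  corner <- apa$matrix[(sz - corner_size + 1L):sz, seq_len(corner_size)]
  if (mean(corner) == 0)
    stop("P2LL undefined: lower-left corner mean is zero")
  center / mean(corner)
}
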