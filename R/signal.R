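# Coverage quantification and the two normalizations used downstream:
# fragments per kbp per million (FPKPM) and pseudo-count + quantile.

#' Count fragments overlapping each locus
#'
#' `bedtools multicov` semantics: a fragment is counted for a locus iff they
#' share at least one base (half-open intervals).
#'
#' @param loci Interval tibble.
#' @param fragments Interval tibble of sequenced fragments.
#' @return Integer vector of raw counts, one per locus row.
#' @export
count_coverage <- function(loci, fragments) {
  validate_intervals(loci)
  validate_intervals(fragments)
  if (nrow(loci) == 0L) return(integer(0))
  if (nrow(fragments) == 0L) return(integer(nrow(loci)))
  GenomicRanges::countOverlaps(as_granges(loci), as_granges(fragments))
}

#' Fragments-per-kbp-per-million normalization
#'
#' `count / (locus_length / 1000) / (library_size / 1e6)` — the read
#' pileup normalization used for ATAC-seq and Sox2 ChIP-seq signal
#' (fragments per kilobase pair per million library fragments).
#'
#' @param count Raw fragment counts (vectorized).
#' @param locus_length Locus width(s) in bp (> 0).
#' @param library_size Total fragments in the library (> 0).
#' @return Numeric normalized signal.
#' @examples
#' normalize_fpkpm(50, 2000, 1e7) # 2.5
#' @export
normalize_fpkpm <- function(count, locus_length, library_size) {
  if (any(locus_length <= 0)) stop("locus_length must be positive", call. = FALSE)
  if (any(library_size <= 0)) stop("library_size must be positive", call. = FALSE)
  count / (locus_length / 1000) / (library_size / 1e6)
}

#' Pseudo-count plus quantile normalization of a count matrix
#'
#' Adds a pseudo-count to every cell and applies classic quantile
#' normalization: each column is ranked, and every value is replaced by the
#' mean across columns of the column-sorted values at its rank; tied values
#' receive the mean of the reference distribution over their rank range.
#' After normalization all columns share the same sorted value vector (up to
#' tie averaging). This is the normalization used for POU ChIP-seq coverage
#' boxplots, where library-size differences are too large for simple depth
#' scaling.
#'
#' @param mat Numeric matrix, loci x samples (>= 2 columns).
#' @param pseudo_count Added to every cell first (default 1).
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(mat, pseudo_count = 1) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) {
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  }
  mat <- mat + pseudo_count
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(col) {
    o <- order(col)
    res <- numeric(length(col))
    # tied values share the mean of the reference values over their rank range
    res[o] <- stats::ave(ref, match(col[o], unique(col[o])), FUN = mean)
    res
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-locus accessibility ratio between two conditions
#'
#' `(day + epsilon) / (mef + epsilon)` on FPKPM-normalized signal over the
#' same loci; `epsilon` bounds ratios at zero-signal MEF loci while
#' preserving ordering.
#'
#' @param day_signal,mef_signal Non-negative normalized signal vectors of
#'   equal length.
#' @param epsilon Stabilizing constant (default 0.1).
#' @return Numeric ratio vector.
#' @export
accessibility_ratio <- function(day_signal, mef_signal, epsilon = 0.1) {
  stopifnot(length(day_signal) == length(mef_signal), epsilon > 0)
  if (any(day_signal < 0) || any(mef_signal < 0)) {
    stop("signals must be non-negative", call. = FALSE)
  }
  (day_signal + epsilon) / (mef_signal + epsilon)
}

#' Binned signal profiles around locus centers
#'
#' For each locus, counts fragments per bin over a window centered on the
#' representative position (`rep_pos` if present, else the midpoint) and
#' FPKPM-normalizes each bin — the matrix behind signal heatmaps and pileup
#' plots. Bins falling below position 0 are empty (zero-padded).
#'
#' @param loci Interval tibble.
#' @param fragments Fragment interval tibble.
#' @param library_size Library size for FPKPM (default: `nrow(fragments)`).
#' @param window Window width in bp centered on each locus (default 2000).
#' @param n_bins Number of bins; must divide `window`.
#' @return Numeric matrix, loci x bins, of FPKPM per bin.
#' @export
heatmap_matrix <- function(loci, fragments, library_size = nrow(fragments),
                           window = 2000, n_bins = 40) {
  validate_intervals(loci)
  validate_intervals(fragments)
  if (window %% n_bins != 0) {
    stop("window must be divisible by n_bins", call. = FALSE)
  }
  bw <- window / n_bins
  center <- if ("rep_pos" %in% names(loci)) loci$rep_pos else floor((loci$start + loci$end) / 2)
  n <- nrow(loci)
  out <- matrix(0, nrow = n, ncol = n_bins)
  if (n == 0L) return(out)
  bin_left <- rep(center - window / 2, times = n_bins) +
    rep((seq_len(n_bins) - 1L) * bw, each = n)
  bins <- tibble::tibble(
    chrom = rep(loci$chrom, times = n_bins),
    start = bin_left,
    end = bin_left + bw
  )
  keep <- bins$start >= 0
  counts <- numeric(nrow(bins))
  if (any(keep) && nrow(fragments) > 0L) {
    counts[keep] <- GenomicRanges::countOverlaps(as_granges(bins[keep, ]),
                                                 as_granges(fragments))
  }
  out[] <- counts
  out <- normalize_fpkpm(out, bw, max(library_size, 1))
  rownames(out) <- if ("locus_id" %in% names(loci)) loci$locus_id else NULL
  colnames(out) <- sprintf("bin_%02d", seq_len(n_bins))
  out
}
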