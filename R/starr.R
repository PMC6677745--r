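# STARR-seq consensus enhancer calling and input-normalized activity
# profiles.

#' Call consensus STARR-seq enhancers from merged and replicate peaks
#'
#' A merged-library peak is a consensus ("true") enhancer iff it overlaps
#' (>= 1 bp) peaks from at least `min_replicates` distinct biological
#' replicates — the 2-of-3 rule with the default settings. Output
#' coordinates are the merged-peak coordinates.
#'
#' @param merged_peaks Interval tibble of peaks called on pooled replicate
#'   reads.
#' @param replicate_peaks List of interval tibbles, one per replicate
#'   (>= 2).
#' @param min_replicates Minimum distinct replicates supporting a merged
#'   peak (default 2).
#' @return Subset of `merged_peaks` with an added `n_replicates` support
#'   column.
#' @export
call_consensus_enhancers <- function(merged_peaks, replicate_peaks,
                                     min_replicates = 2) {
  validate_intervals(merged_peaks)
  if (length(replicate_peaks) == 0L) stop("no replicates supplied", call. = FALSE)
  if (min_replicates > length(replicate_peaks)) {
    stop("min_replicates exceeds the number of replicates", call. = FALSE)
  }
  support <- vapply(replicate_peaks, function(rep) {
    overlaps_any(merged_peaks, rep)
  }, logical(nrow(merged_peaks)))
  if (nrow(merged_peaks) == 1L) support <- matrix(support, nrow = 1)
  n_rep <- if (nrow(merged_peaks)) rowSums(support) else integer(0)
  out <- merged_peaks[n_rep >= min_replicates, , drop = FALSE]
  out$n_replicates <- n_rep[n_rep >= min_replicates]
  out
}

#' Input-normalized STARR-seq activity profiles
#'
#' Per-locus binned profile of `FPKPM(starr) - FPKPM(input)`: the
#' depth-normalized subtraction used to visualize enhancer activity over
#' bound regions. Antisymmetric under swapping the two libraries.
#'
#' @param starr_fragments,input_fragments Fragment interval tibbles.
#' @param loci Interval tibble of regions to profile.
#' @param starr_library_size,input_library_size Library sizes (defaults:
#'   fragment counts).
#' @param window Profile window in bp (default 2000).
#' @param n_bins Bins per window; default 200 gives 10 bp bins.
#' @return Numeric matrix, loci x bins.
#' @export
input_normalized_signal <- function(starr_fragments, input_fragments, loci,
                                    starr_library_size = nrow(starr_fragments),
                                    input_library_size = nrow(input_fragments),
                                    window = 2000, n_bins = 200) {
  heatmap_matrix(loci, starr_fragments, starr_library_size, window, n_bins) -
    heatmap_matrix(loci, input_fragments, input_library_size, window, n_bins)
}

#' Fraction of query intervals overlapping a reference set
#'
#' @param query Non-empty interval tibble.
#' @param reference Interval tibble.
#' @return Scalar in `[0, 1]`: the fraction of query intervals overlapping
#'   (>= 1 bp) at least one reference interval.
#' @export
overlap_fraction <- function(query, reference) {
  validate_intervals(query)
  if (nrow(query) == 0L) stop("empty query", call. = FALSE)
  mean(overlaps_any(query, reference))
}
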