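# STARR-seq fixture generator: per-replicate peak calls with imperfect
# sensitivity plus injected false positives, and a pooled ("merged") call
# set with the pooled detection probability.

#' Simulate STARR-seq replicate and merged peak calls
#'
#' Each true enhancer is called in each replicate independently with
#' probability `sensitivity`, and in the merged (pooled-reads) set with
#' probability `1 - (1 - sensitivity)^n_replicates` (approximating pooled
#' power). False-positive peaks are injected into every call set at rate
#' `fp_rate` (as a fraction of the number of true enhancers), at random
#' positions drawn away from the true set.
#'
#' @param enhancers Interval tibble of true enhancers (needs `chrom`,
#'   `start`, `end`; `locus_id` preserved if present).
#' @param n_replicates Number of biological replicates (default 3).
#' @param sensitivity Per-replicate detection probability in (0, 1].
#' @param fp_rate False positives per true enhancer (default 0.05).
#' @param chrom_lengths Named lengths used to place false positives;
#'   defaults to the maximum coordinate seen per chromosome plus 10 kb.
#' @param seed RNG seed.
#' @return List of class `starr_call_set`: `replicate_peaks` (list of
#'   interval tibbles), `merged_peaks` (interval tibble), `truth` (the
#'   input enhancers), `min_replicates` default 2.
#' @export
simulate_starr <- function(enhancers, n_replicates = 3, sensitivity = 0.8,
                           fp_rate = 0.05, chrom_lengths = NULL, seed = 1) {
  validate_intervals(enhancers)
  if (sensitivity <= 0 || sensitivity > 1) {
    stop("sensitivity must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(enhancers)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(enhancers$end, enhancers$chrom, max) + 10000
  }
  width <- if (n) round(median(enhancers$end - enhancers$start)) else 500
  n_fp <- round(fp_rate * n)
  set.seed(seed)
  random_fps <- function() {
    if (n_fp == 0L) return(empty_intervals())
    ch <- sample(names(chrom_lengths), n_fp, replace = TRUE)
    at <- floor(runif(n_fp) * (unlist(chrom_lengths)[ch] - width))
    fp <- tibble::tibble(chrom = ch, start = at, end = at + width)
    # keep false positives off the true set so they stay false
    fp[!overlaps_any(fp, enhancers), , drop = FALSE]
  }
  replicate_peaks <- lapply(seq_len(n_replicates), function(r) {
    hit <- runif(n) < sensitivity
    dplyr::bind_rows(enhancers[hit, , drop = FALSE], random_fps())
  })
  merged_hit <- runif(n) < (1 - (1 - sensitivity)^n_replicates)
  merged_peaks <- dplyr::bind_rows(enhancers[merged_hit, , drop = FALSE],
                                   random_fps())
  structure(
    list(replicate_peaks = replicate_peaks, merged_peaks = merged_peaks,
         truth = enhancers, min_replicates = 2),
    class = "starr_call_set"
  )
}
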