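# The default synthetic scenario: one call that wires the genome, binding,
# accessibility and STARR generators together with the default study
# conditions, returning everything plus the truth tables.

#' Default motif-class mix of the synthetic scenario
#'
#' Fractions of planted loci per motif class; scaled to `n_loci` by
#' [simulate_scenario()].
#'
#' @return Named numeric vector summing to 1.
#' @export
default_motif_mix <- function() {
  c(SoxOct = 0.30, MORE = 7 / 30, octamer = 1 / 6, MORE_plus1 = 0.10,
    Sox_single = 0.20)
}

#' Run the full default synthetic scenario
#'
#' Generates a genome with planted motif instances, simulates
#' dimerization-ruled binding for the Oct4, Oct4defSox2 and Oct6 cocktails
#' at days 1 and 5, simulates MEF and per-condition ATAC-seq accessibility
#' under the logistic opening model, and simulates STARR-seq replicate and
#' merged peak calls over the loci open in the Oct4 day-1 condition.
#' Deterministic given `seed`; sub-stages draw from fixed offsets of it.
#'
#' @param n_loci Total planted loci (default 3000).
#' @param seed Master seed.
#' @param params Opening-model parameters ([opening_params()]).
#' @param rules Binding rules ([default_factor_rules()]).
#' @param motif_mix Named fractions per motif class
#'   ([default_motif_mix()]).
#' @param chrom_lengths Chromosome lengths for the synthetic genome.
#' @param starr_sensitivity Per-replicate STARR detection probability.
#' @param starr_fp_rate STARR false-positive rate.
#' @return List: `genome`, `truth` (planted motifs), `binding`, `summits`,
#'   `chip_peaks`, `atac` (see [simulate_accessibility()]), `starr`
#'   ([simulate_starr()]), `params`, `rules`, `config` (echo of all
#'   arguments).
#' @export
simulate_scenario <- function(n_loci = 3000, seed = 1,
                              params = opening_params(),
                              rules = default_factor_rules(),
                              motif_mix = default_motif_mix(),
                              chrom_lengths = c(chrS1 = 2e6, chrS2 = 1e6),
                              starr_sensitivity = 0.8,
                              starr_fp_rate = 0.05) {
  counts <- floor(motif_mix * n_loci)
  # distribute rounding remainder over the largest classes
  rem <- n_loci - sum(counts)
  if (rem > 0) {
    top <- order(motif_mix, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  gs <- generate_genome(counts, chrom_lengths = chrom_lengths, seed = seed)
  bd <- simulate_binding(gs$truth, rules = rules, seed = seed + 1)
  at <- simulate_accessibility(gs$truth, bd$binding, params = params,
                               seed = seed + 2)
  open_day1 <- at$state[at$state$condition == "Oct4.day1" & at$state$open, ]
  enhancers <- at$windows[at$windows$locus_id %in% open_day1$locus_id, ]
  st <- simulate_starr(enhancers, sensitivity = starr_sensitivity,
                       fp_rate = starr_fp_rate,
                       chrom_lengths = chrom_lengths, seed = seed + 3)
  list(
    genome = gs$genome, truth = gs$truth,
    binding = bd$binding, summits = bd$summits, chip_peaks = bd$peaks,
    atac = at, starr = st, params = params, rules = rules,
    config = list(n_loci = n_loci, seed = seed, motif_counts = counts,
                  chrom_lengths = chrom_lengths,
                  starr_sensitivity = starr_sensitivity,
                  starr_fp_rate = starr_fp_rate)
  )
}
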