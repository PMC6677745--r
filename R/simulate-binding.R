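# Factor- and day-specific binding simulation governed by dimerization
# rules: Oct4 heterodimerizes with Sox2 on SoxOct; Oct6 homodimerizes on
# MORE; the Sox2-heterodimerization-deficient Oct4 mutant binds SoxOct early
# but loses it by day 5 while retaining residual MORE binding; Sox2 binds
# single Sox sites on its own and co-binds SoxOct only alongside a
# heterodimerization-competent POU partner.

#' Default per-(factor, day, motif-class) binding probabilities
#'
#' Encodes the dimerization preferences of the default scenario: Oct4 high
#' on SoxOct at both days; the Sox2-heterodimerization-deficient Oct4
#' mutant (`Oct4defSox2`) high on SoxOct at day 1 but near zero by day 5,
#' with residual MORE binding persisting; Oct6 high on MORE (and the 1-bp
#' spacer variant) at both days and low on SoxOct; Sox2 binding single Sox
#' sites independently of the POU partner. Sox2 at SoxOct loci is governed
#' by the co-binding rule in [simulate_binding()], not by this table.
#'
#' @return Tibble `(factor, day, class, prob)` covering all four factors,
#'   both days and all five motif classes.
#' @export
default_factor_rules <- function() {
  rule <- function(factor, octamer, SoxOct, MORE, MORE_plus1, Sox_single, day) {
    tibble::tibble(
      factor = factor, day = day,
      class = c("octamer", "SoxOct", "MORE", "MORE_plus1", "Sox_single"),
      prob = c(octamer, SoxOct, MORE, MORE_plus1, Sox_single)
    )
  }
  dplyr::bind_rows(
    rule("Oct4",        0.50, 0.85, 0.40, 0.30, 0.05, "day1"),
    rule("Oct4",        0.50, 0.90, 0.40, 0.30, 0.05, "day5"),
    rule("Oct4defSox2", 0.40, 0.80, 0.40, 0.30, 0.05, "day1"),
    rule("Oct4defSox2", 0.20, 0.02, 0.30, 0.20, 0.02, "day5"),
    rule("Oct6",        0.50, 0.10, 0.85, 0.60, 0.02, "day1"),
    rule("Oct6",        0.50, 0.10, 0.85, 0.60, 0.02, "day5"),
    rule("Sox2",        0.02, 0.00, 0.02, 0.02, 0.70, "day1"),
    rule("Sox2",        0.02, 0.00, 0.02, 0.02, 0.70, "day5")
  )
}

#' Simulate factor binding over planted loci
#'
#' For every reprogramming cocktail (a POU factor co-expressed with Sox2)
#' and day, each planted locus is bound by the POU factor with the
#' probability its `(factor, day, class)` rule specifies, independently
#' across loci. Sox2 binds per its own rules, except at SoxOct loci where
#' the co-binding rule applies: Sox2 co-binds iff the POU partner is bound
#' there *and* is heterodimerization-competent (in addition to any residual
#' direct-binding probability). Bound loci emit a ChIP-seq summit at the
#' motif center plus uniform jitter.
#'
#' @param truth Planted-motif truth from [generate_genome()].
#' @param rules Rule table (see [default_factor_rules()]); must cover every
#'   requested `(factor, day, class)` combination.
#' @param cocktails POU factors to simulate as cocktails (each paired with
#'   Sox2).
#' @param days Ordered day labels.
#' @param competent Named logical: which POU factors are
#'   Sox2-heterodimerization-competent.
#' @param jitter Maximum absolute summit jitter in bp (uniform on
#'   `-jitter..jitter`).
#' @param seed RNG seed.
#' @return List: `binding` (tibble `locus_id`, `class`, `cocktail`, `tf`,
#'   `day`, `bound`), `summits` (tibble `chrom`, `pos`, `source`,
#'   `locus_id` for bound loci; `source` is `<cocktail>.<tf>.<day>`), and
#'   `peaks` (narrowPeak-style tibble, 100 bp flanks around each summit).
#' @export
simulate_binding <- function(truth, rules = default_factor_rules(),
                             cocktails = c("Oct4", "Oct4defSox2", "Oct6"),
                             days = c("day1", "day5"),
                             competent = c(Oct4 = TRUE, Oct4defSox2 = FALSE,
                                           Oct6 = FALSE),
                             jitter = 20, seed = 1) {
  stopifnot(all(cocktails %in% names(competent)))
  n <- nrow(truth)
  lookup <- function(factor, day, class) {
    p <- rules$prob[rules$factor == factor & rules$day == day &
                      rules$class == class]
    if (length(p) != 1L) {
      stop("missing binding rule for (", factor, ", ", day, ", ", class, ")",
           call. = FALSE)
    }
    p
  }
  set.seed(seed)
  rows <- list()
  for (ck in cocktails) {
    for (d in days) {
      p_pou <- vapply(truth$class, function(cl) lookup(ck, d, cl), numeric(1))
      pou_bound <- runif(n) < p_pou
      p_sox <- vapply(truth$class, function(cl) lookup("Sox2", d, cl), numeric(1))
      sox_bound <- runif(n) < p_sox
      at_soxoct <- truth$class == "SoxOct"
      # heterodimer co-binding: Sox2 joins the POU factor on SoxOct only
      # when the partner can heterodimerize
      sox_bound[at_soxoct] <- sox_bound[at_soxoct] |
        (pou_bound[at_soxoct] & isTRUE(competent[[ck]]))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        locus_id = rep(truth$locus_id, 2L),
        class = rep(truth$class, 2L),
        cocktail = ck,
        tf = rep(c(ck, "Sox2"), each = n),
        day = d,
        bound = c(pou_bound, sox_bound)
      )
    }
  }
  binding <- dplyr::bind_rows(rows)
  bound <- binding[binding$bound, ]
  m <- match(bound$locus_id, truth$locus_id)
  pos <- truth$center[m] + sample(-jitter:jitter, nrow(bound), replace = TRUE)
  pos <- pmax(pos, 0)
  summits <- tibble::tibble(
    chrom = truth$chrom[m],
    pos = pos,
    source = paste(bound$cocktail, bound$tf, bound$day, sep = "."),
    locus_id = bound$locus_id
  )
  peaks <- tibble::tibble(
    chrom = summits$chrom,
    start = pmax(summits$pos - 100, 0),
    end = summits$pos + 100,
    name = paste0(summits$locus_id, "_", summits$source),
    score = 0, strand = ".",
    signal = 0, pvalue = -1, qvalue = -1,
    summit_offset = summits$pos - pmax(summits$pos - 100, 0),
    summit = summits$pos,
    source = summits$source
  )
  list(binding = binding, summits = summits, peaks = peaks)
}
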