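# Logistic chromatin-opening model with overdispersed count emission, plus
# the refit used for parameter recovery. Sox2 binding is the dominant
# opening term and POU binding an augmenting one.

#' Opening-model parameters
#'
#' The probability a locus is open in a condition is
#' `plogis(beta0 + betaS * S + betaO * O + betaOS * S * O)` where `S` and
#' `O` indicate Sox2 and POU binding. Open loci emit negative-binomial
#' fragment counts with mean `open_mean`, closed loci with mean
#' `closed_mean`; `dispersion` is the NB overdispersion (variance
#' `mu + dispersion * mu^2`).
#'
#' @param beta0 Baseline log-odds of open (default -2).
#' @param betaS Sox2-binding coefficient (default 2).
#' @param betaO POU-binding coefficient (default 0.5).
#' @param betaOS Interaction coefficient (default 1).
#' @param open_mean,closed_mean Expected fragment counts for open/closed
#'   loci (defaults 40 / 5; must satisfy `open_mean > closed_mean > 0`).
#' @param dispersion NB overdispersion (> 0, default 0.3).
#' @return List of class `opening_params`.
#' @export
opening_params <- function(beta0 = -2, betaS = 2, betaO = 0.5, betaOS = 1,
                           open_mean = 40, closed_mean = 5, dispersion = 0.3) {
  if (!(open_mean > closed_mean && closed_mean > 0)) {
    stop("need open_mean > closed_mean > 0", call. = FALSE)
  }
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  structure(list(beta0 = beta0, betaS = betaS, betaO = betaO, betaOS = betaOS,
                 open_mean = open_mean, closed_mean = closed_mean,
                 dispersion = dispersion),
            class = "opening_params")
}

#' Simulate ATAC-seq accessibility from binding truth
#'
#' For each condition (MEF plus every cocktail x day), each locus is open
#' with the logistic probability given its Sox2/POU binding state in that
#' condition; in MEF no factor is present so both binding indicators are
#' zero and opening occurs at the baseline rate `plogis(beta0)`. Open and
#' closed loci emit negative-binomial fragment counts (means `open_mean` /
#' `closed_mean`), and each count materializes as that many fragments of
#' length `frag_len` placed uniformly within the locus window
#' (`center +/- locus_halfwidth`). ATAC peaks are the windows of loci whose
#' emitted count reaches `peak_min`.
#'
#' @param truth Planted-motif truth from [generate_genome()].
#' @param binding Binding tibble from [simulate_binding()].
#' @param params An [opening_params()] object.
#' @param conditions Cocktail/day conditions to emit, as a tibble
#'   `(cocktail, day)`; defaults to every combination present in `binding`.
#' @param locus_halfwidth Half-width of the locus window in bp (default
#'   250, i.e. 500 bp windows).
#' @param frag_len Fragment length in bp (default 100).
#' @param peak_min Minimum count for a locus window to be called an ATAC
#'   peak (default 15).
#' @param seed RNG seed.
#' @return List: `state` (tibble `locus_id`, `condition`, `sox2_bound`,
#'   `pou_bound`, `p_open`, `open`, `count`), `fragments` (named list of
#'   interval tibbles per condition), `peaks` (named list of interval
#'   tibbles per condition), `windows` (locus-window tibble with `rep_pos`),
#'   `library_sizes` (named numeric).
#' @export
simulate_accessibility <- function(truth, binding, params = opening_params(),
                                   conditions = NULL, locus_halfwidth = 250,
                                   frag_len = 100, peak_min = 15, seed = 1) {
  stopifnot(inherits(params, "opening_params"))
  if (is.null(conditions)) {
    conditions <- dplyr::distinct(binding[c("cocktail", "day")])
  }
  windows <- tibble::tibble(
    locus_id = truth$locus_id,
    chrom = truth$chrom,
    start = pmax(truth$center - locus_halfwidth, 0),
    end = truth$center + locus_halfwidth,
    rep_pos = truth$center
  )
  n <- nrow(truth)
  cond_names <- c("MEF", paste(conditions$cocktail, conditions$day, sep = "."))
  set.seed(seed)
  state_rows <- list()
  fragments <- list()
  peaks <- list()
  for (ci in seq_along(cond_names)) {
    cname <- cond_names[ci]
    if (cname == "MEF") {
      S <- O <- rep(FALSE, n)
    } else {
      ck <- conditions$cocktail[ci - 1L]
      d <- conditions$day[ci - 1L]
      sub <- binding[binding$cocktail == ck & binding$day == d, ]
      pou <- sub[sub$tf == ck, ]
      sox <- sub[sub$tf == "Sox2", ]
      O <- pou$bound[match(truth$locus_id, pou$locus_id)]
      S <- sox$bound[match(truth$locus_id, sox$locus_id)]
      O[is.na(O)] <- FALSE
      S[is.na(S)] <- FALSE
    }
    p_open <- stats::plogis(params$beta0 + params$betaS * S +
                              params$betaO * O + params$betaOS * (S & O))
    open <- runif(n) < p_open
    mu <- ifelse(open, params$open_mean, params$closed_mean)
    count <- rnbinom(n, size = 1 / params$dispersion, mu = mu)
    state_rows[[ci]] <- tibble::tibble(
      locus_id = truth$locus_id, condition = cname,
      sox2_bound = S, pou_bound = O, p_open = p_open,
      open = open, count = count
    )
    idx <- rep.int(seq_len(n), count)
    fstart <- windows$start[idx] +
      floor(runif(length(idx)) * (windows$end[idx] - windows$start[idx] - frag_len + 1))
    fragments[[cname]] <- tibble::tibble(
      chrom = windows$chrom[idx],
      start = fstart,
      end = fstart + frag_len,
      locus_id = windows$locus_id[idx]
    )
    peaks[[cname]] <- windows[count >= peak_min, , drop = FALSE]
  }
  list(
    state = dplyr::bind_rows(state_rows),
    fragments = fragments,
    peaks = peaks,
    windows = windows,
    library_sizes = vapply(fragments, nrow, numeric(1))
  )
}

#' Simulate opening-model truth for parameter recovery
#'
#' Draws independent Bernoulli Sox2/POU binding indicators and an open
#' state from the logistic model — the minimal design for refitting the
#' model coefficients.
#'
#' @param n Number of loci.
#' @param params An [opening_params()] object.
#' @param p_sox,p_pou Marginal binding probabilities (default 0.5).
#' @param seed RNG seed.
#' @return Tibble `(sox2_bound, pou_bound, open)`.
#' @export
simulate_opening_truth <- function(n, params = opening_params(),
                                   p_sox = 0.5, p_pou = 0.5, seed = 1) {
  stopifnot(inherits(params, "opening_params"))
  set.seed(seed)
  S <- runif(n) < p_sox
  O <- runif(n) < p_pou
  p <- stats::plogis(params$beta0 + params$betaS * S + params$betaO * O +
                       params$betaOS * (S & O))
  tibble::tibble(sox2_bound = S, pou_bound = O, open = runif(n) < p)
}

#' Refit the logistic opening model
#'
#' Logistic regression of the open state on the Sox2 and POU binding
#' indicators and their interaction; the inverse operation of
#' [simulate_accessibility()]'s opening step.
#'
#' @param state Tibble with logical columns `sox2_bound`, `pou_bound`,
#'   `open` (e.g. from [simulate_opening_truth()] or the `state` table of
#'   [simulate_accessibility()]).
#' @return Named numeric `c(beta0, betaS, betaO, betaOS)`.
#' @export
fit_opening_model <- function(state) {
  fit <- stats::glm(open ~ sox2_bound * pou_bound,
                    family = stats::binomial(), data = state)
  co <- stats::coef(fit)
  stats::setNames(as.numeric(co), c("beta0", "betaS", "betaO", "betaOS"))
}
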