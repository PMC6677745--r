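# Co-binding classification of close-to-open loci and the opening
# attribution report: per-class accessibility-ratio summaries with pairwise
# rank-sum tests and Holm correction.

#' Classify loci by co-binding of two factors
#'
#' Overlap-based (>= 1 bp) membership against two ChIP-seq peak sets:
#' `shared` (overlaps both), `A_only`, `B_only`, `neither`. The class labels
#' can be renamed for the factors at hand (e.g. `Sox2_only`, `Oct4_only`).
#'
#' @param universe Locus interval tibble.
#' @param peaks_a,peaks_b Peak interval tibbles for the two factors.
#' @param labels Length-4 character vector naming the
#'   `(A_only, B_only, shared, neither)` classes.
#' @return Factor of class labels, one per universe row.
#' @export
classify_cobinding <- function(universe, peaks_a, peaks_b,
                               labels = c("A_only", "B_only", "shared", "neither")) {
  stopifnot(length(labels) == 4L)
  in_a <- overlaps_any(universe, peaks_a)
  in_b <- overlaps_any(universe, peaks_b)
  cls <- ifelse(in_a & in_b, labels[3],
                ifelse(in_a, labels[1], ifelse(in_b, labels[2], labels[4])))
  factor(cls, levels = labels)
}

#' Unpaired two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney U with midrank tie handling. The p-value is exact (full
#' enumeration of rank assignments) when `length(x) + length(y) <= 12` and
#' there are no ties, and a normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `statistic` (U for `x`) and `p.value`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12)) # exact p = 0.1
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided")
  )
  p <- wt$p.value
  # fully degenerate samples (every value tied) carry no evidence
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p.value = p)
}

#' Holm step-down adjustment of p-values
#'
#' Sort ascending, multiply the i-th smallest p by `m - i + 1`, enforce the
#' running maximum, cap at 1 and restore the input order.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04)) # 0.03 0.04 0.04
#' @export
holm_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "holm")
}

#' Opening-attribution report across co-binding classes
#'
#' Summarises per-class accessibility ratios (n, median, quartiles) and
#' tests every pair of eligible classes with the unpaired Wilcoxon rank-sum
#' test, adjusting the whole pairwise family with the Holm method (the
#' `pairwise.wilcox.test` convention). Classes with fewer than `min_n` loci
#' are excluded from testing with a warning.
#'
#' @param classes Factor (or character) of co-binding class labels, one per
#'   locus.
#' @param ratios Per-locus accessibility ratios, parallel to `classes`.
#' @param min_n Minimum class size to enter testing (default 3).
#' @return List of class `attribution_report`: `summary` tibble
#'   `(class, n, q25, median, q75)` and `tests` tibble
#'   `(class_a, class_b, statistic, p, p_holm)`.
#' @export
opening_attribution <- function(classes, ratios, min_n = 3) {
  stopifnot(length(classes) == length(ratios))
  classes <- as.factor(classes)
  keep <- !is.na(ratios) & !is.na(classes)
  classes <- droplevels(classes[keep])
  ratios <- ratios[keep]
  summ <- tibble::tibble(class = levels(classes)) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n = sum(classes == .data$class),
      q25 = quantile(ratios[classes == .data$class], 0.25),
      median = median(ratios[classes == .data$class]),
      q75 = quantile(ratios[classes == .data$class], 0.75)
    ) |>
    dplyr::ungroup()
  eligible <- summ$class[summ$n >= min_n]
  dropped <- setdiff(summ$class, eligible)
  if (length(dropped)) {
    warning("class(es) excluded from testing (n < ", min_n, "): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(eligible) < 2L) {
    stop("fewer than 2 classes eligible for testing", call. = FALSE)
  }
  pairs <- utils::combn(eligible, 2)
  tests <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    rs <- rank_sum_test(ratios[classes == a], ratios[classes == b])
    tibble::tibble(class_a = a, class_b = b,
                   statistic = rs$statistic, p = rs$p.value)
  })
  tests <- dplyr::bind_rows(tests)
  tests$p_holm <- holm_adjust(tests$p)
  structure(list(summary = summ, tests = tests), class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("Opening attribution report\n\nPer-class accessibility ratios:\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat("\nPairwise rank-sum tests (Holm-adjusted):\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}

#' Export an attribution report
#'
#' Writes the summary and test tables as tab-separated files and a combined
#' JSON document.
#'
#' @param report An `attribution_report`.
#' @param prefix Output path prefix; writes `<prefix>_summary.tsv`,
#'   `<prefix>_tests.tsv`, `<prefix>.json`.
#' @return The JSON path, invisibly.
#' @export
write_attribution_report <- function(report, prefix) {
  stopifnot(inherits(report, "attribution_report"))
  write.table(report$summary, paste0(prefix, "_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$tests, paste0(prefix, "_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  json_path <- paste0(prefix, ".json")
  jsonlite::write_json(list(summary = report$summary, tests = report$tests),
                       json_path, digits = NA, auto_unbox = TRUE)
  invisible(json_path)
}
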