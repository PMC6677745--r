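# Binary occupancy trajectories, accessibility tiers and open/closed
# chromatin trajectory labels.

#' Assign binary occupancy codes to merged loci across conditions
#'
#' Pools the summits of all conditions, merges them into loci
#' ([merge_summits()], default 100 bp single linkage) and assigns each locus
#' a binary code over the ordered condition list: digit *i* is `1` iff the
#' locus contains at least one summit from condition *i* (e.g. `"110"` =
#' bound at days 1 and 5 but not day 7). All-zero codes cannot arise because
#' loci are built from the union of the conditions' summits.
#'
#' @param summits Tibble with columns `chrom`, `pos`, `source`; `source`
#'   values must be drawn from `conditions`.
#' @param conditions Character vector giving the condition order (left to
#'   right in the code). Must be unique.
#' @param max_dist Summit merge distance in bp (default 100).
#' @return The [merge_summits()] tibble with an added `code` column.
#' @examples
#' s <- tibble::tibble(chrom = "chr1", pos = c(1000, 1010, 5000),
#'                     source = c("day1", "day5", "day7"))
#' assign_occupancy_codes(s, c("day1", "day5", "day7"))
#' @export
assign_occupancy_codes <- function(summits, conditions, max_dist = 100) {
  if (anyDuplicated(conditions)) {
    stop("duplicate condition labels", call. = FALSE)
  }
  if (nrow(summits) && !all(summits$source %in% conditions)) {
    bad <- setdiff(unique(summits$source), conditions)
    stop("summit source(s) not in conditions: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  loci <- merge_summits(summits, max_dist = max_dist)
  loci$code <- vapply(loci$members, function(m) {
    paste(as.integer(conditions %in% m$source), collapse = "")
  }, character(1))
  loci
}

#' Enumerate all possible occupancy trajectory codes
#'
#' All binary strings of length `k` except the all-zero string, in
#' descending binary order: 7 trajectory groups for 3 conditions, 15 for 4.
#'
#' @param k Number of conditions (>= 1).
#' @return Character vector of `2^k - 1` codes.
#' @examples
#' enumerate_trajectories(3)
#' @export
enumerate_trajectories <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  vals <- (2^k - 1):1
  vapply(vals, function(v) {
    paste(rev(as.integer(intToBits(v))[seq_len(k)]), collapse = "")
  }, character(1))
}

#' Summarise trajectory group sizes
#'
#' @param coded Output of [assign_occupancy_codes()].
#' @return Tibble `(code, n, fraction)` sorted in descending binary code
#'   order; codes absent from the data are omitted.
#' @export
trajectory_summary <- function(coded) {
  stopifnot("code" %in% names(coded))
  k <- nchar(coded$code[1])
  lev <- enumerate_trajectories(k)
  coded |>
    dplyr::count(code = factor(.data$code, levels = lev), name = "n") |>
    dplyr::mutate(code = as.character(.data$code),
                  fraction = .data$n / sum(.data$n))
}

#' Classify loci into accessibility tiers by raw fragment count
#'
#' The canonical MEF accessibility tiering of bound sites: counts below
#' `low_below` are `low`, counts from `low_below` to `high_above` inclusive
#' are `medium`, counts above `high_above` are `high` (defaults 15/30, i.e.
#' low < 15, medium = 15 to 30, high > 30).
#'
#' @param count Non-negative raw fragment counts (vectorized).
#' @param low_below,high_above Tier boundaries; `low_below <= high_above`.
#' @return Factor with levels `low`, `medium`, `high`.
#' @examples
#' accessibility_tier(c(14, 15, 30, 31))
#' @export
accessibility_tier <- function(count, low_below = 15, high_above = 30) {
  if (low_below > high_above) stop("low_below must be <= high_above", call. = FALSE)
  if (any(count < 0)) stop("negative count", call. = FALSE)
  tier <- ifelse(count < low_below, "low",
                 ifelse(count > high_above, "high", "medium"))
  factor(tier, levels = c("low", "medium", "high"))
}

#' Classify open/closed chromatin trajectories between two time points
#'
#' Builds the locus universe as the overlap-merged union of the two peak
#' sets and labels every universe locus:
#' `PO` (permanently open: ATAC peak in both MEF and the later condition),
#' `OC` (open to close: MEF only), `CO` (close to open: later only).
#' Presence is >= 1 bp interval overlap.
#'
#' @param mef_peaks,later_peaks ATAC peak interval tibbles for the starting
#'   (MEF) and later condition.
#' @return Tibble of universe loci (`chrom`, `start`, `end`) with a `label`
#'   factor (`PO`/`OC`/`CO`).
#' @export
chromatin_trajectory <- function(mef_peaks, later_peaks) {
  validate_intervals(mef_peaks)
  validate_intervals(later_peaks)
  universe <- merge_intervals(dplyr::bind_rows(
    mef_peaks[c("chrom", "start", "end")],
    later_peaks[c("chrom", "start", "end")]
  ))
  in_mef <- overlaps_any(universe, mef_peaks)
  in_later <- overlaps_any(universe, later_peaks)
  universe$label <- factor(
    ifelse(in_mef & in_later, "PO", ifelse(in_mef, "OC", "CO")),
    levels = c("PO", "OC", "CO")
  )
  universe
}
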