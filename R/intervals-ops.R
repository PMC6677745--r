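# Overlap logic, summit merging and resizing. All coordinates are BED
# convention (0-based half-open); two intervals overlap iff they share >= 1 bp.

# Convert a BED-convention tibble to GRanges (1-based closed) for the bulk
# overlap machinery. The +1 shift is confined to this helper and its inverse.
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Test whether two genomic intervals overlap
#'
#' Half-open overlap: `a` and `b` overlap iff they are on the same chromosome
#' and share at least one base, i.e. `a$start < b$end && b$start < a$end`.
#' Adjacent intervals (`a$end == b$start`) do not overlap. Vectorized and
#' symmetric in its arguments.
#'
#' @param a,b Interval tibbles (columns `chrom`, `start`, `end`), recycled
#'   row-wise to a common length.
#' @return Logical vector.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 199, end = 300)
#' overlaps(a, b) # TRUE: one shared base
#' @export
overlaps <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Flag query intervals overlapping any reference interval
#'
#' `bedtools intersect -wa -u` semantics: one logical per query row, `TRUE`
#' iff it overlaps (>= 1 bp) at least one interval in `reference`.
#'
#' @param query,reference Interval tibbles.
#' @return Logical vector of length `nrow(query)`.
#' @export
overlaps_any <- function(query, reference) {
  validate_intervals(query)
  validate_intervals(reference)
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(reference) == 0L) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_granges(query), as_granges(reference))
}

#' Collapse overlapping intervals into a non-overlapping union
#'
#' bedtools-merge-like reduction: intervals sharing at least one base are
#' merged transitively into their envelope. Used to build locus universes
#' (e.g. the union of MEF and day-1 ATAC peaks).
#'
#' @param x Interval tibble.
#' @return Tibble of disjoint intervals sorted by `chrom`, `start`, with an
#'   `n_members` column counting collapsed inputs.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0L) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_members = integer()))
  }
  gr <- as_granges(x)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = as.numeric(GenomicRanges::end(red)),
    n_members = lengths(S4Vectors::mcols(red)$revmap)
  )
}

#' Merge ChIP-seq summits within a distance into loci
#'
#' Single-linkage merging of summit positions: two summits on the same
#' chromosome end up in the same locus iff they are connected by a chain of
#' pairwise distances `<= max_dist`. This is the classic binary-group
#' preprocessing step for occupancy-trajectory analysis, with the canonical
#' 100 bp merge distance as default.
#'
#' Each merged locus records the envelope of its member summits
#' (`start` = min position, `end` = max position + 1), a representative
#' position `rep_pos` (floor of the envelope midpoint) and its members as a
#' list-column of `(source, pos)` tibbles.
#'
#' @param summits Tibble with columns `chrom`, `pos` (0-based summit
#'   position) and optionally `source` (condition label; defaults to `"."`).
#' @param max_dist Maximum distance (bp) for two summits to be chained into
#'   one locus. Default 100.
#' @return Tibble with columns `locus_id`, `chrom`, `start`, `end`,
#'   `rep_pos`, `n_summits`, `members` (list-column).
#' @examples
#' s <- tibble::tibble(chrom = "chr1", pos = c(1000, 1090, 1500),
#'                     source = c("d1", "d5", "d1"))
#' merge_summits(s, max_dist = 100)
#' @export
merge_summits <- function(summits, max_dist = 100) {
  stopifnot(is.data.frame(summits), max_dist >= 0)
  if (!all(c("chrom", "pos") %in% names(summits))) {
    stop("summit table needs columns chrom, pos", call. = FALSE)
  }
  if (nrow(summits) && any(summits$pos < 0)) {
    stop("negative summit position", call. = FALSE)
  }
  if (!"source" %in% names(summits)) summits$source <- "."
  if (nrow(summits) == 0L) {
    return(tibble::tibble(locus_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          rep_pos = numeric(), n_summits = integer(),
                          members = list()))
  }
  s <- dplyr::arrange(summits, .data$chrom, .data$pos)
  # a new locus starts at each within-chromosome gap exceeding max_dist;
  # sorted single-linkage on a line reduces to this split
  grp <- s |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.grp = cumsum(c(TRUE, diff(.data$pos) > max_dist))) |>
    dplyr::ungroup()
  out <- grp |>
    dplyr::group_by(.data$chrom, .data$.grp) |>
    dplyr::summarise(
      start = min(.data$pos),
      end = max(.data$pos) + 1,
      n_summits = dplyr::n(),
      members = list(dplyr::pick(dplyr::all_of(c("source", "pos")))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(
      rep_pos = floor((.data$start + .data$end) / 2),
      locus_id = sprintf("locus_%05d", dplyr::row_number())
    ) |>
    dplyr::select("locus_id", "chrom", "start", "end", "rep_pos",
                  "n_summits", "members")
  out
}

#' Resize intervals to a fixed width around an anchor
#'
#' Re-centers each interval on its anchor (the interval center, or its
#' `summit` column) and extends to the requested width. Even widths place
#' the anchor in the left-center cell (`start = anchor - width %/% 2` for odd
#' widths; for even widths the anchor sits at `start + width/2`). Intervals
#' running off the chromosome start are clipped at 0 and extended rightward
#' so the output width is always exactly `width`.
#'
#' @param x Interval tibble; needs a `summit` column when
#'   `anchor = "summit"`.
#' @param width Target width in bp (> 0).
#' @param anchor `"center"` (midpoint of the input interval) or `"summit"`.
#' @return Tibble with `start`/`end` replaced; other columns preserved.
#' @export
resize_to_width <- function(x, width, anchor = c("center", "summit")) {
  anchor <- match.arg(anchor)
  validate_intervals(x)
  stopifnot(width > 0)
  pos <- if (anchor == "summit") {
    if (!"summit" %in% names(x)) stop("anchor = \"summit\" needs a summit column", call. = FALSE)
    x$summit
  } else {
    floor((x$start + x$end) / 2)
  }
  start <- pos - width %/% 2
  start <- pmax(start, 0)
  x$start <- start
  x$end <- start + width
  x
}
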