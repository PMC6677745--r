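#' Read genomic intervals from BED or narrowPeak files
#'
#' Intervals are represented throughout the package as tibbles in BED
#' convention: `start` is 0-based inclusive, `end` is 0-based exclusive.
#' Comment lines beginning with `#`, `track` or `browser` are skipped.
#'
#' For narrowPeak input (ENCODE 10-column format) the point-source offset in
#' column 10 is resolved to an absolute `summit` position
#' (`summit = start + offset`); an offset of -1 (no summit called) yields
#' `NA`.
#'
#' @param path Path to a tab-separated BED3/BED6 or narrowPeak file.
#' @param format Either `"bed"` or `"narrowpeak"`.
#'
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`; narrowPeak adds `signal`, `pvalue`,
#'   `qvalue`, `summit_offset` and `summit`. Row order follows the file.
#'
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", tf)
#' read_intervals(tf)
#' @export
read_intervals <- function(path, format = c("bed", "narrowpeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  line_no <- seq_along(lines)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  line_no <- line_no[keep]
  min_cols <- if (format == "bed") 3L else 10L
  if (length(lines) == 0L) {
    return(empty_intervals(format))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    bad <- line_no[which(nf < min_cols)[1]]
    stop(sprintf("malformed line %d in %s: expected >= %d tab-separated columns",
                 bad, path, min_cols), call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- line_no[which(is.na(start) | is.na(end))[1]]
    stop(sprintf("malformed line %d in %s: non-numeric coordinates", bad, path),
         call. = FALSE)
  }
  if (any(start < 0) || any(end < 0)) {
    bad <- line_no[which(start < 0 | end < 0)[1]]
    stop(sprintf("malformed line %d in %s: negative coordinate", bad, path),
         call. = FALSE)
  }
  if (any(end <= start)) {
    bad <- line_no[which(end <= start)[1]]
    stop(sprintf("malformed line %d in %s: end must exceed start", bad, path),
         call. = FALSE)
  }
  out <- tibble::tibble(chrom = col(1), start = start, end = end)
  maxf <- max(nf)
  if (maxf >= 4L) out$name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else ".", character(1))
  if (maxf >= 5L) out$score <- suppressWarnings(as.numeric(vapply(fields, function(f) if (length(f) >= 5) f[[5]] else "0", character(1))))
  if (maxf >= 6L) out$strand <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else ".", character(1))
  if (format == "narrowpeak") {
    out$signal <- as.numeric(col(7))
    out$pvalue <- as.numeric(col(8))
    out$qvalue <- as.numeric(col(9))
    off <- as.numeric(col(10))
    out$summit_offset <- off
    out$summit <- ifelse(off < 0, NA_real_, out$start + off)
  }
  out
}

empty_intervals <- function(format = "bed") {
  out <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  if (format == "narrowpeak") {
    out$name <- character(); out$score <- numeric(); out$strand <- character()
    out$signal <- numeric(); out$pvalue <- numeric(); out$qvalue <- numeric()
    out$summit_offset <- numeric(); out$summit <- numeric()
  }
  out
}

#' Write genomic intervals to BED or narrowPeak files
#'
#' Inverse of [read_intervals()]: the fields a format carries survive a
#' write/read round trip. A BED file is written with as many of the optional
#' `name`/`score`/`strand` columns as the input provides (missing
#' intermediate columns are filled with `.` / `0`); narrowPeak always writes
#' 10 columns, deriving column 10 from `summit` when present.
#'
#' @param x Interval tibble (see [read_intervals()] for the schema).
#' @param path Output path.
#' @param format Either `"bed"` or `"narrowpeak"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "narrowpeak")) {
  format <- match.arg(format)
  validate_intervals(x)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write to ", path, ": directory does not exist", call. = FALSE)
  }
  n <- nrow(x)
  get_or <- function(nm, default) if (nm %in% names(x)) x[[nm]] else rep(default, n)
  if (format == "bed") {
    cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
    have <- intersect(c("name", "score", "strand"), names(x))
    upto <- if ("strand" %in% have) 3L else if ("score" %in% have) 2L else if ("name" %in% have) 1L else 0L
    if (upto >= 1L) cols <- c(cols, list(get_or("name", ".")))
    if (upto >= 2L) cols <- c(cols, list(get_or("score", 0)))
    if (upto >= 3L) cols <- c(cols, list(get_or("strand", ".")))
  } else {
    off <- if ("summit" %in% names(x)) {
      ifelse(is.na(x$summit), -1, x$summit - x$start)
    } else {
      get_or("summit_offset", -1)
    }
    cols <- list(x$chrom, format_coord(x$start), format_coord(x$end),
                 get_or("name", "."), get_or("score", 0), get_or("strand", "."),
                 get_or("signal", 0), get_or("pvalue", -1), get_or("qvalue", -1),
                 format_coord(off))
  }
  df <- as.data.frame(cols, optional = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("interval table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x)) {
    if (any(!nzchar(x$chrom))) stop("empty chromosome name", call. = FALSE)
    if (any(x$start < 0)) stop("negative start coordinate", call. = FALSE)
    if (any(x$end <= x$start)) stop("end must exceed start", call. = FALSE)
  }
  invisible(x)
}
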