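# Position weight matrices: construction from consensus strings, palindrome
# detection, and readers for MEME-minimal and plain tab-matrix formats.

DNA_BASES <- c("A", "C", "G", "T")

#' Build a PWM from an IUPAC consensus string
#'
#' Each consensus base receives probability `match_prob` and the three other
#' bases `(1 - match_prob) / 3`; `N` positions get a uniform column. Columns
#' are floored at a pseudo-probability (default 1e-3) and renormalized. The
#' match threshold is set to `threshold_frac` of the maximum attainable
#' log-odds score against a uniform background, and palindromicity is
#' auto-detected (a palindromic motif equals its own reverse complement and
#' is scanned on one strand only, avoiding double counts).
#'
#' @param consensus Consensus string over `A`,`C`,`G`,`T`,`N` (width >= 4).
#' @param match_prob Probability of the consensus base, in (0.25, 1).
#' @param name Motif-class label (defaults to the consensus string).
#' @param threshold_frac Match threshold as a fraction of the maximum score
#'   (default 0.85).
#' @param pseudo_floor Minimum cell probability before renormalization.
#' @return An object of class `pwm`: list with `name`, `matrix` (4 x width,
#'   rows A/C/G/T), `log_odds`, `width`, `score_threshold`, `max_score`,
#'   `palindromic`.
#' @examples
#' pwm_from_consensus("ATGCAAAT", name = "octamer")
#' @export
pwm_from_consensus <- function(consensus, match_prob = 0.85, name = consensus,
                               threshold_frac = 0.85, pseudo_floor = 1e-3) {
  consensus <- toupper(consensus)
  bases <- strsplit(consensus, "")[[1]]
  if (!all(bases %in% c(DNA_BASES, "N"))) {
    stop("consensus may only contain A, C, G, T, N", call. = FALSE)
  }
  if (length(bases) < 4L) stop("consensus width must be >= 4", call. = FALSE)
  if (match_prob <= 0.25 || match_prob >= 1) {
    stop("match_prob must lie in (0.25, 1)", call. = FALSE)
  }
  mat <- vapply(bases, function(b) {
    if (b == "N") rep(0.25, 4) else ifelse(DNA_BASES == b, match_prob, (1 - match_prob) / 3)
  }, numeric(4))
  rownames(mat) <- DNA_BASES
  colnames(mat) <- NULL
  new_pwm(name = name, matrix = mat, threshold_frac = threshold_frac,
          pseudo_floor = pseudo_floor)
}

new_pwm <- function(name, matrix, threshold_frac = 0.85, pseudo_floor = 1e-3,
                    score_threshold = NULL) {
  stopifnot(nrow(matrix) == 4L, ncol(matrix) >= 4L)
  rownames(matrix) <- DNA_BASES
  matrix <- pmax(matrix, pseudo_floor)
  matrix <- sweep(matrix, 2, colSums(matrix), "/")
  lo <- log(matrix / 0.25)
  max_score <- sum(apply(lo, 2, max))
  if (is.null(score_threshold)) score_threshold <- threshold_frac * max_score
  if (score_threshold > max_score + 1e-9) {
    stop("score threshold exceeds the maximum attainable score", call. = FALSE)
  }
  structure(
    list(name = name, matrix = matrix, log_odds = lo, width = ncol(matrix),
         score_threshold = score_threshold, max_score = max_score,
         palindromic = pwm_matrix_palindromic(matrix)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  width %d  threshold %.2f/%.2f  %s\n",
              x$name, x$width, x$score_threshold, x$max_score,
              if (x$palindromic) "palindromic" else "non-palindromic"))
  invisible(x)
}

reverse_complement_string <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
}

# reverse complement of a 4 x w probability (or log-odds) matrix:
# reverse the columns and swap A<->T, C<->G rows
revcomp_matrix <- function(mat) {
  out <- mat[c("T", "G", "C", "A"), rev(seq_len(ncol(mat))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

pwm_matrix_palindromic <- function(mat, tol = 1e-9) {
  all(abs(mat - revcomp_matrix(mat)) < tol)
}

#' Test whether a motif is a reverse-complement palindrome
#'
#' A DNA motif is palindromic iff its reverse complement equals itself
#' (only possible for even widths). Accepts a consensus string or a `pwm`
#' object (matrix compared to its reverse complement within 1e-9).
#'
#' @param x Consensus string or `pwm`.
#' @return Logical scalar.
#' @examples
#' is_palindromic("ATGCATATGCAT") # MORE: TRUE
#' is_palindromic("ATGCAAAT")     # octamer: FALSE
#' @export
is_palindromic <- function(x) {
  if (inherits(x, "pwm")) return(pwm_matrix_palindromic(x$matrix))
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x) == reverse_complement_string(x)
}

#' Default POU motif PWM set
#'
#' Consensus-derived PWMs for the five motif classes the occupancy and
#' accessibility analyses use: the octamer (`ATGCAAAT`), the composite
#' SoxOct element (`CATTGTTATGCAAAT`), the palindromic MORE
#' (`ATGCATATGCAT`), the MORE variant with a 1 bp spacer
#' (`ATGCATNATGCAT`) and the single Sox site (`CATTGTT`). The SoxOct and
#' MORE+1 consensus are configurable placeholders for the corresponding
#' motif-database entries; any PWM read with [read_pwms()] may be
#' substituted.
#'
#' @param match_prob,threshold_frac Passed to [pwm_from_consensus()].
#' @return Named list of `pwm` objects.
#' @export
pou_pwms <- function(match_prob = 0.85, threshold_frac = 0.85) {
  consensi <- c(
    octamer = "ATGCAAAT",
    SoxOct = "CATTGTTATGCAAAT",
    MORE = "ATGCATATGCAT",
    MORE_plus1 = "ATGCATNATGCAT",
    Sox_single = "CATTGTT"
  )
  lapply(setNames(names(consensi), names(consensi)), function(nm) {
    pwm_from_consensus(consensi[[nm]], match_prob = match_prob, name = nm,
                       threshold_frac = threshold_frac)
  })
}

#' Read PWMs from MEME minimal or tab-matrix text
#'
#' Supports (i) MEME minimal format (`MOTIF` blocks with a
#' `letter-probability matrix` header, rows = positions, columns = A C G T)
#' and (ii) a bare tab-separated matrix with 4 columns (A C G T; rows =
#' positions) and an optional `>name` header line per motif.
#'
#' @param path Text file path.
#' @param format `"meme"` or `"tab"`.
#' @param threshold_frac Match threshold fraction passed to the constructor.
#' @return Named list of `pwm` objects.
#' @export
read_pwms <- function(path, format = c("meme", "tab"), threshold_frac = 0.85) {
  format <- match.arg(format)
  lines <- readLines(path)
  out <- list()
  if (format == "meme") {
    motif_at <- grep("^MOTIF\\b", lines)
    if (!length(motif_at)) stop("no MOTIF blocks in ", path, call. = FALSE)
    bounds <- c(motif_at, length(lines) + 1L)
    for (i in seq_along(motif_at)) {
      block <- lines[motif_at[i]:(bounds[i + 1L] - 1L)]
      name <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
      hdr <- grep("letter-probability matrix", block)
      if (!length(hdr)) stop("MOTIF ", name, " lacks a letter-probability matrix", call. = FALSE)
      rows <- block[-seq_len(hdr)]
      rows <- rows[grepl("^\\s*[0-9.eE+-]", rows)]
      m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
      out[[name]] <- new_pwm(name, t(m), threshold_frac = threshold_frac)
    }
  } else {
    lines <- lines[nzchar(trimws(lines))]
    name_at <- grep("^>", lines)
    if (!length(name_at)) {
      name_at <- 0L
      names_vec <- "pwm_1"
    } else {
      names_vec <- sub("^>\\s*", "", lines[name_at])
    }
    bounds <- c(name_at, length(lines) + 1L)
    for (i in seq_along(names_vec)) {
      rows <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
      m <- do.call(rbind, lapply(strsplit(rows, "\t", fixed = TRUE), as.numeric))
      if (ncol(m) != 4L) stop("tab PWM must have 4 columns (A C G T)", call. = FALSE)
      out[[names_vec[i]]] <- new_pwm(names_vec[i], t(m), threshold_frac = threshold_frac)
    }
  }
  out
}
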