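# PWM scanning and per-locus motif-class annotation.

#' Scan a DNA sequence with a PWM
#'
#' Scores every offset by log-odds against a uniform (0.25) background and
#' reports the offsets reaching the PWM's score threshold. Non-palindromic
#' motifs are scanned on both strands (a minus-strand match is a match of
#' the reverse-complemented PWM on the forward sequence, reported at its
#' forward-strand offset); palindromic motifs are scanned on the plus strand
#' only so a perfect palindrome is counted once, not twice. `N` bases score
#' 0 (neutral): an N run can never reach a stringent threshold on its own.
#'
#' @param seq DNA string over `A`,`C`,`G`,`T`,`N` (case-insensitive).
#' @param pwm A `pwm` object.
#' @return Tibble `(offset, strand, score)` sorted by offset; `offset` is
#'   the 0-based start of the match window on the forward strand. Sequences
#'   shorter than the motif yield an empty tibble.
#' @examples
#' more <- pwm_from_consensus("ATGCATATGCAT", name = "MORE")
#' scan_sequence("ATGCATATGCAT", more) # one match, not two
#' @export
scan_sequence <- function(seq, pwm) {
  stopifnot(inherits(pwm, "pwm"), is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) && !all(chars %in% c(DNA_BASES, "N"))) {
    stop("sequence may only contain A, C, G, T, N", call. = FALSE)
  }
  codes <- match(chars, DNA_BASES) # N -> NA, scored 0 in score_offsets
  n <- length(codes) - pwm$width + 1L
  empty <- tibble::tibble(offset = integer(), strand = character(),
                          score = numeric())
  if (n < 1L) return(empty)
  thr <- pwm$score_threshold - 1e-9
  plus <- score_offsets(codes, pwm$log_odds)
  hits <- tibble::tibble(offset = which(plus >= thr) - 1L, strand = "+",
                         score = plus[plus >= thr])
  if (!pwm$palindromic) {
    minus <- score_offsets(codes, revcomp_matrix(pwm$log_odds))
    hits <- dplyr::bind_rows(hits, tibble::tibble(
      offset = which(minus >= thr) - 1L, strand = "-",
      score = minus[minus >= thr]
    ))
  }
  dplyr::arrange(hits, .data$offset, .data$strand)
}

# integer codes (A=1..T=4, N=NA) for a DNA string
seq_to_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
}

# fast presence test over pre-coded sequences: TRUE iff any offset on any
# scanned strand reaches the threshold; avoids per-window result assembly
scan_presence <- function(codes_list, pwm) {
  thr <- pwm$score_threshold - 1e-9
  lo <- pwm$log_odds
  lo_rc <- if (!pwm$palindromic) revcomp_matrix(lo) else NULL
  vapply(codes_list, function(codes) {
    if (length(codes) < pwm$width) return(FALSE)
    if (any(score_offsets(codes, lo) >= thr)) return(TRUE)
    !is.null(lo_rc) && any(score_offsets(codes, lo_rc) >= thr)
  }, logical(1), USE.NAMES = FALSE)
}

# total log-odds at every offset; one vectorized pass per motif column
score_offsets <- function(codes, lo) {
  w <- ncol(lo)
  n <- length(codes) - w + 1L
  s <- numeric(n)
  for (j in seq_len(w)) {
    v <- unname(lo[, j])[codes[j:(j + n - 1L)]]
    v[is.na(v)] <- 0
    s <- s + v
  }
  s
}

#' Read a genome FASTA into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; record names are
#' truncated at the first whitespace (chromosome names).
#'
#' @param path FASTA path (multi-record, wrapped lines supported).
#' @return Named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Annotate loci with motif-class presence
#'
#' Extracts a window (default 200 bp) centered on each locus's
#' representative position (`rep_pos` if present, else the interval
#' midpoint), scans it with every PWM and records per-class presence plus
#' the derived categories: `any` (>= 1 class present), `none` (no class),
#' `all` (every class present). Windows are clipped at chromosome
#' boundaries.
#'
#' @param loci Interval tibble (optionally with `rep_pos`, `locus_id`).
#' @param genome Named character vector of chromosome sequences (see
#'   [read_genome()]), or a FASTA path.
#' @param pwms Named list of `pwm` objects (default [pou_pwms()]).
#' @param window Scan window width in bp (default 200, i.e. +/- 100 around
#'   the center).
#' @return Tibble with `locus_id`, one logical column per PWM name, and
#'   `any`, `none`, `all`.
#' @export
annotate_loci <- function(loci, genome, pwms = pou_pwms(), window = 200) {
  validate_intervals(loci)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  stopifnot(is.character(genome), !is.null(names(genome)), length(pwms) >= 1L)
  missing_chroms <- setdiff(unique(loci$chrom), names(genome))
  if (length(missing_chroms)) {
    stop("chromosome(s) missing from genome: ",
         paste(missing_chroms, collapse = ", "), call. = FALSE)
  }
  center <- if ("rep_pos" %in% names(loci)) loci$rep_pos else floor((loci$start + loci$end) / 2)
  half <- window %/% 2
  wstart <- pmax(center - half, 0)
  wend <- pmin(wstart + window, nchar(genome)[match(loci$chrom, names(genome))])
  seqs <- substring(genome[match(loci$chrom, names(genome))], wstart + 1, wend)
  codes_list <- lapply(seqs, seq_to_codes)
  pres <- vapply(pwms, function(p) scan_presence(codes_list, p),
                 logical(nrow(loci)))
  if (nrow(loci) == 1L) pres <- matrix(pres, nrow = 1, dimnames = list(NULL, names(pwms)))
  out <- tibble::as_tibble(as.data.frame(pres))
  out$any <- rowSums(pres) > 0
  out$none <- !out$any
  out$all <- rowSums(pres) == length(pwms)
  id <- if ("locus_id" %in% names(loci)) loci$locus_id else sprintf("locus_%05d", seq_len(nrow(loci)))
  dplyr::bind_cols(tibble::tibble(locus_id = id), out)
}

#' Flag loci carrying two motif classes concurrently
#'
#' @param annotations Output of [annotate_loci()].
#' @param class_x,class_y Column names of the two classes.
#' @return Logical vector (`TRUE` where both classes are present).
#' @export
has_both <- function(annotations, class_x, class_y) {
  stopifnot(class_x %in% names(annotations), class_y %in% names(annotations))
  annotations[[class_x]] & annotations[[class_y]]
}

#' Per-group motif-class fractions
#'
#' For annotations grouped by an occupancy-trajectory code (or any other
#' grouping), computes the fraction of loci in each group carrying each
#' motif class or derived category. `any` and `none` sum to 1 within every
#' group.
#'
#' @param annotations Output of [annotate_loci()].
#' @param groups Grouping vector (e.g. trajectory codes), one per
#'   annotation row.
#' @param classes Columns to summarise (default: every logical column).
#' @return Tibble `(group, class, n, fraction)`.
#' @export
motif_fractions <- function(annotations, groups,
                            classes = NULL) {
  stopifnot(nrow(annotations) == length(groups))
  if (is.null(classes)) {
    classes <- names(annotations)[vapply(annotations, is.logical, logical(1))]
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(annotations[classes], group = as.character(groups)),
    cols = dplyr::all_of(classes), names_to = "class", values_to = "present"
  )
  long |>
    dplyr::group_by(.data$group, .data$class) |>
    dplyr::summarise(n = dplyr::n(), fraction = mean(.data$present),
                     .groups = "drop")
}

#' Measure the empirical false-positive rate of a PWM set
#'
#' Scans `n_windows` i.i.d. uniform random windows (no planted motifs) and
#' reports, per class, the fraction of windows with at least one match —
#' the per-window false-positive rate of the chosen threshold.
#'
#' @param pwms Named list of `pwm` objects.
#' @param n_windows Number of random windows.
#' @param window Window width in bp.
#' @param seed RNG seed.
#' @return Tibble `(class, fp_rate)`.
#' @export
measure_fp_rate <- function(pwms = pou_pwms(), n_windows = 1000, window = 200,
                            seed = 1) {
  set.seed(seed)
  codes_list <- lapply(seq_len(n_windows), function(i) {
    sample.int(4L, window, replace = TRUE)
  })
  rates <- vapply(pwms, function(p) mean(scan_presence(codes_list, p)),
                  numeric(1))
  tibble::tibble(class = names(pwms), fp_rate = unname(rates))
}
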