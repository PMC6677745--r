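# Synthetic genome with planted motif instances. Everything downstream of
# the generator (binding, accessibility, STARR) is keyed to the truth table
# it returns, so every analysis stage has a ground truth to recover.

MOTIF_CONSENSI <- c(
  octamer = "ATGCAAAT",
  SoxOct = "CATTGTTATGCAAAT",
  MORE = "ATGCATATGCAT",
  MORE_plus1 = "ATGCATNATGCAT",
  Sox_single = "CATTGTT"
)

#' Generate a synthetic genome with planted motif instances
#'
#' Background bases are i.i.d. uniform over A/C/G/T; motif instances are
#' exact consensus strings (`N` positions drawn uniformly) planted
#' non-overlapping at recorded positions and strands, at least
#' `min_spacing` bp apart so each scan window contains at most one
#' instance. Fully deterministic given the seed: the same `(config, seed)`
#' reproduces the genome byte for byte.
#'
#' @param motif_counts Named integer vector: instances to plant per motif
#'   class (names from `octamer`, `SoxOct`, `MORE`, `MORE_plus1`,
#'   `Sox_single`).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param min_spacing Minimum distance between planted instances (>= 200).
#' @param seed RNG seed.
#' @return List: `genome` (named character vector), `truth` (tibble
#'   `locus_id`, `chrom`, `start`, `end`, `center`, `class`, `strand`).
#' @examples
#' gs <- generate_genome(c(SoxOct = 5, MORE = 5),
#'                       chrom_lengths = c(chrS1 = 50000), seed = 1)
#' gs$truth
#' @export
generate_genome <- function(motif_counts,
                            chrom_lengths = c(chrS1 = 2e6, chrS2 = 1e6),
                            min_spacing = 500, seed = 1) {
  stopifnot(!is.null(names(motif_counts)), !is.null(names(chrom_lengths)))
  unknown <- setdiff(names(motif_counts), names(MOTIF_CONSENSI))
  if (length(unknown)) {
    stop("unknown motif class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (min_spacing < 200) stop("min_spacing must be >= 200 bp", call. = FALSE)
  n_total <- sum(motif_counts)
  max_w <- max(nchar(MOTIF_CONSENSI[names(motif_counts)]))
  pitch <- min_spacing + max_w
  set.seed(seed)
  slot_tbl <- dplyr::bind_rows(lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(from = min_spacing,
                  to = len - min_spacing - max_w, by = pitch)
    tibble::tibble(chrom = ch, start = starts)
  }))
  if (nrow(slot_tbl) < n_total) {
    stop("infeasible packing: ", n_total, " motifs requested but only ",
         nrow(slot_tbl), " slots available at min_spacing = ", min_spacing,
         call. = FALSE)
  }
  chosen <- slot_tbl[sort(sample.int(nrow(slot_tbl), n_total)), ]
  classes <- sample(rep(names(motif_counts), times = motif_counts))
  strands <- sample(c("+", "-"), n_total, replace = TRUE)
  widths <- nchar(MOTIF_CONSENSI[classes])
  seqs <- lapply(names(chrom_lengths), function(ch) {
    sample(DNA_BASES, chrom_lengths[[ch]], replace = TRUE)
  })
  names(seqs) <- names(chrom_lengths)
  planted <- vapply(seq_len(n_total), function(i) {
    cons <- MOTIF_CONSENSI[[classes[i]]]
    bases <- strsplit(cons, "")[[1]]
    bases[bases == "N"] <- sample(DNA_BASES, sum(bases == "N"), replace = TRUE)
    s <- paste(bases, collapse = "")
    if (strands[i] == "-") s <- reverse_complement_string(s)
    s
  }, character(1))
  for (i in seq_len(n_total)) {
    ch <- chosen$chrom[i]
    at <- chosen$start[i]
    seqs[[ch]][(at + 1):(at + widths[i])] <- strsplit(planted[i], "")[[1]]
  }
  genome <- vapply(seqs, paste, character(1), collapse = "")
  truth <- tibble::tibble(
    locus_id = sprintf("locus_%05d", seq_len(n_total)),
    chrom = chosen$chrom,
    start = chosen$start,
    end = chosen$start + widths,
    center = floor((chosen$start + chosen$start + widths) / 2),
    class = classes,
    strand = strands
  )
  list(genome = genome, truth = truth)
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output FASTA path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
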