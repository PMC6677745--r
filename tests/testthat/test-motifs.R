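# PWM construction, palindrome handling, scanning vs brute-force oracle,
# locus annotation and motif fractions.

test_that("pwm_from_consensus builds normalized columns and validates input", {
  p <- pwm_from_consensus("ATGCAAAT", name = "octamer")
  expect_s3_class(p, "pwm")
  expect_equal(p$width, 8)
  expect_false(p$palindromic)
  expect_true(all(abs(colSums(p$matrix) - 1) < 1e-9))
  expect_equal(unname(p$matrix["A", 1]), 0.85, tolerance = 1e-3)

  m <- pwm_from_consensus("ATGCATATGCAT", name = "MORE")
  expect_true(m$palindromic)
  mp1 <- pwm_from_consensus("ATGCATNATGCAT")
  expect_equal(unname(mp1$matrix[, 7]), rep(0.25, 4))

  expect_error(pwm_from_consensus("ATGX"), "A, C, G, T, N")
  expect_error(pwm_from_consensus("ATGCAAAT", match_prob = 0.25), "match_prob")
  expect_error(pwm_from_consensus("ATG"), "width")
})

test_that("palindrome detection on strings and matrices", {
  expect_true(is_palindromic("ATGCATATGCAT"))
  expect_false(is_palindromic("ATGCAAAT"))
  expect_false(is_palindromic("ATTTGAAATGCAAAT")) # odd length: never palindromic
  expect_true(is_palindromic(pwm_from_consensus("ATGCATATGCAT")))
  expect_false(is_palindromic(pwm_from_consensus("CATTGTTATGCAAAT")))
})

test_that("scanning matches the brute-force two-strand oracle on random sequences", {
  withr::local_seed(21)
  pwms <- list(pwm_from_consensus("ATGCAAAT", name = "octamer",
                                  threshold_frac = 0.6),
               pwm_from_consensus("CATTGTT", name = "Sox_single",
                                  threshold_frac = 0.5))
  for (p in pwms) {
    for (rep in 1:10) {
      seq <- random_dna(sample(200:1000, 1))
      impl <- scan_sequence(seq, p)
      oracle <- oracle_scan(seq, p$matrix, p$score_threshold, p$palindromic)
      expect_equal(impl$offset, oracle$offset)
      expect_equal(impl$strand, oracle$strand)
      expect_equal(impl$score, oracle$score, tolerance = 1e-9)
    }
  }
})

test_that("palindromic motifs are counted once, minus-strand matches found", {
  more <- pwm_from_consensus("ATGCATATGCAT", name = "MORE",
                             threshold_frac = 0.9)
  hits <- scan_sequence("ATGCATATGCAT", more)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  # on exact-consensus hits, one-strand scanning halves naive double counting:
  # a hypothetical two-strand scan of a perfect palindrome scores both
  # strands identically
  oracle_two_strand <- oracle_scan("ATGCATATGCAT", more$matrix,
                                   more$score_threshold, palindromic = FALSE)
  expect_equal(nrow(oracle_two_strand), 2 * nrow(hits))

  oct <- pwm_from_consensus("ATGCAAAT", name = "octamer")
  rc_hit <- scan_sequence("ATTTGCAT", oct)
  expect_equal(rc_hit$strand, "-")
  expect_equal(rc_hit$offset, 0)
  expect_equal(nrow(scan_sequence("GGGGGGGGGGGG", oct)), 0)
  # short sequence yields empty result, no error
  expect_equal(nrow(scan_sequence("ATG", oct)), 0)
  # N runs never match
  expect_equal(nrow(scan_sequence(strrep("N", 50), oct)), 0)
})

test_that("annotate_loci detects planted motifs and derives categories", {
  withr::local_seed(8)
  flank <- function() random_dna(95)
  genome <- c(
    chrA = paste0(flank(), "CATTGTTATGCAAAT", flank(), # SoxOct at 95
                  "ATGCATATGCAT", flank(), flank())    # MORE at ~205
  )
  loci <- tibble::tibble(chrom = "chrA",
                         start = c(50, 160, 320), end = c(150, 260, 420),
                         rep_pos = c(100, 210, 370))
  ann <- annotate_loci(loci, genome, pou_pwms())
  expect_true(ann$SoxOct[1])
  expect_false(ann$none[1])
  expect_true(ann$MORE[2])
  expect_equal(ann$any, !ann$none)
  # locus 3 sits in random flank: no planted class
  expect_false(ann$SoxOct[3] || ann$MORE[3] || ann$MORE_plus1[3])

  # both(SoxOct, MORE) when the window spans both planted instances
  wide <- tibble::tibble(chrom = "chrA", start = 60, end = 260, rep_pos = 160)
  ann_wide <- annotate_loci(wide, genome, pou_pwms(), window = 250)
  expect_true(has_both(ann_wide, "SoxOct", "MORE"))

  expect_error(annotate_loci(tibble::tibble(chrom = "chrZ", start = 0, end = 10),
                             genome), "chrZ")
})

test_that("annotation is invariant to reverse-complementing the window", {
  withr::local_seed(13)
  pwms <- pou_pwms()[c("octamer", "SoxOct")] # non-palindromic, two strands
  for (rep in 1:10) {
    seq <- paste0(random_dna(60), "CATTGTTATGCAAAT", random_dna(60))
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
    g <- c(fwd = seq, rev = rc)
    loci <- tibble::tibble(chrom = c("fwd", "rev"), start = 0,
                           end = nchar(seq))
    ann <- annotate_loci(loci, g, pwms, window = nchar(seq))
    expect_equal(ann$octamer[1], ann$octamer[2])
    expect_equal(ann$SoxOct[1], ann$SoxOct[2])
  }
})

test_that("PWM readers parse MEME minimal and tab-matrix text", {
  meme <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF octamer", "letter-probability matrix: alength= 4 w= 8",
    " 0.85 0.05 0.05 0.05", " 0.05 0.05 0.05 0.85",
    " 0.05 0.05 0.85 0.05", " 0.05 0.85 0.05 0.05",
    " 0.85 0.05 0.05 0.05", " 0.85 0.05 0.05 0.05",
    " 0.85 0.05 0.05 0.05", " 0.05 0.05 0.05 0.85"
  ), meme)
  pw <- read_pwms(meme, "meme")
  expect_named(pw, "octamer")
  expect_equal(pw$octamer$width, 8)
  # parses to the same matrix as the consensus constructor
  ref <- pwm_from_consensus("ATGCAAAT", name = "octamer")
  expect_equal(pw$octamer$matrix, ref$matrix, tolerance = 1e-6)
  expect_equal(nrow(scan_sequence("ATGCAAAT", pw$octamer)), 1)

  tab <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">simple", "0.97\t0.01\t0.01\t0.01", "0.01\t0.01\t0.01\t0.97",
               "0.01\t0.01\t0.97\t0.01", "0.01\t0.97\t0.01\t0.01"), tab)
  pt <- read_pwms(tab, "tab")
  expect_named(pt, "simple")
  expect_equal(pt$simple$width, 4)
  expect_equal(nrow(scan_sequence("ATGC", pt$simple)), 1)
  expect_error(read_pwms(tab, "meme"), "MOTIF")
})

test_that("measured false-positive rate of the default thresholds is below 5%", {
  fp <- measure_fp_rate(pou_pwms(), n_windows = 2000, seed = 99)
  expect_true(all(fp$fp_rate < 0.05))
})

test_that("motif fractions recover planted per-class frequencies", {
  # 0.4 SoxOct / 0.3 MORE / 0.3 none at n = 500
  gs <- generate_genome(c(SoxOct = 200, MORE = 150),
                        chrom_lengths = c(chrS1 = 1e6), seed = 42)
  planted <- tibble::tibble(
    chrom = gs$truth$chrom,
    start = pmax(gs$truth$center - 100, 0),
    end = gs$truth$center + 100,
    rep_pos = gs$truth$center
  )
  # "none" loci: windows placed in motif-free background
  withr::local_seed(43)
  cand <- tibble::tibble(chrom = "chrS1",
                         start = sample.int(999000, 600), end = NA)
  cand$end <- cand$start + 200
  cand$rep_pos <- cand$start + 100
  none_loci <- cand[!overlaps_any(cand, tibble::tibble(
    chrom = gs$truth$chrom, start = gs$truth$start - 200,
    end = gs$truth$end + 200)), ][1:150, ]
  loci <- dplyr::bind_rows(planted, none_loci)
  ann <- annotate_loci(loci, gs$genome, pou_pwms())
  frac <- motif_fractions(ann, rep("all_loci", nrow(ann)))
  get <- function(cl) frac$fraction[frac$class == cl]
  ci <- function(p, n = 500) 1.96 * sqrt(p * (1 - p) / n)
  expect_lt(abs(get("SoxOct") - 0.4), ci(0.4) + 0.01)
  expect_lt(abs(get("MORE") - 0.3), ci(0.3) + 0.01)
  # any + none = 1 in every group
  expect_equal(get("any") + get("none"), 1)
})
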