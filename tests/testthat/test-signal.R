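# Coverage counting, normalizations, ratios, profile matrices and
# motif-accessibility deviations.

test_that("count_coverage matches the brute-force all-pairs oracle", {
  loci <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  frags <- tibble::tibble(chrom = "chr1",
                          start = c(120, 150, 190, 50, 200),
                          end = c(170, 199, 250, 100, 260))
  # 3 fragments overlap; one ends exactly at locus start (half-open: out),
  # one starts exactly at locus end (out)
  expect_equal(count_coverage(loci, frags), 3)

  withr::local_seed(17)
  for (rep in 1:5) {
    l <- random_intervals(30)
    f <- random_intervals(200)
    impl <- count_coverage(l, f)
    brute <- vapply(seq_len(nrow(l)), function(i) {
      sum(vapply(seq_len(nrow(f)), function(j) oracle_overlaps(l[i, ], f[j, ]),
                 logical(1)))
    }, numeric(1))
    expect_equal(as.numeric(impl), brute)
  }
  expect_equal(count_coverage(l, f[0, ]), rep(0L, nrow(l)))
})

test_that("FPKPM normalization arithmetic and scaling laws", {
  expect_equal(normalize_fpkpm(50, 2000, 1e7), 2.5)
  expect_equal(normalize_fpkpm(0, 2000, 1e7), 0)
  expect_equal(normalize_fpkpm(50, 2000, 2e7), 1.25) # doubling depth halves
  expect_error(normalize_fpkpm(10, 0, 1e6), "locus_length")
  expect_error(normalize_fpkpm(10, 100, 0), "library_size")
})

test_that("quantile normalization matches the sort-and-average oracle", {
  withr::local_seed(31)
  # tie-free instances against the independent oracle
  for (rep in 1:10) {
    m <- matrix(sample.int(10000, 30), ncol = 3)
    expect_equal(quantile_normalize(m), oracle_quantile_norm(m),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # 3x2 instance worked by hand via the oracle
  m32 <- matrix(c(5, 2, 3, 4, 1, 6), ncol = 2)
  expect_equal(unname(quantile_normalize(m32)),
               matrix(c(6.5, 2.5, 4.5, 4.5, 2.5, 6.5), ncol = 2))
  # identical columns: output = input + pseudo-count
  mi <- matrix(c(3, 9, 1, 3, 9, 1), ncol = 2)
  expect_equal(unname(quantile_normalize(mi)), mi + 1)
  # permuted columns share one multiset; all columns identical when sorted
  mp <- cbind(c(4, 8, 15, 16), c(16, 4, 15, 8))
  qn <- quantile_normalize(mp)
  expect_equal(sort(qn[, 1]), sort(qn[, 2]))
  expect_error(quantile_normalize(matrix(1:4, ncol = 1)), "2 samples")
})

test_that("quantile normalization agrees with limma's implementation", {
  withr::local_seed(32)
  m <- matrix(sample.int(50000, 200), ncol = 4)
  ours <- quantile_normalize(m, pseudo_count = 0)
  ref <- limma::normalizeQuantiles(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-9)
})

test_that("accessibility ratios are epsilon-guarded and monotone", {
  expect_equal(accessibility_ratio(2, 2), 1)
  r0 <- accessibility_ratio(5, 0)
  expect_true(is.finite(r0) && r0 > 1)
  day <- seq(0, 10, by = 0.5)
  r <- accessibility_ratio(day, rep(2, length(day)))
  expect_true(all(diff(r) > 0))
  expect_error(accessibility_ratio(-1, 2), "non-negative")
})

test_that("binned profiles place signal where fragments are", {
  loci <- tibble::tibble(chrom = "chr1", start = 4500, end = 5500,
                         rep_pos = 5000)
  # single fragment at the representative position: center bin only
  frag <- tibble::tibble(chrom = "chr1", start = 4995, end = 5005)
  hm <- heatmap_matrix(loci, frag, library_size = 1e6, window = 2000,
                       n_bins = 20)
  expect_equal(unname(which(hm[1, ] > 0)), c(10, 11)) # fragment straddles center
  # uniform carpet gives near-constant rows
  carpet <- tibble::tibble(chrom = "chr1", start = seq(3000, 7000, by = 10),
                           end = seq(3000, 7000, by = 10) + 10)
  hm2 <- heatmap_matrix(loci, carpet, library_size = 1e6, window = 2000,
                        n_bins = 20)
  expect_lt(diff(range(hm2[1, ])) / mean(hm2[1, ]), 0.15)
  # window off the chromosome start: left bins zero-padded
  near0 <- tibble::tibble(chrom = "chr1", start = 0, end = 400, rep_pos = 200)
  hm3 <- heatmap_matrix(near0, carpet, library_size = 1e6, window = 2000,
                        n_bins = 20)
  expect_true(all(hm3[1, 1:8] == 0))
  expect_error(heatmap_matrix(loci, frag, window = 2000, n_bins = 30),
               "divisible")
})

test_that("deviation raw values match hand-computed (X - E) / E", {
  counts <- matrix(c(10, 0, 5, 0, 10, 5), ncol = 2,
                   dimnames = list(NULL, c("s1", "s2")))
  dev <- motif_deviation(counts, list(m1 = 1L), n_background = 50, seed = 1)
  # T = (10, 10, 10), N_s = (15, 15), N_tot = 30 -> E = (5, 5); X = (10, 0)
  expect_equal(dev$expected, c(5, 5))
  expect_equal(dev$raw_deviation, c(1, -1))

  # all-peaks set: raw deviation identically zero
  dev_all <- motif_deviation(counts, list(all = 1:3), n_background = 50,
                             seed = 1)
  expect_equal(dev_all$raw_deviation, c(0, 0))

  # proportional columns: raw = 0 for every set, and a zero-sd background
  # reports z as missing with a warning
  prop <- matrix(c(10, 20, 30, 5, 10, 15), ncol = 2)
  # one zero-sd warning per degenerate set
  expect_warning(expect_warning(
    dev_prop <- motif_deviation(prop, list(a = 1:2, b = 2:3),
                                n_background = 50, seed = 1),
    "background sd is zero"
  ), "background sd is zero")
  expect_equal(dev_prop$raw_deviation, rep(0, 4), tolerance = 1e-12)
  expect_true(all(is.na(dev_prop$z)))

  # seeded sampling is reproducible
  withr::local_seed(10)
  big <- matrix(rpois(600, 20), ncol = 3)
  d1 <- motif_deviation(big, list(m = 1:40), n_background = 60, seed = 7)
  d2 <- motif_deviation(big, list(m = 1:40), n_background = 60, seed = 7)
  expect_equal(d1, d2)
  expect_error(motif_deviation(big, list(m = integer(0))), "empty")
  expect_error(motif_deviation(big, list(m = 1:3), n_background = 10), ">= 50")
})

test_that("deviation z ranks conditions by the planted opening pattern", {
  # SoxOct-marked peaks opened only in condition A: z positive in A and
  # A ranks above the other conditions
  withr::local_seed(77)
  n_peaks <- 300
  soxoct <- 1:80
  base <- matrix(rnbinom(n_peaks * 3, mu = 10, size = 5), ncol = 3,
                 dimnames = list(NULL, c("A", "B", "C")))
  base[soxoct, "A"] <- rnbinom(length(soxoct), mu = 40, size = 5)
  dev <- motif_deviation(base, list(SoxOct = soxoct), n_background = 50,
                         seed = 3)
  zA <- dev$z[dev$sample == "A"]
  expect_gt(zA, 0)
  expect_equal(dev$sample[which.max(dev$z)], "A")
})
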