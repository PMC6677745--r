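# Synthetic-data generator: determinism, planted-motif recovery, binding
# rules, the opening model and parameter recovery.

test_that("genome generation is deterministic and plants exactly the config", {
  cfg <- c(SoxOct = 30, MORE = 30, octamer = 20)
  g1 <- generate_genome(cfg, chrom_lengths = c(chrS1 = 2e5), seed = 9)
  g2 <- generate_genome(cfg, chrom_lengths = c(chrS1 = 2e5), seed = 9)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth, g2$truth)
  expect_equal(nrow(g1$truth), 80)
  expect_equal(as.integer(table(g1$truth$class)[c("SoxOct", "MORE", "octamer")]),
               c(30L, 30L, 20L))
  # FASTA bytes identical too
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(g1$genome, f1); write_genome(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  # planted instances respect spacing and do not overlap
  tr <- g1$truth[order(g1$truth$chrom, g1$truth$start), ]
  expect_true(all(diff(tr$start) >= 500))
  expect_error(generate_genome(c(MORE = 1e6),
                               chrom_lengths = c(chrS1 = 1e5)),
               "infeasible")
  expect_error(generate_genome(cfg, min_spacing = 100), "min_spacing")
  expect_error(generate_genome(c(bogus = 5)), "unknown motif class")
})

test_that("scanning the synthetic genome recovers >= 99% of planted instances", {
  cfg <- c(SoxOct = 100, MORE = 100, octamer = 100, MORE_plus1 = 50,
           Sox_single = 50)
  gs <- generate_genome(cfg, chrom_lengths = c(chrS1 = 1e6, chrS2 = 5e5),
                        seed = 33)
  loci <- tibble::tibble(chrom = gs$truth$chrom,
                         start = pmax(gs$truth$center - 100, 0),
                         end = gs$truth$center + 100,
                         rep_pos = gs$truth$center)
  ann <- annotate_loci(loci, gs$genome, pou_pwms())
  hit <- vapply(seq_len(nrow(loci)), function(i) {
    ann[[gs$truth$class[i]]][i]
  }, logical(1))
  expect_gte(mean(hit), 0.99)
})

test_that("binding follows the rules: degenerate probabilities and binomial recovery", {
  gs <- generate_genome(c(SoxOct = 500), chrom_lengths = c(chrS1 = 6e5),
                        seed = 12)
  rules <- default_factor_rules()
  rules$prob[rules$factor == "Oct4" & rules$day == "day1" &
               rules$class == "SoxOct"] <- 1
  rules$prob[rules$factor == "Oct4defSox2" & rules$day == "day5" &
               rules$class == "SoxOct"] <- 0
  rules$prob[rules$factor == "Oct6" & rules$day == "day1" &
               rules$class == "SoxOct"] <- 0.6
  bd <- simulate_binding(gs$truth, rules, seed = 101)
  b <- bd$binding
  # p = 1: every SoxOct locus carries an Oct4 day-1 summit
  expect_true(all(b$bound[b$cocktail == "Oct4" & b$tf == "Oct4" &
                            b$day == "day1"]))
  # p = 0: the deficient mutant loses all SoxOct binding by day 5
  expect_false(any(b$bound[b$cocktail == "Oct4defSox2" &
                             b$tf == "Oct4defSox2" & b$day == "day5"]))
  # p = 0.6 at n = 500: bound fraction within the binomial 95% CI
  frac <- mean(b$bound[b$cocktail == "Oct6" & b$tf == "Oct6" &
                         b$day == "day1"])
  expect_lt(abs(frac - 0.6), 1.96 * sqrt(0.6 * 0.4 / 500))
  # co-binding rule: Sox2 joins Oct4 (competent) on bound SoxOct loci but
  # not the deficient mutant
  oct4_bound <- b$bound[b$cocktail == "Oct4" & b$tf == "Oct4" & b$day == "day1"]
  sox_oct4 <- b$bound[b$cocktail == "Oct4" & b$tf == "Sox2" & b$day == "day1"]
  expect_true(all(sox_oct4[oct4_bound]))
  sox_def <- b$bound[b$cocktail == "Oct4defSox2" & b$tf == "Sox2" &
                       b$day == "day1"]
  expect_lt(mean(sox_def), 0.05)
  # missing rule errors
  expect_error(simulate_binding(gs$truth, rules[rules$factor != "Sox2", ]),
               "missing binding rule")
})

test_that("summits fall within jitter of planted motif centers", {
  gs <- generate_genome(c(MORE = 50), chrom_lengths = c(chrS1 = 1e5),
                        seed = 2)
  bd <- simulate_binding(gs$truth, seed = 3)
  m <- match(bd$summits$locus_id, gs$truth$locus_id)
  expect_true(all(abs(bd$summits$pos - gs$truth$center[m]) <= 20))
})

test_that("the opening model hits its limiting behaviors", {
  gs <- generate_genome(c(SoxOct = 400), chrom_lengths = c(chrS1 = 5e5),
                        seed = 19)
  bd <- simulate_binding(gs$truth, seed = 20)
  # null model: no binding effect, open fraction ~ plogis(beta0) everywhere
  p0 <- opening_params(beta0 = -1, betaS = 0, betaO = 0, betaOS = 0)
  at0 <- simulate_accessibility(gs$truth, bd$binding, p0, seed = 21)
  for (cond in unique(at0$state$condition)) {
    frac <- mean(at0$state$open[at0$state$condition == cond])
    expect_lt(abs(frac - stats::plogis(-1)), 0.06)
  }
  # saturation: huge betaS opens every Sox2-bound locus
  psat <- opening_params(betaS = 50)
  atsat <- simulate_accessibility(gs$truth, bd$binding, psat, seed = 22)
  sx <- atsat$state[atsat$state$sox2_bound, ]
  expect_true(all(sx$open))
  # MEF carries no binding terms
  mef <- atsat$state[atsat$state$condition == "MEF", ]
  expect_false(any(mef$sox2_bound | mef$pou_bound))
  expect_equal(unique(mef$p_open), stats::plogis(psat$beta0))
  # fragment counts match the emitted counts over the locus windows
  cond1 <- atsat$state[atsat$state$condition == "Oct4.day1", ]
  cc <- count_coverage(atsat$windows, atsat$fragments[["Oct4.day1"]])
  expect_equal(as.numeric(cc), cond1$count)
  expect_error(opening_params(open_mean = 3, closed_mean = 5), "open_mean")
  expect_error(opening_params(dispersion = -1), "dispersion")
})

test_that("logistic refit recovers the generating coefficients", {
  params <- opening_params()
  est <- vapply(1:20, function(seed) {
    truth <- simulate_opening_truth(3000, params, seed = seed + 500)
    fit_opening_model(truth)
  }, numeric(4))
  bias <- rowMeans(est) - c(params$beta0, params$betaS, params$betaO,
                            params$betaOS)
  expect_true(all(abs(bias) < 0.3))
  expect_gte(mean(est["betaS", ] > est["betaO", ]), 0.95)
})

test_that("the full scenario is deterministic and internally consistent", {
  sc1 <- simulate_scenario(n_loci = 200, seed = 4,
                           chrom_lengths = c(chrS1 = 3e5))
  sc2 <- simulate_scenario(n_loci = 200, seed = 4,
                           chrom_lengths = c(chrS1 = 3e5))
  expect_identical(sc1$genome, sc2$genome)
  expect_identical(sc1$binding, sc2$binding)
  expect_identical(sc1$atac$state, sc2$atac$state)
  expect_identical(sc1$starr$merged_peaks, sc2$starr$merged_peaks)
  expect_equal(nrow(sc1$truth), 200)
  # every summit's locus exists in the planted truth
  expect_true(all(sc1$summits$locus_id %in% sc1$truth$locus_id))
  # STARR truth is the set of loci open in the Oct4 day-1 condition
  open1 <- sc1$atac$state[sc1$atac$state$condition == "Oct4.day1" &
                            sc1$atac$state$open, "locus_id", drop = TRUE]
  expect_setequal(sc1$starr$truth$locus_id, open1)
})
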