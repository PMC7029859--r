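test_that("genotype tallies exclude missing calls", {
  pop <- pop_from_calls(rbind(c("AA", "AB", "BB", "AB"),
                              c("AA", NA, "BB", NA),
                              c("AB", "AB", "AB", "AB")),
                        map = tiny_map(3))
  cnt <- tabulate_counts(pop)
  expect_equal(cnt$a, c(1, 1, 0))
  expect_equal(cnt$h, c(2, 0, 4))
  expect_equal(cnt$b, c(1, 1, 0))
})

test_that("magnitude of distortion is a/(a+b) with NA for no homozygotes", {
  expect_equal(magnitude(0, 10), 0)
  expect_equal(magnitude(48, 48), 0.5)
  expect_equal(magnitude(95, 100), 95 / 195, tolerance = 1e-12)
  expect_true(is.na(magnitude(0, 0)))
  # antisymmetry under allele-label swap
  set.seed(1)
  a <- rpois(50, 20); b <- rpois(50, 20)
  expect_equal(magnitude(a, b), 1 - magnitude(b, a))
})

test_that("chi-square GOF matches a brute-force oracle and printed values", {
  # independent oracle: direct sum over classes
  brute <- function(obs, prop) {
    e <- prop / sum(prop) * sum(obs)
    sum((obs - e)^2 / e)
  }
  set.seed(2)
  for (i in 1:25) {
    x <- rmultinom(1, sample(50:500, 1), c(0.25, 0.5, 0.25))[, 1]
    expect_equal(chisq_gof(x[1], x[2], x[3], "1:2:1")$chi2,
                 brute(x, c(1, 2, 1)), tolerance = 1e-9)
    expect_equal(chisq_gof(x[1], b = x[3], ratio = "1:1")$chi2,
                 brute(x[c(1, 3)], c(1, 1)), tolerance = 1e-9)
  }
  expect_equal(chisq_gof(75, 150, 75, "1:2:1")$chi2, 0)
  expect_error(chisq_gof(0, 0, 0), "zero")
})

test_that("p-value adjustments match brute-force step-up/Bonferroni oracles", {
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_pvalues(p, "none"), p)
    expect_equal(adjust_pvalues(p, "bonferroni"), oracle_bonferroni(p))
    expect_equal(adjust_pvalues(p, "fdr"), oracle_bh(p), tolerance = 1e-12)
    # cross-check against the reference implementation in stats
    expect_equal(adjust_pvalues(p, "fdr"), p.adjust(p, "BH"))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(adjust_pvalues(p[perm], "fdr"),
                 adjust_pvalues(p, "fdr")[perm])
  }
  expect_equal(adjust_pvalues(c(0.01, 0.2, 0.03), "bonferroni"),
               c(0.03, 0.6, 0.09))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "fdr"),
               rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("distortion scans flag markers correctly and order p-values", {
  # exact 1:2:1 fit: nothing significant under any correction
  n <- 100
  calls <- matrix(rep(c(rep("AA", 25), rep("AB", 50), rep("BB", 25)), 4),
                  nrow = 4, byrow = TRUE)
  pop <- pop_from_calls(calls, tiny_map(4))
  for (corr in c("none", "fdr", "bonferroni"))
    expect_equal(sum(scan_distortion(pop, correction = corr)$significant), 0)

  # lethal selection: selected locus significant under all corrections
  map <- make_clustered_map(50, 60)
  regime <- selection_regime(selection_target("1A", 25, "B", 1))
  pop2 <- simulate_ssd_population(map, 300, "F2", regime, seed = 4)
  for (corr in c("none", "fdr", "bonferroni")) {
    sc <- scan_distortion(pop2, correction = corr)
    expect_true(sc$significant[25])
  }

  # monotone: p_bonf >= p_fdr >= p_raw elementwise
  pop3 <- simulate_ssd_population(map, 96, "F2", seed = 5)
  sc3 <- scan_distortion(pop3)
  expect_true(all(sc3$p_fdr >= sc3$p_raw - 1e-12))
  expect_true(all(sc3$p_bonf >= sc3$p_fdr - 1e-12))

  # auto ratio rule: F2 tests 1:2:1 (df 2), later generations 1:1 (df 1)
  expect_equal(unique(sc3$df), 2L)
  pop6 <- simulate_ssd_population(map, 96, "F6", seed = 6)
  sc6 <- scan_distortion(pop6)
  expect_equal(unique(sc6$df), 1L)
  expect_equal(attr(sc6, "ratio"), "1:1")
})

test_that("SDR detection finds maximal runs of >= 2 significant markers", {
  flags <- c(TRUE, TRUE, FALSE, TRUE)
  cnt <- data.frame(a = c(10, 12, 5, 8), b = c(2, 3, 5, 9))
  sdrs <- detect_sdrs(flags, cnt)
  expect_equal(nrow(sdrs), 1)
  expect_equal(sdrs$start_index, 1)
  expect_equal(sdrs$end_index, 2)
  expect_equal(sdrs$skew, "A")

  expect_equal(nrow(detect_sdrs(c(FALSE, FALSE, FALSE))), 0)

  sdrs3 <- detect_sdrs(rep(TRUE, 3), data.frame(a = c(1, 1, 1), b = c(5, 5, 5)))
  expect_equal(sdrs3$length, 3)
  expect_equal(sdrs3$skew, "B")

  # runs do not straddle chromosome boundaries
  cnt2 <- data.frame(a = rep(5, 4), b = rep(1, 4),
                     chromosome = c("c1", "c1", "c2", "c2"))
  expect_equal(nrow(detect_sdrs(c(FALSE, TRUE, TRUE, FALSE), cnt2)), 0)
})

test_that("SDR overlaps report width and skew agreement", {
  r1 <- data.frame(chromosome = "c1", start_index = 1, end_index = 6,
                   length = 6, skew = "A")
  r2 <- data.frame(chromosome = "c1", start_index = 5, end_index = 10,
                   length = 6, skew = "B")
  ov <- sdr_overlap(r1, r2)
  expect_equal(ov$width, 2)
  expect_false(ov$same_skew)

  r3 <- data.frame(chromosome = "c1", start_index = 8, end_index = 9,
                   length = 2, skew = "A")
  expect_equal(nrow(sdr_overlap(r1, r3)), 0)
  ov2 <- sdr_overlap(r1, r1)
  expect_equal(ov2$width, 6)
  expect_true(ov2$same_skew)
})

test_that("deviation score sums squared departures from 1:1", {
  expect_equal(deviation_score(rep(0.5, 20)), 0)
  expect_equal(deviation_score(1), 0.25)
  expect_equal(deviation_score(c(0.6, 0.4)), 0.02)
  expect_equal(deviation_score(numeric(0)), 0)
  expect_equal(deviation_score(c(0.7, NA)), 0.04)
})

test_that("crossover transition counts weight hom-hom changes double", {
  calls <- cbind(c("AA", "AA", "AA"), c("AA", "AB", "BB"), c("AA", "BB", "AA"))
  pop <- pop_from_calls(calls, tiny_map(3))
  expect_equal(unname(count_crossovers(pop)), c(0, 2, 4))
  # two markers, opposite homozygotes: both gametes recombined
  pop2 <- pop_from_calls(cbind(c("AA", "BB")), tiny_map(2))
  expect_equal(unname(count_crossovers(pop2)), 2)
  # missing-adjacent pairs are skipped
  pop3 <- pop_from_calls(cbind(c("AA", NA, "BB")), tiny_map(3))
  expect_equal(unname(count_crossovers(pop3)), 0)
})

test_that("pairwise distances use the co-dominant mismatch weights", {
  calls <- rbind(c("AA", "AA"), c("AA", "BB"), c("AA", "AA"))
  pop <- pop_from_calls(calls, tiny_map(3))
  D <- pairwise_distance(pop)
  expect_equal(unname(D[1, 3]), 0)
  expect_equal(unname(D[1, 2]), 0.5)
  expect_true(isSymmetric(D))
  calls2 <- rbind(rep("AA", 4), rep("BB", 4), rep("AB", 4))
  D2 <- pairwise_distance(pop_from_calls(calls2, tiny_map(3)))
  expect_equal(unname(D2[1, 2]), 1)
  expect_equal(unname(D2[1, 3]), 0.5)
})

test_that("lag-1 autocorrelation behaves on linear, noise and constant series", {
  expect_equal(segregation_autocorrelation(seq(0, 1, length.out = 50)), 1)
  set.seed(7)
  expect_equal(segregation_autocorrelation(runif(10000)), 0, tolerance = 0.04)
  expect_true(is.na(segregation_autocorrelation(rep(0.5, 10))))
})

test_that("map length estimation inverts the Haldane map function", {
  # single interval with known mismatch fraction: 2 individuals, one
  # recombinant gamete out of 4 -> r proxy 0.25 -> d = -50 log(0.5)
  calls <- cbind(c("AA", "AA"), c("AA", "AB"))
  pop <- pop_from_calls(rbind(calls[1, ], calls[2, ]), tiny_map(2))
  expect_equal(estimate_map_length(pop), -50 * log(1 - 2 * 0.25))
  # zero-distance pairs give length 0
  pop0 <- pop_from_calls(rbind(c("AA", "BB"), c("AA", "BB")), tiny_map(2))
  expect_equal(estimate_map_length(pop0), 0)
})
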