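test_that("the F1 of a biparental cross is heterozygous everywhere", {
  map <- tiny_map(8)
  f1 <- make_f1(map)
  expect_true(all(f1$maternal == "A"))
  expect_true(all(f1$paternal == "B"))
  expect_identical(make_f1(map), f1)
})

test_that("meiosis respects homozygosity and zero-length chromosomes", {
  map <- tiny_map(6, 30)
  homA <- make_f1(map)
  homA$paternal[] <- "A"
  set.seed(1)
  for (i in 1:20) expect_true(all(simulate_gamete(homA, map) == "A"))

  # all markers co-located: no crossovers, gamete is one unrecombined strand
  map0 <- make_custom_map(c(5, 5, 5))
  f1 <- make_f1(map0)
  set.seed(2)
  g <- replicate(50, simulate_gamete(f1, map0))
  expect_true(all(g %in% c("A", "B")))
  expect_true(all(apply(g, 2, function(x) length(unique(x))) == 1))
})

test_that("crossover counts are Poisson with mean L/100 (no interference)", {
  # dense map so that virtually every crossover is visible as an allele
  # switch in an F1 gamete
  map <- make_uniform_map(401, 100)
  f1 <- make_f1(map)
  set.seed(3)
  switches <- replicate(3000, {
    g <- simulate_gamete(f1, map)
    sum(g[-1] != g[-length(g)])
  })
  expect_equal(mean(switches), 1, tolerance = 3 * sqrt(1 / 3000) / 1)
  expect_equal(var(switches), 1, tolerance = 0.12)
})

test_that("selfing an individual combines two independent gametes", {
  map <- tiny_map(5)
  f1 <- make_f1(map)
  set.seed(4)
  off <- self_individual(f1, map)
  expect_s3_class(off, "individual")
  expect_true(all(off$maternal %in% c("A", "B")))

  # fully homozygous parent breeds true
  homB <- make_f1(map)
  homB$maternal[] <- "B"
  off2 <- self_individual(homB, map)
  expect_true(all(off2$maternal == "B") && all(off2$paternal == "B"))

  # Mendelian selfing: single-marker genotype ratio ~ 1/4 : 1/2 : 1/4
  m1 <- make_custom_map(0)
  f1s <- make_f1(m1)
  set.seed(5)
  geno <- replicate(4000, {
    o <- self_individual(f1s, m1)
    sum(c(o$maternal, o$paternal) == "B")
  })
  frac <- as.numeric(table(factor(geno, levels = 0:2)) / 4000)
  expect_lt(max(abs(frac - c(0.25, 0.5, 0.25))), 0.03)
})

test_that("SSD populations have the right shape and are seed-reproducible", {
  map <- tiny_map(7, 50)
  pop <- simulate_ssd_population(map, 30, "F3", seed = 42)
  expect_s3_class(pop, "ssd_pop")
  expect_equal(dim(pop$genotypes), c(7, 30))
  expect_equal(pop$generation, 3L)
  expect_false(anyNA(pop$genotypes))

  pop2 <- simulate_ssd_population(map, 30, 3, seed = 42)
  expect_identical(pop$genotypes, pop2$genotypes)
  pop3 <- simulate_ssd_population(map, 30, 3, seed = 43)
  expect_false(identical(pop$genotypes, pop3$genotypes))

  expect_error(simulate_ssd_population(map, 0, 2), "positive")
  expect_error(simulate_ssd_population(map, 10, 1), "F2 or later")
  expect_error(simulate_ssd_population(map, 10, "F0"), "F2 or later")
})

test_that("F2 genotype frequencies are 1:2:1 multinomial at a marker", {
  pop <- simulate_ssd_population(make_custom_map(0), 1e5, "F2", seed = 7)
  cnt <- tabulate_counts(pop)
  chi <- chisq_gof(cnt$a, cnt$h, cnt$b, "1:2:1")
  expect_gt(chi$p, 0.01)
})

test_that("heterozygosity halves per selfing generation", {
  map <- tiny_map(10, 60)
  set.seed(8)
  for (k in c(2, 4)) {
    het <- mean(replicate(60, heterozygosity(
      simulate_ssd_population(map, 50, k))))
    expected <- 0.5^(k - 1)
    # markers are linked and lines correlated within a replicate, so the
    # replicate-level spread (~2 pp) dominates the binomial s.e.
    expect_lt(abs(het - expected), 0.015)
  }
})

test_that("multi-chromosome maps simulate chromosomes independently", {
  map <- genetic_map(paste0("m", 1:6), rep(c("1A", "6B"), each = 3),
                     c(0, 10, 20, 0, 15, 30))
  pop <- simulate_ssd_population(map, 40, "F2", seed = 9)
  expect_equal(dim(pop$genotypes), c(6, 40))
  expect_equal(pop$map$chromosome, rep(c("1A", "6B"), each = 3))
})
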