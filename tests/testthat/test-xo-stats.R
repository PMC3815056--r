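test_that("fisher_exact matches boundary expectations and published calls", {
  expect_equal(fisher_exact(rbind(c(5, 5), c(5, 5))), 1)
  # the double-crossover comparison: 16 vs 1 among ~100 spores each
  expect_lt(fisher_exact(rbind(c(16, 84), c(1, 99))), 0.01)
  expect_error(fisher_exact(matrix(1, 2, 3)), "2x2")
  expect_error(fisher_exact(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("fisher_exact equals enumeration and the reference implementation", {
  set.seed(11)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:15, 1)), 2, 2)
    if (sum(tab) == 0) next
    p <- fisher_exact(tab)
    expect_equal(p, fisher_enum_2x2(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Pearson chi-square matches the hand formula", {
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  res <- chisq_indep(prop)
  expect_equal(res[["statistic"]], 0)
  expect_equal(res[["p_value"]], 1)

  tab <- rbind(c(10, 90), c(30, 70))
  res2 <- chisq_indep(tab)
  expect_equal(res2[["statistic"]], 12.5)
  expect_equal(res2[["df"]], 1)
  expect_equal(res2[["statistic"]], pearson_x2(tab))

  t25 <- rbind(c(78, 13, 7, 0, 1) + 1, c(62, 11, 12, 4, 17) + 1)
  expect_equal(chisq_indep(t25)[["df"]], 4)
  expect_error(chisq_indep(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("Monte-Carlo chi-square is reproducible and sane at the null", {
  prop <- rbind(c(10, 20), c(20, 40))
  res <- chisq_mc(prop, B = 2000, seed = 1)
  expect_gte(res[["p_value"]], 0.99)

  tab <- rbind(c(12, 3, 9), c(4, 8, 7))
  a <- chisq_mc(tab, B = 2000, seed = 99)
  b <- chisq_mc(tab, B = 2000, seed = 99)
  expect_identical(a, b)
  expect_error(chisq_mc(tab, B = 0), "B")

  # p never collapses to zero: (1 + x) / (B + 1)
  extreme <- rbind(c(50, 0), c(0, 50))
  expect_gte(chisq_mc(extreme, B = 2000, seed = 3)[["p_value"]], 1 / 2001)
})

test_that("Monte-Carlo p converges to the exact conditional p", {
  tab <- rbind(c(7, 2, 1), c(2, 6, 4))
  p_exact <- chisq_perm_exact_2xc(tab)   # X2-ordered permutation p
  p2k <- chisq_mc(tab, B = 2000, seed = 5)[["p_value"]]
  p50k <- chisq_mc(tab, B = 50000, seed = 5)[["p_value"]]
  expect_lt(abs(p2k - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 2000))
  expect_lt(abs(p50k - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 50000))
})

test_that("total viability is the spore-weighted tetrad mean", {
  expect_equal(total_viability(tetrad_counts(rep(4, 100))), 100)
  expect_equal(total_viability(tetrad_counts(rep(0, 100))), 0)
  # published wild-type column: counts sum to 99 tetrads, 365 viable spores
  tc <- tetrad_counts(c(rep(4, 78), rep(3, 13), rep(2, 7), rep(0, 1)))
  expect_equal(total_viability(tc), 100 * 365 / 396)
  expect_error(total_viability(structure(integer(5), class = "tetrad_counts",
                                         names = as.character(4:0))),
               "no tetrads")
})

test_that("tetrad distribution test is exact on small tables", {
  a <- tetrad_counts(c(rep(4, 10), rep(3, 3), rep(2, 2)))
  expect_equal(tetrad_distribution_test(a, a)$p_value, 1, tolerance = 1e-9)

  far_a <- tetrad_counts(rep(4, 100)); far_b <- tetrad_counts(rep(0, 100))
  expect_lt(tetrad_distribution_test(far_a, far_b)$p_value, 1e-15)

  set.seed(23)
  for (i in 1:5) {
    ca <- tetrad_counts(sample(0:4, 15, replace = TRUE))
    cb <- tetrad_counts(sample(0:4, 15, replace = TRUE,
                               prob = c(1, 1, 2, 2, 4)))
    tab <- rbind(as.numeric(ca), as.numeric(cb))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    res <- tetrad_distribution_test(ca, cb)
    expect_identical(res$method, "exact")
    expect_equal(res$p_value, fisher_enum_2xc(tab), tolerance = 1e-7)
  }
})

test_that("spore viability is the unweighted spot mean", {
  expect_equal(spore_viability(data.frame(germinated = rep(50, 5),
                                          total = rep(50, 5))), 100)
  expect_equal(spore_viability(data.frame(germinated = rep(25, 5),
                                          total = rep(50, 5))), 50)
  # unweighted, not pooled: (10% + 60%) / 2, not 40/150
  expect_equal(spore_viability(data.frame(germinated = c(10, 30),
                                          total = c(100, 50))), 35)
  expect_error(spore_viability(data.frame(germinated = numeric(0),
                                          total = numeric(0))), "no spots")
})

test_that("identical maps compare as indistinguishable", {
  ch <- cc_chromosome("chr3")
  mt <- marker_table(data.frame(marker = ch$markers$name, chrom = "chr3",
                                pos_bp = ch$markers$pos_bp))
  pop <- simulate_population(ch, cc_crossover_model("chr3", "wildtype"),
                             sim_config(40, seed = 17))
  im <- interval_map(pop$genotypes, mt)
  cmp <- compare_maps(im, im, B = 500, seed = 2)
  expect_true(all(cmp$per_interval$p_value > 1 - 1e-9, na.rm = TRUE))
  expect_equal(cmp$total$chisq[["p_value"]], 1)
  expect_equal(cmp$total$map_length_a, cmp$total$map_length_b)
})

test_that("map comparison detects a locally tripled interval rate", {
  ch <- cc_chromosome("chr8")
  mt <- marker_table(data.frame(marker = ch$markers$name, chrom = "chr8",
                                pos_bp = ch$markers$pos_bp))
  base <- cc_crossover_model("chr8", "wildtype")
  bumped <- base
  bumped$interval_rates[9] <- base$interval_rates[9] * 3   # I/J hotspot
  hits <- 0
  for (r in 1:10) {
    a <- simulate_population(ch, base, sim_config(25, seed = 300 + r))
    b <- simulate_population(ch, bumped, sim_config(25, seed = 400 + r))
    cmp <- compare_maps(interval_map(a$genotypes, mt),
                        interval_map(b$genotypes, mt), B = 200,
                        seed = 500 + r)
    if (!is.na(cmp$per_interval$p_value[9]) &&
        cmp$per_interval$p_value[9] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 6)   # power well above the 5% false-positive level
})
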