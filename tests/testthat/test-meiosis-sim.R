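chrom1 <- chromosome_def("c1", 1e6, 5e5,
                         data.frame(name = c("L", "M", "R"),
                                    pos_bp = c(1, 5e5, 1e6)))

test_that("crossover model validates its parameters", {
  expect_error(crossover_model("renewal", lambda = 0, obligate_co = TRUE),
               "unsatisfiable")
  expect_error(crossover_model("renewal", lambda = 2, nu = 0.5), "nu")
  m0 <- crossover_model("renewal", lambda = 0)
  set.seed(1)
  for (i in 1:20) expect_equal(nrow(simulate_crossovers(chrom1, m0)), 0L)
})

test_that("renewal crossover counts at nu = 1 are Poisson(lambda)", {
  set.seed(42)
  mod <- crossover_model("renewal", lambda = 2, nu = 1)
  n <- 3000
  counts <- vapply(seq_len(n), function(i)
    nrow(simulate_crossovers(chrom1, mod)), integer(1))
  se <- sqrt(2 / n)                       # Poisson variance = mean
  expect_lt(abs(mean(counts) - 2), 3 * se)
  # zero-class frequency vs Poisson oracle
  expect_lt(abs(mean(counts == 0) - dpois(0, 2)),
            3 * sqrt(dpois(0, 2) * (1 - dpois(0, 2)) / n))
})

test_that("obligate crossover leaves no empty bivalent", {
  set.seed(7)
  mod <- crossover_model("renewal", lambda = 0.5, nu = 1, obligate_co = TRUE)
  counts <- vapply(1:500, function(i)
    nrow(simulate_crossovers(chrom1, mod)), integer(1))
  expect_true(all(counts >= 1L))
})

test_that("tetrad segregation honours the nondisjunction contract", {
  set.seed(3)
  none <- segregate_tetrad(data.frame(pos_bp = numeric(0),
                                      chromatid_a = integer(0),
                                      chromatid_b = integer(0)),
                           chrom1, nd_event = "none")
  # no crossovers: two all-P1 and two all-P2 spores, all viable
  h <- none$haplotypes[[1]]
  expect_equal(sum(apply(h, 1, function(r) all(r == "P1"))), 2)
  expect_equal(sum(apply(h, 1, function(r) all(r == "P2"))), 2)
  expect_true(all(none$viable))

  mi <- segregate_tetrad(list(simulate_crossovers(chrom1,
                              crossover_model("renewal", lambda = 1))),
                         chrom1, nd_event = "MI")
  expect_false(any(mi$euploid))
  expect_false(any(mi$viable))

  mii <- segregate_tetrad(data.frame(pos_bp = numeric(0),
                                     chromatid_a = integer(0),
                                     chromatid_b = integer(0)),
                          chrom1, nd_event = "MII_one")
  expect_equal(sum(mii$euploid), 2L)
  expect_equal(sum(mii$viable), 2L)
})

test_that("population simulation honours noise-rate boundaries", {
  clean <- simulate_population(chrom1,
                               crossover_model("renewal", lambda = 1),
                               sim_config(25, seed = 9))
  expect_equal(nrow(clean$genotypes), 100L)
  expect_false(anyNA(clean$genotypes))

  allna <- simulate_population(chrom1,
                               crossover_model("renewal", lambda = 1),
                               sim_config(10, missing_call_rate = 1, seed = 9))
  expect_true(all(is.na(allna$genotypes)))

  dead <- simulate_population(chrom1,
                              crossover_model("renewal", lambda = 1),
                              sim_config(10, mi_nd_rate = 1, seed = 9))
  expect_equal(nrow(dead$genotypes), 0L)
  expect_identical(unname(tetrad_counts(dead$tetrads)["0"]), 10L)

  empty <- simulate_population(chrom1,
                               crossover_model("renewal", lambda = 1),
                               sim_config(0, seed = 9))
  expect_equal(length(empty$tetrads), 0L)
  expect_equal(nrow(empty$genotypes), 0L)
})

test_that("simulation is reproducible from its seed", {
  cfg <- sim_config(20, mi_nd_rate = 0.1, mii_nd_rate = 0.05,
                    spore_death_rate = 0.1, missing_call_rate = 0.05,
                    seed = 123)
  mod <- crossover_model("renewal", lambda = 1.5, nu = 3)
  a <- simulate_population(chrom1, mod, cfg)
  b <- simulate_population(chrom1, mod, cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(tetrad_counts(a$tetrads), tetrad_counts(b$tetrads))
})

test_that("tetrad viability classes match the closed-form model", {
  v <- 0.05; d <- 0.08; m <- 0.04
  n <- 4000
  pop <- simulate_population(chrom1, crossover_model("renewal", lambda = 1),
                             sim_config(n, mi_nd_rate = d, mii_nd_rate = m,
                                        spore_death_rate = v, seed = 31))
  obs <- as.numeric(tetrad_counts(pop$tetrads)) / n
  expct <- nd_model_probs(v, d, m)
  for (k in 1:5) {
    se <- sqrt(expct[k] * (1 - expct[k]) / n)
    expect_lt(abs(obs[k] - expct[k]), 3 * se + 1e-12)
  }
})

test_that("map length estimated from simulated spores converges to 50*lambda", {
  lam <- 1.6
  k <- 40                                 # intervals
  mk <- data.frame(name = sprintf("m%02d", 1:(k + 1)),
                   pos_bp = seq(1, 1e6, length.out = k + 1))
  ch <- chromosome_def("cd", 1e6, 5e5, mk)
  pop <- simulate_population(ch, crossover_model("renewal", lambda = lam),
                             sim_config(2500, seed = 77))
  im <- interval_map(pop$genotypes, marker_table(
    data.frame(marker = mk$name, chrom = "cd", pos_bp = mk$pos_bp)))
  n <- nrow(pop$genotypes)
  p <- (1 - exp(-lam / k)) / 2            # per-interval recombinant fraction
  bias <- abs(100 * k * p - 50 * lam)     # finite-marker discretization
  se_cm <- 100 * sqrt(k * p * (1 - p) / n)
  expect_lt(abs(map_length(im) - 50 * lam), 4 * se_cm + bias)
  expect_lt(bias / (50 * lam), 0.03)      # dense markers: bias is small
})
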