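test_that("hemizygous_ratio and its error cases", {
  expect_equal(hemizygous_ratio(0, 120), 0)
  expect_equal(hemizygous_ratio(50, 100), 0.5)
  expect_equal(hemizygous_ratio(125, 100), 1.25)
  expect_error(hemizygous_ratio(10, 0), "undefined")
  expect_error(hemizygous_ratio(-1, 10), "non-negative")
})

test_that("classify_viability thresholds are exact over a ratio grid", {
  expect_error(classify_viability(-0.1), "negative")
  grid <- seq(0, 2, by = 0.01)
  want <- ifelse(grid == 0, "lethal",
          ifelse(grid < 0.1, "semi_lethal",
          ifelse(grid < 0.7, "low_viability", "viable")))
  expect_equal(classify_viability(grid), want)
  # boundaries are strict "below"
  expect_equal(classify_viability(c(0.1, 0.7)),
               c("low_viability", "viable"))
  expect_equal(classify_viability(1.25), "viable")
})

test_that("kr_neutral_freq closed form, recursion identity and errors", {
  expect_identical(kr_neutral_freq(0.5, 2), 0.25)
  expect_identical(kr_neutral_freq(0.5, 0), 0.5)
  expect_equal(kr_neutral_freq(0.5, 1), 1 / 3)
  expect_error(kr_neutral_freq(0.6, 1), "0.5")
  expect_error(kr_neutral_freq(0, 1), "0.5")

  for (q0 in seq(0.05, 0.5, by = 0.05)) {
    q <- q0
    for (t in 1:50) {
      q <- q / (1 + q)
      expect_equal(kr_neutral_freq(q0, t), q, tolerance = 1e-12)
    }
  }
})

test_that("deterministic trajectory equals the Punnett-square oracle", {
  for (s in c(0, 0.25, 0.6)) for (h in c(0, 0.5)) {
    got <- kr_expected_trajectory(s, h, generations = 4)
    want <- oracle_kr(s, h, 4)
    expect_equal(got$f_II, want$f_II, tolerance = 1e-12)
    expect_equal(got$R, want$R, tolerance = 1e-12)
    expect_equal(got$q, want$q, tolerance = 1e-12)
  }
  # neutral case: published two-generation drop plus genotype ratios
  tr <- kr_expected_trajectory(0, generations = 3)
  expect_equal(tr$R, c(0.5, 1.0, 1.5))
  expect_equal(tr$q, c(1 / 3, 1 / 4, 1 / 5))
  # monotone: q strictly decreasing, neutral R strictly increasing
  expect_true(all(diff(tr$q) < 0))
  expect_true(all(diff(tr$R) > 0))
  tr2 <- kr_expected_trajectory(0.4, h = 0, generations = 5)
  expect_true(all(diff(tr2$q) < 0))
  # s = 1, h = 1: everything carrying the insertion dies with the BBs
  tr3 <- kr_expected_trajectory(1, h = 1, generations = 3)
  expect_equal(nrow(tr3), 0L)
  expect_true(attr(tr3, "extinct"))
})

test_that("stochastic simulator is seeded, unbiased and converges", {
  a <- simulate_kr_population(0.3, N = 50, generations = 3,
                              replicates = 3, seed = 99)
  b <- simulate_kr_population(0.3, N = 50, generations = 3,
                              replicates = 3, seed = 99)
  expect_identical(a, b)

  big <- simulate_kr_population(0, N = 1e5, generations = 2, seed = 1)
  expect_lt(abs(big$q[big$generation == 2] - 0.25), 0.01)

  small <- simulate_kr_population(0, N = 20, generations = 2,
                                  replicates = 2000, seed = 2)
  q2 <- small$q[small$generation == 2]
  mc_se <- sd(q2) / sqrt(length(q2))
  expect_lt(abs(mean(q2) - 0.25), 3 * mc_se + 1e-3)

  ext <- simulate_kr_population(1, h = 1, N = 100, generations = 3,
                                seed = 3)
  expect_true(any(ext$extinct))
})

test_that("estimate_selection: self-consistency and input errors", {
  tr <- kr_expected_trajectory(0.3, generations = 3)
  obs <- data.frame(generation = 1:3,
                    n_II = round(1e6 * tr$f_II),
                    n_IB = round(1e6 * tr$f_IB))
  est <- estimate_selection(obs)
  expect_equal(est$s_hat, 0.3, tolerance = 1e-9)  # grid resolution exact
  expect_false(est$boundary)

  expect_error(estimate_selection(data.frame(generation = 1, n_II = 0,
                                             n_IB = 0)), "zero")
  bound <- estimate_selection(data.frame(generation = 1:2,
                                         n_II = c(0, 0),
                                         n_IB = c(100, 100)))
  expect_true(bound$boundary)
})

test_that("estimate_selection recovers planted s with covered CIs", {
  set.seed(17)
  for (s in c(0, 0.5)) {
    hats <- replicate(60, {
      sim <- simulate_kr_population(s, N = 500, generations = 3)
      est <- estimate_selection(sim[c("generation", "n_II", "n_IB")])
      c(est$s_hat, est$ci)
    })
    expect_lt(median(abs(hats[1, ] - s)), 0.1)
    expect_gte(mean(hats[2, ] <= s & hats[3, ] >= s), 0.85)
  }
})

test_that("fitness statistics and classification", {
  expect_equal(kr_genotype_ratio(30, 60), 0.5)
  expect_error(kr_genotype_ratio(10, 0), "undefined")
  # allele ratio: q = n_IB / (2(n_II + n_IB))
  expect_equal(kr_allele_ratio(50, 50), (1 - 0.25) / 0.25)

  expect_equal(classify_fitness(0.10, generation = 2), "lower_fitness")
  expect_equal(classify_fitness(1.0, generation = 3), "equilibrated")
  expect_equal(classify_fitness(2.0, generation = 3), "higher_fitness")
  # band edges at default tolerance 0.15
  expect_equal(classify_fitness(c(0.84, 0.86, 1.14, 1.16)),
               c("lower_fitness", "equilibrated", "equilibrated",
                 "higher_fitness"))
  expect_warning(classify_fitness(1, generation = 5), "generations")
})

test_that("hemizygous_test agrees with the exact binomial", {
  expect_equal(hemizygous_test(50, 50), 1)
  expect_equal(hemizygous_test(0, 20),
               binom.test(0, 20, 0.5)$p.value)
})
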