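test_that("baseline sampling is reproducible and respects its ranges", {
  b1 <- sample_baseline(100, seed = 3)
  b2 <- sample_baseline(100, seed = 3)
  expect_identical(b1, b2)
  expect_true(all(b1$mu1 >= 1 & b1$mu1 <= 1e4))
  expect_true(all(b1$theta1 >= 0.1 & b1$theta1 <= 50))
})

test_that("baseline mu has the truncated-lognormal median", {
  b <- sample_baseline(1e4, seed = 5)
  # closed-form median of the truncated lognormal
  plo <- pnorm(log(1), log(50), 1.5)
  phi <- pnorm(log(1e4), log(50), 1.5)
  med <- exp(qnorm((plo + phi) / 2, log(50), 1.5))
  expect_lt(abs(median(b$mu1) - med) / med, 0.2)
  expect_lt(abs(median(b$mu1) - 50) / 50, 0.2)
})

test_that("explicit baseline vectors pass through verbatim", {
  mu <- c(5, 10, 20)
  th <- c(1, 2, 3)
  b <- sample_baseline(3, mu1 = mu, theta1 = th)
  expect_identical(b$mu1, mu)
  expect_identical(b$theta1, th)
  expect_error(sample_baseline(3, mu1 = mu), "both")
  expect_error(sample_baseline(2, mu1 = mu, theta1 = th), "length")
  expect_error(sample_baseline(3, config = list(mu_range = c(5, 1))),
               "configuration")
})

test_that("cluster parameters shift multiplicatively on the DE subset only", {
  sc0 <- nbmix_scenario(n = 20, g = 10, k = 3, delta_mu = 0,
                        delta_theta = 0, de_fraction = 0.5, seed = 1)
  base <- sample_baseline(10, seed = 1)
  p0 <- build_cluster_params(base, sc0)
  for (j in 1:3) expect_equal(p0$components[[j]]$mu, base$mu1)

  sc <- nbmix_scenario(n = 20, g = 10, k = 3, delta_mu = 1,
                       de_fraction = 0.5, seed = 1)
  base10 <- sample_baseline(10, mu1 = rep(10, 10), theta1 = rep(2, 10))
  p <- build_cluster_params(base10, sc)
  de <- p$de_genes
  expect_length(de, 5)
  expect_equal(p$components[[2]]$mu[de], rep(10 * exp(1), 5))
  expect_equal(p$components[[3]]$mu[de], rep(10 * exp(2), 5))
  # non-DE genes identical in every component; cluster 1 equals baseline
  expect_equal(p$components[[1]]$mu, rep(10, 10))
  expect_equal(p$components[[3]]$mu[-de], rep(10, 5))

  big <- build_cluster_params(
    sample_baseline(1000, seed = 2),
    nbmix_scenario(n = 50, g = 1000, k = 2, delta_mu = 1,
                   de_fraction = 0.05, seed = 9))
  expect_length(big$de_genes, 50)
  expect_equal(big$components[[1]]$mu[-big$de_genes],
               big$components[[2]]$mu[-big$de_genes])
})

test_that("de_mode = 'all' shifts every gene", {
  sc <- nbmix_scenario(n = 10, g = 4, k = 2, delta_mu = 1,
                       de_fraction = 0.25, seed = 1)
  base <- sample_baseline(4, mu1 = rep(3, 4), theta1 = rep(1, 4))
  p <- build_cluster_params(base, sc, de_mode = "all")
  expect_equal(p$components[[2]]$mu, rep(3 * exp(1), 4))
})

test_that("simulated counts are reproducible with ordered cluster means", {
  sc <- nbmix_scenario(n = 40, g = 20, k = 3, delta_mu = 3, seed = 7)
  s1 <- simulate_nbmix_counts(sc)
  s2 <- simulate_nbmix_counts(sc)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$labels, s2$labels)

  gene <- s1$de_genes[1]
  means <- tapply(s1$counts[, gene], s1$labels, mean)
  expect_true(all(diff(means) > 0))  # delta_mu = 3 separates means strongly
})

test_that("simulated counts show NB over-dispersion", {
  sc <- nbmix_scenario(n = 500, g = 1, k = 2, delta_mu = 0, seed = 5)
  base <- sample_baseline(1, mu1 = 50, theta1 = 0.5)
  s <- simulate_nbmix_counts(sc, baseline = base)
  x <- s$counts[, 1]
  expect_gt(var(x), mean(x))  # Var = mu + mu^2/theta >> mu at theta = 0.5
  # and close to the NB oracle variance
  expect_lt(abs(var(x) - (50 + 50^2 / 0.5)) / (50 + 50^2 / 0.5), 0.5)
})

test_that("per-cluster empirical means converge to the component means", {
  sc <- nbmix_scenario(n = 10000, g = 2, k = 2, delta_mu = 1,
                       de_fraction = 0.5, seed = 13)
  s <- simulate_nbmix_counts(sc)
  for (j in 1:2) {
    idx <- s$labels == j
    emp <- colMeans(s$counts[idx, ])
    expect_true(all(abs(emp - s$components[[j]]$mu) /
                      s$components[[j]]$mu < 0.05))
  }
  # uniform label proportions
  expect_lt(abs(mean(s$labels == 1) - 0.5), 0.03)
})

test_that("exact split balances cluster sizes", {
  sc <- nbmix_scenario(n = 30, g = 5, k = 3, delta_mu = 1, seed = 2)
  s <- simulate_nbmix_counts(sc, exact_split = TRUE)
  expect_equal(unname(table(s$labels)), rep(10L, 3), ignore_attr = TRUE)
})

test_that("non-DE genes carry no systematic between-cluster shift", {
  sc <- nbmix_scenario(n = 400, g = 40, k = 2, delta_mu = 1,
                       de_fraction = 0.1, seed = 21)
  s <- simulate_nbmix_counts(sc)
  non_de <- setdiff(seq_len(40), s$de_genes)
  diffs <- sapply(non_de, function(g) {
    mean(s$counts[s$labels == 2, g]) - mean(s$counts[s$labels == 1, g])
  })
  # sign test: positive diffs should be near half
  expect_lt(abs(mean(diffs > 0) - 0.5), 0.2)
})

test_that("the scenario grid enumerates the full factorial design", {
  expect_equal(nrow(scenario_grid()), 480)
  expect_equal(nrow(scenario_grid(n = 50)), 120)
  expect_equal(nrow(scenario_grid(k = 2, delta_mu = 1, delta_theta = 0,
                                  de_fraction = 0.1, n = 50, g = 100)), 1)
  expect_error(scenario_grid(k = integer(0)), "Empty")
  # derived seeds are deterministic and 32-bit safe
  g1 <- scenario_grid(master_seed = 4)
  g2 <- scenario_grid(master_seed = 4)
  expect_identical(g1$seed, g2$seed)
  expect_true(all(g1$seed > 0 & g1$seed <= .Machine$integer.max))
})

test_that("scenario validation catches degenerate configurations", {
  expect_error(nbmix_scenario(n = 10, g = 5, k = 1, delta_mu = 1))
  expect_error(nbmix_scenario(n = 10, g = 5, k = 2, delta_mu = 1,
                              de_fraction = 0.01), "at least 1")
})
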