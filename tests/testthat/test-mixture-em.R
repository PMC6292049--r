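test_that("initialization shifts components off the shared MLE", {
  sim <- quick_sim()
  mle <- list(mu_hat = rep(100, 5), theta_hat = rep(2, 5),
              at_cap = rep(FALSE, 5))
  x <- sim$counts[, 1:5]

  init1 <- nbmix_init(x, 1, mle = mle)
  expect_equal(init1$priors, 1)
  expect_equal(init1$components[[1]]$mu, rep(100, 5))

  init3 <- nbmix_init(x, 3, init_shift = 0.01, mle = mle)
  expect_equal(init3$priors, rep(1 / 3, 3))
  expect_equal(sapply(init3$components, function(c) c$mu[1]),
               c(100, 101, 102))
  expect_equal(sapply(init3$components, function(c) c$theta[1]),
               2 * c(1, 1.01, 1.02))

  expect_error(nbmix_init(x, nrow(x) + 1), "cannot exceed")
})

test_that("zero init shift gives exactly uniform first responsibilities", {
  sim <- quick_sim(n = 10, g = 8)
  init <- nbmix_init(sim$counts, 2, init_shift = 0)
  ld <- nbmix_log_density_matrix(sim$counts, init$components)
  post <- nbmix_e_step(ld, init$priors, nbmix_offsets(ld, 8), tau = 1)
  expect_true(all(post == 0.5))
})

test_that("log density matrix equals per-gene sums and is symmetric for identical components", {
  comp <- list(mu = 1, theta = 1)
  x1 <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "g1"))
  ld <- nbmix_log_density_matrix(x1, list(comp, comp))
  expect_equal(unname(ld), matrix(log(0.5), 2, 2))

  sim <- quick_sim(n = 3, g = 2)
  comps <- list(list(mu = c(5, 10), theta = c(1, 2)),
                list(mu = c(20, 2), theta = c(0.5, 3)))
  ld <- nbmix_log_density_matrix(sim$counts, comps)
  brute <- sapply(comps, function(cp) {
    apply(sim$counts, 1, function(row) {
      sum(sapply(1:2, function(g) nb_log_density(row[g], cp$mu[g],
                                                 cp$theta[g])))
    })
  })
  expect_equal(unname(ld), unname(brute), tolerance = 1e-12)
})

test_that("rescaling offsets are the mean log density over components and genes", {
  expect_equal(nbmix_offsets(matrix(-7, 1, 1), n_genes = 1), -7)
  expect_equal(nbmix_offsets(matrix(c(-10, -20), 1, 2), n_genes = 1), -15)
  ld <- matrix(c(-100, -300, -200, -400), 2, 2)
  expect_equal(nbmix_offsets(ld, n_genes = 10), rowSums(ld) / 20)
})

test_that("E-step reproduces the two-component softmax and annealing flattens it", {
  ld <- matrix(c(-10, -12), 1, 2)
  p1 <- nbmix_e_step(ld, c(0.5, 0.5), offsets = 0, tau = 1)
  expect_equal(as.numeric(p1),
               c(1 / (1 + exp(-2)), exp(-2) / (1 + exp(-2))),
               tolerance = 1e-12)
  p2 <- nbmix_e_step(ld, c(0.5, 0.5), offsets = 0, tau = 2)
  expect_equal(as.numeric(p2),
               c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_lt(p2[1], p1[1])  # flatter responsibilities at higher temperature

  # identical components: exactly 1/K at any temperature
  ld3 <- matrix(-5, 4, 3)
  for (tau in c(1, 2, 10)) {
    expect_true(all(nbmix_e_step(ld3, rep(1 / 3, 3), 0, tau) == 1 / 3))
  }
})

test_that("E-step errors when a sample has zero density everywhere", {
  ld <- matrix(c(-1, -Inf, -2, -Inf), 2, 2,
               dimnames = list(c("s1", "s2"), NULL))
  expect_error(nbmix_e_step(ld, c(0.5, 0.5)), "s2")
})

test_that("posteriors are invariant to the rescaling offsets", {
  sim <- quick_sim(n = 25, g = 40)
  init <- nbmix_init(sim$counts, 3)
  ld <- nbmix_log_density_matrix(sim$counts, init$components)
  for (tau in c(1, 2)) {
    with_m <- nbmix_e_step(ld, init$priors, nbmix_offsets(ld, 40), tau)
    without <- nbmix_e_step(ld, init$priors, 0, tau)
    expect_equal(with_m, without, tolerance = 1e-12)
  }
})

test_that("M-step computes floored priors and weighted means", {
  sim <- quick_sim(n = 4, g = 2)
  x <- sim$counts

  uni <- matrix(0.5, 4, 2)
  up <- nbmix_m_step(x, uni)
  expect_equal(up$priors, c(0.5, 0.5))
  expect_equal(up$mu, rbind(colMeans(x), colMeans(x)), ignore_attr = TRUE)

  hard <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  up2 <- nbmix_m_step(x, hard)
  expect_equal(up2$mu, rbind(colMeans(x[1:2, ]), colMeans(x[3:4, ])),
               ignore_attr = TRUE)

  set.seed(2)
  w <- matrix(runif(8), 4, 2)
  w <- w / rowSums(w)
  up3 <- nbmix_m_step(x, w)
  oracle <- t(sapply(1:2, function(j) {
    colSums(w[, j] * x) / sum(w[, j])
  }))
  expect_equal(up3$mu, oracle, ignore_attr = TRUE, tolerance = 1e-12)

  expect_warning(nbmix_m_step(x, cbind(rep(1, 4), rep(0, 4))), "empty")
})

test_that("well-separated clusters are recovered with correct means", {
  sim <- quick_sim(n = 60, g = 50, k = 2, delta_mu = 2, seed = 1)
  fit <- fit_nbmix(sim$counts, 2)
  expect_equal(adjusted_rand_index(fit$labels, sim$labels), 1)
  # map fitted components to truth via label agreement, then compare means
  map <- sapply(1:2, function(j) {
    as.integer(names(which.max(table(sim$labels[fit$labels == j]))))
  })
  for (j in 1:2) {
    truth <- sim$components[[map[j]]]$mu
    # deviation from truth is sampling noise: per-gene relative SE is about
    # sqrt(1/(n_k * theta)) ~ 0.13 at ~30 samples/cluster
    expect_lt(median(abs(fit$mu[j, ] - truth) / truth), 0.15)
    # with a crisp posterior the EM fixed point is the within-cluster mean
    expect_equal(fit$mu[j, ], colMeans(sim$counts[fit$labels == j, ]),
                 ignore_attr = TRUE, tolerance = 1e-3)
  }
})

test_that("a single component reduces to the MLE fixed point", {
  sim <- quick_sim(n = 20, g = 10)
  fit <- fit_nbmix(sim$counts, 1)
  expect_equal(unname(fit$mu[1, ]), unname(colMeans(sim$counts)),
               tolerance = 1e-10)
  mle <- fit_matrix_nb_mle(sim$counts)
  ll <- sum(nbmix_log_density_matrix(
    sim$counts, list(list(mu = colMeans(sim$counts), theta = mle$theta_hat))))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  expect_true(all(fit$posteriors == 1))
})

test_that("log-likelihood is non-decreasing during the tau = 1 phase", {
  for (seed in 1:3) {
    sim <- quick_sim(n = 30, g = 25, k = 3, delta_mu = 1, seed = seed)
    for (tau0 in c(1, 10)) {
      fit <- fit_nbmix(sim$counts, 3, tau0 = tau0)
      lls <- fit$trace$loglik[fit$trace$tau == 1]
      expect_true(all(diff(lls) >= -1e-8))
      expect_equal(unname(rowSums(fit$posteriors)), rep(1, nrow(sim$counts)),
                   tolerance = 1e-10)
    }
  }
})

test_that("fits are deterministic and equivariant under permutations", {
  sim <- quick_sim(n = 30, g = 20, k = 2, delta_mu = 1.5, seed = 4)
  f1 <- fit_nbmix(sim$counts, 2)
  f2 <- fit_nbmix(sim$counts, 2)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$loglik, f2$loglik)

  set.seed(31)
  perm <- sample(nrow(sim$counts))
  fp <- fit_nbmix(sim$counts[perm, ], 2)
  expect_equal(unname(fp$labels), unname(f1$labels[perm]))

  gperm <- sample(ncol(sim$counts))
  fg <- fit_nbmix(sim$counts[, gperm], 2)
  expect_equal(unname(fg$labels), unname(f1$labels))
  expect_equal(fg$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("BIC follows the free-parameter count", {
  expect_equal(nbmix_bic(-100, k = 1, n_genes = 1, n = 10),
               200 + log(10))
  # same loglik, more components: penalty (K-1) + K*G grows
  expect_equal(nbmix_bic(-100, k = 2, n_genes = 1, n = 10),
               200 + 3 * log(10))
  expect_gt(nbmix_bic(-100, 2, 1, 10), nbmix_bic(-100, 1, 1, 10))
  expect_equal(nbmix_bic(-50, k = 2, n_genes = 3, n = 20,
                         count_theta = TRUE),
               100 + (1 + 12) * log(20))
})

test_that("BIC prefers k = 2 over k = 1 for genuinely clustered data", {
  wins <- 0
  for (seed in 1:100) {
    sim <- quick_sim(n = 30, g = 15, k = 2, delta_mu = 2, seed = seed)
    mle <- fit_matrix_nb_mle(sim$counts)
    b1 <- fit_nbmix(sim$counts, 1, mle = mle)$bic
    b2 <- fit_nbmix(sim$counts, 2, mle = mle)$bic
    wins <- wins + (b2 < b1)
  }
  expect_gte(wins, 95)
})

test_that("BIC selection recovers the true number of clusters", {
  expect_equal(select_nbmix_k(quick_sim()$counts, k_range = 2)$k, 2)

  sim <- quick_sim(n = 60, g = 60, k = 3, delta_mu = 1.5, seed = 8)
  sel <- select_nbmix_k(sim$counts, k_range = 2:5)
  expect_equal(sel$k, 3)
  expect_equal(nrow(sel$bic_trace), 4)
  # reversed candidate order gives the same answer
  sel_rev <- select_nbmix_k(sim$counts, k_range = 5:2)
  expect_equal(sel_rev$k, sel$k)
  expect_identical(sel_rev$labels, sel$labels)
})

test_that("degenerate data falls to the smallest candidate k", {
  x <- matrix(5, 12, 4,
              dimnames = list(paste0("s", 1:12), paste0("g", 1:4)))
  # constant data collapses all components; empty-component warnings expected
  sel <- suppressWarnings(select_nbmix_k(x, k_range = 2:4))
  expect_equal(sel$k, 2)
})

test_that("model export and label CSV round-trip", {
  sim <- quick_sim(n = 20, g = 10)
  sel <- select_nbmix_k(sim$counts, 2:3)
  tmp <- withr::local_tempdir()
  jpath <- file.path(tmp, "model.json")
  write_nbmix_model(sel, jpath)
  back <- jsonlite::read_json(jpath)
  expect_equal(back$selected_k, sel$k)
  expect_equal(back$model$bic, sel$best$bic, tolerance = 1e-9)

  cpath <- file.path(tmp, "labels.csv")
  write_cluster_labels(sel, cpath)
  lab <- read_labels(cpath)
  expect_equal(adjusted_rand_index(lab, sel$labels), 1)
})
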