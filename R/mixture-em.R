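# Negative binomial mixture model fitted by deterministic-annealing EM.
#
# Model: sample rows x_i (length G) are i.i.d. from a K-component mixture in
# which component k has independent NB(mu_kg, theta_kg) margins. The observed
# log-likelihood is
#   L = sum_i log( sum_k p_k prod_g f(x_ig | mu_kg, theta_kg) ).
# Dispersion vectors theta_k are fixed at their initialization values (gene
# MLEs, plus the small inter-component shift); only p_k and mu_k are updated.
# The E-step raises responsibilities to the power 1/tau with tau cooling
# geometrically from tau0 to 1 (deterministic annealing), which flattens early
# responsibilities and avoids poor local optima.

#' Initialize mixture parameters from gene-wise MLEs
#'
#' All components start at the gene-wise NB maximum-likelihood estimates, with
#' a small multiplicative shift between components so that the first E-step
#' does not return identical responsibilities for every component: component k
#' gets `mu_hat * (1 + init_shift * (k - 1))` and the same relative shift on
#' theta (clipped back into `theta_bounds`). Priors start uniform at 1/K.
#'
#' @param x Samples-by-genes numeric matrix.
#' @param k Number of mixture components (>= 1, <= number of samples).
#' @param init_shift Relative shift between consecutive components
#'   (default 0.01).
#' @param theta_bounds Dispersion bounds, see [nb_theta_bounds()].
#' @param mle Optional precomputed result of [fit_matrix_nb_mle()] for `x`.
#'
#' @return List with `priors` (length k) and `components` (list of k lists,
#'   each with `mu` and `theta` vectors of length G).
#' @export
nbmix_init <- function(x, k, init_shift = 0.01,
                       theta_bounds = nb_theta_bounds(), mle = NULL) {
  x <- as_count_matrix(x)
  k <- check_k(k, nrow(x))
  if (!is.numeric(init_shift) || length(init_shift) != 1 ||
      init_shift < 0 || init_shift >= 1) {
    stop("`init_shift` must be a single value in [0, 1).", call. = FALSE)
  }
  if (is.null(mle)) mle <- fit_matrix_nb_mle(x, theta_bounds)

  components <- lapply(seq_len(k), function(j) {
    fac <- 1 + init_shift * (j - 1)
    theta <- mle$theta_hat * fac
    clipped <- theta < theta_bounds[1] | theta > theta_bounds[2]
    if (any(clipped)) {
      warning(sprintf(
        "init_shift pushed %d theta value(s) outside bounds for component %d; clipped.",
        sum(clipped), j), call. = FALSE)
      theta <- pmin(pmax(theta, theta_bounds[1]), theta_bounds[2])
    }
    list(mu = mle$mu_hat * fac, theta = theta)
  })
  list(priors = rep(1 / k, k), components = components)
}

#' Per-sample, per-component NB log joint density matrix
#'
#' Entry (i, k) is the log joint density of sample row i under component k,
#' i.e. the sum over genes of [nb_log_density()] at that component's
#' parameters (genes are modeled as independent).
#'
#' @param x Samples-by-genes numeric matrix.
#' @param components List of component parameter lists (`mu`, `theta`).
#'
#' @return N x K numeric matrix of log densities.
#' @export
nbmix_log_density_matrix <- function(x, components) {
  x <- as_count_matrix(x)
  vapply(components, function(comp) {
    component_log_density(x, comp$mu, comp$theta)
  }, numeric(nrow(x)))
}

# Log joint density of every sample row under one component. Vectorized as
#   rowSums(lgamma(X + theta)) - sum(lgamma(theta)) - rowSums(lgamma(X + 1))
#   + X %*% log(mu/(theta+mu)) + sum(theta * log(theta/(theta+mu)))
# Genes with mu == 0 are point masses at zero: they contribute 0 where x = 0
# and -Inf where x > 0. `lconst` optionally carries the precomputed
# theta-only row constants (they do not change across EM iterations).
component_log_density <- function(x, mu, theta, lconst = NULL) {
  if (is.null(lconst)) lconst <- component_log_const(x, theta)
  pos <- mu > 0
  w <- numeric(length(mu))
  w[pos] <- log(mu[pos]) - log(theta[pos] + mu[pos])
  ld <- lconst +
    drop(x %*% w) +
    sum(theta[pos] * (log(theta[pos]) - log(theta[pos] + mu[pos])))
  if (any(!pos)) {
    hit <- rowSums(x[, !pos, drop = FALSE] > 0) > 0
    ld[hit] <- -Inf
  }
  ld
}

# Row constants c_i = rowSums(lgamma(X + theta) - lgamma(theta) - lgamma(X+1));
# depends only on x and theta, so computed once per fit and reused.
component_log_const <- function(x, theta, lgamma_x1 = rowSums(lgamma(x + 1))) {
  tm <- matrix(theta, nrow(x), ncol(x), byrow = TRUE)
  rowSums(lgamma(x + tm)) - sum(lgamma(theta)) - lgamma_x1
}

#' Per-sample rescaling offsets for the annealed E-step
#'
#' The mean of the per-gene log densities over all components and genes,
#' `M_i = (sum_k logdens[i, k]) / (K * G)` when `logdens` already holds
#' per-gene sums. Subtracting `M_i` inside the E-step exponent keeps the
#' component densities on a representable scale for large G; responsibilities
#' are algebraically invariant to it.
#'
#' @param logdens N x K matrix of per-sample log joint densities.
#' @param n_genes Number of genes G that each entry of `logdens` sums over.
#'
#' @return Numeric vector of length N.
#' @export
nbmix_offsets <- function(logdens, n_genes) {
  m <- rowSums(logdens) / (ncol(logdens) * n_genes)
  # a sample with a -Inf entry (zero-mean gene with a positive count) has no
  # finite mean; any per-sample constant is valid, so fall back to 0 there
  m[!is.finite(m)] <- 0
  m
}

#' Deterministic-annealing E-step
#'
#' Responsibilities `p_ik` proportional to
#' `p_k * exp((logdens[i,k] - offsets[i]) / tau)`, renormalized per row. The
#' computation uses the log-sum-exp pattern, so no intermediate value
#' overflows or underflows even for thousands of genes. `tau = 1` is the
#' ordinary EM E-step; `tau > 1` flattens responsibilities toward uniform.
#'
#' @param logdens N x K matrix of per-sample log joint densities.
#' @param priors Mixing proportions, length K.
#' @param offsets Per-sample rescaling offsets (any per-sample constant;
#'   see [nbmix_offsets()]). Use 0 to disable.
#' @param tau Annealing temperature, >= 1.
#'
#' @return N x K posterior matrix; every row sums to 1.
#' @export
nbmix_e_step <- function(logdens, priors, offsets = 0, tau = 1) {
  if (tau < 1) stop("`tau` must be >= 1.", call. = FALSE)
  a <- (logdens - offsets) / tau
  a <- sweep(a, 2, log(priors), "+")
  amax <- apply(a, 1, max)
  bad <- !is.finite(amax)
  if (any(bad)) {
    nm <- rownames(logdens)
    who <- if (is.null(nm)) which(bad)[1] else nm[which(bad)[1]]
    stop(sprintf(
      "Sample %s has zero density under every component (all log densities -Inf).",
      who), call. = FALSE)
  }
  e <- exp(a - amax)
  e / rowSums(e)
}

#' M-step: update mixing proportions and component means
#'
#' Priors become the posterior column means, floored at `prior_floor` and
#' renormalized; component means become the posterior-weighted averages of the
#' sample rows. Dispersions are never updated.
#'
#' @param x Samples-by-genes numeric matrix.
#' @param posteriors N x K responsibility matrix.
#' @param prior_floor Lower bound applied to the updated priors.
#'
#' @return List with `priors` (length K) and `mu` (K x G matrix of component
#'   means, one row per component), plus logical `empty` flagging components
#'   whose total responsibility fell below `prior_floor * N`.
#' @export
nbmix_m_step <- function(x, posteriors, prior_floor = 1e-10) {
  x <- as_count_matrix(x)
  wsum <- colSums(posteriors)
  empty <- wsum < prior_floor * nrow(x)
  if (any(empty)) {
    warning(sprintf("Component(s) %s are empty (responsibility below floor).",
                    paste(which(empty), collapse = ", ")), call. = FALSE)
  }
  priors <- pmax(wsum / nrow(x), prior_floor)
  priors <- priors / sum(priors)
  mu <- crossprod(posteriors, x) / pmax(wsum, .Machine$double.xmin)
  list(priors = priors, mu = mu, empty = empty)
}

#' BIC of a fitted NB mixture
#'
#' `BIC = -2 L + nu log(N)` with `nu = (K - 1) + K G` free parameters: the
#' mixing proportions and the component means. Dispersions are held fixed
#' during EM and by default are not counted; set `count_theta = TRUE` to
#' penalize them as well (`nu = (K - 1) + 2 K G`) for sensitivity checks.
#' Lower is better.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of components.
#' @param n_genes Number of genes G.
#' @param n Number of samples N.
#' @param count_theta Whether dispersions count as free parameters.
#'
#' @return The BIC value.
#' @export
#' @examples
#' nbmix_bic(-100, k = 1, n_genes = 1, n = 10)  # 200 + log(10)
nbmix_bic <- function(loglik, k, n_genes, n, count_theta = FALSE) {
  nu <- (k - 1) + k * n_genes * (if (count_theta) 2 else 1)
  -2 * loglik + nu * log(n)
}

#' Fit a negative binomial mixture by deterministic-annealing EM
#'
#' Initializes at the gene-wise MLEs ([nbmix_init()]), then alternates the
#' annealed E-step and the M-step. The temperature follows
#' `tau_{s+1} = max(1, anneal_rate * tau_s)` from `tau0` down to 1; convergence
#' of the observed log-likelihood is only tested once `tau = 1` (relative
#' change below `tol`), so the annealing ladder always runs to completion.
#' Dispersions stay fixed at their initial values throughout. The algorithm is
#' deterministic: rerunning on the same input reproduces the fit exactly.
#'
#' @param x Samples-by-genes numeric matrix (or data frame) of non-negative
#'   normalized counts.
#' @param k Number of mixture components.
#' @param tau0 Initial annealing temperature (>= 1). 10 works best in most
#'   settings; 2 is the common lighter alternative.
#' @param anneal_rate Geometric cooling rate r in (0, 1), default 0.9.
#' @param init_shift Relative parameter shift between components at
#'   initialization (default 0.01).
#' @param tol Relative log-likelihood convergence tolerance at tau = 1.
#' @param max_iter Maximum number of EM iterations.
#' @param prior_floor Lower bound for mixing proportions.
#' @param theta_bounds Dispersion bounds, see [nb_theta_bounds()].
#' @param mle Optional precomputed [fit_matrix_nb_mle()] result (shared across
#'   fits with different `k` on the same data).
#' @param count_theta Whether BIC counts dispersions as free parameters.
#'
#' @return An object of class `"nbmix_fit"`: a list with elements `k`,
#'   `priors`, `mu` (K x G), `theta` (K x G), `posteriors` (N x K, at tau = 1),
#'   `labels` (named integer vector, argmax posterior, ties to the lowest
#'   component), `loglik`, `bic`, `n_iter`, `converged`, and `trace` (a tibble
#'   with per-iteration `iter`, `tau`, `loglik`).
#' @seealso [select_nbmix_k()] for BIC selection of `k`, [tidy.nbmix_fit()],
#'   [glance.nbmix_fit()].
#' @export
#' @examples
#' sim <- simulate_nbmix_counts(nbmix_scenario(n = 40, g = 30, k = 2,
#'                                             delta_mu = 2, seed = 1))
#' fit <- fit_nbmix(sim$counts, k = 2)
#' table(fit$labels, sim$labels)
fit_nbmix <- function(x, k, tau0 = 10, anneal_rate = 0.9, init_shift = 0.01,
                      tol = 1e-6, max_iter = 1000, prior_floor = 1e-10,
                      theta_bounds = nb_theta_bounds(), mle = NULL,
                      count_theta = FALSE) {
  x <- as_count_matrix(x)
  n <- nrow(x); g <- ncol(x)
  k <- check_k(k, n)
  stopifnot(tau0 >= 1, anneal_rate > 0, anneal_rate < 1, tol > 0, max_iter >= 1)

  init <- nbmix_init(x, k, init_shift, theta_bounds, mle)
  priors <- init$priors
  theta <- do.call(rbind, lapply(init$components, `[[`, "theta"))
  mu <- do.call(rbind, lapply(init$components, `[[`, "mu"))

  # theta_k never changes, so the lgamma row constants are fixed per component
  lgx1 <- rowSums(lgamma(x + 1))
  lconst <- lapply(seq_len(k), function(j) {
    component_log_const(x, theta[j, ], lgx1)
  })
  logdens_at <- function(mu) {
    vapply(seq_len(k), function(j) {
      component_log_density(x, mu[j, ], theta[j, ], lconst[[j]])
    }, numeric(n))
  }

  tau <- tau0
  loglik <- -Inf
  trace <- vector("list", max_iter)
  converged <- FALSE
  iter <- 0
  posteriors <- NULL

  while (iter < max_iter) {
    iter <- iter + 1
    logdens <- logdens_at(mu)
    ll_new <- sum(log_row_sum_exp(sweep(logdens, 2, log(priors), "+")))
    trace[[iter]] <- list(iter = iter, tau = tau, loglik = ll_new)
    if (tau == 1 && is.finite(ll_new) && is.finite(loglik) &&
        abs(ll_new - loglik) / (abs(loglik) + 1) < tol) {
      loglik <- ll_new
      converged <- TRUE
      break
    }
    loglik <- ll_new
    posteriors <- nbmix_e_step(logdens, priors, nbmix_offsets(logdens, g), tau)
    upd <- nbmix_m_step(x, posteriors, prior_floor)
    priors <- upd$priors
    mu <- upd$mu
    tau <- max(1, anneal_rate * tau)
  }
  if (!converged) {
    warning(sprintf("EM did not converge in %d iterations (k = %d).",
                    max_iter, k), call. = FALSE)
  }

  # final responsibilities at tau = 1 under the final parameters
  logdens <- logdens_at(mu)
  posteriors <- nbmix_e_step(logdens, priors, nbmix_offsets(logdens, g), 1)
  labels <- apply(posteriors, 1, which.max)  # which.max ties -> lowest index
  names(labels) <- rownames(x)
  dimnames(posteriors) <- list(rownames(x), paste0("cluster", seq_len(k)))
  dimnames(mu) <- list(paste0("cluster", seq_len(k)), colnames(x))
  dimnames(theta) <- dimnames(mu)

  structure(
    list(
      k = k, priors = priors, mu = mu, theta = theta,
      posteriors = posteriors, labels = labels,
      loglik = loglik,
      bic = nbmix_bic(loglik, k, g, n, count_theta),
      n_iter = iter, converged = converged,
      trace = dplyr::bind_rows(trace[seq_len(iter)]),
      n = n, g = g
    ),
    class = "nbmix_fit"
  )
}

#' Select the number of clusters by BIC
#'
#' Fits the NB mixture for every candidate `k` and keeps the fit with the
#' smallest BIC; ties go to the smaller `k`. The gene-wise MLEs used for
#' initialization do not depend on `k`, so they are computed once and shared.
#'
#' @param x Samples-by-genes numeric matrix of non-negative normalized counts.
#' @param k_range Integer vector of candidate component counts (default 2:6).
#' @param ... Passed on to [fit_nbmix()].
#' @param keep_fits Keep every candidate fit (default keeps only the best).
#'
#' @return An object of class `"nbmix_selection"`: list with `best` (the
#'   winning [fit_nbmix()] object), `k`, `bic_trace` (tibble of k, loglik,
#'   bic, n_iter, converged), `labels`, and optionally `fits`.
#' @export
#' @examples
#' sim <- simulate_nbmix_counts(nbmix_scenario(n = 40, g = 30, k = 2,
#'                                             delta_mu = 2, seed = 1))
#' sel <- select_nbmix_k(sim$counts, k_range = 2:3)
#' sel$k
select_nbmix_k <- function(x, k_range = 2:6, ..., keep_fits = FALSE) {
  x <- as_count_matrix(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0 || any(k_range < 1)) {
    stop("`k_range` must be a non-empty set of integers >= 1.", call. = FALSE)
  }
  mle <- fit_matrix_nb_mle(x)

  fits <- vector("list", length(k_range))
  errors <- character(0)
  for (i in seq_along(k_range)) {
    fits[[i]] <- tryCatch(
      fit_nbmix(x, k_range[i], ..., mle = mle),
      error = function(e) {
        warning(sprintf("k = %d failed: %s", k_range[i], conditionMessage(e)),
                call. = FALSE)
        errors <<- c(errors, conditionMessage(e))
        NULL
      }
    )
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("Every candidate k failed to fit: ", paste(errors, collapse = "; "),
         call. = FALSE)
  }
  bic_trace <- dplyr::bind_rows(lapply(fits[ok], function(f) {
    tibble::tibble(k = f$k, loglik = f$loglik, bic = f$bic,
                   n_iter = f$n_iter, converged = f$converged)
  }))
  # min BIC; k_range is sorted ascending so which.min ties break to smaller k
  kept <- fits[ok]
  best <- kept[[which.min(vapply(kept, `[[`, numeric(1), "bic"))]]

  structure(
    list(best = best, k = best$k, bic_trace = bic_trace,
         labels = best$labels,
         fits = if (keep_fits) kept else NULL),
    class = "nbmix_selection"
  )
}

check_k <- function(k, n) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("`k` must be a single integer >= 1.", call. = FALSE)
  }
  if (k > n) {
    stop(sprintf("`k` (%d) cannot exceed the number of samples (%d).", k, n),
         call. = FALSE)
  }
  as.integer(k)
}

log_row_sum_exp <- function(a) {
  amax <- apply(a, 1, max)
  amax + log(rowSums(exp(a - amax)))
}

#' @export
print.nbmix_fit <- function(x, ...) {
  cat(sprintf(
    "<nbmix_fit> k = %d, N = %d, G = %d\n  logLik = %.3f, BIC = %.3f, %d iterations%s\n  cluster sizes: %s\n",
    x$k, x$n, x$g, x$loglik, x$bic, x$n_iter,
    if (x$converged) "" else " (NOT converged)",
    paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' @export
print.nbmix_selection <- function(x, ...) {
  cat(sprintf("<nbmix_selection> selected k = %d by BIC from {%s}\n",
              x$k, paste(x$bic_trace$k, collapse = ", ")))
  print(x$best)
  invisible(x)
}

#' Write a fitted mixture model to JSON
#'
#' Serializes k, priors, component means and dispersions, the BIC trace (for
#' selections), labels and fit statistics to a JSON file that round-trips
#' through [jsonlite::read_json()].
#'
#' @param fit An `nbmix_fit` or `nbmix_selection` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nbmix_model <- function(fit, path) {
  if (inherits(fit, "nbmix_selection")) {
    payload <- list(
      selected_k = fit$k,
      bic_trace = fit$bic_trace,
      model = nbmix_fit_payload(fit$best)
    )
  } else if (inherits(fit, "nbmix_fit")) {
    payload <- nbmix_fit_payload(fit)
  } else {
    stop("`fit` must be an nbmix_fit or nbmix_selection.", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

nbmix_fit_payload <- function(f) {
  list(k = f$k, n = f$n, g = f$g, priors = f$priors,
       mu = apply(f$mu, 1, identity, simplify = FALSE),
       theta = apply(f$theta, 1, identity, simplify = FALSE),
       loglik = f$loglik, bic = f$bic, n_iter = f$n_iter,
       converged = f$converged,
       labels = as.list(stats::setNames(f$labels, names(f$labels))))
}

#' Write hard cluster assignments to CSV
#'
#' Two columns: `sample_id`, `cluster`.
#'
#' @param fit An `nbmix_fit` or `nbmix_selection` object, or a named vector of
#'   labels.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_labels <- function(fit, path) {
  labels <- if (inherits(fit, c("nbmix_fit", "nbmix_selection"))) {
    fit$labels
  } else {
    fit
  }
  readr::write_csv(
    tibble::tibble(sample_id = names(labels), cluster = as.integer(labels)),
    path)
  invisible(path)
}
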