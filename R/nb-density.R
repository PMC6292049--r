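# Negative binomial density and per-gene maximum-likelihood estimation.
#
# The NB parameterization used throughout is the (mu, theta) "size" form:
#   f(x | mu, theta) = Gamma(x + theta) / (Gamma(theta) x!) *
#                      (mu / (theta + mu))^x * (theta / (theta + mu))^theta
# with Var(X) = mu + mu^2 / theta, so larger theta means less over-dispersion
# and theta -> Inf recovers the Poisson. Because clustering is applied to
# library-size normalized (CPM) expression, x need not be an integer: x! is
# generalized to Gamma(x + 1).

#' Default bounds for the NB dispersion parameter
#'
#' Lower and upper bounds used when profiling the dispersion (size) parameter
#' theta. The cap encodes the Poisson limit: data with variance at or below the
#' mean are fitted at `theta_cap`.
#'
#' @return Named numeric vector with elements `floor` and `cap`.
#' @export
#' @examples
#' nb_theta_bounds()
nb_theta_bounds <- function() {
  c(floor = 1e-3, cap = 1e5)
}

#' Negative binomial log density with continuous support
#'
#' Log density of the negative binomial distribution in mean/size form,
#' computed entirely in log space via `lgamma()`. The factorial `x!` is
#' generalized to `Gamma(x + 1)` so normalized (non-integer) expression values
#' are valid inputs. For `mu = 0` the distribution degenerates to a point mass
#' at zero: the log density is 0 at `x = 0` and `-Inf` otherwise.
#'
#' @param x Non-negative numeric vector of observed values.
#' @param mu Non-negative numeric vector of means (recycled against `x`).
#' @param theta Positive numeric vector of size/dispersion parameters.
#'
#' @return Numeric vector of log densities, finite wherever `mu > 0`.
#' @export
#' @examples
#' nb_log_density(0, mu = 1, theta = 1)   # log(1/2)
#' nb_log_density(3, mu = 2, theta = 4)
nb_log_density <- function(x, mu, theta) {
  if (!is.numeric(x) || !is.numeric(mu) || !is.numeric(theta)) {
    stop("`x`, `mu` and `theta` must be numeric.", call. = FALSE)
  }
  if (anyNA(x) || anyNA(mu) || anyNA(theta) ||
      any(!is.finite(x)) || any(!is.finite(mu)) || any(!is.finite(theta))) {
    stop("`x`, `mu` and `theta` must be finite and non-missing.", call. = FALSE)
  }
  if (any(x < 0)) stop("`x` must be non-negative.", call. = FALSE)
  if (any(mu < 0)) stop("`mu` must be non-negative.", call. = FALSE)
  if (any(theta <= 0)) stop("`theta` must be positive.", call. = FALSE)

  n <- max(length(x), length(mu), length(theta))
  x <- rep_len(x, n)
  mu <- rep_len(mu, n)
  theta <- rep_len(theta, n)

  out <- numeric(n)
  pos <- mu > 0
  if (any(pos)) {
    xp <- x[pos]; mp <- mu[pos]; tp <- theta[pos]
    # x * log(mu/(theta+mu)) is 0*-Inf-safe here because mu > 0
    out[pos] <- lgamma(xp + tp) - lgamma(tp) - lgamma(xp + 1) +
      xp * (log(mp) - log(tp + mp)) + tp * (log(tp) - log(tp + mp))
  }
  if (any(!pos)) {
    out[!pos] <- ifelse(x[!pos] == 0, 0, -Inf)
  }
  out
}

#' Per-gene negative binomial maximum-likelihood fit
#'
#' Fits a single-gene NB model by exact maximum likelihood: the mean MLE is the
#' sample mean, and the dispersion MLE maximizes the profile log-likelihood
#' over `theta` by bounded one-dimensional optimization on the log scale
#' (convergence tolerance 1e-8). Under-dispersed genes (sample variance at or
#' below the sample mean, including constant and all-zero genes) are fitted at
#' the upper cap, the Poisson-limit boundary.
#'
#' @param x Numeric vector of non-negative values, length >= 2.
#' @param theta_bounds Length-2 positive numeric: lower and upper bound for
#'   theta. Defaults to [nb_theta_bounds()].
#'
#' @return A list of class `"gene_nb_estimate"` with elements `mu_hat`,
#'   `theta_hat`, `converged`, and `at_cap` (`TRUE` when theta hit the cap).
#' @export
#' @examples
#' set.seed(1)
#' fit_gene_nb_mle(rnbinom(500, mu = 10, size = 2))
fit_gene_nb_mle <- function(x, theta_bounds = nb_theta_bounds()) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("`x` must be a numeric vector of length >= 2.", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("`x` must be finite and non-negative.", call. = FALSE)
  }
  theta_bounds <- as.numeric(theta_bounds)
  if (length(theta_bounds) != 2 || any(theta_bounds <= 0) ||
      theta_bounds[1] >= theta_bounds[2]) {
    stop("`theta_bounds` must be two increasing positive values.", call. = FALSE)
  }
  lo <- theta_bounds[1]; hi <- theta_bounds[2]

  mu_hat <- mean(x)
  est <- function(theta_hat, converged, at_cap) {
    structure(
      list(mu_hat = mu_hat, theta_hat = theta_hat,
           converged = converged, at_cap = at_cap),
      class = "gene_nb_estimate"
    )
  }

  # No over-dispersion (incl. all-zero / constant genes): Poisson-limit cap.
  if (mu_hat == 0 || stats::var(x) <= mu_hat) {
    return(est(hi, TRUE, TRUE))
  }

  profile <- function(log_theta) {
    sum(nb_log_density(x, mu_hat, exp(log_theta)))
  }
  opt <- stats::optimize(profile, interval = c(log(lo), log(hi)),
                         maximum = TRUE, tol = 1e-8)
  theta_hat <- exp(opt$maximum)
  # optimize() never returns an exact endpoint; snap to a boundary when the
  # profile is still climbing there.
  at_cap <- FALSE
  if (profile(log(hi)) >= opt$objective) {
    theta_hat <- hi; at_cap <- TRUE
  } else if (profile(log(lo)) >= opt$objective) {
    theta_hat <- lo
  }
  est(theta_hat, TRUE, at_cap)
}

#' Gene-wise NB maximum-likelihood estimates for a count matrix
#'
#' Applies [fit_gene_nb_mle()] independently to every gene (column) of a
#' samples-by-genes matrix; genes are assumed independent.
#'
#' @param x Numeric samples-by-genes matrix (or data frame) with >= 2 rows.
#' @param theta_bounds Passed to [fit_gene_nb_mle()].
#'
#' @return A list with numeric vectors `mu_hat` and `theta_hat` (one entry per
#'   gene, named when `x` has column names) and logical vector `at_cap`.
#' @export
fit_matrix_nb_mle <- function(x, theta_bounds = nb_theta_bounds()) {
  x <- as_count_matrix(x)
  if (nrow(x) < 2) stop("Need at least 2 samples (rows).", call. = FALSE)
  fits <- apply(x, 2, fit_gene_nb_mle, theta_bounds = theta_bounds,
                simplify = FALSE)
  list(
    mu_hat = vapply(fits, `[[`, numeric(1), "mu_hat"),
    theta_hat = vapply(fits, `[[`, numeric(1), "theta_hat"),
    at_cap = vapply(fits, `[[`, logical(1), "at_cap")
  )
}

# Coerce a matrix-like object to a validated samples x genes numeric matrix.
as_count_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric samples x genes matrix.", arg),
         call. = FALSE)
  }
  if (anyNA(x)) stop(sprintf("`%s` contains missing values.", arg), call. = FALSE)
  if (any(x < 0)) stop(sprintf("`%s` contains negative values.", arg), call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("gene", seq_len(ncol(x)))
  x
}

#' @export
print.gene_nb_estimate <- function(x, ...) {
  cat(sprintf("<gene_nb_estimate> mu_hat = %.4g, theta_hat = %.4g%s\n",
              x$mu_hat, x$theta_hat,
              if (x$at_cap) " (at dispersion cap: no over-dispersion)" else ""))
  invisible(x)
}
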