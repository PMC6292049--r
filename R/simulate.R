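# Synthetic clustered NB count matrices.
#
# The generator mirrors a standard RNA-seq clustering simulation design:
# per-gene baseline parameters (mu1, theta1) define cluster 1; cluster k gets
# multiplicative shifts mu_k = mu1 * exp((k-1) * delta_mu) and
# theta_k = theta1 * exp((k-1) * delta_theta) on a designated subset of
# differentially expressed (DE) genes; non-DE genes are identical across
# clusters. Sample labels are uniform over the K clusters and counts are
# independent NB draws.

#' Define a simulation scenario
#'
#' One configuration of the simulation design: sample size, gene count, number
#' of clusters, the log-scale shift steps between adjacent clusters for means
#' (`delta_mu`) and dispersions (`delta_theta`), the DE-gene fraction, and the
#' seed that makes the dataset reproducible.
#'
#' @param n Number of samples.
#' @param g Number of genes.
#' @param k True number of clusters (>= 2).
#' @param delta_mu Log-scale mean shift step between adjacent clusters
#'   (0.1 small / 0.5 medium / 1 large are the conventional settings).
#' @param delta_theta Log-scale dispersion shift step (0 or 1 conventionally).
#' @param de_fraction Fraction of genes carrying the cluster signal, in
#'   (0, 1]; `de_fraction * g` must be >= 1.
#' @param seed Integer seed.
#'
#' @return A list of class `"nbmix_scenario"`.
#' @export
#' @examples
#' nbmix_scenario(n = 50, g = 1000, k = 2, delta_mu = 1, delta_theta = 1,
#'                de_fraction = 0.05, seed = 7)
nbmix_scenario <- function(n, g, k, delta_mu, delta_theta = 0,
                           de_fraction = 1, seed = 1) {
  stopifnot(n >= 2, g >= 1, k >= 2, delta_mu >= 0, delta_theta >= 0,
            de_fraction > 0, de_fraction <= 1)
  if (de_fraction * g < 1) {
    stop("`de_fraction * g` must be at least 1 (no DE genes otherwise).",
         call. = FALSE)
  }
  structure(
    list(n = as.integer(n), g = as.integer(g), k = as.integer(k),
         delta_mu = delta_mu, delta_theta = delta_theta,
         de_fraction = de_fraction, seed = as.integer(seed)),
    class = "nbmix_scenario"
  )
}

#' Draw per-gene baseline NB parameters
#'
#' A configurable stochastic stand-in for baseline parameters estimated from a
#' real highly variable gene set: `log(mu1)` from a Normal(log 50, sd 1.5)
#' truncated so mu1 lies in `[1, 1e4]` (spanning low- to high-expression
#' genes on the CPM scale), and `theta1` from Gamma(shape 2, scale 1)
#' truncated to `[0.1, 50]` (strong to mild over-dispersion). Truncation uses
#' exact inverse-CDF sampling. Alternatively pass explicit vectors through
#' `mu1`/`theta1` (e.g. loaded from file) and they are validated and returned
#' verbatim.
#'
#' @param g Number of genes.
#' @param seed Integer seed.
#' @param mu1,theta1 Optional explicit length-`g` baseline vectors; when both
#'   are given no sampling happens.
#' @param config Named list overriding the sampling distributions:
#'   `mu_meanlog`, `mu_sdlog`, `mu_range`, `theta_shape`, `theta_scale`,
#'   `theta_range`.
#'
#' @return List of class `"nbmix_baseline"` with positive length-`g` vectors
#'   `mu1` and `theta1`.
#' @export
sample_baseline <- function(g, seed = 1, mu1 = NULL, theta1 = NULL,
                            config = list()) {
  if (!is.null(mu1) || !is.null(theta1)) {
    if (is.null(mu1) || is.null(theta1)) {
      stop("Supply both `mu1` and `theta1`, or neither.", call. = FALSE)
    }
    if (length(mu1) != g || length(theta1) != g) {
      stop("`mu1` and `theta1` must have length `g`.", call. = FALSE)
    }
    if (any(mu1 <= 0) || any(theta1 <= 0) ||
        any(!is.finite(mu1)) || any(!is.finite(theta1))) {
      stop("Baseline parameters must be finite and strictly positive.",
           call. = FALSE)
    }
    return(structure(list(mu1 = as.numeric(mu1), theta1 = as.numeric(theta1)),
                     class = "nbmix_baseline"))
  }
  cfg <- utils::modifyList(
    list(mu_meanlog = log(50), mu_sdlog = 1.5, mu_range = c(1, 1e4),
         theta_shape = 2, theta_scale = 1, theta_range = c(0.1, 50)),
    config)
  if (cfg$mu_range[1] <= 0 || cfg$mu_range[1] >= cfg$mu_range[2] ||
      cfg$theta_range[1] <= 0 || cfg$theta_range[1] >= cfg$theta_range[2] ||
      cfg$mu_sdlog <= 0 || cfg$theta_shape <= 0 || cfg$theta_scale <= 0) {
    stop("Invalid baseline generator configuration.", call. = FALSE)
  }
  with_seed(seed, {
    # inverse-CDF sampling from the truncated distributions (exact, no
    # rejection loop)
    plo <- stats::pnorm(log(cfg$mu_range[1]), cfg$mu_meanlog, cfg$mu_sdlog)
    phi <- stats::pnorm(log(cfg$mu_range[2]), cfg$mu_meanlog, cfg$mu_sdlog)
    mu1 <- exp(stats::qnorm(stats::runif(g, plo, phi),
                            cfg$mu_meanlog, cfg$mu_sdlog))
    qlo <- stats::pgamma(cfg$theta_range[1], cfg$theta_shape,
                         scale = cfg$theta_scale)
    qhi <- stats::pgamma(cfg$theta_range[2], cfg$theta_shape,
                         scale = cfg$theta_scale)
    theta1 <- stats::qgamma(stats::runif(g, qlo, qhi), cfg$theta_shape,
                            scale = cfg$theta_scale)
    structure(list(mu1 = mu1, theta1 = theta1), class = "nbmix_baseline")
  })
}

#' Build per-cluster NB parameters from a baseline and a scenario
#'
#' Designates a seeded random subset of `ceiling(de_fraction * g)` genes as
#' differentially expressed. For DE genes, cluster k carries
#' `mu1 * exp((k - 1) * delta_mu)` and `theta1 * exp((k - 1) * delta_theta)`;
#' non-DE genes keep the baseline parameters in every cluster, so cluster 1
#' always equals the baseline. With `de_mode = "all"` the shifts apply to
#' every gene regardless of `de_fraction`.
#'
#' @param baseline A [sample_baseline()] result.
#' @param scenario A [nbmix_scenario()].
#' @param de_mode `"subset"` (default) or `"all"`.
#'
#' @return List with `components` (K lists of `mu`, `theta`) and `de_genes`
#'   (sorted integer indices of the DE subset).
#' @export
build_cluster_params <- function(baseline, scenario,
                                 de_mode = c("subset", "all")) {
  de_mode <- match.arg(de_mode)
  stopifnot(inherits(baseline, "nbmix_baseline"),
            inherits(scenario, "nbmix_scenario"),
            length(baseline$mu1) == scenario$g)
  g <- scenario$g
  n_de <- ceiling(scenario$de_fraction * g)
  de_genes <- if (de_mode == "all") {
    seq_len(g)
  } else {
    sort(with_seed(derive_seed(scenario$seed, 1), sample.int(g, n_de)))
  }
  components <- lapply(seq_len(scenario$k), function(j) {
    mu <- baseline$mu1
    theta <- baseline$theta1
    mu[de_genes] <- mu[de_genes] * exp((j - 1) * scenario$delta_mu)
    theta[de_genes] <- theta[de_genes] * exp((j - 1) * scenario$delta_theta)
    list(mu = mu, theta = theta)
  })
  list(components = components, de_genes = de_genes)
}

#' Simulate a clustered NB count matrix
#'
#' Draws sample labels i.i.d. uniform over the K clusters (or an exact equal
#' split when `exact_split = TRUE`), then gene counts independently from
#' `NB(mu_label,g, theta_label,g)`. Bit-identical output for a given scenario.
#'
#' @param scenario A [nbmix_scenario()].
#' @param baseline Optional [sample_baseline()] result; by default one is
#'   drawn with the scenario's seed and the default generator configuration.
#' @param exact_split Assign samples to clusters in equal blocks (shuffled)
#'   instead of i.i.d. uniform.
#' @param de_mode Passed to [build_cluster_params()].
#'
#' @return List with `counts` (samples-by-genes integer-valued matrix),
#'   `labels` (true cluster of each sample), `components` (per-cluster NB
#'   parameters), `de_genes`, and the `scenario`.
#' @export
#' @examples
#' sim <- simulate_nbmix_counts(nbmix_scenario(n = 30, g = 20, k = 2,
#'                                             delta_mu = 1, seed = 3))
#' dim(sim$counts); table(sim$labels)
simulate_nbmix_counts <- function(scenario, baseline = NULL,
                                  exact_split = FALSE,
                                  de_mode = c("subset", "all")) {
  stopifnot(inherits(scenario, "nbmix_scenario"))
  if (is.null(baseline)) baseline <- sample_baseline(scenario$g, scenario$seed)
  params <- build_cluster_params(baseline, scenario, de_mode)
  n <- scenario$n; g <- scenario$g; k <- scenario$k

  with_seed(derive_seed(scenario$seed, 2), {
    labels <- if (exact_split) {
      sample(rep_len(seq_len(k), n))
    } else {
      sample.int(k, n, replace = TRUE)
    }
    counts <- matrix(0, n, g,
                     dimnames = list(paste0("sample", seq_len(n)),
                                     paste0("gene", seq_len(g))))
    for (j in seq_len(k)) {
      idx <- which(labels == j)
      if (length(idx) == 0) next
      comp <- params$components[[j]]
      counts[idx, ] <- matrix(
        stats::rnbinom(length(idx) * g,
                       mu = rep(comp$mu, each = length(idx)),
                       size = rep(comp$theta, each = length(idx))),
        length(idx), g)
    }
    list(counts = counts, labels = labels, components = params$components,
         de_genes = params$de_genes, scenario = scenario)
  })
}

#' Enumerate a grid of simulation scenarios
#'
#' Crosses the supplied axes into a tibble of scenarios, one row each, with a
#' per-scenario seed derived deterministically from `master_seed`. The default
#' axes form the full 480-scenario benchmark grid
#' (K 5 x delta_mu 3 x delta_theta 2 x DE 2 x N 4 x G 2); restrict any axis
#' for scaled-down runs.
#'
#' @param k,delta_mu,delta_theta,de_fraction,n,g Axis values (each non-empty).
#' @param master_seed Integer seed from which per-scenario seeds are derived.
#'
#' @return Tibble with one row per scenario: the six axis columns plus
#'   `scenario_id` and `seed`.
#' @export
#' @examples
#' nrow(scenario_grid())                  # 480
#' nrow(scenario_grid(n = 50))            # 120
scenario_grid <- function(k = 2:6,
                          delta_mu = c(0.1, 0.5, 1),
                          delta_theta = c(0, 1),
                          de_fraction = c(0.05, 0.1),
                          n = c(50, 100, 150, 200),
                          g = c(1000, 5000),
                          master_seed = 1) {
  axes <- list(k = k, delta_mu = delta_mu, delta_theta = delta_theta,
               de_fraction = de_fraction, n = n, g = g)
  empty <- lengths(axes) == 0
  if (any(empty)) {
    stop("Empty scenario axis: ", paste(names(axes)[empty], collapse = ", "),
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    n = as.integer(n), g = as.integer(g), k = as.integer(k),
    delta_mu = delta_mu, delta_theta = delta_theta,
    de_fraction = de_fraction)
  seeds <- with_seed(master_seed,
                     sample.int(.Machine$integer.max, nrow(grid)))
  dplyr::mutate(grid, scenario_id = dplyr::row_number(), seed = seeds)
}

# Convert one row of a scenario_grid() tibble to an nbmix_scenario.
grid_row_scenario <- function(row) {
  nbmix_scenario(n = row$n, g = row$g, k = row$k, delta_mu = row$delta_mu,
                 delta_theta = row$delta_theta,
                 de_fraction = row$de_fraction, seed = row$seed)
}

# Derive a related seed without leaving 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + offset) %% (.Machine$integer.max - 1))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
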