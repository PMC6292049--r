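# Benchmarking: adjusted Rand index, Gaussian-mixture comparators, and the
# simulation-study driver that scores methods against the true labels.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie form) computed from
#' the contingency table:
#' `ARI = (Index - E[Index]) / (Max - E[Index])` where Index counts sample
#' pairs placed together in both partitions. Invariant to relabeling; 1 for
#' identical partitions, about 0 for independent ones, and can be negative.
#' When both partitions are degenerate in the same way (e.g. both put all
#' samples in one cluster, making the denominator zero) the partitions are
#' identical and the value is 1 by convention.
#'
#' @param labels_a,labels_b Label vectors of equal length >= 2 (any atomic
#'   type; coerced to factors).
#'
#' @return A single number in [-1, 1].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("Label vectors must have equal length.", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 2) stop("Need at least 2 samples.", call. = FALSE)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(n, 2)
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions degenerate alike
  (sum_ij - expected) / (max_index - expected)
}

#' Gaussian-mixture comparator clustering
#'
#' The reference pipeline NB mixture clustering is compared against: apply a
#' transform (`none`, `log` with pseudocount 1, or the rank-based
#' inverse-normal `blom`), fit Gaussian mixtures over `k_range`, select k by
#' BIC, return hard labels. The Gaussian EM and BIC selection are delegated to
#' [mclust::Mclust()]; the default model family is the diagonal set (`EII`,
#' `VII`, `EEI`, `VEI`, `EVI`, `VVI`), over which mclust also selects by BIC
#' while skipping singular fits — per-component-variance models are
#' frequently singular when genes far outnumber samples, so the
#' pooled-variance diagonal models keep the comparator fittable there.
#'
#' @param x Samples-by-genes matrix of non-negative counts (the transform is
#'   applied internally).
#' @param transform `"none"`, `"log"`, or `"blom"`.
#' @param k_range Candidate component counts (default 2:6).
#' @param model_names mclust model family (default: all diagonal models).
#' @param seed Seed for mclust's (rarely exercised) internal randomness.
#'
#' @return List of class `"gmm_fit"` with `labels`, `k`, `transform`, and the
#'   underlying `Mclust` object as `model`.
#' @export
gmm_cluster <- function(x, transform = c("none", "log", "blom"),
                        k_range = 2:6,
                        model_names = c("EII", "VII", "EEI", "VEI", "EVI",
                                        "VVI"),
                        seed = 1) {
  transform <- match.arg(transform)
  x <- as_count_matrix(x)
  y <- switch(transform,
              none = x,
              log = log_transform(x, 1),
              blom = blom_transform(x))
  fit <- with_seed(seed, {
    mclust::Mclust(y, G = k_range, modelNames = model_names, verbose = FALSE)
  })
  if (is.null(fit)) {
    stop("Gaussian mixture fit failed for every k in k_range.", call. = FALSE)
  }
  structure(
    list(labels = stats::setNames(as.integer(fit$classification), rownames(x)),
         k = fit$G, transform = transform, model = fit),
    class = "gmm_fit"
  )
}

#' Run a simulation study over a grid of scenarios
#'
#' For every scenario row and replicate: simulate a clustered count matrix,
#' cluster it with each requested method (k selected from `k_range` by BIC),
#' and score the labels against the truth with the adjusted Rand index.
#' Replicate seeds are derived deterministically from the scenario seed and
#' replicate index, so results are reproducible and independent of execution
#' order. A method failure on one replicate is recorded in the `error` column
#' (ARI `NA`) and does not stop the run.
#'
#' @param scenarios A [scenario_grid()] tibble (or any tibble with columns
#'   `n, g, k, delta_mu, delta_theta, de_fraction, seed`).
#' @param n_replicates Simulated datasets per scenario.
#' @param methods Subset of `"nbmix"`, `"gmm_none"`, `"gmm_log"`,
#'   `"gmm_blom"`.
#' @param k_range Candidate cluster numbers for every method (default 2:6).
#' @param tau0,anneal_rate Annealing settings for the NB mixture method.
#' @param ... Further arguments passed to [fit_nbmix()] via
#'   [select_nbmix_k()].
#'
#' @return Tibble with one row per scenario x replicate x method: the six
#'   scenario axis columns, `scenario_id`, `replicate`, `seed`, `method`,
#'   `ari`, `k_selected`, `error`.
#' @seealso [summarize_ari()] to aggregate, [plot_ari_summary()] to display.
#' @export
#' @examples
#' grid <- scenario_grid(k = 2, delta_mu = 1, delta_theta = 0,
#'                       de_fraction = 0.5, n = 30, g = 40)
#' res <- run_simulation_study(grid, n_replicates = 2, methods = "nbmix",
#'                             k_range = 2:3)
#' summarize_ari(res)
run_simulation_study <- function(scenarios, n_replicates = 5,
                                 methods = c("nbmix", "gmm_none", "gmm_log",
                                             "gmm_blom"),
                                 k_range = 2:6, tau0 = 10, anneal_rate = 0.9,
                                 ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_replicates >= 1)
  if (!"scenario_id" %in% names(scenarios)) {
    scenarios$scenario_id <- seq_len(nrow(scenarios))
  }

  purrr::map_dfr(seq_len(nrow(scenarios)), function(i) {
    row <- scenarios[i, ]
    purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
      rep_seed <- derive_seed(row$seed, 7919 * rep_i)
      sc <- grid_row_scenario(dplyr::mutate(row, seed = rep_seed))
      sim <- simulate_nbmix_counts(sc)
      purrr::map_dfr(methods, function(method) {
        out <- tryCatch({
          res <- switch(
            method,
            nbmix = select_nbmix_k(sim$counts, k_range = k_range,
                                   tau0 = tau0, anneal_rate = anneal_rate,
                                   ...),
            gmm_none = gmm_cluster(sim$counts, "none", k_range,
                                   seed = rep_seed),
            gmm_log = gmm_cluster(sim$counts, "log", k_range,
                                  seed = rep_seed),
            gmm_blom = gmm_cluster(sim$counts, "blom", k_range,
                                   seed = rep_seed))
          list(ari = adjusted_rand_index(res$labels, sim$labels),
               k_selected = res$k, error = NA_character_)
        }, error = function(e) {
          list(ari = NA_real_, k_selected = NA_integer_,
               error = conditionMessage(e))
        })
        tibble::tibble(
          scenario_id = row$scenario_id, n = row$n, g = row$g, k = row$k,
          delta_mu = row$delta_mu, delta_theta = row$delta_theta,
          de_fraction = row$de_fraction,
          replicate = rep_i, seed = rep_seed, method = method,
          ari = out$ari, k_selected = as.integer(out$k_selected),
          error = out$error)
      })
    })
  })
}

#' Summarize simulation-study ARI results
#'
#' Long-format summary keyed by the scenario axes and method: mean, sd,
#' median, min and max ARI over successful replicates, the modal selected k,
#' and replicate counts.
#'
#' @param results A [run_simulation_study()] tibble.
#' @return Tibble of class `"nbmix_ari_summary"`, one row per
#'   scenario x method.
#' @export
summarize_ari <- function(results) {
  if (nrow(results) == 0) stop("`results` is empty.", call. = FALSE)
  out <- results |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("scenario_id", "n", "g", "k", "delta_mu", "delta_theta",
        "de_fraction", "method")))) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_failed = sum(is.na(.data$ari)),
      mean_ari = mean(.data$ari, na.rm = TRUE),
      sd_ari = stats::sd(.data$ari, na.rm = TRUE),
      median_ari = stats::median(.data$ari, na.rm = TRUE),
      min_ari = min(.data$ari, na.rm = TRUE),
      max_ari = max(.data$ari, na.rm = TRUE),
      modal_k = modal_value(.data$k_selected),
      .groups = "drop")
  class(out) <- c("nbmix_ari_summary", class(out))
  out
}

modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}
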