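# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted NB mixture
#'
#' One row per sample: the hard cluster assignment, its posterior
#' probability, and the full posterior spread across `.posterior_*` columns.
#'
#' @param x An [fit_nbmix()] object.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `cluster`, `posterior`, and one
#'   `.posterior_k` column per component.
#' @method tidy nbmix_fit
#' @export
tidy.nbmix_fit <- function(x, ...) {
  post <- tibble::as_tibble(x$posteriors, .name_repair = ~ paste0(
    ".posterior_", seq_along(.x)))
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = names(x$labels),
      cluster = as.integer(x$labels),
      posterior = x$posteriors[cbind(seq_along(x$labels), x$labels)]),
    post)
}

#' One-row fit summary
#'
#' @param x An [fit_nbmix()] object.
#' @param ... Unused.
#' @return Tibble with `k`, `n`, `g`, `loglik`, `bic`, `n_iter`, `converged`.
#' @method glance nbmix_fit
#' @export
glance.nbmix_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, g = x$g, loglik = x$loglik, bic = x$bic,
                 n_iter = x$n_iter, converged = x$converged)
}

#' Tidy a BIC model selection
#'
#' The per-k BIC trace as a tibble.
#'
#' @param x A [select_nbmix_k()] object.
#' @param ... Unused.
#' @method tidy nbmix_selection
#' @export
tidy.nbmix_selection <- function(x, ...) {
  x$bic_trace
}

#' One-row selection summary
#'
#' @param x A [select_nbmix_k()] object.
#' @param ... Unused.
#' @method glance nbmix_selection
#' @export
glance.nbmix_selection <- function(x, ...) {
  dplyr::mutate(glance(x$best), k_candidates = list(x$bic_trace$k))
}
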