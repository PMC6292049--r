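# File-to-file pipeline runners behind the command-line interface
# (inst/cli/nbmix). Each runner resolves its configuration, writes a
# resolved_config.json beside its outputs so any run can be replayed exactly,
# and returns its main result invisibly.

#' Cluster a count file end to end
#'
#' Pipeline: read counts, optionally upper-quartile CPM normalize, optionally
#' keep the top-MAD genes, cluster with the NB mixture selecting k by BIC,
#' and write `labels.csv` (sample_id, cluster), `model.json`,
#' `bic_trace.csv`, and `resolved_config.json` to `out_dir`. Deterministic:
#' rerunning with the same configuration reproduces the outputs byte for
#' byte.
#'
#' @param counts Path to a counts file (see [read_counts()]).
#' @param out_dir Output directory (created if needed).
#' @param orientation,format Passed to [read_counts()].
#' @param normalize Apply [upper_quartile_cpm()] before clustering.
#' @param top_mad If non-NULL, keep this many top-MAD genes.
#' @param k_min,k_max Candidate cluster range.
#' @param tau0,anneal_rate,tol,max_iter,init_shift Passed to [fit_nbmix()].
#'
#' @return The [select_nbmix_k()] result, invisibly.
#' @export
run_cluster <- function(counts, out_dir,
                        orientation = "samples_in_rows", format = "auto",
                        normalize = FALSE, top_mad = NULL,
                        k_min = 2, k_max = 6,
                        tau0 = 10, anneal_rate = 0.9, tol = 1e-6,
                        max_iter = 1000, init_shift = 0.01) {
  config <- list(subcommand = "cluster", counts = counts,
                 orientation = orientation, format = format,
                 normalize = normalize, top_mad = top_mad,
                 k_min = k_min, k_max = k_max, tau0 = tau0,
                 anneal_rate = anneal_rate, tol = tol, max_iter = max_iter,
                 init_shift = init_shift)
  x <- read_counts(counts, format, orientation)
  if (normalize) x <- upper_quartile_cpm(x)
  if (!is.null(top_mad)) x <- mad_top_genes(x, top_mad)
  sel <- select_nbmix_k(x, k_range = seq(k_min, k_max), tau0 = tau0,
                        anneal_rate = anneal_rate, tol = tol,
                        max_iter = max_iter, init_shift = init_shift)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cluster_labels(sel, file.path(out_dir, "labels.csv"))
  write_nbmix_model(sel, file.path(out_dir, "model.json"))
  readr::write_csv(sel$bic_trace, file.path(out_dir, "bic_trace.csv"))
  write_resolved_config(config, out_dir)
  invisible(sel)
}

#' Simulate datasets for a scenario grid
#'
#' Writes one counts TSV and one labels CSV per scenario x replicate, plus a
#' `manifest.csv` recording every axis value and seed (re-feeding a manifest
#' row's seed regenerates the identical dataset) and a
#' `resolved_config.json`. Filenames embed the scenario axes and replicate
#' index.
#'
#' @param out_dir Output directory.
#' @param scenarios A [scenario_grid()] tibble.
#' @param n_replicates Datasets per scenario.
#'
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(out_dir, scenarios, n_replicates = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!"scenario_id" %in% names(scenarios)) {
    scenarios$scenario_id <- seq_len(nrow(scenarios))
  }
  manifest <- purrr::map_dfr(seq_len(nrow(scenarios)), function(i) {
    row <- scenarios[i, ]
    purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
      rep_seed <- derive_seed(row$seed, 7919 * rep_i)
      sc <- grid_row_scenario(dplyr::mutate(row, seed = rep_seed))
      sim <- simulate_nbmix_counts(sc)
      stem <- sprintf("N%d_G%d_K%d_dmu%g_dth%g_de%g_rep%d",
                      row$n, row$g, row$k, row$delta_mu, row$delta_theta,
                      row$de_fraction, rep_i)
      counts_file <- file.path(out_dir, paste0(stem, "_counts.tsv"))
      labels_file <- file.path(out_dir, paste0(stem, "_labels.csv"))
      write_counts(sim$counts, counts_file)
      readr::write_csv(
        tibble::tibble(sample_id = rownames(sim$counts),
                       cluster = sim$labels),
        labels_file)
      dplyr::mutate(row, replicate = rep_i, seed = rep_seed,
                    counts_file = basename(counts_file),
                    labels_file = basename(labels_file))
    })
  })
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  write_resolved_config(list(subcommand = "simulate",
                             n_scenarios = nrow(scenarios),
                             n_replicates = n_replicates), out_dir)
  invisible(manifest)
}

#' Run and persist a simulation benchmark
#'
#' Calls [run_simulation_study()] and writes `ari_replicates.csv` (one row
#' per scenario x replicate x method), `ari_summary.csv`, and
#' `resolved_config.json`.
#'
#' @param out_dir Output directory.
#' @param scenarios A [scenario_grid()] tibble.
#' @param n_replicates Replicates per scenario.
#' @param methods Methods to benchmark (see [run_simulation_study()]).
#' @param k_range Candidate cluster numbers.
#' @param tau0,anneal_rate Annealing settings.
#'
#' @return The per-replicate results tibble, invisibly.
#' @export
run_benchmark <- function(out_dir, scenarios, n_replicates = 5,
                          methods = c("nbmix", "gmm_none", "gmm_log",
                                      "gmm_blom"),
                          k_range = 2:6, tau0 = 10, anneal_rate = 0.9) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- run_simulation_study(scenarios, n_replicates, methods,
                                  k_range, tau0, anneal_rate)
  readr::write_csv(results, file.path(out_dir, "ari_replicates.csv"))
  readr::write_csv(summarize_ari(results),
                   file.path(out_dir, "ari_summary.csv"))
  write_resolved_config(
    list(subcommand = "benchmark", n_scenarios = nrow(scenarios),
         n_replicates = n_replicates, methods = methods,
         k_range = k_range, tau0 = tau0, anneal_rate = anneal_rate),
    out_dir)
  invisible(results)
}

#' Apply a standalone transform to a count file
#'
#' Reads a counts file, applies one of the preprocessing transforms, and
#' writes the result in the same format family.
#'
#' @param counts Input counts file.
#' @param out Output file.
#' @param transform One of `"uqcpm"`, `"log"`, `"blom"`, `"mad"`.
#' @param top_n Number of genes kept when `transform = "mad"`.
#' @param pseudocount Pseudocount for `transform = "log"`.
#' @param orientation,format Passed to [read_counts()].
#'
#' @return The transformed matrix, invisibly.
#' @export
run_transform <- function(counts, out,
                          transform = c("uqcpm", "log", "blom", "mad"),
                          top_n = 1000, pseudocount = 1,
                          orientation = "samples_in_rows", format = "auto") {
  transform <- match.arg(transform)
  x <- read_counts(counts, format, orientation)
  y <- switch(transform,
              uqcpm = upper_quartile_cpm(x),
              log = log_transform(x, pseudocount),
              blom = blom_transform(x),
              mad = mad_top_genes(x, top_n))
  # log/blom outputs may be negative, so bypass the count-matrix writer checks
  df <- tibble::as_tibble(y, rownames = "sample_id")
  delim <- if (tolower(tools::file_ext(out)) == "csv") "," else "\t"
  readr::write_delim(df, out, delim = delim)
  invisible(y)
}

write_resolved_config <- function(config, out_dir) {
  config$package_version <- as.character(utils::packageVersion("nbmixclust"))
  jsonlite::write_json(config, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(config)
}
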