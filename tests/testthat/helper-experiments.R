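# Builders for small in-memory experiments used across the unit tests.

# layout with one soluble/insoluble channel pair per time point per batch;
# each batch is one replicate of the same cell line
layout_grid <- function(batches = "b1", tps = c(0, 12), line = "WT",
                        phases = NULL) {
  if (is.null(phases)) {
    phases <- ifelse(tps == min(tps), "DMSO", "treatment")
  }
  rows <- list()
  for (bi in seq_along(batches)) {
    k <- 0
    for (ti in seq_along(tps)) {
      for (fr in c("soluble", "insoluble")) {
        k <- k + 1
        rows[[length(rows) + 1]] <- tibble::tibble(
          channel = k, batch = batches[bi], cell_line = line,
          time_point_h = tps[ti], phase = phases[ti], fraction = fr,
          replicate = bi)
      }
    }
  }
  validate_layout(dplyr::bind_rows(rows))
}

make_experiment <- function(intensities, layout,
                            reverse = FALSE, contaminant = FALSE,
                            site_only = FALSE) {
  n <- nrow(intensities)
  proteins <- tibble::tibble(
    protein_id = rownames(intensities),
    protein_ids_full = rownames(intensities),
    gene_name = rownames(intensities),
    reverse = rep_len(reverse, n),
    contaminant = rep_len(contaminant, n),
    site_only = rep_len(site_only, n)
  )
  new_mpq_experiment(intensities, proteins, layout)
}

# a small noise-free simulation configuration: exact arithmetic end to end
noiseless_config <- function(n_proteins = 60, seed = 42, ...) {
  sim_config(n_proteins = n_proteins, noise_log2_sd = 0,
             loading_log2_sd = 0, detection_limit_quantile = 0,
             seed = seed, ...)
}

# run the in-memory analysis stages on a simulation (no disk round trip)
run_stages <- function(sim, impute = FALSE, seed = 1) {
  x <- sim$experiment
  x <- normalize_to_spikein(x, sim$config$spike_id)
  x <- apply_quality_filters(x)
  if (impute) {
    x <- impute_missing(x, params = imputation_params(seed = seed))
  }
  annotate_mito(x, sim$annotation, sim$config$spike_id)
}
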