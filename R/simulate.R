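#' Configuration for a synthetic fractionation experiment
#'
#' Builds the parameter set for [simulate_experiment()]. The defaults
#' emulate the study design the package targets: five cell lines (wild type
#' plus four knockout analogues with stronger aggregation and slower
#' recovery), a vehicle control, a 12-hour stress time point and 24/48-hour
#' recovery time points, three replicates, one multiplexed batch per
#' (cell line, replicate) holding paired soluble/insoluble channels plus a
#' pooled control channel, a constant-amount spike-in row in every channel,
#' per-channel log-normal loading biases, log-normal measurement noise, and
#' left-censored missingness below a detection-limit quantile.
#'
#' @param n_proteins number of mitochondrial proteins (default 1000).
#' @param cell_lines tibble with `cell_line`, `effect_multiplier`
#'   (scales stress-induced solubility shifts) and `recovery_k_per_h`
#'   (exponential return-to-baseline rate constant, per hour).
#' @param time_points tibble with `time_point_h`, `phase`
#'   (`DMSO`/`treatment`/`recovery`) and `label`; hours strictly increasing.
#' @param n_replicates replicates per cell line (default 3).
#' @param abundance_log2_mean,abundance_log2_sd log2 protein abundance
#'   distribution (defaults 20 and 2).
#' @param loading_log2_sd per-channel loading bias SD on log2 scale
#'   (default 0.25).
#' @param noise_log2_sd multiplicative measurement noise SD on log2 scale
#'   (default 0.1).
#' @param spike_intensity spike-in signal before loading/noise (constant
#'   across channels, default `2^18`; the spike is added in fixed ratio to
#'   starting material so only per-channel loading moves it).
#' @param spike_id accession used for the spike-in row (default "AG85A").
#' @param detection_limit_quantile fraction of (protein, batch) run-level
#'   observations censored to missing from the bottom (default 0.01).
#'   Reporter-ion quantification requires identification of the protein in
#'   the multiplexed run, so detection failure removes the protein from
#'   every channel of that batch at once.
#' @param frac_aggregation_prone fraction of proteins that aggregate under
#'   stress (default 0.2).
#' @param shift_pp_range range of true stress-induced shifts for
#'   aggregation-prone proteins, in percentage points of the insoluble
#'   share (default `c(35, 70)`).
#' @param baseline_theta_range range of baseline insoluble fractions
#'   (default `c(0.02, 0.30)`).
#' @param process_groups labels assigned to proteins.
#' @param sensitive_groups groups with elevated aggregation propensity.
#' @param group_effect_strength 0..1 knob for how strongly aggregation
#'   proneness concentrates in the sensitive groups (default 0.7).
#' @param include_pooled_control add a pooled-control channel per batch.
#' @param n_nonmito,n_reverse,n_contaminant,n_site_only extra
#'   quality-control rows exercising the ingest filters.
#' @param seed RNG seed.
#' @return A validated list of class `mpq_sim_config`.
#' @export
sim_config <- function(
    n_proteins = 1000,
    cell_lines = tibble::tibble(
      cell_line = c("WT", "CHOP_KO", "ATF4_KO", "ATF5_KO", "TKO"),
      effect_multiplier = c(1, 1.5, 1.5, 1.5, 1.5),
      recovery_k_per_h = c(0.135, 0.012, 0.012, 0.012, 0.012)
    ),
    time_points = tibble::tibble(
      time_point_h = c(0, 12, 36, 60),
      phase = c("DMSO", "treatment", "recovery", "recovery"),
      label = c("DMSO", "GTPP_12h", "R_24h", "R_48h")
    ),
    n_replicates = 3,
    abundance_log2_mean = 20, abundance_log2_sd = 2,
    loading_log2_sd = 0.25,
    noise_log2_sd = 0.1,
    spike_intensity = 2^18,
    spike_id = "AG85A",
    detection_limit_quantile = 0.01,
    frac_aggregation_prone = 0.2,
    shift_pp_range = c(35, 70),
    baseline_theta_range = c(0.02, 0.30),
    process_groups = c("translation", "oxidative phosphorylation",
                       "transcription", "metabolism", "morphology",
                       "calcium signalling", "import & sorting",
                       "proteostasis"),
    sensitive_groups = c("translation", "transcription",
                         "oxidative phosphorylation", "metabolism"),
    group_effect_strength = 0.7,
    include_pooled_control = TRUE,
    n_nonmito = 50, n_reverse = 15, n_contaminant = 10, n_site_only = 5,
    seed = 1) {
  cfg <- structure(as.list(environment()), class = "mpq_sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_proteins >= 1, "n_proteins must be >= 1")
  chk(all(c("cell_line", "effect_multiplier", "recovery_k_per_h") %in%
            names(cfg$cell_lines)), "cell_lines lacks required columns")
  chk(all(c("time_point_h", "phase") %in% names(cfg$time_points)),
      "time_points lacks required columns")
  chk(!is.unsorted(cfg$time_points$time_point_h, strictly = TRUE),
      "time points must be strictly increasing")
  chk(all(cfg$time_points$phase %in% c("DMSO", "treatment", "recovery")),
      "unknown phase label")
  ph <- cfg$time_points$phase
  chk(identical(unique(ph), intersect(c("DMSO", "treatment", "recovery"),
                                      unique(ph))),
      "phases must follow DMSO -> treatment -> recovery order")
  chk(cfg$abundance_log2_sd >= 0 && cfg$loading_log2_sd >= 0 &&
        cfg$noise_log2_sd >= 0, "SDs must be >= 0")
  chk(cfg$spike_intensity > 0, "spike_intensity must be positive")
  chk(cfg$detection_limit_quantile >= 0 && cfg$detection_limit_quantile < 1,
      "detection_limit_quantile must lie in [0, 1)")
  chk(cfg$frac_aggregation_prone >= 0 && cfg$frac_aggregation_prone <= 1,
      "frac_aggregation_prone must lie in [0, 1]")
  chk(diff(cfg$shift_pp_range) >= 0 && cfg$shift_pp_range[1] >= 0,
      "shift_pp_range must be a non-negative ascending interval")
  chk(cfg$group_effect_strength >= 0 && cfg$group_effect_strength <= 1,
      "group_effect_strength must lie in [0, 1]")
  if (length(problems) > 0) {
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

# true insoluble fraction of one protein in one line at one time point
theta_at <- function(base, peak, phase, t, t_peak, k) {
  switch(phase,
         DMSO = base,
         treatment = peak,
         recovery = base + (peak - base) * exp(-k * (t - t_peak)))
}

#' Simulate a multi-batch fractionation experiment with known ground truth
#'
#' Generates reporter intensities under the measurement model
#' `soluble = A_p (1 - theta) L_c eps` and `insoluble = A_p theta L_c' eps'`
#' with log-normal channel loadings `L` and noise `eps`; the spike-in row is
#' `K L_c eps` in every channel. The true insoluble fraction `theta` follows
#' baseline at the vehicle time point, jumps to `baseline + shift x
#' line-multiplier` under stress for aggregation-prone proteins, and decays
#' exponentially back toward baseline during recovery at the line's rate
#' constant. Missingness is left-censored at the run level: a protein whose
#' total signal in one multiplexed batch falls below the detection limit is
#' missing from all of that batch's channels, the mechanism behind
#' batch-level absence in reporter-ion data. Decoy/contaminant/site-only and
#' non-mitochondrial rows are added to exercise the ingest filters.
#'
#' @param config an `mpq_sim_config` from [sim_config()].
#' @return List of class `mpq_simulation` with elements `experiment` (an
#'   `mpq_experiment`), `layout`, `annotation`, and `truth` (true `theta`
#'   per protein x cell line x time point, channel loadings, censoring
#'   bound, aggregation-prone flags and true shifts, seed, config).
#' @export
simulate_experiment <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  with_local_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  n <- cfg$n_proteins
  ids <- sprintf("MPQ%05d", seq_len(n))
  genes <- sprintf("Gene%05d", seq_len(n))

  # process groups with aggregation propensity concentrated in sensitive ones
  group <- sample(cfg$process_groups, n, replace = TRUE)
  w <- ifelse(group %in% cfg$sensitive_groups,
              1 + 4 * cfg$group_effect_strength, 1)
  n_prone <- round(cfg$frac_aggregation_prone * n)
  prone <- logical(n)
  if (n_prone > 0) prone[sample.int(n, n_prone, prob = w)] <- TRUE
  shift_pp <- ifelse(prone,
                     stats::runif(n, cfg$shift_pp_range[1],
                                  cfg$shift_pp_range[2]), 0)
  base_theta <- stats::runif(n, cfg$baseline_theta_range[1],
                             cfg$baseline_theta_range[2])
  abundance <- 2^stats::rnorm(n, cfg$abundance_log2_mean,
                              cfg$abundance_log2_sd)

  # layout: one batch per (cell line, replicate)
  tp <- cfg$time_points
  t_peak <- max(tp$time_point_h[tp$phase == "treatment"])
  lay_rows <- list()
  for (li in seq_len(nrow(cfg$cell_lines))) {
    line <- cfg$cell_lines$cell_line[li]
    for (r in seq_len(cfg$n_replicates)) {
      batch <- sprintf("%s_r%d", line, r)
      k <- 0
      for (ti in seq_len(nrow(tp))) {
        for (fr in c("soluble", "insoluble")) {
          k <- k + 1
          lay_rows[[length(lay_rows) + 1]] <- tibble::tibble(
            channel = k, batch = batch, cell_line = line,
            time_point_h = tp$time_point_h[ti], phase = tp$phase[ti],
            fraction = fr, replicate = r)
        }
      }
      if (cfg$include_pooled_control) {
        lay_rows[[length(lay_rows) + 1]] <- tibble::tibble(
          channel = k + 1, batch = batch, cell_line = "pool",
          time_point_h = NA_real_, phase = "pool",
          fraction = "pooled_control", replicate = r)
      }
    }
  }
  layout <- validate_layout(dplyr::bind_rows(lay_rows))

  # true theta per protein x line x time
  truth_theta <- tidyr::expand_grid(
    protein_id = ids,
    cfg$cell_lines[, c("cell_line", "effect_multiplier",
                       "recovery_k_per_h")],
    tp[, c("time_point_h", "phase")]
  )
  pidx <- match(truth_theta$protein_id, ids)
  peak <- pmin(base_theta[pidx] +
                 shift_pp[pidx] / 100 * truth_theta$effect_multiplier, 0.99)
  truth_theta$theta <- mapply(
    theta_at, base_theta[pidx], peak, truth_theta$phase,
    truth_theta$time_point_h,
    MoreArgs = NULL, t_peak = t_peak, k = truth_theta$recovery_k_per_h
  )
  truth_theta <- truth_theta[, c("protein_id", "cell_line", "time_point_h",
                                 "phase", "theta")]

  # extra rows exercising ingest filters: static solubility, never stressed
  extra <- function(n_extra, prefix, gene_prefix) {
    if (n_extra == 0) {
      return(list(ids = character(), genes = character(),
                  theta = numeric(), abundance = numeric()))
    }
    list(ids = sprintf("%s%03d", prefix, seq_len(n_extra)),
         genes = sprintf("%s%03d", gene_prefix, seq_len(n_extra)),
         theta = stats::runif(n_extra, 0, 1),
         abundance = 2^stats::rnorm(n_extra, cfg$abundance_log2_mean,
                                    cfg$abundance_log2_sd))
  }
  nonmito <- extra(cfg$n_nonmito, "NMITO", "NmGene")
  rev_rows <- extra(cfg$n_reverse, "REV__Q", "RevGene")
  con_rows <- extra(cfg$n_contaminant, "CON__P", "ConGene")
  so_rows <- extra(cfg$n_site_only, "SITE", "SiteGene")

  all_ids <- c(ids, nonmito$ids, rev_rows$ids, con_rows$ids, so_rows$ids,
               cfg$spike_id)
  n_all <- length(all_ids)
  all_ab <- c(abundance, nonmito$abundance, rev_rows$abundance,
              con_rows$abundance, so_rows$abundance, NA)
  static_theta <- c(rep(NA_real_, n), nonmito$theta, rev_rows$theta,
                    con_rows$theta, so_rows$theta, NA)

  loading <- 2^stats::rnorm(nrow(layout), 0, cfg$loading_log2_sd)
  names(loading) <- layout$channel_id

  theta_lookup <- truth_theta
  key <- paste(theta_lookup$protein_id, theta_lookup$cell_line,
               theta_lookup$time_point_h)
  theta_map <- stats::setNames(theta_lookup$theta, key)

  # pre-loading signal per protein for each sample channel
  signal <- matrix(NA_real_, n_all, nrow(layout))
  for (ci in seq_len(nrow(layout))) {
    fr <- layout$fraction[ci]
    if (fr == "pooled_control") next
    th <- numeric(n_all)
    th[seq_len(n)] <- theta_map[paste(ids, layout$cell_line[ci],
                                      layout$time_point_h[ci])]
    extra_idx <- setdiff(seq_len(n_all - 1), seq_len(n))
    th[extra_idx] <- static_theta[extra_idx]
    sig <- all_ab * (if (fr == "soluble") 1 - th else th)
    sig[n_all] <- cfg$spike_intensity
    signal[, ci] <- sig
  }
  if (cfg$include_pooled_control) {
    for (b in unique(layout$batch)) {
      pool_ci <- which(layout$batch == b &
                         layout$fraction == "pooled_control")
      samp_ci <- which(layout$batch == b &
                         layout$fraction != "pooled_control")
      if (length(pool_ci) == 1) {
        signal[, pool_ci] <- rowMeans(signal[, samp_ci, drop = FALSE])
        signal[n_all, pool_ci] <- cfg$spike_intensity
      }
    }
  }
  noise <- 2^matrix(stats::rnorm(n_all * nrow(layout), 0, cfg$noise_log2_sd),
                    n_all, nrow(layout))
  intens <- signal * rep(loading, each = n_all) * noise
  dimnames(intens) <- list(all_ids, layout$channel_id)

  # left-censored missingness at the run (protein x batch) level: reporter
  # quantification requires the protein to be identified in the plex, so a
  # protein whose total signal in a run falls below the detection limit is
  # missing from every channel of that batch. The spike row is exempt: it
  # is abundant by design and required in every channel.
  sample_cols <- which(layout$fraction != "pooled_control")
  censor_bound <- -Inf
  if (cfg$detection_limit_quantile > 0) {
    batches <- unique(layout$batch)
    totals <- vapply(batches, function(b) {
      cols <- intersect(which(layout$batch == b), sample_cols)
      rowSums(intens[-n_all, cols, drop = FALSE])
    }, numeric(n_all - 1))
    censor_bound <- stats::quantile(totals, cfg$detection_limit_quantile,
                                    names = FALSE)
    for (bi in seq_along(batches)) {
      drop_rows <- which(totals[, bi] < censor_bound)
      if (length(drop_rows) > 0) {
        intens[drop_rows, layout$batch == batches[bi]] <- NA_real_
      }
    }
  }

  proteins <- tibble::tibble(
    protein_id = all_ids,
    protein_ids_full = all_ids,
    gene_name = c(genes, nonmito$genes, rev_rows$genes, con_rows$genes,
                  so_rows$genes, "ag85A"),
    reverse = all_ids %in% rev_rows$ids,
    contaminant = all_ids %in% con_rows$ids,
    site_only = all_ids %in% so_rows$ids
  )

  compartment <- sample(c("matrix", "IMS", "inner membrane",
                          "outer membrane"), n, replace = TRUE,
                        prob = c(0.4, 0.15, 0.3, 0.15))
  complex <- rep(NA_character_, n)
  submodule <- rep(NA_character_, n)
  oxphos <- which(group == "oxidative phosphorylation")
  complex[oxphos] <- sample(paste0("C", c("I", "II", "III", "IV", "V")),
                            length(oxphos), replace = TRUE)
  ci_rows <- oxphos[complex[oxphos] == "CI"]
  submodule[ci_rows] <- sample(c("N", "Q", "ND1", "ND5"), length(ci_rows),
                               replace = TRUE)
  # half the non-mito rows are annotated is_mito = FALSE, half left
  # unannotated, so both drop paths of the mito filter are exercised
  nm_half <- nonmito$ids[seq_len(floor(length(nonmito$ids) / 2))]
  annotation <- dplyr::bind_rows(
    tibble::tibble(protein_id = ids, is_mito = TRUE, process_group = group,
                   compartment = compartment, complex = complex,
                   submodule = submodule),
    tibble::tibble(protein_id = nm_half, is_mito = FALSE,
                   process_group = NA_character_,
                   compartment = NA_character_, complex = NA_character_,
                   submodule = NA_character_)
  )

  experiment <- new_mpq_experiment(intens, proteins, layout,
                                   log = list(n_simulated = n_all))
  truth <- list(
    theta = truth_theta,
    loadings = tibble::tibble(channel_id = layout$channel_id,
                              loading = unname(loading)),
    censor_bound = censor_bound,
    proteins = tibble::tibble(protein_id = ids, aggregation_prone = prone,
                              shift_pp = shift_pp,
                              base_theta = base_theta,
                              abundance = abundance,
                              process_group = group),
    seed = cfg$seed
  )
  structure(list(experiment = experiment, layout = layout,
                 annotation = annotation, truth = truth, config = cfg),
            class = "mpq_simulation")
}

#' Write a simulated experiment as on-disk fixtures
#'
#' Emits the MaxQuant-dialect protein-group table (missing written as 0,
#' per the MaxQuant convention), the sample layout, the mitochondrial
#' annotation and the ground-truth tables, all tab-separated, readable back
#' through the ingest functions.
#'
#' @param sim an `mpq_simulation`.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "mpq_simulation"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      stop("cannot create fixture directory: ", dir, call. = FALSE)
    }
  }
  x <- sim$experiment
  flag <- function(v) ifelse(v, "+", "")
  pg <- tibble::tibble(
    `Majority protein IDs` = x$proteins$protein_ids_full,
    `Gene names` = x$proteins$gene_name,
    Reverse = flag(x$proteins$reverse),
    `Potential contaminant` = flag(x$proteins$contaminant),
    `Only identified by site` = flag(x$proteins$site_only)
  )
  intens <- x$intensities
  intens[is.na(intens)] <- 0
  colnames(intens) <- paste("Reporter intensity corrected",
                            x$layout$channel, x$layout$batch)
  pg <- dplyr::bind_cols(pg, tibble::as_tibble(intens))

  paths <- c(
    protein_groups = file.path(dir, "proteinGroups.txt"),
    layout = file.path(dir, "layout.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth_theta = file.path(dir, "truth_theta.tsv"),
    truth_loadings = file.path(dir, "truth_loadings.tsv"),
    truth_proteins = file.path(dir, "truth_proteins.tsv"),
    meta = file.path(dir, "sim_meta.json")
  )
  readr::write_tsv(pg, paths[["protein_groups"]])
  readr::write_tsv(dplyr::select(sim$layout, -dplyr::any_of("channel_id")),
                   paths[["layout"]])
  readr::write_tsv(sim$annotation, paths[["annotation"]])
  readr::write_tsv(sim$truth$theta, paths[["truth_theta"]])
  readr::write_tsv(sim$truth$loadings, paths[["truth_loadings"]])
  readr::write_tsv(sim$truth$proteins, paths[["truth_proteins"]])
  jsonlite::write_json(list(censor_bound = sim$truth$censor_bound,
                            seed = sim$truth$seed,
                            spike_id = sim$config$spike_id),
                       paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
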