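profiles_from_pct <- function(pct_matrix, line = "WT") {
  # pct_matrix: proteins x samples; one replicate per sample time point
  tps <- (seq_len(ncol(pct_matrix)) - 1) * 12
  dplyr::bind_rows(lapply(seq_len(ncol(pct_matrix)), function(j) {
    tibble::tibble(
      protein_id = rownames(pct_matrix),
      cell_line = line, time_point_h = tps[j],
      phase = if (j == 1) "DMSO" else "treatment",
      replicate = 1L,
      soluble = 100 - pct_matrix[, j], insoluble = pct_matrix[, j],
      total = 100, pct_insoluble = pct_matrix[, j],
      status = "both", comparable = TRUE, imputed = FALSE
    )
  }))
}

test_that("the aggregation index is the unweighted group mean of percent insoluble", {
  m <- matrix(c(20, 40), 2, 1, dimnames = list(c("A", "B"), NULL))
  prof <- profiles_from_pct(m)
  expect_equal(aggregation_index(prof)$ai, 30)
  expect_equal(aggregation_index(prof, proteins = "A")$ai, 20)
})

test_that("group AI equals the membership-weighted mean of part AIs", {
  # brute-force oracle: independently coded mean over 100 random proteins
  set.seed(41)
  pct <- matrix(runif(100, 0, 100), 100, 1,
                dimnames = list(sprintf("P%03d", 1:100), NULL))
  prof <- profiles_from_pct(pct)
  split_at <- sample(30:70, 1)
  part1 <- rownames(pct)[1:split_at]
  part2 <- rownames(pct)[(split_at + 1):100]

  ai_all <- aggregation_index(prof)$ai
  ai1 <- aggregation_index(prof, proteins = part1)$ai
  ai2 <- aggregation_index(prof, proteins = part2)$ai
  weighted <- (length(part1) * ai1 + length(part2) * ai2) / 100
  expect_equal(ai_all, weighted)
  expect_equal(ai_all, sum(pct[, 1]) / 100)  # brute-force mean
})

test_that("grouped AI is order invariant and degenerates to the global AI", {
  set.seed(43)
  pct <- matrix(runif(40, 0, 100), 20, 2,
                dimnames = list(sprintf("P%02d", 1:20), NULL))
  prof <- profiles_from_pct(pct)
  annot <- tibble::tibble(
    protein_id = rownames(pct), is_mito = TRUE,
    process_group = rep(c("translation", "morphology"), each = 10),
    compartment = "matrix",
    complex = NA_character_, submodule = NA_character_
  )
  g <- grouped_aggregation(prof, annot, "process_group")
  g_perm <- grouped_aggregation(prof[sample(nrow(prof)), ], annot,
                                "process_group")
  expect_equal(dplyr::arrange(g, group, time_point_h),
               dplyr::arrange(g_perm, group, time_point_h))

  # all proteins in one compartment: compartment AI equals global AI
  comp <- grouped_aggregation(prof, annot, "compartment")
  glob <- aggregation_index(prof)
  expect_equal(comp$ai, glob$ai)

  expect_error(grouped_aggregation(prof, annot[, -3], "process_group"),
               "process_group")
})

test_that("groups enriched for aggregators show the highest stress AI", {
  cfg <- noiseless_config(n_proteins = 400, seed = 17,
                          sensitive_groups = "translation",
                          group_effect_strength = 1)
  sim <- simulate_experiment(cfg)
  x <- run_stages(sim)
  prof <- quantify_solubility(x)
  wt_peak <- grouped_aggregation(
    dplyr::filter(prof, cell_line == "WT"), x$annotation, "process_group") |>
    summarize_ai() |>
    dplyr::filter(time_point_h == 12)
  # ground truth: mean theta uplift concentrated in the translation group
  uplift <- sim$truth$proteins |>
    dplyr::group_by(process_group) |>
    dplyr::summarise(mean_shift = mean(shift_pp))
  top_truth <- uplift$process_group[which.max(uplift$mean_shift)]
  expect_equal(top_truth, "translation")
  delta <- wt_peak |>
    dplyr::inner_join(
      grouped_aggregation(dplyr::filter(prof, cell_line == "WT"),
                          x$annotation, "process_group") |>
        summarize_ai() |> dplyr::filter(time_point_h == 0) |>
        dplyr::select(group, ai0 = ai),
      by = "group") |>
    dplyr::mutate(rise = ai - ai0)
  expect_equal(delta$group[which.max(delta$rise)], "translation")
  expect_true(all(delta$rise[delta$group == "translation"] >
                    delta$rise[delta$group != "translation"]))
})

test_that("recovery rates follow the closed form", {
  # full recovery within 24 h
  expect_equal(recovery_rate(c(10, 40, 10), c(0, 12, 36), 0, 12, 36), 100)
  # half of the above-baseline aggregation removed over 48 h
  expect_equal(recovery_rate(c(10, 40, 25), c(0, 12, 60), 0, 12, 60), 25)
  # flat series above baseline: nothing removed
  expect_equal(recovery_rate(c(10, 40, 40), c(0, 12, 36), 0, 12, 36), 0)
  # invariant to adding a constant to the whole series
  expect_equal(recovery_rate(c(10, 40, 25) + 7, c(0, 12, 60), 0, 12, 60), 25)
  # no above-baseline aggregation at peak: undefined
  expect_warning(r <- recovery_rate(c(10, 10, 10), c(0, 12, 36), 0, 12, 36),
                 "undefined")
  expect_true(is.na(r))
  expect_error(recovery_rate(c(10, 40, 25), c(0, 12, 60), 0, 12, 12),
               "after peak")
})

test_that("exponential return to baseline reproduces the analytic recovery rate", {
  base <- 12; a0 <- 30; t_peak <- 12
  for (k in c(0.01, 0.05, 0.135)) {
    for (dt in c(24, 48)) {
      ai <- c(base, base + a0,
              base + a0 * exp(-k * dt))
      rate <- recovery_rate(ai, c(0, t_peak, t_peak + dt), 0, t_peak,
                            t_peak + dt)
      expect_equal(rate, 100 * (1 - exp(-k * dt)) * 24 / dt)
    }
  }
})

test_that("window selection uses 24 h when recovery is effectively complete", {
  mk <- function(line, ais) tibble::tibble(cell_line = line,
                                           time_point_h = c(0, 12, 36, 60),
                                           phase = c("DMSO", "treatment",
                                                     "recovery", "recovery"),
                                           ai = ais, n_proteins = 10L)
  fast <- mk("fast", c(10, 40, 10.5, 10))   # recovered at +24 h
  slow <- mk("slow", c(10, 40, 30, 25))
  rates <- recovery_rates(dplyr::bind_rows(fast, slow), 0, 12)
  expect_equal(rates$t_end[rates$cell_line == "fast"], 36)
  expect_equal(rates$t_end[rates$cell_line == "slow"], 60)
  # explicit window overrides the auto rule
  rates48 <- recovery_rates(fast, 0, 12, window = 48)
  expect_equal(rates48$t_end, 60)
})

test_that("the AI matrix is heatmap-ready and renders to file", {
  set.seed(47)
  pct <- matrix(runif(40, 0, 100), 20, 2,
                dimnames = list(sprintf("P%02d", 1:20), NULL))
  prof <- profiles_from_pct(pct)
  annot <- tibble::tibble(
    protein_id = rownames(pct), is_mito = TRUE,
    process_group = rep(c("translation", "morphology", "metabolism",
                          "transcription"), each = 5),
    compartment = "matrix", complex = NA_character_,
    submodule = NA_character_)
  m <- ai_matrix(summarize_ai(grouped_aggregation(prof, annot,
                                                  "process_group")))
  expect_equal(dim(m), c(4L, 2L))
  expect_setequal(rownames(m), unique(annot$process_group))

  skip_if_not_installed("pheatmap")
  f <- withr::local_tempfile(fileext = ".png")
  ai_heatmap(summarize_ai(grouped_aggregation(prof, annot,
                                              "process_group")), file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("AI is invariant to positive per-channel rescaling upstream", {
  cfg <- sim_config(n_proteins = 80, seed = 23,
                    detection_limit_quantile = 0)
  sim <- simulate_experiment(cfg)
  x <- run_stages(sim)          # spike-normalized
  prof_n <- quantify_solubility(x)

  # same data but with raw (loading-biased) intensities rescaled by an
  # arbitrary extra positive per-channel factor before normalization
  x2 <- sim$experiment
  set.seed(99)
  extra <- runif(ncol(x2$intensities), 0.5, 2)
  x2$intensities <- sweep(x2$intensities, 2, extra, `*`)
  x2 <- run_stages(list(experiment = x2, annotation = sim$annotation,
                        config = sim$config))
  prof_r <- quantify_solubility(x2)
  expect_equal(aggregation_index(prof_n)$ai, aggregation_index(prof_r)$ai)
})
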