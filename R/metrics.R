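#' Aggregation index per sample
#'
#' The aggregation index (AI) of a protein group in one sample is the
#' unweighted arithmetic mean of percent insoluble over the group's
#' eligible proteins. To keep AI differences attributable to solubility
#' rather than membership churn, eligibility is complete-case by default:
#' only proteins with a defined (both-fraction) percentage in every sample
#' under comparison enter the mean.
#'
#' @param profiles an `mpq_profiles` tibble from [quantify_solubility()].
#' @param proteins optional character vector restricting the group; default
#'   all proteins present.
#' @param complete_cases require a defined percentage in every sample
#'   (default `TRUE`).
#' @param include_imputed include imputed values in the mean (default
#'   `TRUE`; imputation was performed precisely to allow inclusion).
#' @return Tibble: `cell_line`, `time_point_h`, `phase`, `replicate`, `ai`,
#'   `n_proteins`. AI is `NA` with a warning when no protein is eligible.
#' @export
aggregation_index <- function(profiles, proteins = NULL,
                              complete_cases = TRUE, include_imputed = TRUE) {
  dat <- profiles
  if (!is.null(proteins)) {
    dat <- dplyr::filter(dat, .data$protein_id %in% proteins)
  }
  if (!include_imputed) {
    dat <- dplyr::filter(dat, !.data$imputed)
  }
  n_samples <- nrow(dplyr::distinct(dat, .data$cell_line, .data$time_point_h,
                                    .data$replicate))
  if (complete_cases) {
    eligible <- dat |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::summarise(ok = sum(.data$comparable) == n_samples,
                       .groups = "drop") |>
      dplyr::filter(.data$ok)
    dat <- dplyr::filter(dat, .data$protein_id %in% eligible$protein_id)
  } else {
    dat <- dplyr::filter(dat, .data$comparable)
  }
  out <- dat |>
    dplyr::group_by(.data$cell_line, .data$time_point_h, .data$phase,
                    .data$replicate) |>
    dplyr::summarise(ai = mean(.data$pct_insoluble),
                     n_proteins = dplyr::n(), .groups = "drop")
  if (nrow(out) == 0 || any(out$n_proteins == 0)) {
    warning("no eligible protein in group; AI undefined", call. = FALSE)
  }
  out
}

#' Aggregation indices per annotation group
#'
#' Computes one AI per group x cell line x time point (x replicate) for a
#' chosen annotation grouping: functional `process_group`, sub-mitochondrial
#' `compartment`, respiratory `complex`, or assembly `submodule`.
#' Complete-case eligibility is applied within each group independently.
#'
#' @param profiles an `mpq_profiles` tibble.
#' @param annotation annotation tibble (e.g. `x$annotation` after
#'   [annotate_mito()]).
#' @param grouping one of `"process_group"`, `"compartment"`, `"complex"`,
#'   `"submodule"`.
#' @param ... passed to [aggregation_index()].
#' @return Tibble of class `mpq_ai`: `group`, `cell_line`, `time_point_h`,
#'   `phase`, `replicate`, `ai`, `n_proteins`.
#' @export
grouped_aggregation <- function(profiles, annotation,
                                grouping = c("process_group", "compartment",
                                             "complex", "submodule"), ...) {
  grouping <- match.arg(grouping)
  if (!grouping %in% names(annotation)) {
    stop("grouping field '", grouping, "' absent from annotation",
         call. = FALSE)
  }
  members <- annotation |>
    dplyr::filter(!is.na(.data[[grouping]])) |>
    dplyr::select("protein_id", group = dplyr::all_of(grouping))
  out <- members |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(function(rows, key) {
      ai <- aggregation_index(profiles, proteins = rows$protein_id, ...)
      dplyr::mutate(ai, group = key$group, .before = 1)
    }) |>
    dplyr::bind_rows()
  class(out) <- c("mpq_ai", class(out))
  out
}

#' Replicate-averaged AI series
#'
#' @param ai tibble from [aggregation_index()] or [grouped_aggregation()].
#' @return The same table averaged over replicates.
#' @export
summarize_ai <- function(ai) {
  grp_cols <- intersect(c("group", "cell_line", "time_point_h", "phase"),
                        names(ai))
  ai |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(ai = mean(.data$ai),
                     n_proteins = .data$n_proteins[1], .groups = "drop")
}

#' Heatmap-ready AI matrix
#'
#' @param ai_summary replicate-averaged grouped AI from [summarize_ai()].
#' @return Numeric matrix, groups in rows, `cell_line @ time` in columns.
#' @export
ai_matrix <- function(ai_summary) {
  wide <- ai_summary |>
    dplyr::mutate(sample = paste0(.data$cell_line, "@", .data$time_point_h,
                                  "h")) |>
    dplyr::select("group", "sample", "ai") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "ai")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$group
  m
}

#' Render a clustered AI heatmap
#'
#' Hierarchical clustering with Euclidean distance and average linkage by
#' default; parameters are exposed.
#'
#' @param ai_summary replicate-averaged grouped AI.
#' @param file optional output path (PNG or PDF by extension).
#' @param distance,linkage clustering parameters.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
ai_heatmap <- function(ai_summary, file = NULL, distance = "euclidean",
                       linkage = "average", ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("ai_heatmap requires the pheatmap package", call. = FALSE)
  }
  m <- ai_matrix(ai_summary)
  args <- list(mat = m, clustering_distance_rows = distance,
               clustering_method = linkage, cluster_cols = FALSE,
               silent = !is.null(file), ...)
  if (!is.null(file)) args$filename <- file
  invisible(do.call(pheatmap::pheatmap, args))
}

#' Stress-recovery (resolubilization) rate
#'
#' With `A(t) = max(AI(t) - AI(baseline), 0)` the above-baseline
#' aggregation, the recovery rate over the window from the stress peak to
#' the window end is the percentage of peak above-baseline aggregation
#' removed, normalized to a 24-hour period:
#' `100 * (A(peak) - A(end)) / A(peak) * 24 / (t_end - t_peak)`.
#' Undefined (NA) when there is no above-baseline aggregation at the peak.
#'
#' @param ai numeric AI values (percent).
#' @param time_h numeric time points (hours), parallel to `ai`.
#' @param baseline_tp,peak_tp,end_tp the baseline, peak and window-end time
#'   points (values of `time_h`).
#' @return Rate in percent of peak aggregation removed per 24 h.
#' @export
recovery_rate <- function(ai, time_h, baseline_tp, peak_tp, end_tp) {
  stopifnot(length(ai) == length(time_h))
  look <- function(tp) {
    i <- which(time_h == tp)
    if (length(i) != 1) {
      stop("AI not defined at time point ", tp, " h", call. = FALSE)
    }
    ai[i]
  }
  if (end_tp <= peak_tp) stop("window end must be after peak", call. = FALSE)
  base <- look(baseline_tp)
  a_peak <- max(look(peak_tp) - base, 0)
  a_end <- max(look(end_tp) - base, 0)
  if (a_peak == 0) {
    warning("no above-baseline aggregation at peak; rate undefined",
            call. = FALSE)
    return(NA_real_)
  }
  100 * (a_peak - a_end) / a_peak * 24 / (end_tp - peak_tp)
}

#' Recovery rates per cell line over a time course
#'
#' Window selection mirrors the study design: the first 24-hour window is
#' used when the series has effectively recovered within it (above-baseline
#' aggregation at peak + 24 h at most 5% of the peak value), otherwise the
#' full window to the last time point is used; either window is normalized
#' to per-24-hour units. Explicit windows can be forced per call.
#'
#' @param ai_summary replicate-averaged AI series (from [summarize_ai()])
#'   with one row per cell line x time point.
#' @param baseline_tp,peak_tp baseline and peak time points (hours).
#' @param window `"auto"` (default), or a fixed window length in hours
#'   (e.g. 24 or 48) measured from the peak.
#' @param recovered_frac auto-rule threshold: fraction of peak
#'   above-baseline aggregation remaining at +24 h under which the short
#'   window is chosen (default 0.05).
#' @return Tibble: `cell_line`, `t_peak`, `t_end`, `rate_pct_per_24h`.
#' @export
recovery_rates <- function(ai_summary, baseline_tp, peak_tp,
                           window = "auto", recovered_frac = 0.05) {
  ai_summary |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::group_map(function(rows, key) {
      tps <- rows$time_point_h
      t_end <- if (identical(window, "auto")) {
        t24 <- peak_tp + 24
        t_last <- max(tps)
        base <- rows$ai[tps == baseline_tp]
        a_peak <- max(rows$ai[tps == peak_tp] - base, 0)
        a_24 <- if (t24 %in% tps) max(rows$ai[tps == t24] - base, 0) else NA
        if (!is.na(a_24) && a_peak > 0 && a_24 <= recovered_frac * a_peak)
          t24 else t_last
      } else {
        peak_tp + window
      }
      tibble::tibble(
        cell_line = key$cell_line, t_peak = peak_tp, t_end = t_end,
        rate_pct_per_24h = recovery_rate(rows$ai, tps, baseline_tp, peak_tp,
                                         t_end)
      )
    }) |>
    dplyr::bind_rows()
}
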