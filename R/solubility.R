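#' Percent insoluble from paired fraction intensities
#'
#' The derived total of a protein in a sample is the sum of its normalized
#' soluble and insoluble fraction intensities; percent insoluble is
#' `100 * insoluble / (soluble + insoluble)`. Vectorized; returns `NA`
#' where either fraction is missing.
#'
#' @param soluble,insoluble non-negative normalized intensities (`NA` for
#'   not detected).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
percent_insoluble <- function(soluble, insoluble) {
  if (any(soluble < 0, na.rm = TRUE) || any(insoluble < 0, na.rm = TRUE)) {
    stop("negative intensity", call. = FALSE)
  }
  100 * insoluble / (soluble + insoluble)
}

#' Per-sample solubility profiles
#'
#' Pairs each sample's soluble and insoluble channels and computes, per
#' protein and sample, the derived total, percent insoluble and a detection
#' status: `both` (both fractions detected; percent defined and
#' comparable), `soluble_only` / `insoluble_only` (recorded as 0 / 100 but
#' flagged non-comparable — solubility shifts are not calculated for
#' proteins detected in only one fraction), or `absent`.
#'
#' @param x a normalized (and, where applicable, imputed) `mpq_experiment`.
#' @return Long tibble of class `mpq_profiles`: `protein_id`, `cell_line`,
#'   `time_point_h`, `phase`, `replicate`, `soluble`, `insoluble`, `total`,
#'   `pct_insoluble`, `status`, `comparable`, `imputed`.
#' @export
quantify_solubility <- function(x) {
  stopifnot(inherits(x, "mpq_experiment"))
  lay <- dplyr::filter(x$layout, .data$fraction %in% c("soluble", "insoluble"))
  pairs <- lay |>
    dplyr::select("cell_line", "time_point_h", "phase", "replicate",
                  "fraction", "channel_id") |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "channel_id")
  if (!all(c("soluble", "insoluble") %in% names(pairs))) {
    stop("layout lacks soluble/insoluble channel pairs", call. = FALSE)
  }
  n_p <- nrow(x$intensities)
  imput <- x$imputed
  res <- purrr::pmap(pairs, function(cell_line, time_point_h, phase,
                                     replicate, soluble, insoluble) {
    sol <- if (!is.na(soluble)) unname(x$intensities[, soluble]) else
      rep(NA_real_, n_p)
    ins <- if (!is.na(insoluble)) unname(x$intensities[, insoluble]) else
      rep(NA_real_, n_p)
    imp <- rep(FALSE, n_p)
    if (!is.null(imput)) {
      if (!is.na(soluble)) imp <- imp | imput[, soluble]
      if (!is.na(insoluble)) imp <- imp | imput[, insoluble]
    }
    status <- dplyr::case_when(
      !is.na(sol) & !is.na(ins) ~ "both",
      !is.na(sol) ~ "soluble_only",
      !is.na(ins) ~ "insoluble_only",
      TRUE ~ "absent"
    )
    pct <- percent_insoluble(sol, ins)
    pct[status == "soluble_only"] <- 0
    pct[status == "insoluble_only"] <- 100
    pct[status == "absent"] <- NA_real_
    tibble::tibble(
      protein_id = x$proteins$protein_id,
      cell_line = cell_line, time_point_h = time_point_h, phase = phase,
      replicate = replicate,
      soluble = sol, insoluble = ins,
      total = ifelse(status == "both", sol + ins, NA_real_),
      pct_insoluble = pct,
      status = status,
      comparable = status == "both",
      imputed = imp
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("mpq_profiles", class(out))
  out
}

#' Replicate-averaged percent insoluble per condition
#'
#' Percent insoluble is computed per replicate and then averaged across the
#' replicates of a condition (cell line x time point); only replicates in
#' which the protein was detected in both fractions contribute.
#' Alternatively (`method = "sum_intensity"`) replicate intensities are
#' summed per fraction before the percentage is taken.
#'
#' @param profiles an `mpq_profiles` tibble from [quantify_solubility()].
#' @param method `"mean_pct"` (default) or `"sum_intensity"`.
#' @param min_replicates minimum number of comparable replicates for the
#'   condition mean to be defined (default 1).
#' @return Tibble: `protein_id`, `cell_line`, `time_point_h`, `phase`,
#'   `pct_insoluble`, `n_replicates`, `any_imputed`.
#' @export
condition_means <- function(profiles, method = c("mean_pct", "sum_intensity"),
                            min_replicates = 1) {
  method <- match.arg(method)
  grp <- profiles |>
    dplyr::filter(.data$comparable) |>
    dplyr::group_by(.data$protein_id, .data$cell_line, .data$time_point_h,
                    .data$phase)
  out <- if (method == "mean_pct") {
    dplyr::summarise(grp,
                     pct_insoluble = mean(.data$pct_insoluble),
                     n_replicates = dplyr::n(),
                     any_imputed = any(.data$imputed), .groups = "drop")
  } else {
    dplyr::summarise(grp,
                     pct_insoluble = percent_insoluble(sum(.data$soluble),
                                                       sum(.data$insoluble)),
                     n_replicates = dplyr::n(),
                     any_imputed = any(.data$imputed), .groups = "drop")
  }
  dplyr::filter(out, .data$n_replicates >= min_replicates)
}

#' Solubility shifts between two conditions
#'
#' For each protein quantified (in both fractions) in both conditions, the
#' shift is the difference of replicate-averaged percent-insoluble values,
#' in percentage points (treated minus control). Proteins without a defined
#' percentage in either condition get an undefined shift.
#'
#' @param means condition means from [condition_means()].
#' @param treated,control named lists (or one-row tibbles) selecting the
#'   two conditions, e.g. `list(cell_line = "WT", time_point_h = 12)`.
#' @param thresholds length-2 numeric: the aggregating and highly
#'   aggregating percentage-point thresholds (default `c(25, 50)`).
#' @return Tibble of class `mpq_shifts`: `protein_id`, `pct_treated`,
#'   `pct_control`, `delta_pp`, `class`.
#' @export
solubility_shifts <- function(means, treated, control,
                              thresholds = c(25, 50)) {
  pick <- function(sel) {
    out <- means
    for (nm in names(sel)) {
      out <- out[out[[nm]] == sel[[nm]], , drop = FALSE]
    }
    out
  }
  t_tab <- pick(treated)
  c_tab <- pick(control)
  joined <- dplyr::full_join(
    dplyr::select(t_tab, "protein_id", pct_treated = "pct_insoluble"),
    dplyr::select(c_tab, "protein_id", pct_control = "pct_insoluble"),
    by = "protein_id"
  )
  out <- joined |>
    dplyr::mutate(
      delta_pp = .data$pct_treated - .data$pct_control,
      class = classify_shift(.data$delta_pp, thresholds = thresholds)
    )
  class(out) <- c("mpq_shifts", class(out))
  out
}

#' Classify a solubility shift
#'
#' Percentage-point shifts of the insoluble share are binned with strict
#' inequalities: above the high threshold (default 50 pp) the protein is
#' `highly_aggregating`, above the low threshold (default 25 pp)
#' `aggregating`, below minus the low threshold `resolubilizing`, otherwise
#' `stable`. Undefined shifts map to `undefined`. The classes partition the
#' real line and are monotone in the shift.
#'
#' @param delta_pp numeric vector of shifts in percentage points (`NA` for
#'   undefined).
#' @param thresholds length-2 ascending numeric, `c(aggregating, highly)`.
#' @return Character vector of class labels.
#' @export
classify_shift <- function(delta_pp, thresholds = c(25, 50)) {
  stopifnot(length(thresholds) == 2, thresholds[1] > 0,
            thresholds[1] < thresholds[2])
  dplyr::case_when(
    is.na(delta_pp) ~ "undefined",
    delta_pp > thresholds[2] ~ "highly_aggregating",
    delta_pp > thresholds[1] ~ "aggregating",
    delta_pp < -thresholds[1] ~ "resolubilizing",
    TRUE ~ "stable"
  )
}
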