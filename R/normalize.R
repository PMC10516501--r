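#' Compute per-channel scaling factors from the spike-in protein
#'
#' The spike-in (Ag85A) is added to every fraction in fixed proportion to
#' starting material, so its reporter intensity measures each channel's
#' effective loading. Within each batch the spike intensities are averaged
#' over the batch's channels to give a reference mean, and every channel's
#' factor is `reference_mean / spike_c`. After applying the factors the
#' spike-in has identical intensity in every channel of a batch, making
#' soluble and insoluble channels directly comparable.
#'
#' @param x an `mpq_experiment` containing the spike-in row.
#' @param spike_id accession of the spike-in protein.
#' @param per_fraction average the spike over fraction-matched channels only
#'   instead of all channels of a batch (default `FALSE`: all channels of a
#'   batch share one reference mean).
#' @return A tibble of class `mpq_factors` with columns `batch`,
#'   `channel_id`, `spike_intensity`, `reference_mean`, `factor`.
#' @export
compute_spikein_factors <- function(x, spike_id, per_fraction = FALSE) {
  stopifnot(inherits(x, "mpq_experiment"))
  if (!spike_id %in% x$proteins$protein_id) {
    stop("spike-in protein ", spike_id, " not present in the table",
         call. = FALSE)
  }
  spike <- x$intensities[match(spike_id, x$proteins$protein_id), ]
  bad <- is.na(spike) | spike <= 0
  if (any(bad)) {
    stop("spike-in missing or zero in channel(s): ",
         paste(names(spike)[bad], collapse = ", "),
         "; normalization is undefined without the spike-in", call. = FALSE)
  }
  fac <- x$layout |>
    dplyr::select("batch", "channel_id", dplyr::all_of("fraction")) |>
    dplyr::mutate(spike_intensity = unname(spike[.data$channel_id]))
  grp <- if (per_fraction) c("batch", "fraction") else "batch"
  fac <- fac |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(reference_mean = mean(.data$spike_intensity),
                  factor = .data$reference_mean / .data$spike_intensity) |>
    dplyr::ungroup() |>
    dplyr::select("batch", "channel_id", "spike_intensity",
                  "reference_mean", "factor")
  class(fac) <- c("mpq_factors", class(fac))
  fac
}

#' Apply per-channel scaling factors
#'
#' Multiplies every intensity in channel `c` by `factor_c`. Missing values
#' stay missing; within-channel ratios between proteins are unchanged
#' (scaling is a positive per-channel rescaling).
#'
#' @param x an `mpq_experiment`.
#' @param factors an `mpq_factors` tibble from [compute_spikein_factors()].
#' @return The rescaled experiment.
#' @export
apply_factors <- function(x, factors) {
  stopifnot(inherits(x, "mpq_experiment"))
  ch <- colnames(x$intensities)
  i <- match(ch, factors$channel_id)
  if (anyNA(i)) {
    stop("no scaling factor for channel(s): ",
         paste(ch[is.na(i)], collapse = ", "), call. = FALSE)
  }
  f <- factors$factor[i]
  if (any(!is.finite(f) | f <= 0)) {
    stop("scaling factors must be positive and finite", call. = FALSE)
  }
  x$intensities <- sweep(x$intensities, 2, f, `*`)
  log_count(x, normalized = ncol(x$intensities))
}

#' Normalize an experiment to its spike-in
#'
#' Convenience wrapper: compute spike-in factors and apply them.
#'
#' @inheritParams compute_spikein_factors
#' @return The normalized experiment with the factor table stored in
#'   `x$factors` for audit.
#' @export
normalize_to_spikein <- function(x, spike_id, per_fraction = FALSE) {
  factors <- compute_spikein_factors(x, spike_id, per_fraction = per_fraction)
  x <- apply_factors(x, factors)
  x$factors <- factors
  x
}
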