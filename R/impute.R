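#' Imputation parameters for left-censored (QRILC-style) imputation
#'
#' Missing reporter intensities in this kind of data are dominated by
#' left-censoring: low-abundance signals falling below the detection limit.
#' QRILC estimates the underlying Gaussian of the log2 intensities of a
#' channel by quantile regression against standard-normal quantile
#' positions, assuming the missing values occupy the lowest ranks, then
#' draws each missing value from that Gaussian truncated above at the
#' channel's minimum observed value.
#'
#' @param tune_sigma positive multiplier on the estimated spread used for
#'   the draws (default 1).
#' @param fit_quantile_range length-2 interval in (0, 1]: the fraction of
#'   observed ranks used in the regression fit. The default `c(0.25, 1)`
#'   uses the upper 75% of observed ranks, where the observed quantiles are
#'   least distorted by censoring.
#' @param seed RNG seed for the draws, or `NULL` to use the session RNG
#'   state.
#' @param log_base base of the log transform (default 2).
#' @return A list of class `mpq_impute_params`.
#' @export
imputation_params <- function(tune_sigma = 1, fit_quantile_range = c(0.25, 1),
                              seed = NULL, log_base = 2) {
  stopifnot(is.numeric(tune_sigma), tune_sigma > 0,
            length(fit_quantile_range) == 2,
            fit_quantile_range[1] >= 0, fit_quantile_range[2] <= 1,
            fit_quantile_range[1] < fit_quantile_range[2],
            log_base > 1)
  structure(list(tune_sigma = tune_sigma,
                 fit_quantile_range = fit_quantile_range,
                 seed = seed, log_base = log_base),
            class = "mpq_impute_params")
}

#' Fit the censored-Gaussian model of one channel
#'
#' Sorted observed log intensities are regressed on standard-normal
#' quantile positions assigned under the assumption that missing values
#' occupy the lowest ranks; the intercept estimates the mean and the slope
#' the standard deviation of the uncensored distribution.
#'
#' @param values numeric vector of log-scale intensities, `NA` for missing.
#' @param params an `mpq_impute_params`.
#' @return List with `mu`, `sigma`, `bound` (minimum observed value),
#'   `n_obs`, `n_missing`.
#' @export
qrilc_fit <- function(values, params = imputation_params()) {
  obs <- values[!is.na(values)]
  n_obs <- length(obs)
  n_missing <- sum(is.na(values))
  if (n_obs < 10) {
    stop("fewer than 10 observed values; censored-Gaussian estimate is ",
         "unstable", call. = FALSE)
  }
  n <- length(values)
  y <- sort(obs)
  # global rank of the i-th smallest observed value, missing at the bottom
  rank_global <- n_missing + seq_len(n_obs)
  q <- stats::qnorm((rank_global - 0.5) / n)
  frac <- (seq_len(n_obs) - 0.5) / n_obs
  use <- frac >= params$fit_quantile_range[1] &
    frac <= params$fit_quantile_range[2]
  fit <- stats::lm.fit(cbind(1, q[use]), y[use])
  mu <- unname(fit$coefficients[1])
  sigma <- unname(fit$coefficients[2])
  if (!is.finite(sigma) || sigma <= 0) {
    stop("estimated spread is not positive; channel distribution is ",
         "degenerate", call. = FALSE)
  }
  list(mu = mu, sigma = sigma, bound = min(obs),
       n_obs = n_obs, n_missing = n_missing)
}

# draw n values from Normal(mu, sd^2) truncated above at `bound`
rtruncnorm_upper <- function(n, mu, sd, bound) {
  p_bound <- stats::pnorm(bound, mean = mu, sd = sd)
  u <- stats::runif(n) * p_bound
  stats::qnorm(pmin(pmax(u, 1e-300), 1 - 1e-16), mean = mu, sd = sd)
}

#' Impute missing values of one channel (QRILC)
#'
#' Completes a channel's log-scale intensity vector: the censored-Gaussian
#' model is fitted with [qrilc_fit()] and every missing entry is drawn from
#' `Normal(mu, (tune_sigma * sigma)^2)` truncated above at the channel's
#' minimum observed value. Observed values are never modified, and imputed
#' values never exceed the observed minimum.
#'
#' @param values numeric vector of log-scale intensities with `NA` for
#'   missing entries.
#' @param params an `mpq_impute_params`; `params$seed`, when non-`NULL`,
#'   makes the draws reproducible without disturbing the session RNG.
#' @return The completed vector, with attribute `imputed` (logical vector)
#'   and attribute `fit` (the [qrilc_fit()] estimate).
#' @export
qrilc_impute <- function(values, params = imputation_params()) {
  miss <- is.na(values)
  if (!any(miss)) return(values)
  est <- qrilc_fit(values, params)
  draws <- with_local_seed(params$seed, {
    rtruncnorm_upper(sum(miss), est$mu, params$tune_sigma * est$sigma,
                     est$bound)
  })
  values[miss] <- draws
  attr(values, "imputed") <- miss
  attr(values, "fit") <- est
  values
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Select batch-level imputation targets
#'
#' Mirrors the pipeline's eligibility rule: a (protein, batch, fraction)
#' cell qualifies for imputation when the protein is detected in that
#' fraction group in at least one batch but entirely missing in exactly one
#' other batch of the group (strict reading). Proteins absent in two or
#' more batches of a fraction group are not eligible under the strict rule
#' and are reported in the `ineligible` attribute; `mode = "at_least_one"`
#' relaxes the rule to any number of fully-missing batches.
#'
#' @param x an `mpq_experiment` with a multi-batch layout.
#' @param mode `"strict"` (exactly one missing batch, default) or
#'   `"at_least_one"`.
#' @return Tibble with columns `protein_id`, `batch`, `fraction`; attribute
#'   `ineligible` lists (protein, fraction) groups excluded by the strict
#'   rule.
#' @export
select_imputation_targets <- function(x, mode = c("strict", "at_least_one")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "mpq_experiment"))
  batches <- unique(x$layout$batch)
  out <- list()
  inel <- list()
  if (length(batches) >= 2) {
    for (fr in intersect(c("soluble", "insoluble"), x$layout$fraction)) {
      fr_batches <- unique(x$layout$batch[x$layout$fraction == fr])
      if (length(fr_batches) < 2) next
      # proteins x batches: is the protein detected anywhere in that batch's
      # channels of this fraction?
      det <- vapply(fr_batches, function(b) {
        ch <- batch_channels(x$layout, b, fr)
        rowSums(!is.na(x$intensities[, ch, drop = FALSE])) > 0
      }, logical(nrow(x$intensities)))
      det <- matrix(det, nrow = nrow(x$intensities),
                    dimnames = list(x$proteins$protein_id, fr_batches))
      n_missing_batches <- rowSums(!det)
      detected_somewhere <- rowSums(det) > 0
      eligible <- detected_somewhere &
        if (mode == "strict") n_missing_batches == 1 else n_missing_batches >= 1
      strict_excluded <- detected_somewhere & n_missing_batches >= 2 &
        mode == "strict"
      if (any(eligible)) {
        idx <- which(!det[eligible, , drop = FALSE], arr.ind = TRUE)
        out[[fr]] <- tibble::tibble(
          protein_id = rownames(det)[which(eligible)][idx[, 1]],
          batch = fr_batches[idx[, 2]],
          fraction = fr
        )
      }
      if (any(strict_excluded)) {
        inel[[fr]] <- tibble::tibble(
          protein_id = x$proteins$protein_id[strict_excluded],
          fraction = fr,
          n_missing_batches = unname(n_missing_batches[strict_excluded])
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(protein_id = character(), batch = character(),
                          fraction = character())
  }
  attr(res, "ineligible") <- dplyr::bind_rows(inel)
  res
}

#' Impute selected missing cells of an experiment
#'
#' Applies QRILC channel by channel, but only adopts draws for the missing
#' cells selected by the eligibility rule; all other missingness is
#' propagated unchanged (imputing everywhere would change the denominators
#' of downstream solubility summaries). Intensities are imputed on the log
#' scale and exponentiated back.
#'
#' @param x an `mpq_experiment` (normalized).
#' @param targets target cells from [select_imputation_targets()]; computed
#'   with the strict rule when omitted.
#' @param params an `mpq_impute_params`. Per-channel seeds are derived from
#'   `params$seed` so the result is reproducible yet channels are not
#'   identically seeded.
#' @return The experiment with imputed intensities and a logical `imputed`
#'   matrix marking filled cells.
#' @export
impute_missing <- function(x, targets = NULL, params = imputation_params()) {
  stopifnot(inherits(x, "mpq_experiment"))
  if (is.null(targets)) targets <- select_imputation_targets(x)
  imputed <- matrix(FALSE, nrow(x$intensities), ncol(x$intensities),
                    dimnames = dimnames(x$intensities))
  if (nrow(targets) > 0) {
    target_channels <- x$layout |>
      dplyr::inner_join(targets, by = c("batch", "fraction"),
                        relationship = "many-to-many")
    by_channel <- split(target_channels$protein_id, target_channels$channel_id)
    for (k in seq_along(by_channel)) {
      ch <- names(by_channel)[k]
      rows <- match(by_channel[[k]], x$proteins$protein_id)
      col <- x$intensities[, ch]
      fill <- rows[is.na(col[rows])]
      if (length(fill) == 0) next
      logv <- log(col, base = params$log_base)
      est <- qrilc_fit(logv, params)
      seed_k <- if (is.null(params$seed)) NULL else
        (params$seed + match(ch, colnames(x$intensities))) %% .Machine$integer.max
      draws <- with_local_seed(seed_k, {
        rtruncnorm_upper(length(fill), est$mu,
                         params$tune_sigma * est$sigma, est$bound)
      })
      x$intensities[fill, ch] <- params$log_base^draws
      imputed[fill, ch] <- TRUE
    }
  }
  x$imputed <- imputed
  log_count(x, n_cells_imputed = sum(imputed))
}
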