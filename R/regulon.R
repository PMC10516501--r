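#' Transcription-factor dependency classification of a stress regulon
#'
#' Partitions a differential-expression gene set into transcription-factor
#' dependent and independent classes. A gene belongs to the stress regulon
#' (`uprmt_member`) when its WT stress-versus-vehicle contrast is
#' significant (FDR at or below `fdr`) with a log2 fold change exceeding
#' `lfc` in magnitude. Among members, a gene depends on factor F when its
#' expression is significantly *decreased* (same FDR bound, log2FC below
#' `-lfc`) in the F-knockout stress contrast relative to WT stress; the
#' dependency set collects such single-knockout factors. Genes decreased in
#' no knockout contrast are transcription-factor independent. A gene
#' decreased only in the triple-knockout contrast is reported as its own
#' `TKO_only` category; the TKO contrast otherwise annotates redundancy.
#'
#' @param records tibble with columns `gene_id`, `contrast`, `log2fc`,
#'   `fdr`. Contrast labels come from a controlled vocabulary: `"WT"` (WT
#'   stress vs WT vehicle) and knockout contrasts `"CHOP"`, `"ATF4"`,
#'   `"ATF5"`, `"TKO"` (each KO stress vs WT stress).
#' @param fdr FDR threshold (default 0.05).
#' @param lfc log2 fold-change magnitude threshold (default 0.2); the
#'   knockout decrease criterion is one-sided at `-lfc`.
#' @return Tibble of class `mpq_dependency`: `gene_id`, `uprmt_member`,
#'   `direction` (`up`/`down` for members), `dependency_set`
#'   (comma-separated factor labels), `category`, `tko_decreased`.
#' @export
classify_dependency <- function(records, fdr = 0.05, lfc = 0.2) {
  stopifnot(all(c("gene_id", "contrast", "log2fc", "fdr") %in%
                  names(records)))
  known <- c("WT", "CHOP", "ATF4", "ATF5", "TKO")
  bad <- setdiff(unique(records$contrast), known)
  if (length(bad) > 0) {
    stop("unknown contrast label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"WT" %in% records$contrast) {
    stop("WT stress contrast is required", call. = FALSE)
  }
  if (!any(records$contrast %in% c("CHOP", "ATF4", "ATF5", "TKO"))) {
    stop("at least one knockout contrast is required", call. = FALSE)
  }
  if (any(records$fdr < 0 | records$fdr > 1, na.rm = TRUE)) {
    stop("FDR values must lie in [0, 1]", call. = FALSE)
  }

  wide <- records |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "contrast",
                       values_from = c("log2fc", "fdr"))
  get_col <- function(nm) {
    if (nm %in% names(wide)) wide[[nm]] else rep(NA_real_, nrow(wide))
  }
  member <- !is.na(wide$fdr_WT) & wide$fdr_WT <= fdr &
    abs(wide$log2fc_WT) > lfc
  decreased_in <- function(ko) {
    lf <- get_col(paste0("log2fc_", ko))
    fd <- get_col(paste0("fdr_", ko))
    !is.na(fd) & fd <= fdr & !is.na(lf) & lf < -lfc
  }
  singles <- c("CHOP", "ATF4", "ATF5")
  dec <- vapply(singles, decreased_in, logical(nrow(wide)))
  dec <- matrix(dec, nrow = nrow(wide), dimnames = list(NULL, singles))
  tko_dec <- decreased_in("TKO")

  dep_set <- apply(dec, 1, function(r) paste(singles[r], collapse = ","))
  n_dep <- rowSums(dec)
  category <- dplyr::case_when(
    !member ~ NA_character_,
    n_dep == 0 & tko_dec ~ "TKO_only",
    n_dep == 0 ~ "independent",
    n_dep == 1 ~ paste0("single:", dep_set),
    n_dep == 2 ~ paste0("pair:", dep_set),
    n_dep == 3 ~ "triple:CHOP,ATF4,ATF5"
  )
  out <- tibble::tibble(
    gene_id = wide$gene_id,
    uprmt_member = member,
    direction = dplyr::if_else(member,
                               dplyr::if_else(wide$log2fc_WT > 0, "up",
                                              "down"),
                               NA_character_),
    dependency_set = dplyr::if_else(member, dep_set, NA_character_),
    category = category,
    tko_decreased = tko_dec
  )
  class(out) <- c("mpq_dependency", class(out))
  out
}

#' Composition of a dependency classification
#'
#' Counts and percentages per category over the regulon members, plus
#' dependent/independent totals. A member is transcription-factor
#' dependent when it is decreased in at least one knockout contrast
#' (including the triple knockout). Percentages are reported to integer
#' precision; category counts sum exactly to the member count.
#'
#' @param table an `mpq_dependency` tibble from [classify_dependency()].
#' @return List with `n_members`, `n_dependent`, `n_independent`,
#'   `pct_dependent`, `pct_independent`, and a `categories` tibble
#'   (`category`, `n`, `pct_of_dependent`).
#' @export
dependency_composition <- function(table) {
  members <- dplyr::filter(table, .data$uprmt_member)
  n_members <- nrow(members)
  if (n_members == 0) {
    return(list(n_members = 0L, n_dependent = 0L, n_independent = 0L,
                pct_dependent = 0, pct_independent = 0,
                categories = tibble::tibble(category = character(),
                                            n = integer(),
                                            pct_of_dependent = numeric())))
  }
  dependent <- members$category != "independent"
  n_dep <- sum(dependent)
  cats <- members |>
    dplyr::filter(dependent) |>
    dplyr::count(.data$category) |>
    dplyr::mutate(pct_of_dependent = round(100 * .data$n / n_dep))
  list(
    n_members = n_members,
    n_dependent = n_dep,
    n_independent = n_members - n_dep,
    pct_dependent = round(100 * n_dep / n_members),
    pct_independent = round(100 * (n_members - n_dep) / n_members),
    categories = cats
  )
}
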