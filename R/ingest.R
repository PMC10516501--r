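#' Read a sample layout table
#'
#' The layout maps every reporter channel to its biological sample: cell
#' line, time point (hours plus phase), fraction (soluble / insoluble /
#' pooled_control) and replicate. Soluble and insoluble channels carrying the
#' same (cell_line, time_point_h, replicate) key are the paired fractions of
#' one sample.
#'
#' @param path TSV file with columns `channel`, `batch`, `cell_line`,
#'   `time_point_h`, `phase`, `fraction`, `replicate`. A YAML file with a
#'   top-level `channels:` list of records with the same fields is also
#'   accepted.
#' @return A validated layout tibble with an additional `channel_id` column
#'   (`<batch>.<channel>`), unique across the experiment.
#' @export
read_layout <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    recs <- yaml::read_yaml(path)$channels
    layout <- dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  } else {
    layout <- readr::read_tsv(path, show_col_types = FALSE)
  }
  validate_layout(layout)
}

#' Validate (and key) a sample layout
#'
#' @param layout tibble with the columns described in [read_layout()].
#' @return The layout with a `channel_id` key column, after invariant checks.
#' @export
validate_layout <- function(layout) {
  required <- c("channel", "batch", "cell_line", "time_point_h", "phase",
                "fraction", "replicate")
  miss <- setdiff(required, names(layout))
  if (length(miss) > 0) {
    stop("layout is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_frac <- setdiff(unique(layout$fraction),
                      c("soluble", "insoluble", "pooled_control"))
  if (length(bad_frac) > 0) {
    stop("unknown fraction label(s): ", paste(bad_frac, collapse = ", "),
         call. = FALSE)
  }
  layout <- dplyr::mutate(
    layout,
    channel_id = paste(.data$batch, .data$channel, sep = "."),
    time_point_h = as.numeric(.data$time_point_h),
    replicate = as.integer(.data$replicate)
  )
  if (anyDuplicated(layout$channel_id) > 0) {
    stop("duplicate channel within a batch", call. = FALSE)
  }
  dup <- layout |>
    dplyr::filter(.data$fraction %in% c("soluble", "insoluble")) |>
    dplyr::count(.data$cell_line, .data$time_point_h, .data$replicate,
                 .data$fraction) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("a (cell_line, time_point, replicate) sample has more than one ",
         "channel for the same fraction", call. = FALSE)
  }
  layout
}

#' Read a mitochondrial annotation table
#'
#' A curated protein-level annotation assigning each protein a mitochondrial
#' membership flag, a functional process group, a sub-mitochondrial
#' compartment, and optional respiratory-complex / assembly-sub-module
#' membership (complex I sub-modules N, Q, ND1, ND5 and so on).
#'
#' @param path TSV with columns `protein_id`, `is_mito`, `process_group`,
#'   `compartment`, `complex`, `submodule`.
#' @return A validated annotation tibble.
#' @export
read_mito_annotation <- function(path) {
  annot <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             protein_id = readr::col_character(),
                             is_mito = readr::col_logical(),
                             .default = readr::col_character()
                           ))
  validate_annotation(annot)
}

validate_annotation <- function(annot) {
  required <- c("protein_id", "is_mito", "process_group", "compartment",
                "complex", "submodule")
  miss <- setdiff(required, names(annot))
  if (length(miss) > 0) {
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(annot$protein_id) > 0) {
    stop("duplicate protein_id in annotation", call. = FALSE)
  }
  orphan <- !is.na(annot$submodule) & is.na(annot$complex)
  if (any(orphan)) {
    stop("submodule set without complex for: ",
         paste(annot$protein_id[orphan], collapse = ", "), call. = FALSE)
  }
  annot
}

# MaxQuant flag convention: any non-empty, non-NA value marks the row.
mq_flag <- function(x) {
  if (is.null(x)) return(logical(0))
  !is.na(x) & trimws(as.character(x)) != ""
}

#' Read a MaxQuant-dialect protein-group table
#'
#' Parses a `proteinGroups.txt`-style tab-separated table into the internal
#' experiment container. Reporter-ion intensity columns are located from the
#' layout as `Reporter intensity corrected <channel> <batch>`. Intensities of
#' exactly zero are MaxQuant's encoding for "not quantified" and are
#' converted to missing.
#'
#' @param path path to the tab-separated protein-group table.
#' @param layout layout tibble from [read_layout()].
#' @return An `mpq_experiment`. The protein key is the first accession of the
#'   `Majority protein IDs` column; the full ID string is kept as metadata.
#' @export
read_protein_groups <- function(path, layout) {
  layout <- validate_layout(dplyr::select(layout, -dplyr::any_of("channel_id")))
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE)
  required <- c("Majority protein IDs", "Gene names", "Reverse",
                "Potential contaminant", "Only identified by site")
  for (col in required) {
    if (!col %in% names(tab)) {
      stop("protein-group table lacks required column: ", col, call. = FALSE)
    }
  }
  reporter_cols <- paste("Reporter intensity corrected",
                         layout$channel, layout$batch)
  absent <- !reporter_cols %in% names(tab)
  if (any(absent)) {
    stop("layout channel(s) absent from protein-group table: ",
         paste(layout$channel_id[absent], collapse = ", "), call. = FALSE)
  }

  ids_full <- as.character(tab$`Majority protein IDs`)
  protein_id <- vapply(strsplit(ids_full, ";", fixed = TRUE),
                       function(p) p[[1]], character(1))
  if (anyDuplicated(protein_id) > 0) {
    stop("duplicate protein_id after taking the leading accession: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "),
         call. = FALSE)
  }
  proteins <- tibble::tibble(
    protein_id = protein_id,
    protein_ids_full = ids_full,
    gene_name = as.character(tab$`Gene names`),
    reverse = mq_flag(tab$Reverse),
    contaminant = mq_flag(tab$`Potential contaminant`),
    site_only = mq_flag(tab$`Only identified by site`)
  )

  if (nrow(tab) == 0) {
    intens <- matrix(numeric(0), nrow = 0, ncol = nrow(layout),
                     dimnames = list(character(0), layout$channel_id))
    proteins <- proteins[0, ]
  } else {
    intens <- as.matrix(tab[, reporter_cols, drop = FALSE])
    colnames(intens) <- layout$channel_id
    rownames(intens) <- protein_id
    storage.mode(intens) <- "double"
    if (any(intens < 0, na.rm = TRUE)) {
      stop("negative reporter intensity encountered", call. = FALSE)
    }
    intens[!is.na(intens) & intens == 0] <- NA_real_
  }
  new_mpq_experiment(intens, proteins, layout,
                     log = list(n_read = nrow(proteins)))
}

#' Remove reverse-decoy, contaminant and site-only identifications
#'
#' Drops every protein group carrying any of the three MaxQuant quality
#' flags ("Reverse", "Potential contaminant", "Only identified by site").
#' The operation is idempotent; removal counts are recorded in the
#' experiment log.
#'
#' @param x an `mpq_experiment`.
#' @return The filtered experiment.
#' @export
apply_quality_filters <- function(x) {
  stopifnot(inherits(x, "mpq_experiment"))
  flagged <- x$proteins$reverse | x$proteins$contaminant | x$proteins$site_only
  n_in <- nrow(x$proteins)
  x$intensities <- x$intensities[!flagged, , drop = FALSE]
  x$proteins <- x$proteins[!flagged, , drop = FALSE]
  if (!is.null(x$imputed)) x$imputed <- x$imputed[!flagged, , drop = FALSE]
  log_count(x,
            n_before_quality_filter = n_in,
            n_flagged_removed = sum(flagged),
            n_after_quality_filter = n_in - sum(flagged))
}

#' Restrict an experiment to annotated mitochondrial proteins
#'
#' Keeps only proteins annotated as mitochondrial and attaches their process
#' group, sub-compartment and complex/sub-module labels. The spike-in protein
#' is by construction not mitochondrial: it is removed from the annotated
#' table but retained separately (in `x$spike`) so normalization factors
#' remain auditable. Unmatched proteins are dropped and counted in the log.
#'
#' @param x a quality-filtered `mpq_experiment`.
#' @param annot annotation tibble from [read_mito_annotation()].
#' @param spike_id accession of the spike-in protein, or `NULL`.
#' @return The experiment restricted to mitochondrial proteins, with
#'   `annotation` attached row-parallel to the intensity matrix.
#' @export
annotate_mito <- function(x, annot, spike_id = NULL) {
  stopifnot(inherits(x, "mpq_experiment"))
  annot <- validate_annotation(annot)
  if (nrow(annot) == 0) stop("empty annotation table", call. = FALSE)
  n_in <- nrow(x$proteins)

  if (!is.null(spike_id) && spike_id %in% x$proteins$protein_id) {
    i <- match(spike_id, x$proteins$protein_id)
    x$spike <- list(protein = x$proteins[i, ],
                    intensities = x$intensities[i, ])
  }

  mito_ids <- annot$protein_id[annot$is_mito]
  keep <- x$proteins$protein_id %in% mito_ids
  if (!is.null(spike_id)) keep <- keep & x$proteins$protein_id != spike_id
  n_unmatched <- sum(!keep)

  x$intensities <- x$intensities[keep, , drop = FALSE]
  x$proteins <- x$proteins[keep, , drop = FALSE]
  if (!is.null(x$imputed)) x$imputed <- x$imputed[keep, , drop = FALSE]
  x$annotation <- x$proteins |>
    dplyr::select("protein_id") |>
    dplyr::left_join(annot, by = "protein_id")
  log_count(x,
            n_before_mito_filter = n_in,
            n_not_mito_removed = n_unmatched,
            n_mito = sum(keep))
}
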