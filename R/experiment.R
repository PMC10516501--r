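#' Reporter-intensity experiment container
#'
#' Internal container tying together a protein-by-channel intensity matrix,
#' per-protein metadata (identifiers and MaxQuant quality flags), the sample
#' layout mapping channels to biological samples, and, once attached, the
#' mitochondrial annotation. Missing intensities are `NA`; MaxQuant's zero
#' encoding is converted to `NA` on ingest.
#'
#' @param intensities numeric matrix, rows named by protein accession,
#'   columns named by channel id (`<batch>.<channel>`), `NA` for missing.
#' @param proteins tibble with one row per matrix row: `protein_id`,
#'   `protein_ids_full`, `gene_name`, and logical flags `reverse`,
#'   `contaminant`, `site_only`.
#' @param layout sample layout tibble as returned by [read_layout()].
#' @param annotation optional mitochondrial annotation tibble (attached by
#'   [annotate_mito()]).
#' @param imputed optional logical matrix marking imputed cells.
#' @param log named list of per-stage record counts.
#'
#' @return An object of class `mpq_experiment`.
#' @keywords internal
new_mpq_experiment <- function(intensities, proteins, layout,
                               annotation = NULL, imputed = NULL,
                               log = list()) {
  stopifnot(is.matrix(intensities), nrow(intensities) == nrow(proteins))
  if (nrow(intensities) > 0 &&
      !identical(rownames(intensities), proteins$protein_id)) {
    stop("intensity rownames must match proteins$protein_id", call. = FALSE)
  }
  missing_ch <- setdiff(layout$channel_id, colnames(intensities))
  if (length(missing_ch) > 0) {
    stop("layout channel(s) absent from intensity matrix: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  structure(
    list(intensities = intensities, proteins = proteins, layout = layout,
         annotation = annotation, imputed = imputed, log = log),
    class = "mpq_experiment"
  )
}

#' @export
print.mpq_experiment <- function(x, ...) {
  cat("<mpq_experiment>\n")
  cat("  proteins: ", nrow(x$intensities), "\n", sep = "")
  cat("  channels: ", ncol(x$intensities),
      " (", length(unique(x$layout$batch)), " batch(es))\n", sep = "")
  cat("  missing cells: ", sum(is.na(x$intensities)), "\n", sep = "")
  if (!is.null(x$annotation)) cat("  mitochondrial annotation attached\n")
  if (length(x$log) > 0) {
    cat("  log: ", paste(names(x$log), unlist(x$log), sep = "=",
                         collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of proteins in an experiment
#' @param x an `mpq_experiment`.
#' @param ... ignored.
#' @export
dim.mpq_experiment <- function(x) dim(x$intensities)

# internal: channels of one batch (optionally one fraction)
batch_channels <- function(layout, batch, fraction = NULL) {
  sel <- layout$batch == batch
  if (!is.null(fraction)) sel <- sel & layout$fraction == fraction
  layout$channel_id[sel]
}

# internal: append a named count to the stage log
log_count <- function(x, ...) {
  x$log <- utils::modifyList(x$log, list(...))
  x
}
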