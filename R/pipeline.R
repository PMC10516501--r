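#' Pipeline configuration
#'
#' Collects every input path and analysis parameter of a full run. All
#' thresholds the analysis depends on are surfaced as named keys with the
#' standard values as defaults: solubility-shift classes at >25 / >50
#' percentage points, differential-expression membership at FDR <= 0.05
#' with |log2FC| > 0.2.
#'
#' @param protein_groups,layout,annotation input paths (see
#'   [read_protein_groups()], [read_layout()], [read_mito_annotation()]).
#' @param de_tables optional path to a TSV of differential-expression
#'   results with columns `gene_id`, `contrast`, `log2fc`, `fdr` for the
#'   dependency partition.
#' @param spike_id spike-in accession (default "AG85A").
#' @param shift_thresholds percentage-point thresholds
#'   `c(aggregating, highly)` (default `c(25, 50)`).
#' @param de_fdr,de_lfc dependency-partition thresholds.
#' @param impute run batch-level left-censored imputation (default `TRUE`).
#' @param impute_tune_sigma QRILC spread multiplier.
#' @param baseline_tp,peak_tp baseline and stress-peak time points (hours);
#'   detected from the layout phases when `NULL`.
#' @param recovery_window `"auto"` or a fixed window length in hours.
#' @param groupings annotation groupings to summarize AIs over.
#' @param output_dir optional directory for the report bundle.
#' @param seed RNG seed for the run.
#' @return List of class `mpq_config`.
#' @export
pipeline_config <- function(protein_groups, layout, annotation,
                            de_tables = NULL, spike_id = "AG85A",
                            shift_thresholds = c(25, 50),
                            de_fdr = 0.05, de_lfc = 0.2,
                            impute = TRUE, impute_tune_sigma = 1,
                            baseline_tp = NULL, peak_tp = NULL,
                            recovery_window = "auto",
                            groupings = c("process_group", "compartment"),
                            output_dir = NULL, seed = 1) {
  stopifnot(length(shift_thresholds) == 2, all(shift_thresholds > 0),
            shift_thresholds[1] < shift_thresholds[2],
            de_fdr > 0, de_lfc > 0)
  structure(as.list(environment()), class = "mpq_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return List of class `mpq_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$shift_thresholds)) {
    vals$shift_thresholds <- as.numeric(unlist(vals$shift_thresholds))
  }
  if (!is.null(vals$groupings)) vals$groupings <- unlist(vals$groupings)
  do.call(pipeline_config, vals)
}

#' Run the full quantification pipeline
#'
#' Executes ingest -> spike-in normalization -> quality filters ->
#' left-censored imputation -> mitochondrial filter -> solubility
#' quantification -> aggregation/recovery metrics (-> dependency partition
#' when DE tables are configured), logging per-stage record counts, and
#' writes the report bundle when an output directory is configured.
#'
#' @param config an `mpq_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return List of class `mpq_bundle`: `profiles`, `condition_means`,
#'   `shifts`, `ai_global`, `ai_by_group` (one element per grouping),
#'   `recovery`, optional `dependency` and `composition`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mpq_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  layout <- stage("ingest", read_layout(config$layout))
  x <- stage("ingest", read_protein_groups(config$protein_groups, layout))
  annot <- stage("ingest", read_mito_annotation(config$annotation))

  x <- stage("normalize", normalize_to_spikein(x, config$spike_id))
  x <- stage("quality_filter", apply_quality_filters(x))
  if (isTRUE(config$impute)) {
    params <- imputation_params(tune_sigma = config$impute_tune_sigma,
                                seed = config$seed)
    x <- stage("impute", impute_missing(x, params = params))
  }
  x <- stage("mito_filter", annotate_mito(x, annot, config$spike_id))
  if (nrow(x$proteins) == 0) {
    stop("pipeline stage 'mito_filter': no mitochondrial protein retained",
         call. = FALSE)
  }

  profiles <- stage("quantify", quantify_solubility(x))
  means <- stage("quantify", condition_means(profiles))

  tps <- sort(unique(x$layout$time_point_h[x$layout$fraction %in%
                                             c("soluble", "insoluble")]))
  baseline_tp <- config$baseline_tp %||%
    min(x$layout$time_point_h[x$layout$phase == "DMSO"])
  peak_tp <- config$peak_tp %||%
    max(x$layout$time_point_h[x$layout$phase == "treatment"])

  cell_lines <- unique(x$layout$cell_line[x$layout$fraction %in%
                                            c("soluble", "insoluble")])
  shifts <- dplyr::bind_rows(lapply(cell_lines, function(line) {
    s <- solubility_shifts(
      means,
      treated = list(cell_line = line, time_point_h = peak_tp),
      control = list(cell_line = line, time_point_h = baseline_tp),
      thresholds = config$shift_thresholds)
    dplyr::mutate(s, cell_line = line, .before = 1)
  }))

  ai_global <- stage("metrics", aggregation_index(profiles))
  ai_by_group <- lapply(config$groupings, function(g) {
    stage("metrics", grouped_aggregation(profiles, x$annotation, g))
  })
  names(ai_by_group) <- config$groupings
  recovery <- stage("metrics", recovery_rates(
    summarize_ai(ai_global), baseline_tp, peak_tp,
    window = config$recovery_window))

  bundle <- list(profiles = profiles, condition_means = means,
                 shifts = shifts, ai_global = ai_global,
                 ai_by_group = ai_by_group, recovery = recovery)

  if (!is.null(config$de_tables)) {
    de <- stage("regulon", readr::read_tsv(config$de_tables,
                                           show_col_types = FALSE))
    dep <- stage("regulon", classify_dependency(de, fdr = config$de_fdr,
                                                lfc = config$de_lfc))
    bundle$dependency <- dep
    bundle$composition <- dependency_composition(dep)
  }

  cfg_for_manifest <- config
  cfg_for_manifest$output_dir <- NULL
  cfg_json <- jsonlite::toJSON(unclass(cfg_for_manifest), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("mitopq")),
    seed = config$seed,
    config = unclass(cfg_for_manifest),
    config_hash = unname(tools::md5sum(tmp)),
    log = x$log,
    baseline_tp = baseline_tp, peak_tp = peak_tp,
    time_points = tps
  )
  unlink(tmp)
  class(bundle) <- "mpq_bundle"

  if (!is.null(config$output_dir)) {
    write_bundle(bundle, config$output_dir)
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a report bundle to disk
#'
#' Tables are written as TSV, the dependency composition and manifest as
#' JSON. Files are staged in a temporary sibling directory and moved into
#' place only after every file has been written, so a failed run never
#' leaves a partial bundle.
#'
#' @param bundle an `mpq_bundle` from [run_pipeline()].
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mpq_bundle"))
  parent <- dirname(dir)
  if (!dir.exists(parent)) dir.create(parent, recursive = TRUE)
  staging <- tempfile("bundle_", tmpdir = parent)
  dir.create(staging)
  write1 <- function(obj, name) {
    readr::write_tsv(obj, file.path(staging, name))
    name
  }
  files <- c(
    write1(bundle$profiles, "solubility.tsv"),
    write1(bundle$condition_means, "condition_means.tsv"),
    write1(bundle$shifts, "shifts.tsv"),
    write1(bundle$ai_global, "ai_global.tsv"),
    write1(bundle$recovery, "recovery_rates.tsv")
  )
  for (g in names(bundle$ai_by_group)) {
    files <- c(files, write1(bundle$ai_by_group[[g]],
                             paste0("ai_by_", g, ".tsv")))
  }
  if (!is.null(bundle$dependency)) {
    files <- c(files, write1(bundle$dependency, "dependency.tsv"))
    jsonlite::write_json(bundle$composition,
                         file.path(staging, "composition.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "composition.json")
  }
  jsonlite::write_json(bundle$manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  files <- c(files, "manifest.json")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (f in files) {
    file.rename(file.path(staging, f), file.path(dir, f))
  }
  unlink(staging, recursive = TRUE)
  invisible(file.path(dir, files))
}
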