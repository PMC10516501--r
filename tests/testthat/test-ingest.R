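test_that("simulated fixtures survive a write/read round trip", {
  sim <- simulate_experiment(sim_config(n_proteins = 30, seed = 3,
                                        n_nonmito = 6, n_reverse = 4,
                                        n_contaminant = 2, n_site_only = 2))
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)

  layout <- read_layout(file.path(dir, "layout.tsv"))
  x <- read_protein_groups(file.path(dir, "proteinGroups.txt"), layout)

  expect_identical(x$proteins$protein_id, sim$experiment$proteins$protein_id)
  expect_identical(x$proteins$gene_name, sim$experiment$proteins$gene_name)
  expect_identical(x$proteins$reverse, sim$experiment$proteins$reverse)
  expect_identical(x$proteins$contaminant,
                   sim$experiment$proteins$contaminant)
  expect_identical(x$proteins$site_only, sim$experiment$proteins$site_only)
  expect_identical(colnames(x$intensities),
                   colnames(sim$experiment$intensities))
  expect_equal(x$intensities, sim$experiment$intensities)

  annot <- read_mito_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(annot, sim$annotation, ignore_attr = TRUE)
})

test_that("a header-only table parses to an empty experiment", {
  layout <- layout_grid("b1", tps = 0)
  header <- paste(c("Majority protein IDs", "Gene names", "Reverse",
                    "Potential contaminant", "Only identified by site",
                    paste("Reporter intensity corrected", layout$channel,
                          layout$batch)),
                  collapse = "\t")
  path <- withr::local_tempfile(lines = header)
  x <- read_protein_groups(path, layout)
  expect_s3_class(x, "mpq_experiment")
  expect_equal(nrow(x$proteins), 0)
  expect_equal(dim(x$intensities), c(0L, nrow(layout)))
})

test_that("format violations are reported by name", {
  layout <- layout_grid("b1", tps = 0)
  base_cols <- c("Majority protein IDs", "Gene names", "Reverse",
                 "Potential contaminant", "Only identified by site")
  reporter <- paste("Reporter intensity corrected", layout$channel,
                    layout$batch)

  # missing Reverse column
  cols <- setdiff(c(base_cols, reporter), "Reverse")
  path <- withr::local_tempfile(lines = paste(cols, collapse = "\t"))
  expect_error(read_protein_groups(path, layout), "Reverse")

  # layout channel absent from the file
  cols2 <- c(base_cols, reporter[-1])
  lines2 <- c(paste(cols2, collapse = "\t"),
              paste(c("P1", "G1", "", "", "", rep("5", length(reporter) - 1)),
                    collapse = "\t"))
  path2 <- withr::local_tempfile(lines = lines2)
  expect_error(read_protein_groups(path2, layout), "absent")

  # duplicate leading accession
  lines3 <- c(paste(c(base_cols, reporter), collapse = "\t"),
              paste(c("P1;X2", "G1", "", "", "", rep("5", length(reporter))),
                    collapse = "\t"),
              paste(c("P1;Y9", "G2", "", "", "", rep("6", length(reporter))),
                    collapse = "\t"))
  path3 <- withr::local_tempfile(lines = lines3)
  expect_error(read_protein_groups(path3, layout), "duplicate")
})

test_that("zero reporter intensities are read as missing", {
  layout <- layout_grid("b1", tps = 0)
  reporter <- paste("Reporter intensity corrected", layout$channel,
                    layout$batch)
  lines <- c(paste(c("Majority protein IDs", "Gene names", "Reverse",
                     "Potential contaminant", "Only identified by site",
                     reporter), collapse = "\t"),
             paste(c("P1;ALT", "G1", "", "", "", "0", "120.5"),
                   collapse = "\t"))
  path <- withr::local_tempfile(lines = lines)
  x <- read_protein_groups(path, layout)
  expect_true(is.na(x$intensities[1, 1]))
  expect_equal(x$intensities[1, 2], 120.5)
  expect_equal(x$proteins$protein_id, "P1")
  expect_equal(x$proteins$protein_ids_full, "P1;ALT")
})

test_that("quality filtering removes flagged records, is idempotent, and keeps counts", {
  layout <- layout_grid("b1", tps = 0)
  m <- matrix(1:10, nrow = 5, ncol = 2,
              dimnames = list(paste0("P", 1:5), layout$channel_id))
  x <- make_experiment(m, layout,
                       reverse = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                       contaminant = c(FALSE, TRUE, FALSE, FALSE, FALSE),
                       site_only = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  f <- apply_quality_filters(x)
  expect_equal(nrow(f$proteins), 2)
  expect_setequal(f$proteins$protein_id, c("P3", "P4"))
  # bookkeeping: input = output + flagged
  expect_equal(f$log$n_before_quality_filter,
               nrow(f$proteins) + f$log$n_flagged_removed)
  # idempotent
  f2 <- apply_quality_filters(f)
  expect_equal(f2$proteins, f$proteins)
  expect_equal(f2$intensities, f$intensities)
  # no flagged records -> identity
  clean <- make_experiment(m, layout)
  expect_equal(apply_quality_filters(clean)$intensities, m)
})

test_that("mitochondrial filter keeps annotated proteins and sets the spike aside", {
  layout <- layout_grid("b1", tps = 0)
  ids <- c(paste0("P", 1:9), "AG85A")
  m <- matrix(runif(20, 1, 10), nrow = 10, ncol = 2,
              dimnames = list(ids, layout$channel_id))
  x <- make_experiment(m, layout)
  annot <- tibble::tibble(
    protein_id = c("P1", "P2", "P3", "P4", "P5", "P6"),
    is_mito = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    process_group = c("translation", "translation", "oxidative phosphorylation",
                      "metabolism", NA, NA),
    compartment = c("matrix", "IMS", "inner membrane", "matrix", NA, NA),
    complex = c(NA, NA, "CI", NA, NA, NA),
    submodule = c(NA, NA, "N", NA, NA, NA)
  )
  a <- annotate_mito(x, annot, spike_id = "AG85A")
  expect_setequal(a$proteins$protein_id, paste0("P", 1:4))
  # spike excluded from the annotated table but kept for audit
  expect_false("AG85A" %in% a$proteins$protein_id)
  expect_equal(a$spike$protein$protein_id, "AG85A")
  expect_equal(unname(a$spike$intensities), unname(m["AG85A", ]))
  # annotation fields preserved verbatim
  p3 <- a$annotation[a$annotation$protein_id == "P3", ]
  expect_equal(p3$complex, "CI")
  expect_equal(p3$submodule, "N")
  # counts: input = kept + dropped
  expect_equal(a$log$n_before_mito_filter,
               a$log$n_mito + a$log$n_not_mito_removed)
  expect_error(annotate_mito(x, annot[0, ]), "empty annotation")
})

test_that("a YAML layout parses identically to its TSV form", {
  lay_tsv <- layout_grid("b1", tps = c(0, 12))
  yaml_lines <- c("channels:", unlist(lapply(seq_len(nrow(lay_tsv)),
    function(i) {
      r <- lay_tsv[i, ]
      c(sprintf("  - channel: %d", r$channel),
        sprintf("    batch: %s", r$batch),
        sprintf("    cell_line: %s", r$cell_line),
        sprintf("    time_point_h: %s", r$time_point_h),
        sprintf("    phase: %s", r$phase),
        sprintf("    fraction: %s", r$fraction),
        sprintf("    replicate: %d", r$replicate))
    })))
  path <- withr::local_tempfile(lines = yaml_lines, fileext = ".yaml")
  expect_equal(read_layout(path), lay_tsv, ignore_attr = TRUE)
})

test_that("the bundled synthetic fixtures load through the full ingest path", {
  pg <- system.file("extdata", "synthetic_proteinGroups.txt",
                    package = "mitopq")
  lay <- system.file("extdata", "synthetic_layout.tsv", package = "mitopq")
  ann <- system.file("extdata", "synthetic_annotation.tsv",
                     package = "mitopq")
  layout <- read_layout(lay)
  x <- read_protein_groups(pg, layout)
  x <- normalize_to_spikein(x, "AG85A")
  x <- apply_quality_filters(x)
  x <- annotate_mito(x, read_mito_annotation(ann), "AG85A")
  expect_equal(nrow(x$proteins), 30)
  expect_equal(x$log$n_flagged_removed, 5)
  prof <- quantify_solubility(x)
  expect_true(all(prof$pct_insoluble >= 0 & prof$pct_insoluble <= 100,
                  na.rm = TRUE))
})

test_that("layout and annotation invariants are enforced", {
  lay <- layout_grid("b1", tps = c(0, 12))
  dup <- dplyr::bind_rows(lay[, !names(lay) %in% "channel_id"],
                          lay[1, !names(lay) %in% "channel_id"])
  expect_error(validate_layout(dup), "duplicate channel")

  two_sol <- lay[, !names(lay) %in% "channel_id"]
  two_sol$channel[2] <- 9
  two_sol$fraction[2] <- "soluble"
  expect_error(validate_layout(two_sol), "more than one")

  bad_sub <- tibble::tibble(protein_id = "P1", is_mito = TRUE,
                            process_group = "x", compartment = "matrix",
                            complex = NA_character_, submodule = "N")
  expect_error(validate_annotation(bad_sub), "submodule")
})
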