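# Tabular input/output and validation: OTU count tables, sample metadata
# encoding the factorial invasion design, taxonomy with per-rank confidence,
# scalar functioning measurements, and the YAML run configuration.

ENVIRONMENTS <- c("litter", "agar")
ROLES <- c("invader_inoculum", "resident_initial", "final_invaded",
           "final_resident_resident", "final_killed_resident")
COMMUNITIES <- c("MC1", "MC2", "MC3", "MC4")
DOSES <- c("high", "low", "killed", "none")
FREQUENCIES <- c("1", "4", "none")
MICROCOSM_ROLES <- c("final_invaded", "final_resident_resident",
                     "final_killed_resident")

METADATA_COLUMNS <- c("sample_id", "environment", "role", "resident_id",
                      "invader_id", "dose", "frequency", "replicate")
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")
TAXONOMY_COLUMNS <- c("otu_id", TAXONOMY_RANKS, "family_confidence")

#' Validate an OTU count matrix
#'
#' An OTU table is a plain integer matrix with samples as rows and OTUs as
#' columns, uniquely named on both axes. Counts must be non-negative
#' integers.
#'
#' @param counts Numeric matrix, samples x OTUs, with `rownames` (sample
#'   identifiers) and `colnames` (OTU identifiers).
#' @param allow_empty_samples Keep samples whose row sum is zero? Default
#'   `FALSE`: an all-zero sample is almost always an upstream mistake.
#' @return The validated matrix (in `storage.mode` integer), invisibly
#'   unchanged otherwise.
#' @export
validate_otu_table <- function(counts, allow_empty_samples = FALSE) {
  if (!is.matrix(counts)) {
    stop_invasim("OTU table must be a matrix (samples x OTUs)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_invasim("OTU table must have sample ids as rownames and OTU ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop_invasim("duplicate sample identifiers: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- unique(colnames(counts)[duplicated(colnames(counts))])
    stop_invasim("duplicate OTU identifiers: ", paste(dup, collapse = ", "))
  }
  if (anyNA(counts)) stop_invasim("OTU table contains missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_invasim(sprintf(
      "OTU table cell [%s, %s] = %s is not a non-negative integer",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])))
  }
  if (!allow_empty_samples && any(rowSums(counts) == 0)) {
    empty <- rownames(counts)[rowSums(counts) == 0]
    stop_invasim("samples with zero total counts: ", paste(empty, collapse = ", "))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read an OTU count table from TSV
#'
#' Canonical on-disk orientation is samples-as-rows with a `sample_id`
#' identifier column; `orientation = "otus_as_rows"` accepts the transpose
#' (identifier column holds OTU ids, remaining columns are samples).
#'
#' @param path Path to a tab-separated file with one header row.
#' @param orientation `"samples_as_rows"` (default) or `"otus_as_rows"`.
#' @inheritParams validate_otu_table
#' @return Validated integer matrix, samples x OTUs.
#' @export
read_otu_table <- function(path, orientation = c("samples_as_rows", "otus_as_rows"),
                           allow_empty_samples = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_invasim("OTU table needs an id column plus at least one count column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_invasim("non-numeric count cells in ", path)
  rownames(m) <- ids
  if (orientation == "otus_as_rows") m <- t(m)
  validate_otu_table(m, allow_empty_samples = allow_empty_samples)
}

#' Write an OTU count table as TSV
#'
#' @param counts Validated OTU matrix (samples x OTUs).
#' @param path Output path; first column is `sample_id`.
#' @export
write_otu_table <- function(counts, path) {
  counts <- validate_otu_table(counts, allow_empty_samples = TRUE)
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU table from a BIOM v1 (JSON) file
#'
#' Thin wrapper over the biomformat package, returning the same
#' samples x OTUs integer matrix as [read_otu_table()].
#'
#' @param path Path to a BIOM v1 JSON file.
#' @inheritParams validate_otu_table
#' @export
read_biom_otu_table <- function(path, allow_empty_samples = FALSE) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop_invasim("the biomformat package is required to read BIOM files")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
  validate_otu_table(t(m), allow_empty_samples = allow_empty_samples)
}

check_levels <- function(x, allowed, column) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad) > 0) {
    stop_invasim(sprintf("invalid %s level(s) %s; allowed: %s",
                         column, paste(bad, collapse = ", "),
                         paste(allowed, collapse = ", ")))
  }
}

#' Validate a sample-metadata data frame
#'
#' Enforces the factorial-design contract: strict factor levels, and role
#' consistency (a final invaded sample needs `resident_id != invader_id`, a
#' real dose and a real frequency; a resident-resident final needs
#' `resident_id == invader_id`).
#'
#' @param meta Data frame with columns `sample_id, environment, role,
#'   resident_id, invader_id, dose, frequency, replicate`.
#' @return The validated data frame with character factor columns and an
#'   integer `replicate` column.
#' @export
validate_metadata <- function(meta) {
  missing_cols <- setdiff(METADATA_COLUMNS, names(meta))
  if (length(missing_cols) > 0) {
    stop_invasim("metadata missing required column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (col in setdiff(METADATA_COLUMNS, "replicate")) {
    meta[[col]] <- as.character(meta[[col]])
  }
  if (anyDuplicated(meta$sample_id)) {
    stop_invasim("duplicate sample_id in metadata: ",
                 paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  check_levels(meta$environment, ENVIRONMENTS, "environment")
  check_levels(meta$role, ROLES, "role")
  check_levels(meta$resident_id, c(COMMUNITIES[1:2], "none"), "resident_id")
  check_levels(meta$invader_id, c(COMMUNITIES, "none"), "invader_id")
  check_levels(meta$dose, DOSES, "dose")
  check_levels(meta$frequency, FREQUENCIES, "frequency")
  meta$replicate <- as.integer(meta$replicate)
  if (anyNA(meta$replicate) || any(meta$replicate < 1)) {
    stop_invasim("replicate must be a positive integer")
  }

  inv <- meta$role == "final_invaded"
  bad <- inv & (meta$resident_id == meta$invader_id |
                  !(meta$dose %in% c("high", "low")) |
                  !(meta$frequency %in% c("1", "4")))
  if (any(bad)) {
    stop_invasim("inconsistent final_invaded sample(s): ",
                 paste(meta$sample_id[bad], collapse = ", "),
                 " (need resident != invader, dose in {high, low}, frequency in {1, 4})")
  }
  rr <- meta$role == "final_resident_resident"
  if (any(rr & meta$resident_id != meta$invader_id)) {
    stop_invasim("final_resident_resident sample(s) with resident_id != invader_id: ",
                 paste(meta$sample_id[rr & meta$resident_id != meta$invader_id],
                       collapse = ", "))
  }
  meta
}

#' Read sample metadata from TSV
#'
#' @param path Tab-separated file with the columns listed in
#'   [validate_metadata()].
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Write sample metadata as TSV
#' @param meta Validated metadata data frame.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  meta <- validate_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a taxonomy table
#'
#' One row per OTU with labels ordered domain to genus plus a family-level
#' bootstrap-style confidence on the 0-100 scale. A missing family label is
#' allowed (such OTUs are simply excluded from family-level competitor
#' scoring), but a present family label requires a confidence value.
#'
#' @param tax Data frame with columns `otu_id, domain, phylum, class, order,
#'   family, genus, family_confidence`.
#' @export
validate_taxonomy <- function(tax) {
  missing_cols <- setdiff(TAXONOMY_COLUMNS, names(tax))
  if (length(missing_cols) > 0) {
    stop_invasim("taxonomy missing required column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  tax <- as.data.frame(tax, stringsAsFactors = FALSE)
  if (anyDuplicated(tax$otu_id)) {
    stop_invasim("duplicate otu_id in taxonomy")
  }
  tax$family_confidence <- as.numeric(tax$family_confidence)
  has_family <- !is.na(tax$family) & nzchar(tax$family)
  if (any(has_family & is.na(tax$family_confidence))) {
    stop_invasim("family label present without family_confidence for: ",
                 paste(utils::head(tax$otu_id[has_family & is.na(tax$family_confidence)], 5),
                       collapse = ", "))
  }
  conf <- tax$family_confidence[!is.na(tax$family_confidence)]
  if (any(conf < 0 | conf > 100)) {
    stop_invasim("family_confidence must lie in [0, 100]")
  }
  tax
}

#' Read a taxonomy table from TSV
#' @param path Tab-separated taxonomy file (see [validate_taxonomy()]).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_taxonomy(df)
}

#' Write a taxonomy table as TSV
#' @param tax Validated taxonomy data frame.
#' @param path Output path.
#' @export
write_taxonomy <- function(tax, path) {
  tax <- validate_taxonomy(tax)
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-microcosm functioning measurements (CO2, DOC) from TSV
#'
#' @param path Tab-separated file with columns `sample_id, co2_total, doc`.
#' @export
read_functioning <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_functioning(df)
}

#' Validate a functioning table
#' @param fun Data frame with columns `sample_id, co2_total, doc`.
#' @export
validate_functioning <- function(fun) {
  missing_cols <- setdiff(c("sample_id", "co2_total", "doc"), names(fun))
  if (length(missing_cols) > 0) {
    stop_invasim("functioning table missing column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  fun <- as.data.frame(fun, stringsAsFactors = FALSE)
  if (anyDuplicated(fun$sample_id)) stop_invasim("duplicate sample_id in functioning table")
  fun$co2_total <- as.numeric(fun$co2_total)
  fun$doc <- as.numeric(fun$doc)
  if (any(!is.finite(fun$co2_total)) || any(!is.finite(fun$doc))) {
    stop_invasim("functioning values must be finite")
  }
  if (any(fun$co2_total < 0) || any(fun$doc < 0)) {
    stop_invasim("functioning values must be non-negative")
  }
  fun
}

#' Write a functioning table as TSV
#' @param fun Validated functioning data frame.
#' @param path Output path.
#' @export
write_functioning <- function(fun, path) {
  fun <- validate_functioning(fun)
  utils::write.table(fun, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-validate an OTU table, metadata and taxonomy
#'
#' Checks identifier consistency across the three tables. A sample in the
#' OTU table that the metadata does not describe is a failure (the design
#' factors are unknowable); an OTU missing from the taxonomy is only a
#' warning, because invasion-category classification is taxonomy-free and
#' the OTU is merely excluded from family-level competitor scoring.
#'
#' @param otus OTU matrix (samples x OTUs).
#' @param meta Metadata data frame.
#' @param tax Optional taxonomy data frame.
#' @return A list of class `invasim_validation` with elements `pass`
#'   (logical), `errors` and `warnings` (character vectors), and counts.
#' @export
validate_dataset <- function(otus, meta, tax = NULL) {
  otus <- validate_otu_table(otus, allow_empty_samples = TRUE)
  meta <- validate_metadata(meta)
  errors <- character()
  warnings <- character()

  orphan_samples <- setdiff(rownames(otus), meta$sample_id)
  if (length(orphan_samples) > 0) {
    errors <- c(errors, paste0("samples in OTU table absent from metadata: ",
                               paste(sort(orphan_samples), collapse = ", ")))
  }
  unsequenced <- setdiff(meta$sample_id, rownames(otus))
  if (length(unsequenced) > 0) {
    warnings <- c(warnings, paste0(length(unsequenced),
                                   " metadata sample(s) without OTU counts"))
  }
  if (!is.null(tax)) {
    tax <- validate_taxonomy(tax)
    untaxed <- setdiff(colnames(otus), tax$otu_id)
    if (length(untaxed) > 0) {
      warnings <- c(warnings, paste0(length(untaxed),
                                     " OTU(s) absent from taxonomy (excluded from family-level scoring)"))
    }
  }
  structure(list(pass = length(errors) == 0,
                 errors = errors, warnings = warnings,
                 n_samples = nrow(otus), n_otus = ncol(otus)),
            class = "invasim_validation")
}

#' @export
print.invasim_validation <- function(x, ...) {
  cat(sprintf("dataset validation: %s (%d samples, %d OTUs)\n",
              if (x$pass) "PASS" else "FAIL", x$n_samples, x$n_otus))
  for (e in x$errors) cat("  error:  ", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Read a YAML run configuration
#'
#' Recognised keys (all optional, defaults in parentheses): `depths`
#' (1020), `n_rarefactions` (100), `alpha` (0.05), `n_permutations` (999),
#' `competitor_threshold` (50), `min_family_confidence` (70), `seed` (1).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(depths = 1020L, n_rarefactions = 100L, alpha = 0.05,
                   n_permutations = 999L, competitor_threshold = 50,
                   min_family_confidence = 70, seed = 1L)
  out <- utils::modifyList(defaults, cfg[names(cfg) %in% names(defaults)])
  out$depths <- as.integer(out$depths)
  assert_that(all(out$depths > 0), "depths must be positive integers")
  assert_that(out$n_rarefactions >= 1, "n_rarefactions must be >= 1")
  assert_that(out$alpha > 0 && out$alpha < 1, "alpha must be in (0, 1)")
  assert_that(out$n_permutations >= 99, "n_permutations must be >= 99")
  out
}
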