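#' Feature tables
#'
#' A feature table is a tibble with one row per cell: metadata columns
#' `cell_id` (unique), `condition`, `replicate`, optional ground-truth
#' columns (`phase`, `arrest_state`, `latent_pseudotime`, `ploidy` --
#' synthetic-data plumbing), and any number of numeric feature columns.
#' Feature names conventionally encode marker, compartment and statistic
#' (e.g. `pcna_nucleus_median`), but the schema does not enforce the
#' encoding: unknown feature columns are carried through untouched.
#'
#' @name feature_table
NULL

.metadata_cols <- c("cell_id", "condition", "replicate")
.truth_cols <- c("phase", "arrest_state", "latent_pseudotime", "ploidy")

#' Feature column names of a feature table
#'
#' @param table A feature table (tibble).
#' @return Character vector of feature column names (everything that is not
#'   metadata or ground truth).
#' @export
feature_names <- function(table) {
  setdiff(names(table), c(.metadata_cols, .truth_cols))
}

#' Validate a feature table
#'
#' Checks the feature-table invariants: mandatory metadata columns present,
#' `cell_id` unique, feature columns numeric, and (optionally) `condition`
#' drawn from a declared vocabulary.  Missing numeric values are permitted
#' (they are `NA`) but are counted and reported via a message.
#'
#' @param table A tibble.
#' @param condition_vocabulary Optional character vector of allowed
#'   condition labels.
#' @return The table, invisibly, if valid.  Errors otherwise.
#' @export
validate_feature_table <- function(table, condition_vocabulary = NULL) {
  missing_cols <- setdiff(.metadata_cols, names(table))
  if (length(missing_cols) > 0) {
    am_abort(
      paste0("Missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      "arrestmap_schema_error"
    )
  }
  dup <- unique(table$cell_id[duplicated(table$cell_id)])
  if (length(dup) > 0) {
    am_abort(
      paste0("Duplicated cell_id(s): ", paste(utils::head(dup, 5), collapse = ", ")),
      "arrestmap_integrity_error"
    )
  }
  feats <- feature_names(table)
  bad <- feats[!vapply(table[feats], is.numeric, logical(1))]
  if (length(bad) > 0) {
    am_abort(
      paste0("Non-numeric feature column(s): ", paste(bad, collapse = ", ")),
      "arrestmap_schema_error"
    )
  }
  if (!is.null(condition_vocabulary)) {
    unknown <- setdiff(unique(table$condition), condition_vocabulary)
    if (length(unknown) > 0) {
      am_abort(
        paste0("Condition label(s) outside declared vocabulary: ",
               paste(unknown, collapse = ", ")),
        "arrestmap_schema_error"
      )
    }
  }
  n_missing <- sum(vapply(table[feats], function(x) sum(is.na(x)), numeric(1)))
  if (n_missing > 0) {
    rlang::inform(paste0(n_missing, " missing feature value(s) flagged (kept as NA)."))
  }
  invisible(table)
}

#' Read a feature table from CSV
#'
#' Missing numeric cells (empty fields) become `NA` and are flagged, never
#' silently dropped.  Feature columns absent from any configured schema are
#' accepted and carried through untouched.
#'
#' @param path Path to a CSV file with a header row.
#' @param condition_vocabulary Optional allowed condition labels, checked
#'   on read.
#' @return A validated feature table tibble.
#' @export
read_feature_table <- function(path, condition_vocabulary = NULL) {
  if (!file.exists(path)) {
    am_abort(paste0("File not found: ", path), "arrestmap_io_error")
  }
  meta_types <- list(
    cell_id = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_character(),
    phase = readr::col_character(),
    arrest_state = readr::col_character(),
    ploidy = readr::col_character()
  )
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE))
  meta_types <- meta_types[intersect(names(meta_types), header)]
  table <- readr::read_csv(
    path,
    col_types = do.call(readr::cols, c(meta_types, list(.default = readr::col_double()))),
    progress = FALSE
  )
  validate_feature_table(table, condition_vocabulary)
  table
}

#' Write a feature table to CSV
#'
#' Numeric values round-trip at full precision (shortest exact decimal
#' representation); two writes of the same table are byte-identical.
#'
#' @param table A feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    am_abort(paste0("Directory does not exist: ", dir), "arrestmap_io_error")
  }
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}
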