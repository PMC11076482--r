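# Borane candidate library and experiment tables: validation, CSV I/O and
# assembly of model-ready descriptor/TOF datasets.

# Exact, ordered CSV schema for the descriptor library. `accessible` is an
# optional trailing boolean column used by the campaign's final
# recommendation; any other unknown column is rejected.
.library_columns <- c(
  "borane_id", "core", "aryl_variant",
  "lumo_ev", "dGw_kcal", "dGh_kcal",
  "edef_h2o_kcal", "edef_thf_kcal", "qB_e", "qC_e"
)

.descriptor_columns <- .library_columns[-(1:3)]

.experiment_columns <- c("borane_id", "yield_fraction", "loading_fraction",
                         "time_h")

#' Names of the numeric descriptor columns
#'
#' The descriptor vocabulary of the library: LUMO energy (`lumo_ev`, eV; an
#' intrinsic Lewis-acidity proxy), water-adduct formation energy
#' (`dGw_kcal`, kcal/mol; catalyst-deactivation proxy), the H2 heterolysis
#' barrier (`dGh_kcal`, kcal/mol; rate-determining-step proxy), deformation
#' energies of the H2O and THF adducts (`edef_h2o_kcal`, `edef_thf_kcal`,
#' kcal/mol; back-strain proxies) and Mulliken charges on boron and the
#' ipso-carbons (`qB_e`, `qC_e`, e).
#'
#' @return Character vector of descriptor column names.
#' @export
descriptor_names <- function() .descriptor_columns

.valid_borane_id <- function(id) {
  grepl("^B[1-6][a-w]$", id) | id == "BCF"
}

#' Validate a borane descriptor library
#'
#' Checks the library invariants: unique identifiers obeying the
#' core-plus-aryl grammar (`B1a` ... `B6w`, or `BCF` for B(C6F5)3), cores in
#' B1--B6/BCF consistent with the identifier, strictly positive barrier and
#' deformation energies where present, finite LUMO energies. Missing
#' descriptors are explicit `NA`s, never silent zeros.
#'
#' @param df A data frame with the library columns (see Details of
#'   [read_borane_library()]).
#' @return The validated data frame, classed `"borane_library"`, with a
#'   logical `accessible` column (defaulting to `TRUE` when absent).
#' @export
as_borane_library <- function(df) {
  if (!is.data.frame(df)) stopf("as_borane_library(): expected a data frame")
  missing_cols <- setdiff(.library_columns, names(df))
  if (length(missing_cols)) {
    stopf("library is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), c(.library_columns, "accessible"))
  if (length(extra)) {
    stopf("library has unknown column(s): %s", paste(extra, collapse = ", "))
  }
  df$borane_id <- as.character(df$borane_id)
  df$core <- as.character(df$core)
  df$aryl_variant <- as.character(df$aryl_variant)
  df$aryl_variant[is.na(df$aryl_variant)] <- ""
  if (is.null(df$accessible)) df$accessible <- TRUE
  df$accessible <- as.logical(df$accessible)
  if (anyNA(df$accessible)) stopf("library column 'accessible' must be TRUE/FALSE")

  dup <- df$borane_id[duplicated(df$borane_id)]
  if (length(dup)) {
    stopf("duplicate borane_id in library: %s",
          paste(unique(dup), collapse = ", "))
  }
  bad <- df$borane_id[!.valid_borane_id(df$borane_id)]
  if (length(bad)) {
    stopf("invalid borane_id (expected B<1-6><a-w> or BCF): %s",
          paste(bad, collapse = ", "))
  }
  expected_core <- ifelse(df$borane_id == "BCF", "BCF",
                          substr(df$borane_id, 1, 2))
  mism <- df$borane_id[df$core != expected_core]
  if (length(mism)) {
    stopf("core tag inconsistent with borane_id for: %s",
          paste(mism, collapse = ", "))
  }
  expected_aryl <- ifelse(df$borane_id == "BCF", "",
                          substr(df$borane_id, 3, 3))
  mism <- df$borane_id[df$aryl_variant != expected_aryl]
  if (length(mism)) {
    stopf("aryl_variant inconsistent with borane_id for: %s",
          paste(mism, collapse = ", "))
  }

  for (col in .descriptor_columns) {
    v <- df[[col]]
    if (is.logical(v) && all(is.na(v))) v <- df[[col]] <- as.numeric(v)
    if (!is.numeric(v)) stopf("library column '%s' must be numeric", col)
    if (any(is.nan(v) | is.infinite(v), na.rm = FALSE)) {
      # NA is allowed (missing descriptor); NaN/Inf are not
      if (any(!is.na(v) & !is.finite(v))) {
        stopf("library column '%s' contains non-finite values", col)
      }
    }
  }
  for (col in c("dGh_kcal", "edef_h2o_kcal", "edef_thf_kcal")) {
    v <- df[[col]]
    bad <- df$borane_id[!is.na(v) & v <= 0]
    if (length(bad)) {
      stopf("column '%s' must be strictly positive; violated by: %s",
            col, paste(bad, collapse = ", "))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("borane_library", "data.frame")
  df
}

#' Read and write a borane descriptor library CSV
#'
#' The CSV schema is fixed and ordered: `borane_id, core, aryl_variant,
#' lumo_ev, dGw_kcal, dGh_kcal, edef_h2o_kcal, edef_thf_kcal, qB_e, qC_e`,
#' optionally followed by a boolean `accessible` column (synthetic
#' accessibility, used when recommending a catalyst). UTF-8, "." decimal;
#' an empty cell is an explicitly missing descriptor. `write_borane_library()`
#' prints numerics with 17 significant digits so a write/read round trip is
#' bit-identical.
#'
#' @param path Path to the CSV file.
#' @return `read_borane_library()` returns a validated `borane_library`
#'   data frame.
#' @export
read_borane_library <- function(path) {
  if (!file.exists(path)) stopf("library file not found: %s", path)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    na.strings = character()),
    error = function(e) stopf("could not read library CSV '%s': %s",
                              path, conditionMessage(e))
  )
  if (nrow(raw) == 0L) stopf("library CSV '%s' contains no records", path)
  extra <- setdiff(names(raw), c(.library_columns, "accessible"))
  if (length(extra)) {
    stopf("library CSV '%s' has unknown column(s): %s", path,
          paste(extra, collapse = ", "))
  }
  for (col in .descriptor_columns) {
    if (is.null(raw[[col]])) next
    v <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(v))
    bad <- which(v != "" & is.na(out))
    if (length(bad)) {
      stopf("library CSV '%s': unparseable value '%s' in column '%s', row %d",
            path, v[bad[1]], col, bad[1])
    }
    out[v == ""] <- NA_real_
    raw[[col]] <- out
  }
  if (!is.null(raw$accessible)) {
    v <- toupper(trimws(raw$accessible))
    acc <- rep(NA, length(v))
    acc[v %in% c("TRUE", "T", "1")] <- TRUE
    acc[v %in% c("FALSE", "F", "0")] <- FALSE
    bad <- which(is.na(acc))
    if (length(bad)) {
      stopf("library CSV '%s': unparseable boolean '%s' in column 'accessible', row %d",
            path, raw$accessible[bad[1]], bad[1])
    }
    raw$accessible <- acc
  }
  as_borane_library(raw)
}

#' @rdname read_borane_library
#' @param library A `borane_library` data frame (see [as_borane_library()]).
#' @export
write_borane_library <- function(library, path) {
  library <- as_borane_library(library)
  out <- library[, c(.library_columns, "accessible")]
  for (col in .descriptor_columns) {
    v <- out[[col]]
    s <- ifelse(is.na(v), "", sprintf("%.17g", v))
    out[[col]] <- s
  }
  out$accessible <- ifelse(out$accessible, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an experiment table and derive turnover frequencies
#'
#' An experiment records the model-reaction outcome for one borane: product
#' yield (fraction), catalyst loading (mole fraction) and reaction time
#' (hours). The derived response `tof_h = yield_fraction /
#' (loading_fraction * time_h)` is (re)computed at full precision; if the
#' table already carries a `tof_h` column it must agree to within 1e-9.
#'
#' @param df Data frame with columns `borane_id`, `yield_fraction`,
#'   `loading_fraction`, `time_h` (and optionally `tof_h`).
#' @return The validated table, classed `"borane_experiments"`, with the
#'   derived `tof_h` column.
#' @export
as_experiments <- function(df) {
  if (!is.data.frame(df)) stopf("as_experiments(): expected a data frame")
  missing_cols <- setdiff(.experiment_columns, names(df))
  if (length(missing_cols)) {
    stopf("experiment table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), c(.experiment_columns, "tof_h"))
  if (length(extra)) {
    stopf("experiment table has unknown column(s): %s",
          paste(extra, collapse = ", "))
  }
  df$borane_id <- as.character(df$borane_id)
  dup <- df$borane_id[duplicated(df$borane_id)]
  if (length(dup)) {
    stopf("duplicate borane_id in experiment table: %s",
          paste(unique(dup), collapse = ", "))
  }
  for (col in c("yield_fraction", "loading_fraction", "time_h")) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      stopf("experiment column '%s' must be numeric with no missing values", col)
    }
  }
  tof <- compute_tof(df$yield_fraction, df$loading_fraction, df$time_h)
  if (!is.null(df$tof_h)) {
    off <- which(abs(df$tof_h - tof) > 1e-9)
    if (length(off)) {
      stopf("tof_h inconsistent with yield/(loading*time) for: %s",
            paste(df$borane_id[off], collapse = ", "))
    }
  }
  df$tof_h <- tof
  rownames(df) <- NULL
  class(df) <- c("borane_experiments", "data.frame")
  df
}

#' Read and write the experiments CSV
#'
#' Columns: `borane_id, yield_fraction, loading_fraction, time_h`; the
#' derived `tof_h` is written on export (full precision) and validated on
#' read if present.
#'
#' @param path Path to the CSV file.
#' @return `read_experiments()` returns a validated `borane_experiments`
#'   data frame.
#' @export
read_experiments <- function(path) {
  if (!file.exists(path)) stopf("experiments file not found: %s", path)
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stopf("could not read experiments CSV '%s': %s",
                              path, conditionMessage(e))
  )
  if (nrow(raw) == 0L) stopf("experiments CSV '%s' contains no records", path)
  as_experiments(raw)
}

#' @rdname read_experiments
#' @param experiments A `borane_experiments` data frame.
#' @export
write_experiments <- function(experiments, path) {
  experiments <- as_experiments(experiments)
  out <- experiments[, c(.experiment_columns, "tof_h")]
  for (col in c("yield_fraction", "loading_fraction", "time_h", "tof_h")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a descriptor-pair/TOF training dataset
#'
#' Joins an experiment table to the library on `borane_id` and extracts the
#' requested descriptor pair as the feature matrix, with the experimental
#' TOF as the response. Rows follow the experiment order. Any experiment
#' whose borane lacks one of the requested descriptors aborts the assembly
#' (no imputation), listing the offending identifiers.
#'
#' @param library A `borane_library` (or coercible data frame).
#' @param experiments A `borane_experiments` (or coercible data frame).
#' @param feature_pair Character vector of two distinct descriptor names
#'   (see [descriptor_names()]).
#' @return A `tof_dataset`: list with `X` (n x 2 matrix), `y` (TOF, h^-1),
#'   `borane_ids` and `feature_names`.
#' @examples
#' lib <- sample_library(synthetic_config(n_boranes = 8, seed = 1))
#' exps <- sample_experiments(lib, synthetic_config(n_boranes = 8, seed = 1))
#' ds <- assemble_dataset(lib, exps, c("dGw_kcal", "dGh_kcal"))
#' dim(ds$X)
#' @export
assemble_dataset <- function(library, experiments, feature_pair) {
  library <- as_borane_library(library)
  experiments <- as_experiments(experiments)
  if (!is.character(feature_pair) || length(feature_pair) != 2L ||
      feature_pair[1] == feature_pair[2]) {
    stopf("feature_pair must name two distinct descriptors")
  }
  unknown <- setdiff(feature_pair, .descriptor_columns)
  if (length(unknown)) {
    stopf("unknown descriptor(s): %s", paste(unknown, collapse = ", "))
  }
  idx <- match(experiments$borane_id, library$borane_id)
  if (anyNA(idx)) {
    stopf("experiment borane(s) absent from library: %s",
          paste(experiments$borane_id[is.na(idx)], collapse = ", "))
  }
  X <- as.matrix(library[idx, feature_pair, drop = FALSE])
  colnames(X) <- feature_pair
  if (anyNA(X)) {
    off <- experiments$borane_id[apply(is.na(X), 1, any)]
    stopf("missing descriptor value(s) for (%s) in borane(s): %s",
          paste(feature_pair, collapse = ", "), paste(off, collapse = ", "))
  }
  y <- experiments$tof_h
  if (length(y) < 3L) stopf("dataset needs at least 3 rows, got %d", length(y))
  structure(
    list(X = unname(X), y = y, borane_ids = experiments$borane_id,
         feature_names = feature_pair),
    class = "tof_dataset"
  )
}

#' @export
print.tof_dataset <- function(x, ...) {
  cat(sprintf("TOF dataset: %d boranes, features (%s)\n",
              length(x$y), paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  TOF range [%.3g, %.3g] h^-1\n", min(x$y), max(x$y)))
  invisible(x)
}
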