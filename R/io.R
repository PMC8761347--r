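#' Read an age-indexed rate table from CSV
#'
#' The expected dialect has columns `age` (integer attained age) or
#' `age_band_start`/`age_band_end` (inclusive band), `quantity` (e.g.
#' `mortality`, `yld`, `incidence`, `fatality`, `prevalence`), and `value`.
#' Rows are validated: non-numeric or negative values raise a parse error
#' naming the offending row.
#'
#' @param path CSV file path.
#' @return a named list of data frames, one per `quantity`, each with the age
#'   columns and `value`; convert to per-cohort schedules with
#'   [schedule_from_age_table()].
#' @seealso [write_rate_table()]
#' @export
load_rate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  has_age <- "age" %in% names(df)
  has_band <- all(c("age_band_start", "age_band_end") %in% names(df))
  if (!has_age && !has_band) {
    stop(sprintf("%s: need an `age` column or `age_band_start`/`age_band_end`",
                 path), call. = FALSE)
  }
  for (col in c("quantity", "value")) {
    if (!col %in% names(df)) {
      stop(sprintf("%s: missing required column `%s`", path, col), call. = FALSE)
    }
  }
  vals <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(vals) | vals < 0)
  if (length(bad)) {
    stop(sprintf("%s: non-numeric or negative rate value in row %d ('%s')",
                 path, bad[1L], df$value[bad[1L]]), call. = FALSE)
  }
  df$value <- vals
  split(df[setdiff(names(df), "quantity")], df$quantity)
}

#' Write an age-indexed rate table to CSV
#'
#' Inverse of [load_rate_table()]: values round-trip at full double
#' precision.
#'
#' @param tables named list of data frames as returned by
#'   [load_rate_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(tables, path) {
  rows <- do.call(rbind, lapply(names(tables), function(q) {
    cbind(tables[[q]][setdiff(names(tables[[q]]), "quantity")], quantity = q)
  }))
  # full precision so load(write(x)) is bit-identical
  rows$value <- vapply(rows$value, function(v) sprintf("%.17g", v), character(1))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stratum rate-ratio table from CSV
#'
#' Columns: `stratum`, `age_band_start`, `age_band_end`, `ratio`. The
#' reference stratum (given first in `labels`, or taken as the first stratum
#' appearing in the file) must have ratio 1 in every row; ratios are constant
#' within each band and looked up by attained age.
#'
#' @param path CSV file path.
#' @param labels optional stratum ordering (reference first).
#' @return a data frame with the validated columns.
#' @seealso [ratios_from_age_table()]
#' @export
load_ratio_table <- function(path, labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum", "age_band_start", "age_band_end", "ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(df$ratio))
  bad <- which(is.na(vals) | vals <= 0)
  if (length(bad)) {
    stop(sprintf("%s: non-numeric or non-positive ratio in row %d", path, bad[1L]),
         call. = FALSE)
  }
  df$ratio <- vals
  ref <- (labels %||% unique(df$stratum))[1L]
  if (any(abs(df$ratio[df$stratum == ref] - 1) > 1e-12)) {
    stop(sprintf("%s: reference stratum '%s' must have ratio 1 in every row",
                 path, ref), call. = FALSE)
  }
  df
}

#' Build a stratum-by-cycle ratio matrix from a banded ratio table
#'
#' @param df a data frame as returned by [load_ratio_table()].
#' @param labels stratum ordering (reference first).
#' @param start_age cohort attained age in cycle 1.
#' @param horizon number of cycles.
#' @return an `n x horizon` matrix of ratios.
#' @export
ratios_from_age_table <- function(df, labels, start_age, horizon) {
  out <- matrix(NA_real_, length(labels), horizon,
                dimnames = list(labels, NULL))
  for (k in seq_along(labels)) {
    sub <- df[df$stratum == labels[k], , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop(sprintf("no ratio rows for stratum '%s'", labels[k]), call. = FALSE)
    }
    sched <- schedule_from_age_table(
      data.frame(age_band_start = sub$age_band_start,
                 age_band_end = sub$age_band_end, value = sub$ratio),
      start_age, horizon, quantity = "mortality")
    out[k, ] <- as.numeric(sched)
  }
  out
}

#' Read a model configuration file
#'
#' Reads a YAML scenario configuration (keys: `base_year`, `horizon`,
#' `cohort` with `start_age`/`N`, `scenario` with `kind` and its parameters,
#' optional `apc` blocks, file paths for rate and ratio tables). Referenced
#' CSV paths are resolved relative to the configuration file's directory and
#' must exist.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("horizon", "cohort", "scenario")) {
    if (is.null(cfg[[key]])) {
      stop(sprintf("%s: missing required config key `%s`", path, key),
           call. = FALSE)
    }
  }
  if (cfg$horizon < 1) stop("`horizon` must be >= 1", call. = FALSE)
  dir <- dirname(path)
  resolve <- function(x) {
    if (is.character(x) && length(x) == 1L && grepl("\\.csv$", x)) {
      p <- if (file.exists(x)) x else file.path(dir, x)
      if (!file.exists(p)) stop(sprintf("referenced file not found: %s", x),
                                call. = FALSE)
      return(p)
    }
    if (is.list(x)) return(lapply(x, resolve))
    x
  }
  resolve(cfg)
}

#' Write empty CSV input templates
#'
#' Creates header-only CSV files matching each input dialect (aggregate
#' rates, stratum rate ratios, disease inputs, risk-exposure categories) so
#' that externally sourced tables can be transcribed and fed to
#' [run_case_study()]. Copies of these templates ship under
#' `inst/extdata/templates`.
#'
#' @param dir output directory (created if needed).
#' @return character vector of file paths written, invisibly.
#' @export
write_input_templates <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tpl <- list(
    aggregate_rates.csv = "age,quantity,value",
    stratum_rate_ratios.csv = "stratum,age_band_start,age_band_end,ratio",
    stratum_prevalence_ratios.csv = "stratum,ratio",
    disease_inputs.csv = "age,quantity,value",
    exposure_categories.csv = "category,proportion,mean_exposure",
    rr_per_unit.csv = "disease,rr_per_unit"
  )
  paths <- character(0)
  for (nm in names(tpl)) {
    p <- file.path(dir, nm)
    writeLines(tpl[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
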