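.long_cols <- c("block_id", "drug_row", "drug_col", "conc_row", "conc_col",
                "response", "conc_unit", "replicate")

.check_scale <- function(v) {
  if (max(v, na.rm = TRUE) <= 1.5) {
    rlang::abort(paste0(
      "Viability looks fraction-scaled (max <= 1.5); this package works on ",
      "the percent scale (100 = untreated control). Rescale before reading."))
  }
}

.check_complete_grid <- function(data) {
  dup <- duplicated(data[c("block_id", "conc_row", "conc_col", "replicate")])
  if (any(dup)) rlang::abort("Duplicate (dose, dose, replicate) wells found.")
  R1 <- length(unique(data$conc_row))
  C1 <- length(unique(data$conc_col))
  counts <- dplyr::count(data, .data$block_id, .data$replicate)
  if (any(counts$n != R1 * C1)) {
    rlang::abort(sprintf(
      "Incomplete or truncated grid: expected %d wells per replicate, found %s.",
      R1 * C1, paste(unique(counts$n[counts$n != R1 * C1]), collapse = ", ")))
  }
}

#' Read a checkerboard viability dataset
#'
#' Two CSV dialects are supported:
#'
#' * `"long_table"`: one row per well with columns `block_id`, `drug_row`,
#'   `drug_col`, `conc_row`, `conc_col`, `response` (% viability),
#'   `conc_unit`, `replicate`; a single file holds all replicates.
#' * `"wide_grid"`: a concentration-labelled grid -- first column holds the
#'   row-drug concentrations, remaining column names the column-drug
#'   concentrations, cells hold % viability; one file per replicate, passed
#'   as a vector of paths.
#'
#' Readers validate rather than repair: a missing zero-dose axis, duplicate
#' wells, non-numeric cells, truncated grids and fraction-scaled viability
#' are all errors. Axes are returned sorted ascending with values permuted
#' accordingly.
#'
#' @param path File path (`long_table`) or vector of per-replicate paths
#'   (`wide_grid`).
#' @param dialect `"long_table"` or `"wide_grid"`.
#' @param drug_row,drug_col,conc_unit Metadata for the `wide_grid` dialect
#'   (the long dialect carries its own).
#' @return A [as_checkerboard()] tibble.
#' @export
read_checkerboard <- function(path, dialect = c("long_table", "wide_grid"),
                              drug_row = "drug_A", drug_col = "drug_B",
                              conc_unit = "uM") {
  dialect <- match.arg(dialect)
  if (dialect == "long_table") {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(.long_cols, names(raw))
    if (length(missing)) {
      rlang::abort(paste0("long_table is missing columns: ",
                          paste(missing, collapse = ", "), "."))
    }
    for (col in c("conc_row", "conc_col", "response", "replicate")) {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(v) & !is.na(raw[[col]]))
      if (length(bad)) {
        rlang::abort(sprintf("Non-numeric value in column `%s`, data row %d.",
                             col, bad[1]))
      }
      if (anyNA(v)) {
        rlang::abort(sprintf("Missing value in column `%s`.", col))
      }
      raw[[col]] <- v
    }
    .check_scale(raw$response)
    data <- dplyr::rename(raw, viability = "response")
    .check_complete_grid(data)
    as_checkerboard(data)
  } else {
    reps <- purrr::imap(path, function(p, r) {
      m <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
      col_doses <- suppressWarnings(as.numeric(names(m)[-1]))
      row_doses <- suppressWarnings(as.numeric(m[[1]]))
      if (anyNA(col_doses) || anyNA(row_doses)) {
        rlang::abort(sprintf("Non-numeric concentration label in %s.", p))
      }
      vals <- suppressWarnings(
        vapply(m[-1], as.numeric, numeric(nrow(m))))
      if (anyNA(vals)) {
        bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
        rlang::abort(sprintf("Non-numeric viability at grid row %d, column %d of %s.",
                             bad[1], bad[2], p))
      }
      tidyr::expand_grid(conc_row = row_doses, conc_col = col_doses) |>
        dplyr::mutate(viability = as.vector(t(vals)), replicate = r)
    })
    dims <- purrr::map(reps, ~ sort(unique(.x$conc_row)))
    if (length(unique(purrr::map_chr(dims, paste, collapse = ","))) > 1) {
      rlang::abort("Replicate files have differing dose grids.")
    }
    data <- dplyr::bind_rows(reps)
    .check_scale(data$viability)
    if (!any(data$conc_row == 0) || !any(data$conc_col == 0)) {
      rlang::abort("single-agent data required: each axis needs a zero-dose entry.")
    }
    as_checkerboard(dplyr::mutate(
      data, block_id = 1L, drug_row = drug_row, drug_col = drug_col,
      conc_unit = conc_unit))
  }
}

#' Write a checkerboard viability dataset
#'
#' Inverse of [read_checkerboard()]; `write_checkerboard()` then
#' `read_checkerboard()` round-trips exactly. For the `wide_grid` dialect one
#' file per replicate is written, `<path stem>_rep<k>.csv`.
#'
#' @param data A `checkerboard` tibble.
#' @param path Output path (for `wide_grid`, the stem used to derive the
#'   per-replicate paths).
#' @param dialect `"long_table"` or `"wide_grid"`.
#' @return Invisibly, the path(s) written.
#' @export
write_checkerboard <- function(data, path,
                               dialect = c("long_table", "wide_grid")) {
  dialect <- match.arg(dialect)
  data <- as_checkerboard(data)
  if (dialect == "long_table") {
    out <- data |>
      dplyr::rename(response = "viability") |>
      dplyr::select(dplyr::all_of(.long_cols))
    readr::write_csv(out, path)
    invisible(path)
  } else {
    stem <- sub("\\.csv$", "", path)
    reps <- sort(unique(data$replicate))
    paths <- purrr::map_chr(reps, function(r) {
      p <- sprintf("%s_rep%d.csv", stem, r)
      wide <- data |>
        dplyr::filter(.data$replicate == r) |>
        dplyr::select("conc_row", "conc_col", "viability") |>
        tidyr::pivot_wider(names_from = "conc_col", values_from = "viability") |>
        dplyr::arrange(.data$conc_row)
      readr::write_csv(wide, p)
      p
    })
    invisible(paths)
  }
}

#' Write a full analysis report to disk
#'
#' Emits a deterministic, versioned JSON report (scores, shifts,
#' classifications, fitted parameters, settings in effect), one CSV grid per
#' reference surface, and one delta-heatmap PNG per regime and model.
#' Wall-clock metadata goes to a separate sidecar so the JSON is
#' byte-identical across reruns on the same input.
#'
#' @param analysis A [run_full_analysis()] result.
#' @param dir Output directory (created if needed).
#' @param figures Also render heatmap PNGs (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(analysis, dir, figures = TRUE) {
  stopifnot(inherits(analysis, "synergy_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    rlang::abort(sprintf("Cannot write to `%s`.", dir))
  }
  report <- list(
    schema_version = "1.0",
    drug_row = analysis$drug_row,
    drug_col = analysis$drug_col,
    conc_unit = analysis$conc_unit,
    settings = analysis$settings,
    fits = purrr::map(analysis$fits,
                      ~ purrr::map(.x, function(f) glance(f))),
    scores = analysis$report,
    shifts = analysis$shifts
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  writeLines(format(Sys.time(), tz = "UTC"), file.path(dir, "run_time.txt"))

  paths <- json_path
  for (regime in names(analysis$surfaces)) {
    for (model in names(analysis$surfaces[[regime]])) {
      p <- file.path(dir, sprintf("surface_%s_%s.csv", regime, model))
      wide <- tibble::as_tibble(analysis$surfaces[[regime]][[model]]) |>
        dplyr::select("conc_row", "conc_col", "expected") |>
        tidyr::pivot_wider(names_from = "conc_col", values_from = "expected") |>
        dplyr::arrange(.data$conc_row)
      readr::write_csv(wide, p)
      paths <- c(paths, p)
      if (figures) {
        fp <- file.path(dir, sprintf("delta_%s_%s.png", regime, model))
        ggplot2::ggsave(fp,
                        ggplot2::autoplot(analysis$results[[regime]][[model]]),
                        width = 6, height = 5, dpi = 120)
        paths <- c(paths, fp)
      }
    }
  }
  invisible(paths)
}
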