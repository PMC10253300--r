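#' Construct a checkerboard viability dataset
#'
#' A checkerboard dataset is a tidy tibble with one row per well: all pairwise
#' combinations of the two drugs' concentration grids, plus single-agent rows
#' and columns (the other drug at dose 0) and the untreated control at
#' (0, 0), replicated. Viability is expressed as % of the untreated control.
#'
#' @param data A data frame with columns `block_id`, `drug_row`, `drug_col`,
#'   `conc_row`, `conc_col`, `replicate`, `viability`, `conc_unit`.
#' @return A tibble of class `checkerboard`.
#' @export
as_checkerboard <- function(data) {
  req <- c("block_id", "drug_row", "drug_col", "conc_row", "conc_col",
           "replicate", "viability", "conc_unit")
  missing <- setdiff(req, names(data))
  if (length(missing)) {
    rlang::abort(paste0("Missing columns: ", paste(missing, collapse = ", "), "."))
  }
  data <- tibble::as_tibble(data)[req]
  if (!is.numeric(data$conc_row) || !is.numeric(data$conc_col) ||
      !is.numeric(data$viability)) {
    rlang::abort("`conc_row`, `conc_col` and `viability` must be numeric.")
  }
  if (any(!is.finite(data$viability))) rlang::abort("Non-finite viability values.")
  if (any(data$conc_row < 0) || any(data$conc_col < 0)) {
    rlang::abort("Concentrations must be non-negative.")
  }
  if (!any(data$conc_row == 0) || !any(data$conc_col == 0)) {
    rlang::abort("single-agent data required: each axis needs a zero-dose entry.")
  }
  dup <- duplicated(data[c("block_id", "conc_row", "conc_col", "replicate")])
  if (any(dup)) {
    rlang::abort("Duplicate (dose, dose, replicate) wells found.")
  }
  data <- dplyr::arrange(data, .data$replicate, .data$conc_row, .data$conc_col)
  tibble::new_tibble(data, class = "checkerboard")
}

#' @export
print.checkerboard <- function(x, ...) {
  cat(sprintf("<checkerboard> %s x %s, %d x %d doses (+controls), %d replicate(s) [%s]\n",
              x$drug_row[1], x$drug_col[1],
              sum(unique(x$conc_row) > 0), sum(unique(x$conc_col) > 0),
              length(unique(x$replicate)), x$conc_unit[1]))
  NextMethod()
}

#' Dose grids of a checkerboard
#'
#' @param data A `checkerboard` tibble.
#' @param margin `"row"` or `"col"`.
#' @param include_zero Keep the zero-dose (single-agent axis) entry.
#' @return Increasing numeric vector of concentrations.
#' @export
cb_doses <- function(data, margin = c("row", "col"), include_zero = FALSE) {
  margin <- match.arg(margin)
  d <- sort(unique(data[[paste0("conc_", margin)]]))
  if (!include_zero) d <- d[d > 0]
  d
}

#' Subset the combination cells (both doses positive) of a checkerboard
#' @param data A `checkerboard` tibble.
#' @return A tibble of combination wells only.
#' @export
cb_combinations <- function(data) {
  dplyr::filter(tibble::as_tibble(data), .data$conc_row > 0, .data$conc_col > 0)
}

#' Extract single-agent wells for one drug
#'
#' Returns the wells where the other drug is at dose 0, including the shared
#' untreated control, as a `dose` / `viability` / `replicate` table ready for
#' [fit_hill()].
#'
#' @inheritParams cb_doses
#' @return A tibble with columns `dose`, `viability`, `replicate`.
#' @export
cb_single_agent <- function(data, margin = c("row", "col")) {
  margin <- match.arg(margin)
  other <- if (margin == "row") "conc_col" else "conc_row"
  tibble::as_tibble(data) |>
    dplyr::filter(.data[[other]] == 0) |>
    dplyr::transmute(dose = .data[[paste0("conc_", margin)]],
                     viability = .data$viability,
                     replicate = .data$replicate)
}

.check_sim_doses <- function(doses, what) {
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE)) {
    rlang::abort(sprintf("`%s` must be strictly increasing and positive.", what))
  }
}

#' Simulate a checkerboard viability dataset with known ground truth
#'
#' Generates replicate % viability over the full (zero-dose augmented)
#' checkerboard grid. Single-agent truth comes from the two 4PL parameter
#' sets; combination truth is the chosen null-model expectation of the two
#' true curves (computed with the same surface formulas the analysis uses, so
#' with no noise and no offset the generated data are an exact fixed point of
#' their own analysis) minus `interaction_offset`. Each well then receives
#' independent Gaussian noise, and observations are optionally clipped to the
#' physical \[0, 100\] range -- offsets model biology and are applied before
#' clipping, which models the assay floor.
#'
#' @param row_params,col_params [hill_params()] ground-truth curves.
#' @param row_doses,col_doses Strictly increasing positive dose grids
#'   (defaults: the presets' 9-point base-2 series when params came from
#'   [drug_preset()] are passed explicitly via [preset_doses()]).
#' @param null_model `"hsa"`, `"loewe"` or `"bliss"`: the interaction null
#'   under which combination truth is generated.
#' @param interaction_offset R x C matrix of % viability subtracted from the
#'   null surface at combination cells (positive = injected synergy), or a
#'   scalar recycled to the grid. Default 0.
#' @param noise_sd Gaussian well noise SD in % viability (default 5, the
#'   scale of typical replicate scatter in resazurin viability assays).
#' @param n_replicates Number of independent replicates (default 4).
#' @param clip_observations Clip emitted viabilities into \[0, 100\]
#'   (default `TRUE`).
#' @param seed Integer seed; the dataset is bit-reproducible for a fixed seed.
#' @param drug_row,drug_col Drug names carried in the output.
#' @param conc_unit Concentration unit string (default `"uM"`).
#'
#' @return A [as_checkerboard()] tibble.
#' @export
simulate_checkerboard <- function(row_params, col_params,
                                  row_doses, col_doses,
                                  null_model = c("bliss", "hsa", "loewe"),
                                  interaction_offset = 0,
                                  noise_sd = 5, n_replicates = 4,
                                  clip_observations = TRUE, seed = 1,
                                  drug_row = "drug_A", drug_col = "drug_B",
                                  conc_unit = "uM") {
  null_model <- match.arg(null_model)
  stopifnot(inherits(row_params, "hill_params"), inherits(col_params, "hill_params"))
  .check_sim_doses(row_doses, "row_doses")
  .check_sim_doses(col_doses, "col_doses")
  if (noise_sd < 0) rlang::abort("`noise_sd` must be >= 0.")
  if (n_replicates < 1) rlang::abort("`n_replicates` must be >= 1.")
  R <- length(row_doses); C <- length(col_doses)
  if (length(interaction_offset) == 1) {
    interaction_offset <- matrix(interaction_offset, R, C)
  }
  if (!all(dim(interaction_offset) == c(R, C))) {
    rlang::abort(sprintf("`interaction_offset` must be a %d x %d matrix.", R, C))
  }

  d1 <- c(0, row_doses); d2 <- c(0, col_doses)
  truth <- .expected_grid(row_params, col_params, d1, d2, null_model,
                          clip = TRUE)$expected
  # zero-dose axes are single agents by construction
  truth[1, ] <- hill_viability(col_params, d2)
  truth[, 1] <- hill_viability(row_params, d1)
  truth[1, 1] <- 100
  truth[-1, -1] <- truth[-1, -1] - interaction_offset

  grid <- tidyr::expand_grid(conc_row = d1, conc_col = d2)
  idx <- cbind(match(grid$conc_row, d1), match(grid$conc_col, d2))
  truth_vec <- truth[idx]

  wells <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      v <- truth_vec + stats::rnorm(length(truth_vec), 0, noise_sd)
      if (clip_observations) v <- .clip01(v)
      dplyr::mutate(grid, replicate = r, viability = v)
    })
  })
  as_checkerboard(dplyr::mutate(
    wells,
    block_id = 1L, drug_row = drug_row, drug_col = drug_col,
    conc_unit = conc_unit
  ))
}

#' Simulate an extreme (fully synergistic or fully antagonistic) checkerboard
#'
#' The yardstick datasets used for score normalization: single-agent rows and
#' columns follow the noise-free 4PL curves, while every combination cell
#' (both doses positive) is exactly 0% viability (`"synergistic"`) or exactly
#' 100% (`"antagonistic"`), replicated identically without noise so the
#' derived normalization constants are deterministic.
#'
#' @param direction `"synergistic"` or `"antagonistic"`.
#' @inheritParams simulate_checkerboard
#' @return A [as_checkerboard()] tibble.
#' @export
extreme_checkerboard <- function(direction = c("synergistic", "antagonistic"),
                                 row_params, col_params,
                                 row_doses, col_doses, n_replicates = 4,
                                 drug_row = "drug_A", drug_col = "drug_B",
                                 conc_unit = "uM") {
  direction <- match.arg(direction)
  stopifnot(inherits(row_params, "hill_params"), inherits(col_params, "hill_params"))
  .check_sim_doses(row_doses, "row_doses")
  .check_sim_doses(col_doses, "col_doses")
  d1 <- c(0, row_doses); d2 <- c(0, col_doses)
  combo_value <- if (direction == "synergistic") 0 else 100
  grid <- tidyr::expand_grid(conc_row = d1, conc_col = d2)
  v <- dplyr::case_when(
    grid$conc_row == 0 & grid$conc_col == 0 ~ 100,
    grid$conc_col == 0 ~ hill_viability(row_params, grid$conc_row),
    grid$conc_row == 0 ~ hill_viability(col_params, grid$conc_col),
    TRUE ~ combo_value
  )
  wells <- purrr::map_dfr(seq_len(n_replicates),
                          ~ dplyr::mutate(grid, replicate = .x, viability = v))
  as_checkerboard(dplyr::mutate(
    wells,
    block_id = 1L, drug_row = drug_row, drug_col = drug_col,
    conc_unit = conc_unit
  ))
}
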