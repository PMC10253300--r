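.tol_zero <- 1e-9

# one-sample two-sided p-values against 0 for each cell's replicate deltas
.p_t_test <- function(deltas) {
  m <- mean(deltas)
  s <- stats::sd(deltas)
  if (length(deltas) < 2) {
    rlang::warn("Single replicate: no inference possible, p = 1.")
    return(1)
  }
  if (!is.finite(s) || s < .tol_zero) {
    # degenerate zero-variance limit (noise-free fixtures): any non-zero
    # mean delta is maximally significant
    return(if (abs(m) > .tol_zero) 0 else 1)
  }
  stats::t.test(deltas)$p.value
}

.p_bootstrap <- function(deltas, B) {
  n <- length(deltas)
  if (n < 2) {
    rlang::warn("Single replicate: no inference possible, p = 1.")
    return(1)
  }
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  means <- rowMeans(matrix(deltas[idx], nrow = B))
  p <- 2 * min(mean(means <= 0), mean(means >= 0))
  min(1, max(p, 1 / B))
}

#' Per-point significance of replicate deltas
#'
#' Two-sided one-sample test of each cell's replicate deltas against 0.
#' `"t_test"` is Student's t with a degenerate-variance limit: when the
#' replicate deltas are (numerically) identical, p is 0 for a non-zero mean
#' delta and 1 otherwise, so noise-free extreme fixtures are maximally
#' significant. `"bootstrap"` resamples the replicate deltas with replacement
#' `B` times; p is the two-sided tail proportion of resampled mean deltas
#' crossing 0, floored at `1/B`.
#'
#' @param deltas A numeric vector of one cell's replicate deltas, or a list
#'   of such vectors (one per cell).
#' @param method `"t_test"` or `"bootstrap"`.
#' @param B Bootstrap resamples.
#' @param seed Integer seed (bootstrap only).
#' @return Numeric p-value(s), one per cell.
#' @export
point_significance <- function(deltas, method = c("t_test", "bootstrap"),
                               B = 1000, seed = 1) {
  method <- match.arg(method)
  if (!is.list(deltas)) deltas <- list(deltas)
  if (method == "t_test") {
    purrr::map_dbl(deltas, .p_t_test)
  } else {
    withr::with_seed(seed, purrr::map_dbl(deltas, .p_bootstrap, B = B))
  }
}

#' Per-point deltas and significance against a reference surface
#'
#' Compares observed combination viability to a reference surface point by
#' point over the combination cells (both doses positive; single-agent axes
#' are excluded). The delta at a cell is `expected - mean(observed)` in %
#' viability, so positive deltas mean the combination killed more cells than
#' the null model predicts (synergy) and negative deltas mean antagonism.
#' Per-cell significance comes from a two-sided one-sample test of the
#' replicate deltas against 0: Student's t (`"t_test"`) or a resampling test
#' (`"bootstrap"`, replicate wells resampled with replacement, two-sided tail
#' proportion of resampled mean deltas crossing 0, floored at `1/B`).
#'
#' Matrix-level scores under both conventions are attached:
#' `mean_score` is the arithmetic mean of delta over all combination cells;
#' `weighted_score` is the significance-gated signed sum divided by the same
#' cell count (non-significant cells contribute 0), which credits synergistic
#' and penalizes antagonistic cells while ignoring noise-level cells, and
#' reduces exactly to `mean_score` when every cell is significant.
#'
#' @param data A `checkerboard` tibble with >= 1 replicate.
#' @param surface A [reference_surface()] on the same combination dose grids.
#' @param method `"t_test"` or `"bootstrap"`.
#' @param B Bootstrap resamples (default 1000).
#' @param alpha Per-point significance level (default 0.05, no
#'   multiple-testing correction by default, matching the flat p < 0.05 rule
#'   common in checkerboard software).
#' @param p_adjust Optional [stats::p.adjust()] method applied across cells
#'   (default `"none"`).
#' @param seed Integer seed for the bootstrap (ignored for the t-test).
#' @param thresholds Length-2 additive band `c(t_ant, t_syn)` on the raw
#'   score, default `c(-5, 5)` % viability, used for the attached
#'   classification.
#'
#' @return A tibble of class `synergy_result` with one row per combination
#'   cell (`conc_row`, `conc_col`, `expected`, `observed`, `delta`,
#'   `p_value`, `significant`) and attributes `model`, `regime`, `method`,
#'   `alpha`, `mean_score`, `weighted_score`, `classification`,
#'   `replicate_deltas`. See [glance.synergy_result()].
#' @export
score_synergy <- function(data, surface, method = c("t_test", "bootstrap"),
                          B = 1000, alpha = 0.05, p_adjust = "none",
                          seed = 1, thresholds = c(-5, 5)) {
  method <- match.arg(method)
  stopifnot(inherits(surface, "reference_surface"))
  combos <- cb_combinations(data)
  surf_tbl <- tibble::as_tibble(surface)

  obs_doses_r <- sort(unique(combos$conc_row))
  obs_doses_c <- sort(unique(combos$conc_col))
  mis_r <- setdiff(union(obs_doses_r, unique(surf_tbl$conc_row)),
                   intersect(obs_doses_r, unique(surf_tbl$conc_row)))
  mis_c <- setdiff(union(obs_doses_c, unique(surf_tbl$conc_col)),
                   intersect(obs_doses_c, unique(surf_tbl$conc_col)))
  if (length(mis_r) || length(mis_c)) {
    rlang::abort(paste0(
      "Dataset and surface dose grids differ. Offending doses: ",
      paste(signif(c(mis_r, mis_c), 4), collapse = ", "), "."
    ))
  }

  rep_deltas <- combos |>
    dplyr::inner_join(surf_tbl, by = c("conc_row", "conc_col")) |>
    dplyr::mutate(delta = .data$expected - .data$viability)

  cells <- rep_deltas |>
    dplyr::summarise(
      expected = .data$expected[1],
      observed = mean(.data$viability),
      deltas = list(.data$delta),
      delta = mean(.data$delta),
      .by = c("conc_row", "conc_col")
    )

  if (method == "t_test") {
    cells$p_value <- purrr::map_dbl(cells$deltas, .p_t_test)
  } else {
    cells$p_value <- withr::with_seed(
      seed, purrr::map_dbl(cells$deltas, .p_bootstrap, B = B))
  }
  cells$p_value <- stats::p.adjust(cells$p_value, method = p_adjust)
  cells$significant <- cells$p_value < alpha

  mean_score <- mean(cells$delta)
  weighted_score <- sum(cells$delta[cells$significant]) / nrow(cells)
  out <- dplyr::select(cells, -"deltas") |>
    dplyr::arrange(.data$conc_row, .data$conc_col)
  structure(
    tibble::new_tibble(out, class = "synergy_result"),
    model = attr(surface, "model"),
    regime = attr(surface, "regime"),
    method = method, alpha = alpha,
    mean_score = mean_score,
    weighted_score = weighted_score,
    classification = classify_score(mean_score, thresholds),
    thresholds = thresholds,
    replicate_deltas = rep_deltas[c("conc_row", "conc_col", "replicate", "delta")]
  )
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf(
    "<synergy_result> model=%s regime=%s method=%s: mean=%.3f weighted=%.3f (%s)\n",
    attr(x, "model"), attr(x, "regime"), attr(x, "method"),
    attr(x, "mean_score"), attr(x, "weighted_score"), attr(x, "classification")))
  NextMethod()
}

#' Matrix-level score of a synergy result
#'
#' @param result A [score_synergy()] result.
#' @param convention `"mean"` (plain average of per-cell deltas) or
#'   `"weighted"` (significance-gated signed sum over the cell count).
#' @return A single score in % viability units; positive = synergistic
#'   tendency.
#' @export
matrix_score <- function(result, convention = c("mean", "weighted")) {
  convention <- match.arg(convention)
  stopifnot(inherits(result, "synergy_result"))
  attr(result, paste0(convention, "_score"))
}

#' Classify a matrix score into synergistic / additive / antagonistic
#'
#' Strict inequalities: a score exactly on a threshold is additive.
#'
#' @param score Numeric score(s), raw (% viability) or normalized.
#' @param thresholds `c(t_ant, t_syn)` with `t_ant < 0 < t_syn`. Defaults to
#'   the symmetric small band `c(-5, 5)` on raw scores; use `c(-0.05, 0.05)`
#'   for normalized scores.
#' @return Character vector in `{"synergistic", "additive", "antagonistic"}`.
#' @export
classify_score <- function(score, thresholds = c(-5, 5)) {
  if (!(thresholds[1] < 0 && thresholds[2] > 0)) {
    rlang::abort("`thresholds` must satisfy t_ant < 0 < t_syn.")
  }
  dplyr::case_when(
    score > thresholds[2] ~ "synergistic",
    score < thresholds[1] ~ "antagonistic",
    TRUE ~ "additive"
  )
}

#' @describeIn score_synergy One-row summary with both matrix scores.
#' @param x A `synergy_result`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.synergy_result <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model"), regime = attr(x, "regime"),
    method = attr(x, "method"), alpha = attr(x, "alpha"),
    mean_score = attr(x, "mean_score"),
    weighted_score = attr(x, "weighted_score"),
    classification = attr(x, "classification"),
    n_cells = nrow(x), n_significant = sum(x$significant)
  )
}
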