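#' Extreme-matrix normalization constants
#'
#' Scores of the two simulated extreme checkerboards -- every combination
#' cell at 0% viability (fully synergistic) or at 100% (fully antagonistic),
#' with single agents following the supplied fitted curves -- under one
#' (model, convention) pair. Raw matrix scores are later divided by these
#' constants so the extremes map to exactly +1 and -1, putting differently
#' scaled scoring conventions on one axis. The extremes are noise-free, so
#' the constants are deterministic; they reuse the analysis' own fitted
#' single-agent curves (per regime), keeping the normalization
#' regime-consistent.
#'
#' @param fit_row,fit_col Converged [fit_hill()] objects.
#' @param row_doses,col_doses Positive combination dose grids.
#' @param model `"hsa"`, `"loewe"` or `"bliss"`.
#' @param convention `"mean"` or `"weighted"`. On noise-free extremes every
#'   cell with a non-zero delta is maximally significant, so the two
#'   conventions give identical constants; both are supported for symmetry.
#' @param alpha,clip,tol Passed through to scoring and surface construction.
#' @return An object of class `normalization_constants`: list with `s_syn`
#'   (> 0), `s_ant` (< 0), `model`, `convention`, `fits`, dose grids.
#' @export
normalization_constants <- function(fit_row, fit_col, row_doses, col_doses,
                                    model = c("hsa", "loewe", "bliss"),
                                    convention = c("mean", "weighted"),
                                    alpha = 0.05, clip = TRUE, tol = 1e-6) {
  model <- match.arg(model)
  convention <- match.arg(convention)
  surface <- reference_surface(fit_row, fit_col, row_doses, col_doses,
                               model = model, clip = clip, tol = tol)
  score_extreme <- function(direction) {
    extreme <- extreme_checkerboard(direction,
                                    row_params = fit_row$params,
                                    col_params = fit_col$params,
                                    row_doses = row_doses, col_doses = col_doses,
                                    n_replicates = 2)
    matrix_score(score_synergy(extreme, surface, method = "t_test",
                               alpha = alpha),
                 convention = convention)
  }
  s_syn <- score_extreme("synergistic")
  s_ant <- score_extreme("antagonistic")
  if (s_syn <= 0 || s_ant >= 0) {
    rlang::abort("extreme datasets do not separate (degenerate single-agent curves).")
  }
  structure(
    list(model = model, convention = convention, s_syn = s_syn, s_ant = s_ant,
         fits = list(row = fit_row, col = fit_col),
         row_doses = row_doses, col_doses = col_doses),
    class = "normalization_constants"
  )
}

#' @export
print.normalization_constants <- function(x, ...) {
  cat(sprintf("<normalization_constants> model=%s convention=%s s_syn=%.3f s_ant=%.3f\n",
              x$model, x$convention, x$s_syn, x$s_ant))
  invisible(x)
}

#' Normalize a raw matrix score against the extreme-matrix constants
#'
#' Direction-matched scaling: non-negative raw scores are divided by the
#' fully-synergistic constant, negative raw scores by the magnitude of the
#' fully-antagonistic constant, so the two anchors map to +1 and -1, sign and
#' rank order are preserved, and any achievable score on the same grid lands
#' in \[-1, 1\].
#'
#' @param score Numeric raw score(s) from [matrix_score()].
#' @param constants A [normalization_constants()] object from the same grid
#'   and fits.
#' @return Normalized score(s) in \[-1, 1\].
#' @export
normalize_score <- function(score, constants) {
  stopifnot(inherits(constants, "normalization_constants"))
  out <- ifelse(score >= 0, score / constants$s_syn, score / abs(constants$s_ant))
  if (any(abs(out) > 1 + 1e-6)) {
    rlang::abort("Normalized score outside [-1, 1]: constants come from a different grid or fits.")
  }
  out
}

.fit_both_margins <- function(data, regime) {
  list(row = fit_hill(cb_single_agent(data, "row"), regime = regime),
       col = fit_hill(cb_single_agent(data, "col"), regime = regime))
}

#' Regime shift of a synergy score
#'
#' Runs the full chain (single-agent fits, reference surface, per-point
#' scoring, extreme-matrix normalization) twice on one dataset -- once per
#' fitting regime -- and reports how the matrix score and its classification
#' move. The two runs differ *only* in the single-agent fits, isolating the
#' fitting-induced component of score differences between analysis
#' conventions.
#'
#' @param data A `checkerboard` tibble with >= 2 replicates.
#' @param model `"hsa"`, `"loewe"` or `"bliss"`.
#' @param convention `"mean"` or `"weighted"`.
#' @param method,B,alpha,seed Passed to [score_synergy()].
#' @param thresholds Raw-score additive band, default `c(-5, 5)` % viability.
#' @param norm_thresholds Normalized-score additive band, default
#'   `c(-0.05, 0.05)`.
#' @param clip,tol Passed to [reference_surface()].
#' @return One-row tibble: raw and normalized scores under both regimes,
#'   `score_shift` (constrained - unconstrained, raw) and `norm_shift`,
#'   classifications under each regime on both scales, and `flip_raw` /
#'   `flip_norm` flags marking a classification change between regimes.
#' @export
regime_shift <- function(data, model = c("hsa", "loewe", "bliss"),
                         convention = c("mean", "weighted"),
                         method = c("t_test", "bootstrap"), B = 1000,
                         alpha = 0.05, seed = 1,
                         thresholds = c(-5, 5),
                         norm_thresholds = c(-0.05, 0.05),
                         clip = TRUE, tol = 1e-6) {
  model <- match.arg(model)
  convention <- match.arg(convention)
  method <- match.arg(method)
  row_doses <- cb_doses(data, "row")
  col_doses <- cb_doses(data, "col")

  one_regime <- function(regime) {
    fits <- .fit_both_margins(data, regime)
    surface <- reference_surface(fits$row, fits$col, row_doses, col_doses,
                                 model = model, clip = clip, tol = tol)
    result <- score_synergy(data, surface, method = method, B = B,
                            alpha = alpha, seed = seed, thresholds = thresholds)
    constants <- normalization_constants(fits$row, fits$col, row_doses,
                                         col_doses, model = model,
                                         convention = convention,
                                         alpha = alpha, clip = clip, tol = tol)
    raw <- matrix_score(result, convention)
    list(raw = raw, norm = normalize_score(raw, constants))
  }
  un <- one_regime("unconstrained")
  co <- one_regime("constrained")
  cls <- function(s, thr) classify_score(s, thr)
  out <- tibble::tibble(
    model = model, convention = convention,
    score_unconstrained = un$raw, score_constrained = co$raw,
    norm_unconstrained = un$norm, norm_constrained = co$norm,
    score_shift = co$raw - un$raw,
    norm_shift = co$norm - un$norm,
    class_raw_unconstrained = cls(un$raw, thresholds),
    class_raw_constrained = cls(co$raw, thresholds),
    class_norm_unconstrained = cls(un$norm, norm_thresholds),
    class_norm_constrained = cls(co$norm, norm_thresholds)
  )
  dplyr::mutate(
    out,
    flip_raw = .data$class_raw_unconstrained != .data$class_raw_constrained,
    flip_norm = .data$class_norm_unconstrained != .data$class_norm_constrained
  )
}

#' Full checkerboard synergy analysis under every model, regime and convention
#'
#' The pipeline entry point: fits both regimes' single-agent curves, builds
#' the three reference surfaces per regime, scores every surface per point,
#' normalizes against the extreme matrices, and assembles a long report over
#' model x regime x convention together with the per-(model, convention)
#' regime shifts and classification flips.
#'
#' @inheritParams regime_shift
#' @return An object of class `synergy_analysis`: list with `fits` (per
#'   regime), `surfaces` (per regime x model), `results`
#'   ([score_synergy()] objects per regime x model), `report` (long tibble:
#'   model, regime, convention, raw and normalized score, classifications),
#'   and `shifts` (the [regime_shift()]-style tibble per model x convention).
#'   `tidy()` returns the report, `glance()` the shifts.
#' @export
run_full_analysis <- function(data, method = c("t_test", "bootstrap"),
                              B = 1000, alpha = 0.05, seed = 1,
                              thresholds = c(-5, 5),
                              norm_thresholds = c(-0.05, 0.05),
                              clip = TRUE, tol = 1e-6) {
  method <- match.arg(method)
  row_doses <- cb_doses(data, "row")
  col_doses <- cb_doses(data, "col")
  regimes <- c("unconstrained", "constrained")
  models <- .synergy_models
  conventions <- c("mean", "weighted")

  fits <- purrr::map(rlang::set_names(regimes),
                     ~ .fit_both_margins(data, .x))
  surfaces <- purrr::map(fits, function(f) {
    purrr::map(rlang::set_names(models),
               ~ reference_surface(f$row, f$col, row_doses, col_doses,
                                   model = .x, clip = clip, tol = tol))
  })
  results <- purrr::map(surfaces, function(s) {
    purrr::map(s, ~ score_synergy(data, .x, method = method, B = B,
                                  alpha = alpha, seed = seed,
                                  thresholds = thresholds))
  })
  constants <- purrr::map(fits, function(f) {
    purrr::map(rlang::set_names(models), function(m) {
      purrr::map(rlang::set_names(conventions),
                 ~ normalization_constants(f$row, f$col, row_doses, col_doses,
                                           model = m, convention = .x,
                                           alpha = alpha, clip = clip,
                                           tol = tol))
    })
  })

  report <- tidyr::expand_grid(model = models, regime = regimes,
                               convention = conventions) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      raw_score = matrix_score(results[[.data$regime]][[.data$model]],
                               .data$convention),
      normalized_score = normalize_score(
        .data$raw_score,
        constants[[.data$regime]][[.data$model]][[.data$convention]]),
      classification = classify_score(.data$raw_score, thresholds),
      classification_norm = classify_score(.data$normalized_score,
                                           norm_thresholds)
    ) |>
    dplyr::ungroup()

  shifts <- report |>
    tidyr::pivot_wider(names_from = "regime",
                       values_from = c("raw_score", "normalized_score",
                                       "classification",
                                       "classification_norm")) |>
    dplyr::mutate(
      score_shift = .data$raw_score_constrained - .data$raw_score_unconstrained,
      norm_shift = .data$normalized_score_constrained -
        .data$normalized_score_unconstrained,
      flip_raw = .data$classification_constrained !=
        .data$classification_unconstrained,
      flip_norm = .data$classification_norm_constrained !=
        .data$classification_norm_unconstrained
    )

  structure(
    list(drug_row = data$drug_row[1], drug_col = data$drug_col[1],
         conc_unit = data$conc_unit[1],
         settings = list(method = method, B = B, alpha = alpha, seed = seed,
                         thresholds = thresholds,
                         norm_thresholds = norm_thresholds, clip = clip,
                         tol = tol),
         fits = fits, surfaces = surfaces, results = results,
         report = report, shifts = shifts),
    class = "synergy_analysis"
  )
}

#' @export
print.synergy_analysis <- function(x, ...) {
  cat(sprintf("<synergy_analysis> %s x %s\n", x$drug_row, x$drug_col))
  print(x$report)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.synergy_analysis <- function(x, ...) x$report

#' @exportS3Method generics::glance
glance.synergy_analysis <- function(x, ...) x$shifts

#' Separation between synergistic and antagonistic dataset panels
#'
#' For each scoring convention, the distance between the mean normalized
#' score of a designated synergistic panel and that of an antagonistic panel,
#' computed on identical inputs. A convention that gates out noise-level
#' cells (the weighted convention) concentrates the score on the real signal
#' and typically widens this distance without changing the rank order of the
#' datasets.
#'
#' @param panel A tibble with columns `dataset` (identifier), `direction`
#'   (`"synergistic"` or `"antagonistic"`), `convention`, `normalized_score`
#'   -- e.g. from [separation_panel()].
#' @return A tibble with one row per convention: `separation` = mean
#'   normalized score (synergistic) - mean normalized score (antagonistic).
#' @export
separation_statistic <- function(panel) {
  panel <- tibble::as_tibble(panel)
  req <- c("dataset", "direction", "convention", "normalized_score")
  stopifnot(all(req %in% names(panel)))
  counts <- table(panel$direction)
  if (!all(c("synergistic", "antagonistic") %in% names(counts))) {
    rlang::abort("Panel needs at least one dataset per direction.")
  }
  panel |>
    dplyr::summarise(
      separation = mean(.data$normalized_score[.data$direction == "synergistic"]) -
        mean(.data$normalized_score[.data$direction == "antagonistic"]),
      .by = "convention"
    )
}

#' Simulated six-dataset panel of synergistic and antagonistic checkerboards
#'
#' Builds and scores the designated panel used to compare scoring
#' conventions: three synergistic and three antagonistic checkerboards on one
#' drug pair, each carrying a strong localized interaction (a 5 x 5 mid-dose
#' block of graded offset `sizes`) on top of a weak opposite-signed
#' background (2% viability) that sits within noise -- the configuration
#' where a plain mean is diluted by noise-level cells while the
#' significance-gated convention is not. The graded sizes keep the six
#' datasets' scores well separated so their rank order is stable under
#' replicate noise.
#'
#' @param seed Integer master seed.
#' @param sizes Block offset magnitudes for the three datasets per direction
#'   (% viability).
#' @param noise_sd,n_replicates Generator noise settings.
#' @param model,method,alpha Analysis settings (unconstrained regime).
#' @return A panel tibble suitable for [separation_statistic()], with one row
#'   per dataset x convention.
#' @export
separation_panel <- function(seed = 1, sizes = c(40, 26, 12), noise_sd = 5,
                             n_replicates = 4, model = "bliss",
                             method = "t_test", alpha = 0.05) {
  p_row <- drug_preset("indomethacin_like")
  p_col <- drug_preset("carboplatin_like")
  d_row <- preset_doses("indomethacin_like")
  d_col <- preset_doses("carboplatin_like")
  block <- matrix(0, 9, 9)
  block[3:7, 3:7] <- 1

  one <- function(size, direction, k) {
    sgn <- if (direction == "synergistic") 1 else -1
    offset <- sgn * (size * block - 2 * (1 - block))
    data <- simulate_checkerboard(
      p_row, p_col, d_row, d_col, null_model = model,
      interaction_offset = offset, noise_sd = noise_sd,
      n_replicates = n_replicates, seed = seed + k,
      drug_row = "indomethacin_like", drug_col = "carboplatin_like")
    fits <- .fit_both_margins(data, "unconstrained")
    surface <- reference_surface(fits$row, fits$col, d_row, d_col,
                                 model = model)
    result <- score_synergy(data, surface, method = method, alpha = alpha,
                            seed = seed + k)
    purrr::map_dfr(rlang::set_names(c("mean", "weighted")), function(conv) {
      constants <- normalization_constants(fits$row, fits$col, d_row, d_col,
                                           model = model, convention = conv,
                                           alpha = alpha)
      raw <- matrix_score(result, conv)
      tibble::tibble(
        dataset = sprintf("%s_%d", direction, k),
        direction = direction, convention = conv,
        raw_score = raw,
        normalized_score = normalize_score(raw, constants))
    })
  }
  purrr::map_dfr(seq_along(sizes), function(i) {
    dplyr::bind_rows(one(sizes[i], "synergistic", i),
                     one(sizes[i], "antagonistic", i + length(sizes)))
  })
}
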