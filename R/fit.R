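#' @importFrom generics tidy glance augment
#' @export
generics::tidy
#' @export
generics::glance
#' @export
generics::augment

# unchecked constructor for fitted parameter sets (noisy flat data can land
# with emax marginally above emin; user-facing hill_params() stays strict)
.new_hill_params <- function(emin, emax, ec50, h) {
  structure(list(emin = emin, emax = emax, ec50 = ec50, h = h),
            class = "hill_params")
}

.regime_bounds <- function(regime) {
  if (regime == "constrained") {
    # plateaus boxed into the physical 0-100% viability band
    list(lower = c(emin = 0, emax = 0, lec = -Inf, h = 0.05),
         upper = c(emin = 100, emax = 100, lec = Inf, h = 20))
  } else {
    # lower plateau free (may fall below 0); upper plateau softly anchored
    # near the untreated control since viability is normalized to it
    list(lower = c(emin = 80, emax = -1000, lec = -Inf, h = 0.05),
         upper = c(emin = 120, emax = 120, lec = Inf, h = 20))
  }
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of `v(d) = emax + (emin - emax) / (1 + (d/ec50)^h)` to
#' replicate-level viability wells, under one of the two fitting regimes whose
#' divergence drives regime-dependent synergy bias:
#'
#' * `"constrained"`: both plateaus boxed into \[0, 100\] % viability
#'   (Combenefit-style). Data steeper than any curve in that box -- e.g. a
#'   drug whose true lower plateau lies below 0, observed clipped at the assay
#'   floor -- cannot be fitted faithfully, producing a characteristic signed
#'   residual pattern (fit above the data below the midpoint, below the data
#'   above it).
#' * `"unconstrained"`: the lower plateau is free and may fall below 0%
#'   (SynergyFinder-style); the upper plateau stays anchored in \[80, 120\]
#'   because viability is normalized to the untreated control.
#'
#' Fitting is on raw replicate wells (not replicate means), by bounded
#' Levenberg-Marquardt with a multi-start over log-spaced EC50 initializations
#' (one per dose decade) crossed with Hill slopes \{0.5, 1, 2, 4\}; the best
#' converged start by RMSE wins, ties broken toward the lowest slope.
#' Zero-dose wells are excluded from the fit but anchor the `emin`
#' initialization.
#'
#' @param data A data frame with columns `dose` (concentration, >= 0) and
#'   `viability` (% of untreated control); a `replicate` column is optional.
#'   Typically [cb_single_agent()] output.
#' @param regime `"unconstrained"` or `"constrained"`.
#' @return An object of class `hill_fit`: a list with `params`
#'   ([hill_params()]), `regime`, `rmse`, `residuals` (tibble of per-well
#'   signed residuals, observed - fitted), `converged`, `flat` (all-flat
#'   input, slope pinned at its lower bound), `absolute_ec50` (dose where the
#'   fitted curve crosses 50% viability, `NA` if it never does), and the
#'   fitting `data`.
#' @examples
#' d <- preset_doses("vinorelbine_like")
#' obs <- tibble::tibble(dose = d,
#'                       viability = hill_viability(drug_preset("vinorelbine_like"), d))
#' fit_hill(obs, regime = "unconstrained")
#' @export
fit_hill <- function(data, regime = c("unconstrained", "constrained")) {
  regime <- match.arg(regime)
  data <- tibble::as_tibble(data)
  stopifnot(all(c("dose", "viability") %in% names(data)))
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  if (any(data$dose < 0)) rlang::abort("`dose` must be non-negative.")
  fit_data <- dplyr::filter(data, .data$dose > 0)
  if (dplyr::n_distinct(fit_data$dose) < 4) {
    rlang::abort("At least 4 distinct positive doses are required.")
  }

  dose_means <- fit_data |>
    dplyr::summarise(m = mean(.data$viability), .by = "dose") |>
    dplyr::arrange(.data$dose)
  zero_mean <- if (any(data$dose == 0)) {
    mean(data$viability[data$dose == 0])
  } else {
    max(dose_means$m)
  }

  b <- .regime_bounds(regime)
  # all-flat input: no identifiable midpoint or slope
  if (diff(range(c(dose_means$m, zero_mean))) < 1e-7) {
    level <- mean(fit_data$viability)
    level_c <- min(max(level, b$lower["emin"]), b$upper["emin"])
    params <- .new_hill_params(level_c, level_c,
                               exp(mean(log(dose_means$dose))), b$lower[["h"]])
    return(.finish_fit(params, regime, fit_data, flat = TRUE))
  }

  decades <- 10^seq(floor(log10(min(fit_data$dose))),
                    ceiling(log10(max(fit_data$dose))))
  emin0 <- min(max(zero_mean, b$lower["emin"] + 1e-6), b$upper["emin"] - 1e-6)
  emax0 <- min(max(min(dose_means$m), b$lower["emax"] + 1e-6),
               b$upper["emax"] - 1e-6)
  starts <- tidyr::expand_grid(lec = log(decades), h = c(0.5, 1, 2, 4))

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        viability ~ emax + (emin - emax) / (1 + exp(h * (log(dose) - lec))),
        data = fit_data,
        start = list(emin = emin0, emax = emax0,
                     lec = starts$lec[k], h = starts$h[k]),
        lower = b$lower, upper = b$upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    rmse <- sqrt(mean(stats::resid(fit)^2))
    if (is.null(best) || rmse < best$rmse - 1e-9 ||
        (abs(rmse - best$rmse) <= 1e-9 && cf[["h"]] < best$cf[["h"]])) {
      best <- list(cf = cf, rmse = rmse)
    }
    if (best$rmse < 1e-6) break
  }
  if (is.null(best)) {
    rlang::abort(sprintf(
      "4PL fit failed to converge from any of %d starts (regime %s, %d doses).",
      nrow(starts), regime, nrow(dose_means)))
  }
  cf <- best$cf
  params <- .new_hill_params(cf[["emin"]], cf[["emax"]], exp(cf[["lec"]]), cf[["h"]])
  .finish_fit(params, regime, fit_data, flat = FALSE)
}

.finish_fit <- function(params, regime, fit_data, flat) {
  fitted <- hill_viability(params, fit_data$dose)
  residuals <- dplyr::mutate(
    fit_data[c("dose", "replicate")],
    observed = fit_data$viability,
    fitted = fitted,
    residual = fit_data$viability - fitted
  )
  abs_ec50 <- if (!flat && params$emax < 50 && params$emin > 50) {
    hill_inverse_params(params, 50)
  } else {
    NA_real_
  }
  structure(
    list(params = params, regime = regime,
         rmse = sqrt(mean(residuals$residual^2)),
         residuals = residuals, converged = TRUE, flat = flat,
         absolute_ec50 = abs_ec50, data = fit_data),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> regime=%s emin=%.3g emax=%.3g ec50=%.4g h=%.3g rmse=%.3g%s\n",
    x$regime, x$params$emin, x$params$emax, x$params$ec50, x$params$h,
    x$rmse, if (x$flat) " (flat)" else ""))
  invisible(x)
}

#' Predict viability from a fitted curve
#'
#' @param object A [fit_hill()] object.
#' @param dose Vector of non-negative concentrations.
#' @param ... Unused.
#' @return % viability; `predict(fit, 0)` is the fitted `emin`.
#' @export
predict.hill_fit <- function(object, dose, ...) {
  if (!object$converged) rlang::abort("Fit did not converge.")
  hill_viability(object$params, dose)
}

#' Dose producing a target viability under a fitted curve
#'
#' Closed-form inversion of the fitted 4PL. Effects at or below the fitted
#' lower plateau are unreachable at any finite dose: `Inf` is returned as the
#' infinite-dose sentinel consumed by the Loewe dose-equivalence solver.
#'
#' @param fit A converged, non-flat [fit_hill()] object.
#' @param target % viability; must not exceed the fitted `emin`.
#' @return Concentration (0 at `target = emin`, `Inf` at `target <= emax`).
#' @export
inverse_dose <- function(fit, target) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!fit$converged) rlang::abort("Fit did not converge.")
  hill_inverse_params(fit$params, target)
}

#' Signed residual bias profile of a fit
#'
#' Summarises where a fitted curve sits relative to the data: the per-dose
#' mean signed deviation `fitted - observed` (positive = curve above the
#' data), split into the regions below and above the absolute EC50 (the dose
#' where the fitted curve crosses 50% viability). A constrained fit of data
#' steeper than the 0-100 box shows the diagnostic pattern positive-below /
#' negative-above; this is the mid-curve bias that propagates into reference
#' surfaces and synergy scores.
#'
#' When the curve never crosses 50% viability the split falls back to the
#' fitted midpoint `ec50` and the summary is flagged.
#'
#' @param fit A [fit_hill()] object.
#' @param data Optional replacement data (`dose`, `viability`); defaults to
#'   the data the fit was computed from.
#' @return A list with `per_dose` (tibble: `dose`, `mean_bias`), `below`
#'   and `above` (mean signed bias below/above the split dose), `split_at`,
#'   and `fallback` (`TRUE` when the fitted `ec50` replaced an undefined
#'   absolute EC50).
#' @export
residual_profile <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "hill_fit"))
  if (is.null(data)) {
    data <- fit$data
  } else {
    data <- dplyr::filter(tibble::as_tibble(data), .data$dose > 0)
  }
  per_dose <- data |>
    dplyr::mutate(bias = predict(fit, .data$dose) - .data$viability) |>
    dplyr::summarise(mean_bias = mean(.data$bias), .by = "dose") |>
    dplyr::arrange(.data$dose)
  fallback <- is.na(fit$absolute_ec50)
  split_at <- if (fallback) fit$params$ec50 else fit$absolute_ec50
  list(
    per_dose = per_dose,
    below = mean(per_dose$mean_bias[per_dose$dose < split_at]),
    above = mean(per_dose$mean_bias[per_dose$dose > split_at]),
    split_at = split_at,
    fallback = fallback
  )
}

#' @exportS3Method generics::tidy
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("emin", "emax", "ec50", "h"),
    estimate = c(x$params$emin, x$params$emax, x$params$ec50, x$params$h)
  )
}

#' @exportS3Method generics::glance
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    regime = x$regime, emin = x$params$emin, emax = x$params$emax,
    ec50 = x$params$ec50, h = x$params$h, rmse = x$rmse,
    absolute_ec50 = x$absolute_ec50, converged = x$converged,
    flat = x$flat, n = nrow(x$residuals)
  )
}

#' @exportS3Method generics::augment
augment.hill_fit <- function(x, ...) {
  x$residuals
}
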