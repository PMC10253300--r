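#' Four-parameter logistic (Hill) curve parameters
#'
#' Constructs and validates the parameter set of the four-parameter logistic
#' concentration-response model
#' \deqn{v(d) = E_{max} + \frac{E_{min} - E_{max}}{1 + (d/EC_{50})^h}}
#' where `v` is % viability (100 = untreated control).
#'
#' @param emin Upper plateau, % viability at zero dose (typically near 100).
#' @param emax Lower plateau, % viability at infinite dose. May be negative:
#'   a curve whose lower plateau falls below 0 is steeper in-range than any
#'   curve boxed into the 0-100 band, which is the mechanism behind
#'   regime-dependent fitting bias.
#' @param ec50 Curve midpoint concentration (same units as the dose grid),
#'   strictly positive.
#' @param h Hill slope, strictly positive.
#'
#' @return An object of class `hill_params` (a named list).
#' @examples
#' p <- hill_params(emin = 100, emax = 0, ec50 = 1, h = 1)
#' hill_viability(p, 1) # 50
#' @export
hill_params <- function(emin, emax, ec50, h) {
  stopifnot(is.numeric(emin), is.numeric(emax), is.numeric(ec50), is.numeric(h))
  if (ec50 <= 0) rlang::abort("`ec50` must be > 0.")
  if (h <= 0) rlang::abort("`h` must be > 0.")
  if (emax > emin) rlang::abort("`emax` must not exceed `emin` (viability decreases with dose).")
  structure(
    list(emin = as.numeric(emin), emax = as.numeric(emax),
         ec50 = as.numeric(ec50), h = as.numeric(h)),
    class = "hill_params"
  )
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("<hill_params> emin=%.4g emax=%.4g ec50=%.4g h=%.4g\n",
              x$emin, x$emax, x$ec50, x$h))
  invisible(x)
}

#' Evaluate a 4PL curve
#'
#' Forward evaluation of the four-parameter logistic model. `hill_viability`
#' works on a `hill_params` object; fitted curves use [predict.hill_fit()].
#'
#' @param params A [hill_params()] object.
#' @param dose Vector of non-negative concentrations.
#' @return % viability at each dose; `dose = 0` returns `emin`.
#' @export
hill_viability <- function(params, dose) {
  if (any(dose < 0)) rlang::abort("`dose` must be non-negative.")
  out <- params$emax + (params$emin - params$emax) /
    (1 + (dose / params$ec50)^params$h)
  out[dose == 0] <- params$emin
  out
}

#' Invert a 4PL curve
#'
#' Closed-form inversion of the four-parameter logistic: the dose producing a
#' given % viability. Targets at or below the lower plateau `emax` are
#' unreachable at any finite dose and return `Inf`, the infinite-dose sentinel
#' the Loewe solver consumes (that drug's dose-equivalence term vanishes).
#'
#' @param params A [hill_params()] object with `emin > emax`.
#' @param target % viability, strictly below `emin` (equal returns dose 0).
#' @return Concentration; `0` at `target = emin`, `Inf` for `target <= emax`.
#' @keywords internal
hill_inverse_params <- function(params, target) {
  if (params$emin <= params$emax) {
    rlang::abort("curve is flat (`emin <= emax`); no unique inverse exists.")
  }
  if (any(target > params$emin)) {
    rlang::abort("`target` is above the zero-dose effect (`emin`).")
  }
  out <- params$ec50 *
    ((params$emin - target) / (target - params$emax))^(1 / params$h)
  out[target == params$emin] <- 0
  out[target <= params$emax] <- Inf
  out
}

# --- drug archetype presets --------------------------------------------------

.preset_table <- function() {
  list(
    # High-potency NSAID whose response falls faster than any curve confined
    # to the 0-100 band: true lower plateau well below 0, observations clipped
    # at the assay floor.  Top concentration 200 uM.
    celecoxib_like = list(params = hill_params(100, -150, 250, 1.3), top = 200),
    # Weaker NSAID with a conventional full-range curve.  Top 1000 uM.
    indomethacin_like = list(params = hill_params(100, 0, 300, 1.5), top = 1000),
    # Antiproliferative agents plateauing near 20% viability (surviving,
    # non-proliferating cells).  Tops 0.1 and 2 uM.
    vinorelbine_like = list(params = hill_params(100, 20, 0.012, 1.5), top = 0.1),
    gemcitabine_like = list(params = hill_params(100, 20, 0.08, 1.2), top = 2),
    # Platinum drug whose midpoint sits near the top of its usable range, so
    # the in-range curve never approaches its lower plateau.  Top 20 uM.
    carboplatin_like = list(params = hill_params(100, 0, 15, 1), top = 20),
    # Flat no-effect control.
    inactive = list(params = structure(list(emin = 100, emax = 100, ec50 = 1, h = 1),
                                       class = "hill_params"),
                    top = 100)
  )
}

#' Drug archetype presets
#'
#' Fixed ground-truth 4PL parameter sets spanning the concentration-response
#' shapes that stress synergy software differently: `celecoxib_like` has a
#' lower plateau below 0% viability (its clipped observations are steeper than
#' any 0-100-bounded curve can follow); `vinorelbine_like` and
#' `gemcitabine_like` plateau near 20% viability (antiproliferative rather
#' than cytotoxic); `carboplatin_like` does not reach its maximal effect
#' within its dose range; `indomethacin_like` is a conventional full-range
#' curve; `inactive` is flat at 100.
#'
#' @param name One of `"celecoxib_like"`, `"indomethacin_like"`,
#'   `"vinorelbine_like"`, `"gemcitabine_like"`, `"carboplatin_like"`,
#'   `"inactive"`.
#' @return A [hill_params()] object.
#' @seealso [preset_doses()] for the matching 9-point base-2 dose grid.
#' @examples
#' drug_preset("vinorelbine_like")$emax # 20
#' @export
drug_preset <- function(name) {
  tab <- .preset_table()
  if (!is.character(name) || length(name) != 1 || !name %in% names(tab)) {
    rlang::abort(paste0(
      "Unknown preset. Valid presets: ",
      paste(names(tab), collapse = ", "), "."
    ))
  }
  tab[[name]]$params
}

#' Default dose grid for a drug preset
#'
#' Nine-point base-2 dilution series descending from the preset's top
#' concentration (so the lowest dose is top/256), the standard checkerboard
#' axis design.
#'
#' @inheritParams drug_preset
#' @param n Number of concentrations (default 9).
#' @return Increasing numeric vector of positive concentrations.
#' @export
preset_doses <- function(name, n = 9) {
  tab <- .preset_table()
  if (!is.character(name) || length(name) != 1 || !name %in% names(tab)) {
    rlang::abort(paste0(
      "Unknown preset. Valid presets: ",
      paste(names(tab), collapse = ", "), "."
    ))
  }
  tab[[name]]$top / 2^((n - 1):0)
}
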