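#' @importFrom rlang .data
NULL

.synergy_models <- c("hsa", "loewe", "bliss")

.clip01 <- function(v) pmin(100, pmax(0, v))

# Expected viability for one Loewe cell: solve d1/D1(E) + d2/D2(E) = 1 in E.
# Dk(E) is the dose of drug k alone producing viability E; below a drug's
# plateau Dk = Inf and its term vanishes, so the index is continuous on
# (min(emax), min(emin)), -1 at the bottom and +Inf at the top of the bracket.
.loewe_cell <- function(p1, p2, d1, d2, tol) {
  act1 <- p1$emin > p1$emax
  act2 <- p2$emin > p2$emax
  if (!act1 && !act2) {
    return(list(expected = min(p1$emin, p2$emin), flagged = TRUE))
  }
  if (d1 == 0 && d2 == 0) {
    return(list(expected = min(p1$emin, p2$emin), flagged = FALSE))
  }
  if (d1 == 0) return(list(expected = hill_viability(p2, d2), flagged = FALSE))
  if (d2 == 0) return(list(expected = hill_viability(p1, d1), flagged = FALSE))

  term <- function(p, d, act, e) {
    if (!act) return(rep(0, length(e)))
    D <- hill_inverse_params(p, e)
    out <- d / D
    out[is.infinite(D)] <- 0
    out
  }
  lo <- min(c(if (act1) p1$emax, if (act2) p2$emax))
  hi <- min(p1$emin, p2$emin)
  f <- function(e) term(p1, d1, act1, e) + term(p2, d2, act2, e) - 1
  eps <- max(1e-9 * (hi - lo), 1e-12)
  f_lo <- f(lo + eps)
  if (f_lo >= 0) {
    # index already >= 1 at the deepest reachable effect (numerical corner)
    return(list(expected = lo, flagged = TRUE))
  }
  root <- stats::uniroot(f, lower = lo + eps, upper = hi - eps,
                         f.lower = f_lo, tol = min(tol, 1e-9) / 10,
                         maxiter = 200)
  list(expected = root$root, flagged = FALSE)
}

# Expected-viability grid under one reference model, from two 4PL parameter
# sets.  This single routine backs both the synthetic-data generator (true
# parameters) and reference_surface() (fitted parameters), so a dataset
# generated under model M with no noise and no offset is an exact fixed point
# of its own analysis under M.
.expected_grid <- function(p1, p2, row_doses, col_doses, model,
                           clip = TRUE, tol = 1e-6) {
  model <- match.arg(model, .synergy_models)
  R <- length(row_doses); C <- length(col_doses)
  flagged <- matrix(FALSE, R, C)
  if (model == "loewe") {
    expected <- matrix(NA_real_, R, C)
    for (i in seq_len(R)) {
      for (j in seq_len(C)) {
        cell <- .loewe_cell(p1, p2, row_doses[i], col_doses[j], tol)
        expected[i, j] <- cell$expected
        flagged[i, j] <- cell$flagged
      }
    }
  } else {
    v1 <- hill_viability(p1, row_doses)
    v2 <- hill_viability(p2, col_doses)
    if (clip) {
      v1 <- .clip01(v1)
      v2 <- .clip01(v2)
    }
    expected <- switch(model,
      hsa = outer(v1, v2, pmin),
      bliss = outer(v1, v2) / 100
    )
  }
  list(expected = expected, flagged = flagged)
}

#' Reference combination surface from two fitted single-agent curves
#'
#' Builds the expected % viability at every combination dose pair under one of
#' the three classical null models, using fitted curves only (never raw
#' single-agent observations -- curve fitting is exactly the channel through
#' which the fitting regime biases downstream scores):
#'
#' * **HSA** (highest single agent): expected viability is the minimum of the
#'   two single-agent viabilities (highest effect = lowest viability).
#' * **Bliss** independence: survival fractions multiply,
#'   `expected = v1 * v2 / 100`.
#' * **Loewe** additivity: expected viability `E` solves the dose-equivalence
#'   index equation `d1/D1(E) + d2/D2(E) = 1`, where `Dk(E)` is the dose of
#'   drug k alone producing viability `E`; effects unreachable by one drug
#'   make that term vanish (infinite dose equivalent).
#'
#' @param fit_row,fit_col Converged [fit_hill()] objects for the row and
#'   column drug.
#' @param row_doses,col_doses Positive concentration vectors for the
#'   combination grid.
#' @param model `"hsa"`, `"loewe"` or `"bliss"`.
#' @param clip Clip single-agent fitted viabilities into \[0, 100\] before
#'   combining (HSA and Bliss only). Defaults to `TRUE`: Bliss needs survival
#'   fractions in \[0, 1\]. This flag is the channel by which an unconstrained
#'   fit with a negative lower plateau and a constrained fit diverge in their
#'   surfaces; the policy used is recorded on the result.
#' @param tol Loewe solver tolerance in % viability.
#'
#' @return A tibble of class `reference_surface` with columns `conc_row`,
#'   `conc_col`, `expected`, `flagged` (cells where no bracketed Loewe root
#'   existed, e.g. both drugs inactive), and attributes `model`,
#'   `clip_policy`, `fits`, `regime`.
#' @export
reference_surface <- function(fit_row, fit_col, row_doses, col_doses,
                              model = c("hsa", "loewe", "bliss"),
                              clip = TRUE, tol = 1e-6) {
  model <- match.arg(model)
  stopifnot(inherits(fit_row, "hill_fit"), inherits(fit_col, "hill_fit"))
  if (!fit_row$converged || !fit_col$converged) {
    rlang::abort("Both single-agent fits must have converged.")
  }
  if (any(row_doses <= 0) || any(col_doses <= 0)) {
    rlang::abort("Surface dose grids must be strictly positive (zero-dose axes are single agents).")
  }
  g <- .expected_grid(fit_row$params, fit_col$params, row_doses, col_doses,
                      model, clip = clip, tol = tol)
  out <- tidyr::expand_grid(conc_row = row_doses, conc_col = col_doses)
  idx <- cbind(match(out$conc_row, row_doses), match(out$conc_col, col_doses))
  out$expected <- g$expected[idx]
  out$flagged <- g$flagged[idx]
  regime <- if (identical(fit_row$regime, fit_col$regime)) fit_row$regime else "mixed"
  structure(
    tibble::new_tibble(out, class = "reference_surface"),
    model = model,
    clip_policy = list(clip = clip && model != "loewe", tol = tol),
    fits = list(row = fit_row, col = fit_col),
    regime = regime
  )
}

#' @export
print.reference_surface <- function(x, ...) {
  cat(sprintf("<reference_surface> model=%s regime=%s clip=%s, %d x %d grid\n",
              attr(x, "model"), attr(x, "regime"),
              attr(x, "clip_policy")$clip,
              length(unique(x$conc_row)), length(unique(x$conc_col))))
  NextMethod()
}
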