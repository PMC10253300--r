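fit_of <- function(p, doses = p$ec50 * 2^seq(-4, 4)) {
  quiet(fit_hill(tibble::tibble(dose = doses,
                                viability = hill_viability(p, doses))))
}

test_that("HSA surface is the pointwise minimum viability", {
  f1 <- fit_of(hill_params(100, 0, 1, 1))
  f2 <- fit_of(hill_params(100, 0, 4, 1))
  d1 <- 2^seq(-3, 3); d2 <- 2^seq(-2, 4)
  s <- reference_surface(f1, f2, d1, d2, model = "hsa")
  v1 <- predict(f1, s$conc_row); v2 <- predict(f2, s$conc_col)
  expect_equal(s$expected, pmin(v1, v2), tolerance = 1e-9)
  # inactive partner: every column equals the active drug's own curve
  finact <- fit_of(drug_preset("inactive"), 2^seq(-3, 3))
  s0 <- reference_surface(f1, finact, d1, d2, model = "hsa")
  expect_equal(s0$expected, predict(f1, s0$conc_row), tolerance = 1e-6)
})

test_that("Bliss surface multiplies survival fractions", {
  f1 <- fit_of(hill_params(100, 0, 1, 1))
  f2 <- fit_of(hill_params(100, 0, 4, 1))
  s <- reference_surface(f1, f2, 1, 4, model = "bliss")  # both at midpoint
  expect_equal(s$expected, 25, tolerance = 1e-4)
  finact <- fit_of(drug_preset("inactive"), 2^seq(-3, 3))
  s0 <- reference_surface(f1, finact, 2^seq(-3, 3), 2^seq(-3, 3), model = "bliss")
  expect_equal(s0$expected, predict(f1, s0$conc_row), tolerance = 1e-4)
  # absorbing zero: a fully killed cell stays at 0 whatever the partner does
  s1 <- reference_surface(f1, f2, 1e6, 4, model = "bliss")
  expect_lt(s1$expected, 1e-3)
})

test_that("clipping policy controls negative plateaus entering Bliss", {
  p <- drug_preset("celecoxib_like")
  d <- preset_doses("celecoxib_like")
  # unclipped observations let the unconstrained fit recover the negative tail
  fu <- quiet(fit_hill(tibble::tibble(dose = d, viability = hill_viability(p, d))))
  f2 <- fit_of(hill_params(100, 0, 1, 1))
  d <- preset_doses("celecoxib_like")
  clipped <- reference_surface(fu, f2, d, 2^seq(-3, 3), model = "bliss", clip = TRUE)
  free <- reference_surface(fu, f2, d, 2^seq(-3, 3), model = "bliss", clip = FALSE)
  expect_true(all(clipped$expected >= 0))
  expect_true(any(free$expected < 0))       # negative plateau flows through
  expect_true(attr(clipped, "clip_policy")$clip)
  expect_false(attr(free, "clip_policy")$clip)
})

test_that("Loewe surface solves the dose-equivalence index equation", {
  p <- hill_params(100, 0, 1, 1)
  f <- fit_of(p)
  # a drug combined with itself at half doses reproduces its own midpoint
  s <- reference_surface(f, f, 0.5, 0.5, model = "loewe")
  expect_equal(s$expected, 50, tolerance = 1e-3)
  # inactive partner: the active drug's own curve
  finact <- fit_of(drug_preset("inactive"), 2^seq(-3, 3))
  s0 <- reference_surface(f, finact, 2^seq(-3, 3), 2^seq(-3, 3), model = "loewe")
  expect_equal(s0$expected, predict(f, s0$conc_row), tolerance = 1e-3)
  expect_false(any(s0$flagged))
  # residual of the index equation at the solution
  f2 <- fit_of(hill_params(100, 10, 3, 2))
  s2 <- reference_surface(f, f2, 2^seq(-2, 2), 3 * 2^seq(-2, 2), model = "loewe")
  idx <- purrr::pmap_dbl(list(s2$conc_row, s2$conc_col, s2$expected),
                         function(d1, d2, e) {
                           d1 / inverse_dose(f, e) + d2 / inverse_dose(f2, e)
                         })
  expect_lt(max(abs(idx - 1)), 1e-6)
  # two inactive drugs: no bracketed root, flagged no-effect surface
  sflat <- reference_surface(finact, finact, 1, 1, model = "loewe")
  expect_true(all(sflat$flagged))
  expect_equal(sflat$expected, 100)
})

test_that("sham self-combination is exactly additive under Loewe", {
  p <- hill_params(100, 0, 2, 1.4)
  f <- fit_of(p)
  d <- 2 * 2^seq(-3, 3)
  s <- reference_surface(f, f, d, d, model = "loewe")
  truth <- predict(f, s$conc_row + s$conc_col)
  expect_lt(max(abs(s$expected - truth)), 1e-3)
})

test_that("Loewe agrees with a brute-force scan of the index equation", {
  set.seed(101)
  for (k in 1:10) {
    p1 <- hill_params(100, runif(1, 0, 30), exp(runif(1, -1, 3)), runif(1, 0.7, 3))
    p2 <- hill_params(100, runif(1, 0, 30), exp(runif(1, -1, 3)), runif(1, 0.7, 3))
    f1 <- fit_of(p1); f2 <- fit_of(p2)
    d1 <- p1$ec50 * 2^seq(-2, 2); d2 <- p2$ec50 * 2^seq(-2, 2)
    s <- reference_surface(f1, f2, d1, d2, model = "loewe")
    oracle <- loewe_scan_oracle(f1$params, f2$params, d1, d2)
    got <- matrix(NA_real_, 5, 5)
    got[cbind(match(s$conc_row, d1), match(s$conc_col, d2))] <- s$expected
    expect_lt(max(abs(got - oracle)), 0.1)
  }
})

test_that("model stringency ordering holds for monotone in-range curves", {
  fits <- fx_fits(fx_conforming_board(seed = 3))
  d1 <- cb_doses(fx_conforming_board(seed = 3), "row")
  d2 <- cb_doses(fx_conforming_board(seed = 3), "col")
  hsa <- reference_surface(fits$row, fits$col, d1, d2, "hsa")
  bliss <- reference_surface(fits$row, fits$col, d1, d2, "bliss")
  loewe <- reference_surface(fits$row, fits$col, d1, d2, "loewe")
  expect_true(all(hsa$expected >= bliss$expected - 1e-9))
  expect_true(all(hsa$expected >= loewe$expected - 1e-9))
  # expected viability decreases along both axes
  m <- matrix(NA_real_, 9, 9)
  m[cbind(match(hsa$conc_row, d1), match(hsa$conc_col, d2))] <- hsa$expected
  expect_true(all(apply(m, 2, function(x) all(diff(x) <= 1e-9))))
  expect_true(all(apply(m, 1, function(x) all(diff(x) <= 1e-9))))
})

test_that("surface construction validates its inputs", {
  f <- fit_of(hill_params(100, 0, 1, 1))
  bad <- f; bad$converged <- FALSE
  expect_error(reference_surface(bad, f, 1, 1, "hsa"), "converged")
  expect_error(reference_surface(f, f, c(0, 1), 1, "hsa"), "positive")
})
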