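std_pair <- function() {
  list(p1 = hill_params(100, 0, 1, 1), p2 = hill_params(100, 0, 2, 1),
       d1 = 2^seq(-4, 4), d2 = 2^seq(-3, 5))
}

test_that("noise-free generation reproduces the null-model expectations", {
  s <- std_pair()
  dat <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, null_model = "bliss",
                               noise_sd = 0, seed = 1)
  # both drugs at their midpoints: Bliss product of two half-effects
  cell <- dplyr::filter(dat, conc_row == 1, conc_col == 2, replicate == 1)
  expect_equal(cell$viability, 25)
  # untreated control
  ctrl <- dplyr::filter(dat, conc_row == 0, conc_col == 0)
  expect_true(all(ctrl$viability == 100))
  # single-agent axes follow the true curves
  row_sa <- dplyr::filter(dat, conc_col == 0, conc_row > 0, replicate == 1)
  expect_equal(row_sa$viability, hill_viability(s$p1, row_sa$conc_row))

  # HSA with an inactive partner collapses to the active drug's curve
  dath <- simulate_checkerboard(s$p1, drug_preset("inactive"), s$d1, s$d2,
                                null_model = "hsa", noise_sd = 0, seed = 1)
  combos <- cb_combinations(dath)
  expect_equal(combos$viability, hill_viability(s$p1, combos$conc_row))
})

test_that("generation is bit-reproducible for a fixed seed", {
  s <- std_pair()
  a <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, noise_sd = 5, seed = 42)
  b <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, noise_sd = 5, seed = 42)
  expect_identical(a, b)
  c <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, noise_sd = 5, seed = 43)
  expect_false(identical(a$viability, c$viability))
})

test_that("noise, clipping and replication behave as specified", {
  s <- std_pair()
  dat <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, noise_sd = 25,
                               n_replicates = 3, seed = 7,
                               clip_observations = TRUE)
  expect_true(all(dat$viability >= 0 & dat$viability <= 100))
  expect_equal(sort(unique(dat$replicate)), 1:3)
  # unclipped noise-free values stay inside [emax, emin]
  nf <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, noise_sd = 0, seed = 1,
                              clip_observations = FALSE)
  expect_true(all(nf$viability >= 0 - 1e-12 & nf$viability <= 100 + 1e-12))
  # control mean stays within noise of 100
  noisy <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, noise_sd = 5,
                                 n_replicates = 40, seed = 5,
                                 clip_observations = FALSE)
  ctrl <- dplyr::filter(noisy, conc_row == 0, conc_col == 0)
  expect_lt(abs(mean(ctrl$viability) - 100), 3)
})

test_that("replicate means converge to the true surface", {
  s <- std_pair()
  truth <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, noise_sd = 0,
                                 seed = 1, clip_observations = FALSE)
  big <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, noise_sd = 5,
                               n_replicates = 400, seed = 11,
                               clip_observations = FALSE)
  means <- big |>
    dplyr::summarise(m = mean(viability), .by = c(conc_row, conc_col)) |>
    dplyr::inner_join(
      dplyr::filter(truth, replicate == 1)[c("conc_row", "conc_col", "viability")],
      by = c("conc_row", "conc_col"))
  expect_lt(max(abs(means$m - means$viability)), 1)
})

test_that("interaction offsets are applied to the null surface before clipping", {
  s <- std_pair()
  off <- matrix(15, length(s$d1), length(s$d2))
  base <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, null_model = "bliss",
                                noise_sd = 0, seed = 1)
  shifted <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, null_model = "bliss",
                                   interaction_offset = off, noise_sd = 0,
                                   seed = 1)
  cmp <- dplyr::inner_join(
    cb_combinations(base), cb_combinations(shifted),
    by = c("conc_row", "conc_col", "replicate"), suffix = c("_0", "_s"))
  expect_equal(cmp$viability_s, pmax(0, cmp$viability_0 - 15))
  expect_error(
    simulate_checkerboard(s$p1, s$p2, s$d1, s$d2,
                          interaction_offset = matrix(0, 2, 2)),
    "interaction_offset")
})

test_that("extreme checkerboards pin combination cells at the anchors", {
  s <- std_pair()
  syn <- extreme_checkerboard("synergistic", s$p1, s$p2, s$d1, s$d2)
  expect_true(all(cb_combinations(syn)$viability == 0))
  ant <- extreme_checkerboard("antagonistic", s$p1, s$p2, s$d1, s$d2)
  expect_true(all(cb_combinations(ant)$viability == 100))
  # single agents follow the curves regardless of direction
  sa_syn <- dplyr::filter(syn, conc_col == 0, conc_row > 0, replicate == 1)
  sa_ant <- dplyr::filter(ant, conc_col == 0, conc_row > 0, replicate == 1)
  expect_equal(sa_syn$viability, hill_viability(s$p1, sa_syn$conc_row))
  expect_identical(sa_syn$viability, sa_ant$viability)
  # replicates are identical (noise-free)
  expect_identical(dplyr::filter(syn, replicate == 1)$viability,
                   dplyr::filter(syn, replicate == 4)$viability)
  expect_error(extreme_checkerboard("huge", s$p1, s$p2, s$d1, s$d2))
})

test_that("a noise-free dataset is a fixed point of its own analysis", {
  s <- std_pair()
  for (m in c("hsa", "loewe", "bliss")) {
    dat <- simulate_checkerboard(s$p1, s$p2, s$d1, s$d2, null_model = m,
                                 noise_sd = 0, seed = 1)
    fits <- quiet(list(row = fit_hill(cb_single_agent(dat, "row")),
                       col = fit_hill(cb_single_agent(dat, "col"))))
    surf <- reference_surface(fits$row, fits$col, s$d1, s$d2, model = m)
    res <- quiet(score_synergy(dat, surf))
    expect_lt(max(abs(res$delta)), 1e-4)
  }
})
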