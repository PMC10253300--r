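# Shared fixtures, built once per test run.  All data are generated in code;
# expensive pieces are cached in this environment.

.fx <- new.env(parent = emptyenv())

# a well-behaved 0-100 drug pair (monotone, plateaus inside the box)
fx_conforming_board <- function(noise_sd = 5, seed = 3, clip = TRUE) {
  key <- paste0("conf_", noise_sd, "_", seed, "_", clip)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- simulate_checkerboard(
      drug_preset("indomethacin_like"), drug_preset("carboplatin_like"),
      preset_doses("indomethacin_like"), preset_doses("carboplatin_like"),
      null_model = "bliss", noise_sd = noise_sd, seed = seed,
      clip_observations = clip,
      drug_row = "indomethacin_like", drug_col = "carboplatin_like")
  }
  .fx[[key]]
}

# the clipped steep archetype paired with an antiproliferative drug
fx_celecoxib_board <- function(seed = 2) {
  key <- paste0("clx_", seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- simulate_checkerboard(
      drug_preset("celecoxib_like"), drug_preset("vinorelbine_like"),
      preset_doses("celecoxib_like"), preset_doses("vinorelbine_like"),
      null_model = "bliss", noise_sd = 5, seed = seed,
      drug_row = "celecoxib_like", drug_col = "vinorelbine_like")
  }
  .fx[[key]]
}

fx_fits <- function(board, regime = "unconstrained") {
  key <- paste0("fit_", digest_board(board), "_", regime)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- suppressWarnings(list(
      row = fit_hill(cb_single_agent(board, "row"), regime = regime),
      col = fit_hill(cb_single_agent(board, "col"), regime = regime)))
  }
  .fx[[key]]
}

digest_board <- function(board) {
  paste0(board$drug_row[1], board$drug_col[1], nrow(board),
         round(sum(board$viability) * 1e3))
}

# brute-force Loewe oracle: scan n_grid viability values for the index root
loewe_scan_oracle <- function(p1, p2, d1, d2, n_grid = 1e5) {
  lo <- min(p1$emax, p2$emax)
  hi <- min(p1$emin, p2$emin)
  e_grid <- seq(lo + 1e-9 * (hi - lo), hi - 1e-9 * (hi - lo), length.out = n_grid)
  inv <- function(p, e) {
    d <- p$ec50 * ((p$emin - e) / (e - p$emax))^(1 / p$h)
    d[e <= p$emax] <- Inf
    d
  }
  inv1 <- 1 / inv(p1, e_grid)
  inv2 <- 1 / inv(p2, e_grid)
  out <- matrix(NA_real_, length(d1), length(d2))
  for (i in seq_along(d1)) {
    a <- d1[i] * inv1
    for (j in seq_along(d2)) {
      out[i, j] <- e_grid[which.min(abs(a + d2[j] * inv2 - 1))]
    }
  }
  out
}

quiet <- function(expr) suppressWarnings(expr)
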