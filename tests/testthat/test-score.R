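test_that("deltas compare observation to expectation cell by cell", {
  board <- fx_conforming_board(noise_sd = 0, seed = 1)
  fits <- fx_fits(board)
  d1 <- cb_doses(board, "row"); d2 <- cb_doses(board, "col")
  surf <- reference_surface(fits$row, fits$col, d1, d2, "bliss")
  res <- quiet(score_synergy(board, surf))
  # observed was generated from the same model: identity, delta ~ 0
  expect_lt(max(abs(res$delta)), 1e-4)
  expect_equal(nrow(res), 81)

  # constant -10 shift in observation gives delta = +10 everywhere
  shifted <- dplyr::mutate(
    board, viability = ifelse(conc_row > 0 & conc_col > 0,
                              viability - 10, viability))
  res10 <- quiet(score_synergy(as_checkerboard(shifted), surf))
  expect_equal(res10$delta, rep(10, 81), tolerance = 1e-4)

  # fully synergistic extreme: delta equals the expected surface itself
  ext <- extreme_checkerboard("synergistic", fits$row$params, fits$col$params,
                              d1, d2)
  rese <- score_synergy(ext, surf)
  expect_equal(rese$delta, rese$expected)
})

test_that("per-point tests behave at the degenerate limits", {
  expect_equal(point_significance(c(0, 0, 0, 0), "t_test"), 1)
  expect_equal(point_significance(c(10, 10, 10, 10), "t_test"), 0)
  jitter <- c(10, 10, 10, 10) + c(1, -1, 1, -1) * 1e-12
  expect_equal(point_significance(jitter, "bootstrap", B = 1000), 1 / 1000)
  expect_warning(p1 <- point_significance(5, "t_test"), "Single replicate")
  expect_equal(p1, 1)
  # plain t-test agrees with stats::t.test away from degeneracy
  x <- c(4, 7, 9, 2)
  expect_equal(point_significance(x, "t_test"), t.test(x)$p.value)
})

test_that("bootstrap p-values are seeded and reproducible", {
  x <- c(3, -1, 6, 2)
  a <- point_significance(x, "bootstrap", B = 500, seed = 9)
  b <- point_significance(x, "bootstrap", B = 500, seed = 9)
  expect_identical(a, b)
  expect_gte(a, 1 / 500)
})

test_that("matrix scores follow the two conventions", {
  board <- fx_conforming_board(noise_sd = 0, seed = 1)
  fits <- fx_fits(board)
  d1 <- cb_doses(board, "row"); d2 <- cb_doses(board, "col")
  surf <- reference_surface(fits$row, fits$col, d1, d2, "hsa")

  # craft observations: a 2x4 block sits exactly 30 below expectation in
  # every replicate (zero variance -> maximally significant), the rest sit
  # 2 above with alternating replicate scatter (mean -2, not significant)
  surf_tbl <- tibble::as_tibble(surf)[c("conc_row", "conc_col", "expected")]
  block_r <- d1[3:4]; block_c <- d2[3:6]
  crafted <- board |>
    dplyr::left_join(surf_tbl, by = c("conc_row", "conc_col")) |>
    dplyr::mutate(
      in_block = conc_row %in% block_r & conc_col %in% block_c,
      viability = dplyr::case_when(
        conc_row == 0 | conc_col == 0 ~ viability,
        in_block ~ expected - 30,
        TRUE ~ expected + 2 + c(18, -18, 14, -14)[replicate]),
      expected = NULL, in_block = NULL) |>
    as_checkerboard()
  res <- quiet(score_synergy(crafted, surf))
  expect_equal(sum(res$significant), 8)
  ms <- matrix_score(res, "mean")
  ws <- matrix_score(res, "weighted")
  expect_equal(ms, (8 * 30 + 73 * (-2)) / 81, tolerance = 1e-9)
  expect_equal(ws, 8 * 30 / 81, tolerance = 1e-9)
  expect_gt(ws, ms)

  # when every cell is significant the conventions coincide exactly
  ext <- extreme_checkerboard("synergistic", fits$row$params, fits$col$params,
                              d1, d2)
  rese <- score_synergy(ext, surf)
  expect_true(all(rese$significant))
  expect_equal(matrix_score(rese, "weighted"), matrix_score(rese, "mean"))
})

test_that("classification respects the additive band with strict bounds", {
  expect_equal(classify_score(0), "additive")
  expect_equal(classify_score(5), "additive")     # boundary is additive
  expect_equal(classify_score(5 + 1e-9), "synergistic")
  expect_equal(classify_score(-12), "antagonistic")
  expect_equal(classify_score(c(-0.06, 0.02, 0.07), thresholds = c(-0.05, 0.05)),
               c("antagonistic", "additive", "synergistic"))
  expect_error(classify_score(0, thresholds = c(1, 2)), "t_ant")
})

test_that("t-test and bootstrap concur at the simulation-derived rate", {
  # direct replication with N(8, 4) deltas, n = 4: the two tests agree on
  # significance at alpha = 0.05 in about 78% of draws (the bootstrap with
  # its 1/B floor rejects whenever all resampled means stay positive, the
  # t-test is more conservative at n = 4)
  set.seed(17)
  agree <- sapply(1:100, function(i) {
    x <- rnorm(4, 8, 4)
    (point_significance(x, "t_test") < 0.05) ==
      (point_significance(x, "bootstrap", B = 1000, seed = i) < 0.05)
  })
  expect_gt(mean(agree), 0.66)
  expect_lt(mean(agree), 0.92)
})

test_that("injected synergy is recovered in size and location", {
  p1 <- drug_preset("indomethacin_like"); d1 <- preset_doses("indomethacin_like")
  p2 <- drug_preset("carboplatin_like"); d2 <- preset_doses("carboplatin_like")
  off <- matrix(0, 9, 9); off[3:5, 3:5] <- 15
  runs <- purrr::map_dfr(1:15, function(s) {
    dat <- simulate_checkerboard(p1, p2, d1, d2, null_model = "bliss",
                                 interaction_offset = off, noise_sd = 5,
                                 seed = 300 + s, clip_observations = FALSE)
    fits <- quiet(list(row = fit_hill(cb_single_agent(dat, "row")),
                       col = fit_hill(cb_single_agent(dat, "col"))))
    surf <- reference_surface(fits$row, fits$col, d1, d2, "bliss")
    res <- quiet(score_synergy(dat, surf))
    block <- res$conc_row %in% d1[3:5] & res$conc_col %in% d2[3:5]
    tibble::tibble(score = matrix_score(res, "mean"),
                   block_sig = mean(res$significant[block]))
  })
  expect_equal(mean(runs$score), 15 * 9 / 81, tolerance = 0.35)
  expect_gte(mean(runs$block_sig), 0.8)
})

test_that("grid mismatch between data and surface is an explicit error", {
  board <- fx_conforming_board(seed = 3)
  fits <- fx_fits(board)
  surf <- reference_surface(fits$row, fits$col,
                            cb_doses(board, "row") * 1.01,
                            cb_doses(board, "col"), "hsa")
  expect_error(score_synergy(board, surf), "dose grids differ")
})
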