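test_that("least-squares MVAR fitting is consistent and rejects degenerate input", {
  edges <- data.frame(source = c(1, 3), target = c(2, 4), strength = c(0.4, -0.3))
  vm <- make_var_model(edges, base_diag = 0.5, order = 1)
  x <- simulate_var(vm, 50000, seed = 51)
  fit <- fit_mvar(x, p = 1)
  expect_lt(max(abs(fit$coeffs[1, , ] - vm$coeffs[1, , ])), 0.02)
  expect_equal(fit$residual_cov, diag(4), tolerance = 0.05)

  wn <- simulate_var(make_var_model(NULL, base_diag = 0), 50000, seed = 52)
  fitw <- fit_mvar(wn, p = 1)
  expect_lt(max(abs(fitw$coeffs)), 0.05)

  expect_error(fit_mvar(x[, 1:3], p = 5), "exceed the model order")
  expect_error(fit_mvar(x[, 1:5], p = 1), "too few observations")
})

test_that("SBC follows the Schwarz formula and recovers the true order", {
  # closed form: Sigma = I gives ln det = 0, penalty (ln 1308/1308)*12*16
  fake <- structure(list(order = 12, n_channels = 4, residual_cov = diag(4),
                         n_obs = 1308), class = "mvar_fit")
  expect_equal(sbc(fake), (log(1308) / 1308) * 12 * 16, tolerance = 1e-12)
  expect_equal(sbc(fake), 1.053395, tolerance = 1e-5)

  fake2 <- fake; fake2$residual_cov <- 2 * diag(4)
  expect_equal(sbc(fake2) - sbc(fake), 4 * log(2), tolerance = 1e-12)

  # order recovery on VAR(3) data, epoch-sized records
  edges3 <- data.frame(source = c(1, 2, 3), target = c(2, 3, 4),
                       strength = c(0.3, 0.4, 0.4), lag = c(1, 3, 3))
  vm3 <- make_var_model(edges3, base_diag = 0.4, order = 3)
  hits <- 0L
  for (s in 1:100) {
    x <- simulate_var(vm3, 1320, seed = 5000 + s)
    p_hat <- which.min(vapply(1:12, function(p) fit_mvar(x, p)$sbc, numeric(1)))
    hits <- hits + (p_hat == 3L)
  }
  expect_gte(hits, 90)
})

test_that("select_order scans mean SBC across epochs", {
  edges2 <- data.frame(source = 1, target = 2, strength = 0.35, lag = 2)
  vm2 <- make_var_model(edges2, base_diag = 0.4, order = 2)
  epochs <- make_var_epochs(vm2, 5, seed = 61)
  expect_equal(select_order(epochs, p_max = 8), 2)

  wn_epochs <- make_var_epochs(make_var_model(NULL, base_diag = 0), 5, seed = 62)
  expect_lte(select_order(wn_epochs, p_max = 8), 2)

  expect_warning(p_low <- select_order(epochs, p_max = 1), "p_max")
  expect_equal(p_low, 1)
})

test_that("transfer matrix matches its definition", {
  wn <- make_var_model(NULL, base_diag = 0)
  for (f in c(0, 10, 50)) {
    expect_equal(transfer_matrix(wn, f), diag(1 + 0i, 4), ignore_attr = TRUE)
  }

  m2 <- make_var_model(data.frame(source = 1, target = 2, strength = 0.4),
                       base_diag = 0, n_channels = 2, channels = c("a", "b"))
  m2$coeffs[1, 1, 1] <- 0.5; m2$coeffs[1, 2, 2] <- 0.3
  expect_equal(transfer_matrix(m2, 0),
               matrix(c(0.5, -0.4, 0, 0.7), 2, 2) + 0i, ignore_attr = TRUE)

  # continuity in f
  d <- sapply(c(1e-3, 1e-5), function(dl)
    max(abs(transfer_matrix(m2, 20 + dl) - transfer_matrix(m2, 20))))
  expect_lt(d[2], d[1])
})

test_that("gPDC matches closed form, is column-normalized and scale-invariant", {
  # uncoupled white noise: identity pattern at every frequency
  wn_fit <- fit_mvar(simulate_var(make_var_model(NULL, base_diag = 0), 20000,
                                  seed = 71), p = 1)
  g0 <- gpdc(wn_fit, freqs = c(1, 10, 40))
  expect_lt(max(abs(g0$values[cbind(c(2, 1), c(1, 2), 1)])), 0.05)

  # bivariate worked example, evaluated from the true model
  m2 <- make_var_model(data.frame(source = 1, target = 2, strength = 0.4),
                       base_diag = 0, n_channels = 2, channels = c("a", "b"))
  m2$coeffs[1, 1, 1] <- 0.5; m2$coeffs[1, 2, 2] <- 0.3
  g2 <- gpdc(m2, freqs = 0)
  expect_equal(g2$values[2, 1, 1], 0.4 / sqrt(0.5^2 + 0.4^2), tolerance = 1e-9)
  expect_equal(g2$values[1, 2, 1], 0)

  # column normalization invariant on fitted epochs
  vm <- make_var_model(data.frame(source = "AF07", target = "TP10", strength = 0.4),
                       base_diag = 0.3)
  epochs <- make_var_epochs(vm, 3, seed = 72)
  for (e in epochs) {
    g <- gpdc(fit_mvar(e, p = 12))
    norms <- apply(g$values^2, c(2, 3), sum)
    expect_lt(max(abs(norms - 1)), 1e-8)
  }

  # scale invariance through the full fit
  e <- epochs[[1]]
  e_scaled <- e; e_scaled[2, ] <- 10 * e_scaled[2, ]
  g_a <- gpdc(fit_mvar(e, p = 12))
  g_b <- gpdc(fit_mvar(e_scaled, p = 12))
  expect_lt(max(abs(g_a$values - g_b$values)), 1e-6)
})

test_that("estimated gPDC converges to the true model's closed form", {
  edges <- data.frame(source = c("AF07", "AF08"), target = c("TP10", "TP09"),
                      strength = c(0.4, 0.3))
  vm <- make_var_model(edges, base_diag = 0.3, order = 1)
  x <- simulate_var(vm, 50000, seed = 73)
  g_hat <- gpdc(fit_mvar(x, p = 1))
  g_true <- gpdc(vm)
  expect_lt(max(abs(g_hat$values - g_true$values)), 0.05)
})

test_that("session gPDC averages per-epoch spectra and recovers directionality", {
  vm <- make_var_model(data.frame(source = "AF07", target = "TP10", strength = 0.4),
                       base_diag = 0.3)
  epochs <- make_var_epochs(vm, 2, seed = 81)

  # duplicated epochs: average equals the single-epoch result
  g1 <- session_gpdc(epochs[1], p = 12)
  g_dup <- session_gpdc(c(epochs[1], epochs[1]), p = 12)
  expect_equal(g_dup$values, g1$values, tolerance = 1e-12)
  expect_equal(g_dup$n_epochs, 2)

  # planted direction dominates the reverse in all five bands
  g <- session_gpdc(make_var_epochs(vm, 50, seed = 82), p = 12)
  expect_true(all(g$band_means["TP10", "AF07", ] > g$band_means["AF07", "TP10", ]))

  expect_error(session_gpdc(list()), "no clean epochs")
})
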