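test_that("F-test of variance equality is symmetric and powered", {
  x <- c(1.2, 0.8, 1.5, 0.9, 1.1)
  f_same <- f_test_equal_var(x, x)
  expect_equal(f_same$f_stat, 1)
  expect_equal(f_same$p, 1)

  set.seed(101)
  hits <- sum(vapply(1:100, function(i) {
    a <- rnorm(100, sd = 1); b <- rnorm(100, sd = 3)
    f_test_equal_var(a, b)$p < 0.01
  }, logical(1)))
  expect_gte(hits, 99)

  set.seed(102)
  a <- rnorm(20); b <- rnorm(25, sd = 2)
  expect_equal(f_test_equal_var(a, b)$p, f_test_equal_var(b, a)$p)
  expect_error(f_test_equal_var(rep(1, 5), a), "zero variance")
})

test_that("two-sample t matches the closed-form pooled computation", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  r <- two_sample_t(x, y, equal_var = TRUE)
  expect_equal(r$t, -1)
  expect_equal(r$df, 8)
  expect_equal(r$p, 2 * pt(-1, 8), tolerance = 1e-12)
  expect_equal(r$p, 0.3466, tolerance = 5e-5)
  # per-group 95% CI: mean +/- t_{.975, 4} * s / sqrt(5)
  expect_equal(r$ci_x, 3 + c(-1, 1) * qt(0.975, 4) * sqrt(2.5 / 5), tolerance = 1e-12)

  r0 <- two_sample_t(x, x, equal_var = TRUE)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # Satterthwaite df is pulled below n_x + n_y - 2 by unequal variances
  set.seed(103)
  a <- rnorm(10, sd = 1); b <- rnorm(10, sd = 10)
  rw <- two_sample_t(a, b, equal_var = FALSE)
  expect_lt(rw$df, 18)

  # equal n and equal s: pooled and Welch statistics coincide
  s1 <- c(1, 2, 3, 4); s2 <- c(2, 3, 4, 5)  # same spread, shifted
  expect_equal(two_sample_t(s1, s2, TRUE)$t, two_sample_t(s1, s2, FALSE)$t)

  expect_error(two_sample_t(1, y), "at least 2")
})

test_that("compare_stages gates on the F-test and handles thin cells", {
  set.seed(104)
  tab <- do.call(rbind, lapply(1:12, function(i) {
    stage <- if (i <= 6) "Preparation" else "Generation"
    data.frame(session_id = paste0("s", i), stage = stage,
               metric = "sampen",
               location = c("TP09", "AF07"),
               band_or_freq = "broadband",
               value = c(rnorm(1, 1, 0.1),
                         rnorm(1, if (stage == "Preparation") 1 else 2, 0.1)))
  }))
  out <- compare_stages(tab)
  expect_equal(nrow(out), 2)
  row_af <- out[out$location == "AF07", ]
  expect_true(row_af$significant)
  expect_true(row_af$test_used %in% c("pooled", "satterthwaite"))
  expect_true(all(out$ci_lo_prep <= out$mean_prep & out$mean_prep <= out$ci_hi_prep))
  expect_equal(out$significant, out$p < 0.05)

  # single-session stage: skipped flag, no crash
  thin <- tab[tab$session_id %in% c("s1", "s7", "s8") | tab$location == "AF07", ]
  thin <- thin[!(thin$location == "AF07" & thin$session_id == "s1"), ]
  out_thin <- compare_stages(thin)
  expect_true(out_thin$skipped[out_thin$location == "TP09"])
  expect_false(all(out_thin$skipped))

  # optional Benjamini-Hochberg flag adjusts the decisions
  out_fdr <- compare_stages(tab, fdr = TRUE)
  expect_true(all(out_fdr$p_adj >= out_fdr$p, na.rm = TRUE))
})

test_that("null p-values are approximately uniform", {
  set.seed(105)
  ps <- replicate(400, {
    x <- rnorm(12); y <- rnorm(12)
    f <- f_test_equal_var(x, y)
    two_sample_t(x, y, equal_var = f$p >= 0.05)$p
  })
  ks <- ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("participant yield counts participants with any usable session", {
  rep_tab <- data.frame(
    participant_id = c("P1", "P1", "P2", "P3", "P4"),
    usable = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  y <- participant_yield(rep_tab)
  expect_equal(y$n_retained, 2)
  expect_equal(y$yield_pct, 50)
  y18 <- participant_yield(rep_tab, n_enrolled = 18)
  expect_equal(y18$yield_pct, 100 * 2 / 18)
})
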