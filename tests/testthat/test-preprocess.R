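fs <- 220
tt <- seq(0, 80, by = 1 / fs)

test_that("notch filter removes 60 Hz and leaves the pass band alone", {
  x60 <- 10 * sin(2 * pi * 60 * tt)
  y <- notch_filter(x60)
  expect_lt(sqrt(mean(y[500:(length(y) - 500)]^2)), 0.35)

  x10 <- sin(2 * pi * 10 * tt)
  y10 <- notch_filter(x10)
  expect_equal(sd(y10[500:(length(y10) - 500)]), sd(x10[500:(length(x10) - 500)]),
               tolerance = 0.01)
  expect_equal(notch_filter(rep(0, 2200)), rep(0, 2200))
})

test_that("band-pass filter is zero-phase with the stated band edges", {
  xdc <- rep(50, length(tt))
  expect_lt(abs(mean(bandpass_filter(xdc))), 0.5)

  x10 <- sin(2 * pi * 10 * tt)
  y10 <- bandpass_filter(x10)
  mid <- 2000:(length(tt) - 2000)
  expect_equal(sd(y10[mid]), sd(x10[mid]), tolerance = 0.02)
  cc <- ccf(y10[mid], x10[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)  # zero phase delay

  xslow <- sin(2 * pi * 0.1 * tt)
  expect_lt(sd(bandpass_filter(xslow)) / sd(xslow), 0.1)

  expect_error(bandpass_filter(x10, hi = 110), "Nyquist")
})

test_that("ASR is a near no-op on clean data and suppresses planted bursts", {
  vm <- make_var_model(NULL, base_diag = 0.6)
  rec <- generate_session(vm, 66, artifact_plan(), seed = 21)
  x <- bandpass_filter(rec$eeg)
  out <- asr_clean(x)
  expect_equal(sqrt(mean(out$eeg^2)), sqrt(mean(x^2)), tolerance = 0.05)
  expect_false(any(out$mask))

  # determinism: no internal randomness
  out2 <- asr_clean(x)
  expect_identical(out$eeg, out2$eeg)

  # planted burst: interval RMS reduced by >= 80% or masked instead
  recb <- generate_session(vm, 66, artifact_plan(
    bursts = data.frame(start_s = 30, dur_s = 2), burst_amp_uv = 500,
    burst_accel_ms2 = 0), seed = 22)
  xb <- bandpass_filter(recb$eeg)
  outb <- asr_clean(xb)
  iv <- (30 * fs + 1):(32 * fs)
  subs <- unique((iv - 1) %/% 55 + 1)
  reduced <- sqrt(mean(outb$eeg[, iv]^2)) <= 0.2 * sqrt(mean(xb[, iv]^2))
  masked <- any(outb$mask[, subs])
  expect_true(reduced || masked)

  expect_error(asr_clean(x[, 1:2200]), "60")
})

test_that("rejection mask flags jumps, motion, and dropouts with the right reason", {
  vm <- make_var_model(NULL, base_diag = 0.6)
  rec <- generate_session(vm, 66, artifact_plan(), seed = 23)
  x <- rec$eeg

  rm0 <- rejection_mask(x, rec$accel, rec$contact)
  expect_false(any(rm0$bad))
  expect_true(rm0$usable)

  # 150 uV single-sample step at t = 30 s -> exactly that subwindow, reason jump
  xj <- x
  step_at <- 30 * fs + 10
  xj[2, step_at:ncol(xj)] <- xj[2, step_at:ncol(xj)] + 150
  rmj <- rejection_mask(xj, rec$accel, rec$contact)
  expect_true(rmj$reasons["jump", (step_at - 1) %/% 55 + 1])
  expect_equal(sum(rmj$reasons["jump", ]), 1)
  expect_false(any(rmj$reasons["accel", ]))

  # 1.5 m/s^2 acceleration for 1 s -> overlapping subwindows, reason accel
  acc <- rec$accel
  acc[1, (40 * 50 + 1):(41 * 50)] <- acc[1, (40 * 50 + 1):(41 * 50)] + 1.5
  rma <- rejection_mask(x, acc, rec$contact)
  hit <- which(rma$reasons["accel", ])
  expect_true(all(hit >= 40 / 0.25 & hit <= 41 / 0.25 + 1))
  expect_gt(length(hit), 2)

  # contact dropout upsampled zero-order-hold
  ct <- rec$contact
  ct[3, (10 * 10 + 1):(12 * 10)] <- 3L
  rmc <- rejection_mask(x, rec$accel, ct)
  expect_true(all(rmc$reasons["contact", (10 / 0.25 + 1):(12 / 0.25)]))

  # a session with no clean minute is flagged unusable, not dropped
  ct_all <- rec$contact
  ct_all[1, seq(1, ncol(ct_all), by = 500)] <- 3L  # dropout every 50 s
  rmu <- rejection_mask(x, rec$accel, ct_all)
  expect_false(rmu$usable)
})

test_that("epoch cutting respects the mask and the 1320-sample epoch length", {
  vm <- make_var_model(NULL, base_diag = 0.6)
  rec <- generate_session(vm, 66, artifact_plan(), seed = 24)
  pp <- preprocess_session(rec)
  expect_equal(length(pp$epochs$epochs), 21)  # floor((66-6)/3)+1
  expect_true(all(vapply(pp$epochs$epochs, ncol, integer(1)) == 1320))
  expect_equal(pp$epochs$kept_fraction, 1)

  # mask 30-36 s: every epoch overlapping that interval is absent
  bad <- rep(FALSE, ceiling(ncol(rec$eeg) / 55))
  bad[(30 / 0.25 + 1):(36 / 0.25)] <- TRUE
  es <- cut_epochs(rec$eeg, bad)
  starts_s <- (es$epoch_start_samples - 1) / fs
  expect_false(any(starts_s < 36 & starts_s + 6 > 30))
  expect_equal(length(es$epochs), 21 - 3)  # epochs starting at 27, 30, 33 s
})

test_that("planted artifacts are recalled and clean data is not over-masked", {
  vm <- make_var_model(NULL, base_diag = 0.6)
  plan <- artifact_plan(bursts = data.frame(start_s = c(65, 80), dur_s = c(2, 1.5)),
                        burst_amp_uv = 500, burst_accel_ms2 = 3,
                        line_noise_uv = 5,
                        dropouts = data.frame(electrode = 2, start_s = 72, dur_s = 4))
  for (seed in 1:3) {
    rec <- generate_session(vm, 90, plan, seed = seed)
    pp <- preprocess_session(rec)
    n <- ncol(rec$eeg)
    masked <- pp$bad[pmin((seq_len(n) - 1) %/% 55 + 1, length(pp$bad))]
    expect_gte(sum(masked & rec$planted_bad) / sum(rec$planted_bad), 0.95)

    clean <- generate_session(vm, 90, artifact_plan(line_noise_uv = 5), seed = seed)
    ppc <- preprocess_session(clean)
    expect_lte(mean(ppc$bad), 0.05)
  }
})

test_that("kept fraction decreases as artifact density rises", {
  vm <- make_var_model(NULL, base_diag = 0.6)
  kept <- vapply(c(0, 1, 2, 3), function(k) {
    plan <- if (k == 0) artifact_plan() else
      artifact_plan(bursts = data.frame(start_s = 5 + 15 * seq_len(k), dur_s = 2),
                    burst_amp_uv = 400, burst_accel_ms2 = 3)
    pp <- preprocess_session(generate_session(vm, 70, plan, seed = 31))
    pp$epochs$kept_fraction
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
  expect_lt(kept[4], kept[1])
})
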