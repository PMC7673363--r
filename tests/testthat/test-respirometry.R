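test_that("cycle segmentation yields the expected measurement windows", {
  plan <- cycle_plan()
  mk_trace <- function(dur) o2_trace(seq(0, dur, by = 2), rep(8, dur / 2 + 1))

  w16h <- segment_cycles(mk_trace(16 * 3600), plan)
  expect_length(w16h, 120)
  expect_equal(vapply(w16h, `[[`, numeric(1), "start"),
               (0:119) * 480 + 180)
  expect_equal(vapply(w16h, `[[`, numeric(1), "end"), (1:120) * 480)
  # windows disjoint and ordered
  starts <- vapply(w16h, `[[`, numeric(1), "start")
  ends <- vapply(w16h, `[[`, numeric(1), "end")
  expect_true(all(starts[-1] > ends[-length(ends)]))

  w1 <- segment_cycles(mk_trace(480), plan)
  expect_length(w1, 1)
  expect_equal(w1[[1]]$start, 180)
  expect_equal(w1[[1]]$end, 480)

  # 12-min trace, 8-min cycles: one full window, trailing partial dropped
  expect_length(segment_cycles(mk_trace(720), plan), 1)

  expect_error(segment_cycles(mk_trace(240), plan), "too short")
  bad <- data.frame(time_s = c(0, 2, 2, 4), o2_mg_l = rep(8, 4))
  class(bad) <- c("o2_trace", "data.frame")
  expect_error(segment_cycles(bad, plan), "strictly increasing")
})

test_that("slope fitting is exact on lines and sane on degenerate input", {
  s <- fit_slope(linear_window(8, -0.001))
  expect_equal(s$slope, -3.6, tolerance = 1e-12)
  expect_equal(s$r_squared, 1, tolerance = 1e-12)
  expect_equal(s$intercept, 8, tolerance = 1e-10)

  flat <- fit_slope(linear_window(8, 0))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)  # zero-variance convention

  expect_error(fit_slope(linear_window(t = c(0, 2))), "fewer than 3")
  const_t <- data.frame(time_s = rep(5, 4), o2_mg_l = 8:11)
  expect_error(fit_slope(const_t), "constant time")
})

test_that("slope recovery under measurement noise is within 2%", {
  set.seed(11)
  errs <- replicate(30, {
    w <- linear_window(8, -0.001, t = seq(0, 298, by = 2))
    w$o2_mg_l <- w$o2_mg_l + rnorm(150, 0, 0.02)
    abs(fit_slope(w)$slope - (-3.6)) / 3.6
  })
  expect_lt(median(errs), 0.02)
})

test_that("background interpolation is linear with no extrapolation", {
  m <- background_model(-0.1, -0.3, 0, 1000)
  expect_equal(background_at(m, 500), -0.2)
  expect_equal(background_at(m, 0), -0.1)
  expect_equal(background_at(m, 1000), -0.3)
  m2 <- background_model(-0.1, -0.1, 0, 1000)
  expect_equal(background_at(m2, 731), -0.1)
  m3 <- background_model(0, -0.4, 0, 1000)
  expect_equal(background_at(m3, 250), -0.1)
  expect_error(background_at(m, 1001), "outside")
  expect_warning(background_model(-0.1, NA, 0, 10), "one blank")
})

test_that("slope-to-MO2 conversion applies the effective volume", {
  ch <- test_chamber()  # 75 + 5 - 1.65 mL = 0.07835 L
  expect_equal(compute_mo2(-1.20, -0.20, ch)$mo2, 0.07835)
  ch2 <- chamber_config(73, 0, fish_volume = 0)
  expect_equal(compute_mo2(-1.0, 0, ch2)$mo2, 0.073)
  res <- compute_mo2(-0.2, -0.2, ch)
  expect_equal(res$mo2, 0)
  expect_false(res$flagged)
  over <- compute_mo2(-0.1, -0.2, ch)
  expect_lt(over$mo2, 0)   # retained, not clamped
  expect_true(over$flagged)
  expect_equal(compute_mo2(-1.0, -0.25, ch)$background_share, 0.25)
  expect_error(chamber_config(75, 5, fish_volume = 81), "smaller")
})

test_that("SMR is the 0.2-quantile with interpolation, plus documented switches", {
  x <- c(0.08, 0.09, 0.10, 0.11, 0.12, 0.14, 0.15, 0.18, 0.20, 0.25, 0.30)
  est <- estimate_smr(mo2_series(x))
  expect_equal(est$smr, 0.10)            # (n-1)*0.2 lands on 3rd order stat
  expect_equal(est$n_cycles, 11)
  expect_match(est$method, "quantile")

  expect_equal(estimate_smr(rep(0.2, 10))$smr, 0.2)
  expect_equal(estimate_smr(mo2_series(x), method = "mean_lowest")$smr,
               mean(sort(x)[1:2]))
  expect_error(estimate_smr(c(1, 2, 3)), "minimum is 5")

  # order statistics and monotone-shift invariants over random series
  set.seed(21)
  for (i in 1:20) {
    v <- rexp(sample(5:60, 1))
    s <- estimate_smr(v)$smr
    expect_lte(s, mean(v))
    expect_gte(s, min(v))
    expect_equal(estimate_smr(v + 0.37)$smr, s + 0.37)
  }
})

test_that("background share is summarised as a mean percentage", {
  s <- mo2_series(c(1, 1, 1, 1, 1), background_share = rep(0.166, 5))
  expect_equal(estimate_smr(s)$mean_background_fraction, 16.6)
})

test_that("saturation converts linearly to concentration", {
  expect_equal(convert_saturation(100, 8.26), 8.26)
  expect_equal(convert_saturation(0, 8.26), 0)
  expect_equal(convert_saturation(60, 8.26), 4.956)
  expect_error(convert_saturation(-1, 8.26), ">= 0")
  expect_error(convert_saturation(50, 0), "> 0")
})

test_that("noiseless piecewise-linear traces round-trip exactly", {
  plan <- cycle_plan()
  ch <- test_chamber()
  uptake <- c(0.08, 0.12, 0.1, 0.2, 0.09, 0.15)
  tr <- simulate_o2_trace(ch, plan, uptake, noise_sd = 0, seed = 1)
  series <- trace_to_mo2(tr, plan, ch)
  expect_equal(series$mo2, uptake, tolerance = 1e-9)
})

test_that("a fish-free (background-only) trace corrects to near zero", {
  plan <- cycle_plan()
  ch <- chamber_config(75, 5, fish_volume = 0)
  bg <- background_model(-0.1, -0.3, 0, 20 * 480)
  tr <- simulate_o2_trace(ch, plan, uptake = rep(0, 20), background = bg,
                          noise_sd = 0, seed = 1)
  raw <- trace_to_mo2(tr, plan, ch)               # uncorrected
  corr <- trace_to_mo2(tr, plan, ch, background = bg)
  expect_lt(abs(mean(corr$mo2)) / mean(abs(raw$mo2)), 0.02)
})
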