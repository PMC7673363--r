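test_that("generators are seed-deterministic", {
  ch <- test_chamber()
  plan <- cycle_plan()
  t1 <- simulate_o2_trace(ch, plan, rep(0.1, 5), noise_sd = 0.02, seed = 9)
  t2 <- simulate_o2_trace(ch, plan, rep(0.1, 5), noise_sd = 0.02, seed = 9)
  expect_identical(t1, t2)

  e1 <- simulate_breath_events(7, 720, 0.5, p = 0.5, seed = 4)
  e2 <- simulate_breath_events(7, 720, 0.5, p = 0.5, seed = 4)
  expect_identical(e1, e2)

  r1 <- simulate_trajectories(5, 100, 0.2, kappa = 0.1, seed = 8)
  r2 <- simulate_trajectories(5, 100, 0.2, kappa = 0.1, seed = 8)
  expect_identical(r1, r2)

  s1 <- simulate_study(design = study_design(n_groups = 2, traj_frames = 50),
                       seed = 13)
  s2 <- simulate_study(design = study_design(n_groups = 2, traj_frames = 50),
                       seed = 13)
  expect_identical(s1, s2)
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_breath_events(3, 60, 1, seed = 2))
  expect_identical(rnorm(1), before)
})

test_that("simulated traces honour their generating uptake and fail on hypoxia", {
  ch <- test_chamber()
  plan <- cycle_plan()
  tr <- simulate_o2_trace(ch, plan, uptake = rep(0.12, 8), noise_sd = 0, seed = 1)
  est <- estimate_smr(trace_to_mo2(tr, plan, ch))
  expect_equal(est$smr, 0.12, tolerance = 1e-9)
  expect_equal(attr(tr, "truth")$uptake, rep(0.12, 8))
  # an uptake high enough to exhaust the chamber within a closed phase
  expect_error(simulate_o2_trace(ch, plan, uptake = rep(60, 3), noise_sd = 0),
               "hypoxic chamber")
})

test_that("expected per-fish breath rate is invariant to participation p", {
  totals <- vapply(c(0, 0.5, 1), function(p) {
    mean(vapply(1:300, function(s)
      nrow(simulate_breath_events(7, 720, 0.5, p = p, seed = 600 + s)),
      numeric(1)))
  }, numeric(1))
  # expectation 0.5 * 7 * 12 = 42; SE of the mean ~ 0.45 at p = 0
  expect_true(all(abs(totals - 42) < 3 * 0.6))
})

test_that("straight-line no-noise trajectories move at exactly speed_scale", {
  ar <- arena_config(frame_rate = 25)
  tr <- simulate_trajectories(3, 20, speed_scale = 0.3, kappa = 0,
                              heading_sd = 0, arena = ar, seed = 15)
  # displacement per frame is exactly speed_scale (reflection preserves length)
  sp <- mean_speed(tr, ar)
  expect_equal(sp$mean_speed, 0.3 * 25, tolerance = 1e-9)
})

test_that("cohesion decreases monotonically with the attraction parameter", {
  ar <- arena_config()
  coh <- vapply(c(0, 0.2, 0.5, 1, 2), function(k) {
    mean(vapply(1:3, function(s) {
      tr <- simulate_trajectories(7, 800, 0.12, kappa = k, arena = ar,
                                  seed = 500 + s)
      cohesion(tr)$cohesion
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(coh) < 0))
})

test_that("without attraction, long-run cohesion approaches the uniform-disc value", {
  ar <- arena_config()
  tr <- simulate_trajectories(7, 10000, speed_scale = 1, kappa = 0,
                              heading_sd = 1, arena = ar, seed = 3)
  analytic <- 128 * ar$radius / (45 * pi)  # mean distance, uniform disc
  expect_lt(abs(cohesion(tr)$cohesion - analytic) / analytic, 0.05)
})

test_that("the study generator produces the factorial design with its truth", {
  des <- study_design(traj_frames = 50)
  sim <- simulate_study(design = des, seed = 19)
  expect_equal(nrow(sim$per_trial), 6 * 2 * 3)
  expect_equal(nrow(sim$per_fish), 6 * 7 * 2 * 3)
  expect_equal(nrow(sim$smr_table), 6 * 7 * 2)
  # conservation: group totals equal summed individual counts
  agg <- aggregate(abf ~ trial_id, sim$per_fish, sum)
  m <- merge(agg, sim$per_trial[, c("trial_id", "abf_group")])
  expect_equal(m$abf, m$abf_group)
  # each fish nested in exactly one group
  expect_equal(nrow(unique(sim$per_fish[, c("fish_id", "group")])), 42)
  # truth sidecar carries the generating SMR
  expect_true(all(c("fish_id", "temp", "smr_true") %in%
                    names(sim$truth$smr_true)))
  # SMR values scatter around the allometric truth
  expect_equal(median(abs(log(sim$smr_table$smr / sim$smr_table$smr_true))) <
                 3 * 0.15, TRUE)
})

test_that("raw mode emits consistent streams for the full pipeline", {
  des <- study_design(n_groups = 2, group_size = 3, traj_frames = 40,
                      respirometry_duration = 2 * 3600)
  sim <- simulate_study(design = des, seed = 23, raw = TRUE)
  expect_equal(length(sim$traces), nrow(sim$smr_table))
  expect_equal(sort(unique(sim$events$trial_id)),
               sort(sim$per_trial$trial_id[sim$per_trial$n_events > 0]))
  expect_equal(nrow(sim$roster), 2 * 3 * 2 * 3)  # fish x temp x o2 trials
  # SMR recovered from a raw trace lands near the generating SMR:
  # per-cycle uptake is baseline plus non-negative bursts, so the lowest
  # 20th percentile sits at the baseline
  k <- 1
  ch <- chamber_config(75, 5, fish_mass = sim$smr_table$mass[k])
  plan <- cycle_plan()
  key <- sprintf("%s_t%s", sim$smr_table$fish_id[k],
                 as.character(sim$smr_table$temp[k]))
  series <- trace_to_mo2(sim$traces[[key]], plan, ch,
                         background = sim$blanks[[key]])
  est <- estimate_smr(series)
  expect_lt(abs(est$smr - sim$smr_table$smr[k]) / sim$smr_table$smr[k], 0.15)
})
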