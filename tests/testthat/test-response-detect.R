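# fixture: trials of one stimulus with a controllable five-lick kernel
kernel_fixture <- function(n_trials, mag = 0, lat = 0.1, dur = 0.5, sign = 1,
                           base = 10, seed = 1, timescale = "five_lick") {
  sc <- quick_trials(n_trials, seed = seed)
  k <- if (mag > 0)
    data.frame(stimulus = "X", sign = sign, magnitude = mag, latency = lat,
               duration = dur, timescale = timescale)
  else empty_kernels()
  spec <- cell_spec("u", if (mag > 0) "taste" else "nonresponsive",
                    spont_rate = base, baseline_rate = base,
                    response_kernels = k)
  st <- quick_spikes(sc, spec, seed = seed + 1)
  list(spikes = st, trials = sc$trials, licks = sc$licks, duration = sc$duration)
}

test_that("spontaneous_rate uses the middle 10 s of lick-free 14 s spans", {
  st <- spike_train("u", seq(0.05, 139.95, by = 0.1))  # exactly 10 sps
  no_licks <- lick_train(numeric(0), character(0))
  r <- spontaneous_rate(st, no_licks, duration = 140)
  expect_equal(r$n_windows, 10)
  expect_equal(r$mean, 10)
  silent <- spike_train("s", numeric(0))
  r2 <- spontaneous_rate(silent, no_licks, duration = 140)
  expect_equal(r2$mean, 0)
  expect_equal(r2$sd, 0)
  # licking everywhere except a 13 s gap: no qualifying span
  licks <- lick_train(seq(0, 100, by = 0.2))
  r3 <- spontaneous_rate(spike_train("u", c(104, 105)), licks, duration = 113)
  expect_equal(r3$n_windows, 0)
  expect_true(is.na(r3$mean))
  expect_true(isTRUE(r3$no_spontaneous_window))
})

test_that("spontaneous_rate is Poisson-consistent on homogeneous input", {
  no_licks <- lick_train(numeric(0), character(0))
  spec <- cell_spec("u", "nonresponsive", spont_rate = 10)
  st <- generate_spike_train(spec, no_licks, NULL, 140, seed = 4)
  r <- spontaneous_rate(st, no_licks, duration = 140)
  expect_lt(abs(r$mean - 10), 3 * sqrt(10 / 100))  # 10 windows x 10 s
})

test_that("baseline_rate averages the pre-trial second across trials", {
  tr <- data.frame(stimulus_id = "X", t0 = c(10, 20, 30),
                   lick1 = c(10, 20, 30), lick2 = 0, lick3 = 0,
                   lick4 = 0, lick5 = 0)
  st <- spike_train("u", c(seq(9.05, 9.95, 0.05), seq(19.05, 19.95, 0.05)))
  r <- baseline_rate(st, tr)
  expect_equal(r$mean, mean(c(19, 19, 0)))
  expect_equal(r$n_windows, 3)
  # single trial: SD 0, flagged by n_windows = 1
  r1 <- baseline_rate(st, tr[1, ])
  expect_equal(r1$sd, 0)
  expect_equal(r1$n_windows, 1)
  expect_error(baseline_rate(st, tr[0, ]), "trial")
  # spikes only after t0
  st2 <- spike_train("u", c(10.2, 20.3, 30.1))
  expect_equal(baseline_rate(st2, tr)$mean, 0)
})

test_that("five-lick detector recovers an excitatory step", {
  fx <- kernel_fixture(20, mag = 20, lat = 0.1, dur = 0.5, seed = 10)
  r <- detect_5lick_response(fx$spikes, fx$trials)
  expect_true(r$significant)
  expect_equal(r$sign, "excitatory")
  expect_true(r$latency >= 0.1 && r$latency <= 0.22)
  expect_true(r$duration >= 0.38 && r$duration <= 0.62)
  expect_lt(abs(r$magnitude - 20), 4)
})

test_that("five-lick detector recovers an inhibitory step", {
  fx <- kernel_fixture(20, mag = 14, lat = 0.1, dur = 0.8, sign = -1,
                       base = 15, seed = 12)
  r <- detect_5lick_response(fx$spikes, fx$trials)
  expect_true(r$significant)
  expect_equal(r$sign, "inhibitory")
  expect_lt(abs(r$magnitude - (-14)), 4)
})

test_that("detector is translation invariant", {
  fx <- kernel_fixture(12, mag = 25, lat = 0.15, dur = 0.6, seed = 14)
  r0 <- detect_5lick_response(fx$spikes, fx$trials)
  sh <- 123.456775  # a multiple of 25 us
  st2 <- spike_train("u", fx$spikes$times + sh)
  tr2 <- fx$trials
  for (cn in c("t0", paste0("lick", 1:5))) tr2[[cn]] <- tr2[[cn]] + sh
  r1 <- detect_5lick_response(st2, tr2)
  expect_equal(r1[c("significant", "sign", "magnitude", "latency", "duration")],
               r0[c("significant", "sign", "magnitude", "latency", "duration")])
})

test_that("increasing magnitude never flips significance off", {
  for (seed in c(21, 22, 23)) {
    sig <- vapply(c(12, 24, 48), function(m) {
      fx <- kernel_fixture(15, mag = m, lat = 0.1, dur = 0.5, seed = seed)
      detect_5lick_response(fx$spikes, fx$trials)$significant
    }, TRUE)
    expect_true(all(diff(as.integer(sig)) >= 0))
  }
})

test_that("five-lick parameter recovery over the stated grid", {
  # scaled-down sweep of the recovery grid (full 50-seed sweep lives in
  # the acceptance suite)
  grid <- expand.grid(mag = c(20, 40), lat = c(0.05, 0.3), dur = c(0.5, 1.0))
  err_lat <- err_mag <- numeric(0)
  for (i in seq_len(nrow(grid))) {
    for (seed in 1:5) {
      fx <- kernel_fixture(20, mag = grid$mag[i], lat = grid$lat[i],
                           dur = grid$dur[i], seed = 100 * i + seed)
      r <- detect_5lick_response(fx$spikes, fx$trials)
      if (r$significant && r$sign == "excitatory") {
        err_lat <- c(err_lat, abs(r$latency - grid$lat[i]))
        err_mag <- c(err_mag, abs(r$magnitude - grid$mag[i]) / grid$mag[i])
      }
    }
  }
  expect_gt(length(err_lat), 0.9 * nrow(grid) * 5)
  expect_lte(median(err_lat), 0.06)
  expect_lte(median(err_mag), 0.15)
})

test_that("lick-by-lick detector finds short-latency phasic responses", {
  fx <- kernel_fixture(12, mag = 30, lat = 0.010, dur = 0.055, base = 4,
                       seed = 30, timescale = "lick_by_lick")
  r <- detect_lickbylick_response(fx$spikes, fx$trials)
  expect_true(r$significant)
  expect_equal(r$sign, "excitatory")
  expect_true(r$latency >= 0.008 && r$latency <= 0.035)
  expect_error(detect_lickbylick_response(fx$spikes, fx$trials[1, ]),
               ">= 10 aligned sweeps")
})

test_that("a response shorter than three windows is not significant", {
  # kernel confined to [0, 6] ms cannot span 3 distinct 10 ms windows
  # that all clear the criterion at their trailing edges
  fx <- kernel_fixture(12, mag = 60, lat = 0.0, dur = 0.006, base = 6,
                       seed = 31, timescale = "lick_by_lick")
  r <- detect_lickbylick_response(fx$spikes, fx$trials)
  if (r$significant) {
    expect_lte(r$duration, 0.02)
  } else {
    expect_equal(r$sign, "none")
    expect_true(is.na(r$magnitude))
  }
})

test_that("null inputs stay at the frozen false-positive bounds", {
  # measured once at 200 runs x 20 trials (full 1000-run measurement in
  # the acceptance suite); frozen as a regression bound
  sig5 <- sigl <- logical(200)
  for (s in 1:200) {
    fx <- kernel_fixture(20, mag = 0, seed = 4000 + 3 * s)
    sig5[s] <- detect_5lick_response(fx$spikes, fx$trials)$significant
    sigl[s] <- detect_lickbylick_response(fx$spikes, fx$trials)$significant
  }
  expect_lte(mean(sig5), 0.08)
  expect_lte(mean(sigl), 0.03)
})

test_that("degenerate baselines fall back to the SD floor, flagged", {
  sc <- quick_trials(8, seed = 40)
  # silent before every trial, bursts after
  bursts <- sort(unlist(lapply(sc$trials$t0, function(t0) t0 + seq(0.1, 0.5, 0.01))))
  st <- spike_train("u", bursts)
  r <- detect_5lick_response(st, sc$trials)
  expect_true(r$significant)
  expect_true(r$sd_floor_used)
  expect_equal(r$sign, "excitatory")
})

test_that("tuning_breadth counts quartet stimuli at either time scale", {
  df <- data.frame(
    stimulus_id = rep(traditional_quartet(), each = 2),
    timescale = rep(c("five_lick", "lick_by_lick"), 4),
    significant = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(tuning_breadth(df), 3)
  df$significant <- FALSE
  expect_equal(tuning_breadth(df), 0)
  df$significant <- TRUE
  expect_equal(tuning_breadth(df), 4)
  expect_error(tuning_breadth(df[df$stimulus_id != "N", ]), "missing")
})
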