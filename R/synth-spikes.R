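#' Construct a spike train
#'
#' @param unit_id unit identifier.
#' @param times spike times in seconds; quantized to the 25 us
#'   acquisition grid.
#' @param check validate strict ordering after quantization.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(unit_id, times, check = TRUE) {
  times <- quantize_times(as.numeric(times))
  if (check && length(times) > 1 && any(diff(times) <= 0))
    stop_config("spike times must be strictly increasing after 25 us quantization")
  structure(list(unit_id = as.character(unit_id), times = times),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train %s: %d spikes", x$unit_id, length(x$times)))
  if (length(x$times) > 1)
    cat(sprintf(" over %.1f s (%.2f sps)", diff(range(x$times)),
                length(x$times) / diff(range(x$times))))
  cat("\n")
  invisible(x)
}

# step function from a set of (start, end, height) intervals; returns a
# vectorized evaluator. Overlapping intervals sum.
step_fun <- function(start, end, height) {
  if (length(start) == 0) return(function(t) rep(0, length(t)))
  brk <- c(rbind(start, end))
  dh <- c(rbind(height, -height))
  o <- order(brk)
  brk <- brk[o]; lev <- cumsum(dh[o])
  function(t) {
    i <- findInterval(t, brk)
    ifelse(i == 0, 0, lev[pmax(i, 1L)])
  }
}

# instantaneous-rate evaluator for a cell spec given the session's
# licking structure; returns function(t) in sps
build_rate_fun <- function(spec, licks, trials, pause_threshold = 1) {
  bouts <- lick_bouts(licks, max_ili = pause_threshold, min_length = 0)
  lt <- licks$times
  kap <- spec$lick_mod_depth
  phase0 <- spec$lick_mod_phase
  i0 <- besselI(kap, 0)

  edge_f <- if (spec$bout_edge_mag > 0 && nrow(bouts)) {
    b <- bouts[bouts$end - bouts$start >= 1, , drop = FALSE]
    step_fun(c(b$start - 0.5, b$end), c(b$start, b$end + 0.5),
             rep(spec$bout_edge_mag, 2 * nrow(b)))
  } else function(t) 0

  kern_f <- local({
    k <- spec$response_kernels
    if (is.null(trials) || nrow(k) == 0 || is.null(trials) || nrow(trials) == 0) {
      function(t) 0
    } else {
      ss <- es <- hs <- numeric(0)
      for (r in seq_len(nrow(k))) {
        tr <- trials[trials$stimulus_id == k$stimulus[r], , drop = FALSE]
        if (nrow(tr) == 0) next
        anchors <- if (k$timescale[r] == "five_lick") tr$t0 else
          c(tr$lick1, tr$lick2, tr$lick3, tr$lick4, tr$lick5)
        ss <- c(ss, anchors + k$latency[r])
        es <- c(es, anchors + k$latency[r] + k$duration[r])
        hs <- c(hs, rep(k$sign[r] * k$magnitude[r], length(anchors)))
      }
      step_fun(ss, es, hs)
    }
  })

  function(t) {
    inb <- in_intervals(t, bouts$start, bouts$end)
    base <- ifelse(inb, spec$baseline_rate, spec$spont_rate)
    if (kap > 0 && length(lt) > 1) {
      i <- findInterval(t, lt)
      ok <- inb & i >= 1 & i < length(lt)
      ii <- pmax(pmin(i, length(lt) - 1L), 1L)
      gap <- lt[ii + 1L] - lt[ii]
      ph <- 2 * pi * (t - lt[ii]) / gap
      gain <- ifelse(ok & gap <= pause_threshold,
                     exp(kap * cos(ph - phase0)) / i0, 1)
      base <- base * gain
    }
    base + edge_f(t) + kern_f(t)
  }
}

#' Generate a spike train for one synthetic unit
#'
#' Realizes an inhomogeneous Poisson process by thinning from the rate
#' `lambda(t) = base(t) * lickgain(t) + kernels(t)`, where `base` is
#' the spontaneous rate outside lick bouts and the in-bout baseline
#' inside, `lickgain` is a von Mises-shaped gain locked to lick phase
#' (unit mean over phase), and `kernels` are rectangular taste-evoked
#' rate steps anchored at trial onsets (five-lick time scale) or at
#' individual stimulus licks (lick-by-lick). A 2 ms refractory period
#' is enforced by deletion, matching the unit-isolation criterion, and
#' times are quantized to 25 us.
#'
#' @param spec a [cell_spec].
#' @param licks a [lick_train].
#' @param trials trial table from [schedule_trials()] (or `NULL` for a
#'   stimulus-free train).
#' @param duration session length (s); must cover all trials.
#' @param seed optional RNG seed.
#' @return a [spike_train].
#' @export
generate_spike_train <- function(spec, licks, trials, duration, seed = NULL) {
  stopifnot(inherits(spec, "cell_spec"), inherits(licks, "lick_train"))
  if (!is.numeric(duration) || duration <= 0) stop_config("duration must be > 0")
  if (!is.null(trials) && nrow(trials) &&
      max(trials$lick5) + max(c(0, spec$response_kernels$latency +
                                   spec$response_kernels$duration)) > duration + 1e-9)
    stop_config("duration does not cover all trials and their response kernels")
  lambda0 <- build_rate_fun(spec, licks, trials)
  # 5 ms survey grid bounds the smooth rate envelope; the 8% headroom
  # below covers between-knot excursions of the von Mises gain
  grid <- seq(0, duration, by = 0.005)
  lg <- lambda0(grid)
  if (any(lg < -1e-9))
    stop_config("rate model is negative (min %.3f sps): invalid cell specification", min(lg))
  with_seed(seed, {
    # slow multiplicative excitability drift: lognormal (mean 1) knots
    # every 60 s, linearly interpolated
    lambda <- lambda0
    gmax <- 1
    if (spec$rate_drift_cv > 0) {
      sig <- sqrt(log(1 + spec$rate_drift_cv^2))
      knots <- seq(0, duration + 60, by = 60)
      gk <- exp(rnorm(length(knots), -sig^2 / 2, sig))
      gain <- stats::approxfun(knots, gk, rule = 2)
      gmax <- max(gk)
      lambda <- function(t) lambda0(t) * gain(t)
    }
    lmax <- max(lg) * gmax * 1.08 + 1e-6
    n <- rpois(1, lmax * duration)
    cand <- sort(runif(n, 0, duration))
    lc <- lambda(cand)
    if (any(lc < -1e-9))
      stop_config("rate model is negative at t = %.3f s", cand[which.min(lc)])
    keep <- runif(n) < pmax(lc, 0) / lmax
    t <- cand[keep]
    # enforce the 2 ms refractory period by greedy deletion; the extra
    # tick keeps the ISI strictly above 2 ms after 25 us quantization
    if (length(t) > 1) {
      kept <- logical(length(t)); last <- -Inf
      for (i in seq_along(t)) {
        if (t[i] - last > 0.002 + TICK) { kept[i] <- TRUE; last <- t[i] }
      }
      t <- t[kept]
    }
    spike_train(spec$unit_id, t)
  })
}

#' Generate a complete synthetic session
#'
#' Draws ground-truth cell specifications from a group preset,
#' generates the lick train, schedules taste trials, and realizes one
#' spike train per cell. The returned specs make parameter-recovery
#' tests possible downstream.
#'
#' @param preset a [group_preset] or preset name (`"lean"`, `"DIO"`).
#' @param n_cells number of units (>= 1).
#' @param trials_per_stimulus trials per stimulus (default the
#'   preset's, 6).
#' @param seed optional RNG seed.
#' @param panel stimulus panel (default the preset's 12 stimuli).
#' @param duration session length (s); `NULL` sizes the session to host
#'   all trials plus lick-free rest periods.
#' @param subject_id subject identifier.
#' @return list with `session` (a [session] object) and `specs` (list
#'   of [cell_spec], the ground truth).
#' @export
generate_session <- function(preset, n_cells, trials_per_stimulus = NULL,
                             seed = NULL, panel = NULL, duration = NULL,
                             subject_id = NULL) {
  if (is.character(preset)) preset <- group_preset(preset)
  stopifnot(inherits(preset, "group_preset"))
  if (!is_count(n_cells) || n_cells < 1)
    stop_config("n_cells must be a positive integer")
  if (is.null(trials_per_stimulus)) trials_per_stimulus <- preset$trials_per_stimulus
  if (is.null(panel)) panel <- preset$panel
  if (is.null(subject_id)) subject_id <- paste0(preset$name, "_synth")

  n_trials <- length(panel) * trials_per_stimulus
  # licks consumed per trial: 5 stimulus + 5 rinse + ~5x5 dry
  need_licks <- ceiling(n_trials * 36 * 1.15) + 50
  if (is.null(duration)) {
    # bouts occupy roughly 75% of session time under default pauses
    duration <- ceiling(need_licks * preset$ili_mean / 0.80) + 60
  }
  lk <- generate_lick_train(duration, preset$ili_mean, preset$ili_sd,
                            seed = sub_seed(seed, 11L))
  sched <- NULL
  for (try in 1:5) {
    sched <- tryCatch(
      schedule_trials(lk, panel, trials_per_stimulus, seed = sub_seed(seed, 12L)),
      error = function(e) e)
    if (!inherits(sched, "error")) break
    duration <- ceiling(duration * 1.3)
    lk <- generate_lick_train(duration, preset$ili_mean, preset$ili_sd,
                              seed = sub_seed(seed, 11L))
  }
  if (inherits(sched, "error")) stop(sched)

  # leave room for the longest admissible kernel after the last trial
  duration <- max(duration, max(sched$trials$lick5) + 6)
  specs <- draw_cell_specs(preset, n_cells, panel, seed = sub_seed(seed, 13L))
  units <- lapply(seq_along(specs), function(i) {
    generate_spike_train(specs[[i]], sched$licks, sched$trials, duration,
                         seed = sub_seed(seed, 100L + i))
  })
  ses <- session(subject_id = subject_id, group = preset$name, units = units,
                 licks = sched$licks, trials = sched$trials,
                 duration = duration, panel = panel)
  list(session = ses, specs = specs)
}
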