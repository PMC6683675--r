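#' Construct a lick train
#'
#' @param times lick times in seconds, strictly increasing.
#' @param labels per-lick tag: `"dry"`, `"rinse"`, or `"stimulus:<id>"`.
#' @param check validate invariants (strictly increasing times,
#'   inter-lick intervals >= 0.05 s).
#' @return object of class `lick_train`.
#' @export
lick_train <- function(times, labels = rep("dry", length(times)), check = TRUE) {
  times <- quantize_times(as.numeric(times))
  labels <- as.character(labels)
  if (length(labels) != length(times))
    stop_config("labels and times differ in length")
  if (check && length(times) > 1) {
    d <- diff(times)
    if (any(d <= 0)) stop_config("lick times must be strictly increasing")
    if (any(d < 0.05 - 1e-9))
      stop_config("inter-lick interval below the 50 ms motor floor")
  }
  ok <- labels %in% c("dry", "rinse") | startsWith(labels, "stimulus:")
  if (!all(ok)) stop_config("unknown lick label '%s'", labels[!ok][1])
  structure(list(times = times, labels = labels), class = "lick_train")
}

#' @export
print.lick_train <- function(x, ...) {
  cat(sprintf("lick_train: %d licks over %.1f s (%d stimulus, %d rinse, %d dry)\n",
              length(x$times), if (length(x$times)) diff(range(x$times)) else 0,
              sum(startsWith(x$labels, "stimulus:")),
              sum(x$labels == "rinse"), sum(x$labels == "dry")))
  invisible(x)
}

# truncated-normal inter-lick intervals, floored at the 50 ms motor limit
r_ili <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < 0.05)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a rhythmic lick train with bouts and pauses
#'
#' Licks occur in bouts of near-periodic licking at the species-typical
#' 6-7 Hz rhythm; bouts are separated by pauses. Inter-lick intervals
#' within bouts are truncated-normal with a 50 ms floor. All licks are
#' labeled `"dry"`; [schedule_trials()] assigns reinforcement labels.
#'
#' @param duration session length in seconds (> 0).
#' @param ili_mean mean within-bout inter-lick interval (s), > 0.05.
#' @param ili_sd SD of the inter-lick interval (s).
#' @param bout_length_dist number of licks per bout: a function(n)
#'   returning integer draws, a single number, or `Inf` for one
#'   uninterrupted bout. Default: lognormal, median ~35 licks.
#' @param pause_dist pause length between bouts (s): a function(n), a
#'   single number, or `NULL` for no pauses. Pauses must exceed 1 s.
#'   The default mixes short pauses (~1-4 s) with occasional long
#'   (>= 15 s) lick-free rests so spontaneous-rate windows exist.
#' @param seed optional RNG seed.
#' @return a [lick_train] starting at time 0 and confined to
#'   `[0, duration]`.
#' @export
generate_lick_train <- function(duration, ili_mean = 0.155, ili_sd = 0.02,
                                bout_length_dist = NULL, pause_dist = NULL,
                                seed = NULL) {
  if (!is.numeric(duration) || duration <= 0)
    stop_config("duration must be > 0")
  if (!is.numeric(ili_mean) || ili_mean <= 0.05)
    stop_config("ili_mean must exceed the 50 ms motor floor")
  if (ili_sd < 0) stop_config("ili_sd must be >= 0")
  one_bout <- identical(bout_length_dist, Inf)
  bl <- if (is.null(bout_length_dist)) {
    # near-continuous licking: published microstructure tables show a
    # few pauses per several hundred trials, i.e. runs of hundreds of
    # licks (tens of seconds) between rests
    function(n) pmax(10L, round(exp(rnorm(n, log(400), 0.6))))
  } else if (is.function(bout_length_dist)) {
    bout_length_dist
  } else if (is.numeric(bout_length_dist) && !one_bout) {
    if (bout_length_dist < 1) stop_config("bout length must be >= 1 lick")
    function(n) rep(as.integer(bout_length_dist), n)
  } else if (!one_bout) stop_config("invalid bout_length_dist")
  pl <- if (is.null(pause_dist)) {
    # mixture: short rests plus occasional long (>= 16 s) lick-free
    # periods, which the spontaneous-rate estimator depends on
    function(n) ifelse(runif(n) < 0.25, runif(n, 16, 40), 1.2 + rgamma(n, 2, 1.2))
  } else if (is.function(pause_dist)) {
    pause_dist
  } else if (is.numeric(pause_dist)) {
    if (any(pause_dist <= 1)) stop_config("pauses must exceed 1 s")
    function(n) rep(pause_dist, n)
  } else stop_config("invalid pause_dist")

  with_seed(seed, {
    if (one_bout) {
      n <- floor(duration / ili_mean) + 1L
      ilis <- r_ili(n - 1L, ili_mean, ili_sd)
      t <- cumsum(c(0, ilis))
      return(lick_train(t[t <= duration - TICK]))
    }
    t <- numeric(0); now <- 0
    while (now <= duration) {
      L <- max(1L, as.integer(bl(1)))
      ilis <- r_ili(L - 1L, ili_mean, ili_sd)
      bout <- now + cumsum(c(0, ilis))
      t <- c(t, bout)
      now <- bout[length(bout)] + max(1 + 1e-6, pl(1))
    }
    lick_train(t[t <= duration - TICK])
  })
}

#' Assign taste-trial structure to a lick train
#'
#' Labels licks so that each trial is a block of five consecutive
#' stimulus-reinforced licks, followed by five artificial-saliva rinse
#' licks, each preceded by 4-6 dry (unreinforced) licks (the variable
#' ratio 5 schedule). Stimuli are presented in pseudorandomized blocks:
#' each block contains every panel stimulus once in shuffled order, and
#' the session opens with the designated starter stimulus.
#'
#' @param licks a [lick_train] (labels are overwritten).
#' @param panel character vector of stimulus ids.
#' @param trials_per_stimulus trials per stimulus.
#' @param seed optional RNG seed.
#' @param first_stimulus stimulus of the first trial; default
#'   `"Lo Su"` (low sucrose) when present in the panel, else the first
#'   panel entry.
#' @param dry_range inclusive integer range of dry licks before each
#'   rinse lick; default `c(4, 6)`.
#' @return list with `licks` (relabeled [lick_train]) and `trials`
#'   (data.frame: `stimulus_id`, `t0`, `lick1`..`lick5`).
#' @export
schedule_trials <- function(licks, panel, trials_per_stimulus, seed = NULL,
                            first_stimulus = "Lo Su", dry_range = c(4L, 6L)) {
  stopifnot(inherits(licks, "lick_train"))
  if (length(panel) == 0) stop_config("panel must be nonempty")
  if (anyDuplicated(panel)) stop_config("panel has duplicate stimulus ids")
  if (!is_count(trials_per_stimulus) || trials_per_stimulus < 1)
    stop_config("trials_per_stimulus must be a positive integer")
  starter <- if (first_stimulus %in% panel) first_stimulus else panel[1]

  with_seed(seed, {
    order <- unlist(lapply(seq_len(trials_per_stimulus), function(b) {
      blk <- sample(panel)
      if (b == 1L) blk <- c(starter, blk[blk != starter][seq_len(length(panel) - 1L)])
      blk
    }))
    n_lick <- length(licks$times)
    labels <- rep("dry", n_lick)
    trials <- vector("list", length(order))
    ptr <- 1L
    for (k in seq_along(order)) {
      if (ptr + 4L > n_lick)
        stop_config("scheduling error: lick train exhausted at trial %d of %d (%d licks short)",
                    k, length(order), ptr + 4L - n_lick)
      idx <- ptr:(ptr + 4L)
      labels[idx] <- paste0("stimulus:", order[k])
      trials[[k]] <- data.frame(stimulus_id = order[k], t0 = licks$times[idx[1]],
                                lick1 = licks$times[idx[1]], lick2 = licks$times[idx[2]],
                                lick3 = licks$times[idx[3]], lick4 = licks$times[idx[4]],
                                lick5 = licks$times[idx[5]],
                                stringsAsFactors = FALSE)
      ptr <- ptr + 5L
      # inter-trial block: five rinse licks on the VR5 schedule
      for (r in 1:5) {
        u <- sample(seq.int(dry_range[1], dry_range[2]), 1L)
        ptr <- ptr + u          # u dry licks stay labeled "dry"
        if (ptr > n_lick) {
          if (k == length(order)) break   # session may end mid-rinse
          stop_config("scheduling error: lick train exhausted in rinse block after trial %d of %d",
                      k, length(order))
        }
        labels[ptr] <- "rinse"
        ptr <- ptr + 1L
      }
    }
    list(licks = lick_train(licks$times, labels),
         trials = do.call(rbind, trials))
  })
}
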