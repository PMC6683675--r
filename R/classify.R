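# -------------------------------------------------------------------------
# Lick-relation cell classification. Precedence: any significant taste
# response makes the cell a taste cell; otherwise the cell's relation
# to the lick rhythm and to lick bouts decides the label.
# -------------------------------------------------------------------------

# in-bout vs out-of-bout rates with a circular-shift permutation check.
# Returns observed ratio and the one-sided permutation quantile bounds.
bout_rate_stats <- function(spikes, bouts, duration, n_perm = 200, seed = NULL) {
  st <- spikes$times
  tot_in <- sum(bouts$end - bouts$start)
  tot_out <- duration - tot_in
  if (tot_in <= 0 || tot_out <= 0 || length(st) == 0)
    return(list(ratio = 1, lo = 0, hi = Inf, in_rate = NA, out_rate = NA))
  rate_pair <- function(t) {
    nin <- sum(in_intervals(t, bouts$start, bouts$end))
    c(nin / tot_in, (length(t) - nin) / tot_out)
  }
  obs <- rate_pair(st)
  ratios <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      t <- (st + runif(1, 0, duration)) %% duration
      rp <- rate_pair(t)
      if (rp[2] == 0) Inf else rp[1] / rp[2]
    }, numeric(1))
  })
  list(ratio = if (obs[2] == 0) Inf else obs[1] / obs[2],
       lo = as.numeric(quantile(ratios, 0.05, na.rm = TRUE)),
       hi = as.numeric(quantile(ratios, 0.95, na.rm = TRUE)),
       in_rate = obs[1], out_rate = obs[2])
}

# peri-bout phasic increase: rate in the 0.5 s flanks of bout edges vs
# the remaining out-of-bout time
peri_bout_increase <- function(spikes, bouts, duration) {
  if (nrow(bouts) == 0) return(FALSE)
  st <- spikes$times
  flank_s <- pmax(bouts$start - 0.5, 0)
  flank_e <- pmin(bouts$end + 0.5, duration)
  in_flank <- (in_intervals(st, flank_s, bouts$start) |
                 in_intervals(st, bouts$end, flank_e)) &
    !in_intervals(st, bouts$start, bouts$end)
  t_flank <- sum(bouts$start - flank_s) + sum(flank_e - bouts$end)
  out <- !in_intervals(st, flank_s, flank_e)
  t_out <- duration - sum(flank_e - flank_s) - sum(bouts$end - bouts$start) +
    sum((flank_e - flank_s)) - t_flank
  t_far <- duration - sum(bouts$end - bouts$start) - t_flank
  if (t_flank <= 0 || t_far <= 0) return(FALSE)
  r_flank <- sum(in_flank) / t_flank
  r_far <- sum(out) / t_far
  r_flank > 1.2 * r_far
}

#' Classify a unit's relation to taste and licking
#'
#' Labels follow a fixed precedence. Any significant taste response at
#' either time scale makes the cell `"taste"` (taste-responsive cells
#' with lick-related activity are still classified solely as taste).
#' Otherwise: phase-locked to licking (coherence peak above the
#' circular-shift null) and bout-suppressed gives `"lick_anti_mix"`;
#' phase-locked alone gives `"lick"`; bout suppression with a peri-bout
#' phasic increase gives `"anti_lick"`; bout elevation gives
#' `"lick_bout"`; otherwise `"nonresponsive"`. Bout suppression means
#' an in-bout rate below `suppress_ratio` of the out-of-bout rate,
#' confirmed against a circular-shift permutation null; elevation is
#' the mirror-image criterion.
#'
#' @param detection detection table for this unit (from
#'   [detect_responses()]), or `NULL` for none.
#' @param coherence a `coherence_result` computed with a null
#'   (`n_shifts > 0`), or `NULL`.
#' @param spikes a [spike_train].
#' @param licks a [lick_train].
#' @param duration session length (s).
#' @param suppress_ratio suppression threshold; default 0.75.
#' @param n_perm permutation repetitions for the bout check.
#' @param seed optional RNG seed.
#' @return a single label string.
#' @export
classify_cell <- function(detection, coherence, spikes, licks, duration,
                          suppress_ratio = 0.75, n_perm = 200, seed = NULL) {
  if (!is.null(detection) && nrow(detection) && any(detection$significant))
    return("taste")
  phase_locked <- !is.null(coherence) && isTRUE(coherence$significant)
  bouts <- lick_bouts(licks)
  bs <- bout_rate_stats(spikes, bouts, duration, n_perm = n_perm, seed = seed)
  suppressed <- is.finite(bs$ratio) && bs$ratio < suppress_ratio && bs$ratio < bs$lo
  elevated <- bs$ratio > 1 / suppress_ratio && bs$ratio > bs$hi
  if (phase_locked && suppressed) return("lick_anti_mix")
  if (phase_locked) return("lick")
  if (suppressed && peri_bout_increase(spikes, bouts, duration)) return("anti_lick")
  if (suppressed) return("anti_lick")
  if (elevated) return("lick_bout")
  "nonresponsive"
}

#' Classify every unit in a session
#'
#' @param session a [session].
#' @param detection full detection table (computed when `NULL`).
#' @param n_shifts coherence-null repetitions per cell.
#' @param seed optional RNG seed.
#' @param ... passed to [classify_cell()].
#' @return data.frame: `unit_id`, `label`, `coherence_peak`,
#'   `coherence_sig`.
#' @export
classify_session <- function(session, detection = NULL, n_shifts = 200,
                             seed = NULL, ...) {
  stopifnot(inherits(session, "session"))
  if (is.null(detection)) detection <- detect_responses(session)
  cp <- coherence_peaks(session, n_shifts = n_shifts, seed = seed)
  rows <- lapply(seq_along(session$units), function(i) {
    u <- session$units[[i]]
    det <- detection[detection$unit_id == u$unit_id, , drop = FALSE]
    co <- if (!is.na(cp$peak_value[i]))
      structure(list(peak_value = cp$peak_value[i], peak_freq = cp$peak_freq[i],
                     null_q95 = cp$null_q95[i], significant = cp$significant[i]),
                class = "coherence_result")
    else NULL
    lab <- classify_cell(det, co, u, session$licks, session$duration,
                         seed = sub_seed(seed, 10000L + i), ...)
    data.frame(unit_id = u$unit_id, label = lab,
               coherence_peak = cp$peak_value[i],
               coherence_sig = isTRUE(cp$significant[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
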