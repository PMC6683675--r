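# -------------------------------------------------------------------------
# Spike-lick spectral coherence. Both point processes are binned at
# 1 ms and magnitude-squared coherence is estimated by Welch's method
# (Hann-tapered, overlapping segments). The summary statistic is the
# peak coherence within the 4-9 Hz licking band.
# -------------------------------------------------------------------------

# Hann-tapered segment FFTs of a binned signal (mean removed per
# segment). Returns complex matrix [nfft x nseg].
segment_ffts <- function(x, nfft, hop) {
  n <- length(x)
  nseg <- floor((n - nfft) / hop) + 1L
  if (nseg < 2L)
    stop_config("data shorter than two coherence segments (need >= %.1f s)",
                (nfft + hop) / 1000)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1)))
  out <- matrix(0 + 0i, nfft, nseg)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1L) * hop + 1L):((s - 1L) * hop + nfft)]
    out[, s] <- fft((seg - mean(seg)) * w)
  }
  out
}

msc_from_ffts <- function(FX, FY) {
  Sxy <- rowMeans(FX * Conj(FY))
  Sxx <- rowMeans(Mod(FX)^2)
  Syy <- rowMeans(Mod(FY)^2)
  co <- Mod(Sxy)^2 / (Sxx * Syy)
  co[!is.finite(co)] <- 0
  pmin(pmax(co, 0), 1)
}

bin_events <- function(times, bin_s, nbin) {
  idx <- floor(times / bin_s) + 1L
  idx <- idx[idx >= 1L & idx <= nbin]
  tabulate(idx, nbin)
}

#' Spike-lick coherence with licking-band peak extraction
#'
#' Bins spikes and licks at `bin_s`, estimates magnitude-squared
#' coherence by Welch's method (Hann window, `segment_s`-long segments,
#' `overlap` fractional overlap), and reports the maximum coherence in
#' the `band` (default 4-9 Hz, the licking rhythm). A circular
#' time-shift null can be requested: the spike segment spectra are
#' rotated against the lick spectra by random whole-segment offsets,
#' which preserves both autospectra while destroying spike-lick
#' alignment; the 95th percentile of the null peak is the significance
#' threshold for phase locking.
#'
#' @param spikes a [spike_train].
#' @param licks a [lick_train].
#' @param duration analysis length (s); defaults to the span of the
#'   data. At least 60 s of concurrent data is required.
#' @param bin_s bin width (s); default 0.001.
#' @param segment_s segment length (s); default 4.096 (frequency
#'   resolution 0.244 Hz).
#' @param overlap fractional segment overlap; default 0.5.
#' @param band frequency band (Hz) for the peak; default `c(4, 9)`.
#' @param n_shifts circular-shift null repetitions (0 = skip).
#' @param seed optional RNG seed for the null.
#' @param lick_fft optional precomputed lick segment-FFT matrix (from
#'   repeated calls on one session, see [coherence_peaks()]).
#' @return object of class `coherence_result`: `freqs`, `coherence`,
#'   `peak_value`, `peak_freq`, and (when requested) `null_q95` and
#'   `significant`.
#' @export
lick_coherence <- function(spikes, licks, duration = NULL, bin_s = 0.001,
                           segment_s = 4.096, overlap = 0.5, band = c(4, 9),
                           n_shifts = 0, seed = NULL, lick_fft = NULL) {
  stopifnot(inherits(spikes, "spike_train"), inherits(licks, "lick_train"))
  if (is.null(duration)) duration <- max(c(spikes$times, licks$times, 0))
  if (duration < 60) stop_config("coherence needs >= 60 s of concurrent data")
  nbin <- floor(duration / bin_s)
  nfft <- round(segment_s / bin_s)
  hop <- max(1L, round(nfft * (1 - overlap)))
  FX <- segment_ffts(bin_events(spikes$times, bin_s, nbin), nfft, hop)
  FY <- if (is.null(lick_fft)) segment_ffts(bin_events(licks$times, bin_s, nbin),
                                            nfft, hop) else lick_fft
  if (!identical(dim(FX), dim(FY)))
    stop_config("lick_fft does not match the spike segmentation")
  fs <- 1 / bin_s
  freqs <- (seq_len(nfft) - 1L) * fs / nfft
  half <- seq_len(floor(nfft / 2))
  co <- msc_from_ffts(FX, FY)[half]
  freqs <- freqs[half]
  inb <- which(freqs >= band[1] & freqs <= band[2])
  pk <- inb[which.max(co[inb])]
  res <- list(freqs = freqs, coherence = co,
              peak_value = co[pk], peak_freq = freqs[pk])
  if (n_shifts > 0) {
    # band-limited surrogate: only the 4-9 Hz rows are needed
    FXb <- FX[inb, , drop = FALSE]; FYb <- FY[inb, , drop = FALSE]
    Sxx <- rowMeans(Mod(FXb)^2); Syy <- rowMeans(Mod(FYb)^2)
    nseg <- ncol(FXb)
    null_pk <- with_seed(seed, {
      vapply(seq_len(n_shifts), function(i) {
        s <- sample(nseg - 1L, 1L)
        rot <- c((s + 1L):nseg, 1L:s)
        con <- Mod(rowMeans(FXb[, rot, drop = FALSE] * Conj(FYb)))^2 / (Sxx * Syy)
        max(con, na.rm = TRUE)
      }, numeric(1))
    })
    res$null_q95 <- as.numeric(quantile(null_pk, 0.95))
    res$significant <- res$peak_value > res$null_q95
    res$null_peaks <- null_pk
  }
  class(res) <- "coherence_result"
  res
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("coherence_result: peak %.3f at %.2f Hz", x$peak_value, x$peak_freq))
  if (!is.null(x$null_q95))
    cat(sprintf(" (null 95%% = %.3f, %s)", x$null_q95,
                if (x$significant) "significant" else "n.s."))
  cat("\n")
  invisible(x)
}

#' Coherence peaks for every unit in a session
#'
#' Computes [lick_coherence()] per unit, reusing the lick spectra
#' across units.
#'
#' @param session a [session].
#' @param n_shifts circular-shift null repetitions per unit.
#' @param seed optional RNG seed.
#' @param ... passed to [lick_coherence()].
#' @return data.frame: `unit_id`, `peak_value`, `peak_freq`, and when
#'   a null is requested `null_q95`, `significant`.
#' @export
coherence_peaks <- function(session, n_shifts = 0, seed = NULL, ...) {
  stopifnot(inherits(session, "session"))
  dots <- list(...)
  bin_s <- if (is.null(dots$bin_s)) 0.001 else dots$bin_s
  segment_s <- if (is.null(dots$segment_s)) 4.096 else dots$segment_s
  overlap <- if (is.null(dots$overlap)) 0.5 else dots$overlap
  nbin <- floor(session$duration / bin_s)
  nfft <- round(segment_s / bin_s)
  hop <- max(1L, round(nfft * (1 - overlap)))
  FY <- segment_ffts(bin_events(session$licks$times, bin_s, nbin), nfft, hop)
  rows <- lapply(seq_along(session$units), function(i) {
    u <- session$units[[i]]
    if (length(u$times) < 3)
      return(data.frame(unit_id = u$unit_id, peak_value = NA_real_,
                        peak_freq = NA_real_, null_q95 = NA_real_,
                        significant = NA))
    co <- do.call(lick_coherence,
                  c(list(spikes = u, licks = session$licks,
                         duration = session$duration, n_shifts = n_shifts,
                         seed = sub_seed(seed, i), lick_fft = FY), dots))
    data.frame(unit_id = u$unit_id, peak_value = co$peak_value,
               peak_freq = co$peak_freq,
               null_q95 = if (is.null(co$null_q95)) NA_real_ else co$null_q95,
               significant = if (is.null(co$significant)) NA else co$significant)
  })
  do.call(rbind, rows)
}
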