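#' Identify lick bouts
#'
#' A bout is a run of continuous licking: consecutive licks separated by
#' at most `max_ili` seconds, lasting at least `min_length` seconds in
#' total. Inter-lick gaps above `max_ili` are pauses.
#'
#' @param licks a `lick_train` or numeric vector of lick times (s).
#' @param max_ili maximum inter-lick interval (s) counted as continuous
#'   licking; default 1 s.
#' @param min_length minimum bout length in seconds; default 1 s.
#' @return data.frame with columns `start`, `end`, `n_licks`.
#' @export
lick_bouts <- function(licks, max_ili = 1, min_length = 1) {
  t <- if (inherits(licks, "lick_train")) licks$times else as.numeric(licks)
  if (length(t) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), n_licks = integer(0)))
  brk <- c(0L, which(diff(t) > max_ili), length(t))
  out <- lapply(seq_len(length(brk) - 1L), function(i) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    c(start = t[idx[1L]], end = t[idx[length(idx)]], n = length(idx))
  })
  d <- as.data.frame(do.call(rbind, out))
  names(d) <- c("start", "end", "n_licks")
  d <- d[d$end - d$start >= min_length, , drop = FALSE]
  rownames(d) <- NULL
  d
}

# membership of arbitrary times in bout intervals (vectorized)
in_intervals <- function(t, start, end) {
  if (length(start) == 0) return(rep(FALSE, length(t)))
  i <- findInterval(t, start)
  i > 0 & t <= end[pmax(i, 1L)]
}
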