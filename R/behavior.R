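#' Licking-microstructure metrics per stimulus
#'
#' Summarizes licking during taste trials: trial count, median
#' inter-lick interval among the four intervals between the five
#' stimulus licks (pauses excluded), the number of intra-trial pauses
#' (intervals above `pause_threshold`), the median pause length, and
#' the median time from the first to the fifth stimulus lick.
#'
#' @param session a [session].
#' @param pause_threshold inter-lick interval (s) counted as a pause;
#'   default 1, aligned with the bout definition.
#' @return data.frame: `stimulus_id`, `trials`, `ili`, `n_pauses`,
#'   `pause_length`, `five_lick_time`.
#' @export
lick_behavior_metrics <- function(session, pause_threshold = 1) {
  stopifnot(inherits(session, "session"))
  if (nrow(session$trials) == 0) stop_config("session has no trials")
  rows <- lapply(unique(session$trials$stimulus_id), function(s) {
    tr <- session$trials[session$trials$stimulus_id == s, , drop = FALSE]
    lickmat <- as.matrix(tr[paste0("lick", 1:5)])
    ilis <- as.vector(t(apply(lickmat, 1, diff)))
    pauses <- ilis[ilis > pause_threshold]
    data.frame(
      stimulus_id = s,
      trials = nrow(tr),
      ili = median(ilis[ilis <= pause_threshold]),
      n_pauses = length(pauses),
      pause_length = if (length(pauses)) median(pauses) else NA_real_,
      five_lick_time = median(lickmat[, 5] - lickmat[, 1]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
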