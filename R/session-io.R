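#' Construct a recording session
#'
#' One recording day: the units' spike trains, the lick train with
#' reinforcement labels, the taste-trial table, and session metadata.
#'
#' @param subject_id subject identifier.
#' @param group `"lean"` or `"DIO"`.
#' @param units list of [spike_train] objects.
#' @param licks a [lick_train].
#' @param trials data.frame with columns `stimulus_id`, `t0`,
#'   `lick1`..`lick5`.
#' @param duration session length (s).
#' @param panel stimulus panel.
#' @return object of class `session`.
#' @export
session <- function(subject_id, group, units, licks, trials, duration,
                    panel = default_panel()) {
  if (!group %in% c("lean", "DIO")) stop_config("group must be 'lean' or 'DIO'")
  stopifnot(is.list(units), all(vapply(units, inherits, TRUE, "spike_train")),
            inherits(licks, "lick_train"))
  ids <- vapply(units, `[[`, character(1), "unit_id")
  if (anyDuplicated(ids)) stop_config("duplicate unit_id in session")
  trials <- as.data.frame(trials)
  need <- c("stimulus_id", "t0", paste0("lick", 1:5))
  if (!all(need %in% names(trials)))
    stop_config("trials needs columns: %s", paste(need, collapse = ", "))
  structure(list(subject_id = as.character(subject_id), group = group,
                 units = units, licks = licks, trials = trials,
                 duration = as.numeric(duration), panel = as.character(panel)),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("session %s (%s): %d units, %d licks, %d trials, %.0f s\n",
              x$subject_id, x$group, length(x$units), length(x$licks$times),
              nrow(x$trials), x$duration))
  invisible(x)
}

# times are serialized as integer multiples of 25 us printed with six
# decimals, which is exact for this grid
fmt_time <- function(t) sprintf("%.6f", quantize_times(t))

#' Write / read a session in the portable event-table dialect
#'
#' A session is stored as a directory holding `header.json` (subject,
#' group, duration, panel, trial table) and `events.csv` with columns
#' `time_s`, `kind` (`spike` or `lick`), `label` (unit id for spikes;
#' `dry`/`rinse`/`stimulus:<id>` for licks). Timestamps are written as
#' exact multiples of 25 us, so a write-read round trip reproduces all
#' events bit-for-bit.
#'
#' @param session a [session].
#' @param path directory to create/overwrite.
#' @return `write_session` returns `path` invisibly; `read_session`
#'   returns a [session].
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(
    subject_id = session$subject_id, group = session$group,
    duration = session$duration, panel = as.list(session$panel),
    trials = data.frame(
      stimulus_id = session$trials$stimulus_id,
      t0 = fmt_time(session$trials$t0),
      lick1 = fmt_time(session$trials$lick1), lick2 = fmt_time(session$trials$lick2),
      lick3 = fmt_time(session$trials$lick3), lick4 = fmt_time(session$trials$lick4),
      lick5 = fmt_time(session$trials$lick5), stringsAsFactors = FALSE)
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ev <- rbind(
    do.call(rbind, lapply(session$units, function(u) {
      if (length(u$times) == 0) return(NULL)
      data.frame(time_s = fmt_time(u$times), kind = "spike", label = u$unit_id,
                 stringsAsFactors = FALSE)
    })),
    data.frame(time_s = fmt_time(session$licks$times), kind = "lick",
               label = session$licks$labels, stringsAsFactors = FALSE)
  )
  ev <- ev[order(as.numeric(ev$time_s), ev$kind, ev$label), ]
  # an empty unit leaves no event rows; record its id so it round-trips
  header_units <- vapply(session$units, `[[`, character(1), "unit_id")
  writeLines(paste(header_units, collapse = ","), file.path(path, "units.txt"))
  write.csv(ev, file.path(path, "events.csv"), row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_session
#' @param path directory written by [write_session()].
#' @export
read_session <- function(path) {
  hf <- file.path(path, "header.json"); ef <- file.path(path, "events.csv")
  if (!file.exists(hf) || !file.exists(ef))
    stop_config("not a session directory (missing header.json or events.csv): %s", path)
  header <- jsonlite::read_json(hf, simplifyVector = TRUE)
  ev <- read.csv(ef, stringsAsFactors = FALSE, colClasses =
                   c(time_s = "character", kind = "character", label = "character"))
  bad <- which(!ev$kind %in% c("spike", "lick"))
  if (length(bad))
    stop_config("parse error at events.csv line %d: unknown kind '%s'",
                bad[1] + 1L, ev$kind[bad[1]])
  tm <- suppressWarnings(as.numeric(ev$time_s))
  if (anyNA(tm))
    stop_config("parse error at events.csv line %d: bad time '%s'",
                which(is.na(tm))[1] + 1L, ev$time_s[which(is.na(tm))[1]])
  tm <- quantize_times(tm)

  lick_rows <- ev$kind == "lick"
  llab <- ev$label[lick_rows]
  panel <- as.character(unlist(header$panel))
  stim <- startsWith(llab, "stimulus:")
  unknown <- stim & !sub("^stimulus:", "", llab) %in% panel
  oklab <- llab %in% c("dry", "rinse") | (stim & !unknown)
  if (!all(oklab)) {
    ln <- which(lick_rows)[which(!oklab)[1]] + 1L
    stop_config("parse error at events.csv line %d: unknown lick label '%s'",
                ln, llab[!oklab][1])
  }
  lt <- tm[lick_rows]
  if (is.unsorted(lt, strictly = TRUE))
    stop_config("parse error: lick times not strictly increasing")
  licks <- lick_train(lt, llab, check = FALSE)

  unit_ids <- character(0)
  uf <- file.path(path, "units.txt")
  if (file.exists(uf)) unit_ids <- strsplit(readLines(uf, n = 1L), ",")[[1]]
  sp <- ev[ev$kind == "spike", , drop = FALSE]
  sp_t <- tm[ev$kind == "spike"]
  seen <- unique(sp$label)
  unit_ids <- union(unit_ids[nzchar(unit_ids)], seen)
  units <- lapply(unit_ids, function(id) {
    t <- sort(sp_t[sp$label == id])
    if (is.unsorted(t, strictly = TRUE))
      stop_config("parse error: duplicate spike time for unit %s", id)
    spike_train(id, t)
  })

  tr <- as.data.frame(header$trials)
  for (cn in c("t0", paste0("lick", 1:5))) tr[[cn]] <- quantize_times(as.numeric(tr[[cn]]))
  session(subject_id = header$subject_id, group = header$group, units = units,
          licks = licks, trials = tr, duration = as.numeric(header$duration),
          panel = panel)
}

#' Validate a session's structural invariants
#'
#' Checks every unit for refractory-period violations (inter-spike
#' interval <= 2 ms) and ordering violations, every event for falling
#' inside `[0, duration]`, and every trial lick for existence in the
#' lick train with a matching stimulus label (orphan licks). Violations
#' are reported, never silently fixed.
#'
#' @param session a [session].
#' @return object of class `session_report`: list of data.frames
#'   `refractory`, `ordering`, `orphan_licks`, `out_of_range`, plus
#'   logical `pass`.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "session"))
  refractory <- do.call(rbind, lapply(session$units, function(u) {
    if (length(u$times) < 2) return(NULL)
    isi <- diff(u$times)
    bad <- which(isi <= 0.002 + 1e-12 & isi > 0)
    if (!length(bad)) return(NULL)
    data.frame(unit_id = u$unit_id, time = u$times[bad + 1L], isi = isi[bad])
  }))
  ordering <- do.call(rbind, lapply(session$units, function(u) {
    if (length(u$times) < 2) return(NULL)
    bad <- which(diff(u$times) <= 0)
    if (!length(bad)) return(NULL)
    data.frame(unit_id = u$unit_id, index = bad + 1L)
  }))
  lt <- session$licks$times; ll <- session$licks$labels
  orphan <- do.call(rbind, lapply(seq_len(nrow(session$trials)), function(i) {
    tr <- session$trials[i, ]
    want <- paste0("stimulus:", tr$stimulus_id)
    tms <- as.numeric(tr[paste0("lick", 1:5)])
    miss <- vapply(tms, function(x) {
      j <- which(abs(lt - x) < TICK / 2)
      length(j) == 0 || !any(ll[j] == want)
    }, TRUE)
    if (!any(miss)) return(NULL)
    data.frame(trial = i, stimulus_id = tr$stimulus_id, time = tms[miss])
  }))
  all_t <- c(unlist(lapply(session$units, `[[`, "times")), lt)
  oor <- all_t[all_t < 0 | all_t > session$duration + 1e-9]
  out <- list(
    refractory = if (is.null(refractory)) data.frame() else refractory,
    ordering = if (is.null(ordering)) data.frame() else ordering,
    orphan_licks = if (is.null(orphan)) data.frame() else orphan,
    out_of_range = data.frame(time = oor)
  )
  out$pass <- all(vapply(out, function(d) nrow(d) == 0, TRUE))
  class(out) <- "session_report"
  out
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("session_report: %s\n", if (x$pass) "PASS" else "FAIL"))
  for (f in c("refractory", "ordering", "orphan_licks", "out_of_range"))
    cat(sprintf("  %-13s %d finding(s)\n", f, nrow(x[[f]])))
  invisible(x)
}

#' Screen a pair of units for duplication via the cross-correlogram
#'
#' Units recorded on different wires that are in fact the same cell
#' show a narrow peak at exactly zero lag in their cross-correlation
#' function. The correlogram is computed in `bin`-wide lag bins over
#' `+/- max_lag`; the pair is flagged as duplicate iff the zero-lag bin
#' exceeds the mean plus `k` SD of the off-zero bins and the global
#' peak sits at lag zero.
#'
#' @param a,b [spike_train] objects (both nonempty).
#' @param max_lag half-width of the lag window (s); default 0.05.
#' @param bin lag bin width (s); must be <= 1 ms to resolve "exactly
#'   zero". Default 0.001.
#' @param k SD multiplier for the narrow-peak criterion; default 10.
#' @return list: `is_duplicate`, `ccf_peak_lag` (s), `peak_score`
#'   (z-score of the zero bin), `lags`, `counts`.
#' @export
detect_duplicate_units <- function(a, b, max_lag = 0.05, bin = 0.001, k = 10) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  if (length(a$times) == 0 || length(b$times) == 0)
    stop_config("duplicate screen undefined for an empty spike train")
  if (bin > 0.001 + 1e-12)
    stop_config("bin must be <= 1 ms to resolve a zero-lag peak")
  ta <- a$times; tb <- b$times
  lo <- findInterval(ta - max_lag, tb)
  hi <- findInterval(ta + max_lag, tb)
  diffs <- unlist(lapply(seq_along(ta), function(i) {
    if (hi[i] <= lo[i]) return(NULL)
    tb[(lo[i] + 1L):hi[i]] - ta[i]
  }))
  K <- ceiling(max_lag / bin)
  # round-to-nearest-bin keeps the histogram exactly symmetric under
  # swapping the two trains (diffs negate; round() is odd-symmetric)
  idx <- if (length(diffs)) round(diffs / bin) else integer(0)
  idx <- idx[abs(idx) <= K]
  counts <- tabulate(idx + K + 1L, 2L * K + 1L)
  lags <- seq(-K, K) * bin
  zero <- which.min(abs(lags))
  off <- counts[-zero]
  mu <- mean(off); s <- sd(off)
  score <- if (s > 0) (counts[zero] - mu) / s else
    (if (counts[zero] > mu) Inf else 0)
  cand <- which(counts == max(counts))
  peak <- cand[which.min(abs(lags[cand]))]  # symmetric tie break
  list(is_duplicate = isTRUE(score > k && peak == zero),
       ccf_peak_lag = lags[peak], peak_score = score,
       lags = lags, counts = counts)
}

#' Drop duplicate units from a session
#'
#' Applies [detect_duplicate_units()] to all unit pairs and removes one
#' member of each duplicate pair, keeping the unit with the higher
#' spike count (logged in the result).
#'
#' @param session a [session].
#' @param ... passed to [detect_duplicate_units()].
#' @return list: `session` (deduplicated), `dropped` (data.frame of
#'   removed unit ids and their retained partners).
#' @export
dedupe_session <- function(session, ...) {
  stopifnot(inherits(session, "session"))
  units <- session$units
  n <- length(units)
  drop <- logical(n)
  log <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      if (drop[i] || length(units[[i]]$times) == 0) next
      for (j in (i + 1):n) {
        if (drop[j] || length(units[[j]]$times) == 0) next
        v <- detect_duplicate_units(units[[i]], units[[j]], ...)
        if (v$is_duplicate) {
          loser <- if (length(units[[i]]$times) >= length(units[[j]]$times)) j else i
          winner <- if (loser == j) i else j
          drop[loser] <- TRUE
          log[[length(log) + 1L]] <- data.frame(
            dropped = units[[loser]]$unit_id, kept = units[[winner]]$unit_id,
            peak_score = v$peak_score)
        }
      }
    }
  }
  session$units <- units[!drop]
  list(session = session,
       dropped = if (length(log)) do.call(rbind, log) else
         data.frame(dropped = character(0), kept = character(0),
                    peak_score = numeric(0)))
}
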