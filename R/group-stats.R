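# -------------------------------------------------------------------------
# Group-level summaries, cross-group statistics, and the end-to-end
# pipeline orchestrator.
# -------------------------------------------------------------------------

#' Extract a metric-space response set for one unit
#'
#' Collects, for every trial whose stimulus is in `panel`, the unit's
#' spikes in the `window` seconds following the trial's first stimulus
#' lick, re-referenced to that lick.
#'
#' @param session a [session].
#' @param unit_id unit to extract.
#' @param panel stimulus subset (e.g. [traditional_quartet()], or a
#'   2-stimulus intensity pair).
#' @param window response window (s); canonical values 0.2-2.
#' @return a [response_set].
#' @export
extract_responses <- function(session, unit_id, panel, window = 2) {
  stopifnot(inherits(session, "session"))
  u <- NULL
  for (cand in session$units) if (cand$unit_id == unit_id) u <- cand
  if (is.null(u)) stop_config("unknown unit '%s'", unit_id)
  tr <- session$trials[session$trials$stimulus_id %in% panel, , drop = FALSE]
  if (nrow(tr) == 0) stop_config("no trials for the requested panel")
  resp <- lapply(tr$t0, function(t0) {
    s <- u$times[u$times >= t0 & u$times < t0 + window] - t0
    s[s < window]
  })
  response_set(resp, tr$stimulus_id, window)
}

#' Summarize one analyzed group
#'
#' @param classification output of [classify_session()].
#' @param detection output of [detect_responses()].
#' @param behavior output of [lick_behavior_metrics()].
#' @param msa_sweep output of [window_sweep()], or `NULL`.
#' @param breadth named integer vector of per-unit tuning breadths, or
#'   `NULL`.
#' @param group group tag.
#' @return object of class `group_summary`.
#' @export
summarize_group <- function(classification, detection, behavior = NULL,
                            msa_sweep = NULL, breadth = NULL, group = "lean") {
  sig <- detection[detection$significant, , drop = FALSE]
  resp_tab <- if (nrow(sig)) {
    agg <- aggregate(cbind(magnitude, latency, duration) ~ stimulus_id + timescale + sign,
                     data = sig, FUN = mean)
    agg_sd <- aggregate(cbind(magnitude, latency, duration) ~ stimulus_id + timescale + sign,
                        data = sig, FUN = sd)
    agg_n <- aggregate(magnitude ~ stimulus_id + timescale + sign,
                       data = sig, FUN = length)
    agg$n <- agg_n$magnitude
    agg$magnitude_sem <- agg_sd$magnitude / sqrt(agg$n)
    agg
  } else data.frame()
  cls <- c("taste", "lick", "anti_lick", "lick_bout", "lick_anti_mix",
           "nonresponsive")
  counts <- vapply(cls, function(l) sum(classification$label == l), integer(1))
  structure(list(group = group,
                 class_counts = counts,
                 n_units = nrow(classification),
                 classification = classification,
                 detection = detection,
                 response_table = resp_tab,
                 behavior = behavior,
                 msa_sweep = msa_sweep,
                 breadth = breadth),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group_summary (%s): %d units\n", x$group, x$n_units))
  print(x$class_counts)
  invisible(x)
}

mw_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 1 || length(b) < 1) return(list(statistic = NA, p.value = NA))
  w <- suppressWarnings(wilcox.test(a, b))
  list(statistic = unname(w$statistic), p.value = w$p.value)
}

#' Compare two analyzed groups
#'
#' Reproduces the battery of group contrasts on pipeline outputs:
#' Mann-Whitney U on lick-coherence peaks, chi-square on cell-class
#' proportions, two-sample t tests on response magnitude, latency and
#' duration per time scale, and Kolmogorov-Smirnov on the per-window
#' proportion of temporally coding cells (when metric-space sweeps are
#' present). Each row names the published contrast it mirrors.
#'
#' @param a,b `group_summary` objects (conventionally lean and DIO).
#' @return data.frame: `contrast`, `test`, `statistic`, `p_value`,
#'   `direction` (sign of `a - b` on the relevant scale).
#' @export
compare_groups <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$n_units == 0 || b$n_units == 0) stop_config("empty group")
  rows <- list()
  add <- function(contrast, test, statistic, p, dir) {
    rows[[length(rows) + 1L]] <<- data.frame(
      contrast = contrast, test = test,
      statistic = as.numeric(statistic), p_value = as.numeric(p),
      direction = dir, stringsAsFactors = FALSE)
  }
  # coherence (mirrors the taste-cell Mann-Whitney contrast)
  ca <- a$classification$coherence_peak; cb <- b$classification$coherence_peak
  mw <- mw_test(ca, cb)
  add("lick coherence (all units)", "mann_whitney_U", mw$statistic, mw$p.value,
      sign(median(ca, na.rm = TRUE) - median(cb, na.rm = TRUE)))
  # class proportions (chi-square, df = 5)
  tab <- rbind(a$class_counts, b$class_counts)
  keep <- colSums(tab) > 0
  chi <- suppressWarnings(chisq.test(tab[, keep, drop = FALSE], correct = FALSE))
  add("cell-class proportions", "chi_square", chi$statistic, chi$p.value,
      NA_real_)
  # response parameters, per timescale
  for (ts in c("five_lick", "lick_by_lick")) {
    for (par in c("magnitude", "latency", "duration")) {
      xa <- a$detection[a$detection$significant & a$detection$timescale == ts &
                          a$detection$sign == "excitatory", par]
      xb <- b$detection[b$detection$significant & b$detection$timescale == ts &
                          b$detection$sign == "excitatory", par]
      if (length(xa) > 1 && length(xb) > 1) {
        tt <- tryCatch(t.test(xa, xb), error = function(e)
          list(statistic = NA_real_, p.value = NA_real_))
        add(sprintf("%s %s (excitatory)", ts, par), "t", tt$statistic, tt$p.value,
            sign(mean(xa) - mean(xb)))
        mw <- mw_test(xa, xb)
        add(sprintf("%s %s (excitatory)", ts, par), "mann_whitney_U",
            mw$statistic, mw$p.value, sign(mean(xa) - mean(xb)))
      }
    }
  }
  # temporal-coding proportions across windows (KS)
  if (!is.null(a$msa_sweep) && !is.null(b$msa_sweep)) {
    ks <- suppressWarnings(ks.test(a$msa_sweep$prop_significant,
                                   b$msa_sweep$prop_significant))
    add("temporal-coding proportion by window", "kolmogorov_smirnov",
        ks$statistic, ks$p.value,
        sign(mean(a$msa_sweep$prop_significant) -
               mean(b$msa_sweep$prop_significant)))
    add("mean H_max at 2 s", "difference",
        a$msa_sweep$mean_H_max[which.max(a$msa_sweep$window)] -
          b$msa_sweep$mean_H_max[which.max(b$msa_sweep$window)], NA_real_,
        sign(a$msa_sweep$mean_H_max[which.max(a$msa_sweep$window)] -
               b$msa_sweep$mean_H_max[which.max(b$msa_sweep$window)]))
  }
  do.call(rbind, rows)
}

#' Analyze one session end to end
#'
#' validate -> dedupe -> detect -> classify (with coherence) ->
#' behavior -> metric-space sweep (taste cells) -> group summary.
#'
#' @param session a [session].
#' @param seed optional RNG seed.
#' @param msa_windows analysis windows for the metric-space sweep.
#' @param msa_panel stimulus panel for the sweep; default the
#'   traditional quartet.
#' @param n_shifts coherence-null repetitions.
#' @param n_exchange exchange-control repetitions per cell.
#' @return a `group_summary` for the session's units.
#' @export
analyze_session <- function(session, seed = NULL,
                            msa_windows = c(0.2, 0.5, 1, 1.5, 2),
                            msa_panel = traditional_quartet(),
                            n_shifts = 200, n_exchange = 10) {
  rep <- validate_session(session)
  if (!rep$pass) stop_config("session failed validation; see validate_session()")
  dd <- dedupe_session(session)
  session <- dd$session
  detection <- detect_responses(session)
  classification <- classify_session(session, detection, n_shifts = n_shifts,
                                     seed = sub_seed(seed, 1L))
  behavior <- lick_behavior_metrics(session)
  taste_ids <- classification$unit_id[classification$label == "taste"]
  msa_sweep <- NULL
  if (length(taste_ids)) {
    cells <- lapply(taste_ids, function(id)
      extract_responses(session, id, msa_panel, window = max(msa_windows)))
    msa_sweep <- window_sweep(cells, msa_windows, seed = sub_seed(seed, 2L),
                              n_exchange = n_exchange)
  }
  breadth <- tryCatch(
    setNames(vapply(unique(detection$unit_id), function(id)
      tuning_breadth(detection[detection$unit_id == id, , drop = FALSE]),
      integer(1)), unique(detection$unit_id)),
    error = function(e) NULL)
  summarize_group(classification, detection, behavior, msa_sweep, breadth,
                  group = session$group)
}

#' Run the full two-group synthetic pipeline
#'
#' Generates (or loads) one session per group, analyzes each end to
#' end, compares the groups, and writes the report bundle (CSV tables
#' plus a machine-readable JSON report and config snapshot) to a run
#' directory. Fully reproducible from `(config, seed)`.
#'
#' @param config list with optional fields `presets` (default
#'   `c("lean", "DIO")`), `n_cells` (default 50), `trials_per_stimulus`
#'   (default 6), `panel`, `msa_windows`, `msa_panel`, `n_shifts`,
#'   `out_dir` (default `NULL` = nothing written), `session_paths`
#'   (named list of session directories to load instead of
#'   generating).
#' @param seed RNG seed driving every stage.
#' @return list: `summaries` (per group), `comparison`, `config`.
#' @export
run_pipeline <- function(config = list(), seed = 1) {
  defaults <- list(presets = c("lean", "DIO"), n_cells = 50,
                   trials_per_stimulus = 6, panel = default_panel(),
                   msa_windows = c(0.2, 0.5, 1, 1.5, 2),
                   msa_panel = traditional_quartet(),
                   n_shifts = 200, out_dir = NULL, session_paths = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_config("unknown pipeline config field(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  summaries <- list()
  for (gi in seq_along(cfg$presets)) {
    g <- cfg$presets[gi]
    ses <- if (!is.null(cfg$session_paths)) {
      read_session(cfg$session_paths[[g]])
    } else {
      generate_session(g, cfg$n_cells, cfg$trials_per_stimulus,
                       seed = sub_seed(seed, 50L + gi), panel = cfg$panel)$session
    }
    summaries[[g]] <- analyze_session(ses, seed = sub_seed(seed, 60L + gi),
                                      msa_windows = cfg$msa_windows,
                                      msa_panel = cfg$msa_panel,
                                      n_shifts = cfg$n_shifts)
  }
  comparison <- if (length(summaries) == 2)
    compare_groups(summaries[[1]], summaries[[2]]) else NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in names(summaries)) {
      s <- summaries[[g]]
      write.csv(s$detection, file.path(cfg$out_dir, sprintf("%s_responses.csv", g)),
                row.names = FALSE)
      write.csv(s$classification, file.path(cfg$out_dir, sprintf("%s_classes.csv", g)),
                row.names = FALSE)
      write.csv(s$behavior, file.path(cfg$out_dir, sprintf("%s_behavior.csv", g)),
                row.names = FALSE)
      if (!is.null(s$msa_sweep))
        write.csv(s$msa_sweep, file.path(cfg$out_dir, sprintf("%s_msa_summary.csv", g)),
                  row.names = FALSE)
    }
    if (!is.null(comparison))
      write.csv(comparison, file.path(cfg$out_dir, "group_comparison.csv"),
                row.names = FALSE)
    jsonlite::write_json(list(seed = seed, config = cfg[setdiff(names(cfg), "out_dir")]),
                         file.path(cfg$out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  list(summaries = summaries, comparison = comparison, config = cfg)
}
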