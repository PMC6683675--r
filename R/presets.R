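# -------------------------------------------------------------------------
# Ground-truth cell specifications and group presets for the synthetic
# session generator. Preset means follow the published group summaries
# for lean and diet-induced-obese (DIO) rats; dispersions and any value
# the literature leaves open are stated once here and discussed in the
# methods vignette.
# -------------------------------------------------------------------------

#' The canonical 12-stimulus taste panel
#'
#' Traditional tastants (two sucrose concentrations, NaCl, citric acid,
#' caffeine), naturalistic tastants (grape juice at two concentrations,
#' clam juice, lemon juice, coffee, cream), and the artificial-saliva
#' rinse solution presented as a stimulus in its own right.
#' @return character vector of stimulus ids.
#' @export
default_panel <- function() {
  c("Hi Su", "Lo Su", "N", "CA", "Caf",
    "Hi GJ", "Lo GJ", "Clm J", "Lm J", "Coff", "Crm", "AS")
}

#' The traditional four-tastant quartet used for tuning breadth
#' @return character vector: low sucrose, NaCl, citric acid, caffeine.
#' @export
traditional_quartet <- function() c("Lo Su", "N", "CA", "Caf")

#' Ground-truth specification of one synthetic unit
#'
#' @param unit_id unit identifier.
#' @param cell_class one of `"taste"`, `"lick"`, `"anti_lick"`,
#'   `"lick_bout"`, `"lick_anti_mix"`, `"nonresponsive"`.
#' @param spont_rate spontaneous rate (sps) outside lick bouts.
#' @param baseline_rate rate (sps) inside lick bouts, before any
#'   phase-locked gain or taste kernel.
#' @param lick_mod_depth concentration parameter (dimensionless, >= 0)
#'   of the von Mises rate gain locked to lick phase; 0 = no locking.
#' @param lick_mod_phase preferred lick phase in radians (0 = at lick).
#' @param response_kernels data.frame with columns `stimulus`, `sign`
#'   (+1/-1), `magnitude` (sps), `latency` (s), `duration` (s),
#'   `timescale` (`"five_lick"` or `"lick_by_lick"`); may be empty.
#' @param bout_edge_mag extra rate (sps) in the 0.5 s flanking each
#'   bout edge; models the peri-bout phasic increase of anti-lick cells.
#' @param rate_drift_cv coefficient of variation of a slow (60 s
#'   time scale) multiplicative excitability drift applied to the whole
#'   rate function; emulates behavioral-state fluctuations that make
#'   real across-trial baseline variability super-Poisson. Default 0
#'   (pure inhomogeneous Poisson).
#' @return object of class `cell_spec`.
#' @export
cell_spec <- function(unit_id = "u1",
                      cell_class = "nonresponsive",
                      spont_rate = 10, baseline_rate = spont_rate,
                      lick_mod_depth = 0, lick_mod_phase = 5.5,
                      response_kernels = empty_kernels(),
                      bout_edge_mag = 0, rate_drift_cv = 0) {
  classes <- c("taste", "lick", "anti_lick", "lick_bout", "lick_anti_mix",
               "nonresponsive")
  if (!cell_class %in% classes)
    stop_config("unknown cell_class '%s'", cell_class)
  if (spont_rate < 0 || baseline_rate < 0 || lick_mod_depth < 0 || bout_edge_mag < 0)
    stop_config("rates and modulation depth must be >= 0")
  k <- as.data.frame(response_kernels)
  need <- c("stimulus", "sign", "magnitude", "latency", "duration", "timescale")
  if (!all(need %in% names(k)))
    stop_config("response_kernels needs columns: %s", paste(need, collapse = ", "))
  if (nrow(k)) {
    if (any(!k$sign %in% c(-1, 1))) stop_config("kernel sign must be +1 or -1")
    if (any(k$magnitude < 0)) stop_config("kernel magnitude must be >= 0")
    if (any(k$latency < 0)) stop_config("kernel latency must be >= 0")
    if (any(k$duration <= 0)) stop_config("kernel duration must be > 0")
    if (any(!k$timescale %in% c("five_lick", "lick_by_lick")))
      stop_config("kernel timescale must be 'five_lick' or 'lick_by_lick'")
    gmin <- exp(-lick_mod_depth) / besselI(lick_mod_depth, 0)
    floor_rate <- min(spont_rate, baseline_rate * gmin)
    inh <- k$sign < 0
    if (any(k$magnitude[inh] > floor_rate + 1e-9))
      stop_config("inhibitory kernel magnitude %.2f sps would drive the rate below 0 (floor %.2f sps)",
                  max(k$magnitude[inh]), floor_rate)
  }
  if (rate_drift_cv < 0) stop_config("rate_drift_cv must be >= 0")
  structure(list(unit_id = unit_id, cell_class = cell_class,
                 spont_rate = spont_rate, baseline_rate = baseline_rate,
                 lick_mod_depth = lick_mod_depth, lick_mod_phase = lick_mod_phase,
                 response_kernels = k, bout_edge_mag = bout_edge_mag,
                 rate_drift_cv = rate_drift_cv),
            class = "cell_spec")
}

#' @rdname cell_spec
#' @export
empty_kernels <- function() {
  data.frame(stimulus = character(0), sign = numeric(0), magnitude = numeric(0),
              latency = numeric(0), duration = numeric(0), timescale = character(0),
              stringsAsFactors = FALSE)
}

#' Group presets for the synthetic session generator
#'
#' Encodes the population-level differences between lean and
#' diet-induced-obese (DIO) recordings as sampling distributions for
#' [cell_spec] fields: spontaneous rate 12.18 (lean) vs 15.4 (DIO) sps;
#' in-bout baseline 18.9 vs 13.7 sps for taste cells; class proportions
#' from the published cell taxonomy; DIO lick-by-lick kernels smaller
#' in magnitude, longer in latency and shorter in duration; lick-phase
#' modulation depths calibrated so the coherence medians of the two
#' groups sit near 0.345 (lean) and 0.163 (DIO) for taste cells under
#' the default coherence parameters (a documented calibration, not a
#' universal claim). DIO rats lick slightly slower (mean ILI 0.165 vs
#' 0.155 s).
#'
#' @param name `"lean"` or `"DIO"`.
#' @return object of class `group_preset` (a parameter list).
#' @export
group_preset <- function(name = c("lean", "DIO")) {
  if (!is.character(name) || length(name) != 1L || !name %in% c("lean", "DIO"))
    stop_config("unknown preset '%s' (use 'lean' or 'DIO')", as.character(name)[1])
  lean <- name == "lean"
  p <- list(
    name = name,
    panel = default_panel(),
    # class proportions from the published counts
    # lean: 74 taste, 174 lick, 65 anti-lick, 9 bout, 43 mix, 150 none (N=515)
    # DIO:  49 taste,  65 lick, 12 anti-lick, 3 bout, 19 mix,  80 none (N=228)
    class_probs = if (lean)
      c(taste = 74, lick = 174, anti_lick = 65, lick_bout = 9,
        lick_anti_mix = 43, nonresponsive = 150) / 515
    else
      c(taste = 49, lick = 65, anti_lick = 12, lick_bout = 3,
        lick_anti_mix = 19, nonresponsive = 80) / 228,
    spont_mean = if (lean) 12.18 else 15.4, spont_cv = 0.35,
    baseline_taste_mean = if (lean) 18.9 else 13.7, baseline_cv = 0.25,
    # lick-phase modulation depth (von Mises kappa) by class; calibrated
    # against the group coherence medians under the default estimator
    kappa_taste = if (lean) 1.05 else 0.62,
    kappa_lick = if (lean) 0.55 else 0.20,
    kappa_mix = if (lean) 0.43 else 0.27,
    kappa_cv = 0.30,
    # taste response kernels
    p_respond = if (lean) 0.65 else 0.40,   # per-stimulus response prob.
    p_excitatory = 0.80,
    p_lick_by_lick = 0.60,                  # else five_lick
    mag5_mean = if (lean) 16.4 else 11, mag_cv = 1.0, mag_min = 5,
    maglbl_mean = if (lean) 30 else 13,
    lat5_mean = if (lean) 0.25 else 0.40, lat_cv = 0.30,
    latlbl_mean = if (lean) 0.012 else 0.028,
    dur5_mean = if (lean) 1.4 else 0.55, dur_cv = 0.25,
    durlbl_mean = if (lean) 0.075 else 0.035,
    # phasic (lick-by-lick responding) cells fire sparsely between
    # licks, as in published raster examples: their in-bout baseline is
    # scaled down and their preferred phase sits just after the lick
    lbl_baseline_factor = 0.45,
    lbl_phase = 1.8,
    # slow excitability drift (super-Poisson across-trial variability)
    drift_cv = 0.4,
    # licking microstructure
    ili_mean = if (lean) 0.155 else 0.165, ili_sd = 0.02,
    trials_per_stimulus = 6
  )
  class(p) <- "group_preset"
  p
}

# gamma draw with given mean and coefficient of variation
rgamma_mcv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, rate = shape / mean)
}

#' Draw ground-truth cell specifications from a preset
#'
#' @param preset a [group_preset].
#' @param n number of cells.
#' @param panel stimulus panel (default the preset's).
#' @param seed optional RNG seed.
#' @return list of [cell_spec] objects.
#' @export
draw_cell_specs <- function(preset, n, panel = preset$panel, seed = NULL) {
  stopifnot(inherits(preset, "group_preset"))
  if (!is_count(n) || n < 1) stop_config("n_cells must be a positive integer")
  with_seed(seed, {
    classes <- sample(names(preset$class_probs), n, replace = TRUE,
                      prob = preset$class_probs)
    lapply(seq_len(n), function(i) draw_one_spec(preset, classes[i], i, panel))
  })
}

draw_one_spec <- function(preset, cls, i, panel) {
  spont <- max(0.5, rgamma_mcv(1, preset$spont_mean, preset$spont_cv))
  kap <- function(mu) max(0, rgamma_mcv(1, mu, preset$kappa_cv))
  base <- spont; depth <- 0; edge <- 0; phase <- 5.5
  kern <- empty_kernels()
  if (cls == "taste") {
    base <- max(1, rgamma_mcv(1, preset$baseline_taste_mean, preset$baseline_cv))
    depth <- kap(preset$kappa_taste)
    kern <- draw_kernels(preset, panel)
    if (any(kern$timescale == "lick_by_lick")) {
      # phasic profile: sparse between licks, peak just after the lick
      base <- base * preset$lbl_baseline_factor
      phase <- preset$lbl_phase
    }
    # inhibitory kernels may never drive the rate below zero, even when
    # the tails of two consecutive trials' kernels overlap - hence the
    # pairwise-safe cap at just under half the rate floor
    gmin <- exp(-depth) / besselI(depth, 0)
    floor_rate <- min(spont, base * gmin)
    inh <- kern$sign < 0
    kern$magnitude[inh] <- pmin(kern$magnitude[inh], 0.45 * floor_rate)
  } else if (cls == "lick") {
    base <- spont * 1.1
    depth <- kap(preset$kappa_lick)
  } else if (cls == "anti_lick") {
    base <- spont * 0.45
    edge <- spont * 0.8
  } else if (cls == "lick_bout") {
    base <- spont * 1.6
  } else if (cls == "lick_anti_mix") {
    base <- spont * 0.5
    depth <- kap(preset$kappa_mix)
  }
  cell_spec(unit_id = sprintf("u%03d", i), cell_class = cls,
            spont_rate = spont, baseline_rate = base,
            lick_mod_depth = depth, lick_mod_phase = phase,
            response_kernels = kern, bout_edge_mag = edge,
            rate_drift_cv = preset$drift_cv)
}

draw_kernels <- function(preset, panel) {
  resp <- panel[runif(length(panel)) < preset$p_respond]
  if (length(resp) == 0) resp <- sample(panel, 1)  # a taste cell responds to >= 1
  rows <- lapply(resp, function(s) {
    lbl <- runif(1) < preset$p_lick_by_lick
    sign <- if (runif(1) < preset$p_excitatory) 1 else -1
    if (lbl) {
      mag <- max(preset$mag_min, rgamma_mcv(1, preset$maglbl_mean, preset$mag_cv))
      lat <- min(0.06, max(0.006, rgamma_mcv(1, preset$latlbl_mean, preset$lat_cv)))
      dur <- min(0.165 - lat, max(0.03, rgamma_mcv(1, preset$durlbl_mean, preset$dur_cv)))
      ts <- "lick_by_lick"
    } else {
      mag <- max(preset$mag_min, rgamma_mcv(1, preset$mag5_mean, preset$mag_cv))
      lat <- min(1.5, max(0.05, rgamma_mcv(1, preset$lat5_mean, preset$lat_cv)))
      dur <- min(3, max(0.3, rgamma_mcv(1, preset$dur5_mean, preset$dur_cv)))
      ts <- "five_lick"
    }
    data.frame(stimulus = s, sign = sign, magnitude = mag, latency = lat,
               duration = dur, timescale = ts, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
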