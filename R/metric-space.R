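#' Construct a response set for metric-space analysis
#'
#' A response set bundles spike-time lists (one per trial, aligned to the
#' first stimulus lick of the trial and truncated to an analysis window)
#' with their stimulus labels. It is the input container for the
#' metric-space classifier and information analysis.
#'
#' @param responses list of numeric vectors; spike times in seconds,
#'   relative to trial onset, each within `[0, window)`.
#' @param labels character or factor, one stimulus label per response.
#' @param window analysis window length in seconds.
#' @return an object of class `response_set`.
#' @export
response_set <- function(responses, labels, window) {
  if (!is.list(responses)) stop_config("`responses` must be a list of numeric vectors")
  if (length(labels) != length(responses))
    stop_config("length(labels) [%d] != length(responses) [%d]",
                length(labels), length(responses))
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    stop_config("`window` must be a positive scalar (seconds)")
  responses <- lapply(responses, function(r) {
    r <- as.numeric(r)
    if (anyNA(r) || any(!is.finite(r))) stop_config("non-finite spike time in response")
    if (any(r < 0 | r >= window))
      stop_config("spike time outside [0, window): window = %g s", window)
    sort(r)
  })
  structure(list(responses = responses,
                 labels = as.character(labels),
                 window = window),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("response_set: %d responses, %d labels, window %g s\n",
              length(x$responses), length(unique(x$labels)), x$window))
  invisible(x)
}

#' Spike-count distance between two spike trains
#'
#' The rate-only member of the spike-train metric family: moving a spike
#' in time is free, adding or deleting a spike costs 1, so the distance
#' reduces to the absolute difference in spike counts.
#'
#' @param a,b numeric vectors of spike times (seconds).
#' @return nonnegative numeric distance.
#' @export
count_distance <- function(a, b) abs(length(a) - length(b))

#' Victor-Purpura spike-time distance
#'
#' Minimal total cost of transforming one spike train into the other,
#' where inserting or deleting a spike costs 1 and moving a spike by
#' `dt` seconds costs `q * |dt|`. `q` (in 1/s) sets the temporal
#' precision of the metric; `q = 0` recovers [count_distance()].
#'
#' @param a,b numeric vectors of spike times (seconds).
#' @param q cost per second of spike movement (1/s), `q >= 0`.
#' @return nonnegative numeric distance.
#' @export
vp_distance <- function(a, b, q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0)
    stop_config("`q` must be a single finite nonnegative number")
  a <- as.numeric(a); b <- as.numeric(b)
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b)))
    stop_config("spike times must be finite")
  .vp_pair_cpp(sort(a), sort(b), q)
}

#' All-pairs Victor-Purpura distance matrix
#'
#' @param responses list of spike-time vectors or a [response_set].
#' @param q temporal-precision parameter (1/s).
#' @return symmetric numeric matrix of pairwise distances.
#' @export
vp_distance_matrix <- function(responses, q) {
  if (inherits(responses, "response_set")) responses <- responses$responses
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0)
    stop_config("`q` must be a single finite nonnegative number")
  .vp_matrix_cpp(lapply(responses, function(r) sort(as.numeric(r))), q)
}

# generalized mean with exponent z of a vector of distances.
# Any zero distance dominates for z < 0 (limit value 0), matching the
# convention of the original metric-space classifier.
gen_mean <- function(d, z) {
  if (any(d == 0)) {
    if (z < 0) return(0)
    if (z == 0) return(0)
  }
  if (z == 0) return(exp(mean(log(d))))
  mean(d ^ z) ^ (1 / z)
}

# classifier core working from a precomputed distance matrix.
# Vectorized: scores[i, l] = generalized mean (exponent z) of the
# distances from response i to label l's other responses. Zero
# distances are capped so that, for z < 0, a zero-distance neighbor
# drives the score to (numerically) zero, matching the classic
# convention.
confusion_from_D <- function(D, labels, z) {
  lev <- unique(labels)
  n <- length(labels)
  ind <- vapply(lev, function(l) as.numeric(labels == l), numeric(n))
  # denom[i, l] = #responses with label l, excluding i itself
  denom <- matrix(colSums(ind), n, length(lev), byrow = TRUE) - ind
  if (z == 0) {
    L <- log(D); L[!is.finite(L)] <- -700
    diag(L) <- 0
    S <- L %*% ind
    score <- exp(S / denom)
  } else {
    Dz <- D ^ z
    Dz[!is.finite(Dz)] <- 1e300
    diag(Dz) <- 0
    S <- Dz %*% ind
    score <- (S / denom) ^ (1 / z)
  }
  best <- do.call(pmin, as.data.frame(score))
  cand <- score <= best + 1e-12
  n_ties <- sum(rowSums(cand) > 1L)
  inferred <- max.col(cand, ties.method = "first")
  cm <- matrix(0L, length(lev), length(lev),
               dimnames = list(true = lev, inferred = lev))
  for (k in seq_len(n)) {
    ti <- match(labels[k], lev)
    cm[ti, inferred[k]] <- cm[ti, inferred[k]] + 1L
  }
  attr(cm, "n_ties") <- n_ties
  cm
}

#' Metric-space classifier confusion matrix
#'
#' Each response is assigned to the stimulus label whose other responses
#' (self excluded) are closest on average, where "average" is the
#' generalized mean with exponent `z` of Victor-Purpura distances at
#' temporal precision `q`. Ties are broken toward the smallest label
#' index and counted in the `n_ties` attribute.
#'
#' @param responses a [response_set] (or list of spike-time vectors if
#'   `labels` is given).
#' @param q temporal-precision parameter (1/s).
#' @param z generalized-mean exponent; default -2, the classic
#'   metric-space choice.
#' @param labels optional label vector when `responses` is a bare list.
#' @return square integer confusion matrix, rows = true labels,
#'   columns = inferred labels, with attribute `n_ties`.
#' @export
classify_confusion <- function(responses, q, z = -2, labels = NULL) {
  if (inherits(responses, "response_set")) {
    labels <- responses$labels
    responses <- responses$responses
  }
  if (is.null(labels)) stop_config("labels are required")
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2))
    stop_config("every label needs >= 2 responses (offender: %s)",
                names(tab)[which(tab < 2)[1]])
  D <- .vp_matrix_cpp(lapply(responses, function(r) sort(as.numeric(r))), q)
  confusion_from_D(D, labels, z)
}

#' Mutual information of a confusion matrix
#'
#' Plug-in estimate of the mutual information (log base 2) between true
#' and inferred stimulus labels.
#'
#' @param confusion nonnegative numeric matrix of counts.
#' @return information in bits.
#' @export
mutual_information <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop_config("confusion counts must be nonnegative")
  tot <- sum(confusion)
  if (tot <= 0) stop_config("confusion matrix total must be > 0")
  p <- confusion / tot
  pr <- rowSums(p); pc <- colSums(p)
  idx <- which(p > 0, arr.ind = TRUE)
  sum(p[idx] * log2(p[idx] / (pr[idx[, 1]] * pc[idx[, 2]])))
}

# default temporal-precision ladder (1/s)
default_q_grid <- function() c(0, 1, 2, 4, 8, 16, 32, 64, 128, 256, 512)

# distance matrices for every q in the grid (the expensive part; shuffle
# controls reuse them since label permutation leaves distances unchanged)
vp_dlist <- function(responses, q_grid) {
  tr <- lapply(responses, function(r) sort(as.numeric(r)))
  lapply(q_grid, function(q) .vp_matrix_cpp(tr, q))
}

info_from_dlist <- function(dlist, labels, z) {
  vapply(dlist, function(D) mutual_information(confusion_from_D(D, labels, z)),
         numeric(1))
}

#' Information as a function of temporal precision
#'
#' Runs the metric-space classifier over a grid of `q` values and
#' reports the information curve, its maximum `H_max` (ties resolved
#' toward the smallest `q`), the `q` attaining it, and the rate-only
#' information `H_count` at `q = 0`.
#'
#' @param responses a [response_set].
#' @param q_grid grid of temporal precisions (1/s); must contain 0.
#' @param z generalized-mean exponent.
#' @return list with `q_grid`, `H`, `H_max`, `q_at_max`, `H_count`.
#' @export
info_vs_q <- function(responses, q_grid = default_q_grid(), z = -2) {
  stopifnot(inherits(responses, "response_set"))
  if (!0 %in% q_grid) stop_config("q_grid must include 0 (rate-only limit)")
  q_grid <- sort(unique(as.numeric(q_grid)))
  dlist <- vp_dlist(responses$responses, q_grid)
  H <- info_from_dlist(dlist, responses$labels, z)
  imax <- which(H >= max(H) - 1e-12)[1L]
  list(q_grid = q_grid, H = H, H_max = H[imax], q_at_max = q_grid[imax],
       H_count = H[q_grid == 0])
}

#' Shuffle control: information under random label permutation
#'
#' Stimulus labels are randomly reassigned to responses (preserving
#' label multiplicities) and the full classifier + information analysis
#' is repeated; the mean and SD across repetitions estimate the
#' small-sample bias floor of the plug-in information.
#'
#' @param responses a [response_set].
#' @param q_grid temporal-precision grid (1/s).
#' @param n number of shuffle repetitions (default 40).
#' @param seed optional RNG seed.
#' @param z generalized-mean exponent.
#' @return list with per-q `mean` and `sd` vectors and the `H` matrix
#'   (`n` rows).
#' @export
shuffle_control <- function(responses, q_grid = default_q_grid(), n = 40,
                            seed = NULL, z = -2) {
  stopifnot(inherits(responses, "response_set"))
  if (!is_count(n) || n < 1) stop_config("`n` must be a positive integer")
  q_grid <- sort(unique(as.numeric(q_grid)))
  dlist <- vp_dlist(responses$responses, q_grid)
  lab <- responses$labels
  H <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      info_from_dlist(dlist, sample(lab), z)
    }, numeric(length(q_grid))))
  })
  list(q_grid = q_grid, mean = colMeans(H), sd = apply(H, 2, sd), H = H)
}

# redeal pooled same-label spike times to responses, preserving each
# response's spike count and the label-wise pooled time multiset
exchange_responses <- function(responses, labels) {
  out <- responses
  for (l in unique(labels)) {
    idx <- which(labels == l)
    pool <- unlist(responses[idx], use.names = FALSE)
    if (length(pool) == 0) next
    pool <- pool[sample.int(length(pool))]  # sample(x) misbehaves for length-1 x
    counts <- lengths(responses[idx])
    split_idx <- rep(seq_along(idx), counts)
    for (k in seq_along(idx)) {
      out[[idx[k]]] <- sort(pool[split_idx == k])
    }
  }
  out
}

#' Exchange control: information after within-label spike redeal
#'
#' Within each stimulus label, all spike times are pooled across that
#' label's responses and randomly redealt to responses, preserving each
#' response's original spike count. This conserves the label-wise rate
#' envelope (pooled PSTH) and all spike counts while destroying
#' response-specific spike timing; information surviving the exchange is
#' attributable to the rate envelope rather than to fine timing.
#'
#' @inheritParams shuffle_control
#' @param n number of exchange repetitions (default 10).
#' @return list with per-q `mean` and `sd` vectors and the `H` matrix.
#' @export
exchange_control <- function(responses, q_grid = default_q_grid(), n = 10,
                             seed = NULL, z = -2) {
  stopifnot(inherits(responses, "response_set"))
  if (!is_count(n) || n < 1) stop_config("`n` must be a positive integer")
  q_grid <- sort(unique(as.numeric(q_grid)))
  lab <- responses$labels
  H <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      ex <- exchange_responses(responses$responses, lab)
      info_from_dlist(vp_dlist(ex, q_grid), lab, z)
    }, numeric(length(q_grid))))
  })
  list(q_grid = q_grid, mean = colMeans(H), sd = apply(H, 2, sd), H = H)
}

#' Classify the coding mode of an information result
#'
#' Applies the significance ladder: a cell conveys significant
#' information iff `H_max > H_shuffled + 2 SD`; a significant cell is a
#' pure rate (count) coder if `H_max` equals `H_count` (within
#' tolerance), a rate-envelope coder if `H_max` does not exceed the
#' exchange-control mean, and a spike-timing coder otherwise. Controls
#' are read out at the `q` attaining `H_max`.
#'
#' @param info result of [msa()] (or a compatible list).
#' @param eps absolute tolerance (bits) for `H_max == H_count`.
#' @param rel optional relative tolerance (fraction of `H_max`); the
#'   larger of the two tolerances applies.
#' @return one of `"not_significant"`, `"rate_count"`,
#'   `"rate_envelope"`, `"spike_timing"`.
#' @export
coding_class <- function(info, eps = 1e-9, rel = 0) {
  need <- c("H_max", "H_count", "H_shuffled_mean", "H_shuffled_sd", "H_exchange_mean")
  if (!all(need %in% names(info))) stop_config("info lacks fields: %s",
      paste(setdiff(need, names(info)), collapse = ", "))
  thr <- info$H_shuffled_mean + 2 * info$H_shuffled_sd
  if (info$H_max <= thr) return("not_significant")
  tol <- max(eps, rel * info$H_max)
  if (abs(info$H_max - info$H_count) <= tol) return("rate_count")
  if (info$H_max <= info$H_exchange_mean + tol) return("rate_envelope")
  "spike_timing"
}

#' Full metric-space analysis of one response set
#'
#' Computes the information curve over the `q` grid, shuffle and
#' exchange controls, and the coding-mode classification. Shuffle
#' repetitions reuse the distance matrices (label permutation leaves
#' distances unchanged); exchange repetitions recompute them.
#'
#' @param responses a [response_set].
#' @param q_grid temporal-precision grid (1/s), must contain 0.
#' @param z generalized-mean exponent (default -2).
#' @param n_shuffle shuffle repetitions (default 40).
#' @param n_exchange exchange repetitions (default 10); set 0 to skip
#'   (coding class then distinguishes only significance and rate_count).
#' @param seed optional RNG seed.
#' @param eps,rel tolerances passed to [coding_class()].
#' @return object of class `info_result`: list with `q_grid`, `H`,
#'   `H_max`, `q_at_max`, `H_count`, `H_shuffled_mean/sd`,
#'   `H_exchange_mean/sd` (at `q_at_max`), full control curves, and
#'   `coding_class`.
#' @export
msa <- function(responses, q_grid = default_q_grid(), z = -2,
                n_shuffle = 40, n_exchange = 10, seed = NULL,
                eps = 1e-9, rel = 0) {
  stopifnot(inherits(responses, "response_set"))
  if (!0 %in% q_grid) stop_config("q_grid must include 0")
  q_grid <- sort(unique(as.numeric(q_grid)))
  dlist <- vp_dlist(responses$responses, q_grid)
  lab <- responses$labels
  H <- info_from_dlist(dlist, lab, z)
  imax <- which(H >= max(H) - 1e-12)[1L]

  sh <- with_seed(sub_seed(seed, 1L), {
    t(vapply(seq_len(n_shuffle), function(i) info_from_dlist(dlist, sample(lab), z),
             numeric(length(q_grid))))
  })
  # the null for H_max is the shuffled H_max (per-repetition maximum
  # over the q grid); comparing against a single-q null would ignore
  # the selection of q and admit noise cells
  shmax <- apply(sh, 1, max)
  res <- list(
    q_grid = q_grid, H = H,
    H_max = H[imax], q_at_max = q_grid[imax], H_count = H[q_grid == 0],
    H_shuffled_curve_mean = colMeans(sh),
    H_shuffled_curve_sd = apply(sh, 2, sd),
    H_shuffled_mean = mean(shmax),
    H_shuffled_sd = sd(shmax)
  )
  if (n_exchange > 0) {
    ex <- with_seed(sub_seed(seed, 2L), {
      t(vapply(seq_len(n_exchange), function(i) {
        exr <- exchange_responses(responses$responses, lab)
        info_from_dlist(vp_dlist(exr, q_grid), lab, z)
      }, numeric(length(q_grid))))
    })
    res$H_exchange_curve_mean <- colMeans(ex)
    res$H_exchange_curve_sd <- apply(ex, 2, sd)
    res$H_exchange_mean <- mean(ex[, imax])
    res$H_exchange_sd <- sd(ex[, imax])
  } else {
    res$H_exchange_mean <- -Inf
    res$H_exchange_sd <- NA_real_
  }
  res$coding_class <- coding_class(res, eps = eps, rel = rel)
  class(res) <- "info_result"
  res
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf(
    "info_result: H_max %.3f bits at q = %g 1/s; H_count %.3f bits\n",
    x$H_max, x$q_at_max, x$H_count))
  cat(sprintf("  shuffle %.3f +/- %.3f, exchange %s; coding class: %s\n",
              x$H_shuffled_mean, x$H_shuffled_sd,
              if (is.finite(x$H_exchange_mean)) sprintf("%.3f", x$H_exchange_mean) else "n/a",
              x$coding_class))
  invisible(x)
}

#' Information summary across analysis windows
#'
#' Truncates each cell's responses to each analysis window, runs the
#' full metric-space analysis, and summarizes, per window: the mean
#' `H_max` across all cells (cells failing the shuffle criterion
#' contribute zero), the mean `H_count` among significant cells, and
#' the proportion of significant cells.
#'
#' @param cells list of [response_set] objects, one per cell, whose
#'   window is at least `max(windows)`.
#' @param windows analysis windows in seconds; the canonical sweep is
#'   `c(0.2, 0.5, 1, 1.5, 2)`. Other values are allowed but flagged in
#'   the `noncanonical` column.
#' @param ... passed to [msa()].
#' @param seed optional RNG seed (one sub-seed per cell x window).
#' @return data.frame with columns `window`, `mean_H_max`,
#'   `mean_H_count_sig`, `prop_significant`, `n_cells`, `noncanonical`.
#' @export
window_sweep <- function(cells, windows = c(0.2, 0.5, 1, 1.5, 2),
                         seed = NULL, ...) {
  stopifnot(length(cells) >= 1, all(vapply(cells, inherits, TRUE, "response_set")))
  canonical <- c(0.2, 0.5, 1, 1.5, 2)
  rows <- lapply(seq_along(windows), function(wi) {
    W <- windows[wi]
    per <- lapply(seq_along(cells), function(ci) {
      rs <- cells[[ci]]
      if (rs$window < W)
        stop_config("cell %d window (%g s) shorter than sweep window %g s",
                    ci, rs$window, W)
      trunc <- response_set(lapply(rs$responses, function(r) r[r < W]),
                            rs$labels, W)
      msa(trunc, seed = sub_seed(seed, wi * 1000L + ci), ...)
    })
    sig <- vapply(per, function(p) p$coding_class != "not_significant", TRUE)
    hmax <- vapply(per, `[[`, numeric(1), "H_max")
    hcnt <- vapply(per, `[[`, numeric(1), "H_count")
    data.frame(
      window = W,
      mean_H_max = mean(ifelse(sig, hmax, 0)),
      mean_H_count_sig = if (any(sig)) mean(hcnt[sig]) else 0,
      prop_significant = mean(sig),
      n_cells = length(per),
      noncanonical = !any(abs(W - canonical) < 1e-12)
    )
  })
  do.call(rbind, rows)
}
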