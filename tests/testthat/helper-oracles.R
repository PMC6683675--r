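# Independent oracles and small fixture builders used across the suite.

# Brute-force Victor-Purpura distance: recursive minimization over all
# edit plans (delete a, delete b, or match heads). Exponential; only
# for tiny trains.
vp_bruteforce <- function(a, b, q) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  min(vp_bruteforce(a[-1], b, q) + 1,
      vp_bruteforce(a, b[-1], q) + 1,
      vp_bruteforce(a[-1], b[-1], q) + q * abs(a[1] - b[1]))
}

# Plug-in mutual information computed directly from the definition,
# independent of the package implementation.
mi_oracle <- function(cm) {
  p <- cm / sum(cm)
  h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  h(rowSums(p)) + h(colSums(p)) - h(as.vector(p))
}

# random spike train of n spikes in [0, W)
rand_train <- function(n, W = 2) sort(runif(n, 0, W))

# a perfectly count-separable response set: class k has n_k spikes
separable_set <- function(counts, n_per = 10, W = 2) {
  resp <- unlist(lapply(counts, function(k)
    replicate(n_per, rand_train(k, W), simplify = FALSE)), recursive = FALSE)
  response_set(resp, rep(paste0("S", seq_along(counts)), each = n_per), W)
}

# a timing-only response set: both classes have `n_spk` spikes, class B
# delayed by `offset`
timing_set <- function(n_per = 10, n_spk = 5, offset = 0.05, W = 2) {
  base <- seq(0.2, 1.4, length.out = n_spk)
  jit <- function() sort(pmin(pmax(base + rnorm(n_spk, 0, 0.002), 0), W - 1e-6))
  respA <- replicate(n_per, jit(), simplify = FALSE)
  respB <- replicate(n_per, jit() + offset, simplify = FALSE)
  response_set(c(respA, respB), rep(c("A", "B"), each = n_per), W)
}

# deterministic rhythmic lick train covering `n_trials` trials of one
# stimulus, plus the scheduled trial table
quick_trials <- function(n_trials, stimulus = "X", ili = 0.16, seed = 1) {
  dur <- n_trials * 40 * ili * 1.3 + 30
  lt <- generate_lick_train(dur, ili, 0.01, bout_length_dist = 500,
                            pause_dist = 2, seed = seed)
  sc <- schedule_trials(lt, stimulus, n_trials, seed = seed + 1,
                        first_stimulus = stimulus)
  c(sc, list(duration = dur))
}

# spike train for one cell over a quick_trials fixture
quick_spikes <- function(sc, spec, seed = 1) {
  generate_spike_train(spec, sc$licks, sc$trials, sc$duration, seed = seed)
}
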