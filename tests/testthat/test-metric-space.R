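test_that("count_distance and vp_distance basic identities", {
  expect_equal(count_distance(numeric(0), numeric(0)), 0)
  expect_equal(count_distance(c(1, 2, 3), c(1, 2, 3, 4, 5)), 2)
  # two deletions regardless of q
  for (q in c(0, 1, 50)) expect_equal(vp_distance(c(0.1, 0.2), numeric(0), q), 2)
  # shift beats delete+insert: 10 * 0.01 = 0.1 < 2
  expect_equal(vp_distance(0.100, 0.110, 10), 0.1)
  # delete+insert beats shift at high q
  expect_equal(vp_distance(0.1, 0.9, 10), 2)
  expect_error(vp_distance(0.1, 0.2, -1), "nonnegative")
})

test_that("vp_distance q = 0 limit equals count_distance", {
  set.seed(41)
  for (i in 1:300) {
    a <- rand_train(sample(0:8, 1)); b <- rand_train(sample(0:8, 1))
    expect_identical(vp_distance(a, b, 0), as.numeric(count_distance(a, b)))
  }
})

test_that("vp_distance agrees with the brute-force oracle", {
  set.seed(42)
  for (i in 1:200) {
    a <- rand_train(sample(0:5, 1)); b <- rand_train(sample(0:5, 1))
    q <- sample(c(0, 1, 10, 100), 1)
    expect_equal(vp_distance(a, b, q), vp_bruteforce(a, b, q), tolerance = 1e-12)
  }
})

test_that("vp_distance satisfies metric axioms and bounds", {
  set.seed(43)
  for (i in 1:300) {
    a <- rand_train(sample(0:6, 1)); b <- rand_train(sample(0:6, 1))
    cc <- rand_train(sample(0:6, 1))
    q <- runif(1, 0, 64)
    dab <- vp_distance(a, b, q); dba <- vp_distance(b, a, q)
    expect_identical(dab, dba)
    expect_identical(vp_distance(a, a, q), 0)
    expect_lte(dab, vp_distance(a, cc, q) + vp_distance(cc, b, q) + 1e-12)
    expect_lte(dab, length(a) + length(b) + 1e-12)
  }
  # non-decreasing in q for equal-count trains
  set.seed(44)
  a <- rand_train(5); b <- rand_train(5)
  d <- vapply(c(0, 1, 2, 4, 8, 32, 128), function(q) vp_distance(a, b, q), 1)
  expect_true(all(diff(d) >= -1e-12))
})

test_that("classifier separates count-coded classes and flags degenerate ties", {
  set.seed(45)
  rs <- separable_set(c(0, 10, 20, 30))
  cm <- classify_confusion(rs, q = 0)
  expect_equal(unname(diag(cm)), rep(10L, 4))
  expect_equal(sum(cm), 40)
  # all-identical responses: every assignment ties, flagged
  same <- response_set(replicate(8, c(0.5, 1.0), simplify = FALSE),
                       rep(c("A", "B"), each = 4), 2)
  cm2 <- classify_confusion(same, q = 0)
  expect_equal(attr(cm2, "n_ties"), 8L)
  expect_true(all(cm2[, 1] == 4))  # smallest-index tie break
  expect_error(classify_confusion(response_set(list(c(0.1), c(0.2), c(0.3)),
                                               c("A", "A", "B"), 2), q = 0),
               ">= 2 responses")
})

test_that("timing-only classes need temporal precision", {
  set.seed(46)
  rs <- timing_set(n_per = 10, offset = 0.05)
  cm_hi <- classify_confusion(rs, q = 40)
  expect_equal(unname(diag(cm_hi)), rep(10L, 2))
  # at q = 0 counts are equal, so assignment collapses to ties
  cm_lo <- classify_confusion(rs, q = 0)
  expect_lt(mi_oracle(cm_lo), 0.05)
})

test_that("mutual_information matches the direct formula", {
  expect_equal(mutual_information(diag(10, 4)), 2)
  expect_equal(mutual_information(matrix(10, 4, 4)), 0)
  cm <- matrix(c(9, 1, 1, 9), 2, byrow = TRUE)
  expect_equal(mutual_information(cm), 1 + 0.9 * log2(0.9) + 0.1 * log2(0.1),
               tolerance = 1e-12)
  set.seed(47)
  for (i in 1:20) {
    cm <- matrix(rpois(16, 5), 4)
    expect_equal(mutual_information(cm), mi_oracle(cm), tolerance = 1e-12)
  }
  expect_error(mutual_information(matrix(0, 2, 2)), "total")
})

test_that("info_vs_q locates rate and timing codes", {
  set.seed(48)
  rs <- separable_set(c(2, 10, 20, 30))
  iv <- info_vs_q(rs)
  expect_equal(iv$q_at_max, 0)
  expect_equal(iv$H_max, iv$H_count)
  expect_equal(iv$H_max, 2)
  rs2 <- timing_set()
  iv2 <- info_vs_q(rs2)
  expect_gt(iv2$H_max, iv2$H_count)
  expect_gt(iv2$q_at_max, 0)
  # a single label can carry no information
  one <- response_set(replicate(4, rand_train(3), simplify = FALSE),
                      rep("A", 4), 2)
  expect_true(all(info_vs_q(one)$H == 0))
  expect_error(info_vs_q(rs, q_grid = c(1, 2)), "include 0")
})

test_that("H is bounded by log2(#labels) and H_count = H at q 0", {
  set.seed(49)
  for (i in 1:10) {
    nlab <- sample(2:4, 1)
    resp <- replicate(nlab * 4, rand_train(sample(0:12, 1)), simplify = FALSE)
    rs <- response_set(resp, rep(paste0("L", 1:nlab), each = 4), 2)
    iv <- info_vs_q(rs)
    expect_true(all(iv$H >= -1e-12 & iv$H <= log2(nlab) + 1e-12))
    expect_identical(iv$H_count, iv$H[iv$q_grid == 0])
  }
})

test_that("shuffle control reproduces the exhaustive small-sample bias", {
  set.seed(50)
  resp <- replicate(6, rand_train(sample(2:8, 1)), simplify = FALSE)
  labels <- rep(c("A", "B"), each = 3)
  rs <- response_set(resp, labels, 2)
  # exhaustive oracle: MI over every distinct labelling, at q = 0
  D <- vp_distance_matrix(rs, 0)
  combos <- combn(6, 3)
  h_all <- apply(combos, 2, function(ix) {
    lab <- rep("B", 6); lab[ix] <- "A"
    mi_oracle(tastespike:::confusion_from_D(D, lab, -2))
  })
  sh <- shuffle_control(rs, q_grid = c(0, 16), n = 400, seed = 51)
  expect_gt(sh$mean[1], 0)            # bias floor is positive
  expect_equal(sh$mean[1], mean(h_all), tolerance = 0.06)
  expect_error(shuffle_control(rs, n = 0), "positive integer")
})

test_that("shuffle control sits far below a separable signal", {
  set.seed(52)
  rs <- separable_set(c(0, 10, 20, 30))
  m <- msa(rs, seed = 53)
  expect_equal(m$H_max, 2)
  expect_lt(m$H_shuffled_mean, 1)
  expect_gt(m$H_max, m$H_shuffled_mean + 2 * m$H_shuffled_sd)
  expect_false(m$coding_class == "not_significant")
})

test_that("exchange control conserves counts and label-wise PSTHs", {
  set.seed(54)
  for (rep in 1:25) {
    nlab <- sample(2:4, 1)
    resp <- replicate(nlab * 5, rand_train(sample(0:15, 1)), simplify = FALSE)
    labels <- rep(paste0("L", 1:nlab), each = 5)
    ex <- tastespike:::exchange_responses(resp, labels)
    expect_identical(lengths(ex), lengths(resp))
    for (l in unique(labels)) {
      idx <- which(labels == l)
      expect_identical(sort(unlist(ex[idx])), sort(unlist(resp[idx])))
      # 20 ms PSTH conserved exactly
      brk <- seq(0, 2, by = 0.02)
      expect_identical(
        tabulate(findInterval(unlist(ex[idx]), brk), length(brk)),
        tabulate(findInterval(unlist(resp[idx]), brk), length(brk)))
    }
  }
})

test_that("exchange destroys timing information but not count information", {
  set.seed(55)
  rs <- timing_set(n_per = 10, n_spk = 6, offset = 0.06)
  m <- msa(rs, seed = 56)
  expect_gt(m$H_max, m$H_exchange_mean)
  expect_equal(m$coding_class, "spike_timing")
  rs2 <- separable_set(c(2, 12, 25, 40))
  m2 <- msa(rs2, seed = 57)
  expect_equal(m2$coding_class, "rate_count")
})

test_that("coding_class implements the significance ladder", {
  base <- list(H_max = 1.5, H_count = 1.5, H_shuffled_mean = 0.4,
               H_shuffled_sd = 0.1, H_exchange_mean = 1.0)
  expect_equal(coding_class(base), "rate_count")
  expect_equal(coding_class(modifyList(base, list(H_max = 0.55))), "not_significant")
  expect_equal(coding_class(modifyList(base, list(H_count = 0.9))), "spike_timing")
  expect_equal(coding_class(modifyList(base, list(H_count = 0.9, H_exchange_mean = 1.6))),
               "rate_envelope")
})

test_that("window_sweep summarizes per-window information", {
  set.seed(58)
  cells <- list(separable_set(c(1, 8, 16, 24)), separable_set(c(2, 9, 18, 27)))
  sw <- window_sweep(cells, windows = c(0.5, 2), seed = 59, n_exchange = 0)
  expect_equal(nrow(sw), 2)
  expect_false(any(sw$noncanonical))
  expect_true(all(sw$prop_significant >= 0 & sw$prop_significant <= 1))
  # the full 2 s window sees the full (perfectly separable) counts
  expect_equal(sw$mean_H_max[sw$window == 2], 2)
  sw2 <- window_sweep(cells, windows = 0.3, seed = 60, n_exchange = 0)
  expect_true(sw2$noncanonical)
})
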