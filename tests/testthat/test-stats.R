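# Profile similarity, surrogate nulls, windowed profiling and the
# group-distinctness permutation test.

fake_set <- function(profiles_by_pair, owner = "s") {
  # profiles_by_pair: named list "eff->prd" -> numeric skill vector
  rows <- lapply(names(profiles_by_pair), function(nm) {
    pr <- strsplit(nm, "->", fixed = TRUE)[[1]]
    sk <- profiles_by_pair[[nm]]
    tp <- -(seq_along(sk) + 2L)
    data.frame(pair_effect = pr[1], pair_predictor = pr[2],
               delay = -tp - 3L, tp_samples = tp, tp_seconds = tp / 20,
               skill_raw = sk,
               skill_norm = (sk - min(sk)) /
                 max(max(sk) - min(sk), .Machine$double.eps))
  })
  structure(do.call(rbind, rows), owner = owner,
            class = c("profile_set", "data.frame"))
}

test_that("profile similarity is a mean Spearman with its exact symmetries", {
  a <- fake_set(list("a1->a2" = c(1, 2, 3, 4, 5), "a2->a1" = c(0.1, 0.3, 0.4, 0.8, 0.9)))
  expect_equal(profile_similarity(a, a), 1)
  # on monotone profiles, reversing the delay axis flips every rank
  rev_a <- fake_set(list("a1->a2" = c(5, 4, 3, 2, 1),
                         "a2->a1" = c(0.9, 0.8, 0.4, 0.3, 0.1)))
  expect_equal(profile_similarity(a, rev_a), -1)
  # rank invariance: using normalized instead of raw skills changes nothing
  b <- fake_set(list("a1->a2" = c(2, 0, 1, 4, 3), "a2->a1" = c(1, 1.5, 0, 2, 0.5)))
  b_norm <- b
  b_norm$skill_raw <- b_norm$skill_norm
  a_norm <- a
  a_norm$skill_raw <- a_norm$skill_norm
  expect_equal(profile_similarity(a, b), profile_similarity(a_norm, b_norm))
  # mismatched grids are refused with a pointer to resampling
  short <- fake_set(list("a1->a2" = 1:3, "a2->a1" = 3:1))
  expect_error(profile_similarity(a, short), "resample")
})

test_that("similarity matrices are symmetric with unit diagonal", {
  sets <- lapply(1:4, function(i) {
    set.seed(i)
    fake_set(list("a1->a2" = runif(8), "a2->a1" = runif(8)),
             owner = paste0("w", i))
  })
  m <- similarity_matrix(sets)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(1, 4), paste0("w", 1:4)))
  expect_true(all(m >= -1 & m <= 1))
})

test_that("draws from one generative model are more alike than across models", {
  g1 <- graph_three(c(4, 8, 6))
  g2 <- graph_three(c(10, 3, 12))
  mk <- function(g, seed) {
    rec <- synthetic_eigenmodes(duration_s = 45, rate_hz = 20, couplings = g,
                                r = r_headroom, seed = seed)
    profile_set(rec, delays = 0:12, E = 2, library_size = 100, n_repeats = 3,
                seed = seed + 7)
  }
  wins <- 0L
  n_trials <- 20L
  for (trial in seq_len(n_trials)) {
    a <- mk(g1, 3 * trial)
    b <- mk(g1, 3 * trial + 1)
    cc <- mk(g2, 3 * trial + 2)
    if (profile_similarity(a, b) > profile_similarity(a, cc)) wins <- wins + 1L
  }
  expect_gte(wins, 0.9 * n_trials)
})

test_that("phase surrogates preserve the power spectrum, mean and variance", {
  set.seed(1)
  x <- as.numeric(arima.sim(list(ar = c(0.7, -0.2)), 256)) + 3
  s <- phase_surrogate(x, seed = 2)
  expect_length(s, length(x))
  pow <- function(v) Mod(fft(v))^2
  expect_lt(max(abs(pow(s) - pow(x)) / max(pow(x))), 1e-8)
  expect_equal(mean(s), mean(x), tolerance = 1e-10)
  expect_equal(var(s), var(x), tolerance = 1e-8)
  # odd length too (different Hermitian bookkeeping)
  x2 <- x[1:255]
  s2 <- phase_surrogate(x2, seed = 3)
  expect_lt(max(abs(pow(s2) - pow(x2)) / max(pow(x2))), 1e-8)

  expect_error(phase_surrogate(c(1, NA, 3)), "gap-free")
})

test_that("the surrogate of a pure sinusoid is a phase-shifted sinusoid", {
  t <- 0:127
  x <- sin(2 * pi * 8 * t / 128)
  s <- phase_surrogate(x, seed = 4)
  # same single-frequency content and amplitude
  expect_lt(max(abs(Mod(fft(s)) - Mod(fft(x)))), 1e-10)
  # fits A*sin + B*cos at the same frequency essentially perfectly
  fit <- lm(s ~ sin(2 * pi * 8 * t / 128) + cos(2 * pi * 8 * t / 128))
  expect_lt(sd(residuals(fit)), 1e-10)
})

test_that("a coupled pair's best-delay skill exceeds the surrogate null", {
  sim <- coupled_logistic(1200, couplings = list(c(4, 0.1)), seed = 5)
  p <- lag_profile(sim$x, sim$y, delays = 0:8, E = 2, library_size = 150,
                   n_repeats = 5, seed = 6)
  best_tp <- p$tp_samples[which.max(p$skill_raw)]
  surr <- vapply(1:50, function(k) {
    as.numeric(cross_map(phase_surrogate(sim$x, seed = 100 + k),
                         phase_surrogate(sim$y, seed = 200 + k),
                         E = 2, tp = best_tp, library_size = 150,
                         n_repeats = 2, seed = k))
  }, numeric(1))
  expect_gt(max(p$skill_raw), quantile(surr, 0.95))
})

test_that("windows tile the recording and respect feasibility", {
  rec <- synthetic_eigenmodes(duration_s = 500, rate_hz = 2, seed = 7)
  wp <- windowed_profiles(rec, window_s = 20, n_windows = 25, delays = 0:4,
                          E = 2, library_size = "all", n_repeats = 1, seed = 8)
  expect_length(wp, 25)
  expect_named(wp, sprintf("%s_w%d", rec$id, 1:25))
  expect_error(windowed_profiles(rec, window_s = 20, n_windows = 26,
                                 delays = 0:4, E = 2),
               "at most 25")
  short <- eigenmode_record(rec$modes[1:30, ], rate_hz = 2, id = "short")
  expect_error(windowed_profiles(short, window_s = 20, delays = 0:4),
               "shorter than one")
})

test_that("entirely missing windows are skipped with a warning", {
  modes <- synthetic_eigenmodes(duration_s = 90, rate_hz = 2, seed = 9)$modes
  modes[41:80, ] <- NA # second 20-s window at 2 Hz
  rec <- eigenmode_record(modes, rate_hz = 2, id = "gappy")
  expect_warning(
    wp <- windowed_profiles(rec, window_s = 20, delays = 0:3, E = 2,
                            library_size = "all", n_repeats = 1),
    "entirely missing")
  expect_length(wp, 3)
  expect_false("gappy_w2" %in% names(wp))
})

test_that("windowed profiles of a stationary recording are mutually consistent", {
  g <- graph_three(c(3, 8, 5))
  rec <- synthetic_eigenmodes(duration_s = 160, rate_hz = 20, couplings = g,
                              r = r_headroom, seed = 31)
  wp <- windowed_profiles(rec, window_s = 20, delays = 0:14, E = 2,
                          library_size = 150, n_repeats = 4, seed = 4)
  m_real <- similarity_matrix(wp)
  surr <- sapply(1:4, function(j) phase_surrogate(rec$modes[, j], seed = 90 + j))
  colnames(surr) <- colnames(rec$modes)
  rec_null <- eigenmode_record(surr, rate_hz = 20, id = "null")
  wp_null <- windowed_profiles(rec_null, window_s = 20, delays = 0:14, E = 2,
                               library_size = 150, n_repeats = 4, seed = 5)
  m_null <- similarity_matrix(wp_null)
  expect_gt(mean(offdiag(m_real)), quantile(offdiag(m_null), 0.95))
})

test_that("a mid-recording coupling switch splits the windows into two clusters", {
  rA <- synthetic_eigenmodes(duration_s = 80, rate_hz = 20,
                             couplings = graph_three(c(3, 8, 5)),
                             r = r_headroom, seed = 21)
  rB <- synthetic_eigenmodes(duration_s = 80, rate_hz = 20,
                             couplings = graph_three(c(12, 2, 9)),
                             r = r_headroom, seed = 22)
  rec <- eigenmode_record(rbind(rA$modes, rB$modes), rate_hz = 20, id = "switch")
  wp <- windowed_profiles(rec, window_s = 20, delays = 0:14, E = 2,
                          library_size = 100, n_repeats = 2, seed = 3)
  m <- similarity_matrix(wp)
  within <- c(offdiag(m[1:4, 1:4]), offdiag(m[5:8, 5:8]))
  between <- as.vector(m[1:4, 5:8])
  expect_gt(mean(within), mean(between) + 0.05)
})

test_that("distinctness results satisfy their contract and validation", {
  set.seed(10)
  pts <- matrix(rnorm(30 * 5), 30, 5)
  s <- cor(t(pts))
  rownames(s) <- colnames(s) <- paste0("u", 1:30)
  res <- distinctness_test(s, paste0("u", 1:10), paste0("u", 11:30),
                           n_perm = 250, seed = 11)
  expect_s3_class(res, "distinctness_result")
  expect_length(res$null_pcts, 250)
  expect_true(res$observed_pct >= 0 && res$observed_pct <= 100)
  expect_true(res$attained >= 0 && res$attained <= 1)
  expect_error(distinctness_test(s, paste0("u", 1:5), paste0("u", 5:10)),
               "disjoint")
  expect_error(distinctness_test(s, "u1", paste0("u", 2:5)), "at least two")
  expect_error(distinctness_test(s, c("u1", "zz"), c("u3", "u4")), "absent")
})

test_that("well-separated planted groups are detected as distinct", {
  for (trial in 1:3) {
    set.seed(trial)
    a <- matrix(rnorm(10 * 4, mean = 0), 10, 4)
    b <- matrix(rnorm(12 * 4, mean = 6), 12, 4)
    s <- 1 / (1 + as.matrix(dist(rbind(a, b))))
    diag(s) <- 1
    rownames(s) <- colnames(s) <- c(paste0("A", 1:10), paste0("B", 1:12))
    res <- distinctness_test(s, paste0("A", 1:10), paste0("B", 1:12),
                             n_perm = 1000, seed = 40 + trial)
    expect_gte(res$attained, 0.99)
  }
})

test_that("distinctness is invariant under monotone rescaling of similarity", {
  set.seed(12)
  pts <- matrix(rnorm(24 * 6), 24, 6)
  s <- cor(t(pts))
  rownames(s) <- colnames(s) <- paste0("u", 1:24)
  s2 <- tanh(2 * s)
  diag(s2) <- 1
  r1 <- distinctness_test(s, paste0("u", 1:12), paste0("u", 13:24),
                          n_perm = 300, seed = 13)
  r2 <- distinctness_test(s2, paste0("u", 1:12), paste0("u", 13:24),
                          n_perm = 300, seed = 13)
  expect_identical(r1$observed_pct, r2$observed_pct)
  expect_identical(r1$null_pcts, r2$null_pcts)
  expect_identical(r1$attained, r2$attained)
})

test_that("distinctness is directional: a tight cluster inside a diffuse one", {
  hits <- 0L
  n_trials <- 20L
  for (trial in seq_len(n_trials)) {
    set.seed(trial)
    tight <- matrix(rnorm(10 * 10, sd = 0.05), 10, 10)
    diffuse <- matrix(rnorm(20 * 10, sd = 1), 20, 10)
    s <- 1 / (1 + as.matrix(dist(rbind(tight, diffuse))))
    diag(s) <- 1
    rownames(s) <- colnames(s) <- c(paste0("T", 1:10), paste0("D", 1:20))
    a_t <- distinctness_test(s, paste0("T", 1:10), paste0("D", 1:20),
                             n_perm = 500, seed = trial)$attained
    a_d <- distinctness_test(s, paste0("D", 1:20), paste0("T", 1:10),
                             n_perm = 500, seed = trial)$attained
    if (a_t >= 0.95 && a_d < 0.95) hits <- hits + 1L
  }
  expect_gte(hits, 0.8 * n_trials)
})

test_that("distinctness results serialize to JSON", {
  set.seed(14)
  s <- cor(t(matrix(rnorm(12 * 5), 12, 5)))
  rownames(s) <- colnames(s) <- paste0("u", 1:12)
  res <- distinctness_test(s, paste0("u", 1:6), paste0("u", 7:12),
                           n_perm = 100, seed = 15)
  path <- tempfile(fileext = ".json")
  write_distinctness(res, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$observed_pct, res$observed_pct)
  expect_equal(back$attained, res$attained)
  expect_equal(back$n_perm, 100)
})
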