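# Simulators: the coupled logistic worked example and a synthetic
# four-channel eigenmode generator with planted lagged couplings. Both are
# first-class, seeded and bit-reproducible; they define the conditions all
# validation in this package runs under.

#' Coupled logistic maps with lagged unidirectional forcing
#'
#' Simulates the canonical cross-mapping benchmark: a chaotic logistic map
#' `x` driving a second logistic map `y` through one or more lagged
#' additive coupling terms,
#' \deqn{x_{t+1} = x_t (r_x - r_x x_t)}
#' \deqn{y_{t+1} = y_t (r_y - r_y y_t + \sum_k c_k x_{t - L_k})}
#' with defaults `r_x = 3.8`, `r_y = 3.5` and a single coupling of strength
#' `c = 0.1` at lag `L = 4`. `x` evolves autonomously, so the causal
#' arrow runs strictly from `x` to `y`; the interaction profile of `x`'s
#' influence on `y` peaks at displayed delay `L`.
#'
#' @param n_steps Number of samples returned per series (after burn-in).
#' @param couplings Couplings of `x` into `y`: a list of `c(delay, strength)`
#'   pairs or a data frame with columns `delay` and `strength`. Delays are
#'   in steps (>= 1); an empty list decouples the pair.
#' @param r_x,r_y Logistic growth parameters.
#' @param burn_in Initial samples discarded (default 200, enough for the
#'   attractor to forget the random initial conditions).
#' @param seed Optional seed for the uniform `(0.2, 0.8)` initial
#'   conditions; the dynamics themselves are deterministic.
#'
#' @return A list with numeric vectors `x` and `y` of length `n_steps` and
#'   attribute `"truth"`, the coupling table.
#' @export
coupled_logistic <- function(n_steps = 2000, couplings = list(c(4, 0.1)),
                             r_x = 3.8, r_y = 3.5, burn_in = 200,
                             seed = NULL) {
  n_steps <- stopifnot_scalar_count(n_steps, "n_steps", min = 1L)
  burn_in <- stopifnot_scalar_count(burn_in, "burn_in", min = 0L)
  cp <- normalize_couplings(couplings)
  if (nrow(cp) > 0 && any(cp$delay < 1 | cp$delay != round(cp$delay))) {
    stop("coupling delays must be integers >= 1", call. = FALSE)
  }

  total <- burn_in + n_steps
  init <- with_seed(seed, stats::runif(2, 0.2, 0.8))
  x <- numeric(total)
  y <- numeric(total)
  x[1] <- init[1]
  y[1] <- init[2]
  for (t in seq_len(total - 1L)) {
    x[t + 1L] <- x[t] * (r_x - r_x * x[t])
    drive <- 0
    if (nrow(cp) > 0) {
      src <- t - cp$delay
      use <- src >= 1L
      if (any(use)) drive <- sum(cp$strength[use] * x[src[use]])
    }
    y[t + 1L] <- y[t] * (r_y - r_y * y[t] + drive)
    if (!is.finite(y[t + 1L]) || y[t + 1L] <= 0 || y[t + 1L] >= 1) {
      stop(sprintf(paste0("trajectory left (0, 1) at step %d; coupling too ",
                          "strong (max strength %.3g)"),
                   t + 1L, max(cp$strength)), call. = FALSE)
    }
  }
  keep <- (burn_in + 1L):total
  structure(list(x = x[keep], y = y[keep]), truth = cp)
}

normalize_couplings <- function(couplings) {
  if (is.null(couplings) || (is.list(couplings) && length(couplings) == 0L)) {
    return(data.frame(delay = integer(0), strength = numeric(0)))
  }
  if (is.data.frame(couplings)) {
    stopifnot(all(c("delay", "strength") %in% names(couplings)))
    return(couplings[, c("delay", "strength")])
  }
  if (is.numeric(couplings)) couplings <- list(couplings)
  data.frame(delay = vapply(couplings, `[`, numeric(1), 1L),
             strength = vapply(couplings, `[`, numeric(1), 2L))
}

#' Synthetic eigenmode recordings with planted couplings
#'
#' Generates a multichannel test recording emulating the format of tracked
#' postural-mode data: four chaotic logistic-map channels with distinct
#' growth parameters (irregular, short-memory oscillations — the regime
#' cross mapping is designed for), optionally coupled by directed lagged
#' additive forcing, standardized to zero mean and unit variance, observed
#' with Gaussian noise, and interrupted by joint NaN gaps that emulate
#' tracking dropouts. The planted coupling graph is stored as ground truth
#' so delay recovery can be scored.
#'
#' A coupling `(from, to, delay = L, strength = c)` adds `c * x_from(t - L)`
#' to the receiver map's growth term at `t + 1` (exactly as in
#' [coupled_logistic()]), so the pair's interaction profile
#' (effect = `from`, predictor = `to`) peaks at displayed delay `L`.
#'
#' @param duration_s Recording length in seconds.
#' @param rate_hz Sampling rate in Hz (the analyzed recordings span roughly
#'   16-30 Hz; default 20).
#' @param couplings `NULL` for fully uncoupled channels, otherwise a data
#'   frame with columns `from`, `to` (mode names or 1-based indices),
#'   `delay` (samples, >= 1) and `strength`. The total strength into a
#'   channel must keep its map inside (0, 1); an infeasible combination is
#'   an error naming the bound.
#' @param r Logistic growth parameters, one per mode, all in the chaotic
#'   band; receivers of coupling need headroom (`(r + c_total)^2 / (4 r) < 1`).
#' @param noise_sd Observation noise standard deviation, in units of each
#'   channel's (unit) standard deviation.
#' @param nan_fraction Target fraction of frames replaced by joint NaN gaps
#'   across all channels, in `[0, 1)`. Values of 0.25 and above produce
#'   records the standard quality filter rejects (see [filter_records()]).
#' @param gap_mean_len Mean gap length in samples (geometric lengths).
#' @param id,strain,behavior Metadata for the resulting record.
#' @param burn_in Initial samples discarded.
#' @param seed Optional seed; the same spec and seed reproduce the record
#'   bit for bit.
#'
#' @return An [eigenmode_record()] whose `"truth"` attribute holds the
#'   planted coupling table (with mode names resolved).
#' @export
synthetic_eigenmodes <- function(duration_s = 60, rate_hz = 20,
                                 couplings = NULL,
                                 r = c(3.9, 3.6, 3.7, 3.8),
                                 noise_sd = 0.05,
                                 nan_fraction = 0, gap_mean_len = 10,
                                 id = "synthetic", strain = NA_character_,
                                 behavior = NA_character_,
                                 burn_in = 200, seed = NULL) {
  stopifnot(duration_s > 0, rate_hz > 0, noise_sd >= 0,
            nan_fraction >= 0, nan_fraction < 1)
  n_modes <- length(r)
  if (n_modes < 2L) stop("at least two modes are required", call. = FALSE)
  if (any(r <= 3.57 | r >= 4)) {
    stop("growth parameters `r` must lie in the chaotic band (3.57, 4)",
         call. = FALSE)
  }
  mode_names <- paste0("a", seq_len(n_modes))

  cp <- resolve_coupling_graph(couplings, mode_names)
  n <- round(duration_s * rate_hz)
  burn <- stopifnot_scalar_count(burn_in, "burn_in", min = 0L)
  total <- n + burn
  if (nrow(cp) > 0) {
    if (any(cp$delay >= total)) {
      stop("coupling delays must be shorter than the simulated record",
           call. = FALSE)
    }
    c_tot <- tapply(abs(cp$strength), factor(cp$to_idx, seq_len(n_modes)),
                    sum, default = 0)
    bad <- which((r + c_tot)^2 / (4 * r) >= 1)
    if (length(bad) > 0) {
      stop(sprintf(paste0("coupling into %s too strong: (r + c)^2/(4r) = %.3f ",
                          ">= 1, the map would leave (0, 1)"),
                   mode_names[bad[1L]],
                   ((r + c_tot)^2 / (4 * r))[bad[1L]]), call. = FALSE)
    }
  }

  rec <- with_seed(seed, {
    x <- matrix(NA_real_, nrow = total, ncol = n_modes)
    x[1, ] <- stats::runif(n_modes, 0.2, 0.8)
    for (t in seq_len(total - 1L)) {
      growth <- r - r * x[t, ]
      if (nrow(cp) > 0) {
        src_t <- t - cp$delay
        use <- src_t >= 1L
        if (any(use)) {
          v <- cp$strength[use] * x[cbind(src_t[use], cp$from_idx[use])]
          growth <- growth + as.numeric(
            tapply(v, factor(cp$to_idx[use], levels = seq_len(n_modes)),
                   sum, default = 0))
        }
      }
      x[t + 1L, ] <- x[t, ] * growth
      if (any(x[t + 1L, ] <= 0 | x[t + 1L, ] >= 1)) {
        stop(sprintf("channel trajectory left (0, 1) at step %d", t + 1L),
             call. = FALSE)
      }
    }
    a <- scale(x[(burn + 1L):total, , drop = FALSE])
    a <- a + matrix(stats::rnorm(n * n_modes, sd = noise_sd), n, n_modes)
    attr(a, "scaled:center") <- NULL
    attr(a, "scaled:scale") <- NULL
    colnames(a) <- mode_names

    if (nan_fraction > 0) {
      target <- round(nan_fraction * n)
      gap <- logical(n)
      while (sum(gap) < target) {
        len <- 1L + stats::rgeom(1L, 1 / gap_mean_len)
        start <- sample.int(n, 1L)
        gap[start:min(n, start + len - 1L)] <- TRUE
      }
      a[gap, ] <- NA_real_
    }
    a
  })

  out <- eigenmode_record(rec, rate_hz = rate_hz, id = id,
                          strain = strain, behavior = behavior)
  attr(out, "truth") <- cp[, c("from", "to", "delay", "strength")]
  out
}

resolve_coupling_graph <- function(couplings, mode_names) {
  if (is.null(couplings) || (is.data.frame(couplings) && nrow(couplings) == 0L)) {
    return(data.frame(from = character(0), to = character(0),
                      delay = integer(0), strength = numeric(0),
                      from_idx = integer(0), to_idx = integer(0)))
  }
  stopifnot(is.data.frame(couplings),
            all(c("from", "to", "delay", "strength") %in% names(couplings)))
  as_idx <- function(v) {
    if (is.numeric(v)) return(as.integer(v))
    match(as.character(v), mode_names)
  }
  cp <- couplings
  cp$from_idx <- as_idx(cp$from)
  cp$to_idx <- as_idx(cp$to)
  if (anyNA(cp$from_idx) || anyNA(cp$to_idx) ||
      any(cp$from_idx < 1) || any(cp$from_idx > length(mode_names)) ||
      any(cp$to_idx < 1) || any(cp$to_idx > length(mode_names))) {
    stop("coupling endpoints must name existing modes", call. = FALSE)
  }
  if (any(cp$delay < 1 | cp$delay != round(cp$delay))) {
    stop("coupling delays must be integers >= 1 (samples)", call. = FALSE)
  }
  cp$from <- mode_names[cp$from_idx]
  cp$to <- mode_names[cp$to_idx]
  cp
}
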