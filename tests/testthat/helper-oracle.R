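# Independent brute-force cross-mapping oracle: explicit loops, pairwise
# distances computed directly, no shared code with the package internals.
# Only supports library_size = "all" (no resampling), which is all the
# equivalence checks need.
naive_cross_map <- function(effect, predictor, E, tp, exclusion_radius = 0) {
  n <- length(predictor)
  times <- integer(0)
  pts <- list()
  for (t in E:n) {
    v <- predictor[seq(t, t - E + 1L)]
    tgt <- t + tp
    if (!anyNA(v) && tgt >= 1L && !is.na(effect[tgt])) {
      pts[[length(pts) + 1L]] <- v
      times <- c(times, t)
    }
  }
  m <- length(times)
  k <- E + 1L
  pred <- numeric(m)
  for (i in seq_len(m)) {
    d <- rep(Inf, m)
    for (j in seq_len(m)) {
      if (j == i) next
      if (exclusion_radius > 0 && abs(times[j] - times[i]) < exclusion_radius) next
      d[j] <- sqrt(sum((pts[[i]] - pts[[j]])^2))
    }
    nb <- order(d)[seq_len(k)]
    dd <- d[nb]
    w <- if (dd[1L] == 0) as.numeric(dd == 0) else exp(-dd / dd[1L])
    w <- w / sum(w)
    pred[i] <- sum(w * effect[times[nb] + tp])
  }
  obs <- effect[times + tp]
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) return(NA_real_)
  stats::cor(obs, pred)
}

# Shared fixtures: feasible multi-pair coupling graphs for the 4-channel
# synthetic generator (receivers need growth-parameter headroom).
r_headroom <- c(3.9, 3.6, 3.7, 3.75)
graph_three <- function(delays) {
  data.frame(from = c("a1", "a4", "a2"), to = c("a2", "a3", "a4"),
             delay = delays, strength = 0.1)
}

offdiag <- function(m) m[upper.tri(m)]
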