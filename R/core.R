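#' Time-delay embedding of a timeseries
#'
#' Builds the delay-coordinate (shadow manifold) representation of a
#' timeseries: for each time index `t`, the point
#' `[x_t, x_{t-1}, ..., x_{t-(E-1)}]`. Points are only formed where all `E`
#' lagged samples are observed; any point touching a missing (`NA`) sample
#' is dropped.
#'
#' @param x Numeric vector. Missing samples are encoded as `NA`.
#' @param E Embedding dimension (number of lags), an integer >= 2. The lag
#'   step is fixed at one sample.
#'
#' @return A numeric matrix with `E` columns; column `k` holds `x[t - k + 1]`.
#'   The attribute `"time"` gives, for each row, the 1-based time index `t`
#'   of its leading coordinate; `"series_length"` records `length(x)`.
#'
#' @examples
#' m <- delay_embed(c(1, 2, 3, 4, 5), E = 3)
#' attr(m, "time")   # 3 4 5
#' m[3, ]            # 5 4 3
#' @export
delay_embed <- function(x, E) {
  x <- as.numeric(x)
  E <- stopifnot_scalar_count(E, "E", min = 2L)
  n <- length(x)
  if (n < E) {
    stop(sprintf("series of length %d is too short to embed in E = %d dimensions",
                 n, E), call. = FALSE)
  }
  t_idx <- E:n
  m <- vapply(0:(E - 1L), function(k) x[t_idx - k], numeric(length(t_idx)))
  if (length(t_idx) == 1L) m <- matrix(m, nrow = 1L)
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  structure(m, time = t_idx[keep], series_length = n)
}

#' Convergent cross mapping skill via simplex projection
#'
#' Measures how well the delay embedding of `predictor` cross-maps onto
#' `effect`: if `effect` causally influences `predictor`, the predictor's
#' reconstructed attractor carries enough information to predict the effect
#' series, and the skill rises with library size (the CCM convergence
#' signature).
#'
#' For each of `n_repeats` repeats, `library_size` valid embedded time
#' indices of `predictor` are drawn without replacement (a "library"; valid
#' means all `E` lags and the `tp`-shifted target are observed). Each library
#' point is then predicted from its `E + 1` nearest library neighbors in
#' embedding space, excluding the point itself and any neighbor closer than
#' `exclusion_radius` samples in time (Theiler window). Neighbor weights are
#' `exp(-d_i / d_1)` with `d_1` the nearest distance, normalized to sum to
#' one; exact-zero-distance ties share the weight equally. The prediction
#' for a point at time `t` is the weighted average of `effect[t_nbr + tp]`
#' over its neighbors and is scored against the observed `effect[t + tp]`
#' by Pearson correlation. The skill is the mean correlation over repeats.
#'
#' @param effect Numeric vector: the putatively causal series being
#'   predicted (the target of the cross map).
#' @param predictor Numeric vector, same length as `effect`: the series
#'   whose delay embedding is used for prediction.
#' @param E Embedding dimension, integer >= 2 (default 10).
#' @param tp Target time offset in samples, an integer <= 0: the value
#'   predicted for an embedding point at time `t` is `effect[t + tp]`.
#' @param library_size Number of embedded indices sampled per repeat
#'   (at least `E + 2`), or `"all"` to use every valid index.
#' @param n_repeats Number of library resamples to average over.
#' @param exclusion_radius Minimum temporal separation (samples) between a
#'   prediction point and its neighbors; 0 disables the Theiler window
#'   (only the point itself is excluded).
#' @param seed Optional integer seed pinning the library sampling; `NULL`
#'   uses (and advances) the current RNG stream.
#'
#' @return A single numeric skill in `[-1, 1]` (possibly `NA` if the
#'   observed segment had zero variance in every repeat), with attribute
#'   `"skills"` holding the per-repeat correlations.
#'
#' @references Sugihara et al. (2012) Detecting causality in complex
#'   ecosystems. Science 338:496-500.
#' @seealso [lag_profile()] to scan `tp` over a delay grid.
#' @export
cross_map <- function(effect, predictor, E = 10, tp = 0, library_size = "all",
                      n_repeats = 1, exclusion_radius = 0, seed = NULL) {
  effect <- as.numeric(effect)
  predictor <- as.numeric(predictor)
  if (length(effect) != length(predictor)) {
    stop("`effect` and `predictor` must be aligned series of equal length",
         call. = FALSE)
  }
  E <- stopifnot_scalar_count(E, "E", min = 2L)
  if (!is.numeric(tp) || length(tp) != 1L || tp != round(tp) || tp > 0) {
    stop("`tp` must be a single integer <= 0 (the effect's past is predicted)",
         call. = FALSE)
  }
  tp <- as.integer(tp)
  n_repeats <- stopifnot_scalar_count(n_repeats, "n_repeats", min = 1L)
  if (!is.numeric(exclusion_radius) || exclusion_radius < 0) {
    stop("`exclusion_radius` must be >= 0", call. = FALSE)
  }

  if (stats::sd(predictor, na.rm = TRUE) == 0) {
    warning("cross-map skill undefined: predictor series has zero variance",
            call. = FALSE)
    return(structure(NA_real_, skills = rep(NA_real_, n_repeats)))
  }
  emb <- delay_embed(predictor, E)
  times <- attr(emb, "time")
  tgt <- times + tp
  ok <- tgt >= 1L
  ok[ok] <- !is.na(effect[tgt[ok]])
  valid_rows <- which(ok)
  n_valid <- length(valid_rows)

  use_all <- identical(library_size, "all")
  if (!use_all) {
    library_size <- stopifnot_scalar_count(library_size, "library_size",
                                           min = E + 2L)
  }
  lib_n <- if (use_all) n_valid else library_size
  need <- max(lib_n, E + 2L)
  if (n_valid < need) {
    stop(sprintf(paste0("insufficient valid embedded points for cross mapping: ",
                        "need %d, have %d (E = %d, tp = %d)"),
                 need, n_valid, E, tp), call. = FALSE)
  }

  skills <- with_seed(seed, {
    out <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      rows <- if (use_all) valid_rows else sample(valid_rows, lib_n)
      out[r] <- simplex_skill(emb[rows, , drop = FALSE], times[rows],
                              effect, tp, E, exclusion_radius)
    }
    out
  })

  if (all(is.na(skills))) {
    warning("cross-map skill undefined: observed or predicted segment had zero variance",
            call. = FALSE)
  }
  structure(mean(skills, na.rm = TRUE), skills = skills)
}

# One library's simplex-projection skill. `lib` is the embedded library
# (rows aligned with `lib_times`); prediction points are the library points
# themselves, leave-one-out.
simplex_skill <- function(lib, lib_times, effect, tp, E, exclusion_radius) {
  n <- nrow(lib)
  d <- as.matrix(stats::dist(lib))
  if (exclusion_radius > 0) {
    sep <- abs(outer(lib_times, lib_times, "-"))
    d[sep < exclusion_radius] <- Inf
  }
  diag(d) <- Inf
  k <- E + 1L
  obs <- effect[lib_times + tp]
  pred <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    ord <- order(di)[seq_len(k)]
    dd <- di[ord]
    if (!is.finite(dd[k])) {
      stop(sprintf(paste0("insufficient neighbors after exclusion: prediction ",
                          "point at t = %d has only %d candidates, needs %d"),
                   lib_times[i], sum(is.finite(di)), k), call. = FALSE)
    }
    w <- if (dd[1L] == 0) as.numeric(dd == 0) else exp(-dd / dd[1L])
    w <- w / sum(w)
    pred[i] <- sum(w * effect[lib_times[ord] + tp])
  }
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    return(NA_real_)
  }
  stats::cor(obs, pred)
}
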