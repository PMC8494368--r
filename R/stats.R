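# Profile comparison statistics: Spearman profile similarity, the
# phase-randomized surrogate null, windowed profiling, and the directional
# permutation test for group distinctness.

#' Similarity between two interaction profile sets
#'
#' The mean Spearman rank correlation between corresponding pair profiles
#' of two sets (12 values for the canonical 4-mode set, averaged). Spearman
#' on the delay-wise skills is invariant to each profile's monotone min-max
#' normalization, so raw and normalized skills give identical similarities.
#'
#' @param a,b `"profile_set"` objects on matching delay grids and pair
#'   layouts (resample first if the grids differ, see
#'   [resample_profile()]).
#'
#' @return A single correlation in `[-1, 1]`.
#' @export
profile_similarity <- function(a, b) {
  stopifnot(inherits(a, "profile_set"), inherits(b, "profile_set"))
  check_matching_sets(list(a, b))
  key <- paste(a$pair_effect, a$pair_predictor, sep = "->")
  vals <- vapply(split(seq_len(nrow(a)), factor(key, unique(key))),
                 function(rows) {
    suppressWarnings(stats::cor(a$skill_raw[rows], b$skill_raw[rows],
                                method = "spearman",
                                use = "pairwise.complete.obs"))
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Pairwise similarity matrix for a collection of profile sets
#'
#' @param sets A named list of `"profile_set"` objects (names default to
#'   each set's owner).
#' @return A symmetric numeric matrix of mean-Spearman profile similarities
#'   with unit diagonal, dimnames set to the unit labels.
#' @seealso [profile_similarity()], [distinctness_test()]
#' @export
similarity_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  ids <- names(sets) %||% vapply(sets, function(s) attr(s, "owner") %||% "?",
                                 character(1))
  if (anyDuplicated(ids)) {
    stop("profile set labels must be unique", call. = FALSE)
  }
  n <- length(sets)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- profile_similarity(sets[[i]], sets[[j]])
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Fourier phase-randomized surrogate timeseries
#'
#' Randomizes the phases of the series' Fourier transform while preserving
#' every amplitude (and Hermitian symmetry, so the output is real). The
#' surrogate keeps the power spectrum — hence the autocorrelation, mean and
#' variance — of the original but destroys nonlinear cross-dependence,
#' making it the null for cross-mapping skill.
#'
#' @param x Numeric vector with no missing values (segment or mask gappy
#'   series first).
#' @param seed Optional integer seed.
#' @return A numeric vector of the same length.
#' @export
phase_surrogate <- function(x, seed = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) {
    stop("phase surrogates require a gap-free series; extract a contiguous non-missing segment first",
         call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) return(x)
  f <- stats::fft(x)
  half <- (n - 1L) %/% 2L
  g <- f
  with_seed(seed, {
    if (half >= 1L) {
      phi <- stats::runif(half, 0, 2 * pi)
      k <- 2:(half + 1L)
      g[k] <- complex(modulus = Mod(f[k]), argument = phi)
      g[n + 2L - k] <- Conj(g[k])
    }
    if (n %% 2L == 0L) {
      g[n / 2L + 1L] <- Mod(f[n / 2L + 1L]) * sample(c(-1, 1), 1L)
    }
  })
  Re(stats::fft(g, inverse = TRUE)) / n
}

#' Interaction profiles in non-overlapping time windows
#'
#' Splits a recording into non-overlapping windows tiled from the start
#' (default 20 s) and computes a profile set per window, giving a
#' time-resolved view of the interaction structure.
#'
#' @param record An [eigenmode_record()].
#' @param window_s Window length in seconds.
#' @param n_windows Number of windows; default (and maximum) is
#'   `floor(duration / window_s)`. Asking for more is an error that reports
#'   the feasible maximum.
#' @inheritParams profile_set
#'
#' @return A list of `"profile_set"` objects, one per window, named
#'   `<id>_w<k>`. Windows whose frames are entirely missing are skipped
#'   with a warning.
#' @export
windowed_profiles <- function(record, window_s = 20, n_windows = NULL,
                              delays = NULL, tp = NULL, modes = NULL,
                              E = 10, library_size = "all", n_repeats = 1,
                              exclusion_radius = 0, seed = NULL) {
  stopifnot(inherits(record, "eigenmode_record"), window_s > 0)
  wlen <- round(window_s * record$rate_hz)
  n <- nrow(record$modes)
  feasible <- n %/% wlen
  if (feasible < 1L) {
    stop(sprintf("record '%s' (%d frames) is shorter than one %g s window",
                 record$id, n, window_s), call. = FALSE)
  }
  if (is.null(n_windows)) n_windows <- feasible
  if (n_windows > feasible) {
    stop(sprintf("record '%s' supports at most %d non-overlapping %g s windows (%d requested)",
                 record$id, feasible, window_s, n_windows), call. = FALSE)
  }

  with_seed(seed, {
    out <- list()
    for (w in seq_len(n_windows)) {
      rows <- ((w - 1L) * wlen + 1L):(w * wlen)
      wid <- sprintf("%s_w%d", record$id, w)
      sub <- record$modes[rows, , drop = FALSE]
      if (all(is.na(sub))) {
        warning(sprintf("window %d of '%s' is entirely missing; skipped",
                        w, record$id), call. = FALSE)
        next
      }
      wrec <- eigenmode_record(sub, rate_hz = record$rate_hz, id = wid,
                               strain = record$strain,
                               behavior = record$behavior)
      out[[wid]] <- profile_set(wrec, delays = delays, tp = tp, modes = modes,
                                E = E, library_size = library_size,
                                n_repeats = n_repeats,
                                exclusion_radius = exclusion_radius)
    }
    out
  })
}

#' Directional permutation test for group distinctness
#'
#' Asks whether the units (strains) of group A have their most similar
#' unit — by interaction-profile similarity, self excluded, searched over
#' A and B together — preferentially inside A. The observed percentage is
#' compared with `n_perm` random reassignments of the group labels (sizes
#' preserved); the attained fraction is the share of permuted percentages
#' strictly below the observed one. The test is directional: A versus B
#' and B versus A generally differ.
#'
#' Nearest neighbors depend only on similarity ranks, so any monotone
#' rescaling of the similarities leaves the result unchanged. Ties are
#' broken by a seeded random candidate order.
#'
#' @param sim Symmetric similarity matrix with unit labels as dimnames
#'   (see [similarity_matrix()]).
#' @param group_a,group_b Disjoint character vectors of unit labels, each
#'   of size >= 2, all present in `sim`.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional integer seed.
#'
#' @return A list of class `"distinctness_result"`: `observed_pct`,
#'   `null_pcts` (length `n_perm`), `attained`, `group_a`, `group_b`,
#'   `n_perm` and `seed`.
#' @export
distinctness_test <- function(sim, group_a, group_b, n_perm = 1000,
                              seed = NULL) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  ids <- rownames(sim)
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least two members", call. = FALSE)
  }
  absent <- setdiff(c(group_a, group_b), ids)
  if (length(absent) > 0) {
    stop(sprintf("units absent from the similarity matrix: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }

  pool <- c(group_a, group_b)
  s <- sim[pool, pool, drop = FALSE]
  n <- length(pool)
  n_a <- length(group_a)

  with_seed(seed, {
    # nearest neighbor of each pooled unit (self excluded); label-free, so
    # it is fixed across permutations. Ties resolved by a seeded shuffle.
    shuffle <- sample.int(n)
    nn <- vapply(seq_len(n), function(i) {
      v <- s[i, shuffle]
      v[shuffle == i] <- -Inf
      shuffle[which.max(v)]
    }, integer(1))

    pct_for <- function(a_idx) {
      in_a <- logical(n)
      in_a[a_idx] <- TRUE
      100 * mean(in_a[nn[a_idx]])
    }
    observed <- pct_for(seq_len(n_a))
    null_pcts <- vapply(seq_len(n_perm), function(p) {
      pct_for(sample.int(n, n_a))
    }, numeric(1))

    structure(list(observed_pct = observed,
                   null_pcts = null_pcts,
                   attained = mean(null_pcts < observed),
                   group_a = group_a, group_b = group_b,
                   n_perm = n_perm, seed = seed),
              class = "distinctness_result")
  })
}

#' @export
print.distinctness_result <- function(x, ...) {
  cat(sprintf(paste0("Group distinctness (directional): %.1f%% of group A's ",
                     "nearest profiles lie in A\n  attained fraction: %.3f ",
                     "(%d permutations)\n"),
              x$observed_pct, x$attained, x$n_perm))
  invisible(x)
}

#' Serialize a distinctness result to JSON
#'
#' @param x A `"distinctness_result"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_distinctness <- function(x, path) {
  stopifnot(inherits(x, "distinctness_result"))
  jsonlite::write_json(
    list(observed_pct = x$observed_pct, attained = x$attained,
         n_perm = x$n_perm, seed = x$seed,
         group_a = x$group_a, group_b = x$group_b),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
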