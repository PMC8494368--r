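# Interaction profiles: CCM skill scanned over a grid of target delays for
# one ordered pair of channels, plus set-level constructors and averaging.

# Min-max normalization to [0, 1]; a constant (or all-NA) profile maps to
# all zeros rather than 0/0.
minmax_norm <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1L]) || rng[2L] == rng[1L]) {
    return(rep(0, length(x)))
  }
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

# The displayed-delay axis convention. A generative coupling in which the
# source value at time t - L enters the receiver at time t + 1 is displayed
# as delay L, for any embedding dimension. The driver is recoverable from
# consecutive receiver samples throughout the E-lag reconstruction window,
# so cross-map skill peaks when the target sits at lag L relative to the
# window's *central* coordinate, not its newest one. Anchoring the axis at
# the newest coordinate would shift the reported delay by about E/2 and
# make it E-dependent; anchoring at the center keeps profiles computed at
# different E aligned. An embedding point at time t predicts the effect at
# t + tp, so displayed delay d = -tp - offset(E) with offset(E) =
# 1 + ceiling((E - 2) / 2) (the 1 is the receiver's update step; at E = 2
# this reduces to the familiar d = -tp - 1).
delay_offset <- function(E) 1L + as.integer(ceiling((E - 2L) / 2))
delay_to_tp <- function(delay, E) as.integer(-delay - delay_offset(E))
tp_to_delay <- function(tp, E) as.integer(-tp) - delay_offset(E)

#' Lag-scanned interaction profile for one ordered pair
#'
#' Computes [cross_map()] skill over a grid of target delays, producing the
#' delay-versus-skill "interaction profile" that fingerprints how (and at
#' what timescale) the effect channel drives the predictor channel.
#'
#' The grid can be given either as `tp` (target offsets in samples, all
#' `<= 0`, as scanned in the raw analyses) or as `delays` (non-negative
#' displayed delays, the axis used when reading off generative coupling
#' lags). The displayed axis is anchored at the center of the embedding
#' window, `delay = -tp - offset(E)` with
#' `offset(E) = 1 + ceiling((E - 2) / 2)`: information about the driver is
#' spread across the reconstruction window, so skill peaks when the target
#' sits at the generative lag relative to the window center. Under this
#' convention a coupling in which the effect's value at time `t - L` enters
#' the predictor's update at `t + 1` peaks at displayed delay `L`
#' regardless of `E`, and profiles computed at different `E` stay aligned.
#'
#' @param effect,predictor Numeric vectors, the two aligned channels;
#'   `effect` is the putative driver being predicted from `predictor`'s
#'   embedding.
#' @param delays Integer vector of displayed delays (>= 0). Give exactly one
#'   of `delays` and `tp`; the default scans displayed delays 0-15.
#' @param tp Integer vector of target offsets in samples (all <= 0).
#' @param rate_hz Sampling rate in Hz; used only to report delays in
#'   seconds (`NA` seconds if omitted).
#' @param pair Optional character vector of length 2 naming the
#'   (effect, predictor) channels, stored as metadata.
#' @inheritParams cross_map
#'
#' @return A data frame of class `"interaction_profile"`, ordered by
#'   increasing `tp_samples`, with columns `delay`, `tp_samples`,
#'   `tp_seconds`, `skill_raw` and `skill_norm` (min-max normalized so the
#'   profile spans `[0, 1]`; a constant profile normalizes to all zeros).
#'   Attributes `pair`, `rate_hz` and `config` record the provenance.
#'   Delays where the cross map could not be computed are `NA` (with a
#'   warning); an all-`NA` profile is an error.
#' @seealso [profile_set()], [profile_peaks()], [resample_profile()]
#' @export
lag_profile <- function(effect, predictor, delays = NULL, tp = NULL,
                        rate_hz = NULL, E = 10, library_size = "all",
                        n_repeats = 1, exclusion_radius = 0, seed = NULL,
                        pair = c("effect", "predictor")) {
  if (is.null(tp) && is.null(delays)) delays <- 0:15
  if (!is.null(tp) && !is.null(delays)) {
    stop("give either `delays` or `tp`, not both", call. = FALSE)
  }
  if (is.null(tp)) {
    if (any(delays != round(delays))) {
      stop("`delays` must be integers", call. = FALSE)
    }
    tp <- delay_to_tp(delays, E)
    if (any(tp > 0)) {
      stop(sprintf("displayed delays below %d are not reachable at E = %d",
                   -delay_offset(E), E), call. = FALSE)
    }
  } else {
    if (any(tp > 0) || any(tp != round(tp))) {
      stop("`tp` must be integers <= 0", call. = FALSE)
    }
    tp <- as.integer(tp)
  }
  if (anyDuplicated(tp)) stop("delay grid contains duplicates", call. = FALSE)
  tp <- sort(tp)

  skill <- with_seed(seed, {
    vapply(tp, function(tpi) {
      tryCatch(as.numeric(cross_map(effect, predictor, E = E, tp = tpi,
                                    library_size = library_size,
                                    n_repeats = n_repeats,
                                    exclusion_radius = exclusion_radius)),
               error = function(e) {
                 warning(sprintf("tp = %d skipped: %s", tpi, conditionMessage(e)),
                         call. = FALSE)
                 NA_real_
               })
    }, numeric(1))
  })
  if (all(is.na(skill))) {
    stop("interaction profile undefined: no delay produced a valid cross map",
         call. = FALSE)
  }

  out <- data.frame(
    delay = tp_to_delay(tp, E),
    tp_samples = tp,
    tp_seconds = if (is.null(rate_hz)) NA_real_ else tp / rate_hz,
    skill_raw = skill,
    skill_norm = minmax_norm(skill)
  )
  structure(out,
            pair = stats::setNames(as.character(pair)[1:2], c("effect", "predictor")),
            rate_hz = rate_hz,
            config = list(E = E, library_size = library_size,
                          n_repeats = n_repeats,
                          exclusion_radius = exclusion_radius),
            class = c("interaction_profile", "data.frame"))
}

#' All-pairs interaction profiles for one individual
#'
#' Builds the full set of ordered-pair interaction profiles among a
#' record's eigenmode channels (4 modes give the canonical 4 x 3 = 12
#' profiles, no self-pairs), all on one delay grid with one configuration.
#' This set is the unit of comparison between individuals and strains.
#'
#' @param record An [eigenmode_record()].
#' @param modes Character vector of channel names to use; defaults to the
#'   record's first four modes.
#' @inheritParams lag_profile
#'
#' @return A data frame of class `"profile_set"`: the row-bound profiles
#'   with leading columns `pair_effect` and `pair_predictor`. Attributes
#'   `owner` (the record id), `rate_hz` and `config` are attached.
#' @export
profile_set <- function(record, delays = NULL, tp = NULL, modes = NULL,
                        E = 10, library_size = "all", n_repeats = 1,
                        exclusion_radius = 0, seed = NULL) {
  stopifnot(inherits(record, "eigenmode_record"))
  all_modes <- colnames(record$modes)
  if (is.null(modes)) {
    if (length(all_modes) < 4L) {
      stop(sprintf("record '%s' has %d modes; at least 4 are required",
                   record$id, length(all_modes)), call. = FALSE)
    }
    modes <- all_modes[1:4]
  } else if (!all(modes %in% all_modes)) {
    stop(sprintf("record '%s' lacks mode(s): %s", record$id,
                 paste(setdiff(modes, all_modes), collapse = ", ")),
         call. = FALSE)
  }

  parts <- with_seed(seed, {
    out <- list()
    for (eff in modes) {
      for (prd in modes) {
        if (eff == prd) next
        p <- tryCatch(
          lag_profile(record$modes[, eff], record$modes[, prd],
                      delays = delays, tp = tp, rate_hz = record$rate_hz,
                      E = E, library_size = library_size,
                      n_repeats = n_repeats,
                      exclusion_radius = exclusion_radius,
                      pair = c(eff, prd)),
          error = function(e) {
            stop(sprintf("pair (%s, %s): %s", eff, prd, conditionMessage(e)),
                 call. = FALSE)
          })
        out[[paste(eff, prd, sep = "->")]] <-
          cbind(pair_effect = eff, pair_predictor = prd,
                as.data.frame(p), stringsAsFactors = FALSE)
      }
    }
    out
  })

  res <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  structure(res,
            owner = record$id,
            rate_hz = record$rate_hz,
            config = list(E = E, library_size = library_size,
                          n_repeats = n_repeats,
                          exclusion_radius = exclusion_radius),
            class = c("profile_set", "data.frame"))
}

# Shared grid/pair layout check for set-level operations.
check_matching_sets <- function(sets) {
  key <- function(s) s[, c("pair_effect", "pair_predictor", "tp_samples")]
  ref <- key(sets[[1L]])
  for (s in sets[-1L]) {
    if (!isTRUE(all.equal(key(s), ref, check.attributes = FALSE))) {
      stop(paste("profile sets do not share one delay grid and pair layout;",
                 "resample to a common grid first (see resample_profile)"),
           call. = FALSE)
    }
  }
  invisible(ref)
}

#' Average interaction profiles across individuals
#'
#' The group (e.g. strain) average profile: each individual's profiles are
#' min-max normalized first, the normalized skills are averaged per pair and
#' per delay, and the averages are re-normalized to span `[0, 1]`.
#' Normalizing before averaging keeps individuals with different absolute
#' predictability on an equal footing, so the average reflects profile
#' shape, not cross-map magnitude.
#'
#' @param sets A list of `"profile_set"` objects sharing one delay grid and
#'   pair layout, or a list of single `"interaction_profile"` objects for
#'   the same pair on one grid.
#' @param owner Label for the averaged set (e.g. the strain name).
#'
#' @return An object of the same class as the list elements whose
#'   `skill_raw` column holds the mean of the members' normalized skills
#'   and whose `skill_norm` re-normalizes it.
#' @export
average_profiles <- function(sets, owner = "average") {
  if (inherits(sets, c("profile_set", "interaction_profile"))) {
    sets <- list(sets)
  }
  if (length(sets) == 0L) stop("no profile sets to average", call. = FALSE)
  if (all(vapply(sets, inherits, logical(1), "interaction_profile"))) {
    return(average_single_profiles(sets, owner))
  }
  stopifnot(all(vapply(sets, inherits, logical(1), "profile_set")))
  check_matching_sets(sets)

  norm_mat <- vapply(sets, function(s) s$skill_norm, numeric(nrow(sets[[1L]])))
  if (is.null(dim(norm_mat))) norm_mat <- matrix(norm_mat, nrow = 1L)
  res <- as.data.frame(sets[[1L]])
  res$skill_raw <- rowMeans(norm_mat, na.rm = TRUE)
  key <- paste(res$pair_effect, res$pair_predictor, sep = "->")
  res$skill_norm <- stats::ave(res$skill_raw, key, FUN = minmax_norm)
  structure(res,
            owner = owner,
            rate_hz = attr(sets[[1L]], "rate_hz"),
            config = attr(sets[[1L]], "config"),
            n_averaged = length(sets),
            class = c("profile_set", "data.frame"))
}

# Average a list of single-pair interaction profiles on one grid.
average_single_profiles <- function(profiles, owner) {
  ref <- profiles[[1L]]$tp_samples
  for (p in profiles[-1L]) {
    if (!identical(p$tp_samples, ref)) {
      stop("profiles do not share one delay grid", call. = FALSE)
    }
  }
  norm_mat <- vapply(profiles, function(p) p$skill_norm,
                     numeric(length(ref)))
  if (is.null(dim(norm_mat))) norm_mat <- matrix(norm_mat, nrow = 1L)
  res <- as.data.frame(profiles[[1L]])
  res$skill_raw <- rowMeans(norm_mat, na.rm = TRUE)
  res$skill_norm <- minmax_norm(res$skill_raw)
  structure(res,
            pair = attr(profiles[[1L]], "pair"),
            rate_hz = attr(profiles[[1L]], "rate_hz"),
            config = attr(profiles[[1L]], "config"),
            owner = owner, n_averaged = length(profiles),
            class = c("interaction_profile", "data.frame"))
}

#' Scan for the optimal embedding dimension
#'
#' With the target delay held at the profile's best value, scans the
#' embedding dimension and reports the `E` that maximizes cross-map skill:
#' a proxy for the dimensionality needed to resolve the driving dynamics.
#'
#' @param effect,predictor Numeric vectors, the aligned channel pair.
#' @param tp_star Target offset in samples (<= 0), typically the `tp` of
#'   the peak of the average interaction profile.
#' @param E_range Integer vector of embedding dimensions to test
#'   (default `2:40`). Dimensions too large for the available data truncate
#'   the scan with a warning.
#' @inheritParams cross_map
#'
#' @return A list of class `"embedding_scan"` with `best_E` (ties broken
#'   toward the smaller dimension) and `skill_by_E`, a data frame of the
#'   scanned dimensions and skills.
#' @export
optimal_embedding_scan <- function(effect, predictor, tp_star, E_range = 2:40,
                                   library_size = "all", n_repeats = 1,
                                   exclusion_radius = 0, seed = NULL) {
  E_range <- sort(unique(as.integer(E_range)))
  skills <- rep(NA_real_, length(E_range))
  with_seed(seed, {
    for (i in seq_along(E_range)) {
      s <- tryCatch(as.numeric(cross_map(effect, predictor, E = E_range[i],
                                         tp = tp_star,
                                         library_size = library_size,
                                         n_repeats = n_repeats,
                                         exclusion_radius = exclusion_radius)),
                    error = function(e) NA_real_)
      if (is.na(s)) {
        warning(sprintf("scan truncated at E = %d: too few valid points",
                        E_range[i]), call. = FALSE)
        break
      }
      skills[i] <- s
    }
  })
  keep <- !is.na(skills)
  if (!any(keep)) {
    stop("embedding scan failed at every dimension", call. = FALSE)
  }
  skill_by_E <- data.frame(E = E_range[keep], skill = skills[keep])
  structure(list(best_E = skill_by_E$E[which.max(skill_by_E$skill)],
                 skill_by_E = skill_by_E),
            class = "embedding_scan")
}

#' Local maxima of an interaction profile
#'
#' Finds interior local maxima of the normalized profile (ordered by
#' displayed delay) and their topographic prominence: the drop from the
#' peak to the highest of the two saddles separating it from higher
#' terrain (or the grid edge). Peaks below `min_prominence` are treated as
#' sampling noise and dropped.
#'
#' @param profile An `"interaction_profile"` (or a single pair's rows from
#'   a profile set, with `delay` and `skill_norm` columns).
#' @param min_prominence Minimum prominence on the normalized `[0, 1]`
#'   scale (default 0.1).
#'
#' @return A data frame with one row per retained peak: `delay`,
#'   `tp_samples`, `skill_norm` and `prominence`, ordered by delay.
#' @export
profile_peaks <- function(profile, min_prominence = 0.1) {
  df <- as.data.frame(profile)
  df <- df[order(df$delay), , drop = FALSE]
  x <- df$skill_norm
  n <- length(x)
  peaks <- integer(0)
  prom <- numeric(0)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (is.na(x[i]) || is.na(x[i - 1L]) || is.na(x[i + 1L])) next
      if (x[i] > x[i - 1L] && x[i] > x[i + 1L]) {
        base <- function(idx) {
          lo <- x[i]
          for (j in idx) {
            if (is.na(x[j])) break
            if (x[j] > x[i]) return(lo)
            lo <- min(lo, x[j])
          }
          lo
        }
        left <- base(rev(seq_len(i - 1L)))
        right <- base((i + 1L):n)
        p <- x[i] - max(left, right)
        if (p >= min_prominence) {
          peaks <- c(peaks, i)
          prom <- c(prom, p)
        }
      }
    }
  }
  data.frame(delay = df$delay[peaks],
             tp_samples = df$tp_samples[peaks],
             skill_norm = x[peaks],
             prominence = prom)
}

#' @export
print.interaction_profile <- function(x, ...) {
  pair <- attr(x, "pair")
  cat(sprintf("Interaction profile: %s -> %s (%d delays, E = %s)\n",
              pair[["effect"]], pair[["predictor"]], nrow(x),
              attr(x, "config")$E))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
print.profile_set <- function(x, ...) {
  pairs <- unique(paste(x$pair_effect, x$pair_predictor, sep = "->"))
  cat(sprintf("Profile set '%s': %d pairs x %d delays\n",
              attr(x, "owner") %||% "?", length(pairs),
              nrow(x) / max(length(pairs), 1L)))
  invisible(x)
}

#' @export
print.embedding_scan <- function(x, ...) {
  cat(sprintf("Embedding scan: best E = %d (skill %.3f) over E in [%d, %d]\n",
              x$best_E, max(x$skill_by_E$skill), min(x$skill_by_E$E),
              max(x$skill_by_E$E)))
  invisible(x)
}
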