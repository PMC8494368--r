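# Readers, writers, quality filtering and delay-grid resampling for
# eigenmode recordings and profile tables. The canonical on-disk format is
# a tidy CSV (one row per frame, one column per mode).

#' Construct an eigenmode recording
#'
#' Bundles a set of aligned eigenmode timeseries (the leading postural
#' mode amplitudes, conventionally `a1`..`a4`) with its sampling rate and
#' metadata. Missing frames are `NA`.
#'
#' @param modes Numeric matrix or data frame, one column per mode, one row
#'   per frame. Columns must be named (unnamed input is labelled
#'   `a1`, `a2`, ...).
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param id Individual identifier.
#' @param strain,behavior Optional group labels.
#'
#' @return A list of class `"eigenmode_record"` with elements `id`,
#'   `strain`, `behavior`, `rate_hz` and `modes` (numeric matrix).
#' @export
eigenmode_record <- function(modes, rate_hz, id = "record",
                             strain = NA_character_,
                             behavior = NA_character_) {
  modes <- as.matrix(modes)
  storage.mode(modes) <- "double"
  rownames(modes) <- NULL
  if (is.null(colnames(modes))) {
    colnames(modes) <- paste0("a", seq_len(ncol(modes)))
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(modes) & !is.na(modes))) {
    stop("non-missing mode values must be finite", call. = FALSE)
  }
  structure(list(id = as.character(id), strain = strain, behavior = behavior,
                 rate_hz = rate_hz, modes = modes),
            class = "eigenmode_record")
}

#' @export
print.eigenmode_record <- function(x, ...) {
  cat(sprintf("Eigenmode record '%s': %d frames x %d modes at %g Hz (%.1f%% NA)\n",
              x$id, nrow(x$modes), ncol(x$modes), x$rate_hz,
              100 * na_fraction(x)))
  if (!is.na(x$strain)) cat(" strain:", x$strain, "\n")
  if (!is.na(x$behavior)) cat(" behavior:", x$behavior, "\n")
  invisible(x)
}

#' @rdname filter_records
#' @export
na_fraction <- function(record) {
  mean(is.na(record$modes))
}

#' Write eigenmode recordings to tidy CSV
#'
#' One row per frame with columns `id`, `strain`, `behavior`, `time`
#' (seconds) and the mode columns; missing values are blank cells. Numeric
#' values are written with full (17 significant digit) precision so a
#' write/read cycle reproduces the record exactly.
#'
#' @param records An `"eigenmode_record"` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eigenmodes <- function(records, path) {
  if (inherits(records, "eigenmode_record")) records <- list(records)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  tabs <- lapply(records, function(r) {
    n <- nrow(r$modes)
    cbind(data.frame(id = rep(r$id, n),
                     strain = rep(as.character(r$strain), n),
                     behavior = rep(as.character(r$behavior), n),
                     time = fmt((seq_len(n) - 1L) / r$rate_hz),
                     stringsAsFactors = FALSE),
          as.data.frame(apply(r$modes, 2L, fmt), stringsAsFactors = FALSE))
  })
  tab <- do.call(rbind, tabs)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read eigenmode recordings from tidy CSV/TSV
#'
#' Expects one row per frame, a `time` (seconds) or `frame` column, mode
#' columns `a1`, `a2`, ... and optional `id`, `strain` and `behavior`
#' columns; multi-individual files are split by `id`. Blank cells, `NA`
#' and `NaN` all parse as missing.
#'
#' @param path CSV or TSV file path (delimiter inferred from the extension).
#' @param rate_hz Sampling rate in Hz; required when only a `frame` column
#'   is present, otherwise inferred from the `time` column (which must be
#'   monotone and evenly spaced).
#' @param required_modes Mode columns that must be present (default
#'   `a1`..`a4`); a missing one is an error naming it.
#'
#' @return A list of [eigenmode_record()] objects.
#' @export
read_eigenmodes <- function(path, rate_hz = NULL,
                            required_modes = paste0("a", 1:4)) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("", "NA", "NaN"),
                           stringsAsFactors = FALSE)
  missing_modes <- setdiff(required_modes, names(tab))
  if (length(missing_modes) > 0) {
    stop(sprintf("input '%s' lacks required mode column(s): %s", path,
                 paste(missing_modes, collapse = ", ")), call. = FALSE)
  }
  mode_cols <- grep("^a[0-9]+$", names(tab), value = TRUE)
  has_time <- "time" %in% names(tab)
  if (!has_time && !"frame" %in% names(tab)) {
    stop(sprintf("input '%s' needs a 'time' or 'frame' column", path),
         call. = FALSE)
  }
  ids <- if ("id" %in% names(tab)) as.character(tab$id) else
    rep(tools::file_path_sans_ext(basename(path)), nrow(tab))

  lapply(split(seq_len(nrow(tab)), factor(ids, levels = unique(ids))),
         function(rows) {
    sub <- tab[rows, , drop = FALSE]
    rate <- rate_hz
    if (has_time) {
      dt <- diff(sub$time)
      if (any(dt <= 0)) {
        stop(sprintf("non-monotone time column in '%s'", path), call. = FALSE)
      }
      if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
        stop(sprintf("unevenly sampled time column in '%s' (inconsistent rate)",
                     path), call. = FALSE)
      }
      rate <- 1 / stats::median(dt)
    } else if (is.null(rate)) {
      stop("`rate_hz` must be supplied when the file has no time column",
           call. = FALSE)
    }
    first <- function(col, default) {
      if (col %in% names(sub)) as.character(sub[[col]][1L]) else default
    }
    eigenmode_record(as.matrix(sub[, mode_cols, drop = FALSE]),
                     rate_hz = rate, id = sub$id[1L] %||% ids[rows[1L]],
                     strain = first("strain", NA_character_),
                     behavior = first("behavior", NA_character_))
  })
}

#' Quality-filter eigenmode recordings
#'
#' Keeps records with strictly less than `max_na_fraction` missing values
#' and strictly more than `min_length` frames; everything else is dropped
#' with a per-record reason. The defaults (25% NA, 200 frames) are the
#' standard screening thresholds for tracked-posture recordings.
#'
#' @param records A list of `"eigenmode_record"` objects (or a single one).
#' @param max_na_fraction Records with an NA cell fraction `>=` this are
#'   dropped.
#' @param min_length Records with `<=` this many frames are dropped.
#' @param record For `na_fraction()`, a single record.
#'
#' @return A list with `kept` (records) and `dropped`, a data frame of
#'   `id` and `reason` for each rejected record.
#' @export
filter_records <- function(records, max_na_fraction = 0.25, min_length = 200) {
  if (inherits(records, "eigenmode_record")) records <- list(records)
  kept <- list()
  drop_id <- character(0)
  drop_reason <- character(0)
  for (r in records) {
    n <- nrow(r$modes)
    fr <- na_fraction(r)
    if (n <= min_length) {
      drop_id <- c(drop_id, r$id)
      drop_reason <- c(drop_reason,
                       sprintf("length %d not over %d frames", n, min_length))
    } else if (fr >= max_na_fraction) {
      drop_id <- c(drop_id, r$id)
      drop_reason <- c(drop_reason,
                       sprintf("NA fraction %.3f not below %.2f", fr,
                               max_na_fraction))
    } else {
      kept <- c(kept, list(r))
    }
  }
  list(kept = kept,
       dropped = data.frame(id = drop_id, reason = drop_reason,
                            stringsAsFactors = FALSE))
}

#' Resample an interaction profile onto a common delay grid
#'
#' Linearly interpolates a profile's skills onto a regular grid of `tp`
#' values every `grid_step_s` seconds, so profiles computed at different
#' sampling rates (e.g. 16 Hz versus 20 Hz recordings) become comparable.
#' Grid points that coincide with natively resolved delays reproduce the
#' resolved skills exactly; the grid never extends beyond the profile's
#' support (no extrapolation).
#'
#' @param profile An `"interaction_profile"` or `"profile_set"` with known
#'   `tp_seconds` (i.e. built with a sampling rate).
#' @param grid_step_s Grid spacing in seconds (default 0.1).
#'
#' @return An object of the same class on the resampled grid; `tp_samples`
#'   and `delay` become fractional, and `skill_norm` re-normalizes the
#'   interpolated raw skills.
#' @export
resample_profile <- function(profile, grid_step_s = 0.1) {
  stopifnot(grid_step_s > 0)
  if (inherits(profile, "profile_set")) {
    key <- paste(profile$pair_effect, profile$pair_predictor, sep = "->")
    parts <- lapply(split(as.data.frame(profile), factor(key, unique(key))),
                    resample_one, grid_step_s = grid_step_s)
    res <- do.call(rbind, c(unname(parts), list(make.row.names = FALSE)))
    attrs <- attributes(profile)
    return(structure(res, owner = attrs$owner, rate_hz = attrs$rate_hz,
                     config = attrs$config,
                     class = c("profile_set", "data.frame")))
  }
  out <- resample_one(as.data.frame(profile), grid_step_s)
  structure(out, pair = attr(profile, "pair"), rate_hz = attr(profile, "rate_hz"),
            config = attr(profile, "config"),
            class = c("interaction_profile", "data.frame"))
}

resample_one <- function(df, grid_step_s) {
  if (anyNA(df$tp_seconds)) {
    stop("profile has no tp_seconds; rebuild it with a sampling rate",
         call. = FALSE)
  }
  df <- df[order(df$tp_seconds), , drop = FALSE]
  ok <- !is.na(df$skill_raw)
  lo <- min(df$tp_seconds[ok])
  hi <- max(df$tp_seconds[ok])
  k_lo <- ceiling(round(-hi / grid_step_s, 9))
  k_hi <- floor(round(-lo / grid_step_s, 9))
  ks <- if (k_lo <= k_hi) k_lo:k_hi else integer(0)
  if (length(ks) < 2L) {
    stop(sprintf("profile support [%g, %g] s is too narrow for a %g s grid",
                 lo, hi, grid_step_s), call. = FALSE)
  }
  grid <- -rev(ks) * grid_step_s
  # snap grid points that (numerically) coincide with resolved delays, so
  # coincident points reproduce resolved skills (and coordinates) exactly
  hit <- vapply(grid, function(g) {
    j <- which(abs(df$tp_seconds - g) < 1e-9)
    if (length(j) == 1L && ok[j]) j else NA_integer_
  }, integer(1))
  grid[!is.na(hit)] <- df$tp_seconds[hit[!is.na(hit)]]
  grid <- pmin(pmax(grid, lo), hi) # guard last-ulp overshoot of the support
  raw <- stats::approx(df$tp_seconds[ok], df$skill_raw[ok], xout = grid,
                       method = "linear", ties = "ordered")$y
  raw[!is.na(hit)] <- df$skill_raw[hit[!is.na(hit)]]

  rate <- if (nrow(df) >= 2L) {
    (df$tp_samples[2L] - df$tp_samples[1L]) /
      (df$tp_seconds[2L] - df$tp_seconds[1L])
  } else NA_real_
  offset <- -df$tp_samples[1L] - df$delay[1L] # displayed-axis anchor
  out <- data.frame(
    delay = -grid * rate - offset,
    tp_samples = grid * rate,
    tp_seconds = grid,
    skill_raw = raw,
    skill_norm = minmax_norm(raw)
  )
  if ("pair_effect" %in% names(df)) {
    out <- cbind(pair_effect = df$pair_effect[1L],
                 pair_predictor = df$pair_predictor[1L], out,
                 stringsAsFactors = FALSE)
  }
  out
}

#' Serialize and read profile sets
#'
#' Profile sets round-trip through tidy CSV with columns `owner`,
#' `pair_effect`, `pair_predictor`, `delay`, `tp_samples`, `tp_seconds`,
#' `skill_raw`, `skill_norm`.
#'
#' @param set A `"profile_set"`.
#' @param path CSV path.
#' @return `write_profile_set()` returns `path` invisibly;
#'   `read_profile_set()` returns a `"profile_set"`.
#' @export
write_profile_set <- function(set, path) {
  stopifnot(inherits(set, "profile_set"))
  tab <- cbind(owner = attr(set, "owner") %||% "set", as.data.frame(set))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_set
#' @export
read_profile_set <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("owner", "pair_effect", "pair_predictor", "tp_samples",
            "skill_raw", "skill_norm")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(sprintf("'%s' is not a profile-set table (missing: %s)", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  owner <- tab$owner[1L]
  tab$owner <- NULL
  structure(tab, owner = owner, class = c("profile_set", "data.frame"))
}
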