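#' 1 Hz trial recording
#'
#' The unit of replay and evaluation: an ordered 1 Hz record of the measured
#' temperature and the concurrently active device setting. Time must be
#' strictly increasing; nominal 1 s spacing with gaps is allowed, and each
#' present sample accounts for one second in all duration-based metrics.
#'
#' @param time_s Integer-valued seconds since trial start, strictly
#'   increasing.
#' @param temp_c Measured temperature in degC.
#' @param heat Heat level per sample (any dialect [device_setting] accepts).
#' @param speed Speed per sample.
#' @param core_temp_c Optional true core temperature (synthetic trials).
#' @param label Trial label.
#' @param target_temp Target temperature in degC (`NA` when none applies).
#' @param seed Seed recorded for provenance (`NA` for recorded data).
#' @return A data frame of class `trial_series` with columns `time_s`,
#'   `temp_c`, `heat`, `speed` (and `core_temp_c` when supplied), plus
#'   `label`, `target_temp` and `seed` attributes.
#' @export
trial_series <- function(time_s, temp_c, heat, speed, core_temp_c = NULL,
                         label = "trial", target_temp = NA_real_,
                         seed = NA_integer_) {
  n <- length(time_s)
  stopifnot(length(temp_c) == n, length(heat) == n, length(speed) == n,
            is.null(core_temp_c) || length(core_temp_c) == n)
  if (n == 0L) ttm_error("trial series must contain at least one row", "ttm_empty_series")
  if (any(diff(time_s) <= 0)) {
    ttm_error("trial time must be strictly increasing", "ttm_invalid_series")
  }
  heat <- vapply(as.character(heat), normalize_heat, "", USE.NAMES = FALSE)
  speed <- vapply(as.character(speed), normalize_speed, "", USE.NAMES = FALSE)
  df <- data.frame(time_s = as.numeric(time_s), temp_c = as.numeric(temp_c),
                   heat = heat, speed = speed, stringsAsFactors = FALSE)
  if (!is.null(core_temp_c)) df$core_temp_c <- as.numeric(core_temp_c)
  structure(df,
            class = c("trial_series", "data.frame"),
            label = label, target_temp = target_temp, seed = seed)
}

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf("<trial_series> '%s': %d samples over %g s", attr(x, "label"),
              nrow(x), x$time_s[nrow(x)] - x$time_s[1] + 1))
  if (!is.na(attr(x, "target_temp"))) {
    cat(sprintf(" | target %.1f °C", attr(x, "target_temp")))
  }
  cat("\n")
  utils::str(utils::head(as.data.frame(x), 3), give.attr = FALSE)
  invisible(x)
}

# speed-normalization dialects accepted on read
normalize_speed_dialect <- function(x) {
  vapply(tolower(as.character(x)), function(s) {
    s <- switch(s, lo = "slow", low = "slow", hi = "fast", high = "fast", s)
    normalize_speed(s)
  }, "", USE.NAMES = FALSE)
}

#' Read a trial recording from CSV
#'
#' Expects a header row; the canonical schema is
#' `time_s,temp_c,heat,speed` with heat in `{21, 32, 38, 43}` (or the
#' `ambient21/c32/...` names) and speed in `{standby, slow, fast}`.
#' `column_map` adapts foreign column names. Comment lines starting with `#`
#' are treated as metadata (`# key: value`) and recovered into attributes.
#'
#' @param path CSV file path.
#' @param column_map Named list mapping canonical names (`time`, `temp`,
#'   `heat`, `speed`, optionally `core_temp`) to the file's column names.
#' @return A [trial_series].
#' @export
read_trial_csv <- function(path,
                           column_map = list(time = "time_s", temp = "temp_c",
                                             heat = "heat", speed = "speed",
                                             core_temp = "core_temp_c")) {
  if (!file.exists(path)) ttm_error(sprintf("no such file: %s", path), "ttm_load_error")
  meta <- read_csv_metadata(path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) ttm_error(sprintf("cannot parse CSV %s: %s",
                                          path, conditionMessage(e)),
                                  "ttm_load_error"))
  need <- c("time", "temp", "heat", "speed")
  for (k in need) {
    col <- column_map[[k]]
    if (is.null(col) || !col %in% names(df)) {
      ttm_error(sprintf("missing column '%s' (mapped from '%s') in %s",
                        col %||% k, k, path), "ttm_load_error")
    }
  }
  tm <- suppressWarnings(as.numeric(df[[column_map$time]]))
  tp <- suppressWarnings(as.numeric(df[[column_map$temp]]))
  if (anyNA(tm)) ttm_error("unparseable time values", "ttm_load_error")
  if (anyNA(tp)) ttm_error("unparseable temperature values", "ttm_load_error")
  ord <- order(tm)
  tm <- tm[ord]; tp <- tp[ord]
  if (any(diff(tm) <= 0)) {
    ttm_error("non-monotone time: duplicate or decreasing timestamps",
              "ttm_load_error")
  }
  heat <- df[[column_map$heat]][ord]
  speed <- normalize_speed_dialect(df[[column_map$speed]][ord])
  core <- NULL
  if (!is.null(column_map$core_temp) && column_map$core_temp %in% names(df)) {
    core <- suppressWarnings(as.numeric(df[[column_map$core_temp]]))[ord]
  }
  trial_series(
    time_s = tm, temp_c = tp, heat = heat, speed = speed, core_temp_c = core,
    label = meta[["label"]] %||% sub("\\.csv$", "", basename(path)),
    target_temp = as.numeric(meta[["target_temp_c"]] %||% NA_real_),
    seed = as.integer(meta[["seed"]] %||% NA_integer_)
  )
}

read_csv_metadata <- function(path) {
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  head_lines <- head_lines[startsWith(head_lines, "#")]
  kv <- regmatches(head_lines,
                   regexec("^#\\s*([A-Za-z_.]+)\\s*:\\s*(.*)$", head_lines))
  kv <- kv[lengths(kv) == 3L]
  stats::setNames(as.list(trimws(vapply(kv, `[[`, "", 3L))),
                  vapply(kv, `[[`, "", 2L))
}

#' Write a trial recording to CSV
#'
#' Emits the canonical schema with a `#`-prefixed metadata header (label,
#' target, seed, generator version) so that a read/write/read roundtrip
#' preserves the series exactly.
#'
#' @param series A [trial_series].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(series, path) {
  stopifnot(inherits(series, "trial_series"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# label: %s", attr(series, "label")),
    sprintf("# target_temp_c: %s", format(attr(series, "target_temp"), digits = 15)),
    sprintf("# seed: %s", format(attr(series, "seed"))),
    sprintf("# generator: ttmloop %s",
            as.character(utils::packageVersion("ttmloop")))
  ), con)
  df <- as.data.frame(series)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
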