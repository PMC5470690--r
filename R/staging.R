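# Staging analysis of daily series: continuous two-changepoint
# piecewise-linear least squares (exhaustive over candidate day pairs),
# recanalization reversal detection, and heterogeneity metrics.
#
# The changepoint fit is a model-selection device, not a hypothesis test:
# nothing is "significant" here, segments are simply fitted and the best
# pair of break days reported. A changepoint is the last day of the
# preceding segment.

#' Build a daily series from measurement records
#'
#' Replicates are first collapsed with [triplicate_mean()] per animal-day;
#' the per-day value is then the mean across animals and, when at least
#' two animals contribute, the per-day sample SD across animals is
#' attached. Missing days are simply absent — no imputation.
#'
#' @param records a data.frame of elasticity records
#'   (see [read_elasticity_csv()]), or a data.frame with columns
#'   `animal_id, day, part, Rr, Rp, Rb` for composition series.
#' @param part `"head"`, `"body"` or `"tail"`.
#' @param quantity `"ym_kpa"` (elasticity records) or one of
#'   `"Rr"`, `"Rp"`, `"Rb"` (composition records).
#' @param strict_replicates passed to [triplicate_mean()].
#' @return a [daily_series()].
#' @export
build_series <- function(records, part, quantity = "ym_kpa",
                         strict_replicates = FALSE) {
  part <- match.arg(tolower(as.character(part)), PARTS)
  quantity <- match.arg(as.character(quantity), QUANTITIES)
  rows <- records[records$part == part, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop_validation(sprintf("no records for part '%s'", part))

  if (quantity == "ym_kpa") {
    key <- paste(rows$animal_id, rows$day, rows$part, rows$replicate, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      k <- strsplit(key[which(dup)[1]], "\r", fixed = TRUE)[[1]]
      stop_validation(sprintf(
        "duplicate measurement for animal '%s', day %s, part %s, replicate %s",
        k[1], k[2], k[3], k[4]))
    }
    per_animal <- stats::aggregate(
      rows$emean_kpa,
      by = list(animal_id = rows$animal_id, day = rows$day),
      FUN = function(v) triplicate_mean(v, strict = strict_replicates))
  } else {
    if (!quantity %in% names(rows))
      stop_validation(sprintf("records carry no '%s' column", quantity))
    key <- paste(rows$animal_id, rows$day, rows$part, sep = "\r")
    if (any(duplicated(key)))
      stop_validation("duplicate composition row for an animal-day-part")
    per_animal <- data.frame(animal_id = rows$animal_id, day = rows$day,
                             x = rows[[quantity]])
  }

  days <- sort(unique(per_animal$day))
  values <- numeric(length(days))
  sds <- rep(NA_real_, length(days))
  for (i in seq_along(days)) {
    v <- per_animal$x[per_animal$day == days[i]]
    values[i] <- mean(v)
    if (length(v) >= 2L) sds[i] <- stats::sd(v)
  }
  daily_series(part, quantity, days, values,
               sds = if (all(is.na(sds))) NULL else sds)
}

#' Whole-thrombus series from the three part series
#'
#' Day-wise mean of the head, body and tail series (days present in all
#' three). For elasticity this applies [aggregate_whole_elasticity()]
#' (2-decimal rounding); fractions are averaged without rounding.
#'
#' @param head,body,tail [daily_series()] of the same quantity.
#' @return a [daily_series()] with `part = "whole"`.
#' @export
whole_series <- function(head, body, tail) {
  ss <- list(head = head, body = body, tail = tail)
  q <- unique(vapply(ss, function(s) s$quantity, character(1)))
  if (length(q) != 1L) stop_validation("part series measure different quantities")
  days <- Reduce(intersect, lapply(ss, function(s) s$days))
  if (length(days) == 0L) stop_validation("no common days across the three parts")
  days <- sort(days)
  values <- vapply(days, function(d) {
    v <- vapply(ss, function(s) s$values[match(d, s$days)], numeric(1))
    if (q == "ym_kpa") aggregate_whole_elasticity(v[1], v[2], v[3]) else mean(v)
  }, numeric(1))
  daily_series("whole", q, days, values)
}

# admissible changepoint pairs for consecutive-day series: each of the
# three segments must contain >= min_seg points; changepoint = last day of
# its segment
admissible_pairs <- function(days, min_seg = 2L) {
  n <- length(days)
  pairs <- list()
  for (i1 in seq_len(n)) {
    if (i1 < min_seg) next
    for (i2 in seq_len(n)) {
      if (i2 - i1 < min_seg) next
      if (n - i2 < min_seg) next
      pairs[[length(pairs) + 1L]] <- c(days[i1], days[i2])
    }
  }
  pairs
}

fit_piecewise <- function(days, values, d1, d2) {
  X <- cbind(1, days, pmax(0, days - d1), pmax(0, days - d2))
  fit <- stats::lm.fit(X, values)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  sse <- sum(fit$residuals^2)
  slopes <- c(b[2], b[2] + b[3], b[2] + b[3] + b[4])
  list(sse = sse, slopes = unname(slopes))
}

#' Detect the two slope-transition days of a daily series
#'
#' Exhaustive search over all ordered pairs of interior changepoint days
#' (each segment keeping at least `min_seg` points); for each candidate a
#' continuous three-segment piecewise-linear model is fitted by least
#' squares, and the pair minimizing the residual sum of squares is
#' returned. Ties (within relative tolerance 1e-9) are broken by the
#' lexicographically earliest pair, so a perfectly linear series yields
#' the smallest admissible pair.
#'
#' @param series a [daily_series()] with at least 6 consecutive days.
#' @param min_seg minimum number of points per segment (default 2).
#' @return an object of class `transition_report` with fields
#'   `changepoint_days` (ordered integer pair), `segment_slopes` (units of
#'   the quantity per day) and `sse`.
#' @export
detect_transitions <- function(series, min_seg = 2L) {
  if (!inherits(series, "daily_series")) stop_validation("not a daily_series")
  days <- series$days
  if (length(days) < 6L)
    stop_validation(sprintf("series too short for changepoint fitting (%d days, need >= 6)",
                            length(days)))
  if (any(diff(days) != 1L))
    stop_validation("series has day gaps; changepoint fitting needs consecutive days")
  pairs <- admissible_pairs(days, min_seg = as.integer(min_seg))
  if (length(pairs) == 0L)
    stop_validation("no admissible changepoint pair for this series length")
  best <- NULL
  for (p in pairs) {
    f <- fit_piecewise(days, series$values, p[1], p[2])
    if (is.null(best) || f$sse < best$sse * (1 - 1e-9) - 1e-12) {
      best <- list(days = p, sse = f$sse, slopes = f$slopes)
    }
  }
  structure(
    list(changepoint_days = as.integer(best$days),
         segment_slopes = best$slopes,
         sse = best$sse,
         part = series$part, quantity = series$quantity),
    class = "transition_report"
  )
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("transitions (%s %s): days %d and %d; slopes %s /day; SSE %.4g\n",
              x$part, x$quantity, x$changepoint_days[1], x$changepoint_days[2],
              paste(sprintf("%.3f", x$segment_slopes), collapse = ", "), x$sse))
  invisible(x)
}

#' Detect a recanalization reversal in a daily series
#'
#' Recanalization refills an organized thrombus with fresh red cells and
#' platelets, reversing the decline of Rr late in the study. The reversal
#' day is the first day `d >= window_start` with two consecutive
#' increases: `v(d) > v(d-1)` and `v(d+1) > v(d)` (two rises are required
#' to resist single-day noise).
#'
#' @param series a [daily_series()], typically of quantity `"Rr"`
#'   (Young's modulus allowed for exploratory use).
#' @param window_start first candidate day; default 8, just after the
#'   late-stage transition.
#' @return an object of class `reversal_report`; `reversal_day` is `NA`
#'   when no reversal is found.
#' @export
detect_reversal <- function(series, window_start = 8L) {
  if (!inherits(series, "daily_series")) stop_validation("not a daily_series")
  window_start <- as.integer(window_start)
  days <- series$days
  if (window_start - 1L < min(days) || window_start + 1L > max(days))
    stop_validation(sprintf(
      "reversal window starting at day %d does not fit in series days %d..%d",
      window_start, min(days), max(days)))
  found <- NA_integer_
  for (d in window_start:(max(days) - 1L)) {
    i0 <- match(d - 1L, days); i1 <- match(d, days); i2 <- match(d + 1L, days)
    if (anyNA(c(i0, i1, i2))) next
    v <- series$values
    if (v[i1] > v[i0] && v[i2] > v[i1]) { found <- d; break }
  }
  structure(list(reversal_day = found, part = series$part,
                 quantity = series$quantity, window_start = window_start),
            class = "reversal_report")
}

#' @export
print.reversal_report <- function(x, ...) {
  cat(sprintf("reversal (%s %s): %s\n", x$part, x$quantity,
              if (is.na(x$reversal_day)) "none detected"
              else paste("day", x$reversal_day)))
  invisible(x)
}

#' Within-thrombus heterogeneity
#'
#' Sample standard deviation (n-1 denominator) across the three parts of
#' one thrombus for one quantity on one day. Zero iff the three parts are
#' identical; invariant under permutation of the parts.
#'
#' @param head,body,tail finite values of one quantity for one animal-day.
#' @return non-negative scalar.
#' @export
within_thrombus_heterogeneity <- function(head, body, tail) {
  v <- c(head, body, tail)
  if (length(v) != 3L || any(!is.finite(v)))
    stop_validation("need three finite per-part values")
  stats::sd(v)
}

#' Between-thrombus heterogeneity
#'
#' Sample standard deviation (n-1) across animals for one day, part and
#' quantity.
#'
#' @param values at least two finite values, one per animal.
#' @return non-negative scalar.
#' @export
between_thrombus_heterogeneity <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop_validation(sprintf("need >= 2 animals for between-thrombus SD, got %d",
                            length(values)))
  if (any(!is.finite(values))) stop_validation("values must be finite")
  stats::sd(values)
}
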