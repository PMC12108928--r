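# Load-spectrum handling: stress histories, turning-point extraction,
# peak simplification, and four-point rainflow cycle counting.

#' Construct a stress history
#'
#' A stress history is the sampled stress signal at one leaflet integration
#' point over one or more cardiac cycles. Stresses are signed: compressive
#' stress is negative, tensile positive, so that amplitude/mean formulas
#' apply unchanged to both surfaces of the leaflet.
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing.
#' @param stress Numeric vector of stresses in MPa, same length as `time`.
#' @param label Free-text identifier (patient / surface / integration point).
#' @param period Seconds per cardiac cycle, or `NULL` if unknown. At a heart
#'   rate of `bpm` beats per minute the period is `60 / bpm`.
#' @param n_cycles Number of cardiac cycles spanned by the signal, or `NULL`
#'   to infer it from `period` when needed.
#'
#' @return An object of class `stress_history` with elements `time`, `stress`,
#'   `label`, `period`, `n_cycles`.
#' @export
#' @examples
#' h <- stress_history(seq(0, 1, length.out = 5), c(0, 1, 0.5, 2, 0))
#' extract_turning_points(h)
stress_history <- function(time, stress, label = "history", period = NULL,
                           n_cycles = NULL) {
  time <- as.numeric(time)
  stress <- as.numeric(stress)
  if (length(time) != length(stress)) {
    stop("`time` and `stress` must have the same length", call. = FALSE)
  }
  if (length(time) < 3L) {
    stop("a stress history needs at least 3 samples", call. = FALSE)
  }
  if (anyNA(time) || anyNA(stress)) {
    stop("`time` and `stress` must not contain NA", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(period) && period <= 0) {
    stop("`period` must be positive", call. = FALSE)
  }
  structure(
    list(time = time, stress = stress, label = as.character(label)[1L],
         period = period, n_cycles = n_cycles),
    class = "stress_history"
  )
}

#' @export
print.stress_history <- function(x, ...) {
  span <- diff(range(x$time))
  cat(sprintf("<stress_history> %s\n", x$label))
  cat(sprintf("  %d samples over %.3f s; stress range [%.4g, %.4g] MPa\n",
              length(x$time), span, min(x$stress), max(x$stress)))
  if (!is.null(x$period)) {
    cat(sprintf("  cardiac period %.3f s (%.0f bpm)\n",
                x$period, 60 / x$period))
  }
  invisible(x)
}

#' Number of cardiac cycles spanned by a history
#'
#' Uses the stored `n_cycles` when present, otherwise rounds the sampled
#' span (plus one sampling step, since the grid stops one step short of the
#' period boundary) to a whole number of periods. Falls back to 1 when no
#' period is known.
#'
#' @param history A [stress_history()].
#' @return Integer number of cardiac cycles, at least 1.
#' @export
history_n_cycles <- function(history) {
  stopifnot(inherits(history, "stress_history"))
  if (!is.null(history$n_cycles)) {
    return(max(1L, as.integer(round(history$n_cycles))))
  }
  if (is.null(history$period)) {
    return(1L)
  }
  dt <- stats::median(diff(history$time))
  span <- diff(range(history$time)) + dt
  max(1L, as.integer(round(span / history$period)))
}

#' Read / write a stress history as CSV
#'
#' Files carry the two columns `time_s` and `stress_MPa` with a header row,
#' UTF-8 encoded, `.` decimal separator.
#'
#' @param path Path to the CSV file.
#' @param label,period,n_cycles Passed on to [stress_history()]; the CSV
#'   format does not store them.
#' @return `read_history_csv()` returns a [stress_history()];
#'   `write_history_csv()` returns `path` invisibly.
#' @export
read_history_csv <- function(path, label = basename(path), period = NULL,
                             n_cycles = NULL) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  required <- c("time_s", "stress_MPa")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("history CSV '%s' is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  stress_history(df$time_s, df$stress_MPa, label = label, period = period,
                 n_cycles = n_cycles)
}

#' @rdname read_history_csv
#' @param history A [stress_history()] to write.
#' @export
write_history_csv <- function(history, path) {
  stopifnot(inherits(history, "stress_history"))
  utils::write.csv(
    data.frame(time_s = history$time, stress_MPa = history$stress),
    path, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Extract turning points (local extrema) of a stress history
#'
#' Collapses monotone runs and plateaus so that successive retained points
#' strictly alternate between maxima and minima; the first and last samples
#' are always retained as endpoints. A constant signal has no turning points
#' and yields zero counted cycles downstream (not an error).
#'
#' @param history A [stress_history()].
#' @return A data frame with columns `time` (s) and `stress` (MPa).
#' @export
extract_turning_points <- function(history) {
  stopifnot(inherits(history, "stress_history"))
  t <- history$time
  s <- history$stress
  # collapse plateaus: keep the first sample of each run of equal values
  keep <- c(TRUE, diff(s) != 0)
  t <- t[keep]
  s <- s[keep]
  n <- length(s)
  if (n < 2L) {
    # constant signal
    return(data.frame(time = history$time[1L], stress = history$stress[1L])[0, ])
  }
  d <- diff(s)
  interior <- if (n > 2L) d[-length(d)] * d[-1L] < 0 else logical(0)
  keep2 <- c(TRUE, interior, TRUE)
  data.frame(time = t[keep2], stress = s[keep2])
}

#' Average similar peaks in a sequence of turning points
#'
#' Groups same-kind extrema (all maxima, or all minima) whose values differ
#' pairwise by at most `rel_tolerance` times the global absolute maximum of
#' the signal, and replaces each group member by the group mean. Ordering and
#' alternation are preserved; `rel_tolerance = 0` is the identity. This is
#' the load-spectrum simplification step that treats near-identical systolic
#' peaks across cardiac cycles as one repeated peak.
#'
#' @param extrema Data frame from [extract_turning_points()] (columns `time`,
#'   `stress`), or a bare numeric vector of alternating extreme values.
#' @param rel_tolerance Non-negative relative tolerance (default 0.05).
#' @return Object of the same shape as `extrema` with grouped values averaged.
#' @export
simplify_peaks <- function(extrema, rel_tolerance = 0.05) {
  if (rel_tolerance < 0) {
    stop("`rel_tolerance` must be non-negative", call. = FALSE)
  }
  vec_in <- is.numeric(extrema)
  s <- if (vec_in) as.numeric(extrema) else extrema$stress
  n <- length(s)
  if (n == 0L || rel_tolerance == 0) {
    return(extrema)
  }
  band <- rel_tolerance * max(abs(s))
  # classify each extremum as a maximum or minimum relative to neighbours;
  # endpoints take the kind opposite to their single neighbour
  kind <- integer(n)
  if (n >= 2L) {
    for (i in seq_len(n)) {
      nb <- if (i == 1L) s[2L] else s[i - 1L]
      kind[i] <- if (s[i] >= nb) 1L else -1L
    }
  }
  for (k in c(1L, -1L)) {
    idx <- which(kind == k)
    if (length(idx) < 2L) next
    vals <- s[idx]
    ord <- order(vals)
    grp <- integer(length(idx))
    g <- 1L
    grp[ord[1L]] <- g
    base <- vals[ord[1L]]
    for (j in seq_along(ord)[-1L]) {
      # pairwise criterion: group span must stay within the band
      if (vals[ord[j]] - base <= band) {
        grp[ord[j]] <- g
      } else {
        g <- g + 1L
        grp[ord[j]] <- g
        base <- vals[ord[j]]
      }
    }
    means <- tapply(vals, grp, mean)
    s[idx] <- as.numeric(means[as.character(grp)])
  }
  if (vec_in) s else {extrema$stress <- s; extrema}
}

#' Four-point rainflow cycle counting
#'
#' Decomposes an alternating sequence of stress extrema into closed cycles
#' (count 1.0 per occurrence) plus residual unclosed half-cycles (count 0.5
#' each), using the four-point rule: whenever an inner excursion is enclosed
#' by its neighbours on both sides it is extracted as one full cycle.
#' Identical (s_max, s_min) pairs are merged by summing counts, using an
#' absolute stress tolerance so floating-point-identical cycles merge.
#' Conservation holds by construction: twice the summed counts equals the
#' number of half-cycle excursions in the input (`length(extrema) - 1`).
#'
#' @param extrema Data frame from [extract_turning_points()] or a numeric
#'   vector of alternating extreme stresses (MPa).
#' @param merge_tol Absolute stress tolerance (MPa) for merging equal
#'   sub-cycles; default `1e-6`.
#' @return A `subcycles` data frame with columns `s_max`, `s_min`, `s_a`,
#'   `s_m` (MPa) and `count` (multiples of 0.5), ordered by decreasing
#'   amplitude. Fewer than 2 extrema give a zero-row table.
#' @export
#' @examples
#' rainflow_count(c(-2, 1, -3, 5, -1, 3, -4, 4, -2))
rainflow_count <- function(extrema, merge_tol = 1e-6) {
  s <- if (is.numeric(extrema)) as.numeric(extrema) else extrema$stress
  empty <- data.frame(s_max = numeric(0), s_min = numeric(0),
                      s_a = numeric(0), s_m = numeric(0), count = numeric(0))
  class(empty) <- c("subcycles", "data.frame")
  if (length(s) < 2L) {
    return(empty)
  }
  hi <- numeric(0)  # extracted cycle maxima
  lo <- numeric(0)  # extracted cycle minima
  ct <- numeric(0)
  stack <- numeric(0)
  for (p in s) {
    stack <- c(stack, p)
    while (length(stack) >= 4L) {
      m <- length(stack)
      r1 <- abs(stack[m - 2L] - stack[m - 3L])
      r2 <- abs(stack[m - 1L] - stack[m - 2L])
      r3 <- abs(stack[m] - stack[m - 1L])
      if (r2 <= r1 && r2 <= r3) {
        a <- stack[m - 2L]; b <- stack[m - 1L]
        hi <- c(hi, max(a, b)); lo <- c(lo, min(a, b)); ct <- c(ct, 1)
        stack <- stack[-c(m - 2L, m - 1L)]
      } else break
    }
  }
  # residue: unclosed excursions count as half-cycles
  if (length(stack) >= 2L) {
    for (i in seq_len(length(stack) - 1L)) {
      a <- stack[i]; b <- stack[i + 1L]
      hi <- c(hi, max(a, b)); lo <- c(lo, min(a, b)); ct <- c(ct, 0.5)
    }
  }
  if (length(hi) == 0L) {
    return(empty)
  }
  # merge identical (s_max, s_min) pairs within merge_tol
  key_hi <- round(hi / merge_tol)
  key_lo <- round(lo / merge_tol)
  key <- paste(key_hi, key_lo)
  agg_ct <- tapply(ct, key, sum)
  agg_hi <- tapply(hi, key, function(v) v[1L])
  agg_lo <- tapply(lo, key, function(v) v[1L])
  out <- data.frame(
    s_max = as.numeric(agg_hi),
    s_min = as.numeric(agg_lo),
    count = as.numeric(agg_ct)
  )
  st <- cycle_stats(out$s_max, out$s_min)
  out$s_a <- st$s_a
  out$s_m <- st$s_m
  out <- out[order(-out$s_a, -out$s_m), c("s_max", "s_min", "s_a", "s_m", "count")]
  rownames(out) <- NULL
  class(out) <- c("subcycles", "data.frame")
  out
}

#' Alternating and mean stress of a cycle
#'
#' For a cycle between `s_max` and `s_min`, the alternating stress amplitude
#' is `(s_max - s_min) / 2` and the mean stress is `(s_max + s_min) / 2`.
#'
#' @param s_max,s_min Cycle extreme stresses in MPa; `s_max >= s_min`
#'   element-wise.
#' @return A list with numeric elements `s_a` and `s_m` (MPa).
#' @export
cycle_stats <- function(s_max, s_min) {
  if (any(s_max < s_min)) {
    stop("`s_max` must be >= `s_min` (arguments swapped?)", call. = FALSE)
  }
  list(s_a = (s_max - s_min) / 2, s_m = (s_max + s_min) / 2)
}

#' Scale sub-cycle counts to one cardiac cycle
#'
#' When a history spans k cardiac cycles, counting is done on the full signal
#' and the counts divided by k, honouring the assumption that the load
#' spectrum repeats identically in every cardiac cycle.
#'
#' @param subcycles A `subcycles` data frame from [rainflow_count()].
#' @param k Positive number of cardiac cycles spanned by the counted signal.
#' @return The table with `count` divided by `k`.
#' @export
per_cardiac_cycle <- function(subcycles, k) {
  stopifnot(k >= 1)
  subcycles$count <- subcycles$count / k
  subcycles
}

#' Write a sub-cycle table as CSV
#'
#' Columns `s_max_MPa, s_min_MPa, s_a_MPa, s_m_MPa, count`.
#'
#' @param subcycles A `subcycles` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subcycles_csv <- function(subcycles, path) {
  out <- data.frame(
    s_max_MPa = subcycles$s_max, s_min_MPa = subcycles$s_min,
    s_a_MPa = subcycles$s_a, s_m_MPa = subcycles$s_m,
    count = subcycles$count
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
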