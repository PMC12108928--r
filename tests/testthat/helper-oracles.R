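# Independent oracles, deliberately implemented differently from the package
# code paths they cross-check.

# Brute-force four-point cycle extraction: repeatedly scan the WHOLE sequence
# from the start for any enclosed inner excursion, extract it, and restart.
# (The package uses a single-pass stack; the four-point rule is confluent, so
# the final multiset must agree.) Returns a merged table like rainflow_count.
oracle_rainflow <- function(s, merge_tol = 1e-6) {
  s <- as.numeric(s)
  hi <- numeric(0); lo <- numeric(0); ct <- numeric(0)
  repeat {
    n <- length(s)
    extracted <- FALSE
    if (n >= 4L) {
      for (i in seq_len(n - 3L)) {
        r1 <- abs(s[i + 1L] - s[i])
        r2 <- abs(s[i + 2L] - s[i + 1L])
        r3 <- abs(s[i + 3L] - s[i + 2L])
        if (r2 <= r1 && r2 <= r3) {
          a <- s[i + 1L]; b <- s[i + 2L]
          hi <- c(hi, max(a, b)); lo <- c(lo, min(a, b)); ct <- c(ct, 1)
          s <- s[-c(i + 1L, i + 2L)]
          extracted <- TRUE
          break
        }
      }
    }
    if (!extracted) break
  }
  if (length(s) >= 2L) {
    for (i in seq_len(length(s) - 1L)) {
      a <- s[i]; b <- s[i + 1L]
      hi <- c(hi, max(a, b)); lo <- c(lo, min(a, b)); ct <- c(ct, 0.5)
    }
  }
  if (length(hi) == 0L) {
    return(data.frame(s_max = numeric(0), s_min = numeric(0),
                      count = numeric(0)))
  }
  key <- paste(round(hi / merge_tol), round(lo / merge_tol))
  out <- data.frame(
    s_max = as.numeric(tapply(hi, key, function(v) v[1L])),
    s_min = as.numeric(tapply(lo, key, function(v) v[1L])),
    count = as.numeric(tapply(ct, key, sum))
  )
  out[order(out$s_max, out$s_min), , drop = FALSE]
}

# Canonicalise a sub-cycle table for comparison (drop derived columns, sort).
canonical_cycles <- function(df) {
  out <- data.frame(s_max = df$s_max, s_min = df$s_min, count = df$count)
  out <- out[order(out$s_max, out$s_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random strictly alternating extrema sequence of length n, built by
# alternating signed excursions.
random_alternating <- function(n) {
  v <- numeric(n)
  v[1L] <- round(stats::runif(1, -5, 5), 2)
  sgn <- sample(c(-1, 1), 1L)
  for (i in seq_len(n)[-1L]) {
    v[i] <- v[i - 1L] + sgn * round(stats::runif(1, 0.1, 5), 2)
    sgn <- -sgn
  }
  v
}

# Dense bisection solve of the strain-energy-density balance
# sigma^2/E + (2 sigma/(e+1)) (sigma/K)^(1/e) = (Kt S)^2 / E, S > 0.
oracle_glinka_bisection <- function(s, kt, E, e, K, iter = 200L) {
  rhs <- (kt * s)^2 / E
  lhs <- function(x) x^2 / E + (2 * x / (e + 1)) * (x / K)^(1 / e)
  lo <- 0; hi <- kt * s
  stopifnot(lhs(hi) >= rhs)  # bracket: plastic term is non-negative
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (lhs(mid) > rhs) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Closed-form Paris integration for constant stress range and m != 2:
# a(N) = [a0^(1 - m/2) + (1 - m/2) C (dsigma sqrt(pi))^m N]^(2 / (2 - m))
oracle_paris_closed_form <- function(a0, dsigma, C, m, N) {
  stopifnot(m != 2)
  p <- 1 - m / 2
  (a0^p + p * C * (dsigma * sqrt(pi))^m * N)^(1 / p)
}

demo_material <- function() {
  read_material_config(demo_material_path())$material
}
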