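# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps schedule construction and cohort
# generation reproducible without clobbering the user's RNG stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream label; stays within
# 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  h <- 0
  for (ch in utf8ToInt(paste(parts, collapse = "/"))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

side_to_code <- function(side) {
  out <- rep(NA_integer_, length(side))
  out[side == "left"] <- 0L
  out[side == "right"] <- 1L
  bad <- !is.na(side) & !(side %in% c("left", "right"))
  if (any(bad)) {
    stop("unknown side label(s): ", paste(unique(side[bad]), collapse = ", "))
  }
  out
}

code_to_side <- function(code) c("left", "right")[code + 1L]

# log(exp(x) - exp(y)) for x >= y, stable in log space
logspace_sub <- function(x, y) x + log1p(-exp(y - x))

# Truncated normal density/quantile/random draws on [lo, hi]. The log
# normalizer is computed in log space so densities stay finite even when the
# location is far outside the truncation interval (needed by the sampler's
# group-mean conditionals).
dtnorm <- function(x, mean, sd, lo = -1, hi = 1, log = FALSE) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  logz <- if (a > 0) {
    logspace_sub(stats::pnorm(a, lower.tail = FALSE, log.p = TRUE),
                 stats::pnorm(b, lower.tail = FALSE, log.p = TRUE))
  } else if (b < 0) {
    logspace_sub(stats::pnorm(b, log.p = TRUE), stats::pnorm(a, log.p = TRUE))
  } else {
    base::log(stats::pnorm(b) - stats::pnorm(a))
  }
  out_log <- ifelse(x < lo | x > hi, -Inf,
                    stats::dnorm(x, mean, sd, log = TRUE) - logz)
  if (log) out_log else exp(out_log)
}

qtnorm <- function(p, mean, sd, lo = -1, hi = 1) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

rtnorm <- function(n, mean, sd, lo = -1, hi = 1) {
  qtnorm(stats::runif(n), mean, sd, lo, hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
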