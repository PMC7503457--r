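# Shared statistical primitives.

# Spearman correlation with average ranks for ties; NA if either vector is
# constant (correlation undefined).
spearman_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# All permutations of 1..n as an (n! x n) matrix, built by insertion.
# Only used for the exact Spearman null at n < 10.
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 10)
  p <- matrix(1L, nrow = 1, ncol = 1)
  if (n == 1) return(p)
  for (k in 2:n) {
    nr <- nrow(p)
    out <- matrix(0L, nrow = nr * k, ncol = k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1) * nr + seq_len(nr)
      if (pos > 1) out[rows, seq_len(pos - 1)] <- p[, seq_len(pos - 1), drop = FALSE]
      out[rows, pos] <- k
      if (pos < k) out[rows, (pos + 1):k] <- p[, pos:(k - 1), drop = FALSE]
    }
    p <- out
  }
  p
}

# Spearman correlation and two-sided p-value. The p-value uses the
# t-distribution approximation t = r * sqrt((n - 2) / (1 - r^2)); for n < 10
# with untied data, the exact full-enumeration permutation null is used
# instead.
spearman_test <- function(x, y) {
  n <- length(x)
  r <- spearman_r(x, y)
  if (is.na(r) || n < 3) return(list(r = r, p = NA_real_, n = n))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n < 10 && !ties) {
    rx <- rank(x); ry <- rank(y)
    perms <- all_permutations(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    stats_all <- as.numeric(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) / denom
    p <- mean(abs(stats_all) >= abs(r) - 1e-12)
  } else if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

# Stable 32-bit string hash (polynomial, mod 2^31 - 1) used to derive
# per-triplet RNG streams from a master seed, independent of evaluation order.
hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

derive_seed <- function(master_seed, tag) {
  as.integer((as.numeric(master_seed) + hash_string(tag)) %% 2147483647)
}
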