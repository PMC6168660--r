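# Independent oracles, deliberately naive and separate from the
# implementation paths they check.

# Brute-force LZ76 exhaustive-history parser: repeatedly take the
# shortest prefix of the remainder that does not occur in
# history + word-minus-last-symbol; the final word is counted even if
# it is still reproducible.
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  p <- 1L
  count <- 0L
  while (p <= n) {
    m <- 1L
    repeat {
      if (p + m - 1L > n) { # ran off the end: remainder is the final word
        count <- count + 1L
        p <- n + 1L
        break
      }
      word <- substr(s, p, p + m - 1L)
      hist <- substr(s, 1, p + m - 2L)
      if (!grepl(word, hist, fixed = TRUE)) {
        count <- count + 1L
        p <- p + m
        break
      }
      m <- m + 1L
    }
  }
  count
}

# High-density trapezoid quadrature for the JZS paired Bayes factor via
# its other representation: the marginal of the noncentral-t density
# over a Cauchy prior on the standardized effect, mapped through
# delta = r * tan(theta) so the heavy tails are covered exactly.
jzs_bf_oracle <- function(t, n, cauchy_scale = 0.707, nodes = 20001) {
  nu <- n - 1
  theta <- seq(-pi / 2 + 1e-9, pi / 2 - 1e-9, length.out = nodes)
  delta <- cauchy_scale * tan(theta)
  f <- suppressWarnings(dt(t, df = nu, ncp = delta * sqrt(n))) / pi
  num <- sum((f[-1] + f[-nodes]) / 2 * diff(theta))
  num / dt(t, df = nu)
}

# Exhaustive sign-pattern enumeration for the two-sided Wilcoxon
# signed-rank p value (midranks of |d|; two-sided p = 2 min(tail
# probabilities), capped at 1).
wilcoxon_exact_oracle <- function(a, b) {
  d <- (a - b)[a != b]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- grid %*% rk
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Exact Friedman p by enumerating all (k!)^n within-subject rank
# permutations (tiny designs only): p = share of rank tables whose
# statistic is >= the observed one.
friedman_exact_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  stat_of <- function(r) {
    12 * sum((colSums(r) - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  }
  obs <- stat_of(t(apply(m, 1, rank)))
  perms <- all_permutations(k)
  np <- nrow(perms)
  total <- np^n
  count <- 0L
  r <- matrix(0, n, k)
  enum <- function(row, r) {
    if (row > n) {
      if (stat_of(r) >= obs - 1e-12) count <<- count + 1L
      return(invisible(NULL))
    }
    for (i in seq_len(np)) {
      r[row, ] <- perms[i, ]
      enum(row + 1L, r)
    }
  }
  enum(1L, r)
  count / total
}

# all permutations of 1..k, built by inserting k into permutations of 1..k-1
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  row <- 1L
  for (pos in seq_len(k)) {
    for (s in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[s, ], k, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

random_bits <- function(n) sample(0:1, n, replace = TRUE)
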