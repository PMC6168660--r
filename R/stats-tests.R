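#' Kolmogorov-Smirnov normality screen
#'
#' Standardizes the sample (subtract mean, divide by SD) and tests it
#' against the standard normal with a one-sample KS test. Because the
#' null parameters are estimated from the same sample the test is
#' conservative (the Lilliefors caveat); it is used only as a
#' screening decision for the parametric/non-parametric branch, at
#' alpha = 0.05.
#'
#' @param values Numeric vector, n >= 4.
#' @param alpha Decision level (default 0.05).
#' @return List with \code{statistic}, \code{p}, \code{decision}
#'   ("normal" / "non-normal").
#' @export
check_normality <- function(values, alpha = 0.05) {
  if (length(values) < 4) stop("sample-size error: need n >= 4")
  s <- sd(values)
  if (s == 0) stop("degenerate sample: zero variance")
  z <- (values - mean(values)) / s
  kt <- suppressWarnings(ks.test(z, "pnorm"))
  list(statistic = unname(kt$statistic), p = kt$p.value,
       decision = if (kt$p.value >= alpha) "normal" else "non-normal")
}

#' Friedman rank test for a complete repeated-measures matrix
#'
#' Ranks conditions within each subject (midranks for ties) and
#' computes the tie-corrected Friedman chi-square statistic with
#' k - 1 degrees of freedom; the p value comes from the chi-square
#' upper tail. When every subject ranks all conditions identically
#' tied, the statistic is 0 and p = 1.
#'
#' @param m Numeric matrix, subjects x conditions, no missing cells.
#' @return List with \code{statistic}, \code{df}, \code{p},
#'   \code{method}.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("design error: incomplete matrix")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("design error: need >= 2 subjects and >= 2 conditions")
  r <- t(apply(m, 1, rank))
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  ties <- apply(m, 1, function(row) {
    tb <- table(row)
    sum(tb^3 - tb)
  })
  den <- n * k * (k + 1) - sum(ties) / (k - 1)
  if (den <= 0) {
    stat <- 0
  } else {
    stat <- num / den
  }
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  list(statistic = stat, df = k - 1, p = p,
       method = "Friedman rank test (tie-corrected chi-square)")
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Two-sided test of the paired differences. Zero differences are
#' dropped; at least 5 informative pairs are required. For n <= 15 the
#' two-sided p value is computed by exact enumeration of all 2^n sign
#' assignments of the observed |difference| midranks; above that, the
#' normal approximation with continuity and tie correction is used.
#' The (continuity- and tie-corrected) Z statistic is reported in both
#' regimes.
#'
#' @param a,b Paired numeric vectors.
#' @return List with \code{statistic} (W = sum of positive ranks),
#'   \code{z}, \code{p}, \code{n} (informative pairs), \code{method}.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) stop("degenerate error: all paired differences are zero")
  n <- length(d)
  if (n < 5) stop("sample-size error: need >= 5 non-zero differences")
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  tb <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tb^3 - tb) / 48
  cc <- if (W == mu) 0 else 0.5 * sign(W - mu)
  z <- if (sigma2 > 0) (W - mu - cc) / sqrt(sigma2) else 0

  if (n <= 15) {
    # exact: distribution of W over all sign patterns via DP on 2*ranks
    ri <- as.integer(round(2 * rk)) # integers even under midranks
    tot <- sum(ri)
    counts <- numeric(tot + 1) # counts[s+1] = #patterns with 2W = s
    counts[1] <- 1
    for (v in ri) {
      shifted <- c(rep(0, v), counts[seq_len(tot + 1 - v)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (continuity + tie corrected)"
  }
  list(statistic = W, z = z, p = p, n = n, method = method)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Step-down familywise error correction: the i-th smallest p value is
#' multiplied by (m - i + 1), running maxima enforce monotonicity, and
#' results are capped at 1 and returned in input order. Uniformly at
#' least as powerful as Bonferroni.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("value error: p values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Split one subject's epochs into session-order quartiles
#'
#' Assigns each epoch to Q1..Q4 by its position in the session
#' (irrespective of condition). Group sizes differ by at most one, with
#' remainders going to the earliest quartiles: 10 epochs split as
#' 3, 3, 2, 2.
#'
#' @param session_order Numeric vector of session-order indices for one
#'   subject's epochs (any order; at least 4 values, no ties).
#' @return Factor of levels Q1..Q4 aligned with the input.
#' @export
quartile_split <- function(session_order) {
  n <- length(session_order)
  if (n < 4) stop("sample error: need at least 4 epochs per subject")
  if (anyDuplicated(session_order))
    stop("session_order must be a strict order (no ties)")
  sizes <- rep(n %/% 4, 4) + c(rep(1, n %% 4), rep(0, 4 - n %% 4))
  q_by_rank <- rep(1:4, times = sizes)
  factor(paste0("Q", q_by_rank[rank(session_order)]),
         levels = paste0("Q", 1:4))
}
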