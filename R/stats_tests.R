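#' Exact Fisher test for a 2x2 table
#'
#' Full hypergeometric enumeration over all tables with the observed margins.
#' The two-sided p-value follows the probability-mass rule: the sum of the
#' probabilities of all tables no more probable than the observed one (a
#' relative tolerance of 1e-7 guards floating-point ties), so results match
#' the mainstream convention for small-sample incidence comparisons such as
#' arrhythmia induction counts.
#'
#' @param tab 2x2 integer matrix (rows = groups, columns = outcome yes/no),
#'   or the counts `c(a, b, c, d)` row-wise.
#' @return a list with `p.value` (in (0, 1]), `odds_ratio` (sample), and the
#'   enumeration table `support`/`prob`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 3, 4), 2))$p.value  # 0.0808
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- cc + d; k <- a + cc
  if (m + n == 0) stop("all-zero table", call. = FALSE)
  lo <- max(0, k - n); hi <- min(k, m)
  supp <- lo:hi
  logp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  prob <- exp(logp)
  p_obs <- prob[supp == a]
  p <- min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
  list(p.value = p,
       odds_ratio = (a * d) / (b * cc),
       support = supp, prob = prob)
}

# Regularized incomplete beta I_x(a, b) by Lentz's continued fraction
# (accuracy ~1e-12; used for the t-distribution tail).
ibeta <- function(x, a, b) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  front <- exp(lgamma(a + b) - lgamma(a) - lgamma(b) +
                 a * log(x) + b * log1p(-x))
  cf <- function(a, b, x) {
    tiny <- 1e-300
    qab <- a + b; qap <- a + 1; qam <- a - 1
    c_ <- 1; d_ <- 1 - qab * x / qap
    if (abs(d_) < tiny) d_ <- tiny
    d_ <- 1 / d_; h <- d_
    for (m in 1:300) {
      m2 <- 2 * m
      aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
      d_ <- 1 + aa * d_; if (abs(d_) < tiny) d_ <- tiny
      c_ <- 1 + aa / c_; if (abs(c_) < tiny) c_ <- tiny
      d_ <- 1 / d_; h <- h * d_ * c_
      aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
      d_ <- 1 + aa * d_; if (abs(d_) < tiny) d_ <- tiny
      c_ <- 1 + aa / c_; if (abs(c_) < tiny) c_ <- tiny
      d_ <- 1 / d_
      del <- d_ * c_
      h <- h * del
      if (abs(del - 1) < 1e-14) break
    }
    h
  }
  if (x < (a + 1) / (a + b + 2)) front * cf(a, b, x) / a
  else 1 - exp(lgamma(a + b) - lgamma(a) - lgamma(b) +
                 b * log1p(-x) + a * log(x)) * cf(b, a, 1 - x) / b
}

# two-sided p from the t distribution via the incomplete beta
t_two_sided_p <- function(t, df) ibeta(df / (df + t^2), df / 2, 0.5)

#' Summary statistics of one group
#'
#' @param mean,sd,n group mean, standard deviation (>= 0) and size (>= 2 for
#'   testing; `n = 1` is allowed for bookkeeping with `sd = NA` or 0).
#' @return a list of class `summary_stats`.
#' @export
summary_stats <- function(mean, sd, n) {
  if (!is.na(sd) && sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

#' Two-sample t-test from summary statistics
#'
#' Student's unpaired t-test computed from per-group mean, SD and n, as used
#' for comparing percent-positive-area summaries between regions.  The pooled
#' variant uses `Sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)` with
#' `df = n1+n2-2`; Welch uses the Satterthwaite df.  The two-sided p-value is
#' evaluated through the package's own regularized incomplete beta (continued
#' fraction), accurate to well below 1e-6.
#'
#' Degenerate input: both SDs zero with equal means gives `t = 0, p = 1`;
#' both SDs zero with unequal means gives an infinite `t` and `p = 0` as a
#' sentinel.
#'
#' @param g1,g2 [summary_stats()] objects (or lists with mean/sd/n); `n >= 2`
#'   in each group.
#' @param variant `"pooled"` or `"welch"`.
#' @return a list with `statistic` (t), `df`, `p.value`, `variant`.
#' @export
#' @examples
#' t_test_from_summary(summary_stats(0.56, 0.40, 6),
#'                     summary_stats(6.41, 2.78, 6))  # p ~ 0.0005
t_test_from_summary <- function(g1, g2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (g1$n < 2 || g2$n < 2) stop("need n >= 2 per group", call. = FALSE)
  if (g1$sd < 0 || g2$sd < 0) stop("sd must be >= 0", call. = FALSE)
  dm <- g1$mean - g2$mean
  if (g1$sd == 0 && g2$sd == 0) {
    if (dm == 0) return(list(statistic = 0,
                             df = g1$n + g2$n - 2, p.value = 1,
                             variant = variant))
    return(list(statistic = sign(dm) * Inf, df = g1$n + g2$n - 2,
                p.value = 0, variant = variant))
  }
  if (variant == "pooled") {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  }
  t <- dm / se
  list(statistic = t, df = df, p.value = t_two_sided_p(t, df),
       variant = variant)
}

# Exact permutation distribution of the rank sum of group 1 over all
# choose(n1+n2, n1) labelings of the pooled (mid)ranks: dynamic programming
# over doubled ranks (integers even under midrank ties).
ranksum_distribution <- function(r2, n1) {
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  W <- matrix(0, n1 + 1, smax + 1)   # W[j+1, s+1] = #subsets size j, sum s
  W[1, 1] <- 1
  for (d in r2) {
    for (j in n1:1) {                # descending: each rank used at most once
      shifted <- c(rep(0, d), W[j, seq_len(smax + 1 - d)])
      W[j + 1, ] <- W[j + 1, ] + shifted
    }
  }
  W[n1 + 1, ]
}

#' Exact Mann--Whitney test
#'
#' Rank-sum test with midranks for ties.  For combined samples of up to 25
#' observations the null distribution is the exact permutation distribution
#' over all `choose(n1+n2, n1)` group labelings of the pooled ranks, computed
#' by dynamic programming (equivalent to full enumeration, including under
#' ties).  The two-sided p-value doubles the smaller tail (ties included in
#' both tails) and is capped at 1.  Larger samples fall back to the normal
#' approximation with tie correction and continuity correction, flagged by
#' `exact = FALSE`.
#'
#' @param x,y numeric samples (each non-empty).
#' @return a list with `U` (the Mann--Whitney U of `x`), `p.value`, `exact`.
#' @export
#' @examples
#' mann_whitney_exact(1:5, 6:10)$p.value  # 2/252 = 0.0079 (full separation)
mann_whitney_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  N <- n1 + n2
  if (N <= 25) {
    r2 <- round(2 * r)                        # midranks -> integers
    dist <- ranksum_distribution(r2, n1)
    total <- choose(N, n1)
    s_obs <- round(2 * R1)
    p_le <- sum(dist[seq_len(s_obs + 1)]) / total
    p_ge <- sum(dist[(s_obs + 1):length(dist)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U1, p.value = p, exact = TRUE))
  }
  ties <- table(r)
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(sig2)
  list(U = U1, p.value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}
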