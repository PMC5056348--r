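# Row-wise two-group test machinery.  The caller evaluates every CpG site
# under up to choose(n1+n2, n1) group relabelings, so all tests are
# implemented as vectorized row operations; stats::bartlett.test, t.test and
# wilcox.test serve as independent oracles in the test suite, never here.

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Two-group Bartlett statistic vs chi-square(1), vectorized over rows.
# Both variances zero -> p = 1 (perfect homoscedasticity by convention);
# exactly one zero variance -> statistic infinite, p = 0.
bartlett_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2); N <- n1 + n2
  v1 <- row_vars(x1); v2 <- row_vars(x2)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (N - 2)
  C <- 1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (N - 2)) / 3
  stat <- ((N - 2) * log(sp2) - (n1 - 1) * log(v1) - (n2 - 1) * log(v2)) / C
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[v1 == 0 & v2 == 0] <- 1
  p[xor(v1 == 0, v2 == 0)] <- 0
  p
}

# Pooled-variance two-sample t-test, two-sided, vectorized over rows.
# Zero pooled variance: p = 1 when the means agree, else p = 0.
t_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  sp2 <- ((n1 - 1) * row_vars(x1) + (n2 - 1) * row_vars(x2)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(abs((m1 - m2) / se), df = n1 + n2 - 2, lower.tail = FALSE)
  degen <- se == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p
}

# Row-wise mid-ranks of cbind(x1, x2) via pairwise comparisons (ncol is
# small: the number of samples).
row_midranks <- function(X) {
  N <- ncol(X)
  R <- matrix(1, nrow = nrow(X), ncol = N)
  for (j in seq_len(N)) {
    for (k in seq_len(N)) {
      if (k == j) next
      R[, j] <- R[, j] + (X[, k] < X[, j]) + 0.5 * (X[, k] == X[, j])
    }
  }
  R
}

# Mann-Whitney two-sided p, vectorized over rows.  Exact by full
# enumeration of group assignments (ties handled naturally by mid-ranks)
# when choose(N, n1) <= max_enum; otherwise normal approximation with
# mid-rank variance correction.
mw_rows <- function(x1, x2, max_enum = 5000L) {
  n1 <- ncol(x1); n2 <- ncol(x2); N <- n1 + n2
  X <- cbind(x1, x2)
  R <- row_midranks(X)
  mu <- n1 * n2 / 2
  U_obs <- rowSums(R[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
  dev_obs <- abs(U_obs - mu)
  if (choose(N, n1) <= max_enum) {
    combs <- combn(N, n1)
    count <- numeric(nrow(X))
    for (cidx in seq_len(ncol(combs))) {
      U <- rowSums(R[, combs[, cidx], drop = FALSE]) - n1 * (n1 + 1) / 2
      count <- count + (abs(U - mu) >= dev_obs - 1e-9)
    }
    count / ncol(combs)
  } else {
    # tie-corrected normal approximation on the rank sum
    tie_term <- vapply(seq_len(nrow(X)), function(i) {
      t <- table(X[i, ])
      sum(t^3 - t)
    }, numeric(1))
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    z <- (U_obs - mu) / sqrt(sig2)
    p <- 2 * pnorm(abs(z), lower.tail = FALSE)
    p[sig2 == 0] <- 1
    pmin(p, 1)
  }
}

#' Two-group Bartlett test of equal variances
#'
#' The gate that routes each CpG site to a parametric or nonparametric
#' depth comparison: the two-group Bartlett statistic is referred to
#' chi-square with 1 degree of freedom.  If both groups have zero variance
#' the gate returns p = 1 (perfect homoscedasticity) with a message.
#'
#' @param x,y Numeric vectors of depths (>= 2 values each).
#' @return Two-sided p-value in \[0,1\].
#' @export
bartlett_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (var(x) == 0 && var(y) == 0) {
    message("both groups have zero variance; Bartlett p set to 1")
    return(1)
  }
  bartlett_rows(matrix(x, 1), matrix(y, 1))
}

#' Single-site two-group depth test
#'
#' Parametric route: pooled-variance two-sample t-test (equal variances
#' justified by a passed Bartlett gate).  Nonparametric route: two-sided
#' Mann-Whitney U, exact by full enumeration of group assignments for up to
#' 8 samples per group, mid-ranks under ties.  Both return p = 1 when all
#' values are identical.
#'
#' @param x,y Numeric depth vectors for the two groups.
#' @param route `"parametric"` or `"nonparametric"` (as set by
#'   [bartlett_test()] at the gate's alpha).
#' @return Two-sided p-value.
#' @export
site_test <- function(x, y, route = c("parametric", "nonparametric")) {
  route <- match.arg(route)
  if (route == "parametric") t_rows(matrix(x, 1), matrix(y, 1))
  else mw_rows(matrix(x, 1), matrix(y, 1))
}

#' Per-CpG two-group tests for a depth matrix
#'
#' Runs the Bartlett gate at `bartlett_alpha` on every site and applies the
#' routed test: pooled-variance t when the gate passes (p > alpha),
#' Mann-Whitney otherwise.
#'
#' @param dm A [depth_matrix()] (normalized for DMR calling).
#' @param bartlett_alpha Gate level (default 0.05).
#' @param g1,g2 Optional column index overrides for the two groups
#'   (defaults: the matrix's own group labels).
#' @return data.frame with one row per site: `chrom`, `pos`, `mean1`,
#'   `mean2`, `bartlett_p`, `route`, `p`.
#' @export
site_tests <- function(dm, bartlett_alpha = 0.05, g1 = NULL, g2 = NULL) {
  gc <- group_columns(dm)
  if (is.null(g1)) g1 <- gc$g1
  if (is.null(g2)) g2 <- gc$g2
  if (length(g1) < 2 || length(g2) < 2)
    stop("fewer than 2 samples in a group")
  x1 <- dm$depth[, g1, drop = FALSE]
  x2 <- dm$depth[, g2, drop = FALSE]
  bp <- bartlett_rows(x1, x2)
  param <- bp > bartlett_alpha
  p <- numeric(nrow(x1))
  if (any(param)) p[param] <- t_rows(x1[param, , drop = FALSE],
                                     x2[param, , drop = FALSE])
  if (any(!param)) p[!param] <- mw_rows(x1[!param, , drop = FALSE],
                                        x2[!param, , drop = FALSE])
  data.frame(
    chrom = dm$chrom, pos = dm$pos,
    mean1 = rowMeans(x1), mean2 = rowMeans(x2),
    bartlett_p = bp,
    route = ifelse(param, "parametric", "nonparametric"),
    p = p, stringsAsFactors = FALSE
  )
}
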