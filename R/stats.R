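#' Procrustes ANOVA with permutation
#'
#' Linear model on flattened shape coordinates (or any multivariate
#' response): the effect sum of squares of a single predictor (factor or
#' covariate) is measured against the total, giving R^2 and a pseudo-F
#' statistic from summed squared distances; significance comes from
#' permuting the response rows under the intercept-only reduced model
#' (residual-randomization style). The observed statistic is included in the
#' reference set, so p >= 1/(n_perm + 1).
#'
#' @param y Response: n x p matrix, n x k x 3 array of shape coordinates, or
#'   a numeric vector (e.g. centroid size).
#' @param predictor Length-n factor or numeric covariate.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; the permutation schedule is deterministic
#'   given it.
#' @return A `procrustes_anova` list: `r_squared`, `f_stat`, `p_value`,
#'   `df_effect`, `df_residual`, `n_permutations`, `seed`, `n`.
#' @export
procrustes_anova <- function(y, predictor, n_perm = 999L, seed = 1L) {
  Y <- if (length(dim(y)) == 3L) flatten_coords(y)
       else if (is.null(dim(y))) matrix(y, ncol = 1L) else as.matrix(y)
  n <- nrow(Y)
  if (n <= 2L) stop("need more than 2 observations")
  if (length(predictor) != n) stop("predictor length must match rows of y")
  if (is.character(predictor)) predictor <- factor(predictor)
  if (is.factor(predictor)) {
    predictor <- droplevels(predictor)
    if (nlevels(predictor) < 2L) stop("constant predictor: effect undefined")
    X <- stats::model.matrix(~predictor)
  } else {
    if (stats::sd(predictor) == 0) stop("constant predictor: effect undefined")
    X <- stats::model.matrix(~predictor)
  }
  Yc <- sweep(Y, 2, colMeans(Y))
  qrX <- qr(X)
  df1 <- qrX$rank - 1L
  df2 <- n - qrX$rank
  if (df2 <= 0L) stop("no residual degrees of freedom")
  Q <- qr.Q(qrX)[, 2:qrX$rank, drop = FALSE]   # effect subspace beyond intercept
  ss_total <- sum(Yc^2)
  ss_eff <- function(Ymat) sum(crossprod(Q, Ymat)^2)
  f_of <- function(sse) (sse / df1) / ((ss_total - sse) / df2)
  obs_ss <- ss_eff(Yc)
  obs_f <- f_of(obs_ss)
  set.seed(as.integer(seed))
  count <- 1L                                   # observed is in the reference set
  for (b in seq_len(n_perm)) {
    fb <- f_of(ss_eff(Yc[sample.int(n), , drop = FALSE]))
    if (fb >= obs_f - 1e-12) count <- count + 1L
  }
  structure(list(r_squared = obs_ss / ss_total, f_stat = obs_f,
                 p_value = count / (n_perm + 1L),
                 df_effect = df1, df_residual = df2,
                 n_permutations = as.integer(n_perm),
                 seed = as.integer(seed), n = n),
            class = "procrustes_anova")
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat(sprintf("Procrustes ANOVA (n = %d, %d permutations, seed %d)\n",
              x$n, x$n_permutations, x$seed))
  cat(sprintf("  R2 = %.4f, F(%d, %d) = %.3f, p = %.4g\n",
              x$r_squared, x$df_effect, x$df_residual, x$f_stat, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a difference between two independent samples. The
#' statistic W counts pairs in which an `x` value exceeds a `y` value
#' (W in [0, n*m]); the p-value is exact (distribution enumeration) when
#' n*m <= 400 and there are no ties, and uses the tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y Numeric samples.
#' @param alternative One of "two.sided", "less", "greater".
#' @return List with `statistic` (W), `p_value`, `method`
#'   ("exact"/"approximate"), `n`, `m`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  if (length(x) < 1L || length(y) < 1L) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= 400L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = !exact)
  )
  p <- wt$p.value
  # fully tied samples: the tie-corrected normal statistic is 0/0; there is
  # no evidence against the null, so p = 1
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p,
       method = if (exact) "exact" else "approximate",
       n = length(x), m = length(y))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; the p-value uses the t approximation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `statistic` (rho), `p_value`, `method`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance: correlation undefined")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2 + 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(statistic = rho, p_value = min(1, p), method = "t-approximation", n = n)
}
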