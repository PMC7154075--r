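## Percentile-bootstrap robust tests on medians (WRS-style pb2gen /
## pbad2way behaviour, defined explicitly as this package's reference
## algorithms), BH FDR, and omega-squared / r effect sizes.

# column medians of a resample matrix; n == 3 is the hot path
# (3 replicate plots per cell), handled without apply()
.col_medians <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(m[1L, ])
  if (n == 2L) return((m[1L, ] + m[2L, ]) / 2)
  if (n == 3L) {
    return(m[1L, ] + m[2L, ] + m[3L, ] -
             pmax(m[1L, ], m[2L, ], m[3L, ]) -
             pmin(m[1L, ], m[2L, ], m[3L, ]))
  }
  apply(m, 2L, stats::median.default)
}

.boot_medians <- function(x, n_boot) {
  n <- length(x)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  .col_medians(matrix(x[idx], n, n_boot))
}

#' Percentile-bootstrap two-group test on medians
#'
#' Robust two-group comparison with the sample median as M-estimator.
#' The observed statistic is `median(x) - median(y)`. Each group is
#' resampled with replacement `n_boot` times independently; with
#' `d*_b` the bootstrap differences, the generalised p-value is
#' `p* = (#\{d* > 0\} + 0.5 #\{d* = 0\}) / n_boot` and the two-sided
#' p-value `2 min(p*, 1 - p*)`. The smallest reportable p-value is
#' `1/n_boot`; the raw (possibly zero) value is kept in `p_raw`.
#'
#' @param x,y Numeric vectors, at least 2 finite observations each.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Optional integer seed making the result reproducible.
#' @return A one-row data.frame of class `"pb_test"`: `factor`
#'   (`"two-group"`), `statistic` (median difference x - y), `p`
#'   (floored at 1/n_boot), `p_raw`, `effect_r` (Pearson r from the
#'   pooled t statistic; NA when undefined), `n_boot`, `seed`.
#' @export
#' @examples
#' pb_two_group(rnorm(10, 1), rnorm(10), n_boot = 500, seed = 1)
pb_two_group <- function(x, y, n_boot = 2000, seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("insufficient data: each group needs at least 2 observations")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite observations")
  }
  if (!is.null(seed)) set.seed(seed)
  stat <- stats::median(x) - stats::median(y)
  d <- .boot_medians(x, n_boot) - .boot_medians(y, n_boot)
  p_star <- (sum(d > 0) + 0.5 * sum(d == 0)) / n_boot
  p_raw <- 2 * min(p_star, 1 - p_star)
  r <- tryCatch(effect_size_r(x, y), error = function(e) NA_real_)
  out <- data.frame(
    factor = "two-group", statistic = stat,
    p = max(p_raw, 1 / n_boot), p_raw = p_raw, effect_r = r,
    n_boot = n_boot, seed = if (is.null(seed)) NA_integer_ else seed,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pb_test", class(out))
  out
}

# averaging operators over the J x K cell-median grid, cells in
# column-major (j, k) order
.two_way_stats <- function(M, J, K) {
  # M: (J*K) x B matrix of cell medians (B may be 1)
  B <- ncol(M)
  rbar <- matrix(0, J, B)
  for (k in seq_len(K)) rbar <- rbar + M[(k - 1L) * J + seq_len(J), , drop = FALSE]
  rbar <- rbar / K
  cbar <- matrix(0, K, B)
  for (k in seq_len(K)) cbar[k, ] <- colMeans(M[(k - 1L) * J + seq_len(J), , drop = FALSE])
  grand <- colMeans(M)
  sa <- colSums((rbar - rep(grand, each = J))^2)
  sb <- colSums((cbar - rep(grand, each = K))^2)
  fit <- rbar[rep(seq_len(J), K), , drop = FALSE] +
    cbar[rep(seq_len(K), each = J), , drop = FALSE] -
    rep(grand, each = J * K)
  sab <- colSums((M - fit)^2)
  list(A = sa, B = sb, AB = sab)
}

#' Percentile-bootstrap robust two-way ANOVA on cell medians
#'
#' Two-way factorial test with the median as M-estimator. Observed
#' statistics are sums of squared linear contrasts of the J x K cell
#' medians: main effects from the deviations of row / column marginal
#' means of cell medians from their grand mean, the interaction from
#' the usual double-centred residuals. The null distribution is
#' obtained by centring every cell at its own median, resampling
#' within cells `n_boot` times, and recomputing each statistic;
#' `p = #\{stat* >= stat_obs\} / n_boot` (floored at 1/n_boot).
#'
#' Classical omega-squared effect sizes per factor (from the ANOVA
#' sum-of-squares decomposition, see [omega_squared()]) are attached;
#' raw values are kept alongside the zero-clipped report values.
#'
#' @param y Numeric response per sample.
#' @param a,b Factors (or coercible) for the two design factors, e.g.
#'   trial and tillage.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Optional integer seed.
#' @return A three-row data.frame of class `"pb_test"` (factors
#'   `"A"`, `"B"`, `"interaction"`) with columns `statistic`, `p`,
#'   `p_raw`, `omega_sq`, `omega_sq_raw`, `n_boot`, `seed`.
#' @export
pb_two_way <- function(y, a, b, n_boot = 2000, seed = NULL) {
  y <- as.numeric(y)
  a <- factor(a); b <- factor(b)
  if (!all(is.finite(y))) stop("non-finite responses")
  J <- nlevels(a); K <- nlevels(b)
  if (J < 2L || K < 2L) stop("both factors need at least 2 levels")
  cells <- split(y, list(a, b), sep = ":")
  empty <- names(cells)[lengths(cells) == 0L]
  if (length(empty) > 0L) {
    stop("empty design cell(s): ", paste(empty, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  # split(..., list(a, b)) orders cells a-fastest: column-major (j, k)
  m_obs <- vapply(cells, stats::median, numeric(1))
  obs <- .two_way_stats(matrix(m_obs, ncol = 1L), J, K)
  centred <- lapply(cells, function(v) v - stats::median(v))
  mstar <- matrix(0, J * K, n_boot)
  for (i in seq_along(centred)) mstar[i, ] <- .boot_medians(centred[[i]], n_boot)
  null <- .two_way_stats(mstar, J, K)
  p_raw <- c(mean(null$A >= obs$A), mean(null$B >= obs$B),
             mean(null$AB >= obs$AB))
  om <- tryCatch(omega_squared(y, a, b), error = function(e) {
    data.frame(factor = c("A", "B", "interaction"),
               omega_sq = NA_real_, omega_sq_raw = NA_real_)
  })
  out <- data.frame(
    factor = c("A", "B", "interaction"),
    statistic = c(obs$A, obs$B, obs$AB),
    p = pmax(p_raw, 1 / n_boot), p_raw = p_raw,
    omega_sq = om$omega_sq, omega_sq_raw = om$omega_sq_raw,
    n_boot = n_boot, seed = if (is.null(seed)) NA_integer_ else seed,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pb_test", class(out))
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH with enforced monotonicity, order-preserving with the
#' input vector (a validated front-end to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  pp <- p[!is.na(p)]
  if (any(pp < 0 | pp > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classical omega-squared effect sizes for a two-way design
#'
#' From the classical (least-squares) ANOVA decomposition of
#' `y ~ a * b`:
#' \deqn{\omega^2 = (SS_f - df_f MS_{err}) / (SS_{tot} + MS_{err})}
#' Reported values are clipped at 0; raw (possibly negative) values
#' are retained. Designs are expected balanced, as in the 3 trials x
#' 2 tillage x 3 replicates layout.
#'
#' @param y Numeric response.
#' @param a,b Design factors.
#' @return data.frame with rows A, B, interaction and columns
#'   `factor`, `omega_sq`, `omega_sq_raw`.
#' @export
omega_squared <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  if (stats::var(y) == 0) stop("undefined effect size: zero total variance")
  fit <- stats::aov(y ~ a * b)
  tab <- summary(fit)[[1L]]
  ss <- tab[["Sum Sq"]]; df <- tab[["Df"]]
  # rows: a, b, a:b, Residuals
  mse <- ss[4L] / df[4L]
  ss_tot <- sum(ss)
  raw <- (ss[1:3] - df[1:3] * mse) / (ss_tot + mse)
  data.frame(
    factor = c("A", "B", "interaction"),
    omega_sq = pmax(raw, 0), omega_sq_raw = raw,
    stringsAsFactors = FALSE
  )
}

#' Pearson r effect size for a two-group comparison
#'
#' `r = sqrt(t^2 / (t^2 + df))` from the pooled-variance two-sample t
#' statistic. In the complete-separation limit (zero within-group
#' variance, different means) r is 1.
#'
#' @param x,y Numeric vectors.
#' @return r in \[0, 1\].
#' @export
effect_size_r <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs at least 2 observations")
  if (stats::var(c(x, y)) == 0) {
    stop("undefined effect size: zero total variance")
  }
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(1)  # separation limit
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  sqrt(t^2 / (t^2 + df))
}
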