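# Independent oracles, coded separately from the package's own paths.

# Clothing-surface temperature by plain bisection on the residual of the
# balance equation (no fixed-point iteration, no damping).
oracle_tcl <- function(ta, tr, v, met, clo, wme = 0, lo = NULL, hi = 60,
                       steps = 60) {
  icl <- 0.155 * clo
  fcl <- if (icl <= 0.078) 1 + 1.29 * icl else 1.05 + 0.645 * icl
  mw <- met - wme
  g <- function(t) {
    hc <- max(2.38 * abs(t - ta)^0.25, 12.1 * sqrt(v))
    35.7 - 0.028 * mw -
      icl * (3.96e-8 * fcl * ((t + 273)^4 - (tr + 273)^4) +
               fcl * hc * (t - ta)) - t
  }
  if (is.null(lo)) lo <- min(ta, tr) - 30
  stopifnot(g(lo) > 0, g(hi) < 0)
  for (i in seq_len(steps)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Scalar PMV from the oracle t_cl; mirrors the standard equation set but
# shares no code with the package.
oracle_pmv <- function(ta, tr, rh, v, met, clo, wme = 0) {
  tcl <- oracle_tcl(ta, tr, v, met, clo, wme)
  icl <- 0.155 * clo
  fcl <- if (icl <= 0.078) 1 + 1.29 * icl else 1.05 + 0.645 * icl
  hc <- max(2.38 * abs(tcl - ta)^0.25, 12.1 * sqrt(v))
  pa <- rh * 1000 * exp(16.6536 - 4030.183 / (ta + 235))
  mw <- met - wme
  load <- mw - 3.05e-3 * (5733 - 6.99 * mw - pa) -
    0.42 * max(mw - 58.15, 0) -
    1.7e-5 * met * (5867 - pa) -
    0.0014 * met * (34 - ta) -
    3.96e-8 * fcl * ((tcl + 273)^4 - (tr + 273)^4) -
    fcl * hc * (tcl - ta)
  (0.303 * exp(-0.036 * met) + 0.028) * load
}

# Closed-form ordinary least squares via the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tc <- qt(0.975, n - 2)
  list(slope = slope, intercept = intercept, r_squared = r2,
       slope_ci95 = c(slope - tc * se, slope + tc * se))
}

# Exhaustive two-sided permutation p-value for the rank-sum statistic,
# formulated through the Mann-Whitney U count rather than rank sums.
oracle_wilcoxon <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_of <- function(ia) {
    x <- pooled[ia]; y <- pooled[-ia]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(na))
  mu <- na * nb / 2
  combos <- combn(na + nb, na)
  u_all <- apply(combos, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# A small study-range environment grid used by several tests.
study_env_grid <- function(n, seed) {
  set.seed(seed)
  data.frame(
    ta = runif(n, 19.5, 24),
    tr = runif(n, 19.5, 24) + rnorm(n, 0, 0.3),
    rh = runif(n, 0.4, 0.6),
    v = runif(n, 0.05, 0.19),
    met = runif(n, 40, 250),
    clo = runif(n, 0.4, 1.6)
  )
}
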