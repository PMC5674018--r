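#' Luria-Delbrueck mutant-number distribution (MSS recursion)
#'
#' Probability of observing `0..n_max` resistant mutants in a culture when
#' the expected number of mutations per culture is `m`, under the classical
#' fluctuation-assay model (mutations arise at random during exponential
#' growth and found clones whose sizes have the characteristic heavy tail).
#' Computed by the Ma-Sandri-Sarkar recursion
#' `p_0 = exp(-m)`, `p_n = (m/n) * sum_{j<n} p_j / (n-j+1)`.
#'
#' @param m expected mutations per culture (>= 0).
#' @param n_max largest mutant count to evaluate.
#' @return numeric vector of probabilities `p_0 .. p_n_max`.
#' @export
#' @examples
#' mss_pmf(1, 5)
mss_pmf <- function(m, n_max) {
  if (length(m) != 1L || is.na(m) || m < 0) stopf("m must be a non-negative scalar")
  .mss_pmf_cpp(as.numeric(m), as.integer(n_max))
}

# Log-likelihood of counts under the MSS pmf. Without censoring the pmf is
# truncated at n_max and tail-renormalised; with `censor_at`, counts at or
# above the censoring point contribute the exact tail probability
# P(X >= censor_at) instead (the standard treatment of jackpot cultures).
mss_loglik <- function(m, counts, n_max, censor_at = NULL) {
  if (!is.null(censor_at)) {
    p <- mss_pmf(m, censor_at - 1L)
    tail_p <- max(0, 1 - sum(p))
    cens <- counts >= censor_at
    lp <- numeric(length(counts))
    lp[!cens] <- log(p[counts[!cens] + 1L])
    lp[cens] <- log(tail_p)
    if (any(!is.finite(lp))) return(-Inf)
    return(sum(lp))
  }
  p <- mss_pmf(m, n_max)
  tot <- sum(p)
  if (tot <= 0) return(-Inf)
  p <- p / tot  # renormalise the truncated support
  lp <- log(p[counts + 1L])
  if (any(!is.finite(lp))) return(-Inf)
  sum(lp)
}

#' Maximum-likelihood mutation rate from a fluctuation test
#'
#' Fits the expected number of mutations per culture, m, to the observed
#' mutant colony counts of parallel cultures by maximising the
#' Ma-Sandri-Sarkar likelihood, and converts it to a per-cell, per-division
#' mutation rate `mu = m / N_t` when the final population size `N_t` is
#' given. The 95% confidence interval is the profile-likelihood interval at
#' a log-likelihood drop of 1.92 (chi-square(1)/2 at 0.95).
#'
#' The pmf is truncated at `n_max` (default `max(observed, 1500)`) and
#' renormalised; the truncated tail mass at the estimate is reported. All
#' counts equal to zero give `m_hat = 0` with a one-sided interval.
#' Alternatively, `censor_at` right-censors jackpot cultures: counts at or
#' above it enter the likelihood through the exact tail probability
#' `P(X >= censor_at)`, which keeps the recursion short when cultures with
#' enormous early-mutation clones occur.
#'
#' @param counts non-negative integer mutant counts, one per culture.
#' @param n_t final cells per culture (optional; enables `mu`).
#' @param n_max pmf truncation point (ignored when `censor_at` is given).
#' @param censor_at optional right-censoring point for jackpot counts.
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `"mss_fit"` with components `m` (the MLE),
#'   `mu`, `ci_m`, `ci_mu`, `loglik`, `counts`, `n_t`, `n_max`,
#'   `tail_mass`.
#' @export
#' @examples
#' fit <- mss_mle(c(0, 0, 1, 0, 3, 0, 0, 27, 1, 0), n_t = 2e8)
#' fit
mss_mle <- function(counts, n_t = NULL, n_max = max(counts, 1500L),
                    censor_at = NULL, conf_level = 0.95) {
  counts <- as.integer(counts)
  if (length(counts) < 1L) stopf("need at least one culture")
  if (any(counts < 0L)) stopf("counts must be non-negative")
  if (is.null(censor_at)) {
    if (max(counts) > n_max) stopf("n_max smaller than the largest count")
    if (all(counts == n_max) && n_max > 0L)
      stopf("all counts at the truncation point; increase n_max")
  } else {
    if (censor_at < 1L) stopf("censor_at must be at least 1")
    if (all(counts >= censor_at))
      stopf("all counts censored; increase censor_at")
    n_max <- as.integer(censor_at) - 1L
  }
  crit <- 0.5 * stats::qchisq(conf_level, df = 1)
  ll <- function(m) mss_loglik(m, counts, n_max, censor_at)
  if (all(counts == 0L)) {
    m_hat <- 0
    ll_max <- ll(0)
    upper <- uniroot(function(m) ll(m) - (ll_max - crit),
                     lower = 1e-12, upper = 1,
                     extendInt = "downX")$root
    ci <- c(0, upper)
  } else {
    # log-grid scan to bracket, then golden-section refinement
    grid <- exp(seq(log(1e-3), log(max(counts) + 2), length.out = 40L))
    lg <- vapply(grid, ll, numeric(1))
    i <- which.max(lg)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
    m_hat <- opt$maximum
    ll_max <- opt$objective
    target <- ll_max - crit
    lower <- if (ll(1e-10) > target) 0
             else uniroot(function(m) ll(m) - target,
                          lower = 1e-10, upper = m_hat)$root
    hi2 <- m_hat * 2
    while (ll(hi2) > target && hi2 < 1e6) hi2 <- hi2 * 2
    upper <- uniroot(function(m) ll(m) - target,
                     lower = m_hat, upper = hi2)$root
    ci <- c(lower, upper)
  }
  p <- mss_pmf(m_hat, n_max)
  fit <- list(m = m_hat, ci_m = ci,
              mu = if (!is.null(n_t)) m_hat / n_t else NA_real_,
              ci_mu = if (!is.null(n_t)) ci / n_t else c(NA_real_, NA_real_),
              loglik = if (all(counts == 0L)) ll(m_hat) else ll_max,
              counts = counts, n_t = n_t, n_max = as.integer(n_max),
              tail_mass = max(0, 1 - sum(p)), conf_level = conf_level)
  class(fit) <- "mss_fit"
  fit
}

#' @export
print.mss_fit <- function(x, ...) {
  cat("Fluctuation-test mutation rate (MSS maximum likelihood)\n")
  cat(sprintf("  cultures: %d, counts: median %g, max %g\n",
              length(x$counts), stats::median(x$counts), max(x$counts)))
  cat(sprintf("  m = %.4g  [%.4g, %.4g] (%.0f%% profile likelihood)\n",
              x$m, x$ci_m[1], x$ci_m[2], 100 * x$conf_level))
  if (!is.na(x$mu))
    cat(sprintf("  mu = %.4g  [%.4g, %.4g] per cell per division (N_t = %.3g)\n",
                x$mu, x$ci_mu[1], x$ci_mu[2], x$n_t))
  invisible(x)
}

#' @export
summary.mss_fit <- function(object, ...) {
  out <- data.frame(
    cultures = length(object$counts),
    m = object$m, m_lower = object$ci_m[1], m_upper = object$ci_m[2],
    mu = object$mu, mu_lower = object$ci_mu[1], mu_upper = object$ci_mu[2],
    loglik = object$loglik, n_max = object$n_max,
    tail_mass = object$tail_mass)
  rownames(out) <- NULL
  out
}

#' @export
coef.mss_fit <- function(object, ...) c(m = object$m, mu = object$mu)

#' @export
confint.mss_fit <- function(object, parm = "m", level = NULL, ...) {
  if (!is.null(level) && level != object$conf_level)
    stopf("interval computed at level %.2f; refit for a different level",
          object$conf_level)
  parm <- match.arg(parm, c("m", "mu"))
  if (parm == "m") setNames(object$ci_m, c("lower", "upper"))
  else setNames(object$ci_mu, c("lower", "upper"))
}
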