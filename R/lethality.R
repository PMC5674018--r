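#' Parameters of the two-damage-type UV lethality model
#'
#' The model assumes UV exposure inflicts two independent kinds of damage
#' per cell per day: mutations, whose number m is Poisson with rate
#' `lambda` and of which each is lethal independently with probability `l`;
#' and lethal physiological damages (e.g. unrepairable double-strand
#' breaks), whose number p is Poisson with rate `gamma`. A cell survives
#' iff it has no lethal mutation and no physiological damage.
#'
#' @param lambda mutations per genome per day (>= 0).
#' @param l lethal fraction of mutations, in \\[0, 1\\].
#' @param gamma lethal physiological damages per genome per day (>= 0).
#' @return an object of class `"lethality_params"`.
#' @export
lethality_params <- function(lambda, l, gamma) {
  if (lambda < 0 || gamma < 0) stopf("rates must be non-negative")
  if (l < 0 || l > 1) stopf("lethal fraction l must lie in [0, 1]")
  structure(list(lambda = lambda, l = l, gamma = gamma),
            class = "lethality_params")
}

#' @export
print.lethality_params <- function(x, ...) {
  cat("Two-damage-type lethality model parameters\n")
  cat(sprintf("  lambda  = %.4g  mutations/genome/day\n", x$lambda))
  cat(sprintf("  l       = %.4g  lethal fraction of mutations\n", x$l))
  cat(sprintf("  lambda*l= %.4g  lethal mutations/genome/day\n",
              x$lambda * x$l))
  cat(sprintf("  gamma   = %.4g  lethal side effects/genome/day\n", x$gamma))
  cat(sprintf("  S       = %.4g  survival\n", uv_survival(x)))
  cat(sprintf("  rho     = %.4g  mutations per surviving cell\n",
              mean_mutations_survivor(x)))
  cat(sprintf("  efficiency = %.4g\n",
              mutation_efficiency(x$lambda * x$l, x$gamma)))
  invisible(x)
}

#' Joint probability of (m mutations, q lethal mutations, p damages)
#'
#' `P(m, q, p) = Poisson(m; lambda) * Binomial(q; m, l) * Poisson(p; gamma)`,
#' evaluated in log space. Vectorised over `m`, `q`, `p`.
#'
#' @param params a `"lethality_params"` object.
#' @param m total mutation count(s).
#' @param q lethal mutation count(s), `0 <= q <= m`.
#' @param p physiological damage count(s).
#' @param log return log-probabilities.
#' @return probability (or log-probability) vector.
#' @export
lethality_joint_pmf <- function(params, m, q, p, log = FALSE) {
  stopifnot(inherits(params, "lethality_params"))
  if (any(q > m)) stopf("q cannot exceed m")
  if (any(c(m, q, p) < 0)) stopf("counts must be non-negative")
  lp <- dpois(m, params$lambda, log = TRUE) +
    dbinom(q, m, params$l, log = TRUE) +
    dpois(p, params$gamma, log = TRUE)
  if (log) lp else exp(lp)
}

#' Survival fraction under the lethality model
#'
#' Closed form `S = exp(-(lambda*l + gamma))`, the probability of zero
#' lethal mutations and zero physiological damages.
#'
#' @param params a `"lethality_params"` object.
#' @return survival fraction in (0, 1].
#' @export
uv_survival <- function(params) {
  stopifnot(inherits(params, "lethality_params"))
  exp(-(params$lambda * params$l + params$gamma))
}

#' Mean mutation load of surviving cells
#'
#' Survivors carry only non-lethal mutations, so the mean number of
#' mutations per surviving cell is `rho = lambda * (1 - l)`.
#'
#' @param params a `"lethality_params"` object.
#' @return mean mutations per surviving cell.
#' @export
mean_mutations_survivor <- function(params) {
  stopifnot(inherits(params, "lethality_params"))
  params$lambda * (1 - params$l)
}

#' Invert the lethality model from observables
#'
#' Given the measured survival fraction S, the mean mutation load of
#' survivors rho (from genome sequencing) and an assumed lethal fraction l,
#' recovers the model parameters:
#' `lambda = rho / (1 - l)`, `lambda*l`, `gamma = -ln(S) - lambda*l`.
#'
#' @param S survival fraction in (0, 1).
#' @param rho mean mutations per surviving cell (>= 0), e.g. in
#'   bps/genome/day.
#' @param l assumed lethal fraction of mutations in \\[0, 1). The package
#'   default of 0.1 reflects dN/dS values around 0.8-0.9, i.e. roughly
#'   10-20% of mutations removed by selection.
#' @return a `"lethality_params"` object (printing also shows `lambda*l`
#'   and the efficiency).
#' @export
#' @examples
#' invert_lethality(S = 1e-4, rho = 3.13, l = 0.1)
invert_lethality <- function(S, rho, l = 0.1) {
  if (S <= 0 || S >= 1) stopf("S must lie strictly between 0 and 1")
  if (rho < 0) stopf("rho must be non-negative")
  if (l < 0 || l >= 1) stopf("l must lie in [0, 1)")
  lambda <- rho / (1 - l)
  lambda_l <- lambda * l
  gamma <- -log(S) - lambda_l
  if (gamma < 0)
    stopf("inconsistent inputs: lambda*l = %.4g exceeds -ln(S) = %.4g",
          lambda_l, -log(S))
  lethality_params(lambda, l, gamma)
}

#' Mutation production efficiency
#'
#' The share of the lethal exponent due to mutations,
#' `lambda*l / (lambda*l + gamma)`: how much of the killing is "paid for"
#' by informative mutations rather than physiological side effects.
#' Invariant under rescaling of both rates.
#'
#' @param lambda_l lethal mutation rate (lambda * l).
#' @param gamma lethal physiological damage rate.
#' @return efficiency in (0, 1].
#' @export
#' @examples
#' mutation_efficiency(0.3478, 8.8625)  # ~0.038
mutation_efficiency <- function(lambda_l, gamma) {
  if (lambda_l < 0 || gamma < 0) stopf("rates must be non-negative")
  if (lambda_l + gamma == 0) stopf("lambda*l + gamma must be positive")
  lambda_l / (lambda_l + gamma)
}

#' Forward Monte Carlo simulation of the lethality model
#'
#' Draws `cells` independent cells (m ~ Poisson(lambda), q ~ Binomial(m, l),
#' p ~ Poisson(gamma)); a cell survives iff q = 0 and p = 0. Used as an
#' independent check of the closed forms for S and rho.
#'
#' @param params a `"lethality_params"` object.
#' @param cells number of cells to simulate.
#' @param seed optional integer seed.
#' @return list with `S_hat`, `rho_hat`, `survivors` and `cells`.
#' @export
simulate_survival <- function(params, cells = 1e6, seed = NULL) {
  stopifnot(inherits(params, "lethality_params"))
  if (!is.null(seed)) set.seed(seed)
  m <- rpois(cells, params$lambda)
  q <- rbinom(cells, m, params$l)
  p <- rpois(cells, params$gamma)
  alive <- q == 0L & p == 0L
  list(S_hat = mean(alive),
       rho_hat = if (any(alive)) mean(m[alive]) else NA_real_,
       survivors = sum(alive), cells = cells)
}

#' @param object a `"lethality_params"` object.
#' @param nsim number of cells to draw.
#' @param seed optional integer seed.
#' @param ... ignored.
#' @export
#' @rdname simulate_survival
simulate.lethality_params <- function(object, nsim = 1e6, seed = NULL, ...) {
  simulate_survival(object, cells = nsim, seed = seed)
}

#' Fit the mutator growth-defect model
#'
#' Treats the growth-rate cost of hyper-mutator strains as the per-division
#' analogue of UV killing: `mu_mut = mu_WT * exp(-(lambda*l + gamma))` per
#' replication event, with `gamma = c * lambda` proportional to the
#' mutation rate. Fits `c = gamma/lambda` by least squares on the log
#' scale: `ln(mu_mut / mu_WT) = -lambda * (l + c)`.
#'
#' @param lambda mutation rates of the strains (per replication).
#' @param mu growth rates of the strains (same length).
#' @param mu_wt wild-type growth rate (> 0).
#' @param l assumed lethal fraction (default 0.1).
#' @return an object of class `"mutator_fit"`: list with `c` (the
#'   gamma/lambda ratio), `se`, `l`, `efficiency` (= l / (l + c)),
#'   `fitted`, `residuals`, `lambda`, `mu`, `mu_wt`.
#' @export
fit_mutator_gamma <- function(lambda, mu, mu_wt, l = 0.1) {
  stopifnot(length(lambda) == length(mu))
  if (length(lambda) < 2L) stopf("need at least 2 data pairs")
  if (mu_wt <= 0) stopf("mu_wt must be positive")
  if (all(lambda == 0)) stopf("all lambda zero: gamma/lambda unidentifiable")
  y <- log(mu / mu_wt)
  # y = -lambda*(l + c): shift by the known lethal-mutation term, then a
  # no-intercept regression of z = y + lambda*l on -lambda.
  z <- y + lambda * l
  chat <- -sum(lambda * z) / sum(lambda^2)
  fitted <- -lambda * (l + chat)
  res <- y - fitted
  dfree <- length(lambda) - 1L
  sigma2 <- if (dfree > 0) sum(res^2) / dfree else NA_real_
  se <- sqrt(sigma2 / sum(lambda^2))
  structure(list(c = chat, se = se, l = l,
                 efficiency = l / (l + chat),
                 fitted = fitted, residuals = res,
                 lambda = lambda, mu = mu, mu_wt = mu_wt),
            class = "mutator_fit")
}

#' @export
print.mutator_fit <- function(x, ...) {
  cat("Mutator growth-defect fit: ln(mu/mu_WT) = -lambda * (l + c)\n")
  cat(sprintf("  gamma/lambda (c) = %.4g +/- %.4g (SE), l = %.3g fixed\n",
              x$c, x$se, x$l))
  cat(sprintf("  mutation production efficiency l/(l + c) = %.4g\n",
              x$efficiency))
  invisible(x)
}

#' @export
coef.mutator_fit <- function(object, ...) c(c = object$c)

#' @export
residuals.mutator_fit <- function(object, ...) object$residuals

#' @export
predict.mutator_fit <- function(object, newdata = NULL, ...) {
  lambda <- if (is.null(newdata)) object$lambda
            else newdata$lambda %||% newdata
  object$mu_wt * exp(-lambda * (object$l + object$c))
}
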