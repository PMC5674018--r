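#' Genome-wide base-pair substitution accumulation rate
#'
#' Converts a synonymous substitution count into a genome-wide substitution
#' rate per day:
#' \deqn{\rho = \frac{N_{syn} \cdot L}{F(syn) \cdot L_{CDS} \cdot D}}
#' Synonymous changes are used because they are (to first order) invisible
#' to selection, so their count reflects the mutational input; F(syn) and
#' the CDS fraction scale the count back up to all substitutions over the
#' whole genome.
#'
#' @param n_syn synonymous substitution count.
#' @param f_syn synonymous fraction F(syn), see [synonymous_fraction()].
#' @param L genome size in bp.
#' @param L_cds total coding length in bp.
#' @param days experiment duration in days.
#' @return substitutions per genome per day.
#' @export
bps_rate <- function(n_syn, f_syn, L, L_cds, days) {
  if (any(f_syn <= 0)) stopf("F(syn) must be positive")
  if (any(L < L_cds) || any(L_cds <= 0)) stopf("need L >= L_CDS > 0")
  if (any(days <= 0)) stopf("duration must be positive")
  if (any(n_syn < 0)) stopf("counts must be non-negative")
  (n_syn * L) / (f_syn * L_cds * days)
}

#' dN/dS via the synonymous fraction
#'
#' \deqn{dN/dS = \frac{N_{nsyn}}{N_{syn}} \cdot \frac{F(syn)}{1 - F(syn)}}
#' Under neutrality the expected count ratio is
#' \eqn{N_{nsyn}/N_{syn} = (1-F(syn))/F(syn)}, so dN/dS = 1; purifying
#' selection pushes it below 1. Returns `NA` when `n_syn` is zero (the
#' ratio is undefined, as in sparse lineages).
#'
#' @param n_nsyn nonsynonymous substitution count.
#' @param n_syn synonymous substitution count.
#' @param f_syn synonymous fraction F(syn) in (0, 1).
#' @return the dN/dS ratio, or `NA_real_` if `n_syn == 0`.
#' @export
dnds <- function(n_nsyn, n_syn, f_syn) {
  if (any(f_syn <= 0) || any(f_syn >= 1)) stopf("F(syn) must lie in (0, 1)")
  if (any(n_nsyn < 0) || any(n_syn < 0)) stopf("counts must be non-negative")
  out <- (n_nsyn / n_syn) * (f_syn / (1 - f_syn))
  out[n_syn == 0] <- NA_real_
  out
}

#' Malthusian maximum growth rate from a growth curve
#'
#' Least-squares slope of ln(OD) against time, restricted to readings
#' inside the exponential-phase OD window (default OD 0.01-0.06, where
#' growth is unconstrained by the medium).
#'
#' @param time time points in hours, strictly increasing.
#' @param od optical density readings (same length as `time`).
#' @param od_window inclusive OD window defining exponential phase.
#' @return maximum growth rate in 1/h.
#' @export
#' @examples
#' t <- seq(0, 6, by = 0.25)
#' max_growth_rate(t, 0.005 * exp(0.5 * t))  # 0.5
max_growth_rate <- function(time, od, od_window = c(0.01, 0.06)) {
  stopifnot(length(time) == length(od))
  if (is.unsorted(time, strictly = TRUE)) stopf("time must be strictly increasing")
  sel <- od >= od_window[1] & od <= od_window[2]
  if (sum(sel) < 3L)
    stopf("need at least 3 readings inside the OD window [%g, %g], got %d",
          od_window[1], od_window[2], sum(sel))
  fit <- lm(log(od[sel]) ~ time[sel])
  unname(coef(fit)[2])
}
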