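#' Fold a directed substitution into one of six strand-symmetric classes
#'
#' The two strand representations of a substitution (e.g. C>T and G>A) are
#' the same biological event, so the 12 directed substitutions fold into 6
#' classes: AT>GC, GC>AT, AT>TA, GC>TA, AT>CG, GC>CG.
#'
#' @param ref,alt character vectors of single bases (A/C/G/T), `ref != alt`.
#' @return character vector of folded class labels.
#' @export
#' @examples
#' fold_substitution("C", "T")  # "GC>AT"
#' fold_substitution("G", "A")  # "GC>AT" (complement strand)
fold_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!all(ref %in% DNA_BASES) || !all(alt %in% DNA_BASES))
    stopf("ref and alt must be single A/C/G/T bases")
  if (any(ref == alt)) stopf("ref and alt must differ")
  key <- paste0(ref, ">", alt)
  map <- c("A>G" = "AT>GC", "T>C" = "AT>GC",
           "G>A" = "GC>AT", "C>T" = "GC>AT",
           "A>T" = "AT>TA", "T>A" = "AT>TA",
           "G>T" = "GC>TA", "C>A" = "GC>TA",
           "A>C" = "AT>CG", "T>G" = "AT>CG",
           "G>C" = "GC>CG", "C>G" = "GC>CG")
  unname(map[key])
}

#' Construct a substitution spectrum
#'
#' A folded six-class substitution frequency vector, optionally with the
#' underlying counts.
#'
#' @param x named numeric vector over the six folded classes (any order,
#'   missing classes are zero). Interpreted as counts if it sums to more
#'   than 1 + 1e-9 or contains integers > 1; otherwise as frequencies.
#' @param counts optional explicit counts (overrides the heuristic).
#' @return an object of class `"uvma_spectrum"`: list with `freq` (sums to
#'   1), `counts` (or NA) and `n` (total count, NA for pure frequencies).
#' @export
substitution_spectrum <- function(x = NULL, counts = NULL) {
  if (is.null(x) && is.null(counts)) stopf("provide frequencies or counts")
  if (!is.null(counts)) {
    if (is.null(names(counts)) && length(counts) == 6L)
      names(counts) <- SPECTRUM_CLASSES
    if (!all(names(counts) %in% SPECTRUM_CLASSES))
      stopf("unknown spectrum class label(s): %s",
            paste(setdiff(names(counts), SPECTRUM_CLASSES), collapse = ", "))
    cts <- setNames(numeric(6L), SPECTRUM_CLASSES)
    cts[names(counts)] <- counts
    if (any(cts < 0) || any(cts != round(cts)))
      stopf("counts must be non-negative integers")
    if (sum(cts) == 0) stopf("spectrum has zero total count")
    out <- list(freq = cts / sum(cts), counts = cts, n = sum(cts))
  } else {
    v <- setNames(numeric(6L), SPECTRUM_CLASSES)
    if (is.null(names(x)) && length(x) == 6L) names(x) <- SPECTRUM_CLASSES
    if (!all(names(x) %in% SPECTRUM_CLASSES))
      stopf("unknown spectrum class label(s): %s",
            paste(setdiff(names(x), SPECTRUM_CLASSES), collapse = ", "))
    v[names(x)] <- x
    if (any(v < 0)) stopf("spectrum values must be non-negative")
    if (sum(v) <= 0) stopf("spectrum must have positive mass")
    if (sum(v) > 1 + 1e-9) return(substitution_spectrum(counts = v))
    out <- list(freq = v / sum(v), counts = NULL, n = NA_integer_)
  }
  structure(out, class = "uvma_spectrum")
}

#' Uniform spectrum over the six folded classes
#' @return an `"uvma_spectrum"` with frequency 1/6 per class.
#' @export
uniform_spectrum <- function() {
  substitution_spectrum(setNames(rep(1 / 6, 6L), SPECTRUM_CLASSES))
}

#' @export
print.uvma_spectrum <- function(x, ...) {
  cat("<uvma_spectrum>", if (!is.na(x$n)) sprintf("n = %d", x$n) else "", "\n")
  df <- data.frame(class = SPECTRUM_CLASSES,
                   freq = round(unname(x$freq), 4))
  if (!is.null(x$counts)) df$count <- unname(x$counts)
  if (!is.null(x$sd)) df$sd <- round(unname(x$sd), 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compute the folded spectrum of a mutation set, with Monte Carlo error bars
#'
#' Class frequencies are the folded counts divided by n. Standard
#' deviations come from multinomial resampling of the observed frequencies
#' at the same n (the bootstrap scheme behind per-class error bars on
#' spectrum plots).
#'
#' @param muts mutation data frame with `ref` and `alt` columns.
#' @param trials number of Monte Carlo resamples (default 1000).
#' @param seed optional integer seed.
#' @return an `"uvma_spectrum"` with additional fields `sd` (per-class
#'   Monte Carlo SD) and `trials`.
#' @export
compute_spectrum <- function(muts, trials = 1000L, seed = NULL) {
  if (nrow(muts) == 0L) stopf("cannot compute a spectrum from zero mutations")
  if (!is.null(seed)) set.seed(seed)
  cls <- fold_substitution(muts$ref, muts$alt)
  cts <- table(factor(cls, levels = SPECTRUM_CLASSES))
  sp <- substitution_spectrum(counts = as.integer(cts))
  n <- sp$n
  res <- rmultinom(trials, size = n, prob = sp$freq) / n
  sp$sd <- setNames(apply(res, 1L, sd), SPECTRUM_CLASSES)
  sp$trials <- as.integer(trials)
  sp
}

#' @param x an `"uvma_spectrum"` with Monte Carlo SDs (see
#'   [compute_spectrum()]); frequencies are drawn as bars with +/- 1 SD
#'   whiskers when available.
#' @param ... further arguments passed to [graphics::barplot()].
#' @export
#' @rdname compute_spectrum
plot.uvma_spectrum <- function(x, ...) {
  mid <- graphics::barplot(unname(x$freq), names.arg = SPECTRUM_CLASSES,
                           ylab = "frequency", las = 2,
                           ylim = c(0, min(1, max(x$freq + (x$sd %||% 0)) * 1.2)),
                           ...)
  if (!is.null(x$sd)) {
    up <- x$freq + x$sd
    lo <- pmax(0, x$freq - x$sd)
    graphics::arrows(mid, lo, mid, up, angle = 90, code = 3, length = 0.04)
  }
  invisible(mid)
}

#' Compare two spectra by a discrete Kolmogorov-Smirnov statistic
#'
#' D is the maximum absolute difference between the cumulative class
#' frequencies of the two spectra, taken in the fixed class order
#' AT>GC, GC>AT, AT>TA, GC>TA, AT>CG, GC>CG (the statistic on a categorical
#' support depends on the ordering; this package fixes the conventional
#' display order). The p-value is obtained by permuting class labels across
#' the pooled counts (equivalently, sampling tables with fixed margins) and
#' carries the +1 correction, so it is never exactly zero.
#'
#' @param a,b `"uvma_spectrum"` objects with counts.
#' @param trials permutation resamples (default 1000).
#' @param seed optional integer seed.
#' @return list with `statistic` (D) and `p.value`.
#' @export
compare_spectra <- function(a, b, trials = 1000L, seed = NULL) {
  stopifnot(inherits(a, "uvma_spectrum"), inherits(b, "uvma_spectrum"))
  if (is.null(a$counts) || is.null(b$counts))
    stopf("both spectra need counts for the permutation test")
  if (!is.null(seed)) set.seed(seed)
  ks_d <- function(fa, fb) max(abs(cumsum(fa) - cumsum(fb)))
  D <- ks_d(a$freq, b$freq)
  na <- a$n; nb <- b$n
  pooled <- a$counts + b$counts
  tabs <- r2dtable(trials, c(na, nb), pooled)
  dstar <- vapply(tabs, function(tt) ks_d(tt[1, ] / na, tt[2, ] / nb),
                  numeric(1))
  p <- (1 + sum(dstar >= D - 1e-12)) / (trials + 1)
  list(statistic = D, p.value = p)
}
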