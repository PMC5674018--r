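#' Local sequence-context profile around mutated sites
#'
#' For every offset in `-flank..+flank` (singlets) and every half-integer
#' offset in `-(flank-0.5)..+(flank-0.5)` (doublets, read from the two
#' flanking positions), computes the frequency of each base / doublet among
#' windows centred on the mutated sites, read on the reference (plus)
#' strand. The dipyrimidine aggregate sums the eight doublets
#' TT, TC, CT, CC, AA, AG, GA, GG — the purine doublets are dipyrimidines
#' read on the opposite strand, so no strand flipping is needed.
#'
#' On circular genomes windows wrap; on linear contigs mutations without a
#' complete window are excluded with a logged count (attribute
#' `n_excluded`).
#'
#' @param muts mutation data frame with 0-based `pos`.
#' @param g an `"uvma_genome"`.
#' @param flank window half-width in bp (default 10).
#' @return an object of class `"uvma_context_profile"`: list with
#'   `singlet_offsets`, `singlet` (offsets x 4 base-frequency matrix),
#'   `doublet_offsets`, `doublet` (offsets x 16 doublet-frequency matrix),
#'   `dipyr` (dipyrimidine frequency per doublet offset) and `n`.
#' @export
context_profile <- function(muts, g, flank = 10L) {
  stopifnot(inherits(g, "uvma_genome"))
  bases <- genome_bases(g)
  L <- g$length
  pos <- as.integer(muts$pos)
  n_excluded <- 0L
  if (!g$circular) {
    ok <- pos >= flank & pos < L - flank
    n_excluded <- sum(!ok)
    if (n_excluded > 0L)
      uvma_log(sprintf("%d mutation(s) without a complete +/-%d bp window excluded",
                       n_excluded, flank), level = "WARN")
    pos <- pos[ok]
  }
  if (length(pos) == 0L) stopf("no mutations with complete context windows")
  n <- length(pos)
  s_off <- seq.int(-flank, flank)
  singlet <- matrix(0, nrow = length(s_off), ncol = 4L,
                    dimnames = list(s_off, DNA_BASES))
  base_int <- function(o) match(bases[((pos + o) %% L) + 1L], DNA_BASES)
  for (i in seq_along(s_off)) {
    bi <- base_int(s_off[i])
    singlet[i, ] <- tabulate(bi, 4L) / n
  }
  d_off <- seq.int(-flank, flank - 1L) + 0.5
  dlabels <- as.vector(t(outer(DNA_BASES, DNA_BASES, paste0)))
  doublet <- matrix(0, nrow = length(d_off), ncol = 16L,
                    dimnames = list(d_off, dlabels))
  for (i in seq_along(d_off)) {
    bl <- base_int(d_off[i] - 0.5)
    br <- base_int(d_off[i] + 0.5)
    doublet[i, ] <- tabulate((bl - 1L) * 4L + br, 16L) / n
  }
  dipyr <- rowSums(doublet[, DIPYRIMIDINE_DOUBLETS, drop = FALSE])
  structure(list(singlet_offsets = s_off, singlet = singlet,
                 doublet_offsets = d_off, doublet = doublet,
                 dipyr = dipyr, n = n, flank = as.integer(flank),
                 n_excluded = n_excluded),
            class = "uvma_context_profile")
}

#' @rdname context_profile
#' @export
singlet_profile <- function(muts, g, flank = 10L) context_profile(muts, g, flank)

#' @rdname context_profile
#' @export
doublet_profile <- function(muts, g, flank = 10L) context_profile(muts, g, flank)

# Pools of synonymous sites per folded class (union of the two directed
# substitutions). Errors if a class with positive spectrum mass has no
# admissible site.
class_site_pools <- function(index, spectrum, flank = NULL, L = NULL,
                             circular = TRUE) {
  pools <- vector("list", 6L)
  names(pools) <- SPECTRUM_CLASSES
  for (cl in SPECTRUM_CLASSES) {
    d <- directed_subs(cl)
    p <- c(index[[d[1]]], index[[d[2]]])
    if (!circular && !is.null(flank) && !is.null(L))
      p <- p[p >= flank & p < L - flank]
    if (spectrum$freq[cl] > 0 && length(p) == 0L)
      stopf("spectrum class %s has no admissible synonymous site", cl)
    pools[[cl]] <- p
  }
  pools
}

#' Spectrum-matched Monte Carlo null for the context profile
#'
#' Each trial draws `n_mut` synonymous substitutions in the genome at
#' random with the given mutational spectrum: a folded class is sampled
#' from the spectrum, then a site uniformly among the CDS positions where
#' that class produces a synonymous change. Context profiles are computed
#' exactly as for observed data, and the per-offset mean and standard
#' deviation over trials form the null expectation for a genome with no
#' local sequence-context bias.
#'
#' @param g an `"uvma_genome"`.
#' @param ann an `"uvma_annotation"`.
#' @param spectrum an `"uvma_spectrum"`.
#' @param n_mut substitutions per trial (match the observed set size).
#' @param trials Monte Carlo trials (default 10000).
#' @param seed optional integer seed.
#' @param flank window half-width (default 10).
#' @param index optional precomputed [syn_site_index()] (recomputed
#'   otherwise).
#' @return an object of class `"uvma_context_null"`: per-offset `mean` and
#'   `sd` matrices for singlets and doublets, the dipyrimidine aggregate
#'   (`dipyr_mean`, `dipyr_sd`), the per-trial dipyrimidine frequencies
#'   (`dipyr_trials`, for Monte Carlo standard errors of derived
#'   statistics), `trials` and `n_mut`.
#' @export
simulate_context_null <- function(g, ann, spectrum, n_mut, trials = 10000L,
                                  seed = NULL, flank = 10L, index = NULL) {
  stopifnot(inherits(g, "uvma_genome"), inherits(spectrum, "uvma_spectrum"))
  if (n_mut < 1L) stopf("n_mut must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  index <- index %||% syn_site_index(g, ann)
  pools <- class_site_pools(index, spectrum, flank, g$length, g$circular)
  bases <- genome_bases(g)
  L <- g$length
  N <- as.integer(trials) * as.integer(n_mut)
  cls <- sample.int(6L, N, replace = TRUE, prob = spectrum$freq)
  pos <- integer(N)
  for (ci in seq_len(6L)) {
    sel <- which(cls == ci)
    if (length(sel) == 0L) next
    pool <- pools[[ci]]
    pos[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
  }
  P <- matrix(pos, nrow = trials)
  base_int <- function(o) {
    m <- match(bases[((P + o) %% L) + 1L], DNA_BASES)
    dim(m) <- dim(P)
    m
  }
  s_off <- seq.int(-flank, flank)
  singlet_mean <- matrix(0, length(s_off), 4L, dimnames = list(s_off, DNA_BASES))
  singlet_sd <- singlet_mean
  for (i in seq_along(s_off)) {
    bi <- base_int(s_off[i])
    for (b in 1:4) {
      fr <- rowSums(bi == b) / n_mut
      singlet_mean[i, b] <- mean(fr)
      singlet_sd[i, b] <- sd(fr)
    }
  }
  d_off <- seq.int(-flank, flank - 1L) + 0.5
  dlabels <- as.vector(t(outer(DNA_BASES, DNA_BASES, paste0)))
  doublet_mean <- matrix(0, length(d_off), 16L, dimnames = list(d_off, dlabels))
  doublet_sd <- doublet_mean
  dipyr_codes <- match(DIPYRIMIDINE_DOUBLETS, dlabels)
  dipyr_trials <- matrix(0, trials, length(d_off),
                         dimnames = list(NULL, d_off))
  for (i in seq_along(d_off)) {
    bl <- base_int(d_off[i] - 0.5)
    br <- base_int(d_off[i] + 0.5)
    code <- (bl - 1L) * 4L + br
    dip <- numeric(trials)
    for (d in 1:16) {
      fr <- rowSums(code == d) / n_mut
      doublet_mean[i, d] <- mean(fr)
      doublet_sd[i, d] <- sd(fr)
      if (d %in% dipyr_codes) dip <- dip + fr
    }
    dipyr_trials[, i] <- dip
  }
  structure(list(singlet_offsets = s_off, singlet_mean = singlet_mean,
                 singlet_sd = singlet_sd, doublet_offsets = d_off,
                 doublet_mean = doublet_mean, doublet_sd = doublet_sd,
                 dipyr_mean = colMeans(dipyr_trials),
                 dipyr_sd = apply(dipyr_trials, 2L, sd),
                 dipyr_trials = dipyr_trials,
                 trials = as.integer(trials), n_mut = as.integer(n_mut),
                 flank = as.integer(flank)),
            class = "uvma_context_null")
}

#' Dipyrimidine fold enrichment
#'
#' Ratio of the observed dipyrimidine-context frequency, averaged over the
#' given doublet offsets (default the two doublets straddling the mutated
#' site), to the spectrum-matched Monte Carlo null mean. A value of 1 means
#' no local-context bias; UV photolesion chemistry predicts enrichment
#' above 1 at the site-adjacent offsets.
#'
#' @param observed an `"uvma_context_profile"`.
#' @param null an `"uvma_context_null"`.
#' @param offsets doublet offsets to average (default c(-0.5, 0.5)).
#' @return the fold enrichment (numeric scalar) with attribute `mc_se`, the
#'   Monte Carlo standard error of the enrichment of a single
#'   spectrum-matched dataset of the null's `n_mut`.
#' @export
dipyrimidine_enrichment <- function(observed, null, offsets = c(-0.5, 0.5)) {
  stopifnot(inherits(observed, "uvma_context_profile"),
            inherits(null, "uvma_context_null"))
  io <- match(offsets, observed$doublet_offsets)
  inl <- match(offsets, null$doublet_offsets)
  if (anyNA(io) || anyNA(inl)) stopf("offsets not shared by both profiles")
  obs <- mean(observed$dipyr[io])
  nul <- mean(null$dipyr_mean[inl])
  if (nul == 0) stopf("null dipyrimidine mean is zero at the given offsets")
  enr <- obs / nul
  per_trial <- rowMeans(null$dipyr_trials[, inl, drop = FALSE])
  attr(enr, "mc_se") <- sd(per_trial) / nul
  enr
}
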