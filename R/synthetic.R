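#' Generate a random annotated genome
#'
#' Builds a random circular (by default) genome at a target GC content and
#' packs non-overlapping CDS features (ATG start, random non-stop codons,
#' one terminal stop) and optional RNA-gene features into it at random
#' positions and strands. Deterministic for a fixed seed.
#'
#' @param length genome length in bp.
#' @param gc target GC fraction in (0, 1).
#' @param n_cds number of CDS features.
#' @param cds_codons codons per CDS, including start and stop (scalar or
#'   vector of length `n_cds`).
#' @param n_rna number of RNA-gene features.
#' @param rna_length RNA feature length in bp.
#' @param circular logical.
#' @param seed optional integer seed.
#' @return list with `genome` (an `"uvma_genome"`) and `annotation`
#'   (an `"uvma_annotation"`).
#' @export
generate_genome <- function(length, gc = 0.5, n_cds = 3L, cds_codons = 300L,
                            n_rna = 0L, rna_length = 120L, circular = TRUE,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (gc <= 0 || gc >= 1) stopf("gc must lie strictly between 0 and 1")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cds_codons <- rep_len(as.integer(cds_codons), n_cds)
  if (any(cds_codons < 3L)) stopf("a CDS needs at least 3 codons")
  feat_len <- c(cds_codons * 3L, rep(as.integer(rna_length), n_rna))
  n_feat <- n_cds + n_rna
  if (sum(feat_len) > length)
    stopf("infeasible packing: features total %d bp > genome %d bp",
          sum(feat_len), length)
  # random gaps between features (multinomial split of the slack)
  slack <- length - sum(feat_len)
  gaps <- as.integer(rmultinom(1L, slack, rep(1, n_feat + 1L)))
  ord <- sample.int(n_feat)
  feat_len <- feat_len[ord]
  type <- c(rep("cds", n_cds), rep("rna", n_rna))[ord]
  strand <- sample(c("+", "-"), n_feat, replace = TRUE)
  start <- integer(n_feat)
  cursor <- gaps[1L]
  pieces <- character(2L * n_feat + 1L)
  rand_bases <- function(k) paste(sample(DNA_BASES, k, TRUE, prob = p),
                                  collapse = "")
  stop_codons <- c("TAA", "TAG", "TGA")
  stop_p <- vapply(strsplit(stop_codons, ""),
                   function(b) prod(p[b]), numeric(1))
  random_cds <- function(ncod) {
    # interior codons: iid bases at the target GC, rejecting stop codons
    need <- ncod - 2L
    cods <- character(0L)
    while (base::length(cods) < need) {
      raw <- matrix(sample(DNA_BASES, 3L * (need + 8L), TRUE, prob = p),
                    ncol = 3L)
      cand <- paste0(raw[, 1L], raw[, 2L], raw[, 3L])
      cods <- c(cods, cand[!cand %in% stop_codons])
    }
    paste0("ATG", paste(cods[seq_len(need)], collapse = ""),
           sample(stop_codons, 1L, prob = stop_p))
  }
  pieces[1L] <- rand_bases(gaps[1L])
  for (k in seq_len(n_feat)) {
    start[k] <- cursor
    s <- if (type[k] == "cds") random_cds(feat_len[k] %/% 3L)
         else rand_bases(feat_len[k])
    if (strand[k] == "-") s <- revcomp(s)
    pieces[2L * k] <- s
    pieces[2L * k + 1L] <- rand_bases(gaps[k + 1L])
    cursor <- cursor + feat_len[k] + gaps[k + 1L]
  }
  g <- genome(paste(pieces, collapse = ""), id = "synthetic_genome",
              circular = circular)
  ann <- annotation(start, start + feat_len, strand, type,
                    sprintf("%s_%03d", type, seq_len(n_feat)))
  validate_annotation(ann, g)
  list(genome = g, annotation = ann)
}

# alt base implied by a folded class at a site with the given ref base,
# or NA when the class cannot act at that base.
alt_for_class <- function(class, refbase) {
  d <- directed_subs(class)
  refs <- substr(d, 1L, 1L)
  i <- match(refbase, refs)
  substr(d[i], 3L, 3L)
}

#' Simulate a mutation set with a given spectrum and context bias
#'
#' Draws `n` base-pair substitutions: a folded class is sampled from the
#' spectrum, then a site among the compatible-base genome positions
#' (restricted to synonymous CDS sites when `synonymous_only`), with sites
#' whose mutated base is the 3' member of a motif doublet — read toward the
#' site on either strand — upweighted by the factor `b`. `b = 1` gives an
#' unbiased, spectrum-matched set.
#'
#' The default motif is 5'-TC, the canonical UV photolesion hotspot: its
#' doublet is a dipyrimidine on both strand readings (TC on the plus
#' strand, GA — the strand mirror — on the minus strand), so raising `b`
#' raises the dipyrimidine-context enrichment monotonically. The 5'-TG
#' motif can be added via `motifs`; note that TG/CA are not dipyrimidine
#' doublets, so weighting TG with equal strength dilutes the
#' dipyrimidine aggregate and largely cancels the TC signal in it.
#'
#' @param g an `"uvma_genome"`.
#' @param ann an `"uvma_annotation"` (required when `synonymous_only`).
#' @param spectrum an `"uvma_spectrum"`.
#' @param n number of substitutions.
#' @param b context-bias multiplier (>= 0; default 1 = unbiased).
#' @param motifs motif doublets whose 3' base is upweighted; any of
#'   `"TC"`, `"TG"` (default `"TC"`).
#' @param synonymous_only restrict to synonymous CDS changes.
#' @param seed optional integer seed.
#' @param index optional precomputed [syn_site_index()].
#' @return mutation data frame (`chrom`, `pos` 0-based, `ref`, `alt`).
#' @export
simulate_mutation_set <- function(g, ann = NULL, spectrum = uniform_spectrum(),
                                  n, b = 1, motifs = "TC",
                                  synonymous_only = FALSE,
                                  seed = NULL, index = NULL) {
  stopifnot(inherits(g, "uvma_genome"), inherits(spectrum, "uvma_spectrum"))
  if (n < 1L) stopf("n must be at least 1")
  if (b < 0) stopf("context bias b must be non-negative")
  if (!all(motifs %in% c("TC", "TG"))) stopf("motifs must be 'TC' and/or 'TG'")
  if (!is.null(seed)) set.seed(seed)
  bases <- genome_bases(g)
  L <- g$length
  if (synonymous_only) {
    if (is.null(ann)) stopf("synonymous_only requires an annotation")
    index <- index %||% syn_site_index(g, ann)
    pools <- class_site_pools(index, spectrum, NULL, L, TRUE)
  } else {
    at_sites <- which(bases %in% c("A", "T")) - 1L
    gc_sites <- which(bases %in% c("G", "C")) - 1L
    pools <- lapply(SPECTRUM_CLASSES, function(cl) {
      if (startsWith(cl, "AT")) at_sites else gc_sites
    })
    names(pools) <- SPECTRUM_CLASSES
    for (cl in SPECTRUM_CLASSES)
      if (spectrum$freq[cl] > 0 && length(pools[[cl]]) == 0L)
        stopf("spectrum class %s has no admissible site", cl)
  }
  # motif weights; each motif is matched on both strands reading toward
  # the mutated (3') base: plus-strand 5'-TC = prev T, site C; the same
  # motif on the minus strand = site G, next A, and analogously for TG
  site_weight <- function(pos) {
    sb <- bases[pos + 1L]
    prev <- bases[((pos - 1L) %% L) + 1L]
    nxt <- bases[((pos + 1L) %% L) + 1L]
    hit <- rep(FALSE, length(pos))
    if ("TC" %in% motifs)
      hit <- hit | (prev == "T" & sb == "C") | (sb == "G" & nxt == "A")
    if ("TG" %in% motifs)
      hit <- hit | (prev == "T" & sb == "G") | (sb == "C" & nxt == "A")
    ifelse(hit, b, 1)
  }
  cls <- sample.int(6L, n, replace = TRUE, prob = spectrum$freq)
  pos <- integer(n)
  for (ci in seq_len(6L)) {
    sel <- which(cls == ci)
    if (length(sel) == 0L) next
    pool <- pools[[ci]]
    w <- site_weight(pool)
    pos[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE,
                                prob = w)]
  }
  ref <- bases[pos + 1L]
  alt <- vapply(seq_len(n), function(i)
    alt_for_class(SPECTRUM_CLASSES[cls[i]], ref[i]), character(1))
  data.frame(chrom = g$id, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Simulate parallel fluctuation-test cultures
#'
#' Forward simulation of the Luria-Delbrueck experiment: each culture grows
#' from `n0` to `nt` cells; every division mutates to the resistant state
#' with probability `mu`; a mutation arising when the population has N
#' cells founds a clone that then grows stochastically alongside the rest
#' of the culture (geometric clone size with mean `nt / N`). Mutant and
#' non-mutant fitness are equal.
#'
#' @param mu mutation rate per cell per division.
#' @param n0 initial cells per culture.
#' @param nt final cells per culture.
#' @param cultures number of parallel cultures.
#' @param seed optional integer seed.
#' @return integer vector of mutant counts, one per culture, with
#'   attribute `n_t`.
#' @export
simulate_fluctuation_cultures <- function(mu, n0, nt, cultures, seed = NULL) {
  if (nt <= n0 || n0 < 1) stopf("need nt > n0 >= 1")
  if (mu < 0 || mu > 1) stopf("mu must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ndiv <- nt - n0
  nmut <- rbinom(cultures, ndiv, mu)
  total <- sum(nmut)
  counts <- integer(cultures)
  if (total > 0L) {
    culture <- rep.int(seq_len(cultures), nmut)
    N_at <- n0 + floor(runif(total) * ndiv)  # population size when mutation arose
    clone <- rgeom(total, prob = N_at / nt) + 1L
    sums <- rowsum(clone, culture)
    counts[as.integer(rownames(sums))] <- as.integer(sums)
  }
  attr(counts, "n_t") <- nt
  counts
}

#' Simulate a growth curve
#'
#' Exponential growth with optional multiplicative measurement noise,
#' saturating at `od_max`.
#'
#' @param rate growth rate in 1/h.
#' @param od0 starting OD.
#' @param hours duration.
#' @param interval sampling interval in hours.
#' @param noise_sd SD of multiplicative log-normal noise (0 = none).
#' @param od_max saturation OD.
#' @param seed optional integer seed.
#' @return data frame with `time` (h) and `od`.
#' @export
simulate_growth_curve <- function(rate, od0 = 0.005, hours = 10,
                                  interval = 0.25, noise_sd = 0,
                                  od_max = 1.0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  time <- seq(0, hours, by = interval)
  od <- pmin(od0 * exp(rate * time), od_max)
  if (noise_sd > 0) od <- od * exp(rnorm(length(od), 0, noise_sd))
  data.frame(time = time, od = od)
}

#' Default configuration of the serial-transfer UV evolution protocol
#'
#' The daily cycle: dilute the overnight culture 100-fold, split into five
#' wells, expose each well through a UV-attenuating film ladder
#' (transmission 0.6^\{0,2,4,6,8\} of the base dose), grow for 24 h, and
#' carry forward the well with the highest dose among those that grew
#' (OD > 0.1).
#'
#' @param days protocol length (default 28).
#' @param lineages independent lineages (default 6).
#' @param base_dose full (unattenuated) daily dose, arbitrary units.
#' @param transmission per-well UV transmission ladder, strictly
#'   decreasing.
#' @param dilution daily dilution factor.
#' @param od_threshold OD defining a "growing" well.
#' @param capacity carrying capacity in cells (OD 1.0).
#' @param mu_max maximal growth rate, 1/h.
#' @param hours incubation hours per day.
#' @return a named list of protocol settings.
#' @export
evolution_config <- function(days = 28L, lineages = 6L, base_dose = 1,
                             transmission = 0.6^c(0, 2, 4, 6, 8),
                             dilution = 100, od_threshold = 0.1,
                             capacity = 1e8, mu_max = 0.7, hours = 24) {
  if (is.unsorted(rev(transmission), strictly = TRUE))
    stopf("transmission ladder must be strictly decreasing")
  if (dilution <= 1) stopf("dilution factor must exceed 1")
  list(days = as.integer(days), lineages = as.integer(lineages),
       base_dose = base_dose, transmission = transmission,
       dilution = dilution, od_threshold = od_threshold,
       capacity = capacity, mu_max = mu_max, hours = hours)
}

#' Simulate the serial-transfer UV evolution protocol
#'
#' Implements the daily dilute-expose-regrow-select cycle of
#' [evolution_config()] for a strain whose per-dose lethality is linear in
#' dose: at dose d the survival of a cell is
#' `exp(-d * (lambda_per_dose * l + gamma_per_dose))` and survivors of the
#' selected well accumulate `Poisson(lambda_per_dose * d * (1 - l))` new
#' (non-lethal) mutations. Regrowth is logistic at `mu_max` towards the
#' carrying capacity; a well "grows" if it exceeds the OD threshold after
#' the day's incubation. If no well grows the lineage is marked extinct and
#' its trace truncated.
#'
#' @param cfg protocol settings from [evolution_config()].
#' @param lambda_per_dose mutations per genome per unit dose.
#' @param gamma_per_dose lethal physiological damages per unit dose.
#' @param l lethal fraction of mutations (default 0.1).
#' @param seed optional integer seed.
#' @return a data frame (class `"uvma_evolution_trace"`) with one row per
#'   lineage-day: `lineage`, `day`, `dose`, `survival`, `new_mut`,
#'   `cum_mut`, `extinct`.
#' @export
simulate_uv_evolution <- function(cfg = evolution_config(),
                                  lambda_per_dose = 3.5,
                                  gamma_per_dose = 8.9, l = 0.1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  logistic_n <- function(n0, t) {
    if (n0 <= 0) return(0)
    cfg$capacity / (1 + (cfg$capacity / n0 - 1) * exp(-cfg$mu_max * t))
  }
  doses <- cfg$base_dose * cfg$transmission  # decreasing
  kill <- lambda_per_dose * l + gamma_per_dose
  rows <- vector("list", cfg$lineages * cfg$days)
  r <- 0L
  for (li in seq_len(cfg$lineages)) {
    N <- cfg$capacity
    cum <- 0L
    for (day in seq_len(cfg$days)) {
      n_in <- N / cfg$dilution
      surv <- rbinom(length(doses), round(n_in), exp(-doses * kill))
      od24 <- vapply(surv, function(s) logistic_n(s, cfg$hours),
                     numeric(1)) / cfg$capacity
      growing <- which(surv > 0L & od24 > cfg$od_threshold)
      r <- r + 1L
      if (length(growing) == 0L) {
        rows[[r]] <- data.frame(lineage = li, day = day, dose = NA_real_,
                                survival = 0, new_mut = NA_integer_,
                                cum_mut = cum, extinct = TRUE)
        break
      }
      w <- growing[1L]  # highest dose among the growing wells
      new_mut <- rpois(1L, lambda_per_dose * doses[w] * (1 - l))
      cum <- cum + new_mut
      N <- od24[w] * cfg$capacity
      rows[[r]] <- data.frame(lineage = li, day = day, dose = doses[w],
                              survival = exp(-doses[w] * kill),
                              new_mut = new_mut, cum_mut = cum,
                              extinct = FALSE)
    }
  }
  trace <- do.call(rbind, rows[seq_len(r)])
  rownames(trace) <- NULL
  attr(trace, "config") <- cfg
  class(trace) <- c("uvma_evolution_trace", "data.frame")
  trace
}

#' @param x an `"uvma_evolution_trace"`.
#' @param ... further arguments passed to [graphics::matplot()].
#' @export
#' @rdname simulate_uv_evolution
plot.uvma_evolution_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  doses <- matrix(NA_real_, cfg$days, cfg$lineages)
  for (li in unique(x$lineage))
    doses[x$day[x$lineage == li], li] <- x$dose[x$lineage == li]
  graphics::matplot(seq_len(cfg$days), doses, type = "s", lty = 1,
                    xlab = "day", ylab = "selected UV dose", ...)
  invisible(doses)
}
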