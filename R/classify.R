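translate_codons <- function(codons) unname(Biostrings::GENETIC_CODE[codons])

# Extract the coding-strand sequence of one annotation row.
coding_seq <- function(g, feat_start, feat_end, feat_strand) {
  s <- substr(g$seq, feat_start + 1L, feat_end)
  if (feat_strand == "-") revcomp(s) else s
}

#' Classify base-pair substitutions against an annotation
#'
#' Each substitution is classified as `synonymous`, `nonsynonymous`, `rna`
#' (inside an annotated RNA gene) or `intergenic`. CDS hits are translated
#' in frame on the coding strand; a change that preserves the encoded
#' residue is synonymous, anything else — including stop gain/loss — is
#' nonsynonymous. A position covered by several CDS frames is synonymous
#' only if it is synonymous in every frame. CDS membership takes precedence
#' over RNA-gene membership.
#'
#' @param g an `"uvma_genome"`.
#' @param ann an `"uvma_annotation"`.
#' @param muts mutation data frame with 0-based `pos`, `ref`, `alt`.
#' @return a data frame with one row per mutation: `pos` (0-based), `ref`,
#'   `alt`, `feature_id` (NA for intergenic) and `class`.
#' @export
#' @examples
#' g <- genome("ATGGGATAA", circular = FALSE)
#' ann <- annotation(0, 9, "+", "cds", "orf1")
#' m <- data.frame(pos = 5L, ref = "A", alt = "G")
#' classify_bps(g, ann, m)$class  # GGA -> GGG, Gly -> Gly: synonymous
classify_bps <- function(g, ann, muts) {
  stopifnot(inherits(g, "uvma_genome"), inherits(ann, "uvma_annotation"))
  n <- nrow(muts)
  pos <- as.integer(muts$pos)
  if (n > 0L && (any(pos < 0L) || any(pos >= g$length)))
    stopf("mutation position(s) outside genome bounds")
  bases <- genome_bases(g)
  if (n > 0L) {
    gref <- bases[pos + 1L]
    bad <- gref != toupper(muts$ref)
    if (any(bad))
      stopf("ref allele does not match genome at 0-based position(s): %s",
            paste(head(pos[bad], 5L), collapse = ", "))
  }
  cls <- rep("intergenic", n)
  feat <- rep(NA_character_, n)
  rna <- ann[ann$type == "rna", , drop = FALSE]
  for (k in seq_len(nrow(rna))) {
    hit <- pos >= rna$start[k] & pos < rna$end[k]
    cls[hit] <- "rna"
    feat[hit] <- rna$id[k]
  }
  cds <- ann[ann$type == "cds", , drop = FALSE]
  syn_all <- rep(NA, n)
  for (k in seq_len(nrow(cds))) {
    hit <- which(pos >= cds$start[k] & pos < cds$end[k])
    if (length(hit) == 0L) next
    s <- coding_seq(g, cds$start[k], cds$end[k], cds$strand[k])
    j <- if (cds$strand[k] == "+") pos[hit] - cds$start[k]
         else cds$end[k] - 1L - pos[hit]
    ci <- j %/% 3L
    wi <- j %% 3L
    codon <- substring(s, ci * 3L + 1L, ci * 3L + 3L)
    altc <- toupper(muts$alt[hit])
    if (cds$strand[k] == "-") altc <- comp_bases(altc)
    mut_codon <- paste0(substring(codon, 1L, wi), altc,
                        substring(codon, wi + 2L, 3L))
    syn <- translate_codons(codon) == translate_codons(mut_codon)
    prev <- syn_all[hit]
    syn_all[hit] <- ifelse(is.na(prev), syn, prev & syn)
    feat[hit] <- cds$id[k]
  }
  in_cds <- !is.na(syn_all)
  cls[in_cds] <- ifelse(syn_all[in_cds], "synonymous", "nonsynonymous")
  data.frame(pos = pos, ref = if (n) toupper(muts$ref) else character(),
             alt = if (n) toupper(muts$alt) else character(),
             feature_id = feat, class = cls, stringsAsFactors = FALSE)
}

#' Count substitution classes per sample
#'
#' Tabulates RNA-gene, synonymous and nonsynonymous substitution counts per
#' (strain, lineage, condition) group, mirroring the usual per-lineage BPS
#' summary of mutation-accumulation studies. Intergenic hits are tallied in
#' their own column and excluded from `n_total` (which covers annotated
#' features only).
#'
#' @inheritParams classify_bps
#' @return a data frame with columns `strain`, `lineage`, `condition`,
#'   `n_rna`, `n_syn`, `n_nsyn`, `n_total`, `n_intergenic`.
#' @export
count_classes <- function(g, ann, muts) {
  cls <- classify_bps(g, ann, muts)$class
  if (nrow(muts) == 0L)
    return(data.frame(strain = character(), lineage = character(),
                      condition = character(), n_rna = integer(),
                      n_syn = integer(), n_nsyn = integer(),
                      n_total = integer(), n_intergenic = integer()))
  label_col <- function(col) {
    v <- muts[[col]]
    if (is.null(v)) return(rep("", nrow(muts)))
    v <- as.character(v)
    v[is.na(v)] <- ""
    v
  }
  grp <- data.frame(strain = label_col("strain"),
                    lineage = label_col("lineage"),
                    condition = label_col("condition"),
                    stringsAsFactors = FALSE)
  key <- interaction(grp$strain, grp$lineage, grp$condition, drop = TRUE)
  tab <- table(key, factor(cls, levels = c("rna", "synonymous",
                                           "nonsynonymous", "intergenic")))
  first <- !duplicated(key)
  out <- data.frame(strain = grp$strain[first], lineage = grp$lineage[first],
                    condition = grp$condition[first], stringsAsFactors = FALSE)
  idx <- match(key[first], rownames(tab))
  out$n_rna <- as.integer(tab[idx, "rna"])
  out$n_syn <- as.integer(tab[idx, "synonymous"])
  out$n_nsyn <- as.integer(tab[idx, "nonsynonymous"])
  out$n_total <- out$n_rna + out$n_syn + out$n_nsyn
  out$n_intergenic <- as.integer(tab[idx, "intergenic"])
  out[order(out$strain, out$lineage, out$condition), , drop = FALSE]
}

#' Codon usage of the annotated coding regions
#'
#' Counts every in-frame codon over all CDS features, read on the coding
#' strand. The counts total `L_CDS / 3`.
#'
#' @inheritParams classify_bps
#' @return a named integer vector over the 64 codons.
#' @export
codon_usage <- function(g, ann) {
  stopifnot(inherits(g, "uvma_genome"), inherits(ann, "uvma_annotation"))
  cds <- ann[ann$type == "cds", , drop = FALSE]
  all_codons <- names(Biostrings::GENETIC_CODE)
  usage <- setNames(integer(64L), all_codons)
  for (k in seq_len(nrow(cds))) {
    len <- cds$end[k] - cds$start[k]
    if (len %% 3L != 0L)
      stopf("CDS '%s' length (%d) not divisible by 3", cds$id[k], len)
    s <- coding_seq(g, cds$start[k], cds$end[k], cds$strand[k])
    codons <- substring(s, seq(1L, len, 3L), seq(3L, len, 3L))
    t <- table(codons)
    usage[names(t)] <- usage[names(t)] + as.integer(t)
  }
  usage
}

#' Synonymous fraction F(syn)
#'
#' The probability that a substitution landing in a coding region is
#' synonymous, given the codon usage of the genome and a folded
#' substitution spectrum. Coding sites are treated as equally likely; at a
#' site, the probability of each of the three alternative bases is the
#' folded class frequency of that (ref, alt) change renormalised over the
#' three alternatives available at the site's base. Sites whose three
#' classes all carry zero spectrum mass contribute nothing.
#'
#' F(syn) converts synonymous substitution counts into genome-wide
#' substitution rates and normalises dN/dS (see [bps_rate()] and [dnds()]).
#'
#' @param usage named codon counts from [codon_usage()].
#' @param spectrum an `"uvma_spectrum"` (see [substitution_spectrum()]).
#' @return F(syn), a probability in \\[0, 1\\].
#' @export
#' @examples
#' usage <- setNames(integer(64), names(Biostrings::GENETIC_CODE))
#' usage["GGG"] <- 100
#' synonymous_fraction(usage, uniform_spectrum())  # 1/3: only 3rd-position
synonymous_fraction <- function(usage, spectrum) {
  stopifnot(inherits(spectrum, "uvma_spectrum"))
  usage <- usage[usage > 0]
  if (length(usage) == 0L) stopf("empty codon usage")
  u <- usage / sum(usage)
  f <- spectrum$freq
  total <- 0
  for (i in seq_along(u)) {
    codon <- names(u)[i]
    aa <- translate_codons(codon)
    for (w in 1:3) {
      b <- substr(codon, w, w)
      alts <- setdiff(DNA_BASES, b)
      fcls <- f[fold_substitution(rep(b, 3L), alts)]
      z <- sum(fcls)
      if (z == 0) next
      mutc <- paste0(substr(codon, 1L, w - 1L), alts,
                     substr(codon, w + 1L, 3L))
      syn <- translate_codons(mutc) == aa
      total <- total + u[[i]] * (1 / 3) * sum((fcls / z) * syn)
    }
  }
  unname(total)
}

# Directed substitutions belonging to each folded class, e.g.
# "GC>AT" -> c("G>A", "C>T").
directed_subs <- function(class) {
  r1 <- substr(class, 1L, 1L); r2 <- substr(class, 2L, 2L)
  a1 <- substr(class, 4L, 4L); a2 <- substr(class, 5L, 5L)
  c(paste0(r1, ">", a1), paste0(r2, ">", a2))
}

#' Index of synonymous sites per directed substitution
#'
#' For each of the 12 directed single-base substitutions, lists the 0-based
#' CDS positions where applying that substitution is synonymous (in every
#' overlapping frame). This index drives the spectrum-matched Monte Carlo
#' context null and the synonymous-only mutation simulator.
#'
#' @inheritParams classify_bps
#' @return a named list of 12 integer vectors of 0-based genome positions.
#' @export
syn_site_index <- function(g, ann) {
  stopifnot(inherits(g, "uvma_genome"), inherits(ann, "uvma_annotation"))
  cds <- ann[ann$type == "cds", , drop = FALSE]
  # coverage to detect positions in >1 CDS (all-frames rule applies there)
  cov <- integer(g$length)
  for (k in seq_len(nrow(cds)))
    cov[(cds$start[k] + 1L):cds$end[k]] <- cov[(cds$start[k] + 1L):cds$end[k]] + 1L
  pos_l <- list(); sub_l <- list(); syn_l <- list()
  for (k in seq_len(nrow(cds))) {
    len <- cds$end[k] - cds$start[k]
    s <- coding_seq(g, cds$start[k], cds$end[k], cds$strand[k])
    sb <- strsplit(s, "", fixed = TRUE)[[1]]
    j <- seq_len(len) - 1L
    gpos <- if (cds$strand[k] == "+") cds$start[k] + j else cds$end[k] - 1L - j
    ci <- j %/% 3L; wi <- j %% 3L
    codon <- substring(s, ci * 3L + 1L, ci * 3L + 3L)
    aa <- translate_codons(codon)
    for (a in DNA_BASES) {
      sel <- sb != a
      mutc <- paste0(substring(codon[sel], 1L, wi[sel]), a,
                     substring(codon[sel], wi[sel] + 2L, 3L))
      syn <- translate_codons(mutc) == aa[sel]
      # map coding-strand (ref, alt) to genome (plus) strand
      gref <- if (cds$strand[k] == "+") sb[sel] else comp_bases(sb[sel])
      galt <- if (cds$strand[k] == "+") a else comp_bases(a)
      pos_l[[length(pos_l) + 1L]] <- gpos[sel]
      sub_l[[length(sub_l) + 1L]] <- paste0(gref, ">", galt)
      syn_l[[length(syn_l) + 1L]] <- syn
    }
  }
  pos <- unlist(pos_l); subk <- unlist(sub_l); syn <- unlist(syn_l)
  multi <- cov[pos + 1L] > 1L
  keys <- paste0(subk, "@", pos)
  if (any(multi)) {
    agg <- tapply(syn[multi], keys[multi], all)
    first_multi <- !duplicated(keys[multi])
    m_pos <- pos[multi][first_multi]
    m_sub <- subk[multi][first_multi]
    m_syn <- as.logical(agg[keys[multi][first_multi]])
    pos <- c(pos[!multi], m_pos)
    subk <- c(subk[!multi], m_sub)
    syn <- c(syn[!multi], m_syn)
  }
  subs <- as.vector(outer(DNA_BASES, DNA_BASES, function(r, a) paste0(r, ">", a)))
  subs <- subs[substr(subs, 1L, 1L) != substr(subs, 3L, 3L)]
  out <- setNames(vector("list", length(subs)), subs)
  for (s12 in subs) out[[s12]] <- sort(unique(pos[subk == s12 & syn]))
  out
}
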