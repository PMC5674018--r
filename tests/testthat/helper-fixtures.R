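# Shared fixtures and independent oracles, all built in code.

# A 9 bp single-ORF genome: ATG GGA TAA (Met-Gly-stop).
tiny_orf_genome <- function() {
  g <- genome("ATGGGATAA", circular = FALSE)
  ann <- annotation(0L, 9L, "+", "cds", "orf1")
  list(genome = g, annotation = ann)
}

# Moderate random annotated genome reused across tests.
fixture_genome <- function(length = 12000L, n_cds = 6L, cds_codons = 150L,
                           n_rna = 1L, seed = 101L) {
  generate_genome(length, gc = 0.5, n_cds = n_cds, cds_codons = cds_codons,
                  n_rna = n_rna, rna_length = 120L, seed = seed)
}

# Independent enumeration oracle for F(syn) under a uniform spectrum:
# mutate every CDS site to every alternative base, translate the whole
# coding sequence with Biostrings, and count synonymous outcomes. Under a
# uniform spectrum every alternative base is equally likely at every site,
# so F(syn) is the plain fraction of synonymous single-base changes.
oracle_fsyn_uniform <- function(g, ann) {
  cds <- ann[ann$type == "cds", , drop = FALSE]
  syn <- 0L; tot <- 0L
  for (k in seq_len(nrow(cds))) {
    d <- Biostrings::DNAString(substr(g$seq, cds$start[k] + 1L, cds$end[k]))
    if (cds$strand[k] == "-") d <- Biostrings::reverseComplement(d)
    aa0 <- as.character(Biostrings::translate(d, no.init.codon = TRUE))
    s <- as.character(d)
    for (j in seq_len(nchar(s))) {
      for (a in setdiff(c("A", "C", "G", "T"), substr(s, j, j))) {
        s2 <- s
        substr(s2, j, j) <- a
        aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(s2),
                                                  no.init.codon = TRUE))
        syn <- syn + (aa2 == aa0)
        tot <- tot + 1L
      }
    }
  }
  syn / tot
}

# Truncated-sum oracles over the joint damage distribution; independent of
# the closed forms they check.
oracle_survival <- function(par, m_max = 200L) {
  sum(lethality_joint_pmf(par, m = 0:m_max, q = 0L, p = 0L))
}

oracle_rho_survivor <- function(par, m_max = 200L) {
  m <- 0:m_max
  pm <- lethality_joint_pmf(par, m = m, q = 0L, p = 0L)
  sum(m * pm) / sum(pm)
}

# Mirror a genome, its annotation and a mutation set onto the opposite
# strand (classification must be invariant).
revcomp_dataset <- function(g, ann, muts) {
  L <- g$length
  g2 <- genome(revcomp(g$seq), id = g$id, circular = g$circular)
  ann2 <- annotation(L - ann$end, L - ann$start,
                     ifelse(ann$strand == "+", "-", "+"), ann$type, ann$id)
  muts2 <- muts
  muts2$pos <- L - 1L - muts$pos
  muts2$ref <- unname(c(A = "T", C = "G", G = "C", T = "A")[muts$ref])
  muts2$alt <- unname(c(A = "T", C = "G", G = "C", T = "A")[muts$alt])
  list(genome = g2, annotation = ann2, muts = muts2)
}

# Goodness-of-fit of observed counts against a discrete pmf, pooling the
# tail so expected cell counts stay reasonable.
chisq_gof_pvalue <- function(counts, pmf_fun, cap) {
  obs <- tabulate(pmin(counts, cap) + 1L, cap + 1L)
  p <- pmf_fun(0:(cap - 1L))
  p <- c(p, 1 - sum(p))
  keep <- p * length(counts) >= 5
  if (all(keep)) {
    obs2 <- obs; p2 <- p
  } else {
    obs2 <- c(obs[keep], sum(obs[!keep]))
    p2 <- c(p[keep], sum(p[!keep]))
  }
  suppressWarnings(stats::chisq.test(obs2, p = p2)$p.value)
}
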