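test_that("singlet profile reads the reference strand at each offset", {
  gen <- fixture_genome()
  bases <- strsplit(gen$genome$seq, "")[[1]]
  # pick mutated sites that all have T immediately 5' of them
  pos <- which(bases == "T") # 1-based index of T
  pos <- pos[pos < gen$genome$length]      # site = T position (0-based: pos)
  sites <- pos[seq_len(200L)]              # 0-based site with T at offset -1
  refs <- bases[sites + 1L]
  alts <- ifelse(refs == "A", "G", ifelse(refs == "C", "T",
                 ifelse(refs == "G", "A", "C")))
  m <- data.frame(pos = sites, ref = refs, alt = alts)
  prof <- singlet_profile(m, gen$genome)
  expect_equal(unname(prof$singlet["-1", "T"]), 1)
  # per-offset frequencies sum to 1
  expect_true(all(abs(rowSums(prof$singlet) - 1) < 1e-12))
  # offset 0 G+C frequency equals the fraction of GC-class mutations
  gc_frac <- mean(refs %in% c("G", "C"))
  expect_equal(unname(prof$singlet["0", "G"] + prof$singlet["0", "C"]), gc_frac)
})

test_that("doublet profile counts the eight dipyrimidine-context doublets", {
  # construct a genome where every mutated site has TC at offset -0.5
  g <- genome(paste(rep("TCAG", 50L), collapse = ""), circular = TRUE)
  sites <- seq(1L, 197L, by = 4L)  # 0-based C positions preceded by T
  m <- data.frame(pos = sites, ref = "C", alt = "T")
  prof <- doublet_profile(m, g)
  expect_equal(unname(prof$doublet["-0.5", "TC"]), 1)
  expect_equal(unname(prof$dipyr["-0.5"]), 1)
  # AG at +0.5 (C followed by A, then G): CA is at +0.5
  expect_equal(unname(prof$doublet["0.5", "CA"]), 1)
  expect_true(all(abs(rowSums(prof$doublet) - 1) < 1e-12))
})

test_that("windows wrap on circular genomes and are dropped on linear contigs", {
  g_circ <- genome("ACGTACGTACGTACGTACGTACGT", circular = TRUE)
  m_edge <- data.frame(pos = 0L, ref = "A", alt = "G")
  prof <- context_profile(m_edge, g_circ, flank = 3L)
  expect_equal(prof$n, 1L)
  # offset -1 wraps to the genome's last base (T)
  expect_equal(unname(prof$singlet["-1", "T"]), 1)
  g_lin <- genome("ACGTACGTACGTACGTACGTACGT", circular = FALSE)
  expect_message(prof_lin <- context_profile(
    data.frame(pos = c(0L, 12L), ref = "A", alt = "G"), g_lin, flank = 3L),
    "excluded")
  expect_equal(prof_lin$n, 1L)
  expect_equal(prof_lin$n_excluded, 1L)
  expect_error(context_profile(m_edge, g_lin, flank = 3L), "no mutations")
})

test_that("profiles have set semantics (order invariance)", {
  gen <- fixture_genome()
  m <- simulate_mutation_set(gen$genome, gen$annotation, uniform_spectrum(),
                             150L, seed = 61L)
  p1 <- context_profile(m, gen$genome)
  p2 <- context_profile(m[sample.int(nrow(m)), ], gen$genome)
  expect_equal(p2$singlet, p1$singlet)
  expect_equal(p2$doublet, p1$doublet)
})

test_that("spectrum-matched null is calibrated against its own generator", {
  gen <- fixture_genome()
  idx <- syn_site_index(gen$genome, gen$annotation)
  sp <- substitution_spectrum(c("AT>GC" = 0.2, "GC>AT" = 0.35, "AT>TA" = 0.1,
                                "GC>TA" = 0.2, "AT>CG" = 0.05, "GC>CG" = 0.1))
  null <- simulate_context_null(gen$genome, gen$annotation, sp, n_mut = 150L,
                                trials = 1500L, seed = 62L, index = idx)
  # null means are proper frequency distributions
  expect_true(all(abs(rowSums(null$singlet_mean) - 1) < 1e-9))
  expect_true(all(abs(rowSums(null$doublet_mean) - 1) < 1e-9))
  expect_true(all(null$singlet_sd >= 0))
  # offset-0 base composition reflects the spectrum's ref-base split
  gc_mass <- sum(sp$freq[c("GC>AT", "GC>TA", "GC>CG")])
  expect_equal(unname(null$singlet_mean["0", "G"] + null$singlet_mean["0", "C"]),
               gc_mass, tolerance = 0.05)
  # data simulated by the same mechanism sit inside the null envelope
  obs <- context_profile(
    simulate_mutation_set(gen$genome, gen$annotation, sp, 150L,
                          synonymous_only = TRUE, seed = 63L, index = idx),
    gen$genome)
  z_ok <- abs(obs$singlet - null$singlet_mean) <= 3 * null$singlet_sd + 1e-12
  expect_gte(mean(z_ok), 0.95)
  enr <- dipyrimidine_enrichment(obs, null)
  expect_lt(abs(enr - 1), 3 * attr(enr, "mc_se"))
})

test_that("null SDs shrink like 1/sqrt(n_mut)", {
  gen <- fixture_genome()
  idx <- syn_site_index(gen$genome, gen$annotation)
  n1 <- simulate_context_null(gen$genome, gen$annotation, uniform_spectrum(),
                              n_mut = 50L, trials = 800L, seed = 64L,
                              index = idx)
  n4 <- simulate_context_null(gen$genome, gen$annotation, uniform_spectrum(),
                              n_mut = 200L, trials = 800L, seed = 65L,
                              index = idx)
  sel <- n1$singlet_sd > 0 & n4$singlet_sd > 0
  ratio <- median(n1$singlet_sd[sel] / n4$singlet_sd[sel])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("a class with positive mass but no synonymous site is reported", {
  g <- genome("ATGTGGTGGTGGTGGTGGTAA", circular = TRUE)  # Trp-only ORF
  ann <- annotation(0L, 21L, "+", "cds", "trp_orf")
  expect_error(
    simulate_context_null(g, ann, uniform_spectrum(), 10L, trials = 10L),
    "no admissible synonymous site")
})
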