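test_that("genome generator: bookkeeping, determinism, GC target, packing", {
  gen <- generate_genome(9000L, n_cds = 3L, cds_codons = 300L, seed = 121L)
  expect_equal(cds_length(gen$annotation), 2700L)
  expect_equal(gen$genome$length, 9000L)
  expect_silent(validate_annotation(gen$annotation, gen$genome))
  gen2 <- generate_genome(9000L, n_cds = 3L, cds_codons = 300L, seed = 121L)
  expect_identical(gen2$genome$seq, gen$genome$seq)
  expect_identical(gen2$annotation, gen$annotation)

  big <- generate_genome(100000L, gc = 0.4, n_cds = 3L, cds_codons = 300L,
                         seed = 122L)
  gc <- mean(strsplit(big$genome$seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.4), 0.01)
  expect_error(generate_genome(1000L, n_cds = 4L, cds_codons = 100L),
               "infeasible")
  # every CDS starts with ATG and ends with a stop on its own strand
  for (k in seq_len(3L)) {
    s <- substr(gen$genome$seq, gen$annotation$start[k] + 1L,
                gen$annotation$end[k])
    if (gen$annotation$strand[k] == "-") s <- uvma:::revcomp(s)
    expect_equal(substr(s, 1L, 3L), "ATG")
    expect_true(substr(s, nchar(s) - 2L, nchar(s)) %in% c("TAA", "TAG", "TGA"))
  }
})

test_that("mutation simulator follows the requested spectrum and genome", {
  gen <- fixture_genome()
  sp <- substitution_spectrum(c("AT>GC" = 0.25, "GC>AT" = 0.40, "AT>TA" = 0.05,
                                "GC>TA" = 0.20, "AT>CG" = 0.05, "GC>CG" = 0.05))
  m <- simulate_mutation_set(gen$genome, gen$annotation, sp, 10000L,
                             seed = 123L)
  bases <- strsplit(gen$genome$seq, "")[[1]]
  expect_true(all(bases[m$pos + 1L] == m$ref))
  emp <- table(factor(fold_substitution(m$ref, m$alt),
                      levels = uvma:::SPECTRUM_CLASSES))
  pv <- suppressWarnings(stats::chisq.test(as.integer(emp), p = sp$freq)$p.value)
  expect_gt(pv, 0.01)
  # synonymous-only sets classify as purely synonymous
  ms <- simulate_mutation_set(gen$genome, gen$annotation, sp, 200L,
                              synonymous_only = TRUE, seed = 124L)
  expect_true(all(classify_bps(gen$genome, gen$annotation, ms)$class ==
                    "synonymous"))
  expect_identical(
    simulate_mutation_set(gen$genome, gen$annotation, sp, 100L, seed = 7L),
    simulate_mutation_set(gen$genome, gen$annotation, sp, 100L, seed = 7L))
})

test_that("context bias raises dipyrimidine enrichment monotonically", {
  gen <- fixture_genome()
  idx <- syn_site_index(gen$genome, gen$annotation)
  null <- simulate_context_null(gen$genome, gen$annotation, uniform_spectrum(),
                                n_mut = 3000L, trials = 600L, seed = 125L,
                                index = idx)
  enr <- vapply(c(1, 3, 10), function(b) {
    m <- simulate_mutation_set(gen$genome, gen$annotation, uniform_spectrum(),
                               3000L, b = b, synonymous_only = TRUE,
                               seed = 126L, index = idx)
    as.numeric(dipyrimidine_enrichment(context_profile(m, gen$genome), null))
  }, numeric(1))
  expect_lt(abs(enr[1] - 1),
            3 * attr(dipyrimidine_enrichment(context_profile(
              simulate_mutation_set(gen$genome, gen$annotation,
                                    uniform_spectrum(), 3000L, b = 1,
                                    synonymous_only = TRUE, seed = 127L,
                                    index = idx), gen$genome), null), "mc_se"))
  expect_true(all(diff(enr) > 0))
  expect_gt(enr[3], 1.08)
})

test_that("fluctuation cultures show the jackpot signature", {
  expect_true(all(simulate_fluctuation_cultures(0, 10L, 1e6, 50L,
                                                seed = 128L) == 0L))
  counts <- simulate_fluctuation_cultures(1e-7, 100L, 1e7, 500L, seed = 129L)
  expect_gt(var(counts) / mean(counts), 5)
})

test_that("the fluctuation loop closes: simulated mu is recovered inside the CI", {
  mu <- 2.5e-7
  counts <- simulate_fluctuation_cultures(mu, 100L, 1e7, 60L, seed = 130L)
  fit <- mss_mle(counts, n_t = 1e7, n_max = max(counts, 500L))
  expect_gt(mu, fit$ci_mu[1])
  expect_lt(mu, fit$ci_mu[2])
})

test_that("UV evolution: dose selection, determinism and extinction policy", {
  cfg <- evolution_config(days = 12L, lineages = 2L)
  # harmless UV: the highest-dose well always grows and is always chosen
  t0 <- simulate_uv_evolution(cfg, lambda_per_dose = 0, gamma_per_dose = 0,
                              seed = 131L)
  expect_true(all(t0$dose == cfg$base_dose * max(cfg$transmission)))
  expect_true(all(!t0$extinct))
  # mutation counts are non-decreasing within a lineage
  t1 <- simulate_uv_evolution(cfg, lambda_per_dose = 3.5,
                              gamma_per_dose = 8.9, seed = 132L)
  for (li in unique(t1$lineage))
    expect_true(all(diff(t1$cum_mut[t1$lineage == li]) >= 0))
  expect_identical(
    simulate_uv_evolution(cfg, lambda_per_dose = 3.5, gamma_per_dose = 8.9,
                          seed = 133L),
    simulate_uv_evolution(cfg, lambda_per_dose = 3.5, gamma_per_dose = 8.9,
                          seed = 133L))
  # overwhelming lethality at every rung extinguishes the lineage
  text <- simulate_uv_evolution(evolution_config(days = 5L, lineages = 1L),
                                lambda_per_dose = 0, gamma_per_dose = 2000,
                                seed = 134L)
  expect_true(any(text$extinct))
  expect_lt(nrow(text), 5L)
})

test_that("daily mutation gain tracks lambda(1-l) at the realised dose", {
  cfg <- evolution_config(days = 28L, lineages = 6L)
  tr <- simulate_uv_evolution(cfg, lambda_per_dose = 3.5, gamma_per_dose = 8.9,
                              l = 0.1, seed = 135L)
  expected <- 3.5 * (1 - 0.1) * tr$dose
  total_exp <- sum(expected)
  expect_lt(abs(sum(tr$new_mut) - total_exp), 3 * sqrt(total_exp))
})
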