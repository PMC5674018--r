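---
title: "Models and methods behind uvma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uvma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvma)
```

`uvma` implements the computational side of a UV mutation-accumulation
study: classifying fixed base-pair substitutions (BPSs) on a bacterial
genome, summarising them as mutational spectra and sequence-context
profiles with Monte Carlo nulls, converting synonymous counts into
genome-wide substitution rates and dN/dS, estimating mutation rates from
fluctuation assays, and partitioning UV killing into lethal mutations
versus physiological side effects. This vignette records the models, the
parameter choices, and the numerical decisions, in the package's own
words.

## Coordinates, formats and filters

Internally every position is 0-based half-open; conversion from the
1-based inclusive conventions of FASTA/GFF3/VCF happens once, at the I/O
boundary, which keeps off-by-one logic out of the analysis code. Reading
uses the field-standard parsers (Biostrings for FASTA, rtracklayer for
GFF3/BED, vcfR for VCF); only single-base substitutions are retained,
since indels and MNVs are outside the analysis scope.

Variant-call filtering keeps calls with Phred quality ≥ 100 **and**
mutant-read fraction ≥ 90%. The thresholds are read literally as
"remove `< 100`" and "remove `< 90%`": strictly smaller values are
dropped, equality is kept. Calls passing both filters are treated as
dominant or fixed in the sequenced population. The 90% fraction is
applied per called site; whether it should instead aggregate across
overlapping read pairs is not decidable from the filter definition alone,
and per-site is the interpretation implemented. The VCF field holding the
fraction varies by caller, so its INFO key is a reader argument
(`fraction_field`, default `"AF"`).

## Substitution classification and F(syn)

A substitution inside a CDS is translated in frame on the coding strand;
if the encoded residue is unchanged it is synonymous, otherwise —
including stop gain and loss — nonsynonymous. Hits in annotated RNA genes
are a separate class (CDS membership takes precedence on overlap), and
everything else is intergenic. A position covered by several CDS frames
is called synonymous only if it is synonymous in *every* frame: a
conservative, deterministic rule for the rare overlapping-gene case.

The synonymous fraction

$$F(syn) = \sum_{\text{codon}} P(\text{codon}) \sum_{\text{pos}=1}^{3}
\tfrac13 \sum_{\text{alt}} P(\text{alt} \mid \text{base})\,
\mathbf{1}[\text{synonymous}]$$

is the probability that a substitution landing in coding sequence is
synonymous, given codon usage and a folded six-class spectrum. The
per-site conditioning is the open design point here: a folded class
frequency is split equally between its two strand representations, and at
a given site the three alternative bases are weighted by their class
frequencies renormalised over the three classes available at that site's
base. Sites where all three classes carry zero mass contribute nothing.
Under a uniform spectrum this reduces to the plain fraction of synonymous
single-base changes, which is what the test suite checks against an
independent whole-protein enumeration oracle (mutate every CDS site,
translate the entire protein with Biostrings, compare).

F(syn) can be computed from any spectrum object: pooled per condition or
separately per lineage. Both modes are deliberately exposed — per-lineage
spectra capture lineage-specific biases at the cost of noisier F(syn) on
small counts — and the package does not privilege either.

F(syn) feeds the two headline conversions:

- accumulation rate $\rho = N_{syn} L / (F(syn)\, L_{CDS}\, D)$ in
  substitutions per genome per day, with $L$ the genome size (3.98 Mbp
  for the reduced-genome *E. coli* strains the defaults emulate),
  $L_{CDS}$ the total coding length from the annotation, and $D$ the
  experiment duration in days;
- $dN/dS = (N_{nsyn}/N_{syn}) \cdot F(syn)/(1-F(syn))$, which is 1 under
  neutrality by construction and is reported as `NA` when $N_{syn} = 0$.

## Spectra, context profiles and the Monte Carlo null

The twelve directed substitutions fold into six strand-symmetric classes.
Spectrum error bars come from multinomial resampling of the observed
frequencies at the observed n (1,000 resamples by default); the exact
resampling scheme behind published error bars of this kind is rarely
stated, and multinomial resampling is the package's choice, not an
asserted reproduction. Spectrum comparison uses the maximum absolute
difference of cumulative class frequencies — a discrete
Kolmogorov–Smirnov statistic, which on a categorical support depends on
the class ordering; the package fixes the conventional display order
(AT→GC, GC→AT, AT→TA, GC→TA, AT→CG, GC→CG) and computes the p-value by
permutation (fixed-margin tables via `r2dtable`) with the +1 correction,
so p is never exactly zero.

Context profiles are read on the reference strand: singlet base
frequencies at offsets −10..+10 around each mutated site, and doublet
frequencies at half-integer offsets −9.5..+9.5. The dipyrimidine
aggregate sums eight doublets — TT, TC, CT, CC and their purine
complements AA, AG, GA, GG — because a purine doublet on the reference
strand is a dipyrimidine read on the other strand; counting the purine
complements makes strand flipping unnecessary. Windows wrap on circular
genomes; on linear contigs, mutations without a complete window are
excluded with a logged count.

The null model generates synonymous substitutions "at random with the
observed spectrum": each trial samples a folded class from the spectrum,
then a site uniformly among the CDS positions where that class produces a
synonymous change (10,000 trials by default, matching the scale used for
published context nulls; spectrum error bars use 1,000). Per-offset means
and SDs over trials form the envelope against which observed profiles and
the dipyrimidine fold enrichment are judged. The per-trial dipyrimidine
frequencies are kept on the object so that Monte Carlo standard errors of
derived statistics (e.g. the enrichment of a single dataset) need no
re-simulation. A spectrum class with positive mass but no admissible
synonymous site is an error naming the class, not a silent renormalisation.

## Fluctuation assays

The mutant-count distribution uses the Ma–Sandri–Sarkar recursion
$p_0 = e^{-m}$, $p_n = (m/n) \sum_{j<n} p_j/(n-j+1)$, implemented in C++
because the likelihood needs $O(n_{max}^2)$ work per evaluation. The
recursion's clone-size distribution has the characteristic heavy tail
$P(\text{clone} = k) = 1/(k(k+1))$, so the truncated mass approaches 1
only at rate $\sim m/n_{max}$ — a property worth stating because it rules
out pushing truncation error to near machine precision; the default
truncation is $\max(\text{observed count}, 1500)$ with tail
renormalisation, and the tail mass at the estimate is reported on the
fit object. For datasets with jackpot cultures (single early mutations
yielding counts of $10^4$ or more) the likelihood supports right
censoring instead: counts at or above `censor_at` contribute
$P(X \ge \text{censor\_at})$, the standard treatment in fluctuation-assay
software.

`mss_mle()` maximises the likelihood over a log-grid bracket refined by
golden-section search and converts $\hat m$ to a per-cell, per-division
rate $\hat\mu = \hat m / N_t$. The 95% interval is the profile-likelihood
interval at a log-likelihood drop of 1.92; published "MSS method"
intervals do not always state their construction, so the profile interval
is documented here as this package's choice. Its coverage is verified by
simulation (500 synthetic 30-culture experiments at m = 2, coverage
checked to lie in 93–97%).

The forward simulator is a Lea–Coulson-style mechanism, independent of
the recursion: each of the $N_t - N_0$ divisions mutates with probability
$\mu$; a mutation arising when the population has $N$ cells founds a
clone whose final size is geometric with mean $N_t/N$ (stochastic growth
alongside the rest of the culture), with mutant fitness equal to
non-mutant fitness. Integrating the geometric clone over the uniform
mutation-opportunity distribution reproduces the $1/(k(k+1))$ clone law
exactly, so simulator and recursion agree in distribution while sharing
no code path — the χ² agreement at $10^5$ cultures is therefore a real
two-route check. A synchronous-doubling variant (all cells divide at
once, mutant clones growing deterministically) was rejected: it confines
single-mutation clones to powers of two and cannot match the continuous
mutant-count distribution that the estimator assumes.

## The two-damage-type lethality model

UV exposure is modelled as inflicting two independent damage types per
cell per day: $m \sim \text{Poisson}(\lambda)$ mutations, each lethal
independently with probability $l$ ($q \mid m \sim \text{Binomial}(m,
l)$), and $p \sim \text{Poisson}(\gamma)$ lethal physiological damages
(e.g. unrepairable double-strand breaks). A cell survives iff $q = 0$ and
$p = 0$, giving

$$S = e^{-(\lambda l + \gamma)}, \qquad \rho = \lambda(1 - l),$$

where $\rho$ is the mean mutation load of survivors — non-lethal
mutations are assumed neutral, so survivors' growth is unaffected. Both
closed forms are verified against blind truncated sums over the joint pmf
(all probability work is done in log space; truncation is set where the
Poisson tails are far below the $10^{-9}$ comparison tolerance) and
against a $10^6$-cell forward simulation.

The inversion takes the three observables a study actually has — $S$
(survival after daily exposure), $\rho$ (substitutions per genome per day
among survivors, from sequencing), and an assumed $l$ — and returns
$\lambda = \rho/(1-l)$, $\lambda l$, and $\gamma = -\ln S - \lambda l$,
erroring if the inputs imply $\gamma < 0$. The default $l = 0.1$ encodes
the observation that dN/dS of such experiments sits around 0.8–0.9,
i.e. roughly 10–20% of nonsynonymous mutations are purged; it is a rough,
overridable constant, and the headline efficiency is insensitive to
moderate changes in it. The **mutation production efficiency**
$\lambda l/(\lambda l + \gamma)$ is scale-invariant: it measures the
share of the lethal exponent attributable to mutations.

For mutators, the same survival term is reused per replication event:
$\mu_{mut} = \mu_{WT} e^{-(\lambda l + \gamma)}$ with $\gamma = c\lambda$
proportional to the mutation rate. `fit_mutator_gamma()` estimates $c$ by
least squares on the log scale, $\ln(\mu_{mut}/\mu_{WT}) = -\lambda(l +
c)$ — the fit's loss function is this package's default (the published
fit of this form does not state one) — and the efficiency becomes
$l/(l + c)$. The "per day" and "per replication event" units are carried
as labels only; the model treats the exponent identically in both
readings. The published numeric value of $c$ from external growth data is
not bundled; the fit is validated by exact parameter recovery on
noiseless synthetic data and by the monotone growth of its standard error
with noise.

## The synthetic-data generators

The generators define the conditions under which the package tests
itself; their defaults are fixed once, here.

- **Genomes**: random sequence at a target GC content (default 0.5, the
  approximate *E. coli* value), with non-overlapping CDS packed at random
  positions and strands (ATG start, iid non-stop codons at the target
  base composition, one terminal stop). RNA-gene intervals are optional
  untranslated features. This emulates coding density and codon structure
  only — no operons, no codon-usage bias, no GC skew, no repeat
  structure. Tests passing on these genomes show the *machinery* is
  correct; they do not show that real-genome covariates (e.g.
  transcription-coupled repair) are absent from real data.
- **Mutation sets**: a folded class is drawn from the target spectrum,
  then a site among compatible-base positions (optionally restricted to
  synonymous CDS sites, which is how the context null's observed
  counterpart is generated). The UV hotspot is emulated by upweighting
  (factor `b`) sites whose mutated base is the 3' member of a 5'-TC
  doublet on either strand reading — the canonical photolesion motif,
  and a dipyrimidine on both readings, so the dipyrimidine-context
  enrichment grows monotonically in `b`. The 5'-TG motif is available as
  an option but is not part of the default bias: TG and its mirror CA
  are not dipyrimidine doublets, and weighting them as strongly as TC
  dilutes the dipyrimidine aggregate by almost exactly what TC adds,
  leaving the enrichment statistic flat — the opposite of what a
  hotspot generator is for.
- **Fluctuation cultures**: the Lea–Coulson mechanism above; default
  condition in tests is $N_0 = 100$, $N_t = 10^7$ cells, matching the
  dilution-to-saturation design of tube-based assays.
- **Serial-transfer protocol**: 28 days × 6 lineages by default; each day
  the culture is diluted 100-fold into five wells irradiated through a
  transmission ladder $0.6^{\{0,2,4,6,8\}}$ (a 40%-per-sheet UV-cut film
  stacked 0–8 deep), regrown for 24 h, and the highest-dose well with
  OD > 0.1 carries forward. Per-dose lethality is linear in dose,
  $(\lambda, \gamma) = (\text{rate} \times d)$ — the dose–response shape
  is not constrained by the protocol description, and linearity is the
  documented default. Regrowth is logistic (default $\mu_{max} = 0.7$/h,
  carrying capacity $10^8$ cells ≙ OD 1.0, threshold checked at 24 h).
  Survivor counts are binomial draws, and survivors accumulate
  $\text{Poisson}(\lambda d (1-l))$ non-lethal mutations per day. A
  lineage whose five wells all fail is marked extinct and its trace
  truncated — the real protocol's hand-tuned exposure times make
  extinction rare, and the simulator leaves the base dose as a free
  schedule rather than guessing the tuning rule. The default per-dose
  rates (λ = 3.5, γ = 8.9 per unit dose at l = 0.1) place the full-dose
  well at the S ≈ 10⁻⁴ survival regime of the study's repair-proficient
  strain.

All generators are deterministic given a seed, and their outputs are
written in the same standard formats the readers consume, so synthetic
data exercise the identical code path as real data.

## Numerical choices and test scale

- Probability computations in log space throughout the lethality model;
  truncated-sum oracles are run where tails are $< 10^{-12}$.
- Permutation and resampling p-values carry the +1 correction.
- The acceptance-style tests run at the sizes the quantitative claims
  refer to: $10^6$ cells for the survival Monte Carlo, $10^5$ cultures
  per χ² comparison at m ∈ {0.5, 1, 2}, 500 datasets for CI coverage,
  10,000 trials for the context null. Unit tests use smaller versions of
  the same checks.
- Genomes in tests are 4–100 kb with 3–18 CDS: large enough for stable
  codon usage and site pools, small enough that the whole suite builds
  every fixture from code.

## Known limitations

- No indels, MNVs, or pseudogene handling; classification is
  single-substitution only.
- The context machinery stops at doublets: no trinucleotide (96-class)
  signatures and no strand-asymmetry decomposition.
- The lethality model treats non-lethal mutations as strictly neutral;
  there is no fitness distribution among survivors, no photoreactivation
  or SOS dynamics, and no dose memory between days.
- F(syn)'s per-site conditioning is one defensible reading of
  "probability of each substitution"; alternatives (e.g. weighting sites
  by total class mass at their base) would shift F(syn) by a few percent
  for strongly skewed spectra.
- The fluctuation model assumes equal mutant and wild-type fitness and no
  plating losses (cultures are plated whole and concentrated, so no
  plating-efficiency correction is applied).
- Empirical quantities measured on real strains are not reproducible from
  this package alone: the dipyrimidine enrichment of a real UV mutation
  dataset (reported around 1.6-fold for *E. coli*) needs the reference
  genome and the study's mutation list; per-lineage dN/dS values depend
  on per-lineage spectra that only the underlying data provide; and
  fold elevations of mutation rate between strains and the realised
  dose series are wet-lab outcomes. The serial-transfer simulator is
  held only to their qualitative structure — a UV-sensitive,
  high-physiological-kill strain settles at lower rungs of the dose
  ladder than a repair-proficient one — which the test suite asserts.
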