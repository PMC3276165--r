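---
title: "Genotype imputation with surrogate-family template selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype imputation with surrogate-family template selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapimpute)
```

## The problem

A genome-wide association study types its samples at a few hundred thousand
array SNPs, while reference panels of phased haplotypes cover millions of
sites. Genotype imputation predicts the genotypes at the untyped sites by
recognizing that each study chromosome is, locally, a near-copy of some
reference chromosome. As reference collections grow large and ancestrally
diverse, two practical questions arise: which haplotypes to copy from, and
how to keep the computation affordable. `hapimpute` implements an answer:
use the whole ("cosmopolitan") panel, but let each study haplotype copy only
from its `k_hap` Hamming-nearest reference haplotypes in each genomic
window — its *surrogate family members*, the haplotypes most likely to share
recent ancestry with it locally.

## The model

The engine is the Li & Stephens haplotype-copying hidden Markov model. A
haplotype is an imperfect mosaic of K template haplotypes. The hidden state
is which template is being copied; between adjacent sites at genetic
distance d Morgans the state switches with probability

  p = 1 − exp(−ρ/K),  ρ = 4·Ne·d,

landing uniformly on the K templates (so staying has probability
(1−p) + p/K). Emissions allow copying errors: the observed allele equals
the template allele with probability 1−λ and differs with probability λ.
Missing observations emit 1 for every state. The copying-error rate λ is
the Watterson-style rate λ = θ/(2(θ+K)) with θ = (Σ_{i<K} 1/i)^{−1},
recomputed for the active template count; a fixed override is available in
`model_params()`.

This transition kernel is a semigroup in ρ, which has a useful consequence:
an untyped site can be inserted between two typed sites as a
missing-observation column *exactly*, by propagating the forward message
from the left typed site and the (emission-weighted) backward message from
the right typed site across the two sub-intervals. `impute_untyped()` does
this in closed form; the result is identical to running the
forward–backward pass with the untyped column included, and the test suite
verifies both routes against brute-force path enumeration to 1e-10.

### The MCMC

Study genotypes arrive unphased, so the sampler alternates
(`run_mcmc()`):

1. **Phase update.** For each individual, build a candidate pool from all
   reference haplotypes plus the other individuals' current haplotypes,
   rank it by Hamming distance to the individual's two current haplotypes
   (k/2 nearest per haplotype, ties at the boundary distance broken
   uniformly at random), and sample a new genotype-consistent haplotype
   pair by a diploid forward-filter/backward-sampling pass over template
   pairs.
2. **Imputation update.** Treat the two sampled haplotypes as independent
   given the reference panel. For each, select the `k_hap`
   Hamming-nearest *reference* haplotypes over the typed sites of the
   window and run the haploid forward–backward, obtaining P(allele 1) at
   every untyped site. The two haplotypes' allele probabilities combine
   into genotype probabilities under conditional independence:
   P(G=0) = (1−p_a)(1−p_b), P(G=2) = p_a·p_b, P(G=1) the rest.

Genotype probability triples from post-burn-in sweeps are averaged with
equal weight. Because step 2 never feeds back into the phase chain, the
engine runs step 2 only on post-burn-in sweeps; the estimand is unchanged
and burn-in costs only phasing time. Typed sites whose input genotype is
missing are imputed the same way and reported separately.

The diploid filter runs over *ordered* template pairs (k² states with
emissions summed over the allele assignments consistent with the genotype).
Ordered pairs with symmetric emissions are marginally equivalent to the
unordered k²/2 parameterization and map directly onto k×k arrays; the
sampler's phase-configuration frequencies are validated against enumerated
posteriors by a χ² test.

### Chunking

The Hamming-distance approximations are motivated by local genealogies, so
analysis proceeds in non-overlapping 5-Mb core windows with 250-kb buffers
on each side (`make_chunks()`); only core results are reported
(`stitch()`). The buffer absorbs HMM edge effects: the copying chain
forgets its state at rate exp(−Σρ/K), so across a 250-kb buffer at
Ne = 20000 the influence of the truncated flank is negligible, and the test
suite checks that chunked and unchunked runs agree to 1e-6 at core sites.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `Ne` | 20000 | effective population size; scales genetic distance into switch rates. Accuracy is insensitive to it over a wide range, and 20000 works across human populations |
| `k` | 80 | templates per phasing update (cost ∝ k² per SNP) |
| `k_hap` | 500 | Hamming-nearest reference haplotypes per imputation update (cost ∝ k_hap); clamped to the panel size |
| `iterations` | 30 | total MCMC sweeps |
| `burnin` | 10 | sweeps discarded before averaging |
| `lambda` | derived | per-site copying-error probability; Watterson-style from the active template count unless overridden |
| chunk / buffer | 5 Mb / 250 kb | analysis window and edge-effect guard |

If no genetic map is supplied, a uniform 1 cM/Mb map is used and reported
with a message; positions are 1-based as in the input file formats.

## The synthetic-data generator

Real reference collections are restricted, so the package ships a seedable
generator (`sim_config()`, `simulate_panels()`,
`simulate_imputation_study()`) that emulates the structure the method
exploits:

- **Ancestral variation.** Per-site ancestral frequencies are drawn from a
  symmetric Beta(0.5, 0.5), skewing toward rare variants as site frequency
  spectra do; a shared pool of 20 ancestral founder haplotypes is sampled
  from these frequencies.
- **Population divergence.** Each population redraws whole founder
  *segments* (expected genome fraction = `split_depth`, the per-population
  divergence scalar) from Balding–Nichols-perturbed frequencies
  Beta(p(1−F)/F, (1−p)(1−F)/F). Segmental redraw mimics coalescent
  sharing: outside redrawn segments a diverged founder is identical by
  descent to the ancestral pool, so low-frequency alleles keep intact
  haplotype backgrounds across populations — the mechanism behind the
  cosmopolitan-panel benefit. At `split_depth = 0` populations are
  exchangeable. Realized pairwise F_ST grows monotonically with the depth
  (roughly with its square) and the defaults c(0.02, 0.06, 0.15) give
  F_ST in the 0.004–0.012 range on the default region.
- **Within-population haplotypes** are imperfect mosaics of the
  population's founders: founder switches at 0.001 per site (segments of
  ~1000 sites, a few hundred kb at the default 5 SNPs/kb — human-scale
  haplotype sharing) and copying errors at 0.002 per site. The first
  switch rate considered, 0.01/site, produced 20-kb segments — too short
  for array-density typed anchors to identify, and unrepresentative of
  panels of this size.
- **Ascertainment.** `ascertain_array()` thins sites to an array-like
  typed set (0.17 SNPs/kb, MAF-weighted, MAF ≥ 0.05), mirroring how
  genotyping arrays favor common SNPs. `ascertain_discovery()` models
  low-coverage sequencing discovery: a user-supplied non-decreasing curve
  maps the variant-allele count in each population's sample to a discovery
  probability, applied independently per SNP per population, with a SNP
  retained (in all panels) if discovered in any population. No default
  curve is claimed; the shape is study-specific.
- **Study samples** (`make_study()`) pair held-out haplotypes uniformly at
  random; truth is retained for evaluation.

The default desk-scale experiment uses 3 populations × 200 haplotypes over
2 Mb (about 10,000 SNPs, 340 typed), with 20 study individuals held out of
the first population — 600 reference haplotypes in total. These sizes keep
a full 30-sweep, k_hap = 600 run around half a minute on one core.

What the generator does *not* emulate: genuine coalescent genealogies
(mosaic segments have exponential, not genealogy-correlated, lengths),
recombination hotspots (the emitted map is uniform), genotyping error in
the study, indels or multiallelic sites, and ascertainment interactions
between array content and population. Passing tests therefore demonstrate
correctness of the inference machinery and qualitative behavior
(plateaus, panel-growth benefits, F_ST ordering), not absolute accuracy
levels on real data.

## Evaluation harness

`dosage()` is the posterior mean genotype P1 + 2·P2. `snp_r2()` is the
squared Pearson correlation between true genotypes and dosages across
individuals, with R² defined as 0 when either vector is constant — a SNP
imputed identically in everyone carries no association power. Masking
protocols: `leave_one_out()` masks the untyped sites of one individual at a
time (the held-out individual's phase is also masked) and imputes from all
other haplotypes; `every_nth_mask()` masks every n-th typed SNP in a
sliding window so every SNP is imputed exactly once. `maf_binned_summary()`
bins per-SNP R² into half-open MAF bins, with an optional MAF ≥ 1% filter
because rarer SNPs give unreliable per-SNP correlations; the count-weighted
bin means recombine exactly to the overall mean. MAF is always computed in
the validation (study) set.

`pairwise_fst()` uses Hudson's estimator as a ratio of averages across
SNPs, chosen for its low sample-size bias; only the ordering it induces is
consumed (to add reference panels in order of increasing divergence), which
limits sensitivity to the estimator choice. Sites monomorphic for the same
allele in both panels are skipped; negative estimates (possible for the
unbiased estimator on effectively identical panels) are truncated to 0.

## Numerical choices and degenerate inputs

- Forward/backward messages are rescaled per site; log-domain arithmetic
  is unnecessary because λ > 0 bounds emissions away from 0.
- Hamming-boundary ties are broken uniformly with the run RNG; selections
  are otherwise deterministic given the distances. Equal seeds give
  bit-identical pipeline outputs; chunk i of `impute_genotypes()` runs
  under `set.seed(seed + i − 1)` so chunks can be executed in any order.
- `k_hap` larger than the panel is clamped with a message (as is the
  convention when panels are smaller than the requested grid).
- A chunk with no typed sites is skipped with a warning. Monomorphic
  reference sites are kept; the HMM then emits the fixed allele with
  probability 1 − λ.
- Single-row genetic maps are valid and extrapolate as a constant;
  duplicate map positions collapse to the first occurrence.
- Study/reference site matching requires identical position and allele
  pair in either order; swapped pairs flip the genotype coding, and
  irreconcilable labels (e.g. A/T vs C/G at the same position) drop the
  site with a warning.

## Known limitations

Scenario coverage is deliberately narrow: one reference panel on one SNP
set (no multi-panel merging), autosomes only, biallelic SNPs only, no
pre-phasing mode, and no attempt at wall-clock parity with production
tools. Surrogate selections are recomputed every sweep; caching them after
early sweeps is a plausible speed-up left as future work.
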