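---
title: "Estimating recombination rates from pedigrees by multilocus iterative peeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating recombination rates from pedigrees by multilocus iterative peeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Livestock breeding programmes routinely genotype very large pedigrees on SNP
arrays of mixed density. Each offspring carries one maternal and one paternal
gamete, and every switch along a chromosome in *which* parental haplotype the
offspring inherited marks a meiotic crossover. Counting these switches over
many meioses yields genetic map lengths, sex-specific recombination
landscapes, and a per-parent recombination-rate phenotype that can be treated
as a quantitative trait. `peelrec` implements this inference for pig-style
pedigree data: tens to hundreds of thousands of animals, 3–6+ overlapping
generations, roughly 39% of animals genotyped at high density, 51% at low
density and 10% not at all.

## The model

### Genotype factors

For each individual and locus we track a probability distribution over the
four *ordered* genotypes (paternal allele, maternal allele) ∈ {aa, aA, Aa,
AA}. Three factors multiply into each distribution:

* **penetrance** — the individual's own dosage call under a symmetric
  genotyping-error model with rate ε: states whose dosage matches the call
  share 1 − ε, the remaining states share ε; a missing call is uninformative;
* **anterior** — evidence flowing from the parents: the probability that the
  father (mother) transmits allele A is the mixture of his (her) two
  haplotype alleles weighted by the offspring's segregation probabilities,
  and the two parental transmissions factorise into an outer product;
* **posterior** — evidence flowing from the offspring, rebuilt each cycle
  from offspring whose genotype *and* segregation have been called (see
  below): each such offspring multiplies the parent state by 1 − ε when the
  parent's haplotype carries the transmitted allele and ε otherwise.

### Segregation as a two-state Markov chain

Which parental haplotype an offspring inherits at a locus is a hidden state
with two values. Crossovers flip the state, so along a chromosome the state
follows a Markov chain whose transition probability in marker interval *j*
is the recombination fraction *r*<sub>j</sub>, obtained from the interval's
genetic length by the Haldane map function `r = (1 − exp(−2d/100))/2`
(Haldane matches the chain's memorylessness; no crossover interference is
modelled). Per-locus evidence compares the child's local likelihood with
each haplotype's transmitted-allele distribution, with an ε floor guarding
against conflicting calls. Exact smoothed marginals come from a scaled
forward–backward pass, and the expected crossover count in interval *j* is
the off-diagonal mass of the pairwise posterior over neighbouring states.
With uninformative data this expectation equals the prior *r*<sub>j</sub>
exactly — a property the test suite checks.

### Calling, and the two simplifications

The engine deliberately simplifies full joint peeling in two ways: (1)
segregation and anterior probabilities are computed separately per parent
rather than jointly, and (2) offspring genotype and segregation
probabilities are *called* — taken as certain — when they reach 0.90 and
0.99 respectively, and set to missing otherwise (missing means all states
equally likely downstream). Calling keeps the posterior a cheap product of
(1 − ε)/ε factors, implemented as per-state match counts, and damps
feedback between offspring with fractional segregation values. Thresholds
are compared with ≥, so a probability exactly at the threshold is called —
a deterministic boundary rule.

The costs of these simplifications are measurable and documented by tests:
on loci where the data leave phase genuinely ambiguous, the per-parent
factorisation can put small mass on jointly-impossible states (the imputed
dosage error vanishes linearly in ε), and in about 2% of individuals the
call/update feedback settles into a two-cycle oscillation rather than a
fixed point, so the early-stopping tolerance never fires and the engine
simply runs its cycle budget. Both effects are deterministic given inputs.

### Iterating the map

The joint distribution of segregation states depends on chromosome length,
which is itself unknown, so estimation alternates: run peeling cycles at
the current map, then set each interval to 100 × the mean expected crossover
count over the contributing gametes, recompute Haldane fractions, and
repeat. The iteration starts at 100 cM (one expected crossover) divided
uniformly over intervals and runs four times, after which lengths are
stable. Only gametes of individuals whose parents and all four grandparents
are genotyped contribute to map updates, mirroring the post-estimation
quality filter. Because the update works in expected-count units, the
all-missing fixed point at 100 cM is exact in recombination-fraction units
and drifts only by the Haldane second-order term `sum(d_j^2)/100` per
iteration in cM (< 0.1 cM at 1522 markers).

An alternative `mode = "total"` update rescales the whole map while keeping
relative spacing, for users who prefer to re-estimate only total length;
the interval-wise update is the default because landscape results need
interval resolution.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `genotype_error` | 0.01 | symmetric call-error rate ε (also the evidence floor) |
| `seg_call_threshold` | 0.99 | call a segregation state at this probability |
| `geno_call_threshold` | 0.90 | call an ordered genotype at this probability |
| `n_outer_cycles` | 5 | peeling cycles per map iteration |
| `convergence_tol` | 1e-4 | early stop on max genotype-probability change |
| `founder_prior` | `"allele_freq"` | Hardy–Weinberg at observed frequencies |
| `n_map_iterations` | 4 | map refinement steps |
| `init_length` | 100 cM | starting chromosome length |

The error rate, cycle count and stopping rule are package choices (five
cycles bounds runtime and matches common iterative-peeling practice; one
cycle moves information one generation, so five cover the pedigrees the
package targets). The founder prior defaults to Hardy–Weinberg at the
observed allele frequency because low-density animals are imputed partly
from population information; the uniform option exists for analyses of
designed crosses and for validation against enumeration, whose symmetry
arguments assume it.

## Post-estimation filters and phenotypes

`filter_informative()` keeps individuals whose two parents and four
grandparents are genotyped (a relaxed mode accepts one genotyped
grandparent per side, since requiring all four is a strict reading of
"genotyped parents and grandparents"). `filter_outliers()` removes
individuals whose average rate exceeds 5 cM/Mb (strictly greater; applied
to the mean of the individual's two gamete rates). Rates use the physical
span of the marker map (last minus first position, summed over
chromosomes) as the denominator, so they are comparable without assembly
lengths. `gametes_to_parent_phenotypes()` then turns each retained
offspring into one repeated observation for its dam and one for its sire.

## The validation simulator

`simulate_dataset()` generates the study conditions end to end:

* a discrete-generation pedigree (default 600 founders + 4 generations of
  630, ≈ 3100 individuals) with polygynous matings — 9 sires and 90 dams
  per generation, litters of 7 — preserving the roughly 1:10 sire:dam ratio
  and ~70 offspring per sire of large pig lines while staying desk-sized;
* founder haplotypes from a seeded Markov model: per-locus allele
  frequencies uniform on (0.1, 0.9) (array-like, common variants), each
  haplotype copying its previous allele with probability 0.7, which gives
  blockwise association decaying with distance as a stand-in for population
  linkage disequilibrium;
* a designed landscape: constant rate over the middle 30–70% of the marker
  map and, on each end, a second-degree polynomial rising continuously from
  the middle rate to 3× at the terminal interval (the elevation is a
  package choice; continuity plus a single end multiplier fully determines
  each quadratic), rescaled to an exact total — default 90 cM male (a
  mid-sized pig autosome) with the female map 1.3× the male everywhere;
* meioses as independent Bernoulli crossovers per interval (consistent
  with the estimator's no-interference chain), with every crossover
  location recorded as truth;
* mixed-density observation: 39% of animals see all 1522 loci, 51% see an
  evenly spaced quarter of them (the low:high array-size ratio), 10% none;
  observed calls are error-free by default, since the validation design
  contains no genotyping error (the estimator still assumes ε = 0.01).

What the simulator does *not* emulate: coalescent founder structure (the
Markov-LD founder model is a deliberate, documented replacement), selection
and overlapping generations, genetic variation in recombination rate
between individuals, crossover interference, and the X chromosome. Passing
accuracy tests on these data therefore demonstrates that the estimator
recovers crossover counts and landscapes *under its own model assumptions
at desk scale* — not that real-data map lengths or heritabilities are
reproduced, which require the original proprietary pedigrees.

## Accuracy accounting

`accuracy_metrics()` correlates true with estimated crossover counts either
per gamete or per parent (`aggregate = "parent"`, the default reporting in
the acceptance script). The per-parent view averages each dam's or sire's
gametes into the repeated-observation phenotype; because a sire's many
offspring share the sire's phase errors, the per-parent mean attenuates
much more for sires than for dams, which is why sire accuracy is expected
to be substantially lower — and why, with only ~27 sires in a desk-scale
pedigree, the sire correlation carries a sampling error of roughly ±0.2.
Landscape accuracy is the correlation between true and estimated
per-interval totals, raw and averaged in non-overlapping 50-SNP windows
(a centred rolling variant is available; the non-overlapping one is used
for reporting).

## Worked example

```{r, eval = FALSE}
library(peelrec)

cfg <- sim_config(n_founders = 100, n_generations = 4, dams_per_gen = 20,
                  sires_per_gen = 4, offspring_per_dam = 6, n_loci = 300,
                  total_length_male = 90, seed = 11)
ds <- simulate_dataset(cfg)
fit <- estimate_recombination(ds$pedigree, ds$genotypes, ds$marker_map)

map_length(fit$map_male[[1]])    # estimated male map, cM
map_length(fit$map_female[[1]])  # estimated female map, cM

pan <- attr(ds$genotypes, "panel")
keep <- filter_informative(ds$pedigree, names(pan)[pan != "ungenotyped"])
acc <- accuracy_metrics(ds$truth, fit$estimates,
                        exc_by_interval = rbind(fit$exc_pat[[1]],
                                                fit$exc_mat[[1]]),
                        ids = keep, aggregate = "parent")
acc$per_individual
acc$landscape
```

## Numerical choices and degenerate inputs

* All per-locus distributions are renormalised after every multiplication;
  forward–backward uses per-locus rescaling, and every reported quantity is
  invariant to evidence scaling.
* An all-zero factor product (conflicting evidence, possible only with
  pathological inputs since ε > 0 keeps penetrances positive) falls back to
  the penetrance alone with a warning.
* Posterior products over many offspring are stored as per-state match
  counts and exponentiated with a per-locus max shift, so sires with
  hundreds of offspring cannot overflow.
* Individuals are processed in generation order (parents before offspring),
  which fixes the update order and makes every result deterministic given
  inputs, parameters and seed.
* Founder allele-frequency priors are clamped to [0.01, 0.99] to stay
  proper at monomorphic loci.
* Ties at calling thresholds are called (≥); ties between equal maximal
  genotype probabilities resolve to the first state index.

## Known limitations

* Pedigree-scale phase information cannot localise crossovers below the
  marker spacing; per-marker landscape correlations are accordingly modest
  (~0.6) while 50-SNP-window correlations are high.
* The per-parent factorisation and calling are approximations; exact
  equivalence with full Bayesian-network enumeration holds in
  near-deterministic regimes (tiny ε, tight linkage — verified by the
  enumeration tests) but not for arbitrarily uncertain data.
* Map lengths inherit an attenuation/inflation trade-off: expected switch
  counts are recombination frequencies, so very sparse maps would
  underestimate cM; at array densities the effect is below 0.1%.
* No X chromosome, no interference, no hotspot-scale resolution.

## Scale of the shipped analyses

The test suite and the acceptance script run the full validation design at
one chromosome × 1522 SNPs × ≈3100 individuals (about 7 minutes), plus
enumeration oracles on ≤ 4 individuals × ≤ 12 loci and moment checks at
5000 meioses. These sizes were chosen so every shipped analysis re-runs
from scratch on a single CPU.
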