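---
title: "Simulating genomic optimum-contribution selection with alternative relationship matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic optimum-contribution selection with alternative relationship matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the simulator answers

Genomic optimum-contribution selection (GOCS) chooses how many offspring
each selection candidate contributes so as to maximize genetic gain while
penalizing the average genomic relationship of the selected parents — the
quantity that becomes next-generation inbreeding. Two distinct roles are
played by a genomic relationship matrix in this machinery: predicting
breeding values (G-BLUP) and measuring coancestry for the penalty. Nothing
forces the same matrix into both roles. `gocsim` simulates closed breeding
schemes in which the prediction matrix is built from markers (`G_M`), from
the causal QTL (`G_Q`), or from both (`G_A`), while coancestry is
controlled with `G_M` or `G_A`, and reports rates of genetic gain, rates of
true (IBD-measured) and pedigree inbreeding, and prediction accuracies.

The interesting regime is a trait governed by few QTL: a QTL-based matrix
then captures the trait-relevant covariance far better than markers can
through linkage disequilibrium, and a marker-based coancestry penalty
leaves QTL-region allele frequencies freer to move. Both effects favor the
`Q_M` combination (predict with `G_Q`, constrain with `G_M`).

## Model components

### Founder population

A Wright–Fisher population of 50 animals (25 of each sex, parents drawn
with replacement) is simulated for a configurable number of discrete
generations under:

* **mutation** — each gamete converts never-mutated candidate loci to the
  derived allele with per-locus probability `mutationRate`; a locus is
  QTL-class with probability `qtlFraction` (1/8, the 1:7 QTL:marker
  ratio). This is an infinite-sites-like model per locus: recurrent and
  back mutation are ignored, and a locus that loses its derived allele is
  not returned to the mutable pool.
* **recombination** — the genome-wide crossover count is Poisson with mean
  equal to the map length in Morgans (30.06 at full scale: 18 chromosomes
  of 167 cM), positions uniform, no interference, and a fair coin for the
  starting haplotype of each chromosome.
* **mild directional selection** — the `ceiling(0.05 N)` offspring with the
  lowest true breeding value are culled and replaced by freshly sampled
  offspring in a single pass (replacements are not re-culled; ties are
  broken at random).

QTL effect magnitudes are exponential with mean 1 and are positive with
probability 0.1, so sustained selection mostly purges deleterious variants.
Loci fixed for the derived allele are dropped: a fixed QTL adds the same
constant to every breeding value and affects no downstream contrast.
Haplotypes are stored sparsely (sets of derived-allele locus ids), since a
dense matrix over 3×10⁷ candidate loci would be prohibitive; dense 0/1
matrices are materialized only for the segregating loci carried into a
breeding scheme, and the test suite verifies that the two representations
transmit identically.

### Trait model and standardization

TBV is the sum over trait QTL of mutant-allele dosage times effect. The
trait architecture keeps all segregating QTL or a uniform random subset
(e.g. 500); effects are then rescaled by a single scalar so that the
*population* variance (divide by n, a documented convention — the paper-scale
reference set of 50 founders makes the n vs n−1 choice visible in the 10th
decimal only) of TBV over the founder generation-0 animals equals 1.
QTL dropped by subsampling cease to exist for the trait and are excluded
from every relationship matrix, including `G_A`. Phenotypes add Gaussian
noise with variance 4, giving heritability 0.2.

### Base population and IBD tracers

Each replicate samples a base population (10 males, 100 females at full
scale) from the founder chromosome pools: per chromosome, two haplotypes
without replacement, pool restored before the next animal. Base animals are
genotyped but not phenotyped. Neutral IBD tracer loci (4/cM at full scale,
12,024 loci; placed at midpoints of the uniform tracer grid) receive 2n
distinct labels across the 2n base haplotypes and recombine jointly with
all other loci in the same meiosis; they never enter a relationship matrix
or a GEBV. An animal's true inbreeding coefficient is the fraction of
tracer loci at which its two labels coincide.

### Relationship matrices

All matrices use the centered-and-scaled cross-product
`G = W D⁻¹ W′ / L` with `D_ii = 2 p_i (1 − p_i)`, where `p_i` is the
derived-allele frequency among the base animals, computed once and frozen.
Centering and 2p(1−p) scaling are invariant to which allele is called
"minor", so using the derived-allele frequency is equivalent to the
minor-allele convention. Loci monomorphic in the base are excluded (their
`D` entry is zero); loci that become monomorphic later are retained — their
centered column is constant and harmless. The matrix grows incrementally as
generations are genotyped; extension is algebraically identical to
recomputation and is tested to 10⁻¹².

### G-BLUP

Breeding values are predicted from `y = 1μ + Zg + e` with
`Var(g) = G σ²_g`, `Var(e) = I σ²_e`, at the true simulation variances
(σ²_g = 1, σ²_e = 4; a configuration hook accepts other values). The solver
works in the observed-data form: `V = σ²_g G_rr + σ²_e I` is always
positive definite even when `G` is rank-deficient (as `G_Q` is with few
QTL), μ̂ is the GLS mean, and every genotyped animal receives
`ĝ = σ²_g G[, r] V⁻¹ (y − 1μ̂)`. Records accumulate from generation 1
onward; candidates are phenotyped before selection, so their own records
inform their GEBVs.

### Optimum contributions

The objective is `U(c) = c′ĝ − w·c′Gc`. The penalty weight `w ≥ 0`
multiplies the average relationship of the selected parents; published
penalty values quoted as −50, −25, −10, −5 follow the optimizer convention
in which the minus sign is carried by the formula, and correspond to
`w = 50, 25, 10, 5` here — a genuinely negative weight would reward
inbreeding and contradict the design.

The mating structure fixes the feasible set: male `i` receives an integer
number of matings `m_i` with `Σ m_i = 25` and contributes
`c_i = m_i / 50`; exactly 25 dams are selected, one mating each. Dam
selection is part of the search space, not a pre-truncation. Selected
sires (expanded by mating count) are paired with the dams by a random
permutation and each mating produces 20 offspring.

Two solvers are provided. The continuous relaxation maximizes `U` under
the per-sex sum constraints and `c ≥ 0` with a primal active-set method
(drop the most negative candidate, re-admit any zeroed candidate with a
positive reduced gradient); it is verified against an exhaustive
enumeration of all zero-sets, which visits every KKT face of the
polyhedron. The integer problem is solved by a small evolutionary
algorithm over (mating vector, dam subset): tournament selection, uniform
crossover with repair of the mating sum, and mutations that move one
mating or swap one dam. The initial population contains the rounded
continuous solution and a truncation-selection plan, and elitism keeps the
best two plans, so the returned objective can never fall below either
reference; on tiny instances the EA's optimum equals exhaustive
enumeration. All searches are deterministic given the R seed.

`calibrateOmega()` bisects `log(w)` against the realized rate of true
inbreeding, which decreases monotonically in `w`, averaging a configurable
number of replicates per evaluation and reporting the achieved rate with
its standard error; unreachable targets are reported with the achieved
extremes rather than extrapolated.

### Scheme orchestration

One replicate runs eleven generations: random mating of the base (each
dam mated once to a uniform random sire, exact equal sex ratio), truncation
selection on GEBV in generations 2–5 (10 sires; 100 dams at full scale;
exact equal sex ratio), and GOCS in generations 6–11 (offspring sex is
Bernoulli(0.5), as specified for this phase — the two phases intentionally
differ). Truncation ties are broken by (GEBV descending, id ascending).
Rates of gain are OLS slopes of cohort-mean TBV on generation over 6–11;
rates of inbreeding are `1 − exp(β)` with `β` the slope of `log(1 − F_t)`;
accuracies are Pearson correlations between GEBV and TBV for the
generation-11 candidates, split by sex. Replicates are bitwise reproducible
from one master seed, from which all stream seeds derive.

## Design choices that were genuinely open

* **Which matrix drives the truncation phase.** The truncation generations
  exist only to create a population with a selection history; the original
  description does not say which matrix produced those GEBVs. `runScheme()`
  defaults to the scenario's own prediction matrix, but the experiment
  runner sets a common marker-based driver (`truncPredSource = "M"`) for
  every scenario: paired-seed replicates then share generations 1–5
  exactly and differ only in the OCS phase, which is the contrast of
  interest. At reduced scale this also avoids exhausting the small QTL
  pool before the OCS phase begins.
* **Matched inbreeding for scenario contrasts.** Scenarios compared at the
  same penalty share the coancestry matrix `G_M`, and their realized rates
  of true inbreeding agree within replicate noise; the directional
  comparison therefore uses a common fixed penalty rather than a separate
  calibration per scenario — conservative for the QTL-prediction scenario,
  which tends to realize equal-or-lower inbreeding at the same penalty.
  `calibrateOmega()` remains available when a specific target rate (1% or
  0.5%) is required, though at reduced scale the penalty-to-inbreeding
  response is noisy enough that calibration needs many replicates per
  evaluation.
* **One founder or several.** A single founder realization can carry a
  QTL pool dominated by rare alleles whose variance is exhausted before
  the OCS span. The reproduction script therefore averages its scenario
  contrast over several independent founder realizations with paired
  base-population replicates inside each, which marginalizes the founder
  draw; the test suite keeps the single-founder design with paired seeds.
* **Random-selection control.** The control used to validate the
  transmission machinery is a random-union step: 25 sires and 25 dams
  drawn at random, every offspring drawing its parents uniformly with
  replacement from that set. This realizes Poisson-like family
  contributions, the assumption behind the classical
  `ΔF = 1/(8·25) + 1/(8·25) = 0.01`; a one-mating-per-parent control
  suppresses contribution variance and realizes measurably less.
* **Culling arithmetic.** "Approximately 5%" is `ceiling(0.05 N)` lowest-TBV
  animals, replaced once without re-culling.
* **Subsampled QTL** are excluded from all matrices rather than
  reclassified as markers; the locus ceases to exist for the study.

## The reduced preset, and what it can and cannot show

Full scale (3×10⁷ candidate loci, 1000 founder generations, hundreds of
replicates) is cluster work. The reduced preset keeps every structural
ratio while shrinking sizes: 2 chromosomes × 100 cM with 100 candidate
loci/cM, mutation rate 4×10⁻⁵, 200 founder generations, 1 IBD tracer/cM,
base 10 males + 50 females, 150 offspring per generation (truncation:
10 sires × 3 dams × 5 offspring; OCS: 15 matings × 10 offspring). One
replicate runs in seconds on one CPU; the test suite and the acceptance
script use this preset with ~10–30 replicates per question.

At this scale the founder equilibrium holds a few hundred segregating loci
and a few dozen segregating QTL — a *moderate-QTL* architecture in which
the QTL-based matrix is strongly advantaged, matching the regime where the
full-scale study sees its largest contrasts. What the reduced runs
demonstrate is *direction*: `Q_M` attains a higher rate of gain than `M_M`
at a matched realized rate of true inbreeding, and higher prediction
accuracy. Magnitudes (rates near 0.1–0.3 trait units per generation,
inbreeding rates above the full-scale 1% target, accuracies near the
ceiling for `G_Q`) are properties of the small genome and cohort sizes and
are not comparable to full-scale numbers. A caveat specific to this scale:
a replicate can nearly exhaust its QTL variance by generation 11, and the
accuracy correlation over such a cohort is unstable — the gain and
accuracy comparisons are therefore read as paired directional contrasts,
with the formal one-sided test applied to the rate of gain. Features of real data the
generator does not emulate at all: sequence context, genotyping error,
non-additive gene action, overlapping generations, and selection on
multiple traits.

## Numerical notes

* The G-BLUP solver never inverts `G`; with `σ²_e > 0` the observed-data
  system is well conditioned regardless of the rank of `G`.
* The continuous OCS active-set system can be singular when the candidate
  submatrix is (e.g. many identical full sibs); a documented ridge of
  `10⁻⁸·mean(diag(2wG))` is then applied with a warning.
* Contribution feasibility (`Σ c = 1/2` per sex, integer mating counts,
  25 distinct dams) is asserted by the tests on every returned solution.
* Degenerate inputs fail loudly: zero segregating loci after the founder
  run, all loci monomorphic in the base, dosages outside {0,1,2},
  phenotypes that are not finite, `F = 1` in the inbreeding-rate
  regression.
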