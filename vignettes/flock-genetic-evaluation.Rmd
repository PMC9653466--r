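---
title: "Genetic evaluation of pedigreed sheep flocks with flockBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic evaluation of pedigreed sheep flocks with flockBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockBLUP)
```

## The problem

Organized sheep farms keep animal registrations, body weights at standard
ages, wool measurements, and lambing/health/disposal events, but breeding
decisions are often made from the most recent record alone. flockBLUP turns
such flat-file ledgers into the standard machinery of pedigree-based
genetic evaluation: who is related to whom and how much (the numerator
relationship matrix and inbreeding), how heritable each trait is in this
flock (sib analysis and REML), which animals carry the best genes (BLUP
breeding values), and how to weigh several traits into one ranking
(selection indices with economic weights). A flock simulator with known
genetic parameters backs every estimator with ground truth.

## The data model

A `flock_dataset` bundles four tables: `animals` (identity, parents, sex —
`MALE`, `FEMALE`, or `WETHER` for castrates — breed, farm, birth/entry/
disposal dates), `traits` (coded records: `BWT`, `WWT`, `W6M`, `W9M`,
`W12M` in kg, `GFY` in kg, `FD` in µm, `SL` in cm), `repro` (matings with
outcome and lamb ids), and `health` (vaccination, deworming, treatment,
castration). Files use ISO-8601 dates; an unknown parent may be an empty
cell or a literal `"0"` on input and is always written back as empty, so
round trips are byte-stable. When the entry date is absent it defaults to
the birth date (on-farm births dominate). Validation (`validate_flock()`)
reports findings as data — dangling references, sires that are not male,
dams that are not female, values outside configured plausibility bounds,
events before birth — rather than failing on the first problem.

One convention deserves emphasis because every inventory depends on it: a
disposal on date *d* removes the animal from snapshots with `as_of >= d`,
i.e. the animal is present through the day before disposal. Farm records
rarely state whether the disposal day itself counts; we fixed the exclusive
convention once and documented it in the CLI help. Similarly, a
`CASTRATION` event reclassifies a male as a wether in all later snapshots.

## Pedigree algebra

`build_pedigree()` topologically sorts animals so parents precede
offspring (cycles are reported with the offending ids; parent ids that
never appear as animals are demoted to unknown with a warning). On the
sorted pedigree:

* `amatrix()` applies the tabular recurrences
  $a_{ij} = \tfrac12 (a_{j,s(i)} + a_{j,d(i)})$, $a_{ii} = 1 +
  \tfrac12 a_{s(i),d(i)}$, with unknown-parent terms contributing zero.
* `inbreeding()` computes $F_i = \tfrac12 a_{s(i),d(i)}$ without forming
  A, by the Meuwissen–Luo ancestor sweep: $a_{ii} = \sum_j L_{ij}^2 D_j$
  with Mendelian-sampling variances $D_j$. Animals with any unknown parent
  are treated as non-inbred founders — the conventional default; explicit
  unknown-parent groups are out of scope.
* `inbreeding_wright()` enumerates sire→ancestor→dam paths and sums
  $(\tfrac12)^{n+1}(1+F_A)$ over paths with $n$ segregations. Path
  enumeration is exponential, so it is guarded (≤ 25 ancestors per side)
  and serves only as the independent oracle for `inbreeding()` in the
  tests; the recursive route is the production path.
* `ainverse()` builds the sparse $A^{-1}$ the mixed-model equations need,
  via the per-animal rank-one updates with
  $d_i = \tfrac12 - \tfrac14 (F_s + F_d)$ (adjusted when parents are
  unknown). A dense A is refused above 5,000 animals; $A^{-1}$ stays
  sparse at any size used here.

## Heritability

Two estimation routes are provided, mirroring how such toolkits are used in
practice.

**Sib analysis.** `nested_anova()` partitions phenotypic variance into
between-sire / between-dam-within-sire / within-dam strata. Unbalanced
designs use the expected-mean-square coefficients
$k_1 = (N - \sum_{ij} n_{ij}^2/n_{i\cdot})/(D-S)$,
$k_2 = (\sum_{ij} n_{ij}^2/n_{i\cdot} - \sum_{ij} n_{ij}^2/N)/(S-1)$,
$k_3 = (N - \sum_i n_{i\cdot}^2/N)/(S-1)$, which collapse to $(n, n, dn)$
in a balanced $s \times d \times n$ design. Components follow as
$\sigma^2_w = MS_w$, $\sigma^2_d = (MS_d - MS_w)/k_1$,
$\sigma^2_s = (MS_s - MS_w - k_2\sigma^2_d)/k_3$; negative solutions are
truncated to zero and flagged (standard practice — the raw values stay
available as an attribute). `h2_from_anova()` then reports
$4\sigma^2_s/\sigma^2_p$, $4\sigma^2_d/\sigma^2_p$ or
$2(\sigma^2_s+\sigma^2_d)/\sigma^2_p$, raw and clamped to [0, 1]. The dam
component absorbs maternal and dominance variance when present, which is
why the sire form is the default selection-relevant estimate. Phenotypes
may optionally be pre-adjusted by fixed-effect subclass means
(`sib_design(adjust_fixed = )`); this is off by default.

**Animal model.** `reml_animal()` estimates $(\sigma^2_u, \sigma^2_e)$ by
EM-REML on Henderson's equations: at each step the MME are solved at the
current ratio, then
$\sigma^2_u \leftarrow (\hat u' A^{-1} \hat u + \sigma^2_e\,
\mathrm{tr}(A^{-1} C^{uu}))/q$ and
$\sigma^2_e \leftarrow (y - X\hat b - Z\hat u)'y/(n - \mathrm{rank}(X))$,
where $C^{uu}$ is the random-effect block of the inverse coefficient
matrix (computed via the Schur complement, so each iteration costs one
$q \times q$ Cholesky). Both updates are non-negative by construction, so
the iteration cannot leave the parameter space; convergence is declared at
relative changes below `tol` (default 1e-6, `maxit` 200; the recovery
studies use 500 because EM crawls near weakly identified optima). Sex and
year (of the record date) are fixed effects, coded as a global mean plus
treatment contrasts dropping the alphabetically first level; a farm factor
joins automatically when records span more than one farm; single-level
factors are dropped with a message. A deliberate design choice: one random
unit is fitted at a time (the animal, through $A^{-1}$, or the sire as an
unrelated-sires model). Fitting animal, sire and dam effects
simultaneously is not identifiable without structure we do not have, and a
deterministic REML point estimate is all the downstream evaluation
consumes — a Monte-Carlo sampler would add diagnostics without changing
the decision.

## BLUP breeding values

`lambda_from_h2()` converts heritability into the shrinkage ratio:
$(1-h^2)/h^2$ for the animal model, $(4-h^2)/h^2$ for the sire model
(the sire's random effect is a transmitting ability, a quarter of the
additive variance). Both models are exposed because flock reports cover
all animals (animal model, the default) while the classical ratio printed
with the equations is the sire-model one. `assemble_mme()` forms the
blocks exactly — no centering or scaling of $y$ — and `solve_mme()` uses a
direct sparse solve; with full-rank fixed effects and $\lambda > 0$ the
system is nonsingular, so solutions are unique and bit-stable, and
$\hat u$ is invariant to the fixed-effect constraint. Unrecorded ancestors
receive predictions through $\lambda A^{-1}$ alone. Repeated records per
animal are allowed (no permanent-environment effect is fitted — none is
derivable from the record schema). With unrelated animals, single records
and a mean-only model, the solutions collapse to
$\hat u_i = h^2 (y_i - \hat\mu)$, the deviation form of individual
selection — a reduction the tests verify numerically, bridging the two
EBV methods. Note the scale difference: `individual_ebv()` returns
$P_m + h^2(P_i - P_m)$, a value on the trait scale, while BLUP solutions
are deviations; both are reported as defined, without invented rescaling.

## Selection indices and economic values

`selection_index()` computes $I = \sum_i v_i\,\mathrm{EBV}_i$ exactly,
excluding (with a message) animals missing any index trait. Weights
default to relative economic values but are overridable per farm. The full
Hazel machinery $b = P^{-1}Gv$ is deliberately out of scope; the weighted
sum over BLUP-EBVs is the design point. Economic values: body weight uses
(book value / trait mean) / days-to-attain × survivability — whether
"book value" is per animal or per kg is the caller's contract, since the
formula is used verbatim; fleece weight uses (book value / days) × mean
fleece weight; wool quality traits use the simple-regression slope of
price per kg on fibre diameter or staple length, unnormalized (no scaling
per genetic standard deviation is applied). The regression is ordinary
least squares, which satisfies the point-slope identity
$y - \bar y = a(x - \bar x)$ through the mean point. Survivability is a
supplied configuration value; `survivability_from_records()` can compute
(alive at target age)/(born) from the ledger when preferred.

## The breeding-value network

The predictor is a deliberately small dense network — 5 features → 4
hidden layers of 10 tanh units → linear output, ~400 parameters — trained
by mini-batch Adam (learning rate 0.001, β₁ 0.9, β₂ 0.999, ε 1e-8, batch
10, 500 epochs, 20% validation split). At this size a framework graph
would be pure overhead, so the forward/backward passes are plain matrix
code (C++ via Rcpp), with *all* randomness — Glorot-uniform
initialization, the validation split, every epoch's shuffle — drawn from
R's seeded RNG, making training bit-reproducible. Data preparation drops
rows with missing fields, removes rows with any feature or label beyond 3
standard deviations, drops constant columns, and fits z-score scalers on
the training portion only. The held-out 20% test split is our protocol
decision (a validation split alone cannot yield an honest test
correlation). By default the weights of the epoch with the lowest
validation MSE are kept (`restore_best`) — the purpose of a validation
split — which matters on noisy labels where late epochs overfit;
`restore_best = FALSE` recovers plain final-epoch training. Metrics are
Pearson r (also rendered ×100, the common reporting style), MAE, MSE and
RMSE. Divergent training (non-finite loss) raises an error advising a
lower learning rate.

## The flock simulator

`simulate_flock()` emulates a small multi-farm breeding operation under
the additive infinitesimal model: founder breeding values
$a \sim N(0, h^2\sigma^2_p)$; offspring
$a = \tfrac12(a_s + a_d) + m$ with
$m \sim N(0, \tfrac12\sigma^2_A(1 - \tfrac12(F_s+F_d)))$ — the parental
inbreeding correction makes consistency with the A-matrix a testable
theorem rather than an assumption; phenotypes
$y = \mu + \text{sex} + \text{year} + a + e$. Defaults describe a
mid-sized farm network: 10 founder sires over 50 dams (sires reused across
dams, creating half-sib families), 3 generations, 2 lambs per dam per
cycle, $h^2 = 0.3$ and $\sigma^2_p = 25\,\mathrm{kg}^2$ around a 30 kg
yearling mean, a +2 kg male advantage, mild year trends, two farms, 90%
survival to 12 months. Mating is random within the parental generation,
which excludes parent–offspring pairs by construction;
`allow_close_mating = TRUE` widens the pool across generations for
inbreeding-focused fixtures. Yearling weight (`W12M`) is the genetically
modelled trait; birth weight carries a small correlated share of the same
merit; wool traits appear only phenotypically in the market simulator —
sufficient for every algorithm exercised here. What the simulator does
*not* emulate: selection across generations (matings are random),
maternal effects, litter-size genetics, genotype–environment interaction,
and seasonality beyond one lambing per year. Passing recovery tests on
these data therefore demonstrate algorithmic correctness under the stated
model, not robustness to real-world violations of it.

## Numerical choices and scales

Degenerate inputs fail loudly and specifically: all-equal phenotypes
(`TOTAL_VARIANCE_ZERO`), designs with no full-sib replication (zero
within-dam df), non-nested dams, degenerate regressors, constant labels.
Ranking ties break by ascending animal id and ranks are dense, so outputs
are reproducible byte for byte; report CSVs carry metadata in
`#`-comment lines so golden-file comparisons ignore timestamps. The
recovery studies in the test suite use problem sizes chosen to make
Monte-Carlo error small relative to the tolerance while keeping the suite
quick on a laptop: 200 pedigrees of ≤ 15 animals against the kinship and
path-counting oracles, 100 random mixed-model systems against the
GLS/V-matrix closed form, 200 sib-design replicates of 100 sires × 3 dams
× 4 progeny, 20 animal-model replicates of ~500 animals, and one
2500 × 5 network table with a planted signal fraction of $R^2 = 0.7$ —
at which the attainable test correlation is about
$\sqrt{0.7} \approx 0.84$, and the trained network reaches ≥ 0.8.

## Known limitations

Heritability standard errors, multi-trait REML and maternal genetic
effects are not estimated; EBV reliabilities (prediction-error variances)
are not reported; genomic relationship matrices and unknown-parent groups
are out of scope; the wool economic value is a raw market slope, not a
discounted gene-flow calculation. The CLI is a thin wrapper over the
exported functions — database storage, web forms and user management
belong to a different layer.
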