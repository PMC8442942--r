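---
title: "Methods: multi-country maternal-effects BLUP in amaci"
author: "amaci authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-country maternal-effects BLUP in amaci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`amaci` implements pedigree BLUP for an international weaning-weight
evaluation under a multi-trait animal model with maternal effects, in which
each country is a separate, genetically correlated trait (the AMACI model).
For country $i$,

$$y_i = X_i b_i + C_i r_i + Z_i u_i + W_i m_i + P_i pe_i + e_i,$$

with fixed effects $b_i$ (by default contemporary group and sex), optional
IID random environmental effects $r_i$, direct breeding values $u_i$,
maternal breeding values $m_i$ carried by the dam of each recorded calf,
the dam's permanent-environment effect $pe_i$, and residuals $e_i$. No
animal is recorded in more than one country, so residuals, environmental
effects and PE effects are block-diagonal by country. The joint genetic
covariance is the Kronecker structure

$$\mathrm{var}\begin{bmatrix} u \\ m \end{bmatrix} = G \otimes A,
\qquad G = S\,\Phi\,S,$$

where $A$ is the numerator relationship matrix, $\Phi$ the
$2n \times 2n$ across-country correlation matrix over the $n$ direct and
$n$ maternal country-traits, and $S$ the diagonal matrix of national
genetic standard deviations. Building $G$ from national variances keeps
each country's published genetic variance untouched whatever happens to
the correlations — including bending, which only ever operates on the
correlation scale.

## Assumptions

* Unknown parents are unrelated base-population animals; no genetic groups
  or phantom-parent grouping is fitted.
* Inbreeding enters the Mendelian-sampling variances of $A^{-1}$
  (Meuwissen-Luo accumulation); a flag can disable it.
* Records with an unknown dam keep their direct term but drop the
  maternal-genetic and PE terms; no phantom dams are created.
* Maternal PE levels exist only for dams appearing in a country's records,
  and a country may omit the PE effect entirely (the DEU-style national
  model).

# Scenarios and bending

Four correlation structures are supported as masks on $\Phi$: `REF` keeps
every estimated correlation; `CUR` zeroes only the between-country
direct-maternal correlations (the off-diagonal of the direct-maternal
block); `NONE` zeroes the whole direct-maternal block; `NAT` zeroes every
between-country correlation, which makes the model mathematically
equivalent to independent single-country evaluations — an equivalence the
test suite checks numerically against eight separate runs.

A masked matrix can lose positive definiteness. `bendUnweighted()`
eigendecomposes, replaces eigenvalues below the threshold (default `1e-3`)
by the threshold, reconstructs, rescales to unit diagonal, and iterates
until the minimum eigenvalue reaches the threshold. Bending is applied to
the whole matrix, not per block. Two open choices were settled as follows:

* *Eigenvalue replacement rule.* Deficient eigenvalues are set to the
  threshold itself. This keeps the previously zeroed entries close to zero
  after bending, which is the behaviour wanted of the `CUR` structure.
* *Convergence test.* Iterate until `min(eigenvalue) >= threshold * (1 -
  1e-6)`, with an iteration cap that raises an error reporting the
  minimum eigenvalue.

The packaged correlation table is printed to two decimals, and rounding at
that precision perturbs the spectrum by roughly 0.01-0.02 — the unmasked
reference matrix itself has a slightly negative minimum eigenvalue. Two
consequences, verified in the test suite: the evaluation bends the printed
matrix even under `REF`, and bent entries can differ by up to about 0.02
from values published for unrounded estimates. The synthetic-data
generator likewise bends a non-PD input correlation matrix before drawing
breeding values, while handing the original matrix to the evaluation side.

# Solving the mixed-model equations

`assembleMME()` keeps the coefficient matrix in operator form: a sparse
matrix holds every record, environmental and PE contribution, while the
genetic precision $A^{-1} \otimes G^{-1}$ is applied through
$(A^{-1} \otimes G^{-1})\,\mathrm{vec}(V) = \mathrm{vec}(G^{-1} V A^{-1})$
with the genetic equations ordered animal-major. A matrix-vector product
then costs a sparse product plus two small dense multiplications, instead
of touching the $256 \times nnz(A^{-1})$ nonzeros an explicit Kronecker
product would carry. `mmeMaterialize()` builds the explicit sparse matrix
for desk-scale oracles and reliabilities, behind a size guard.

`solvePCG()` uses preconditioned conjugate gradients with a block-Jacobi
preconditioner: one inverted $2n \times 2n$ genetic block per animal
(its $A^{-1}_{aa} G^{-1}$ prior plus the record contributions to its own
equations) and scalar inverses elsewhere. The stopping criterion is the
square root of the relative difference between solutions of two
consecutive iterations, default `1e-7`; the relative residual of the
normal equations is computed at exit and reported alongside, not used for
stopping. Fixed effects are kept full rank by treatment-coding every
fixed factor after the first within each country, so dense Cholesky
factorizations of the materialized system exist and PCG needs no
projection step.

## Reliabilities

`computeReliability()` inverts the materialized coefficient matrix and
returns $REL = 1 - PEV/\sigma^2_g$ per animal, country scale and effect.
This is exact and $O(n^3)$, hence guarded to desk scale. By default the
denominator is the national genetic variance; since an animal's prior
variance is really $(1+F)\sigma^2_g$, uninformed inbred animals then show
small negative raw values, which are clamped to zero. The
`adjustInbreeding` flag switches the denominator to $(1+F)\sigma^2_g$,
which is the definition consistent with comparing group mean reliability
against the squared correlation with true breeding values; the package
default stays unadjusted.

# LR validation and re-ranking reports

`rhoPW()` is the Pearson correlation between EBVs of a partial and a whole
evaluation, computed from explicitly centered cross-products; it estimates
the ratio of population accuracies, and `accuracyIncrease()` converts it
to the percent gain $(1/\rho - 1)\cdot 100$. `dispersionB()` is the slope
of the regression of whole on partial EBVs. `lrReport()` generalizes
"partial/whole" to any ordered scenario pair; pairs involving `NAT` are
evaluated per country on the domestic set (animals with an own record in
the country or any ancestor recorded there), other pairs on all animals.
Means are always subtracted within the evaluated group.

`buildComparisonReport()` mirrors the published comparison layout:
Spearman rank correlations (average ranks for ties) between scenario pairs
for the cohorts *all animals*, *common bulls* (sires with recorded
offspring in at least two countries), *publishable sires* (direct: max
REL >= 0.5 on some scale and >= 25 recorded progeny; maternal: publishable
direct EBV, max maternal REL >= 0.3, >= 15 daughters with recorded progeny
and >= 25 recorded grand-progeny through daughters), *young sires*
(publishable direct EBV, maternal REL < 0.3 everywhere), and three REL
classes with closed upper bounds (\(\le 0.3\), \((0.3, 0.6]\), \(> 0.6\)).
Rank correlations at or above 0.990 count as no re-ranking, within
[0.980, 0.990) as small re-ranking. Top-$k$ lists (default $k = 100$) are
taken among publishable sires; the overlap count and the mean absolute
rank shift are computed within the common candidate set.

# The synthetic-data generator

`simulateDataset()` emulates the structure of the real data the method is
used on, not any particular dataset: eight country populations of very
unequal size (one at 87%), herds nested in countries, discrete
generations, and sires serving dams in several countries. Defaults are
the package's reference study conditions:

* 2,500 offspring per generation, three offspring generations after the
  founders, the last two recorded — about 5,000 records on about 10,000
  pedigree animals;
* country proportions 0.3, 2.9, 1.1, 4.1, 0.7, 87.1, 2.8, 1.0 percent
  (CZE, DFS, ESP, GBR, IRL, FRA, DEU, CHE), five herds per country;
* three progeny per mated dam, ten dams per sire, and probability 0.2
  that a mating uses a foreign active sire. Exported bulls keep their
  domestic matings, so cross-country connectedness arises from widely
  used sires, as it does in practice.

True breeding values follow the generative counterpart of the model:
founders are $N(0, G)$; non-founders are the parent average plus a
Mendelian-sampling deviation with covariance
$G \cdot (0.5 - 0.25(F_s + F_d))$, unknown parents contributing as
founders. Phenotypes add the contemporary-group effect (drawn with SD 10
kg), a sex effect (+15 kg for males), the dam's PE effect and a residual.

## Environmental variances

National residual and PE variances are not public, so the package adopts
conventions: per country, the phenotypic variance is set so the direct
heritability is 0.25 ($\sigma^2_p = \sigma^2_d / 0.25$), the maternal PE
variance is 5% of $\sigma^2_p$ (zero for DEU, which does not fit PE), and
the residual picks up the remainder
$\sigma^2_e = \sigma^2_p - \sigma^2_d - \sigma^2_m - \sigma^2_{pe}$.
These are conventions of this package, chosen once; maternal
heritabilities then fall between 0.06 and 0.21 across countries.

## What the generator does and does not emulate

Discrete generations, single-sire litters and three-generation depth are
deliberate simplifications: real pedigrees have overlapping generations,
dams with parities by different sires, and up to 19 generations of depth.
Consequently maternal reliabilities saturate far below real-data levels —
a dam's maternal effect is confounded with her PE and her single mate's
direct effects, so even large families cap maternal REL around 0.3 at
desk scale. Passing tests therefore demonstrate correctness of the
machinery and reproduction of directional findings, not real-data effect
sizes.

# Problem sizes used by the checks

The test suite states its scales explicitly, chosen as the smallest sizes
at which each property is measurable:

* Oracle equivalences (dense assembly, dense solve, $A^{-1}A = I$, exact
  PEV) run on systems up to about 2,000 unknowns.
* Parameter recovery and LR calibration run at the default study
  conditions (about 5,000 recorded animals) over 10 seeds; partial
  evaluations drop the last generation's records, and the focal group is
  the dominant country's newly recorded animals.
* The REL-class re-ranking check needs maternal reliabilities above 0.3,
  which an 8-population run cannot reach under the exact-PEV guard (16
  traits per animal). It therefore uses a three-population subset of the
  reference parameters (DFS, GBR, FRA re-normalized, FRA keeping its
  dominance and its strongest-negative within-country $r_{dm}$) with 300
  offspring per generation, all generations recorded and 25 dams per
  sire: 6 traits per animal allow four times the animals at the same
  system size and populate the $(0.3, 0.6]$ class. The $> 0.6$ class
  stays empty — as it essentially is for maternal EBVs in data of this
  kind — and monotonicity is asserted across the populated classes.
  Because a rank correlation computed on a handful of animals is
  meaningless, EBV pairs are pooled across the 10 seeds within each scale
  and class before one Spearman correlation per cell is taken.
* The remaining directional checks (CUR re-ranks less than NONE; the
  dominant negative-$r_{dm}$ country re-ranks most under NONE) use the
  full 8-country parameters at 100 offspring per generation over 10
  seeds.

# Numerical choices and degenerate inputs

* Bending returns its input untouched (zero iterations) when the matrix
  already satisfies the eigenvalue floor.
* A zero right-hand side short-circuits the solver to the zero solution.
* PCG failure to converge within the iteration cap is an error carrying
  the convergence trace; reliability and materialization guards refuse
  systems beyond desk scale with explicit messages.
* Spearman ties get average ranks; top-$k$ ranking ties break by first
  occurrence; re-ranking category boundaries are closed from below
  (exactly 0.990 is "none", exactly 0.980 is "small").
* Publishability thresholds are applied to raw, unrounded REL values.
* Pedigree cycles are a hard error naming an animal on the cycle; labels
  appearing only as parents become founders; a declared sex conflicting
  with a parental role is an error.

# Known limitations

* Reliabilities are exact but desk-scale only; no sparse-inverse or
  approximation method is provided at population scale.
* No genetic groups, no genomic information, no REML estimation of the
  correlation matrix itself — the parameters are inputs.
* The generator does not model selection, overlapping generations or
  multi-sire dam careers, which limits attainable maternal reliabilities
  (see above).
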