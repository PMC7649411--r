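---
title: "Simulating a selected beef-cattle population and evaluating it with GBLUP and single-step GBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a selected beef-cattle population and evaluating it with GBLUP and single-step GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gblupsim)
```

## What the package simulates

`gblupsim` is a forward-in-time simulator of a closed beef-cattle breeding
programme together with the genetic-evaluation machinery used to study
genomic prediction accuracy in such programmes.  The population model has
three layers:

1. **Historical population.**  A neutral Wright--Fisher-style population
   (discrete generations, random union of gametes, two distinct parents per
   offspring) is run for 1,000 generations at size 1,000 and then for 95
   generations at the bottleneck size 200.  Meiosis follows the Haldane
   model: the number of crossovers per chromosome is Poisson with mean equal
   to its length in Morgans, breakpoints are uniform, and there is no
   interference.  Recurrent symmetric mutation at $10^{-5}$ per locus per
   gamete maintains segregation.  The purpose of this layer is to build
   linkage disequilibrium (LD) and approximate mutation--drift equilibrium:
   the bottleneck is what gives the genome cattle-like short-range LD
   (adjacent-marker $r^2 \approx 0.22$--$0.26$ at 0.23 cM in the default
   configuration, consistent with an effective population size of a few
   hundred).
2. **Expansion.**  100 males and 100 females drawn from the last historical
   generation mate at random for 20 generations with five offspring per dam,
   capped at 10,000 animals per generation.  This grows the census size
   without adding much drift.
3. **Recent, selected generations.**  275 founder sires and 2,475 founder
   dams are drawn from the expanded population and bred for ten discrete
   generations with one offspring per dam.  Each generation the bottom 60%
   of sires and 20% of dams -- ranked on the selection criterion -- are
   culled and replaced by the top-ranked male and female offspring;
   non-replaced parents persist, so the parent pool overlaps generations.
   The criterion is either the animal's own phenotype or its pedigree-BLUP
   EBV, re-fitted each generation on all recorded phenotypes to date with
   the recorded (partially masked) pedigree.  Each offspring's recorded sire
   and dam are masked independently with probability 0.05; the true pedigree
   is retained as simulation truth.

The genome mirrors the bovine autosomes: 29 chromosomes of equal length
summing to 2,349 cM, evenly spaced neutral bi-allelic markers (10K, 50K or
777K genome-wide), and 725 randomly placed QTL carrying 2--4 alleles.  QTL
allelic effects are gamma(0.4) draws with random sign, rescaled so that the
variance of the true breeding value (TBV) among the 2,750 recent founders
equals $h^2 \sigma^2_P$ with $\sigma^2_P = 1$; phenotypes add a normal
residual with variance $1 - h^2$.  Marker genotypes are observed through a
noise model: 1% missing at random and a 0.5% chance that a dosage is
replaced by one of the other two values.

### The candidate-pool construction

Panels are selected *after* the historical phase from an over-dense
candidate map (2.5 candidate markers per final marker by default): the final
markers are the segregating bi-allelic candidates with minor allele
frequency $\ge 0.1$ lying closest to the even-spacing grid, and the 725 QTL
are sampled among candidates that still segregate with minimum
present-allele frequency $\ge 0.01$.  The 2.5x factor was chosen from the
observed post-bottleneck eligibility rate (roughly 60% of candidates pass
the marker threshold), leaving a comfortable margin on every chromosome; a
shortfall raises an error naming the chromosome rather than degrading the
panel silently.

### Historical size profile

The bottleneck phase holds all 95 generations at size 200 (`shrink =
"step"` in `historical_spec()`).  A linear taper from 1,000 to 200 is
available via `shrink = "linear"`; it produces materially weaker short-range
LD (measured $r^2 \approx 0.15$ at 0.23 cM versus $\approx 0.26$ for the
step profile) because the harmonic-mean population size over the LD-relevant
horizon stays near 600.  The step profile is the default because the
programme this package emulates prints the phase as "95 generations (size
200)" and because its LD matches what is observed in beef cattle.

## The evaluation models

All evaluations are Henderson mixed-model equations for the animal model
$y = \mathbf{1}\mu + Zg + e$ with $g \sim N(0, K\sigma^2_g)$ and
$e \sim N(0, I\sigma^2_e)$, solved with the *known* simulation variances
($\lambda = \sigma^2_e/\sigma^2_g$); no variance components are estimated.
The three choices of $K$ are:

* **Pedigree BLUP**: $K = A$, the numerator relationship matrix of the
  recorded pedigree.  $A^{-1}$ is assembled sparsely by Henderson's rules
  with exact inbreeding coefficients (Meuwissen--Luo recursion).
* **GBLUP**: $K = G$, the VanRaden genomic relationship matrix
  $G = (M-P)(M-P)'/(2\sum_j p_j(1-p_j))$ over the genotyped animals
  (training plus validation), with allele frequencies computed from those
  animals and missing dosages imputed to $2p_j$.
* **ssGBLUP**: $K^{-1} = H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 &
  (wG + (1-w)A_{22})^{-1} - A_{22}^{-1}\end{pmatrix}$, the single-step
  blend that lets non-genotyped relatives contribute through the pedigree.
  $A_{22}$ is computed without forming the full $A$ (Colleau's
  gametic-flow solves).  The weight $w \in \{0.95, 0.90, 0.85\}$ acts as a
  relative polygenic weight; the blend is used exactly as written, with no
  hidden ridge -- a numerically singular blend raises an error.

**Invertibility of G.**  With frequencies computed from the genotyped set
itself, the centred $G$ is singular by construction (its rows sum to zero),
so the genotyped-only GBLUP model blends a small identity fraction,
$G^* = (1-b)G + bI$ with $b = 0.01$ (`blend_identity`), the conventional
stabilisation used by production implementations and interpretable as a
small independent residual polygenic component.  Measured on a full-scale
replicate, halving $b$ moves the mean validation accuracy by about 0.003,
so results are insensitive to the exact value.  The ssGBLUP blend needs no
such adjustment because $A_{22}$ is full rank.

**Accuracy.**  Prediction error variance is extracted from the inverse of
the coefficient matrix, $PEV_i = \sigma^2_e [C^{-1}]_{ii}$, and the
reported accuracy is $r_i = \sqrt{\max(0, 1 - PEV_i/\sigma^2_g)}$ with
$\sigma^2_g = h^2\sigma^2_P$, the base-population value.  The square-root
convention is used because the quantity reported in the source tables is an
accuracy (correlation scale), not a reliability; the literal reliability is
available via `accuracy_from_pev(..., square = TRUE)`.  PEV can slightly
exceed $\sigma^2_g$ for animals whose relationship diagonal exceeds one;
such values are clipped to accuracy 0 with a warning.

A design (`evaluation_design()`) draws the training population at random
from generations 7--9 and 200 validation animals from generation 10;
validation phenotypes are always withheld.  GBLUP uses training phenotypes
only (the genotyped-only model has no pedigree channel); ssGBLUP uses all
recorded phenotypes through generation 9 by default (`phenotype_set =
"tp_only"` restricts it).

### What model-based accuracy does and does not measure

PEV-based accuracy is a property of the assumed covariance model.  Under
truncation selection the genetic variance remaining among generation-10
validation animals is well below the base $\sigma^2_g$ that appears in the
denominator, and the marker-based $G$ mismeasures QTL-level relationships,
so the realized correlation between predicted and true breeding values sits
substantially below the PEV-based accuracy (by 0.1--0.3 at the reduced test
scale).  The two measures move together across designs -- the test suite
asserts exactly that -- but the absolute PEV-based values should be read as
model-internal reliabilities of the evaluation, which is also how the
quantities in the emulated study were produced.

## Pedigree errors

`inject_sire_errors()` corrupts the *recorded* pedigree only: within each
generation, exactly `round(rate * n)` of the progeny with a known recorded
sire get a different sire drawn uniformly from that generation's active
sire list, and a change log is returned.  Exact per-generation counts (not
Bernoulli draws) keep the nominal 10--40% labels exact; masked records are
excluded from the denominator.  Genotype transmission always follows the
true pedigree, so the corruption propagates into the evaluation exactly
through $A^{-1}$, $A_{22}$ and $H^{-1}$.

## The scenario runner and reproducibility

`run_grid()` crosses selection method, $h^2$, marker density, evaluation
method/weight, training-population size and pedigree-error rate, with
replicates.  Within a replicate, all cells of one (selection, $h^2$,
density) coordinate reuse one simulated population, and all methods at a
cell share the same training/validation draw and the same observed
genotypes, so method contrasts are paired and their Monte-Carlo noise
largely cancels.  A single master seed drives named, mutually independent
streams (genome layout, historical drift, panel draw, QTL effects,
breeding, phenotype noise, genotype noise, error injection), so the same
configuration is bit-reproducible and individual stages can be re-run in
isolation.  Genotype observation noise is seeded per animal, so an animal's
observed genotypes do not depend on which subset is extracted.

Two scale presets are provided.  `full_scale()` is the emulated programme
itself.  `reduced_scale()` is a structurally identical miniature
(historical 200 generations at 200 then 50 at 100; 2K markers; 145 QTL; 55
sires and 495 dams; training sets of 200--500; 40 validation animals) on
which the whole property suite -- drift decay, crossover distribution,
variance standardization, monotonicity of accuracy in $h^2$, training size,
blending weight and pedigree-error rate, and the ssGBLUP-over-GBLUP
advantage -- runs in well under a minute.  The test suite uses ten
replicates of this miniature; the acceptance script
(`scripts/acceptance.R`) runs five full-scale replicates, which is what one
CPU completes comfortably in a quarter of an hour.

### Numerical choices and degenerate inputs

* Replacement counts are `round(ratio * group size)` (so 60% of 275 sires
  is exactly 165); ranking ties are broken by animal id, making selection
  deterministic given the seed.
* Dams are allocated to active sires uniformly at random each generation;
  "selective" mating is selective *retention*, not mate allocation.
* The mixed-model equations are solved densely below a few thousand
  equations (Cholesky) and sparsely otherwise (CHOLMOD); PEV diagonals are
  obtained from triangular solves for the requested animals only.
* Degenerate inputs error loudly: cyclic or unsorted pedigrees, all-
  monomorphic marker sets, a non-positive-definite ssGBLUP blend, selection
  on EBV without an evaluator, and infeasible training-set draws all raise
  descriptive errors rather than producing silent results.

## Known limitations

* The simulator is additive-only: no dominance, epistasis, or
  genotype-by-environment interaction, and a single trait.
* Physical (bp) coordinates, sex chromosomes, and crossover interference
  are not modelled; positions live on the genetic map.
* The historical layer matches the emulated programme's *printed*
  protocol.  Unprinted internals of the original simulator (exact
  expansion-phase census trajectory, historical MAF filtering time point)
  are degrees of freedom that plausibly shift absolute accuracy levels by
  several points even when every printed parameter matches; the package's
  own replicate means are therefore the reference for its behaviour, and
  relative contrasts (between methods, weights, heritabilities, training
  sizes and error rates) are the robust quantities.
* Full-scale ssGBLUP with 50K markers is supported but slow on one CPU
  (the genotyped block is dense); the pedigree-error experiment at that
  scale is intended as an overnight run, not a test.
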