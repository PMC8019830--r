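---
title: "Reduced animal models: absorption, equivalence and back-solving"
author: "ramsolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced animal models: absorption, equivalence and back-solving}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and the reduction

The animal model predicts breeding values from phenotypes and a
relationship structure,

$$ y = Xb + Zu + e, \qquad u \sim N(0, A\sigma_u^2), \qquad
   e \sim N(0, I\sigma_e^2), $$

with $A$ the pedigree numerator relationship matrix.  Henderson's
mixed-model equations (MME) couple one equation per fixed-effect level
with one per animal, and the animal block carries the penalty
$\lambda A^{-1}$, $\lambda = \sigma_e^2/\sigma_u^2$.  Non-phenotyped
animals contribute no data; they appear only because $A^{-1}$ is built
directly from pedigree rules and needs every ancestor.

`ramsolve` removes those equations exactly.  Writing the index sets
$n$ (non-phenotyped) and $p$ (phenotyped) — carried as index vectors,
never as a physical permutation — the animal block of $A^{-1}$
partitions into $A^{nn}, A^{np}, A^{pp}$, and absorbing the $n$
equations leaves the Schur complement

$$ \Phi = A^{pp} - A^{pn}(A^{nn})^{-1}A^{np} . $$

Equating the absorbed system with the (statistically equivalent) dense
formulation that penalises with $(A_{pp})^{-1}$ shows
$\Phi = (A_{pp})^{-1}$: the reduced system is not an approximation but
the same model re-expressed, with prior
$u_p \sim N(0, \Phi^{-1}\sigma_u^2)$.  The absorbed animals are
recovered afterwards from

$$ A^{nn}\hat u_n = -A^{np}\hat u_p , $$

a sparse solve in the well-structured $A^{nn}$.  Both identities are
verified against dense oracles in the test suite (tabular $A$,
`solve()` of the retained block) rather than assumed.

### The seven families

* **basic** — as above; the reduced penalty is $\lambda\Phi$.
* **multitrait** — $t$ traits with genetic covariance $G_0$ and
  residual covariance $R_0$; the penalty is $G_0^{-1} \otimes A^{-1}$
  (trait-major stacking) and records enter through per-record
  $R_0^{-1}$ blocks, with the rows and columns of missing traits
  deleted before inversion.  Animals phenotyped for at least one trait
  are retained.  The back-solve is the Kronecker form
  $(A^{nn}\otimes G_0^{-1})\hat u_n = -(A^{np}\otimes G_0^{-1})\hat u_p$,
  in which $G_0^{-1}$ cancels — the implementation uses the cancelled
  per-trait path and keeps the explicit Kronecker system only as a
  cross-check.
* **repeatability** — adds a permanent-environment effect with penalty
  $\alpha I$, $\alpha = \sigma_e^2/\sigma_p^2$; its incidence matrix
  equals the phenotyped-animal block of $Z$, so absorption touches only
  the breeding-value block.  Absorbing the PE equations as well is
  deliberately out of scope.
* **maternal** — adds a maternal genetic effect (and optionally a
  maternal permanent-environment effect over dams).  When direct and
  maternal effects are correlated, the retained set is *phenotyped
  animals or dams of phenotyped animals*: that choice zeroes the $n$
  columns of both incidence matrices, every $A^{-1}$ occurrence reduces
  to the same $\Phi$, and both effects back-solve jointly through the
  Kronecker identity with the $2\times 2$ direct/maternal covariance.
  In the uncorrelated family only the direct effect is reduced; the
  maternal block keeps the complete $\lambda_2 A^{-1}$ because the dams
  of phenotyped animals spread over the whole pedigree, so the
  computational gain is partial by construction.
* **groups** — unknown-parent genetic groups via the Quaas–Pollak
  transformation: the extended inverse
  $\Lambda^{-1} = [I, -Q]' A^{-1} [I, -Q]$ appends one equation per
  group, the group rows of the right-hand side are zero, and the
  animal solutions become $\hat u + Q\hat g$ directly.  $Q$ is built by
  the Westell recursion (an unknown parent contributes half the unit
  row of its group) or read from a file.
* **gblup** — the genomic relationship matrix
  $G = ZZ'/(2\sum p_j(1-p_j)) + wI$ over centred marker codes replaces
  $A$.  Pedigree-style indirect inversion does not exist for $G$, so
  the reduced model inverts the phenotyped block $G_{pp}$ directly
  instead of forming $\Phi$ from $G^{-1}$.  Non-phenotyped genotyped
  animals are recovered either from the $G^{-1}$ blocks or through
  marker effects $\hat a = Z_p' G_{pp}^{-1}\hat u_p / k$,
  $\hat u_n = Z_n \hat a$ — exact only when $w = 0$ and $G$ has full
  rank, which is why a blended $G$ triggers a warning there.
* **ssgblup** — the single-step inverse $H^{-1}$ equals $A^{-1}$ with
  the genotyped block incremented by $G^{-1} - A_{22}^{-1}$ (supplied,
  or computed densely at desk scale).  Splitting animals into
  *phenotyped-or-genotyped* versus neither makes the absorbed blocks
  pure $A^{-1}$ blocks, so the kernel $\Theta$ and the back-solve never
  touch the dense genomic block.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| $\sigma_u^2, \sigma_e^2$ | 0.3 / 0.7 | variance components; only their ratio $\lambda$ enters single-trait equations |
| $\sigma_p^2$ | 0.2 | permanent-environment variance (repeatability) |
| $\sigma_m^2, \sigma_{um}, \sigma_{mpe}^2$ | 0.12 / −0.06 / 0.1 | maternal variances; the $2\times2$ direct/maternal matrix must be positive definite |
| $G_0, R_0$ | `[[2,.5],[.5,1]]`, `[[4,1],[1,3]]` | trait covariances (multitrait) |
| blend weight $w$ | 0.1 | diagonal added to $G$; keeps it invertible, breaks the exact marker back-solve |
| `useInbreeding` | `TRUE` | inbreeding-aware Mendelian-sampling variances in $A^{-1}$; classic constants $2, 4/3, 1$ available for parity with non-inbred fixtures |
| `anchorGroup` | `TRUE` | fixes the last group's solution at 0 (below) |
| equivalence tolerance | `1e-8` | direct solver; `1e-6` is appropriate for PCG runs |

All components are stored once; $\lambda$, $\alpha$ and the
$\sigma_e^2 G^{-1}$ maternal coefficients are always derived.

## Numerical choices

* **Factorizations.** $K_{nn}$ (and every MME left-hand side) is
  factored by sparse Cholesky with fill-reducing ordering; the columns
  of $K_{np}$ are solved in blocks of 512 to bound dense working
  memory, and $(K_{nn})^{-1}$ is never formed.  $\Phi$ is stored dense:
  it is small (retained set) but fills in heavily — the 10,000-animal
  run in the acceptance script measures a $\Phi$ roughly three orders
  of magnitude denser than $A^{-1}$.
* **Symmetry.** Assembled systems are symmetrized structurally
  (`forceSymmetric`), and $\Phi$ is averaged with its transpose after
  the blocked solve, so downstream factorizations see exactly
  symmetric input.
* **Singular group systems.** With every lineage grouped, the rows of
  $Q$ sum to one, and whenever the fixed design spans the intercept the
  group equations are confounded with it: $\Lambda^{-1}$ is singular by
  construction (its null space is spanned by $[Q; I]$).  The default
  policy anchors the *last* group's solution at zero by deleting its
  equation — applied identically to the full and the reduced system,
  so equivalence is preserved and all labels stay comparable.  A dense
  SVD minimum-norm solve remains available (`generalized = TRUE`) for
  unanchored runs; comparisons are then meaningful only on estimable
  contrasts such as $u + Qg$.
* **Centring degeneracy in GBLUP.** Centring markers at allele
  frequencies estimated from the same animals makes the unblended $G$
  exactly singular (the centred codes sum to zero), which is one
  reason frequency estimation should not be restricted to the
  phenotyped subset.  Exactness checks of the marker back-solve
  therefore use externally supplied frequencies.
* **Degenerate inputs.** Unknown parents are normalized to 0 from any
  of `0`/empty/`NA`; parents never declared as animals are appended as
  founders unless strict mode; pedigree cycles (including
  self-ancestry) error with an offending id; monomorphic markers
  contribute zero to both $Z$ and the scale $k$ and only an all-
  monomorphic panel errors; missing genotypes are mean-imputed per
  marker unless strict mode rejects them.
* **PCG.** The iterative solver uses a Jacobi preconditioner, relative
  residual tolerance $10^{-10}$ and an iteration cap of $10n$;
  non-convergence is reported, with the partial solution retained.
* **Fixed-effect parameterization.** The first factor is one-hot
  without intercept, later factors drop their first level; numeric
  columns enter as covariates.  This keeps textbook-style fixtures
  full rank, and rank deficiency is detected at assembly with the
  confounded columns named.

## What the simulator does and does not emulate

The generator reproduces the statistical structure the models assume:
discrete generations from a founder population (default 100 founders,
8 generations, 10,000 animals), random mating with one offspring per
mating, true breeding values by gene flow with Mendelian-sampling
variance $\sigma_u^2(1 - \tfrac14(1+F_s) - \tfrac14(1+F_d))$,
herd effects drawn once per herd (spread defaulting to the residual
SD), and unlinked biallelic markers gene-dropped from Hardy–Weinberg
founders.  Defaults phenotype 2,000 animals of the last three
generations across 5 herds; h² defaults to 0.3.

It deliberately omits selection, assortative mating, overlapping
generations, linkage and any QTL architecture.  Passing tests
therefore demonstrate the *algebraic* claims — equivalence of full and
reduced systems, correctness of $A^{-1}$, $\Phi$, $\Theta$ and the
back-solves — under the models' own assumptions; they do not
demonstrate robustness to model misspecification in real data, where
selection and incomplete pedigrees bias any BLUP, full or reduced,
equally.

## Problem sizes

The test suite validates every family at ~300 animals with ~40 %
phenotyped (genomic families: 500 markers, ~30 % genotyped; groups:
two groups; maternal: ≥30 dams), the dense-oracle identities at up to
500 animals, and the reference-scale replication at 10,000 animals
with 2,000 phenotypes.  The unbiasedness check regresses true on
estimated breeding values over 10 replicates of 5,000 animals at
h² = 0.3.  These sizes are the package's reference conditions; all of
them rerun from `scripts/acceptance.R` with a single seed argument.

## Known limitations

Variance-component estimation (REML/MIVQUE) is out of scope: the
components are inputs.  The further "2-fold" reduction to phenotyped
parents of phenotyped progeny, absorption of permanent-environment
equations, reduced-rank genomic inverses (APY and relatives),
metafounders, heterogeneous residual variances and reliability (PEV)
back-solving are not implemented.  Back-solving through $G^{-1}$
blocks is supported but discouraged for large genotyped sets — prefer
marker effects or explicit retention of the animals of interest in the
reduced system (`extras`).
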