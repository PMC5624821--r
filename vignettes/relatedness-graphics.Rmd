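---
title: "Allele-sharing statistics, Cotterman coefficients and compositional graphics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-sharing statistics, Cotterman coefficients and compositional graphics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relkit)
```

relkit detects and identifies family relationships between diploid
individuals from co-dominant marker data (microsatellites, SNPs). This
vignette explains the statistical machinery behind the package: the IBS
summary statistics and their exact attainable domain, the maximum-likelihood
model for the Cotterman IBD coefficients, the compositional (ternary and
log-ratio) view of both, and the gene-dropping simulation that turns point
estimates into uncertainty zones.

## IBS counts and the mean/sd umbrella

At each marker a pair of diploid genotypes shares 0, 1 or 2 alleles
identical by state (IBS), defined as the size of the best matching between
the two unordered allele pairs (`ibs_count()`). For `n` individuals the
package computes, for each of the `choose(n, 2)` pairs, the mean and
standard deviation of the IBS counts and the proportions `p0, p1, p2` of
markers at each sharing level (`ibs_pairs()`).

Two conventions matter and are fixed deliberately:

* **Population variance.** The sd uses divisor `m` (not `m - 1`). Only
  under this convention does the extreme array of fifty 0s and fifty 2s at
  `m = 100` markers attain variance exactly 1, which is the natural
  normalisation for the domain plot below. This also gives the clean
  identities `mean = p1 + 2 p2` and `sd^2 = p1 + 4 p2 - mean^2`, which the
  tests assert on random arrays and on published reference rows.
* **Pairwise deletion.** Proportions and moments are computed over the loci
  observed in *both* members of a pair, so `p` stays on the simplex per
  pair. Nothing principled is available for partially missing pairs beyond
  this; the informative-locus count is carried through all outputs.

Because each count is one of three outcomes and order across markers is
irrelevant, the set of attainable `(mean, sd)` points with `m` markers is
finite: one point per multiset, at most `C(m + 2, m)` of them
(`multiset_coefficient(3, m)`; 5151 for `m = 100`). `msd_domain()`
enumerates all compositions `(n0, n1, n2)` exactly — an `O(m^2)` sweep,
capped at `m = 2000` — and collapses coincident points while retaining
multiplicities, since the multiset coefficient is an upper bound on the
number of *distinct* points, not an equality. The cloud is umbrella-shaped;
no empirical pair can fall outside it, a property the test suite checks by
simulation. The right-hand edge, compositions `(0, m - j, j)`
(`po_boundary()`), is where parent–offspring pairs live: a child inherits at
least one IBS allele from its parent at every locus, so PO pairs have
`p0 = 0` and mean at least 1, with the smallest sd attainable at that mean.
Monozygotic twins and duplicated samples sit at the point `(2, 0)`.

## Cotterman coefficients by maximum likelihood

IBD (identity by descent) probabilities `k = (k0, k1, k2)` — the Cotterman
coefficients — describe the relationship itself rather than its observable
shadow. The standard reference values are built in
(`cotterman_reference()`): PO `(0, 1, 0)`, FS `(1/4, 1/2, 1/4)`, HS/AV/GG
`(1/2, 1/2, 0)`, FC `(3/4, 1/4, 0)`, UN `(1, 0, 0)`, MZ `(0, 0, 1)`.

The likelihood of `k` for an observed pair multiplies, across loci, the
mixture `k0 P0 + k1 P1 + k2 P2`, where `(P0, P1, P2)` are the probabilities
of the observed genotype pair given 0/1/2 shared IBD alleles
(`class_probs()`). The conditional table is the standard non-inbred one
under Hardy–Weinberg proportions (e.g. `(AiAj, AiAj)` gives
`(4 pi^2 pj^2, pi pj (pi + pj), 2 pi pj)`). Rather than validating the
table against any particular printed source, the tests verify its defining
*completeness* property: for every frequency vector, summing each column
over the exhaustive space of genotype pairs gives exactly 1.

`estimate_k()` maximises the likelihood with EM on the simplex: per-locus
responsibilities `r_ml = k_m P_ml / sum_m' k_m' P_m'l` and the update
`k_m = mean_l r_ml`. This optimiser was chosen over ilr-parameterised
quasi-Newton because it is monotone (the log-likelihood trace is recorded
and asserted non-decreasing), respects the simplex by construction, and has
no tuning beyond a stopping rule — log-ratio parameterisations are known to
be sensitive to tolerance and starting point precisely because boundary
optima (`k` components of exactly 0 are the rule for PO, UN and MZ) sit at
infinity in those coordinates. Defaults: start at the barycenter, stop when
the log-likelihood gain drops below `1e-7` or after 2000 iterations;
`corner_starts = TRUE` adds three near-vertex starts and keeps the best run,
which helps when EM creeps slowly along a boundary. A 0.005-resolution grid
search over the whole simplex serves as an independent oracle in the tests:
EM must match it to within the likelihood curvature of one grid step.

Numerical edge cases: loci where either genotype is missing, or where an
observed allele has no frequency (possible when frequencies are estimated
excluding the focal pair, `loo_pair`), are flagged, skipped and counted.
Allele frequencies themselves are plain counting estimates with no
pseudo-counts (`estimate_allele_freqs()`); by default they include the focal
pair, the conventional choice, with exclusion available as an option since
including the pair biases estimates slightly toward relatedness.

Non-inbred pairs obey Thompson's constraint `k1^2 >= 4 k0 k2`.
Estimation is **unconstrained by default**: published unconstrained
estimates for known relationships (e.g. a full-sib pair with
`k = (0.214, 0.617, 0.169)`) are feasible on their own, and leaving the
constraint off keeps violations visible as a diagnostic.
`apply_thompson_constraint()` projects an infeasible estimate by
re-maximising on the boundary curve, for which we use the exact
Hardy–Weinberg parameterisation `k = (s^2, 2 s (1 - s), (1 - s)^2)`,
`s` in [0, 1] — the curve's maximum `k1` is 1/2, attained at the FS
reference point. A dense grid plus golden-section refinement handles the
1D search without assuming unimodality.

`classify_relationship()` labels an estimate with the nearest reference
point, by Euclidean distance on the simplex (default) or Aitchison distance
after zero replacement. Ties break toward the lower-degree relationship: in
quality-control use a false alarm about close relatedness is cheaper to
review than a miss.

## Compositional coordinates

Both `p` and `k` are 3-part compositions, so the same machinery serves
both. The ternary diagram (`ternary_xy()`, `plot_ternary()`) shows all
three parts at once — unlike the two-part scatterplots, where inter-point
distances change with the chosen pair of components. Within the ternary
diagram for `k`, Thompson's constraint carves an arrowhead whose curved
lower boundary is `feasible_boundary()`.

For a metric treatment the package uses isometric log-ratio (ilr)
coordinates (`ilr()`), in the three standard bases `z0`, `z1`, `z2`; for
`z1`, `z11 = ln(c2/c0)/sqrt(2)` and `z12 = ln(c0 c2 / c1^2)/sqrt(6)`.
Euclidean distance between ilr images is the Aitchison distance and is
identical in all three bases (asserted to `1e-10` on random compositions).
The sign of `z11` has a direct reading: positive when the "2"-part exceeds
the "0"-part, i.e. toward closer relatedness.

Two numerical choices deserve note:

* **Zeros.** Log-ratios of zero parts diverge. `ilr()` never returns raw
  infinities; it flags the row and reports the unit *direction* in which
  the image escapes (computed from which parts vanish), which the ilr plot
  renders as arrows at the frame edge. When a finite surrogate is wanted,
  `replace_zeros()` applies multiplicative replacement with
  `delta = 0.5/m` — half the smallest nonzero proportion observable from
  `m` informative loci — which is the standard compositional-data remedy;
  `m` is taken per pair from its informative-locus count.
* **The feasible-region ceiling.** Substituting the boundary equality
  `k1^2 = 4 k0 k2` into the `z1` coordinates makes the second coordinate
  the constant `ln(1/4)/sqrt(6) = -(2/sqrt(6)) ln 2 ≈ -0.566`
  (`ilr_feasible_ceiling()`), so the arrowhead's curved edge maps to a
  horizontal line in the `z1` plot. A ceiling value of `-(2/3) ln 2 ≈
  -0.462` is sometimes quoted for this line; direct evaluation of the
  transform does not reproduce that constant, so the package draws the line
  at the value its own transform implies, and the tests pin the constancy
  of `z12` along the whole boundary curve.

## Gene dropping and uncertainty zones

Point estimates scatter around their references, so relationships
correspond to zones, not points. `simulate_pairs()` builds artificial
pairs of any standard relationship by Mendelian gene dropping: one allele
sampled uniformly from each parent per marker, independently across
markers. Pedigree templates: MZ duplicates a founder; PO is founder +
child; FS two children of one couple; HS children of couples sharing one
founder; AV a founder couple's child versus the other child's offspring
with an outside founder; GG grandparent versus grandchild through one
two-step drop; FC children of two sibs married to unrelated founders. Each
template's expected `k` is unit-tested against the reference table.

Founders come from Hardy–Weinberg equilibrium at supplied frequencies
(`"frequency"` mode, the self-contained default) or are resampled without
replacement from an observed set of unrelated individuals (`"resample"`
mode, which conditions the zones on the observed allele frequencies — the
mode a case study should use). `select_unrelated()` picks that subset
greedily, dropping individuals from pairs whose `k1 + k2` exceeds a
configurable threshold (default 0.2).

`hulls_for()` maps a simulated set into any of the coordinate systems and
computes its convex hull with Andrew's monotone chain (`convex_hull()`),
cross-checked in the tests against an all-pairs brute-force oracle and
`grDevices::chull`. Hull–hull overlap uses a separating-axis test
(`hulls_intersect()`). At 1000 markers the PO, FS and UN hulls in ilr
coordinates of `k` are pairwise disjoint (asserted in the tests); at a few
hundred markers the second- and third-degree zones overlap UN substantially,
which is a property of the statistics, not of the hull construction.

What the simulation does *not* emulate: linkage and linkage disequilibrium
(markers drop independently), mutation, genotyping error and inbreeding.
Zones built under these assumptions can be too tight for dense linked
panels, and real populations with inbreeding shift UN pairs toward higher
`k1` — so passing tests demonstrate correctness of the machinery under the
stated model, not calibration on any particular real cohort.

## Problem sizes and defaults

The package's own validation uses 1000 loci with 10 equifrequent alleles
and 50 pairs per relationship for coefficient recovery (mean estimates
within 0.05 of the references), 200-locus instances for the EM/grid
cross-check, and 100-marker domains for the exact enumerations; these sizes
make every property sharp while keeping the whole suite fast on a single
CPU. `run_case_study()` defaults to a 25-individual, 377-marker simulated
population — the shape of a classical microsatellite panel — with hull
sample sizes of 80 PO, 48 FS, 40 each HS/AV/GG, 36 FC and 250 UN pairs;
counts are parameters because the right number of UN pairs depends on how
many unrelated founders the data offer.

## Limitations

* Only 3-part compositions are supported; the general D-part Aitchison
  geometry (alr/clr, perturbation arithmetic) is out of scope.
* No inbreeding: the likelihood uses three Cotterman coefficients, not the
  nine condensed identity coefficients, and founders are assumed
  non-inbred.
* No hypothesis tests or confidence regions for specified relationships;
  hulls describe simulation scatter, they are not confidence sets.
* VCF/BCF and binary PLINK input are not parsed; use PED/MAP text or the
  tabular dialect.
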