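---
title: "pharmnet: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pharmnet: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmnet)
```

This vignette is the package's own account of its science: what is modeled,
which parameters matter, what the synthetic data does and does not
establish, and where genuinely open design choices were resolved. It states
no empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## 1. The pharmacophore model and matcher

A pharmacophore model is an ordered list of $k$ typed feature spheres —
label, required feature type, radius $r_i$ (Å) — plus a symmetric $k \times
k$ matrix $D$ of pairwise inter-feature distances (Å). The packaged
three-feature IGF-1R model combines an aromatic-hydrophobic sphere
($r = 1.4$ Å), a hydrophobic sphere ($0.8$ Å) and a hydrogen-bond-acceptor
sphere ($0.9$ Å) at distances $D_{12} = 3.75$, $D_{13} = 4.99$,
$D_{23} = 6.79$ Å.

**Matching rule.** The source model ships radii but no matching rule, so
one had to be chosen. `pharmnet` uses the sphere-intersection bound: an
assignment of $k$ distinct, type-compatible feature points $p_i$ matches
when every pair satisfies $|\,\lVert p_i - p_j\rVert - D_{ij}\,| \le r_i +
r_j$. This is the standard geometric reading of feature spheres (two
spheres of radii $r_i, r_j$ centred at model positions can both contain
their points only if the inter-point distance is within $r_i + r_j$ of the
model distance) and is exposed as `tol_scale` for sensitivity analysis.
With $k = 3$, pairwise distances already determine the triangle up to a
rigid motion and reflection, so hit/miss needs no alignment; the
superposition RMSD is computed *post hoc* on the chosen assignment, for
reporting, using the Kabsch algorithm restricted to proper rotations
(a mirror image of a chiral arrangement keeps a non-zero RMSD).

**Type semantics.** An aromatic ring is also hydrophobic, so HYD slots
accept HYD\_ARO points (flag `hyd_accepts_aromatic`), but each point is
used at most once and HYD\_ARO slots accept only aromatic centroids.
Among valid assignments the matcher returns the one minimising the summed
pairwise deviation, ties broken lexicographically on point indices — a pure
determinism device with no chemical meaning.

**Embedding.** `embed_model()` places feature 1 at the origin, feature 2 on
the $+x$ axis and feature 3 in the $y \ge 0$ half-plane (law-of-cosines
closed form), and verifies the recomputed distances to $10^{-9}$ Å.
Distance triples violating the triangle inequality raise a model-infeasible
error rather than embedding approximately.

## 2. Feature perception and descriptors

Vendor tools never publish their perception rules, so `pharmnet`'s rules
are plain data (`default_feature_rules()`), deliberately simple and
auditable:

* **HYD_ARO** — centroid of each aromatic ring (smallest-rings set).
* **HYD** — centroid of each non-aromatic carbocycle, and of each maximal
  cluster of ≥ 3 connected acyclic aliphatic carbons not bound to a
  heteroatom. The threshold of 3 carbons is a common perception default: a
  methyl or ethyl appendage is too small to act as a hydrophobe.
* **HBA** — N/O with an available lone pair: excludes amide nitrogens,
  pyrrole-type aromatic N–H (the lone pair is part of the ring current) and
  positively charged atoms.
* **HBD** — any O–H or N–H heavy atom.

Descriptors reuse the same donor/acceptor rules, so the Lipinski filter can
never disagree with feature perception. Rotatable bonds are acyclic single
bonds between two non-terminal heavy atoms, excluding amide C–N. Ring count
is the cyclomatic number. TPSA is the published fragment-additive scheme
restricted to its original N/O parameterisation; molecules whose polarity
lives on S/P will have TPSA underestimated, which is reported here rather
than hidden.

**Conformers.** When a record arrives without 3-D coordinates, one
conformer is embedded by a seeded distance-geometry-style optimisation
(ideal bond lengths from covalent radii scaled by bond order, 1–3 distances
from hybridisation angles, a soft 2.6 Å lower bound elsewhere, BFGS from a
seeded random start). This is deterministic and adequate for feature
geometry; it is *not* an energy-minimised ensemble, and multi-conformer
records are matched with any-conformer semantics. Reproducing a commercial
conformational search is an explicit non-goal.

## 3. The activity scale and training fixture

IC$_{50}$ classes use inclusive upper bounds toward the more active class:
most active $\le 0.5$ µM, moderately active $\le 20$ µM, less active
$\le 60$ µM, inactive $> 60$ µM. The packaged 23-compound training table
(21 active, 2 inactive; class counts 4/13/4/2; IC$_{50}$ spanning
0.04–200 µM) carries an `ic50_source` flag per row: only the most active
compound's value (picropodophyllin, 0.04 µM) is printed in the source text,
so the remaining values are class-consistent reconstructions — honest
provenance over spurious precision. Every stored class is re-derivable from
its stored IC$_{50}$, and the test suite enforces this.

## 4. The screening cascade

Stage order is pharmacophore match → Lipinski counts → drug-likeness. The
Lipinski counts are applied with strict `<` (HBD < 5, HBA < 10) because
that is how the original cascade prints them; the canonical rule of five
uses `≤`, and `lipinski_inclusive = TRUE` switches to it. Drug-likeness
thresholds are unstated in the source and default to published oral
drug-likeness conventions: rotatable bonds ≤ 10, ring count in [1, 6], TPSA
≤ 140 Å² — all config-overridable, all rejections carrying machine-readable
reasons. Survivor counts are non-increasing by construction and
permutation-invariant, which the property tests check.

The original database screen (2534 Lipinski-positive compounds → 189
pharmacophore hits → 8 final hits) is *not* reproducible at desk scale: it
depends on an external, versioned drug database. The cascade is therefore
validated on synthetic libraries with guaranteed ground truth and on
user-supplied files.

## 5. The continuous Petri-net engine

Places hold non-negative real markings (tokens); a mass-action transition
fires with flux $k \prod_p m(p)^{w(p)}$ over its pre-places, a
Michaelis–Menten transition (exactly one substrate) with $V_{\max}
m/(K_m + m)$. The marking ODE $\dot m = (W_{\text{post}} -
W_{\text{pre}})\,v(m)$ is integrated with an adaptive Dormand–Prince
RK45 (defaults rtol $10^{-6}$, atol $10^{-9}$, output on a fixed 201-point
grid per run for plotting parity).

**Inhibitory arcs.** The source formalism names inhibitory arcs but gives
no continuous semantics. Default is the hard switch used by
continuous-net tools — flux 0 once any inhibitor marking reaches its
threshold — with a smooth Hill-type alternative $\theta^n/(\theta^n + m^n)$
(`inhibition_mode = "smooth"`, exponent `inhibition_hill`); the hard switch
is the pointwise limit of the smooth factor as $n \to \infty$ except
exactly at the threshold, and the tests spot-check that numerically. All
packaged results use the default. Because the hard switch makes the vector
field discontinuous, the integrator localizes threshold crossings by
bisection; without this, step-refinement stability would degrade to the
size of the crossing step.

**Non-negativity** is enforced by flux gating — an emptying transition's
flux is forced to 0 at the boundary — rather than post-hoc clipping, which
would silently destroy conservation. On nets whose transitions have equal
pre- and post-weight totals, the summed marking drifts less than $10^{-6}$
over the packaged horizons.

## 6. The packaged IGF-1R networks

The published network figures are image-only, so the reconstruction encodes
every interaction named in the accompanying text, with mass-action rate 1
and unit weights throughout (the one kinetic statement available) plus
first-order degradation on each signaling species to keep trajectories
bounded:

* activation cascade IGF → IGF-1R → IRS-1 → PI3k → Akt → ER-α, catalytic
  (the upstream place is conserved);
* ER-α positive feedback onto IGF-1R, consuming active ER-α;
* ER-α inhibitory arcs on each tumor-suppressor activation (p53, Mdm2,
  BRCA1 — per-TSG arcs, which the text supports, rather than one pooled
  arc);
* Mdm2 as negative regulator of p53 (catalysed degradation) and activator
  of BRCA1;
* treated net: a constant fulvestrant boundary place (marking 5, matching
  the ligand scale, reflecting sustained inhibition over the horizon rather
  than a decaying dose) with inhibitory arcs on the IGF-1R, IRS-1 and ER-α
  activations — including the feedback transition, which is an IGF-1R
  activation — plus a PTEN branch: homeostatic PTEN/Mdm2 activation
  released once ER-α falls below threshold, p53-catalysed PTEN production,
  and PTEN inhibition of PI3k/Akt activation.

**Initial markings.** The source states one marking (IGF = 5 tokens) and
one rate (1). The remaining initials are free parameters of the
reconstruction. They were calibrated *once* so that the frozen default
discretization thresholds reproduce the published qualitative table, then
frozen and recorded in the model files: receptor/kinase places at 4, ER-α
at 3 (ER-α is abundant at baseline in ER-positive cells, so its relative
induction is moderate), tumor suppressors at 0.2–0.5 (the diseased baseline
has suppressed TSGs), fulvestrant at 5. With these, the untreated steady
state doubles the receptor pool (peak fold ≈ 2.5, the "activated two-fold"
regime) and the treated run collapses IGF-1R/IRS-1/ER-α while p53, BRCA1,
Mdm2 and PTEN recover above baseline.

**Qualitative table.** Per protein and condition the end-of-run fold change
$m(T)/m(0)$ at the 50-unit horizon (the middle of the stated 10/50/100
scenarios) is discretized: ≥ 2.0 → `+++`, [1.2, 2.0) → `++`, ≤ 0.5 →
`---`; values in no band are reported numerically with symbol `+/-` and a
warning. The fold-change *statistic* deserves a note: a peak-over-initial
ratio (max over a grid that includes $t=0$) can never fall below 1, so
down-regulation would be invisible to it. `fold_change()` offers both
`peak_over_initial` and `final_over_initial`; the table uses the final
ratio (what an end-point western blot measures), while the "2-fold
receptor activation" headline uses the peak ratio, and the directional
tests use peak for up- and final for down-regulation.

## 7. Synthetic data: what a green test establishes

`generate_matching_library()` builds positives as rigid motions of the
embedded model with isotropic Gaussian jitter (default $\sigma = 0.2$ Å,
small against the tightest pair tolerance $r_2 + r_3 = 1.7$ Å),
rejection-sampled so the jittered triple still satisfies the tolerance
test, plus 2–5 random-type decoy points in a 10 Å box — large enough to
keep accidental matches rare but possible. Negatives violate *every* pair
constraint by at least $2(r_i + r_j)$ (distance violation is the harder
test of a distance matcher; type-violating negatives would be rejected
trivially). A verification pass re-runs the matcher on every generated set,
so stored labels cannot disagree with the match operation; a jitter so
large that rejection exceeds the attempt budget raises an error advising a
smaller sigma.

Consequently, a perfect accuracy on these libraries establishes that the
matcher implements its geometric definition correctly (independently
confirmed against a brute-force enumeration oracle), *not* that the
pharmacophore separates real actives from real decoys — the sets are
feature points, not molecules, and contain no conformational noise,
tautomers or perception ambiguity. That external-validity question needs a
real annotated database, which is out of scope.

## 8. Numerical choices

* Model embedding verification: $10^{-9}$ Å; matcher tie-break:
  lexicographic point order.
* RK45 defaults rtol $10^{-6}$ / atol $10^{-9}$; max step = horizon/200;
  threshold-crossing bisection to $10^{-12}$ of the step.
* Integration output markings are clipped at 0 after each accepted step to
  absorb $O(\text{atol})$ undershoot; the gating rule, not the clip,
  carries the non-negativity guarantee.
* Conformer embedding: 3 BFGS restarts from a seeded Gaussian start, best
  stress kept; identical seeds give identical coordinates.
* JSON is the on-disk spec format for models and nets (the environment
  provides no YAML parser for R); the reader ignores unknown keys, so the
  packaged files carry a human-readable `comment` header with every
  reconstruction choice.

## 9. Known limitations

* The SMILES reader covers the organic subset, brackets, branches and ring
  closures but not multi-fragment inputs, isotopes-with-meaning or
  stereochemistry (markers are accepted and ignored); aromaticity is taken
  from the input rather than re-perceived.
* TPSA is N/O-parameterised only; MM transitions are single-substrate.
* The packaged nets are qualitative reconstructions: rate constants are
  not fitted to expression data, so trajectories support directional and
  fold-band statements, not quantitative time courses.
* Matching enumerates type-compatible triples with pairwise pruning; for
  the packaged $k = 3$ model this is exact and fast to a few dozen points
  per set, which is the intended screening regime.
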