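---
title: "Fragment-based segment modeling into cryo-EM density: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based segment modeling into cryo-EM density: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Medium-resolution cryo-EM maps (roughly 4–12 Å) resolve secondary-structure
elements but frequently leave flexible loops, hinge regions and inter-domain
linkers unmodeled. `fragfitr` fills such gaps with backbone fragments mined
from known structures, using the density map itself as the final arbiter
among geometrically plausible candidates. The user supplies the structural
context, the two *stem residues* flanking the gap, the segment's amino-acid
sequence, and the map with its nominal resolution.

The pipeline has two phases:

1. **Geometric/sequence search.** An indexed fragment database is queried
   hierarchically: (i) by fragment length and stem-pair distance, (ii) by
   the RMSD of the fragment's terminal residues after rigid superposition
   onto the gap stems, (iii) by clash screening of the grafted placement and
   deletion of redundant candidates, and (iv) by a combined
   sequence-similarity / fingerprint-match score that orders the final
   shortlist (at most 100 from a pool of at most 1000).
2. **Density re-ranking.** Each shortlisted candidate is converted into a
   simulated density on the grid of a *minimal box* cut from the
   experimental map, low-pass filtered to the map's resolution, and scored
   by the Pearson cross-correlation coefficient (CCC) against the box after
   the known context's density has been subtracted. The shortlist is
   re-ordered by descending CCC; the candidate *set* is never changed, only
   its order.

## The geometric fingerprint

Stem-pair geometry is summarized by four rigid-motion invariants:

* `d` — distance between the two stem CA atoms (Å);
* `theta_n` — angle between the N-stem CA→C bond and the stem–stem axis;
* `theta_c` — angle between the C-stem CA→N bond and the reversed axis;
* `phi` — torsion C(n)–CA(n)–CA(c)–N(c), in (−180°, 180°].

Together with the (unconstrained) remaining bond directions these fix the
relative pose of the two stems, use only N/CA/C atoms, and are cheap to
compute, which is what a database pre-filter needs. Any rigid-motion
invariant parameterization would serve; this concrete set is the package's
own choice and is tested for invariance to 1e-6 under random rigid motions.

Fingerprint deviations are combined on a single scale:
`|Δd|/0.75 + Δθn/30 + Δθc/30 + Δφ/30` (torsion difference taken on the
circle). The normalizers place the hard stage-1 distance window (0.75 Å,
strict) at deviation 1, so "one threshold-worth" of error contributes one
unit regardless of which component carries it. The stage-4 score divides
this sum by 4 (its number of components) before weighting:
`score = w_seq · s_seq − w_geo · dev/4` with default weights (0.5, 0.5).

## The stem convention

A database fragment of length `n` serves a gap of `L = n − 2` residues: its
two terminal residues are superposed onto the stems ({N, CA, C, O} when O
is present on both, else {N, CA, C}) and its interior fills the gap. This
convention makes the native fragment an exact self-graft (stem RMSD 0,
interior reproduced to 1e-6). One consequence: with the standard database
length range of 3–35 residues, gaps longer than 33 residues find no serving
fragments unless the database is built with a larger `max_len`.

## Density processing

* **Simulated maps** deposit unit weight per heavy atom by trilinear
  splatting, then apply a Butterworth low-pass
  `H(f) = (1 + (f/f_c)^{2p})^{-1/2}` with `f_c = 1/resolution` and order
  `p = 8` by default. `H(0) = 1`, so total deposited mass is conserved, and
  the gain at the cutoff is exactly `2^{-1/2}` for every order — both are
  tested analytically. Element-weighted deposition is deliberately omitted:
  at the resolutions of interest backbone shape dominates the correlation.
* **The minimal box** around a gap is the axis-aligned bounding box of the
  prolate spheroid `{p : |p − CA_n| + |p − CA_c| ≤ 3.8 (L+1)}` — the
  contour-length reach of an `L`-residue chain anchored at both stems —
  padded by one nominal resolution and clipped to the map. It is guaranteed
  to contain every stereochemically possible placement of the segment,
  which is the property the extraction must not violate; a tighter box
  would only save compute.
* **Context subtraction** simulates the in-box part of the known structure
  on the box's own grid, normalizes both box and simulation to mean 0 / sd 1,
  and subtracts. Scoring against this residual prevents candidates from
  being rewarded for occupying density that is already explained. Whether
  normalization should precede or follow subtraction is genuinely open; the
  package normalizes both inputs and then subtracts, and exposes
  `subtract = FALSE` in `run_fragfit()` for ablation against the raw box.
* **CCC** is computed over all voxels of the box (no mask) — masking is a
  second-order refinement the package omits by default.

Maps with anisotropic voxels are rejected rather than silently resampled.
MRC/CCP4 2014 mode-2 files are read and written with axis order normalized
to x-fastest.

## Search-stage rules and tie-breaking

* Stage-1 distance window, redundancy RMSD and identity cutoff are strict
  exactly as stated: `|Δd| < 0.75` (a record at 0.75 is excluded), pairwise
  placed-backbone RMSD `< 0.5` deletes (exactly 0.5 survives), and identity
  `> 0.90` removes (exactly 90% survives). These boundaries are pinned by
  dedicated tests.
* Clash screening (heavy-atom pairs closer than 2.0 Å, configurable)
  precedes redundancy deletion; the clash context excludes the stem
  residues themselves, whose positions the fragment terminals overlay by
  construction, and the first peptide-bonded neighbors are the stems, so no
  bonded pair is ever counted.
* Redundancy deletion keeps the candidate with the lower stem RMSD; all
  orderings break ties by (score, stem RMSD, fragment id), making results
  invariant to database record order.
* The clash cutoff (2.0 Å) is a conservative heavy-atom bound for
  backbone-only models; no value is prescribed by the method itself.

## Validation metrics

Backbone RMSD is computed in the frame fixed by stem superposition — no
additional fitting — as `sqrt(mean |X_i − Y_i|^2)` over matched backbone
atoms. The TM-score uses the simplified equal-length form
`(1/L) Σ 1/(1 + d_i²/d0²)` on CA atoms in the same frame, with
`d0(L) = 1.24 (L−15)^{1/3} − 1.8`, floored at 0.5 Å. The floor keeps short
segments well-defined but makes the 0.5-score threshold very demanding for
`L ≤ 21` (where `d0` sits at the floor): sub-Ångström predictions can fall
below TM 0.5 there. Rates of `TM > 0.5` reported by the benchmark harness
should be read with that in mind; the mean TM is reported alongside.

ΔRMSD = RMSD(search top hit) − RMSD(density top hit) measures what the map
adds; positive values mean the density improved the prediction.

Secondary-structure labels for benchmark stratification come from a simple
φ/ψ run-length classifier (helix: runs ≥ 4 near (−60°, −45°); strand: runs
≥ 3 near (−120°, 130°); everything else loop). It is intentionally crude —
it only labels benchmark rows — and an external DSSP assignment can be
substituted wherever labels are accepted.

## What the synthetic fixtures emulate — and what they do not

All tests run on generated data:

* **Ideal segments** are built from standard backbone internal coordinates
  (NeRF chain construction) with α-helical torsions (−57°, −47°), ideal
  extended-strand torsions (−139°, 135°), or self-avoiding random coil.
* **Toy proteins** concatenate helix/strand/loop runs into clash-free
  chains of ~40 residues with complete N/CA/C/O backbones and random
  sequences.
* **Decoys** perturb the native fragment's interior with isotropic Gaussian
  noise (scales spaced over 0.35–2.5 Å) while keeping the terminal residues
  fixed bitwise, and mutate ~40% of interior sequence positions. Fixed
  terminals mean every decoy passes the stage-1 geometry filter with stem
  RMSD 0 — deliberately, so the density re-ranking is the deciding stage,
  which is precisely the property under test.
* **"Experimental" maps** are simulated from the full toy structure,
  optionally with i.i.d. Gaussian voxel noise at a declared SNR.

These fixtures do *not* reproduce real data's structured noise, local
resolution variation, map fragmentation, solvent contrast or B-factor
effects, nor the conformational diversity of a PDB-scale fragment library
(~10⁹ fragments). Passing the test suite therefore demonstrates the
pipeline's internal correctness and the qualitative value of density
re-ranking under controlled conditions — not absolute benchmark accuracy on
experimental maps, which is out of scope at desk scale.

## Problem sizes and numerical choices

The default verification runs use: 24 gaps (helix/strand/loop × lengths
{5, 9, 15, 21} × 2 replicates) with 8 Å maps, 1 Å voxels and mini databases
of the native plus 24 decoys; and a resolution sweep over {4, 8, 12, 20} Å
on windows of lengths {5, 7, 9} with 12 decoys per window. Simulation boxes
are padded by one resolution and rounded up to 2/3/5-smooth dimensions for
FFT efficiency. Oracle-equivalence checks run 100 random instances per
operation at tolerances 1e-12 (closed-form sums) or 1e-9 (superposition).
Degenerate inputs fail loudly: constant maps cannot be normalized,
zero-variance volumes cannot be correlated, collinear point sets cannot be
superposed, and atoms outside a simulation box are an error unless clipping
is requested.

## Known limitations

* Grafted junctions inherit small geometric distortions at the stem
  peptide bonds; no loop-closure refinement is attempted (downstream
  real-space refinement is the intended consumer).
* Only backbone atoms are modeled; side chains are carried through I/O but
  never built.
* The identity filter compares position-wise identity of equal-length
  sequences only; no alignment-based homology detection.
* Multi-model PDB input uses model 1 unless told otherwise; clash checking
  considers exactly the atoms in the gap's context set.
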