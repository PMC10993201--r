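---
title: "Deconvolving and assigning peptide oligomers in IM-MS data"
author: "imsOligo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving and assigning peptide oligomers in IM-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imsOligo)
```

## The problem

Self-assembling peptides such as the tau-derived hexapeptide PHF6
(VQIVYK, here studied as the capped form Ac-VQIVYK-NH2) populate a
ladder of noncovalent oligomers. Electrosprayed as protonated ions
\[nM+zH\]^z+^, these oligomers have m/z = (nM + z·m~H+~)/z, so every
species with the same n:z ratio lands at *exactly* the same m/z: the
singly protonated dimer, the doubly charged tetramer, the quadruply
charged octamer and so on all share one peak (m/z 1580 for this
peptide). Mass spectrometry alone cannot separate them; ion mobility
can, because an n-mer at charge kz is physically larger than the
(n/k)-mer at charge z and arrives at a different mobility.

Two instrument artifacts complicate the picture. Fragile noncovalent
assemblies dissociate *inside* the spectrometer at two loci:

* the **TIMS-multipole interface**, after the mobility cell but before
  quadrupole selection — products change m/z but keep the precursor's
  recorded mobility, so a larger oligomer masquerades in a smaller
  one's m/z channel at its own (higher) 1/K~0~;
* the **collision cell**, after the quadrupole — products keep both
  the precursor's mobility and its selected identity.

The package implements the full workflow that turns these artifacts
into an assignment tool: select one isobaric family with the
quadrupole, extract the ion mobility spectrum (EIM) of every predicted
fragment channel, and read each precursor's mobility from the
coincidence of apexes across its channels.

## Mass and envelope arithmetic

Compositions are residue sums plus water, adjusted for terminal caps
(acetyl: +C2H2O; amide: −OH +NH2). All charging is by protons
(m~H+~ = 1.007276 Da); monoisotopic masses are the default and an
average-mass mode exists for completeness. Isotope envelopes are
aggregated (centroided) distributions computed by iterated convolution
of per-element isotope tables, with exponentiation-by-squaring and
centroid merging so that even 25-mers cost microseconds; peaks below
`minAbundance` (default 10^-4^) are dropped and the rest renormalised.
The envelope of an n-mer is identical to the n-fold self-convolution of
the monomer envelope — one of the tested invariants.

```{r}
M <- compositionMass(peptideComposition("Ac-VQIVYK-NH2"))
M
mzLabel(oligomerMz(M, c(2, 1, 8, 9, 11, 3), c(1, 1, 3, 4, 5, 1)))
```

Charge states are read from isotopologue spacing (≈ 1.00336/z Th) and
the oligomer order from the deconvoluted mass; `inferNZ()` accepts the
candidate only if the back-computed m/z matches within `tolPpm`
(default 100 ppm, deliberately generous so that nominal peak labels
such as "1580" round-trip).

```{r}
inferNZ(1580.0, 0.25, M)[c("n", "z", "assigned")]
```

## The coincidence assignment

`assignByCoincidence()` proceeds in six steps:

1. **Channel prediction.** Every family member's binary dissociations
   are enumerated ((k,c) + (n−k,z−c), charge and monomer count
   conserved exactly); charged products give the fragment channels.
   Channels falling back inside the selection window are excluded as
   unresolvable, as are channels outside the instrument m/z range.
2. **Channel EIMs.** Each channel's EIM is extracted (envelope-based
   selection, ±0.05 Th per isotopologue, when the peptide is given),
   Savitzky–Golay smoothed (window 9, order 3 — the same treatment
   vendor software applies to mobility spectra) and peak-picked with a
   3-point parabolic apex refinement.
3. **Peak acceptance.** Fragment channels shared by many precursors
   span a large dynamic range, so acceptance is governed by an
   *absolute* floor — a fraction (default 0.003) of the precursor
   channel's EIM maximum — plus a topographic-prominence filter that
   rejects noise bumps on the flanks of larger peaks. This keeps the
   weak channels of low-abundance high-order oligomers while
   suppressing noise-only channels (so zero fragmentation yields zero
   assignments).
4. **Clustering.** Apexes across channels are clustered by single
   linkage with `tolMobility` as the link threshold (0.01 V·s/cm² on
   TIMS — half the smallest inter-assignment gap the method must
   resolve — and 0.2 ms on TWIMS).
5. **Matching.** A cluster with at least `minChannels` distinct
   supporting channels (default 2: a published assignment rests on
   exactly two channels, so demanding three would break it) is
   attributable to any member whose channel set covers its support.
   Because monomer-loss products of large members can be m/z-degenerate
   with small members' fragments (e.g. a 14-mer at 4+ and a 7-mer at 2+
   coincide exactly), per-cluster attribution is ambiguous by
   construction. The assignment is therefore the *ordered maximum
   matching*: clusters sorted by decreasing mobility are matched to
   members sorted by increasing n such that both orders are preserved —
   within one family, mobility decreases strictly with oligomer order.
   Ties are broken toward lower-mobility clusters, because interface
   artifacts of larger same-charge precursors always sit *above* the
   true precursor mobility.
6. **Residual classification.** With an intact (no-selection) reference
   dataset, clusters coinciding with the intact mobility of an
   interface-source precursor (same charge, up to `maxMonomerLoss = 3`
   neutral monomer losses — matching the largest attributed case) are
   classified `interface_fragment` with the source named, and are
   excluded *before* matching so they cannot steal assignments;
   leftover clusters matching an intact family position are `intact`;
   clusters above their member's assignment without a reference match
   are `interface_candidate`; the rest are `unexplained`. A
   well-supported unexplained cluster triggers the family-order
   validation warning: the observed coincidences cannot be reconciled
   with mobilities strictly decreasing in n (a real inversion or an
   unmodelled artifact).

```{r}
simQ <- simulateDataset(fixtureConfigQuad1580(2L))
simR <- simulateDataset(fixtureConfigNoQuad(1L))
fam <- isobaricFamily(1580, 0.5, M, nMax = 12, zMax = 6)
res <- assignByCoincidence(simQ$dataset, M, fam,
                           intactReference = simR$dataset,
                           peptide = "Ac-VQIVYK-NH2")
res
```

## CCS calibration

TIMS axes are calibrated with a piecewise-linear monotone map anchored
at Tuning-Mix ions of known reference 1/K~0~ (0.732–2.03 V·s/cm² at m/z
322–2422); anchors are reproduced exactly. Conversion to collision
cross section uses the Mason–Schamp relation with the reduced-mobility
convention (standard gas number density, T defaulting to 273.15 K,
N~2~ mass 28.00615 Da); the temperature convention inside vendor
software is not documented, so it is overridable — relative
cross-platform comparisons are unaffected by the choice.

TWIMS drift times follow the standard travelling-wave power law:
dt′ = dt − EDC·√(m/z)/1000, CCS′ = CCS·√μ/z, and ln CCS′ regressed on
ln dt′. The fit report includes R² = 1 − SS~res~/SS~tot~; noiseless
synthetic calibrants are recovered exactly and a 0.5 % drift-time
noise perturbs the slope by well under 2 %.

`comparePlatforms()` matches species across instruments on exact
(n, z) pairs and reports per-species relative differences
100·|a−b|/mean(a,b), their mean and maximum, a linear fit with R², and
which platform reads systematically larger. Per-species reference CCS
tables are instrument measurements that the package cannot ship, so
the cross-platform statistics are exercised through closed-form cases
(identical inputs → 0 %; a 2 % scaling → 100·0.02/1.01 ≈ 1.98 % per
species with R² = 1).

## The synthetic-data generator

`simulateDataset()` renders each configured species as its isotopic
envelope crossed with a Gaussian mobility peak, then applies the
instrument model in physical order: interface fragmentation (neutral
monomer loss only, keeping the precursor's mobility), quadrupole
selection, collision-cell fragmentation (intensity moved to charged
products in proportion to product charge — yields are not measurable
from the published data, so the charge-proportional split is a
documented, configurable default), and finally additive baseline plus
multiplicative Gaussian noise. Intensity is redistributed, never
created; rendering conserves totals exactly because mobility-profile
weights and envelope abundances are normalised. Features outside the
instrument m/z range (50–3000 by default) are dropped, as they would
be on the instrument.

Key generator defaults and why:

* **Mobility peak σ = 0.004 V·s/cm²** (TIMS): a resolving power of
  roughly 100–150 over the 1–2 V·s/cm² range, enough to separate the
  closest reference apexes (1.126 vs 1.203).
* **Grid 0.001 V·s/cm² / 0.05 ms**: finer than the narrowest printed
  peak separation; bin centers sit on grid multiples with
  nearest-center assignment to avoid edge aliasing.
* **Reference mobilities**: the m/z 1580 family uses the reference
  apex values (1.959, 1.606, 1.416, 1.299, 1.203, 1.126 V·s/cm²);
  species without a reference value (the intact channel ions and the
  interface-source precursors 11^5+^, 12^5+^, 13^5+^, 13^6+^) are
  placed by a crude power-law trend 1/K~0~ = c·n^β^/z (c = 1.195,
  β = 0.713, fitted once to the family trend), with the 13^6+^ source
  set to 1.180 so that fixture clusters stay separated by more than
  twice the coincidence tolerance. These placements are synthetic
  stand-ins, not physical predictions.
* **Fragmentation fractions 0.35 (collision) / 0.6 (interface
  sources)** and abundances within one order of magnitude: strong
  enough that every channel clears the absolute peak floor, weak
  enough that intact peaks dominate — the regime the method is
  designed for.
* **Noise**: baseline features at 0.2 % of the strongest feature plus
  0.5 % multiplicative jitter. Real spectra add chemical noise,
  envelope interferences, detector saturation and drifting baselines
  that the generator deliberately omits; passing the recovery tests
  therefore demonstrates correctness of the assignment logic, not
  robustness to every property of real data.

## Numerical choices and degenerate inputs

* Envelope convolution prunes below 10^-12^ during accumulation and
  merges centroids closer than 0.25 Da; truncation at `minAbundance`
  renormalises so abundances always sum to one (±10^-9^).
* `detectPeaks()` resolves plateaus to their left edge, clamps the
  parabolic offset to ±half a bin, and measures FWHM by interpolated
  half-height crossings; all-zero spectra yield an empty table.
* Empty EIM selections return an all-zero spectrum flagged
  `provenance$empty` with a warning rather than an error.
* `tolMobility = 0` degenerates gracefully: every apex is its own
  cluster, nothing reaches `minChannels`, and the result is an empty
  assignment.
* Monomer precursors have no dissociation pathways (empty table, not
  an error); interface sources with `maxMonomerLoss = 0` are empty.
* The family-membership tolerance in `isobaricFamily()` should stay
  below the inter-family spacing at the target m/z; protonated members
  of one family are *exactly* isobaric, so 0.5 Th is comfortable.

## Known limitations

* Overlapping-envelope least-squares deconvolution is out of scope:
  charge-state reading uses apex positions and spacings only, as the
  assignment workflow does.
* Covalent backbone fragments (b/y ions), non-proton adducts and
  charge reduction by proton transfer are not modelled.
* Without an intact reference the interface/intact classifications
  degrade to `interface_candidate`/`unexplained`; the matching itself
  still resolves interface artifacts through the lower-mobility tie
  break, but a cluster that coincides with a source's intact position
  within the tolerance can in principle be misread if the reference is
  absent.
* Detection-grid counts depend on the S/N estimator. The estimator
  here (median + 1.4826·MAD over signal-free regions, strict S/N > 3)
  is robust and deterministic, but vendor software does not document
  its own, so absolute detected-species counts are not comparable
  across implementations — only the threshold properties are
  (monotonicity, strictness at the boundary).

## Problem sizes in the test suite

The simulations used by the tests and the acceptance checks are sized
for a laptop: fixture datasets of roughly 10^4^ features, random
families of four to six members over twenty seeds, exhaustive
enumeration checks over n ≤ 25, z ≤ 8, and brute-force isotopologue
oracles on molecules of at most eight atoms. These sizes exercise every
code path; nothing in the method scales worse than linearly in the
number of features times the number of channels.
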