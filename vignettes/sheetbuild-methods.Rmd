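---
title: "Building beta-sheets from electron density: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building beta-sheets from electron density: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetbuild)
```

`sheetbuild` traces the β-sheet portion of a protein electron-density
map at moderate resolution (2.5–4 Å). This vignette is the package's
own account of the underlying models, the parameters that matter, the
numerical choices made where the design was genuinely open, and the
limitations a user should keep in mind.

## The physical picture

At 2.5–4 Å a polypeptide backbone is an unresolved tube of density.
Three structural regularities of β-sheets make strands recognisable
without any sequence information:

* adjacent strands run nearly parallel (inclination typically below
  ~30°) with axes ~4.5 Å apart, and the gap between them carries only
  weak density (the hydrogen-bond bridges) compared with the strand
  tubes themselves;
* a strand repeats every two residues, with an axial period of about
  6.7 Å;
* within one repeat the carbonyl O atoms point alternately at the two
  neighbouring strands (half a period apart), and the C-β atoms point
  alternately out of the sheet plane, offset by about a third of a
  period from the carbonyls. Reading that pattern along the axis fixes
  both the register and, in principle, the chain direction.

The pipeline (`build_sheets()`) turns each regularity into a filter:
tube detection and pairing, repeat-averaged register analysis, and
greedy assembly of placed idealized strands.

## Stage parameters and defaults

All parameters live in `sheet_config()`, grouped by stage; defaults are
the method's typical operating values.

| group | parameter | default | meaning |
|---|---|---|---|
| tubes | `spacing` | 2.0 Å | target separation of ridgeline points |
| tubes | `density_floor` | 1.0 σ | minimum point density (maps are normalized on load) |
| tubes | `cut1`, `cut2` | 0.5, 0.75 | min / mean density ratios for two points to count as connected |
| tubes | `min_cos` | 0.5 | alignment cosine for link merging and tube pairing |
| tubes | `target_sep`, `sep_tol` | 4.5, 2.0 Å | closest-approach window for tube pairs |
| tubes | `cc_strand_min` | 0.5 | minimum correlation with the ideal tube template |
| tubes | `tube_radius` | 1.5 Å | radius at which the tube template reaches zero |
| register | `period` | 6.7 Å | two-residue strand repeat |
| register | `probe_radius` | 1.5 Å | off-axis distance of the four probe directions |
| register | `phase_tol` | 1/12 | per-peak phase window of the register/direction tests |
| register | `n_phase_bins` | 36 | phase bins per period (~0.19 Å) — finer than the tolerance by >2x |
| assembly | `overlap_dist` | 1.0 Å | Cα coincidence distance |
| assembly | `min_sequential_overlap` | 2 | sequential coincident Cαs to join or delete |
| assembly | `min_fragment` | 4 | shortest fragment kept |
| assembly | `merge_resolutions` | 2.5, 3, 4 Å | analyses pooled before assembly |

## Numerical choices

**Ridgeline definition.** "Ridgeline" is implemented as a local maximum
of ρ in the plane perpendicular to the eigenvector of the density
Hessian (central differences) with the least negative curvature, with
both cross-ridge curvatures required negative, one Newton refinement
step within that plane, and greedy thinning by descending density to
≥1.4 Å spacing. The local-maximum check probes rings out to 1.5 Å so
that thin series-termination side ridges flanking a strong tube are
rejected; a plain nearest-neighbour check accepts them.

**Line sampling.** Connection tests sample at `line_step` = 0.25 Å
with a local 0.05 Å re-sampling around the coarse minimum. A fine-step
(0.05 Å) oracle in the test suite confirms the booleans are unchanged.
Sampled densities are clamped at zero before the ratio tests so that
Fourier-truncation ripples cannot produce negative thresholds.

**Tube merging tie-breaks.** Connections are processed by descending
mean endpoint density, shorter links first on ties, then by point
index. The secondary key matters on flat density: it consumes
nearest-neighbour links before skip-level links, so three collinear
points become one three-point tube rather than a two-point chord.

**Axis smoothing.** The Cα trace of a strand zigzags with the backbone
pleat, which inflates its arclength by ~13% relative to the axial
distance and would corrupt the phase mapping of the register analysis.
Tube axes are therefore smoothed to their midline with a running mean
of one period before scoring, register analysis and placement.

**Register calibration.** At finite resolution the apparent peak of
the off-axis density is shifted from the generating atom's axial
position by the blend of flanking features — by about +0.05 of a
period for the carbonyl peaks at 2.5 Å, and by a different amount at
4 Å. `register_calibration()` measures these per-direction shifts once
on the ideal strand's own model density at the working resolution and
the register and direction tests apply them covariantly (for the
reverse-direction hypothesis the two sheet-perpendicular biases swap
and change sign). Without this correction the half-period carbonyl
check fails systematically at 4 Å and the direction test loses its
margin at 2.5 Å. The structure of the tests — peak positions against
targets at exact sixths of the period, each within 1/12 — is
unchanged, so the ~1% chance-acceptance rate of the direction test is
unaffected.

**Direction pseudo-symmetry.** A β-strand read backwards nearly
reproduces its own density pattern: with standard backbone geometry the
C-β peaks sit ~0.30 and ~0.78 of a period after the carbonyl rather
than at the idealized 1/3 and 5/6, so the forward and reverse target
sets are separated by only ~0.08 of a period — within the 1/12
tolerance. A perfectly measured profile therefore passes *both*
hypotheses and is reported `ambiguous`; this is a property of the
geometry, not of noise, and it is why the fraction of unambiguous calls
stays well below what the idealized sixth-position arithmetic would
suggest. The returned calls are conservative in the right way: on
noise-free fixtures no returned direction is ever wrong. The pipeline
resolves the remaining ambiguity where the information actually is, in
the atoms: both directions are placed, each is refined by a bounded
rigid translation maximizing atomic-number-weighted map density (so
each twin is judged at its own optimum), and the better-fitting twin is
kept. A direction is labelled unambiguous only when the peak-pattern
test and the density fit agree. On the noise-free reference fixture
this selects the true direction for all strands at every analysis
resolution.

**Strand template.** `build_ideal_strand()` uses Engh–Huber-style bond
geometry. The default torsions (φ, ψ) = (−125.09°, +121.95°) were
solved so the per-residue screw rotation is exactly 180°, making the
two-residue transform a pure 6.70 Å translation: the template then has
an exact translational repeat at the period the register search
assumes. Textbook antiparallel values near (−139°, +135°) give a 6.9 Å
repeat plus a residual per-repeat roll with the same bond geometry, and
are still available as arguments. Placement superposes the template's
middle two-residue repeat rigidly onto the local axis frame of each
period window (tangent, neighbour direction, sheet perpendicular),
which follows axis curvature at the cost of slight inter-repeat
distortion — bonded Cα–Cα distances stay within 3.6–4.0 Å at 10° of
bend per residue.

**Assembly scores.** The tube score (mean axis density × √length) is
inherited by candidates as specified; for ranking during assembly each
placed fragment is re-scored with the same functional form evaluated at
its atom positions, which separates direction twins on their O/C-β fit.
Joined chains take the length-weighted mean member density rescaled by
√(total length), staying commensurate with the tube score. Ties are
broken by fragment length, then lexicographic candidate id, so
assembly is deterministic.

## The synthetic-fixture generator

`sheet_fixture()` emulates the test data the method needs: idealized
parallel or antiparallel sheets (side chains truncated at C-β),
adjacent strands 4.5 Å apart and hydrogen-bond registered (each +y
carbonyl O aligned with the facing amide N of the next strand —
aligning carbonyls with carbonyls would clash the facing O atoms),
optional sheet twist up to the ~30° inclination seen in real sheets,
and model density: atomic-number-weighted Gaussian atoms (B = 15 Å²)
sampled at resolution/4 voxels, truncated in Fourier space at
1/resolution, plus optional seeded Gaussian noise. The noise field is
low-pass filtered to the same resolution before scaling —
crystallographic map noise carries no detail beyond the reflection
cutoff, and white voxel noise would disproportionately (and
unrealistically) destroy the Hessian-based ridge detector. Ground
truth (per-residue Cα positions and strand direction vectors) is
exported with every map.

What the fixtures do *not* emulate: real side chains beyond C-β,
solvent, phasing error with its spatially correlated distortions,
sheet curvature combined with twist, or neighbouring non-sheet
structure. Passing the recovery tests therefore demonstrates the
internal consistency of the method under its own assumptions, not
parity with the published experimental-map statistics; on real
density-modified maps the published method recovered roughly half to
two-thirds of strand residues, and the noisy-fixture behaviour here
(recall dropping toward ~0.4 at 0.3 σ band-limited noise) is of that
order.

## Problem sizes used by the tests

The reference recovery fixture is a 4-strand × 6-residue antiparallel
sheet (24 residues, ~50 × 30 × 18 Å map at 0.625 Å voxels), analysed at
2.5, 3 and 4 Å and assembled — a complete three-resolution run takes a
few seconds. The threshold-sweep suite re-runs the single-resolution
pipeline at seven `cc_strand_min` values on ten seeded noisy fixtures
(0.3 σ); the Monte-Carlo null of the direction test uses 100,000
trials. These sizes exercise every code path while keeping the whole
suite in the minutes range.

## Known limitations

* Direction determination is conservative (see above); most candidates
  are placed in both directions and decided by density fit.
* Maps are treated as P1 orthogonal volumes; crystallographic symmetry
  is not expanded, and non-orthogonal cells are rejected on read.
* No hydrogen-bond-based register refinement and no detection of
  β-bulges or strand ends beyond the density stop criterion; strand
  termini are typically built one repeat short or long.
* Strands shorter than two repeats (4 residues) cannot be placed, so
  heavily fragmented tubes (strong noise, resolutions worse than 4 Å)
  lose whole strands rather than building partial ones.
* The tube filter correlation uses a fixed linear-falloff template;
  very curved tubes at 4 Å can score below `cc_strand_min` 0.5 and
  values of 0.3–0.5 are a reasonable operating range, mirroring the
  accuracy/yield trade-off measured by `sweep_cc_strand_min()`.
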