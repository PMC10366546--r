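---
title: "Quantifying 2D protein-crystal assembly in HS-AFM movies"
author: "AFMCrystal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 2D protein-crystal assembly in HS-AFM movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AFMCrystal)
```

## The problem

High-speed atomic force microscopy (HS-AFM) records movies of surface
height maps at a few seconds per frame. When a membrane-binding protein
such as the aegerolysin ostreolysin A6 (OlyA6) is added to a supported
lipid bilayer containing its sphingolipid receptor (ceramide
phosphoethanolamine with cholesterol), the protein first covers the
membrane randomly and then reorganizes into striped two-dimensional
crystals. Quantifying that process from the movies requires a chain of
image-analysis steps: extracting the crystal's lattice geometry, measuring
heights of individual protrusions along the stripes, tracing stripes
through time to measure how much material associates and dissociates
between frames, mapping where the assembly is stable, and comparing the
topographs against what an AFM tip would record over the known atomic
structures. `AFMCrystal` implements that chain as reusable, tested
components, together with a synthetic movie generator that provides exact
ground truth for every estimator.

## The synthetic scene and what it emulates

Raw HS-AFM movies of this system are not publicly archived, so the
generator is a first-class part of the package: it is the reference input
for every test, and its event log is the oracle against which the kinetics
estimators are scored.

The scene has three height levels: the mica support at 0, a bilayer patch
at 7 nm (the rigid ceramide-phosphoethanolamine/cholesterol bilayer images
unusually thick), and protein protrusions reaching 5 nm above the
membrane, the monomer height implied by the crystal structures. Protein
occupies dimer *slots* on a monoclinic lattice with the measured cell
a = 10.8 nm, b = 6.6 nm, gamma = 100 degrees; one unit cell holds three
dimers (slot pitch a/3 = 3.6 nm): the two head dimers (AB, CD) that
together form an almost circular tetramer, and the narrower neck dimer
(EF).

Three template choices are the package's own, made once and calibrated on
the generator itself, because only tetramer-level ellipse axes are
measurable in the published images:

* **Per-dimer footprints** of 5.1 x 3.0 nm (head) and 5.1 x 2.4 nm (neck)
  leave 0.6-1 nm grooves between neighbouring dimers. This makes
  individual dimer protrusions resolvable in line profiles (as they are in
  real high-resolution frames) while keeping the inter-stripe contrast
  dominant in the power spectrum.
* **The neck is displaced** 0.15 b off the stripe centre line and tilted
  20 degrees off the stripe normal. Besides mimicking the observed neck
  orientation, this breaks the *pseudo-translation* by a/3: if all three
  dimers looked alike, the lattice fit would report a cell three times too
  short.
* **The second periodicity.** In alternate repeat units the EF dimer sits
  0.15 nm lower, staggered by one unit between adjacent stripes. This
  reproduces the qualitative long-range height modulation along stripes.
  The real-space geometry behind the reported 14.5 nm Fourier spacing of
  that modulation is not derivable from the printed unit cell (2a would be
  21.6 nm), so the stagger is exposed as a parameter and the generator
  makes no claim to reproduce 14.5 nm.

Growth kinetics follow the observed anisotropy: stripes elongate by whole
dimers at their two ends (Poisson counts per end per frame; means
`kAssoc`, `kDissoc`), while transversal growth happens only by nucleating
a one-dimer stripe on a row adjacent to an existing stripe. Near the
membrane edge, where the real assemblies are transient, dissociation is
amplified by `edgeInstabilityFactor` for stripes whose centroid lies
within `edgeBand` of the patch boundary. Only the *net* end displacement
per frame is applied and logged, because the net change is what any
between-frame measurement (including the manual tracing the package
automates) can observe. Stripes never merge; growth stops one empty slot
short of a same-row neighbour.

The default scan (0.5 nm/px, 256 x 256 px, Gaussian tip blur of 0.5 nm,
i.i.d. Gaussian pixel noise of 0.1 nm, 2 s frame interval) resolves the
6.5 nm stripe pitch with 13 pixels per period. The default kinetic rates
(4 and 1.5 dimers per end per frame, four-fold edge amplification) put the
median association step near 14.4 nm, matching the scale of the reported
event-size distributions. What the generator does *not* emulate: lateral
drift, scan-line artifacts, tip changes, protein diffusing between
binding sites, membrane defects, and partial-height (tilted) protrusions.
Tests passing on this generator therefore validate the estimators'
correctness on an idealized instrument, not robustness to every artifact
of real data.

```{r demo}
mov <- generateMovie(demoConfig(nFrames = 6L, seed = 1L))
mov$stack
head(mov$eventLog)
```

## Lattice analysis

`autocorrelation()` computes the normalized autocorrelation function (ACF)
by the spectral route after mean subtraction and a Hann window. The window
choice is fixed and documented: it suppresses the boundary leakage that
would otherwise scatter spurious ACF maxima, at the cost of a gentle,
radius-dependent decay of peak values (the ACF of a lattice translation is
then slightly below 1, decreasing with lag).

`estimatePeriodicities()` reports the strongest non-DC power-spectrum
peaks as spacings and directions, with sub-bin refinement by a 3 x 3
power-weighted centroid. A peak must exceed both 5x the median spectral
power and a Bonferroni-style quantile of the exponential null (white-noise
power spectra are exponentially distributed, so thousands of bins exceed
5x the median by chance in a 256 x 256 spectrum; the extra null keeps
featureless images empty). Absolute peak powers depend on the window and
detrending and are reported in relative units only; spacings are the
comparable quantity.

`fitUnitCell()` turns ACF maxima into a cell: candidate lag vectors are
filtered, the two shortest non-collinear survivors are Lagrange-reduced to
the unique reduced basis, and the cell is reported with a >= b and gamma
by its obtuse representative (negating b maps gamma to 180 - gamma without
changing the lattice), matching the convention in which the printed cell
is obtuse. Orientation is recovered modulo 180 degrees, an intrinsic
ambiguity of the even ACF. One filter deserves emphasis: the dimer
sublattice (pitch a/3) produces pseudo-translation maxima whose ACF value
approaches that of true translations once tip blur smooths the
differences between dimers. True lattice translations, however, decay
*monotonically* with lag radius under the window, so any candidate whose
value falls below 0.8x the best value found at an equal-or-larger radius
is discarded. The factor 0.8 was set by measuring both peak families on
noise-free and default-noise synthetic crystals across orientations; the
two families are separated by more than 0.15 in ACF value in both
regimes.

```{r lattice}
occ <- do.call(rbind, lapply(-30:30, function(r)
  data.frame(id = r + 31L, row = r, slotMin = -45L, slotMax = 45L)))
topo <- renderTopograph(occ, RepeatUnitTemplate(),
                        LayerModel(membraneMask = list(shape = "full")),
                        Lattice2D(10.8, 6.6, 100, orientation = 25,
                                  origin = c(60, 60)),
                        ScanParams(seed = 3L))
fitUnitCell(topo)
estimatePeriodicities(topo, nPeaks = 2)
```

The dominant spacing equals b sin(gamma) (6.6 sin 100 deg = 6.50 nm): the
stripe pitch and the cell edge are the same measurement seen by two
stages, which the tests assert as the *stripe-pitch identity*.

## Profiles and protrusion statistics

`extractProfile()` samples the height map bilinearly along a segment
(exact on affine fields), averaged over an odd number of parallel
one-pixel-offset lines. `detectProtrusions()` finds local maxima by
prominence (default 0.05 nm, above the noise scale) with a minimum
separation (default 2 nm, below the 3.6 nm dimer pitch); plateaus -
common in noise-free synthetic frames - are compressed to their centre
sample first. Peaks are labelled cyclically 1, 2, 3, 1\*, 2\*, 3\*
reflecting the three-dimer repeat; which peak is "1" is a caller-supplied
phase, since the assignment is a convention. `heightDifferenceStats()`
pools the paired differences h(1)-h(2), h(2)-h(3), h(3)-h(1\*) across
profiles; on generator output with the EF drop enabled the 2-3 median is
positive and the 3-1\* median negative, the programmed signature of the
lowered third protrusion.

`notchedBox()` fixes the quartile convention to Tukey hinges (box-plot
software conventions differ and the original convention is unknowable) and
uses the McGill notch half-width 1.57 IQR/sqrt(n) as the approximate 95%
confidence interval of the median.

## Kinetics

`traceStripes()` automates the manual stripe tracing: the image is probed
at every dimer-slot centre of every lattice row crossing the frame, and
runs of occupied slots become traces. Working on the slot grid quantizes
lengths to multiples of a/3, which removes sub-pixel boundary jitter: with
blur and noise at their defaults, traced lengths still equal the
ground-truth slot counts exactly. The protein/membrane threshold defaults
to the midpoint between the membrane median and the frame maximum; a frame
whose relief above the membrane is under 1 nm is treated as protein-free.

`matchAndMeasure()` compares two traced frames per lattice row as a
slot-set difference: runs of gained slots are associations, runs of lost
slots dissociations, each attributed to the overlapping trace (largest
overlap first, ties by id). This definition handles end growth, interior
gaps, new stripes and vanished stripes uniformly and guarantees the
conservation identity - total traced length changes by exactly the sum of
signed event lengths - which `cumulativeCoverage()` then accumulates into
the coverage-versus-time series (negative increments are legitimate:
dissociation can outweigh association in an interval).
`unitSizeStats()` summarizes event-length distributions per class, and
`gaussianFit()` is a generic four-parameter Gaussian least-squares utility
(Levenberg-Marquardt; near-constant input returns the degenerate
zero-amplitude solution) for summarizing such distributions or coverage
histograms.

Frames may be omitted (as low-quality frames are in practice): records
carry the true frame indices and are never interpolated.

## Stability maps

`stabilityMaps()` computes per-pixel mean and *population* standard
deviation over a frame range (the population convention is the package's
fixed choice; with ~20 frames the difference from the sample SD is
inconsequential but the convention must be stated). No drift correction is
applied; frames are assumed registered. `lineStability()` gives the mean
+/- SD profile along a line across frames; because profile extraction is
linear, the mean profile equals the profile of the mean frame, an identity
the tests assert exactly. On generator movies with edge-amplified
dissociation, the SD map lights up in the edge band - the quantitative
counterpart of "stable centre, restless edge".

## Structure-based tools

`readStructure()` ingests PDB files (alternate locations resolved to the
highest-occupancy atom, first on ties; waters dropped).
`kabschRmsd()` performs least-squares rigid superposition via SVD with a
proper rotation enforced, pairing atoms by residue number and atom name;
by default any unpaired atom is an error, while `strict = FALSE` uses the
common atoms (needed when comparing homologous structures with unresolved
termini). `verticalExtent()` measures the backbone span along an axis
after excluding flexible terminal residues; which residues count as
flexible is not enumerable from the published analysis, so the exclusion
counts are caller parameters, and the axis may be given explicitly or as
the longest principal axis.

`pseudoAFM()` renders what a tip would record: atoms become a hard-sphere
upper envelope (Bondi radii, fixed in-repo for bit-stable rasterization;
cells not covered by any atom sit on a supporting plane at the envelope
minimum), and the surface is grayscale-dilated by a sphere-capped cone
(apex radius 0.5 nm, cone half-angle 8 degrees, scan step 0.25 nm by
default). The "8 degrees" of the simulated-scanning convention is
interpreted as the *half*-angle; both the angle and the interpretation are
configurable. The dilation is computed by an exact maximum search over the
tip support (the support radius follows from the surface height range), so
it equals brute force by construction - the tests verify this against an
independent exhaustive search. `tileCrystal()` places m x n translated
copies of a repeat unit on the lattice with uniquely relabelled chains,
and `depthContours()` extracts iso-height polylines at stated depths below
the surface top, the numerical form of relief contour maps.

```{r pseudo}
unit <- AtomicStructure(data.frame(
  elety = c("C1", "N1"), resid = "LIG", resno = 1, chain = "A",
  x = c(0, 2), y = c(0, 1), z = c(0, 1), element = c("C", "N")))
img <- pseudoAFM(tileCrystal(unit, Lattice2D(2.4, 1.8, 100), 4, 3),
                 TipModel(radius = 0.5, halfAngle = 8, scanStep = 0.25))
img
```

## Numerical choices and degenerate inputs

* Coordinates: image origin at the top-left pixel centre, x along
  columns, y along rows (downward), heights in nm, mica = 0; structure
  files in Angstrom, converted at the module boundary only.
* A constant image has no normalizable ACF and no contours; both are
  errors, not silent results. Zero-variance input to the Gaussian fit
  returns the degenerate zero-amplitude solution instead of failing.
* Collinear ACF peaks cannot generate a 2D lattice and raise a
  degenerate-lattice error.
* Sub-pixel/sub-bin peak refinement uses 3 x 3 weighted centroids; ties in
  peak selection break by descending power, then id/spacing - all
  orderings are total, so results are deterministic.
* All stochastic stages consume a single seed; fixed seeds give
  bit-identical movies, logs and images.
* Stack files store 32-bit float TIFF pages scaled into the unit interval
  with the nm scale recorded in a JSON sidecar (TIFF float readers
  commonly clamp outside [0, 1]); heights are restored on read to ~7
  significant digits.

## Problem sizes in the tests

The test and acceptance workloads use 256 x 256 px frames (128 nm field),
movies of 10-16 frames, and brute-force oracles on grids up to 64 x 64;
these sizes make every property checkable in seconds while leaving all
estimators in the regime they were designed for (>= 10 px per stripe
period, >= 5 repeat units per stripe).

## Known limitations

* The stripe tracer assumes straight stripes on a known lattice; it does
  not handle curved filaments or drifting frames (no drift correction, as
  none is applied in the workflow it automates).
* Lattice orientation is determined modulo 180 degrees.
* The two public crystal structures used by the structure-comparison
  examples (PDB 4OEB and 6MYI) are not redistributed; place them under
  `inst/extdata/` (or the installed package's `extdata/`) to run those
  checks.
* The generator's flat-topped protrusions make noise-free height
  histograms exactly discrete; real protrusions are rounded. Estimators
  that only need thresholds and peak positions are unaffected, but
  absolute peak *shapes* should not be validated against the generator.
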