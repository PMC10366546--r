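# AFMCrystal

Quantitative analysis of two-dimensional protein-crystal assembly on
supported lipid bilayers from high-speed AFM (HS-AFM) height movies, with
a ground-truthed synthetic movie generator for validation.

The package targets the workflow that arises when a membrane-binding
protein (the motivating system is the aegerolysin ostreolysin A6 on a
ceramide-phosphoethanolamine/cholesterol bilayer) reorganizes from random
surface coverage into striped 2D crystals: every analysis stage consumes
height maps in nanometres and produces lattice geometry, protrusion
statistics, growth kinetics, stability maps or structure-based renderings.

## What it computes

* **Lattice geometry** — Gaussian filtering, normalized 2D
  autocorrelation (spectral route, Hann window), FFT periodicity
  estimation with sub-bin peak refinement, and fitting of the primitive
  monoclinic unit cell. The cell is reported in the convention a ≥ b with
  the interaxial angle γ given by its obtuse representative: the
  motivating crystal has a = 10.8 nm, b = 6.6 nm, γ = 100°, whose stripe
  pitch b·sin γ ≈ 6.5 nm is also the dominant Fourier spacing.
* **Profiles and protrusion statistics** — bilinear line profiles,
  prominence-based protrusion detection with cyclic 1, 2, 3, 1\*, ...
  labelling of the three dimers per repeat unit, pooled pairwise height
  differences, and notched box statistics (Tukey hinges, McGill notch
  1.57·IQR/√n ≈ 95% CI of the median).
* **Assembly kinetics** — automated stripe tracing on the dimer-slot grid
  (pitch a/3 = 3.6 nm), frame-pair matching that classifies length
  changes into association and dissociation events, event-size
  distributions, and cumulative surface coverage with signed increments.
* **Stability** — per-pixel mean and SD maps over frame ranges and
  mean ± SD line profiles, quantifying stable interiors versus restless
  membrane edges.
* **Structure tools** — PDB ingestion, Kabsch superposition RMSD,
  backbone vertical extent, m × n crystal tiling, pseudo-AFM rendering by
  grayscale dilation with a sphere-capped conical tip (R = 0.5 nm,
  half-angle 8°, 0.25 nm scan step by default), and depth contours.
* **Synthetic generator** — kinetic Monte-Carlo stripe growth
  (dimer-level association/dissociation at stripe ends, nucleation-driven
  transversal growth, edge instability) rendered into height movies with
  mica/membrane/protein layering (0 / 7 / +5 nm), tip blur and pixel
  noise; every event is logged as exact ground truth.

The pseudo-AFM model is the grayscale dilation
`out(x) = max_u [surface(u) − tip(u − x)]` with the tangent-continuous
sphere-capped cone `tip(r) = R − √(R² − r²)` for `r ≤ R·cosθ`, continued
as `R − R·sinθ + (r − R·cosθ)/tanθ`.

## Worked example

```r
library(AFMCrystal)

# a synthetic assembly movie: 7 seed stripes growing for 20 frames (2 s/frame)
cfg <- demoConfig(nFrames = 20L, seed = 42L)
cfg$init <- data.frame(id = 1:7, row = -3:3,
                       slotMin = c(-6L,-8L,-7L,-9L,-6L,-8L,-5L),
                       slotMax = c( 5L, 7L, 8L, 9L, 6L, 7L, 4L))
mov <- generateMovie(cfg)
mov$stack
#> TopographStack: 20 frames, 256 x 256 px, 0.5 nm/px, t = 0..38 s

# fit the unit cell on the crystalline region of the last frame
crop <- cropTopograph(getFrame(mov$stack, 20L), c(18, 112), c(38, 92))
fitUnitCell(crop)
#> Lattice2D: a = 10.8 nm, b = 6.59 nm, gamma = 99.95 deg, orientation = -179.9 deg
estimatePeriodicities(crop, nPeaks = 1)
#>   spacing_nm direction_deg    power
#> 1   6.518010       90.013 14451976

# trace stripes in every frame and measure growth kinetics
kin <- measureMovieKinetics(mov$stack, cfg$lattice, minLength = 3)
unitSizeStats(kin$records)$association
#> BoxStats: median 7.2 [notch +/- 1.649], hinges 3.6/10.8, range 3.6..25.2, n = 47
tail(cumulativeCoverage(kin$records, frameInterval = 2), 1)
#>    frame time_s increment_nm coverage_nm
#> 16    20     40          7.2       302.4
```

The fitted cell reproduces the generator's lattice to 0.01–0.1 nm, the
dominant spacing is the stripe pitch (6.5 nm), association steps come in
multiples of the 3.6 nm dimer slot with their median near two dimers, and
the crystal gained ~300 nm of total stripe length over 40 s. On real
movies the same calls apply to stacks read with `readTopographStack()`.

## Package layout

S4 classes (`Topograph`, `TopographStack`, `Lattice2D`,
`RepeatUnitTemplate`, `LayerModel`, `GrowthParams`, `ScanParams`,
`OccupancyMovie`, `StabilityMaps`, `AtomicStructure`, `TipModel`,
`BoxStats`, `ContourSet`) carry validity checks, accessors and `show()`
methods; analysis functions are plain camelCase exports. The methods
vignette (`vignettes/afm-crystal-assembly.Rmd`) documents the model
assumptions, parameter choices and known limitations.
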