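---
title: "Methods: quantitative DNA-histone co-structure analysis of two-color SMLM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative DNA-histone co-structure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Two-color 3D single-molecule localization microscopy of chromatin produces
two point clouds per nucleus: STORM localizations of labeled genomic DNA and
DNA-PAINT localizations of the core histone H2B. H2B localizations organize
into *nucleosome clutches* (co-packed groups of nucleosomes) that in turn
cluster into *islands* of higher-order folding. `clutchscope` quantifies how
DNA is packed around those clutches:

1. **Voronoi density.** Each localization receives a Voronoi cell clipped to
   a hand-drawn nuclear mask (boundary polygon minus nucleolar exclusions);
   the local density is the inverse cell area (2D) or volume (3D). This
   estimator needs no bandwidth or search radius and supports compaction
   statistics such as the heterochromatin/euchromatin fold (mean density of
   the smallest 15% of cells by area over the largest 15%).
2. **Clutch segmentation.** Single-linkage clustering of H2B localizations
   at a linkage distance `eps` (default 40 nm, about twice the median
   lateral localization precision), with components below `min_size = 5`
   discarded. Islands are linked at 1.5 x `eps` via minimum inter-member
   distance, transitively.
3. **Clutch-seeded radial profiling.** Clutch centroids seed a second
   Voronoi partition; every DNA localization belongs to exactly one clutch
   polygon, preventing double counting. Disks of increasing radius (10 nm
   steps) around each centroid are clipped to the polygon and the mask; the
   cumulative DNA density is count over clipped area. The fraction of DNA
   within the clipped 120 nm disk (2.5 clutch standard deviations, covering
   about 98.8% of a Gaussian clutch) is the *clutch-associated* fraction.
4. **Annulus similarity.** For each pair of 10 nm annuli, a two-group
   Kruskal-Wallis test compares the per-clutch annulus densities pooled over
   all clutches of all cells. The *clutch-DNA transition radius* r* is the
   smallest radius such that all annulus pairs beyond it are similar
   (p >= alpha = 0.05) while at least one pair at or below it is not.
5. **Registration.** A single second-order polynomial surface maps the
   PAINT channel onto the STORM channel; fiducial beads tracked across
   frames give per-channel drift trajectories; a linear affine transform
   refines the lateral overlay and a rigid z translation aligns the axial
   coordinate; astigmatic z assignment inverts third-order width-vs-z
   calibration curves in square-root width space on a 1 nm grid.

## Key parameters

| parameter | default | units | why |
|---|---|---|---|
| slice thickness | 120 | nm | axial window around the focal plane used for 2D analysis |
| render sigma | 20 (9 optional) | nm | Gaussian rendering width; 9 nm variant kept for display parity |
| `eps` | 40 | nm | about 2 x median localization precision |
| `min_size` | 5 | locs | smallest accepted clutch |
| island link | 1.5 x eps | nm | "close proximity" between clutches |
| `dr`, `r_max` | 10, 200 | nm | radial step and profile extent |
| association radius | 120 | nm | 2.5 clutch sd; >= 98% Gaussian mass |
| NND-curve radius, bin | 70, 20 | nm | clutch-DNA radius of untreated cells; NND bin width |
| density bins | 300 log-spaced, 1e-10 to 0.94 nm^-2 (2D); 5e-7 to 0.0025 nm^-3 (3D) | | cumulative distribution binning |
| QC (control) | occupancy > 35%, clustered area > 15%, clusters/island > 3 | | strict inequalities |
| QC (treated) | > 25%, > 10%, > 1.5 | | TSA reorganizes H2B |
| Nyquist gate | <= 32 | nm/localization | cube root of area-per-localization x slab |
| z grid, reject | 1 nm, 0.5 sqrt-nm | | astigmatic inversion |
| drift window | 50 | frames | moving-average smoothing |
| frame regrouping | 5 | frames | effective 100 ms PAINT exposure |

## The synthetic-data generator: what it emulates, and what it does not

`simulate_nucleus()` draws an elliptical analysis sub-region (default
3.5 x 2.5 um semi-axes) with optional nucleolar exclusions; islands from a
parent Poisson process (0.3 per um^2), each with 1 + Poisson(3) clutches at
gamma-distributed spacings (mean 220 nm, floor 160 nm); per-clutch
localization spreads log-normal around 20 nm; H2B localization counts
Poisson (control mean 150, TSA 90). DNA is a mixture: a clutch-associated
pool (fraction 0.717 control / 0.627 TSA) uniform over disks of the
clutch-DNA radius (70 / 40 nm) around clutch centres with per-clutch counts
proportional to clutch size, and a clutch-free pool drawn from a smooth
log-normal intensity field (sdlog 1.2, 1 um correlation length, 20% uniform
floor) emulating micron-scale chromatin density variation. Fiducial beads,
linear/random-walk drift, a gentle second-order chromatic warp, a rigid z
offset and cubic astigmatic width encoding complete the acquisition model.
The total DNA density default (0.004 nm^-2) puts the Nyquist metric near
30 nm/localization, just inside the 32 nm gate.

Deliberate departures from the source system, and their consequences:

* **Clutch spread vs. NND.** Real clutch ensembles average ~48 nm standard
  deviation with centroid NNDs down to ~50 nm. Blobs that broad and close
  cannot be separated by single-linkage at 40 nm (measured merge fraction
  57% at 150 nm spacing), so the generator uses tighter clutches (median
  20 nm) at >= 160 nm spacing; >85% of true clutches are recovered
  individually. The NND axis of the density-vs-NND curve therefore starts
  near 160 nm rather than 50 nm; the control-above-TSA ordering is
  preserved.
* **DNA at the localization level.** The association fraction and clutch-DNA
  radius parameterize the *localization map* (what the analysis measures),
  so the DNA channel carries no additional lateral noise; localization noise
  is modeled where it matters for registration and precision analyses (H2B,
  beads).
* **Heterogeneous background.** A homogeneous Poisson clutch-free pool makes
  annulus densities non-exchangeable at large clutch counts (count/area
  lattice artifacts; see below); the heterogeneous field both matches the
  orders-of-magnitude density variation seen in real nuclei and keeps
  background annuli exchangeable.
* **Sparse fields.** Island density is set so that the 120 nm influence
  disks tile only a few percent of the field. The positive bias of the
  associated-fraction estimator equals (background share) x (disk area
  coverage); at ~5% coverage the bias stays under half the recovery
  tolerance. Real nuclei are denser; a green recovery test therefore
  establishes estimator correctness, not realism of the density regime.
* **QC thresholds.** The gates describe real acquisitions (millions of
  localizations). The sparse synthetic sub-regions do not reach control
  occupancy; pipeline runs on synthetic presets disable the gate explicitly
  in their configuration, and the gating logic is tested against constructed
  reports at every threshold boundary.

## Numerical choices

* Voronoi cells are built by half-plane clipping with a security-radius
  bound and grid-accelerated neighbour search; masks may be non-convex, so
  mask clipping reduces to Sutherland-Hodgman clipping of the mask against
  the convex cell, with exclusion areas subtracted. 3D volumes clip convex
  polyhedra against the mask prism via a signed fan triangulation of the
  mask polygon. Conservation of the usable mask measure holds to ~1e-15
  relative.
* Circles are polygonized with 128 vertices (area error < 0.1%); a disk
  fully inside its polygon short-circuits to the exact clipped-cell area.
* Duplicate coordinates are jittered deterministically (<= 1e-6 nm, keyed by
  record index).
* Boundary-incident points count as inside at 1e-9 nm tolerance; DNA on a
  polygon boundary is assigned to the lower clutch id.
* Astigmatic inversion searches a 1 nm grid in sqrt-width space with a
  0.5 sqrt-nm rejection threshold.
* The FRC resolution is the first crossing of the smoothed half-split
  correlation from above 1/7; a curve that never rises above the threshold
  (pure noise) reports "not determined".
* Transforms serialize to JSON at 17 significant digits, making reloads
  bit-identical.

## Statistical caveats discovered during validation

These are properties of the prescribed analyses themselves, reproduced here
because they shape what a green or red test means.

* **The all-pairs transition rule saturates at large n.** The per-pair
  Kruskal-Wallis test compares count/area ratios whose discrete support
  differs between annuli of different area. The resulting Mann-Whitney
  offset (computed exactly from Poisson mass functions: |delta| = 0.005-0.07
  for area ratios 1.5-4 at per-annulus means of 1-15 counts) is negligible
  at hundreds of clutches but crosses significance as z ~ delta * sqrt(3n).
  Consequently the transition radius is recovered within one annulus at
  n ~ 10^3 clutches (10/10 seeded runs) but overshoots systematically at
  n >= 10^4, where the corresponding acceptance expectation is left failing
  by design rather than patched. For the same reason uniform DNA almost
  never yields a formally "not determined" radius (some pair among 190 is
  sub-alpha with probability ~1), and the package reports the sub-alpha
  pair fraction alongside r*.
* **The median-curve KS comparison is coarse.** Comparing the 300-bin median
  cumulative curves of two conditions turns a log-density shift into a KS
  statistic of (shift in bins)/300, so only order-of-magnitude density
  changes are detectable that way; the pooled per-cell KS is reported as a
  sensitive secondary statistic.
* **Annulus versus cumulative-disk samples.** The similarity matrix uses
  10 nm annuli by default (`use = "annulus"`); cumulative clipped disks
  (`use = "disk"`) are also available since both framings appear in
  descriptions of this analysis. Percentile classes in `compaction_fold()`
  are count-weighted by default with an area-weighted option.

## Known limitations

* Raw camera frames are out of scope: the pipeline starts from localization
  tables, and the 5-frame PAINT summation is emulated by frame-index
  regrouping.
* The chromatic correction in z is a rigid translation only.
* The generator does not model per-fluorophore blinking kinetics or camera
  noise; blinking is reduced to geometric runs of consecutive frames,
  sufficient for the precision and drift analyses.
* Masks are polygonal and hand-supplied (or elliptical in simulation); no
  automatic nuclear segmentation is attempted, and the manual sub-region
  selection of the reference workflow maps to an explicit mask/ROI input.
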