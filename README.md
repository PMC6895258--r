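# clutchscope

Quantitative co-structure analysis of DNA and histone localizations from
two-color 3D single-molecule localization microscopy (STORM for EdC-labeled
genomic DNA, DNA-PAINT for histone H2B), for researchers studying chromatin
nano-organization: nucleosome clutches, clutch islands, and how much DNA
each clutch compacts around itself.

The package implements, end to end and against synthetic ground truth:

* **Voronoi density maps** (2D and 3D), clipped to a nuclear mask with
  nucleolar exclusions: local density at each localization is the inverse
  Voronoi cell measure; compaction fold = mean density of the smallest 15%
  of cells by area over the largest 15%; 300 log-binned cumulative density
  distributions with median/IQR bands and KS comparison between conditions.
* **Clutch segmentation**: single-linkage clustering at `eps = 40` nm with
  `min_size = 5`; islands linked at 1.5 x `eps`; dataset QC (occupancy,
  clustered area, clusters per island, Nyquist `(area/n x 120)^(1/3)`
  <= 32 nm/localization, FRC resolution at the 1/7 threshold, localization
  precision from >= 5-frame emitter runs) with strict condition-specific
  gates.
* **Clutch-seeded radial DNA profiling**: Voronoi polygons seeded at clutch
  centroids assign every DNA localization to exactly one clutch; disks in
  10 nm steps, clipped to polygon and mask, give cumulative densities; the
  clutch-associated DNA fraction uses the clipped 120 nm disk (2.5 clutch
  sd, i.e. >= 98% of the clutch Gaussian); annulus-pair Kruskal-Wallis
  similarity matrices yield the clutch-DNA transition radius r*; plus
  NND-conditioned density curves, density-vs-clutch-size curves, and
  shift/subsample robustness controls.
* **Two-channel 3D registration**: second-order polynomial chromatic warp,
  fiducial grouping and drift correction, affine refinement, rigid z
  translation, astigmatic z assignment from third-order width-vs-z
  calibrations, 5-frame regrouping, 120 nm focal slice.
* **A synthetic nucleus generator** with full ground truth (clutch centers,
  DNA association labels, true transforms), with `control` and `tsa`
  presets (association fractions 0.717 / 0.627, clutch-DNA radii 70 / 40 nm,
  smaller clutches and 5 nm tighter spacing under TSA).

## Worked example

```r
library(clutchscope)

preset <- condition_presets("control")
preset$nucleus$semi_axes <- c(8000, 6000)          # ~100-clutch field
sim <- simulate_nucleus(preset$nucleus, preset$dna, acquisition_model(),
                        seed = 1)

h2b <- clip_to_mask(select_slice(sim$h2b), sim$mask)   # 120 nm focal slice
dna <- clip_to_mask(select_slice(sim$dna), sim$mask)

print(dna)
vor <- tessellate(dna, sim$mask, dimension = 2)
cat(sprintf("compaction fold (15th/85th area percentiles): %.2f\n",
            compaction_fold(vor)))

clutches <- group_islands(segment_clutches(h2b, eps = 40, min_size = 5),
                          link = 320)
print(clutches)
cat(sprintf("clusters per island: %.2f\n",
            attr(clutches, "islands")$clusters_per_island))

polys <- clutch_voronoi(clutches, sim$mask)
prof  <- radial_profile(polys, dna, dr = 10, r_max = 200)
cat(sprintf("clutch-associated DNA at 120 nm: %.1f%%\n",
            associated_fraction(prof, 120)$percent))
cat(sprintf("clutches with >5 DNA locs in 120 nm: %.1f%%\n",
            colocalized_clutch_fraction(prof, 120, 5)))
cat(sprintf("clutch-DNA transition radius: %s nm\n",
            format(transition_radius(similarity_matrix(prof)))))
```

Output from this exact run:

```
<loc_table> 602420 localizations [nm], columns: x, y, z, frame, channel
compaction fold (15th/85th area percentiles): 382.12
<clutch_set> 145 clutches (eps = 40 nm), mean 161.3 locs/clutch
clusters per island: 4.26
clutch-associated DNA at 120 nm: 70.2%
clutches with >5 DNA locs in 120 nm: 100.0%
clutch-DNA transition radius: 130 nm
```

Reading the numbers: 70.2% of DNA localizations fall inside the clipped
120 nm disks around the 145 recovered clutches (generator truth 71.7%; the
remainder is clutch-free DNA plus boundary losses). Every clutch has more
than 5 DNA localizations nearby. The compaction fold is far above the
~7-fold seen in real nuclei because the synthetic clutch DNA is much denser
relative to its background than real heterochromatin. The transition radius
from a single 145-clutch field is still noisy (130 nm here); pooled over
roughly a thousand clutches the switch-rule estimate stabilizes at the
generative 70 nm - and at very large n (>= 10^4) the literal all-pairs rule
saturates upward again (see the methods vignette for why).

A full two-condition comparison (QC, Voronoi, co-structure, report):

```r
rep <- run_pipeline(list(
  qc = list(enabled = FALSE),          # synthetic fields are sparser than
                                       # the real acquisitions QC describes
  segmentation = list(island_link_factor = 8),
  conditions = list(
    list(label = "control", condition = "control",
         cells = list(list(preset = "control", seed = 11),
                      list(preset = "control", seed = 12))),
    list(label = "tsa", condition = "treated",
         cells = list(list(preset = "tsa", seed = 21),
                      list(preset = "tsa", seed = 22))))))
print(rep)
```

## Command line

```sh
inst/cli/clutchscope simulate    --preset control --seed 1 --out sim/
inst/cli/clutchscope voronoi     --locs sim/dna.csv --mask sim/mask.json --dim 2
inst/cli/clutchscope clutches    --locs sim/h2b.csv --eps 40 --min-size 5
inst/cli/clutchscope register    --beads-a sim/beads_a.csv --beads-b sim/beads_b.csv
inst/cli/clutchscope costructure --dna sim/dna.csv --clutches clutches.csv \
                                 --mask sim/mask.json --dr 10 --rmax 200
```

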