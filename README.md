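# callosoplan

Computer-assisted trajectory planning for minimally invasive laser
interstitial thermal therapy (LITT) anterior two-thirds corpus callosotomy.

Anterior two-thirds corpus callosotomy palliates drug-refractory
generalised epilepsy (drop attacks, Lennox–Gastaut syndrome) by
disconnecting interhemispheric seizure spread through the corpus callosum
while sparing the splenium. LITT performs the disconnection through
straight stereotactic laser catheters, each building a confluent chain of
5–15 mm thermal ablations with 7 mm pull-backs. Because the callosum is
arched, several catheters are needed, and each must balance vascular
clearance, drilling angle, intracerebral length and the proportion of the
catheter actually inside the callosum.

`callosoplan` is aimed at researchers in stereotactic planning and
image-guided neurosurgery. It implements, end to end:

* **Target generation** — anterior, middle and posterior callosal targets
  from a labelled whole-brain parcellation, by 7 mm Euclidean dilations of
  the subcallosal gyrus and cingulate subregions, pairwise intersection,
  and constraint to the callosum.
* **Constrained search** — an exhaustive, deterministic search over
  scalp-surface entry points overlying five canonical entry gyri paired
  with target-region voxels, under per-family length/angle bounds
  (60 mm/15° for the non-dominant frontal row; 110 mm/35° parietal and
  angular; 90 mm/35° dominant frontal rows) and hard ventricle avoidance.
* **Safety metrics** — a 128-node vascular risk score against the Euclidean
  distance map of a vessel segmentation, with the exact calibration
  *score < 1 ⟺ every node is > 3 mm from vasculature*; minimum vessel
  distance; intracerebral length; drilling angle from the skull-surface
  orthogonal; catheter-in-callosum fraction:

  ```
  r(d) = 0                  d ≥ 10 mm
       = (10 − d) / 7       3 mm ≤ d < 10 mm
       = 1 + (3 − d) / 3    d < 3 mm          score = max over 128 nodes
  ```

* **Ablation simulation** — pull-back count = callosal catheter length / 7 mm
  (ceiling, minimum one), sphere-union cavities anchored at the distal end,
  optionally clipped to the callosum + 2 mm thermal margin.
* **Disconnection assessment** — streamline filtering through the simulated
  cavities as exclusion masks, residual-connectivity volumetry in cm³, and
  an exact anterior-two-thirds / splenium partition.
* **A parametric digital head phantom** — labelled parcellation with a
  superelliptical callosal arch, cingulate bands, five entry gyri,
  ventricles hugging the callosal underside, a pericallosal/bridging-vessel
  tree, and seed-deterministic interhemispheric streamlines — so the whole
  pipeline runs without patient data.

Minimal NIfTI-1 and TCK readers/writers are built in; schemas and reports
are JSON.

## Worked example

```r
library(callosoplan)

ph      <- makeHeadPhantom(phantomConfig())          # 96^3, 1 mm head
vol     <- ph$volume
vessels <- rasteriseVessels(ph$vessels, vol@grid)

targets <- generateTargets(vol)                      # 7 mm dilations
targets
#> TargetRegions:
#>   anterior    328 voxels, centroid (0.0, 19.1, 7.7) mm
#>   middle      228 voxels, centroid (0.0, 14.1, 15.8) mm
#>   posterior   276 voxels, centroid (0.0, -8.5, 17.9) mm

plan <- planCallosotomy(vol, vessels)
plan
#> PlanSet: 5 of 5 specs feasible; 3 trajectories selected
#>   anterior  right_superior_frontal   length   29.2 mm, angle  11.6 deg, risk 1.696, minDist  0.91 mm
#>   middle    right_superior_parietal  length   56.5 mm, angle  23.2 deg, risk 1.675, minDist  0.98 mm
#>   posterior left_superior_frontal    length   50.6 mm, angle  22.5 deg, risk 1.662, minDist  1.01 mm

cc  <- roleMask(vol, "corpus_callosum")
cav <- combinedCavity(plan, cc, vol@grid)            # 2 / 5 / 4 pull-backs

streams <- makeInterhemisphericStreamlines(vol, n = 5000, seed = 7)
assessPlan(plan, streams, cc, vol@grid, cavityMask = cav$mask)
#> DisconnectionReport:
#>   streamlines: 5000 in, 440 surviving
#>   corpus callosum 2.15 cm^3 = anterior two-thirds 1.51 + splenium 0.64
#>   residual connectivity 0.227 cm^3 (anterior two-thirds 0.000 cm^3)
#>   residual in anterior two-thirds: FALSE
```

Reading the output: three target regions sit at the rostrum, genu and
posterior body (centroids ordered front to back). The plan search found
feasible candidates for all five entry/target families and selected three
catheters — one per target — whose minimum vessel distances (~1 mm) reflect
the pericallosal arteries flanking every useful corridor; the catheters run
*along* the callosum (2, 5 and 4 pull-backs). After applying the simulated
cavities as exclusion masks, no streamline crossing the anterior two-thirds
survives (residual anterior volume 0 cm³); the 440 survivors cross the
deliberately spared splenium, whose 0.64 cm³ remains intact.

The same chain runs from the shell, on files or self-generated phantom
inputs:

```sh
Rscript inst/cli/callosoplan.R run --phantom --seed 7 --out out/
Rscript inst/cli/callosoplan.R score --trajectories manual.csv \
    --parcellation parc.nii.gz --schema schema.json \
    --vessels vessels.nii.gz --out scored.csv   # score external manual plans
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the risk score of a
straight trajectory with 5 mm perpendicular vessel clearance in a synthetic
64³ tube volume (`t1`), and — on the default phantom — the number of
candidate trajectories returned by the planner (`t2`), the number of
trajectories in the selected plan (`t3`), and the number of disjoint target
regions produced by the dilation-and-intersection procedure (`t4`), writing
one JSON object with a numeric `value` and problem size `n` per target.
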