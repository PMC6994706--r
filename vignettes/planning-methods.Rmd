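---
title: "Computer-assisted planning for laser anterior two-thirds corpus callosotomy"
author: "callosoplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computer-assisted planning for laser anterior two-thirds corpus callosotomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callosoplan)
```

## The problem

Anterior two-thirds corpus callosotomy is a palliative epilepsy procedure:
interhemispheric seizure spread (drop attacks, tonic/atonic seizures) is
interrupted by disconnecting the anterior two-thirds of the corpus callosum
while sparing the splenium, which limits the risk of a disconnection
syndrome. Laser interstitial thermal therapy (LITT) performs this
disconnection through stereotactically implanted straight laser catheters:
each catheter creates a chain of roughly spherical thermal ablations
(5–15 mm diameter), pulled back a fixed distance between ablations to build
a confluent cavity. Because the callosum is arched and the catheters are
straight, several trajectories are needed, and each must respect the
constraints a stereotactic neurosurgeon works under: entry through a safe
gyral corridor, limited drilling angle against the skull (to prevent the
drill skiving), bounded intracerebral length, no ventricular transgression,
and maximal distance from blood vessels.

`callosoplan` implements the full planning chain — automatic target
generation from a labelled parcellation, constrained multi-trajectory
search scored against a vessel segmentation, pull-back ablation simulation,
and tractography-style quantification of the residual interhemispheric
connectivity — together with a parametric digital head phantom that supplies
every input, so the whole pipeline runs and is testable without patient
data.

## Target generation

The anterior, middle and posterior callosal target regions are derived from
the parcellation by morphological dilation and Boolean intersection. The
subcallosal gyrus and the anterior, middle and posterior cingulate are each
dilated by 7 mm (exact Euclidean-distance-transform dilation, so the radius
is honoured in mm on anisotropic grids); the overlap of each adjacent pair
— (subcallosal, anterior), (anterior, middle), (middle, posterior) — is
intersected with the *undilated* corpus callosum. This pairing is the only
arrangement that yields three regions ordered front to back; voxels claimed
by two regions are assigned to the more anterior one, so the regions are
disjoint. Each region is carried both as a voxel set (the planner may
target any of its voxels) and as a canonical target point (the centroid
snapped to the nearest in-region voxel centre). If an intersection is
empty the error reports the dilation radius that would have been needed,
which makes mis-registered or unusually displaced cingulate anatomy
diagnosable.

## Trajectory metrics

Five per-trajectory safety parameters are computed:

* **Vascular risk score.** The trajectory is sampled at 128 equally spaced
  nodes from entry to target; each node looks up the Euclidean distance map
  of the vessel segmentation (trilinearly interpolated). The per-node risk
  is piecewise linear in the vessel distance $d$:
  $$ r(d) = \begin{cases}
     0 & d \ge 10\,\mathrm{mm}\\
     (10 - d)/7 & 3 \le d < 10\,\mathrm{mm}\\
     1 + (3 - d)/3 & d < 3\,\mathrm{mm}
  \end{cases} $$
  and the trajectory score is the maximum over nodes. Reported uses of this
  class of score state its calibration but not a formula; this
  piecewise-linear family with max aggregation was chosen here because it
  is the simplest form under which that calibration —
  *a score below 1 certifies more than 3 mm of vascular clearance along the
  entire course* — is exactly true in both directions. It is an
  interpretation, not a reproduction, and mean aggregation is available as
  a secondary summary.
* **Minimum vessel distance** — the node minimum of the same interpolated
  distances, in mm.
* **Intracerebral length** — from the first brain-mask entry to the target,
  by 0.5 mm sampling.
* **Drilling angle** — angle between the trajectory and the outward surface
  normal at the entry; the normal is the gradient of a signed distance to
  the head mask smoothed with a 2 mm Gaussian, which stabilises normals on
  voxelised surfaces (planar-fixture accuracy is within 2–3 degrees).
* **Callosal fraction** — the fraction of the catheter's distal
  intracerebral segment lying within the callosum, by 0.5 mm sampling.

## The constrained search

One search is run per row of the default constraint table (entry gyrus,
target region, maximum skull-to-target length, maximum drilling angle):
non-dominant superior frontal to the anterior target (60 mm, 15°),
non-dominant superior parietal lobule and angular gyrus to the middle
target (110 mm, 35°), and dominant superior and middle frontal to the
posterior target (90 mm, 35°). With the default left-hemisphere dominance
the non-dominant side is the right; a dominance flag mirrors all laterality
roles. Entry points are the scalp-surface projections (nearest
outer-surface voxel) of the entry-gyrus voxels; candidates pair them with
target-region voxels, both stride-subsampled. The search is exhaustive over
these pairs rather than stochastic: it is deterministic, reproducible, and
every candidate can be re-checked by an independent oracle. Length and
angle bounds, and ventricular transgression, are hard constraints; vessel
avoidance is deliberately soft (through the risk and distance objective
terms), because clinically accepted plans include sub-3 mm corridors where no better
approach exists.

Candidates are ranked by a weighted sum of min–max normalised metrics
(risk, negated minimum vessel distance, intracerebral length, drilling
angle, negated callosal fraction), with deterministic tie-breaking. The
package's default weights are risk 0.25, minimum distance 0.10, length
0.05, angle 0.05 and callosal fraction 0.55. The callosal fraction
dominates by design: the object of the procedure is a complete
disconnection, and during development safety-dominant weightings were
observed to select catheters that skirt the vascular field but barely enter
the callosum (callosal fraction ≈ 0.03) — anatomically "safe" trajectories
that cannot ablate the structure they exist for. With coverage dominant,
vascular safety orders candidates among coverage-equivalent options, which
reproduces the clinically described behaviour: trajectories running along
the callosum, displaced laterally and dorsally off the midline by the
pericallosal arteries.

Five best candidates (one per table row) are returned; the final triple is
the anterior trajectory plus, for the middle and posterior targets, the
better of the two candidate families, decided by re-ranking the pooled
candidates of the pair. Clinical workflows leave this choice to the
surgeon; the deterministic pooled rule replaces the human chooser, and all
ranked candidates remain available for review.

## Ablation simulation

For each selected catheter the callosal segment is the longest contiguous
in-callosum interval of the trajectory (0.5 mm sampling). The number of
pull-backs is the segment length divided by the 7 mm pull-back spacing,
rounded up with a minimum of one, so the cavity always covers the segment.
Ablation centres start at the distal (target) end and step proximally —
pull-*back* semantics. Each ablation is rasterised as a sphere of the
configured diameter (default 15 mm, the conservative setting for confluent
cavities; the clinically achievable range 5–15 mm is enforced); the
confluence condition (spacing ≤ diameter) is a validity constraint. A
sphere union converges to the capped cylinder often used to describe these
cavities while remaining rotation-invariant on the voxel lattice. By
default the cavity is clipped to the callosum dilated by 2 mm, modelling
the surgeon limiting the ablation to the target structure to protect the
adjacent cingulate and fornix; clipping can be disabled for worst-case
cavities.

## Disconnection assessment

Interhemispheric streamlines are filtered through the combined cavity: a
streamline is removed when any point of its 0.5 mm-resampled polyline falls
in the exclusion mask (0.5 mm agrees with 0.1 mm on more than 99% of
phantom streamlines). Residual connectivity is the set of callosal voxels
still traversed by at least one surviving streamline (the visitation
threshold is exposed); volumes are voxel counts in cm³ — meshing would add
no information to a volume and introduces mesher-dependent variance. The
callosum is partitioned into the anterior two-thirds and the spared
splenium by a coronal plane at a configurable fraction (default 2/3) of its
anterior–posterior extent; in real anatomy the splenium share
varies, so the fraction is a parameter rather than a constant. The report
flags residual connectivity in the anterior two-thirds and localises it by
its anterior–posterior position (0 = anterior-most), because the clinically
observed failure mode is residual connectivity at the anterior-most genu
when cortical vasculature blocks the frontal trajectory from the rostrum.

## The digital head phantom

The phantom is a stated world, not a fitted one: a spherical head (scalp
43–45 mm, skull 40–43 mm, brain ≤ 40 mm) holding a corpus callosum modelled
as a superelliptical arch slab in the midsagittal plane. All geometric
defaults were fixed on anatomical grounds at the phantom's ~0.53 linear
scale relative to an adult head:

* arch semi-axes 20 mm (AP) × 13 mm (height): a 40 mm callosal span in a
  90 mm head, the same proportion as the real ~75 mm callosum in a ~170 mm
  head;
* superellipse exponent 2.2: the real callosal body is flat and the genu
  rounded — a plain ellipse bends the body too uniformly and a boxier shape
  makes the genu an unrealistically sharp corner that no straight catheter
  can follow;
* slab half-width 3 mm and half-thickness 3 mm: a 6 mm-wide, 6 mm-thick
  body, matching the real ~11 mm width at scale and giving a 2.15 cm³
  callosum (≈ 14.4 cm³ at full scale, against ~15 cm³ reported in adults);
* a short rostral lip (parametric start −20°) rather than a full recurve,
  which is sub-voxel at this scale;
* cingulate bands wrap the arch 3–10 mm outside its surface and are split
  at arc-length fractions 0.12 / 0.30 / 0.72, placing the three generated
  targets at the rostrum, the genu apex and the posterior body — the
  anatomical target sites of the procedure;
* paired pericallosal arteries run 1 mm above the dorsal callosal surface,
  2 mm lateral to the midline, with a fan of branches ascending to the
  medial cortex along the whole arch: without the branch fan the phantom
  offers artery-free perpendicular corridors with ~6 mm clearance that do
  not exist in vivo (real plans achieve ~1–2 mm of clearance); a dorsal midline
  sinus, bridging cortical veins and anterior cerebral artery segments
  complete the hazard set;
* the lateral ventricles are curved bodies hugging the callosal underside
  (the callosal body *is* the ventricular roof), with frontal horns
  flanking the genu — they seal the sub-callosal lateral corridor exactly
  as real ventricular anatomy does;
* the five entry gyri are angular cortical patches placed at their true
  topography (superior frontal anterior-superior near the midline, superior
  parietal lobule and angular gyrus posterior, middle frontal
  anterior-lateral).

Streamlines emulate interhemispheric tractography products, not diffusion
physics: each is a noisy arc through a crossing point sampled uniformly
over the midline callosal voxels (covering rostrum to splenium), starting
in the left hemisphere and ending in the right, dipping toward the head
centre away from the crossing. The default count is 5000 and generation is
seed-deterministic. An optional paramedian-plane filter mirrors
seed/inclusion-plane streamline selection.

What a green phantom test does and does not establish: it shows the
algorithmic chain behaves as specified on a geometrically faithful but
idealised head — it says nothing about parcellation accuracy, vessel
segmentation quality, registration error or diffusion modelling on real
data, all of which are upstream of this package's inputs.

## Numerical choices and degenerate inputs

Voxel indexing is 0-based and addresses voxel centres; all geometry is in
world mm (RAS), and voxelisation happens only at mask rasterisation and
lookup. Distance transforms are exact (Felzenszwalb–Huttenlocher,
spacing-aware). Dilation thresholds the distance transform rather than
iterating structuring elements. Node distances interpolate the distance
map trilinearly, preserving sub-voxel behaviour. Sampling steps are 0.5 mm
throughout (documented per function); tolerances stated in the tests are
15% for rasterised volumes at 1 mm spacing, 2–3° for surface-normal
angles. Empty vessel masks, empty target intersections, trajectories
missing the callosum, targets outside the brain and out-of-grid nodes all
fail loudly with the offending structure named. The ceiling-with-minimum-
one pull-back rule guarantees coverage of short segments (a zero-length
segment still receives one ablation at the target).

## Known limitations

* No thermal physics: cavities are geometric unions of spheres; heat-sink
  effects near vessels and heat dissipation into adjacent structures are
  not modelled (no validated patient-specific method exists).
* No haemorrhage-probability model: the risk score encodes distance only.
* The phantom's cortex is an unfolded shell; gyral geometry, sulcal CSF and
  the falx are absent, so drilling-angle and entry-corridor statistics are
  idealised.
* All inputs are assumed pre-registered to one grid; the package does not
  register.
* The 128 nodes span entry to target; if the intended span was
  skull-surface to target the difference is absorbed by the entry point
  lying on the scalp surface.
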