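---
title: "Quantifying placental villous tissue in 3D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying placental villous tissue in 3D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Multiphoton microscopy images intact placental villous tissue in 3D at
subcellular resolution: autofluorescence outlines the villi, a nuclear
stain shows the trophoblast layer, and a lectin stain shows the fetal
microvasculature. From such stacks, a small set of morphometric numbers
phenotypes tissue architecture — and is altered in pre-eclampsia:

* **villous volume, surface area, and SA/Vol** (µm⁻¹), a proxy for
  diffusional exchange capacity;
* **nuclear density** (nuclei per mm³ of villous tissue);
* **syncytial knots** — dense, bright aggregates of syncytiotrophoblast
  nuclei — counted, expressed as a **knot volume fraction** (%), and
  described in shape by the **elongation index** EI = L2/L1 and
  **flatness index** FI = L3/L2 of the principal axes of the knot's
  voxel cloud;
* **vascular fraction** (% of villous volume occupied by vessels);
* vessel network **branchpoint density** (junctions per µm of centreline
  length) and per-segment **tortuosity** (arc length over chord length
  between branchpoints).

`villomorph` implements that quantification as a tested library plus a
small CLI, and ships a synthetic phantom generator with planted ground
truth so each stage can be validated without any study data.

# Geometry and units

Stacks are anisotropic (a typical acquisition spacing is 0.7 × 0.7 µm
laterally with a 1.5 µm z-step). All containers carry a `voxel_spacing`
(dz, dy, dx in µm); voxel indices are 0-based and a voxel's physical
position is its centre, `index × spacing`. Every geometric output —
volumes, areas, lengths, diameters, densities — is computed in physical
µm; nothing is reported in voxel units. Internally, arrays are ordered
`(channel, z, y, x)`.

# Segmentation

**Masks (villi, vessels).** Pre-processing is a 3-D median filter (radius
1 voxel, i.e. a 3×3×3 neighbourhood; the conventional denoising step
before threshold segmentation). Masks come from a global threshold (Otsu
on a 256-bin histogram, or a fixed value), followed by removal of
connected components below a physical volume (26-connectivity) and
optional per-slice hole filling. A constant channel makes Otsu an explicit
error rather than an arbitrary split. Externally produced masks (NRRD or
TIFF, e.g. from an interactive pixel classifier) can be supplied at every
point where an internal segmenter would run.

**Nucleus instances.** Trained star-convex networks are the strongest
tool for dense 3-D nuclei, but they need annotated training stacks that a
reusable library cannot assume. The instance stage here is classical and
fully determined by its parameters: seeds are local maxima of a
scale-normalized multi-scale Laplacian-of-Gaussian response with per-axis
sigmas converted through the voxel spacing (default physical scale range
1.2–1.8 µm — the matched filter for a 3 µm-radius nucleus is
σ ≈ r/√3 ≈ 1.7 µm; deliberately narrow, because coarse scales smooth away
the intensity dip between touching nuclei), suppressed below a fraction
of the strongest response (0.1) and within a minimum physical distance of
a stronger seed (2 µm); instances grow by marker-controlled watershed of
the inverted smoothed intensity inside the Otsu foreground. The LoG's own
scale-space smoothing subsumes denoising, so this stage runs on the raw
channel; applying the median prefilter first would smear the z-dips
between nuclei separated by only a few coarse z-steps.

Two refinements matter quantitatively:

* *Half-maximum instance support.* A global threshold makes bright
  objects look bigger than dim ones — their blur halo clears the
  threshold further out. Each watershed region is therefore trimmed to
  the connected set of voxels above half its own (upper-decile) peak
  intensity. Without this, knot nuclei (about twice as bright) carried a
  ~25 % volume bias that propagated straight into the knot fraction.
* Instance volumes and centroids are computed from the refined labels;
  centroid-in-mask membership (not voxel overlap) decides whether a
  nucleus counts toward the villous nuclear density, which is robust to
  partial shells at the tissue surface.

An externally produced instance map can replace this stage entirely
(`read_label_map()`), preserving compatibility with deep-learning
segmenters.

# Surface area and volume

Volume is exact: foreground voxels × voxel volume. Surface area is
mesh-based, not exposed-voxel-face counting (face counting overestimates
curved surfaces by up to ~50 %): the 0.5-isosurface of the lightly
smoothed mask is triangulated by marching tetrahedra on the Kuhn
six-tetrahedron decomposition of each grid cube — within a tetrahedron
the interpolated field's level set is planar, so the triangulation is
watertight and unambiguous (no case table is needed).

Numerical choices:

* *Smoothing is physical*: a Gaussian of σ = 0.8 µm (per-axis sigma in
  voxels = 0.8/spacing). Meshing a raw binary grid overestimates a
  sphere's area by ~9–10 % from voxel staircase ripple; smoothing at a
  fixed physical scale removes the ripple and, because the scale is fixed
  in µm, the residual error *shrinks as the voxel size shrinks* (sphere
  r = 20 µm: +1.0 % at 1 µm voxels, −0.3 % at 0.5 µm). For synthetic
  sharp-edged solids, edge rounding grows linearly with σ, so such
  objects should be meshed with σ of about half a voxel (documented on
  `mesh_surface_area()`).
* *Image borders*: masks are zero-padded before meshing so
  border-touching structures close, and triangles whose centroids fall
  outside the original physical extent — the artificial cut faces at crop
  planes — are subtracted. Crop planes are not diffusion surface; whether
  published villous areas include them is not stated anywhere we know of,
  so excluding them is this package's documented choice (the closed
  surface is available via `keep_border_faces = TRUE`).

# Syncytial knot detection

The knot stage reconstructs a published-but-undocumented pipeline from
its stated ingredients — instance-segmented nuclei, density-based
clustering, and the observation that knots are bright and very dense:

1. optional intensity gate: keep nuclei with mean intensity ≥ 1.3 × the
   median nucleus intensity;
2. DBSCAN on the surviving centroids (Euclidean, inclusive ε, the point
   itself counted toward `min_pts`); border points claimable by two
   clusters go to the lowest-index core neighbour, which makes labels
   deterministic across platforms;
3. clusters with ≥ `min_members` nuclei become knots; shape comes from
   the eigen-decomposition of the covariance of the member nuclei's
   *voxel* positions (centroid-only PCA under-samples small knots), with
   axis lengths `L_i = 2√λ_i`, EI = L2/L1, FI = L3/L2; knot volume is the
   sum of member nucleus volumes (a convex-hull volume would be the main
   alternative; the sum matches the "volume of knot nuclei" semantics and
   is insensitive to single outlier members).

Defaults and why (none of these is published; all are explicit arguments):

* `eps = 9 µm` (three nucleus radii). Touching 3 µm nuclei sit ~4.5 µm
  apart centre-to-centre; the second-neighbour shell of a close-packed
  aggregate is ~√2 × 4.5 ≈ 6.4 µm, so a radius of two nucleus radii
  (6 µm) sits *below* the distance that must be bridged to connect a
  packed cluster, and ε must clear it with margin.
* `min_pts = 3`: a core nucleus needs two bright neighbours within ε.
* `min_members = 10`, the common histopathological convention for calling
  an aggregate a knot.
* `intensity_gate = 1.3` in the pipeline defaults. At realistic
  trophoblast surface densities the shell itself is close-packed, so
  density alone cannot distinguish a knot from the shell; brightness is
  what makes knots identifiable, exactly as in the visual definition.
  Depth attenuation is the known failure mode of a global gate: a bright
  knot deep in the stack can fall under the gate. The gate is therefore a
  parameter, not a constant.

Knots whose centroid falls outside every villous component are assigned
to the nearest component within one nucleus radius, else dropped with a
warning.

# Vessel networks

The vascular mask is reduced to a one-voxel-wide centreline by
topology-preserving thinning: six directional sub-iterations delete
*simple points* — voxels whose removal provably leaves connectivity,
tunnels and cavities unchanged, characterized locally by one 26-connected
foreground component in the 26-neighbourhood and one 6-connected
background component in the 18-neighbourhood — with curve endpoints
retained and candidates re-checked sequentially. Because the topological
guarantees assume isotropic connectivity, anisotropic masks are first
resampled (trilinear, threshold 0.5) to an isotropic grid at the finest
spacing; all outputs stay in physical µm.

Graph construction classifies skeleton voxels by 26-neighbour count
(1 endpoint, ≥3 branch voxel), merges adjacent branch voxels into
branchpoint nodes at their centroid, and traces the paths between nodes
into polyline edges. Three clean-up steps address known thinning
artefacts:

* *Polyline smoothing* (5-point moving average, ends pinned): voxel-to-
  voxel tracing zig-zags on curved paths and inflates arc length by
  ~5 %, which would bias tortuosity upward by exactly that much.
* *Spur pruning*: endpoint edges shorter than one network-mean diameter
  are hair artefacts of thinning on voxelized tubes and are removed (the
  *network* mean is the reference because a spur tip sits in a thin cap
  where its own diameter is uninformative). Config-exposed.
* *Junction merging*: one anatomical junction of a thick tube can thin
  into two nearby branch clusters; branchpoints closer than 1.5 × the
  network mean diameter are merged.

Per-edge metrics: arc length (sum of physical steps), chord length
(node-to-node distance), tortuosity = arc/chord (≥ 1 by construction;
closed loops have no chord and are excluded from means and counted
separately), and a diameter profile = 2 × the anisotropic Euclidean
distance transform of the mask sampled along the polyline, with the two
voxels adjacent to each node excluded (junction inflation guard) and
edges shorter than 5 profile voxels flagged. Mean tortuosity is taken
over branchpoint-to-branchpoint segments by default — tortuosity is
defined between branchpoints — with endpoint-terminated segments
includable by flag. Branchpoint density is branchpoint count over total
arc length. Networks export as node/edge CSV and as legacy-VTK polylines
loadable in 3Dslicer.

# Group statistics

`compare_groups()` reproduces the conventional comparison recipe: one-way
ANOVA with Bonferroni-adjusted pairwise post-tests (pooled SD) for data
treated as normal, and Kruskal–Wallis with Dunn's rank post-test (tie
correction; two-sided z p-values multiplied by the number of comparisons)
otherwise. `method = "auto"` applies Shapiro–Wilk per group when n ≥ 3;
with smaller groups normality cannot be assessed and is assumed, with a
logged caveat. Groups with a single value are reported but excluded from
testing. Images are weighted equally — one row per image, no
placenta-level nesting. Identical constant groups return p = 1 rather
than NaN. Type-I error of both paths is verified by simulation in the
test suite (1000 null datasets, observed rate within [0.03, 0.07] at
nominal 0.05).

# The phantom generator

The generator builds the study conditions the quantification is tested
under:

* **Villous tubes**: flat-capped cylinders, circular arcs, helices and
  Y-junctions rasterized in physical coordinates (a voxel is foreground
  iff its centre lies within the tube radius of a centreline).
* **Nested vessels**: a Y-branched tube (radius 5 µm inside an 18 µm
  trunk), clipped to the villous support.
* **Nuclear shell**: 150 nuclei of radius 3 µm, rejection-sampled in a
  shell within two radii of the villous surface. Placement respects a
  hard core of 1.5 nucleus radii between *all* centres — nuclei are
  incompressible, and touching nuclei sit about two radii apart, so 1.5 r
  is already a slightly-compressed contact — and keeps centres at least
  half a radius below the surface (nuclei are anchored in the tissue;
  only the outer cap protrudes).
* **Knots**: member centres drawn from an anisotropic Gaussian around the
  knot centre (planted covariance recorded as ground truth; axis lengths
  are `2σ` so they line up with the `L_i = 2√λ_i` estimator), subject to
  the same hard core. The demo field plants one round and one elongated
  knot of 15 members each, with intensity gain 2.
* **Imaging model**: per-channel base intensity × exp(−z/attenuation
  length) (the standard light-scattering depth model; default 150 µm over
  a 150 µm-deep stack), optional Poisson resampling, additive Gaussian
  noise (σ = 8 on 8-bit), clipping to bit depth. Base intensities
  (120/110/160 for villi/nuclei/vessels) are chosen so the brightest
  structures — knot nuclei at gain 2 → 220 — stay inside the 8-bit range,
  as any well-set acquisition would; detector clipping would erase the
  intensity dips between touching nuclei.

The default demo field is a 100 × 128 × 128-voxel stack at
1.5 × 0.7 × 0.7 µm (150 × 90 × 90 µm), the problem size used throughout
the tests; analytic fixtures (spheres, cylinders, arcs, random trees) are
rasterized at 1 µm and at 0.5 µm where convergence is asserted.

**What the phantom does not emulate** — hence what passing tests do *not*
show about real data: no optical PSF (edges are sharp up to noise), no
second-harmonic channel, no trophoblast texture or intensity
heterogeneity beyond depth decay, no nuclear shape variation (all planted
nuclei are spheres), no fibrosis, and vessels are perfect tubes without
wall signal. Planted-truth recovery therefore validates the geometry and
the algorithmic chain, not robustness to every optical artefact.

# Degenerate inputs and determinism

Empty masks are errors for area/skeleton operations and zeros for
fractions; constant channels fail Otsu explicitly; coplanar or collinear
point sets make `knot_shape()` fail naming the covariance rank; an
instance segmentation that finds no seeds returns an empty map with a
warning, not an error. Everything stochastic (phantoms, placements,
rendering, pipeline runs) is seeded: the same spec + seed reproduces
stacks bit-for-bit, and a repeated pipeline run writes a byte-identical
report. DBSCAN's border-point rule and the FIFO tie-break in the
watershed queue remove the last sources of platform-dependent labelling.

# Known limitations

* The knot stage is a reconstruction from stated ingredients, not a
  reimplementation of unpublished code; its thresholds are explicit
  configuration and should be re-tuned when nucleus size or staining
  differs.
* The classical instance segmenter under-splits heavily overlapping
  nuclei that a trained network might separate; the pluggable label-map
  import exists for exactly that case.
* Thinning-based centrelines are slightly shorter than the true medial
  axis at tube ends (endpoint erosion of roughly one tube radius), which
  second-order affects terminal-segment lengths but not
  branchpoint-to-branchpoint metrics.
* Surface areas at image borders follow this package's cut-face rule;
  results are comparable across images analysed with the same rule but
  not necessarily with tools that count crop planes.
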