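---
title: "Two-phase voxel classification of intermediate-resolution cryo-EM maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase voxel classification of intermediate-resolution cryo-EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

At intermediate resolution (5-10 Angstrom), a cryo-EM density map no longer
shows side chains or individual bases, but the characteristic shapes of
secondary-structure elements survive: alpha-helices appear as density rods,
beta-sheets as flat slabs, and nucleic-acid duplexes as thick, high-density
ridges. `em2struct` classifies every other grid point of such a map into one
of four structural classes -- alpha-helix, beta-strand, other/coil, or DNA/RNA
-- with an associated probability vector, giving model builders a structural
scaffold where direct tracing is impossible.

## The model

The map is first regridded to a canonical 1.0-Angstrom lattice by trilinear
interpolation and normalized to [0, 1]: simulated maps by plain min-max,
experimental maps by clamping negative densities to zero and using the
author-recommended contour level as the effective minimum (density at or below
the contour maps to 0). Classification then proceeds in two phases over the
stride-2 lattice (every other grid point along each axis, anchored at even
map indices):

* **Phase 1.** Five independent 3D residual convolutional classifiers score
  the 11x11x11-Angstrom density window centered on each lattice point: four
  binary classifiers (one per class, logistic output) and one four-class
  classifier (softmax output). Each network is: a 3^3 convolution with 64
  filters, stride 2, padding 1 (the unique standard stride/pad pair mapping
  11^3 to 6^3), batch norm, ReLU; a 2^3 max pool to 3^3; six residual blocks
  with 128, 256, 256, 512, 512 and 1024 filters of size 3^3 (stride 1, pad 1,
  so the 3^3 side is preserved); a 2^3 average pool producing exactly 1024
  features; and a fully connected head. Residual blocks are the canonical
  two-convolution basic block with an identity shortcut, or a 1^3 projection
  convolution when the channel count changes.
* **Phase 2.** A refinement network takes, for each lattice point, the 7^3
  neighborhood of phase-1 outputs -- 8 probability channels per point (4
  binary + 4 multiclass, in the fixed order helix, strand, other, nucleic) --
  through a 2^3 convolution with 32 filters (stride 1, no padding, 7^3 to
  6^3), batch norm, ReLU, a flatten to 6912 features, one hidden layer of 256
  units, and a 4-way softmax. Because both phases use the same stride-2
  lattice, phase 2 overwrites the phase-1 assignment wherever it runs; its
  effect is a learned smoothing of the label field. Neighborhoods at lattice
  edges (or around excluded points) are zero-filled.

Ground truth for training and evaluation follows the heavy-atom rule: a
lattice point is included iff some heavy atom lies within 3.0 Angstrom of it
(we implement the boundary inclusively); its label set is the set of classes
of all atoms in that radius and its training target is the class of the
nearest atom. Protein classes come from STRIDE codes (H/G/I = helix, B/b/E =
strand, everything else = other); any atom of DNA/RNA makes the class nucleic
regardless of code. Points with no atom within 3.0 Angstrom are excluded from
training and evaluation. At pure prediction time no structure is available,
so inclusion falls back to a configurable surrogate: normalized density
greater than 0, i.e. above the contour level for experimental maps.

## Training

Training follows the published schedule: Adam with learning rate 0.002 and L2
regularization 1e-5, batch size 256, cross-entropy loss. Binary classifiers
draw 128 positive and 128 negative windows per batch; the four-class model
draws 64 windows per class; strata smaller than their quota are sampled with
replacement. Phase 2 is trained on a map pool disjoint from the phase-1 pool
(cluster-respecting splits guarantee no sequence redundancy across pools),
with the frozen phase-1 outputs as input and the center's primary label as
target. Since balanced resampling has no natural epoch boundary, an "epoch"
is defined as `ceil(n_train / 256)` optimizer steps by default, configurable
through `steps_per_epoch`. After each epoch the batch-norm population
statistics are recalibrated by averaging batch statistics over a few training
batches with frozen weights; with short schedules the usual momentum-tracked
running estimates lag far behind the true activation distribution, and
validation/inference uses the calibrated values. The checkpoint with the best
validation voxel accuracy is kept.

## The synthetic-data generator

`build_toy_complex()` assembles idealized segments with known labels:
helices with 1.5 Angstrom rise, 100-degree twist and 2.3 Angstrom C-alpha
radius (4 backbone heavy atoms plus one pseudo side-chain atom per residue);
extended zigzag strands (~3.3 Angstrom rise); self-avoiding random-walk coils
with 3.8 Angstrom steps; and single-stranded helical nucleic chains with 3.4
Angstrom rise and ~20 heavy atoms per nucleotide. Segments are placed with a
minimum inter-segment distance of 5 Angstrom. `simulate_map()` renders the
complex as a sum of isotropic Gaussian kernels with sigma = 0.4247 x
resolution (the resolution is treated as the kernel FWHM, the common
convention for map simulators; the exact kernel used by external simulation
tools is not standardized, so this choice is ours and is configurable in
principle via the resolution), truncated at a spherical radius of 3 sigma,
with uniform atom weights -- at 6-10 Angstrom the class signal comes from
shape and packing, not element contrast. The map origin is snapped to integer
Angstrom so stride-2 lattices are anchored deterministically.

What the toys emulate: the geometry and packing density of the four classes
at intermediate resolution, multi-class contact regions, and per-residue
ground truth. What they do not emulate: real side-chain mass distributions,
base pairing and duplex grooves, solvent noise, B-factor variation,
non-uniform resolution, or map-model misalignment. Passing the desk-scale
tests therefore demonstrates that the pipeline is correctly wired and that
the networks can learn geometrically distinct density signatures; it does not
certify accuracy levels on experimental maps.

## Desk-scale study conditions

The package's self-contained study (`run_desk_study()`, also exercised by the
test suite and `scripts/acceptance.R`) uses 40 simulated maps at 6 Angstrom,
each from a complex with one helix (8-12 residues), one strand (5-8), one
coil (6-9) and one nucleic segment (5-8 nt), split 20/10/10 into
phase-1/phase-2/test pools (80/20 train/validation within pools). The
networks train for 5 epochs of 8 steps with a channel-width multiplier of
1/16 (conv1 4 filters; residual filters 8, 16, 16, 32, 32, 64). The width
knob exists because the full-width network is a GPU-scale object; on one CPU
the 1/16-width variant preserves the architecture's structure (same depth,
same shape arithmetic, verified separately at full width by a forward-pass
audit) at a cost that fits interactive use. These sizes were fixed once as
the package's study conditions.

## Numerical choices

* Trilinear resampling anchors the target lattice at the input origin rounded
  to integer Angstrom; points outside the source box get density 0 (solvent
  padding, matching the zero padding of windows at map edges). The operation
  is idempotent.
* The 3.0-Angstrom labeling radius is boundary-inclusive (<= 3.0).
* Argmax ties break by the canonical class order (helix < strand < other <
  nucleic). Majority-vote ties at residue level break by the higher mean
  class probability over the contributing points.
* F1 with precision + recall = 0 is 0. Overall voxel accuracy/recall/F1 are
  class-size-weighted averages; per-class values are reported so macro
  averages are derivable. Q3 with no protein residues (and segment accuracy
  with no qualifying segment) is reported as not-applicable, never 0.
* Residues with no assigned lattice point within 3.0 Angstrom are excluded
  from Q-score denominators and counted separately.
* The protein-vs-nucleic collapse sums the three protein probabilities; an
  exact tie goes to protein. A four-class nucleic argmax can flip to protein
  under the collapse.
* Complete-linkage clustering merges while the complete-linkage distance is
  at most 1 - 0.35; tied merge candidates are taken in lexicographic order of
  the clusters' smallest members, making the partition deterministic.
* Batch norm uses eps 1e-5; variance estimates are biased (population form);
  inference uses calibrated statistics as described above.
* All map values are float32 on disk (MRC mode 2) and float64 in memory.

## Design decisions taken where the layout was open

* Multi-label voxels train on the nearest atom's class; the full label set is
  kept for evaluation, where a prediction matching any member counts as
  correct.
* Residual block internals (basic two-convolution block, projection shortcut)
  follow the canonical deep-residual design; the phase-2 hidden layer width
  (256) is a configuration default. Both are config-exposed.
* Binary heads emit one logistic probability rather than a 2-way softmax; the
  8-channel order is fixed and documented.
* Checkpoint selection uses the best validation voxel accuracy.
* Prediction-time inclusion without a structure uses the normalized-density >
  0 rule; it is overridable by passing any inclusion grid to `detect()`.
* The neural-network engine is implemented in R over BLAS matrix products
  (im2col gathers for strided convolutions, a dense block-matrix formulation
  for the small 3^3 stride-1 convolutions, pointwise reshaping for 1^3
  projections); gradients are verified against numerical differentiation in
  the test suite.

## Known limitations

* The toy generator produces single-stranded nucleic helices, not duplexes;
  nucleic detection on the toys leans on their high atom density and large
  radius, which is also the dominant cue in real maps but not the only one.
* No map sharpening, masking, B-factor handling or FSC estimation; maps are
  consumed as deposited.
* The desk-scale accuracy numbers characterize the toy conditions only; they
  are not comparable to benchmark values on real simulated-PDB or EMDB
  datasets, which require full-width training at GPU scale.
* Sequence-identity matrices for redundancy clustering are consumed, not
  computed; alignment provenance is out of scope.
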