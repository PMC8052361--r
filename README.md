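# em2struct

Detects protein secondary structure and nucleic acids in cryo-EM density maps
of intermediate resolution (5-10 Å). At these resolutions side chains and
bases are invisible, but helices still show up as density rods, sheets as
slabs, and DNA/RNA as thick high-density ridges. `em2struct` assigns one of
four structural classes — α-helix, β-strand, other/coil, DNA/RNA — with
probabilities to every other grid point of a map, giving model builders a
structural scaffold where direct chain tracing is impossible. It is aimed at
structural biologists interpreting intermediate-resolution maps and at
method developers who want a fully self-contained, trainable reference
implementation of two-phase voxel classification.

## Method

The map is regridded to a 1.0 Å lattice by trilinear interpolation and
normalized to [0, 1] (experimental maps use the author-recommended contour
level as the effective minimum). Classification runs on the stride-2 lattice
in two phases:

1. **Phase 1** — five independent 3D residual convolutional classifiers score
   the 11×11×11 Å density window around each lattice point: four binary
   (one per class) and one four-class. Architecture: conv 3³ ×64 (stride 2,
   pad 1) → BN → ReLU → max-pool 2³ → six residual blocks with 128, 256, 256,
   512, 512, 1024 filters of size 3³ → average-pool 2³ → 1024-dim feature →
   fully connected head (logistic or softmax).
2. **Phase 2** — a refinement network reads the 7³ neighborhood of phase-1
   probabilities (8 channels per point) through a conv 2³ ×32 → BN → ReLU →
   fully connected stack → 4-way softmax, and overwrites the phase-1 call at
   every point: a learned smoothing of the label field.

Ground truth follows the heavy-atom rule: a lattice point is labeled by the
classes of all heavy atoms within 3.0 Å (training target = nearest atom's
class) and excluded if none is that close. Protein classes derive from STRIDE
codes (H/G/I → helix, B/b/E → strand, rest → other); DNA/RNA atoms force the
nucleic class. Evaluation is three-level: multi-label voxel
precision/recall/F1, majority-vote residue/nucleotide Q4/Q3/Q2, and segment
accuracy (helix runs ≥ 6 residues, strand runs ≥ 3; a segment counts as
correct when ≥ 50% of its residues get the right class).

Because no deep-learning framework is assumed, the 3D conv / batch-norm /
residual engine is implemented in R directly over BLAS matrix products, with
gradients verified against numerical differentiation in the test suite.

The package also ships a synthetic-data module — idealized helix / strand /
coil / nucleic segments rendered into density by a truncated Gaussian kernel
(σ = 0.4247 × resolution) — so the whole pipeline is trainable and testable
at desk scale without downloads.

## Worked example

```r
library(em2struct)

# a toy protein/nucleic complex and its simulated 6 A map
cx <- build_toy_complex(list(list(kind = "helix",   length = 10),
                             list(kind = "strand",  length = 6),
                             list(kind = "coil",    length = 7),
                             list(kind = "nucleic", length = 6)), seed = 7)
map <- normalize_map(simulate_map(cx, resolution = 6), "simulated")
lg  <- label_grid(map, cx)
lg
#> <labeled_grid> 26 x 18 x 25 stride-2 lattice, 871 included points
#>   primary labels: HELIX=220 STRAND=148 OTHER=158 NUCLEIC=345
```

871 stride-2 points lie within 3 Å of a heavy atom; each carries the class of
its nearest atom. The full desk-scale study — 40 such maps, split 20/10/10
into phase-1 / phase-2 / test pools, 5 training epochs at 1/16 network width —
trains and evaluates in about 10 minutes:

```r
st <- run_desk_study(seed = 1)
round(c(voxel_accuracy = st$voxel_accuracy,
        nucleic_recall = st$nucleic_recall,
        q4_phase1 = mean(st$q4_phase1),
        q4_phase2 = mean(st$q4_phase2),
        maps_improved = st$frac_q4_improved), 3)
#> voxel_accuracy nucleic_recall      q4_phase1      q4_phase2  maps_improved
#>          0.782          0.947          0.784          0.826          0.800
```

Held-out voxel accuracy is 0.782 (chance is 0.25), nucleic-acid recall 0.947
(nucleic blobs are geometrically distinctive at 6 Å), and phase-2 refinement
raises the residue-level Q4 on 80% of the held-out maps (0.784 → 0.826 on
average) — the same qualitative behavior reported for the full-scale method,
at toy scale.

A thin command-line interface wraps the same functions:

```sh
exec/em2struct fixtures --out fx --n 10 --seed 1
exec/em2struct train    --fixtures fx --out model --seed 1
exec/em2struct detect   --map fx/fx001.mrc --model model --out fx001_detect
```

`detect` writes a TSV (one row per grid point: coordinates, four
probabilities, label, phase tag) and a pseudo-atom PDB for visualization
(ALA = helix, VAL = strand, GLY = other, ADE = nucleic; B-factor = max
probability).

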