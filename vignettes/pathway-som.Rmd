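---
title: "Classifying mechanical unfolding pathways with self-organizing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mechanical unfolding pathways with self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Steered molecular dynamics (SMD) pulls a protein apart with a moving
harmonic restraint. Because unfolding is a stochastic process, a single
replica says little: the same construct may unfold through different
sequences of events, and only an ensemble of replicas reveals the
alternative routes and their relative probabilities (kinetic
partitioning). The practical obstacle is that fifty replicas of a large
conformational change are an enormous, redundant body of coordinates in
which "which route did this replica take?" is hard to answer by
inspection.

`pathsom` addresses this by compressing the conformational ensemble onto a
small two-dimensional grid -- a self-organizing map (SOM) -- and then
treating each replica as a discrete route across that grid. Everything
downstream (pathway classification, transition graphs, force maps,
intermediate detection) operates on those routes.

## Featurization: native C&beta; contact distances

A conformation is represented by the vector of distances between C&beta;
atom pairs (C&alpha; for glycine, which has no C&beta;) that are closer
than a cutoff -- 1.0 nm by default -- in the native structure. This choice
has three properties that matter here:

* it is superposition-free, so the dissimilarity between two highly
  distorted conformations does not depend on a structural alignment that
  becomes ill-defined during unfolding;
* restricting to *native* contacts makes the measure sensitive to the loss
  of native-like structure, which is exactly the signal in an unfolding
  simulation;
* with the default strict `< 1.0 nm` rule the feature count stays in the
  hundreds, which a SOM handles comfortably.

Pairs are enumerated in (i, j)-lexicographic order, so the feature space is
reproducible; the dissimilarity between two feature vectors is the dRMSD,
`sqrt(mean((a - b)^2))`. For multi-model (NMR) references, the model index
is an explicit argument recorded in the output; the pair count depends on
it, so it should be reported alongside any cutoff calibration. Glycine
fallback to C&alpha; is controlled by `gly_ca` and also recorded.

## The map

`path_som()` trains a non-periodic, sheet-shaped, hexagonally packed SOM
(default 8 x 8). Neuron positions use the standard hexagonal offset
convention (odd rows shifted by half a cell, row spacing sqrt(3)/2);
"neighboring neurons" are those within lattice distance 1.01. Training is
the classical online rule: present one frame, find its best matching unit
(BMU; ties to the lowest neuron id), pull the BMU and its neighbors toward
the frame with a Gaussian neighborhood. The absence of periodic boundaries
is deliberate: the folded and fully unfolded end states settle in opposite
corners of the sheet, which keeps the map readable.

Defaults, all exposed and logged in the fitted object:

| parameter | default | why |
|---|---|---|
| learning rate | 0.05 -> 0.01, linear | conventional online-SOM range |
| neighborhood radius | 2/3 grid diagonal -> 1, linear | starts global (topological ordering), ends local without decoupling adjacent neurons |
| epochs | 100 | on datasets of a few thousand frames the quantization error plateaus well before this; raise it for larger inputs |
| initialization | uniform in per-feature ranges | scale-free; `init = "sample"` (codebook = random data frames) is available and more robust on very small maps |
| feature scaling | off | all features share nm units |

Frames are presented in a fresh seeded random order each epoch. This
matters because trajectory data arrive blocked by replica; cycling through
them in file order biases the online updates toward whichever replica was
presented last.

Determinism: the codebook is a pure function of (data, hyperparameters,
seed). Ties everywhere resolve to the lowest index.

Two caveats of the online algorithm worth knowing: a very small map
confronted with widely separated, symmetric clusters can "fold" (two
neurons share two clusters while the others starve); and the final radius
of 1 keeps adjacent codebooks correlated, which is desired for smooth maps
but means individual neurons are not independent cluster estimates. Neuron
quality is therefore checked empirically: `neuron_quality()` compares
within-neuron pairwise dRMSD against lattice-adjacent-neuron dRMSD, and a
well-trained map shows clearly smaller intra-neuron values.

## Neuron clusters and centrotypes

For a coarser view, codebook vectors are grouped by agglomerative
hierarchical clustering (Euclidean, complete linkage). The cut is either
user-chosen or selected by maximizing the average silhouette width, with
near-ties (within 0.01) resolved toward the cut with fewest
negative-silhouette neurons -- negative silhouettes are neurons sitting in
the "wrong" cluster, which is worth avoiding even at equal average width.
Each neuron is represented structurally by its centrotype: the assigned
frame closest to its codebook vector.

## Pathways

A replica's trace is its frame-by-frame BMU sequence. The distance between
two traces of equal length is the mean over frames of the codebook-space
BMU distance, where the distance between two neurons is the *mean square
deviation* of their codebook vectors -- deliberately left in squared
feature units, matching the definition used for the map. Because this
frame-wise distance is squared, the trace distance is a squared-type
pseudometric; its square root satisfies the triangle inequality, which is
what the tests assert.

Traces are clustered with average linkage on this distance matrix; the cut
defaults to 2 (the two-pathway question) and the full dendrogram is always
kept, because minor sub-branches -- replicas that detour through otherwise
unused neurons -- are a real phenomenon and merging them into major
pathways is a judgement call the package does not automate.

Unequal-length traces are an error by default; with `resample = TRUE`
the shorter trace is resampled to the longer one's frame times by nearest
time. This is intentionally cruder than alignment-based comparison
(dynamic time warping is out of scope); it exists for the case of replicas
stored at different strides, not for comparing physically different
pulling speeds, for which `cluster_visit_order()` on a shared neuron
clustering is the supported tool.

## Transition graph

Consecutive-frame neuron transitions, pooled over replicas, give a count
matrix; dividing each row by its sum gives an empirical row-stochastic
matrix. Self-transitions are counted by default -- at typical strides most
consecutive frames stay on one neuron, and removing them changes every
outgoing probability; an option drops them for sparser graphs. Rows with
no observed transitions stay zero and the neuron is flagged isolated
rather than given a fabricated distribution.

The directed graph weights each existing edge by `-log p` (natural log;
the base is a convention recorded in the object, and shortest paths are
invariant to it). A shortest path then minimizes the negative log of the
probability product along the route, so "distance" means "improbability":
the returned distance is checked internally to equal both the edge-weight
sum and `-log` of the probability product within 1e-9. Unreachable pairs
report an infinite distance explicitly. This is an *approximate* empirical
transition description for visualization and route comparison -- not a
Markov state model; no lag-time analysis, reversibility enforcement or
spectral machinery is implied.

## Scalar maps, intermediates, and work

Any per-frame scalar carried by the traces can be averaged per neuron.
The canonical use is the pulling force: a neuron whose visiting frames
carry systematically higher force than its surroundings marks a mechanical
resistance -- the signature of an unfolding intermediate just before it.
Neurons never visited are reported missing (`NA`), not zero, since zero
force is a physical value. Cumulative pulling work is the trapezoidal
integral of force over extension, computed per replica.

## Local structure profiles

To localize *where* in the chain a neuron's ensemble deviates from the
folded state, conformations are encoded as strings over a structural
alphabet: each overlapping 4-residue fragment maps to the letter with the
nearest prototype descriptor. The descriptor is the triple of
non-consecutive distances d(1,3), d(1,4), d(2,4) plus the signed dihedral
of the four positions (separating handedness). Per fragment position,
divergence of a neuron's letter distribution from the folded reference is
the Jensen-Shannon divergence (base 2, bounded in [0, 1], symmetric), with
a pseudocount of 1/(sample size) so finite ensembles with empty categories
stay well-defined.

The packaged 25-letter alphabet is synthetic: prototypes are ideal
fragments on a deterministic 5 x 5 grid of bend angle (80-160 degrees) x
dihedral (-144 to 144 degrees) at 0.38 nm virtual bond length. It spans
the geometries a C&alpha;/C&beta; trace visits, but it is a neutral default,
not a published alphabet; any alphabet in the same CSV layout (letter +
descriptor columns), with its own descriptor function if needed, can be
supplied instead, and results should be reported against the alphabet
used.

## The synthetic unfolding generator

All statistical claims in the test suite are made against synthetic data
with known ground truth, generated directly in feature space:

* a deterministic compact helical bead chain (0.5 nm radius, ~6.5 residues
  per turn) provides a native structure whose contact set under the 1.0 nm
  rule mixes sequence-local and turn-to-turn pairs (179 pairs over 40
  residues at the defaults -- a few hundred features over a few dozen
  residues, proportionate to a small protein domain);
* native pairs are partitioned into 4 sequence-local blocks (quantiles of
  the pair midpoint), standing in for structural regions;
* a pathway is an order in which blocks rupture; each block's distances
  ramp linearly from native to 3x native inside its window. The two
  default pathways share the same blocks but break them in different
  orders, mirroring the two-route phenomenology of mechanical unfolding
  (route 1: terminal block detaches first, then the far end -- this route
  carries the intermediate; route 2: blocks fail in sequence order);
* i.i.d. Gaussian noise (default sigma = 5% of the mean native contact
  distance, floored so distances stay above 0.05 nm) models thermal
  fluctuation;
* the force trace is a baseline (300 kJ mol^-1 nm^-1, SD 15) plus a
  scripted 250-unit peak inside the second rupture window of the
  intermediate-bearing pathway only; extension ramps linearly to 24 nm;
* the default dataset is 50 replicas split 12/38, a minority/majority
  kinetic partitioning; 60 frames per replica stands in for a
  fixed-stride sampling of each trajectory.

What the generator does *not* emulate: Cartesian geometry of unfolding
(features are generated directly as distances), correlated noise between
contacts, back-and-forth recrossing of partially broken blocks, replicas
of varying speed within one dataset, or any force-field physics. Passing
the recovery tests therefore demonstrates that the pipeline's logic is
correct under its own assumptions -- clean block-ordered signals are
recoverable -- not that any particular real system will separate as
cleanly.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: the default 50-replica
dataset (3000 frames, 179 features) for pathway recovery over 5 master
seeds; 16-replica datasets (4/12 split) for the 20-seed map-level checks
(intra- vs inter-neuron dRMSD, force-peak localization); and a noiseless
16-replica dataset for retracing, with a 10x-frame low-speed analogue.
These sizes were chosen so the complete validation runs comfortably on a
single CPU while keeping every dataset larger than the 64-neuron map.

Other numerical conventions: BMU and nearest-prototype ties resolve to the
lowest index; dRMSD pair sampling within `neuron_quality()` is capped at
200 seeded pairs per neuron (pair); degenerate inputs (empty trajectories,
non-finite features, traces shorter than 2 frames, scalars of mismatched
length) raise immediate errors rather than propagating silently; and the
quantization error is always reported next to its value at initialization
so a failed training is visible at a glance.

## Known limitations

* The SOM is trained online; results depend on the seed (initialization
  and presentation order). Train with several seeds before interpreting
  fine map detail; pathway-level conclusions are robust to this in our
  tests, individual neuron boundaries are not.
* The path distance compares same-index frames; it assumes replicas of
  equal length and broadly synchronized progress, as is typical for
  constant-velocity pulling at one speed.
* The transition graph is descriptive, not kinetic.
* The packaged structural alphabet is a geometric default; conclusions
  about local unfolding should be checked against a purpose-built
  alphabet when one is available.
* Trajectory input is limited to multi-model PDB and DCD files (what the
  underlying bio3d reader supports); convert other formats upstream.
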