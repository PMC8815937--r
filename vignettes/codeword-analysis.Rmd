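---
title: "Visual codewords of protein distance matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual codewords of protein distance matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcodex)
```

## The representation

A protein domain's tertiary structure is summarized by its C-alpha distance
matrix, $D_{ij} = \lVert \mathbf{r}_i - \mathbf{r}_j \rVert$. This 2-D view
is invariant under rigid rotation and translation and displays local,
short-, medium- and long-range contacts simultaneously: secondary structure
as texture along the main diagonal, tertiary packing as off-diagonal
features, and tandem structural repeats as periodic off-diagonal bands.

`dmcodex` renders $D$ as a grayscale image
$I_{ij} = 1 - D_{ij} / \max(D)$, so white encodes short range (the diagonal
is exactly 1) and black the longest-range pair. The inversion is linear and
per-matrix by default. Whether one should normalize per matrix or clamp at a
fixed physical distance is genuinely open: per-matrix scaling preserves the
full dynamic range for domains of any size at the cost of making absolute
intensity incomparable between domains, and is the default here; a
`fixed_cap` mode (clamp at a configurable distance, 50 Å by default) is
provided for cross-domain comparability. Images are stored as 8-bit
single-channel PNG, which bounds the write-read round-trip error by
$1/510$ — far below anything the detector responds to.

## From image to codeword histogram

The bag-of-visual-words pipeline has four stages.

**1. Feature extraction.** Keypoints and descriptors come from a KAZE-style
detector implemented in this package: a nonlinear scale space built by
Perona–Malik diffusion
$\partial_t L = \mathrm{div}\,(g(|\nabla L|)\,\nabla L)$ with conductivity
$g = 1/(1 + |\nabla L|^2 / k^2)$, which smooths noise while preserving the
edges that make distance-matrix texture informative. The contrast parameter
$k$ is the 70th percentile of gradient magnitudes; evolution times
$t_i = \sigma_i^2/2$ follow a geometric ladder $\sigma_i = 1.6 \cdot
2^{o + s/4}$ over up to 4 octaves (capped by image size so that the coarsest
level still resolves structure), integrated by an explicit scheme with step
$\tau = 0.2$. Keypoints are strict spatial maxima of the scale-normalized
determinant of the Hessian, $\sigma^4(L_{xx}L_{yy} - L_{xy}^2)$, that also
dominate the neighbouring scale levels. Each keypoint receives an upright
64-dimensional descriptor: first-order derivative responses $(d_x, d_y)$
sampled on a $20\times20$ grid spaced $\sigma$ apart, Gaussian-weighted,
pooled over $4\times4$ subregions into
$(\sum d_x, \sum d_y, \sum|d_x|, \sum|d_y|)$ and L2-normalized. Rotation
invariance is deliberately omitted: distance matrices have a canonical
orientation, so an upright descriptor is both cheaper and more
discriminative here.

The only tunable that matters in practice is the detector threshold
(default $10^{-4}$). It was calibrated once so that images of 120–180
residue domains yield on the order of a few hundred keypoints, the feature
density typical of domain-scale corpora; lowering it admits weaker, noisier
extrema, raising it thins out coarse-scale features first.

**2. Visual dictionary.** Descriptors from all corpus images are pooled,
with provenance, into one $M \times 64$ matrix.

**3. Codebook.** The dictionary is clustered by k-means (k-means++
initialization from a caller-supplied seed, Lloyd iterations, Euclidean
metric) and the $K$ centroids become the codewords. The implementation is
the package's own because downstream checks rely on behaviour most library
clusterers do not expose: a recorded per-iteration inertia trace (which must
be non-increasing), deterministic lowest-index tie-breaking, empty-cluster
re-seeding from the farthest point, and bit-reproducibility from the seed.
Iteration stops at assignment convergence, a relative inertia improvement
below $10^{-4}$, or 100 iterations. Defaults mirror the corpus sizes this
package targets: $K = 200$ for the bundled synthetic benchmark (about 6,500
dictionary features), with larger vocabularies appropriate for larger
corpora — accuracy grows with $K$ up to a plateau, and past it quantization
overfits.

**4. Histogram (hard coding).** Every feature is assigned to its nearest
codeword (ties to the lower index) and counts accumulate into a length-$K$
histogram per image; assignments and keypoint coordinates are retained so
spatial statistics remain computable after quantization. Histogram mass
always equals the feature count.

## The statistics on top

*Cosine distance* between histograms drives leave-one-out nearest-neighbour
retrieval, scored at each level of a SCOP-style hierarchy
(class/fold/superfamily/family, parsed from sids like `a.1.1.1`). Cosine
similarity is scale-invariant, so raw counts and frequency-normalized
histograms give identical retrievals; ties are broken toward the
lexicographically smaller image id for determinism.

*Relative frequency* of a codeword is presence-based: the fraction of
corpus images containing it at least once (an occurrence-weighted variant
sits behind a flag). *Diagonal distance* of a keypoint at pixel $(x, y)$ in
an $n \times n$ image is $|\hat{x} - \hat{y}|/\sqrt{2}$ with coordinates
normalized by $n - 1$, so it is 0 on the diagonal and attains its bound
$\sqrt{2}/2 \approx 0.7$ exactly at the far corners — the longest-range
contact. Coordinates are normalized by $n-1$ rather than $n$ precisely so
the bound is attained. The per-codeword profile (mean and sd of diagonal
distances of its assigned features, plus frequency rank) quantifies the
association between how common a codeword is and where it lives: frequent
codewords encode near-diagonal local structure shared by most domains, rare
ones encode long-range corner contacts. Whether a per-codeword mean or the
raw per-feature distances are the right summary is not settled; both are
available (the profile keeps the feature table).

*Unique-word ratio* (uwr) of an image is the number of distinct codewords
present divided by its feature count — e.g. 500 features quantized into 400
distinct words give $400/500 = 0.8$. Tandem repeats in 3-D produce repeated
distance-matrix patches, many features quantized into few words, and hence
low uwr; diverse globular texture pushes it toward 1. It is a vocabulary-
relative statistic: it is only meaningful against a codebook trained on a
diverse corpus, and comparisons are only valid within one codebook.

*PCA embedding* of the images-by-codewords matrix (mean-centered,
`stats::prcomp`) gives the low-dimensional view of fold space; *Pearson
correlations* (`stats::cor`) quantify the size/feature-count/uwr
relationships.

*Classification*: histograms are L1-normalized (removing the domain-size
confound; the statistic of interest is texture composition, not image area)
and fed to a linear-kernel SVM (`e1071`, $C = 1$, solenoid as positive
class). Two-fold cross-validation follows the strict protocol: a stratified
random 50/50 split, a fresh codebook per fold built from training images
only (so no test-image texture leaks into the vocabulary), both halves
encoded against it, confusion counts summed over the folds so each item is
tested exactly once. Per-class accuracies are $100\,\mathrm{TP}/(\mathrm{TP
+ FN})$ and $100\,\mathrm{TN}/(\mathrm{TN + FP})$, reported to one decimal
from exact integer counts.

## The synthetic corpus

The generator exists so every stage is testable without external structure
databases, and its defaults are the study conditions used throughout the
tests:

- **Helix**: parametric ideal alpha-helix (radius 2.3 Å, rise 1.5 Å/residue,
  100°/residue), giving the canonical ~3.83 Å C-alpha chord.
- **Solenoid**: a 24-residue helical unit laid perpendicular to the
  solenoid axis, stacked with 4.8 Å rise and 15° twist per repeat —
  an elongated helical-unit solenoid of the LRR/HEAT kind, the geometry
  with the strongest off-diagonal banding. With zero noise the distance
  matrix is exactly repeat-block Toeplitz; 0.3 Å isotropic Gaussian noise
  (the benchmark default) keeps the bands visible but realistic rather
  than degenerate.
- **Globular**: a self-avoiding random chain (3.8 Å steps, 4.0 Å minimum
  non-bonded separation) confined to a sphere of radius $3.0\,n^{1/3}$ Å —
  the repeat-free, compact contrast class. Geometric self-avoidance stands
  in for an energy model deliberately: only distance-matrix texture matters
  downstream, not physical realism.

The benchmark corpus is 10 solenoids (5–7 repeats, 120–168 residues,
noise 0.3 Å) and 10 globular chains (120–180 residues), all derived from a
single corpus seed via per-item child seeds, so PNGs regenerate
byte-identically. Problem sizes throughout (20 domains, $K = 200$, ~6,500
dictionary features) were chosen as the smallest corpus on which the
class-contrast statistics are stable and the whole analysis reruns in about
a minute on a laptop core.

What the generator does *not* emulate: beta-sheet topology, closed
beta-propeller solenoids (whose mixed short/long-range repeats raise uwr),
disorder, missing residues, or any sequence-level signal. Passing tests on
this corpus therefore demonstrate that the pipeline detects repeat-driven
texture contrast under controlled conditions — not that any particular
accuracy transfers to real structure databases, where the contrast is
weaker and the label structure far richer.

## Numerical and design choices worth knowing

- **Noise vs uwr.** Adding coordinate noise to solenoids raises their uwr
  monotonically *when probes are encoded against a fixed diverse-corpus
  codebook* — the setting in which uwr is defined. Retraining a codebook on
  each noise level instead inverts the trend at zero noise (identical
  images make the corpus degenerate and the vocabulary over-resolves it);
  this is a property of the statistic, not an implementation artifact.
- **Determinism.** Every stochastic step (corpus generation, k-means
  initialization, CV splits) flows from explicit seeds through a
  save/restore RNG wrapper; the detector and encoder are fully
  deterministic. Nearest-centroid and nearest-neighbour ties break to the
  lowest index / smaller id.
- **Degenerate inputs.** Images under 16 px or with constant intensity
  yield empty feature sets (valid, encodes to a zero histogram); zero
  histograms are rejected where a direction is required (cosine distance,
  L1 normalization); all-identical point sets cannot be rendered (max
  distance 0); empty classes are rejected by the classifier and the metric
  arithmetic.
- **Run provenance.** The command-line layer writes a JSON run-record
  (command, config, seed, input digests) per run, and histogram/statistics
  tables carry the digest of the codebook they were computed against;
  mixing codebooks is rejected at read time. Digests are md5
  (`tools::md5sum`), chosen because it is the digest base R ships.
- **Known limitations.** The detector has no subpixel/scale interpolation
  and no rotation invariance (intentional for this image class); k-means
  uses a single restart (seeded) rather than best-of-many; the PDB reader
  takes the first model of NMR files and the first altloc; uwr values are
  not comparable across codebooks of different size or training corpus.
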