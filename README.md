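# dmcodex — visual codeword analysis of protein distance matrices

`dmcodex` is an R package and command-line tool for the quantitative
analysis of protein domain structure through the *bag-of-visual-words*
representation of the C-alpha distance matrix. It is aimed at structural
bioinformaticians who want a rotation/translation-invariant, image-based
descriptor of tertiary structure — for fold retrieval, for embedding fold
space, and in particular for detecting and quantifying tandem structural
repeats (solenoid proteins) directly from distance-matrix texture.

## The method

For a domain with C-alpha coordinates $\mathbf{r}_1,\dots,\mathbf{r}_N$:

1. **Distance matrix → image.** $D_{ij} = \lVert \mathbf{r}_i -
   \mathbf{r}_j \rVert$ is rendered as the grayscale image $I_{ij} = 1 -
   D_{ij}/\max(D)$, white = short range, black = the longest-range pair.
2. **Features.** A KAZE-style detector (nonlinear-diffusion scale space,
   determinant-of-Hessian extrema) extracts keypoints, each described by an
   upright 64-dimensional gradient descriptor.
3. **Codebook.** Descriptors pooled across a corpus are clustered with
   k-means (k-means++, seeded); the $K$ centroids are the *codewords*.
4. **Histogram.** Each image's features are hard-assigned to their nearest
   codeword, giving a length-$K$ count histogram per domain.

On top of the histograms the package computes the statistics that make the
representation interpretable:

- **cosine nearest-neighbour retrieval** with accuracy at each SCOP-style
  hierarchy level (class / fold / superfamily / family);
- **relative frequency** of each codeword (fraction of domains containing
  it) and its **diagonal-distance profile** — frequent codewords sit near
  the matrix diagonal (local structure), rare ones in the long-range
  corners;
- the **unique-word ratio** `uwr = distinct codewords / total features`, a
  quantitative measure of structural repeats (solenoids score low, globular
  domains high);
- **PCA embedding** of the domain-by-codeword matrix;
- **linear-SVM classification** of solenoid vs globular domains with
  stratified two-fold cross-validation and per-fold, train-only codebooks.

A synthetic backbone generator (ideal helices, solenoids with a controlled
repeat unit, self-avoiding compact globular chains) provides fully seeded,
reproducible corpora, so the entire pipeline runs and is tested without any
external structure database.

## Worked example

```r
library(dmcodex)

corpus   <- make_benchmark_corpus(n_solenoid = 10, n_globular = 10, seed = 1)
features <- lapply(corpus$images, extract_features)
codebook <- build_codebook(build_dictionary(features), k = 200, seed = 1)
#> <codebook> k = 200 codewords (seed 1, 18 iterations, inertia 467.8)
encoding <- encode_corpus(features, codebook)

uwr <- unique_word_ratios(encoding)
lab <- corpus$manifest$binary_label
mean(uwr$ratio[lab == "solenoid"])   # 0.221
mean(uwr$ratio[lab == "globular"])   # 0.384
```

The ~6,250 pooled features quantize so that solenoid domains reuse far
fewer distinct codewords than globular domains of the same size — the
repeat units of a solenoid tile its distance matrix with near-identical
patches, which all land in the same words. The spatial profile shows the
frequency/position relationship:

```r
prof <- codeword_diagonal_profile(encoding)
mean(prof$mean_diag_dist[prof$rank_by_freq <= 20], na.rm = TRUE)   # 0.168
mean(prof$mean_diag_dist[prof$rank_by_freq > 180], na.rm = TRUE)   # 0.310
```

The 20 most frequent codewords lie close to the diagonal (normalized
distance 0.168 of a possible √2/2 ≈ 0.7): they encode the local backbone
texture every domain shares. The 20 rarest sit twice as far out, toward the
long-range corners. Finally, the classifier:

```r
cv <- twofold_cv(features, lab, vocab_size = 200, seed = 1)
cv$confusion
#> <confusion_counts> TP 10  FP 0  TN 10  FN 0
cv$metrics
#> <benchmark_metrics> solenoid 100.0%  globular 100.0%  overall 100.0%
```

Every domain is classified correctly from its codeword histogram alone,
with each fold's codebook built only from that fold's training images.

The same pipeline is scriptable from a shell via the installed CLI
(`inst/cli/dmcodex`): `synth`, `distmat`, `extract`, `codebook`, `encode`,
`stats`, `nn` and `svm` subcommands, each writing a JSON run-record with
its configuration, seed and input digests.

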