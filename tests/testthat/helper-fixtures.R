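# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# The standard synthetic benchmark corpus (10 solenoid + 10 globular,
# 120-180 residues, seed 1) with features, a k = 200 codebook and the
# corpus encoding. Used by the corpus-scale statistical checks.
benchmark_fixture <- function() {
  if (is.null(.fixture_cache$bench)) {
    corp <- make_benchmark_corpus(seed = 1)
    feats <- lapply(corp$images, extract_features)
    cb <- build_codebook(build_dictionary(feats), k = 200, seed = 1)
    enc <- encode_corpus(feats, cb)
    .fixture_cache$bench <- list(corpus = corp, features = feats,
                                 codebook = cb, encoding = enc)
  }
  .fixture_cache$bench
}

# Features of a 100-residue ideal helix image (deterministic).
helix_features <- function() {
  if (is.null(.fixture_cache$helix)) {
    img <- to_gray_image(distance_matrix(make_helix(100)))
    .fixture_cache$helix <- extract_features(img)
  }
  .fixture_cache$helix
}

# A random proper rigid transform (rotation + translation).
random_rigid <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = stats::rnorm(3, sd = 20))
}

apply_rigid <- function(coords, rt) {
  sweep(coords %*% t(rt$R), 2, rt$t, "+")
}

# Minimal synthetic feature sets for bovw unit tests.
fake_features <- function(descriptors, image_id = "img", image_size = 64,
                          xs = NULL, ys = NULL) {
  n <- nrow(descriptors)
  image_features(
    keypoints = data.frame(x = xs %||% rep(1, n), y = ys %||% rep(1, n),
                           scale = rep(1.6, n), response = rep(1, n)),
    descriptors = descriptors, image_id = image_id, image_size = image_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
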