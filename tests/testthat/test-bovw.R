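test_that("the visual dictionary is a provenance-tracked row concatenation", {
  set.seed(2)
  fa <- fake_features(matrix(runif(10 * 64), 10), "a")
  fb <- fake_features(matrix(runif(15 * 64), 15), "b")
  dict <- build_dictionary(list(fa, fb))
  expect_equal(dict$M, 25L)
  expect_equal(nrow(dict$provenance), 25L)
  expect_equal(dict$descriptors[11, ], fb$descriptors[1, ])
  expect_equal(table(dict$provenance$image_id)[["a"]], 10L)
  single <- build_dictionary(list(fa))
  expect_identical(single$descriptors, fa$descriptors)
  empty <- image_features(data.frame(x = numeric(0), y = numeric(0),
                                     scale = numeric(0), response = numeric(0)),
                          matrix(numeric(0), 0, 64), "flat", 32)
  expect_error(build_dictionary(list(empty)), "zero features")
})

test_that("k-means closed forms hold: k = 1 is the mean, k = M is exact", {
  set.seed(5)
  X <- matrix(runif(20 * 64), 20)
  cb1 <- build_codebook(X, k = 1, seed = 3)
  expect_equal(cb1$centroids[1, ], colMeans(X))
  cbM <- build_codebook(X, k = 20, seed = 3)
  expect_lt(cbM$train_meta$inertia, 1e-12)
  # every descriptor is its own centroid, up to ordering
  reorder <- nearest_index(X, cbM$centroids)
  expect_equal(sort(reorder), 1:20)
  expect_equal(cbM$centroids[reorder, ], unname(X))
  expect_error(build_codebook(X, k = 21), "exceeds")
  expect_error(build_codebook(X, k = 0), ">= 1")
})

test_that("Lloyd iterations match an independent k-means oracle from the same start", {
  set.seed(9)
  X <- matrix(rnorm(30 * 64), 30)
  seed <- 17
  cb <- build_codebook(X, k = 3, seed = seed, tol = 0)
  init <- dmcodex:::with_local_seed(seed, dmcodex:::kmeanspp_init(X, 3))
  km <- stats::kmeans(X, centers = init, algorithm = "Lloyd", iter.max = 200)
  expect_equal(nearest_index(X, cb$centroids), unname(km$cluster))
  expect_equal(cb$train_meta$inertia, km$tot.withinss, tolerance = 1e-8)
})

test_that("inertia trace is non-increasing and seeded rebuilds are bit-identical", {
  set.seed(4)
  X <- matrix(runif(200 * 64), 200)
  cb <- build_codebook(X, k = 8, seed = 21)
  expect_true(all(diff(cb$train_meta$inertia_trace) <= 1e-9))
  cb2 <- build_codebook(X, k = 8, seed = 21)
  expect_identical(cb$centroids, cb2$centroids)
  cb3 <- build_codebook(X, k = 8, seed = 22)
  expect_false(identical(cb$centroids, cb3$centroids))
})

test_that("hard coding assigns exact matches, breaks ties low, conserves mass", {
  C <- matrix(0, 3, 64)
  C[1, 1] <- 1; C[2, 2] <- 1; C[3, 3] <- 1
  cb <- structure(list(centroids = C, k = 3L,
                       train_meta = list(seed = 1L, n_iter = 0L, inertia = 0)),
                  class = "codebook")
  f <- fake_features(C[c(1, 3), ])
  h <- encode(f, cb)
  expect_equal(h$counts, c(1L, 0L, 1L))
  # equidistant from centroids 1 and 2 -> lowest index
  tie <- matrix(0, 1, 64); tie[1, 1] <- 0.5; tie[1, 2] <- 0.5
  expect_equal(encode(fake_features(tie), cb)$assignments, 1L)
  # empty input -> zero histogram
  empty <- image_features(data.frame(x = numeric(0), y = numeric(0),
                                     scale = numeric(0), response = numeric(0)),
                          matrix(numeric(0), 0, 64), "none", 32)
  h0 <- encode(empty, cb)
  expect_equal(h0$counts, c(0L, 0L, 0L))
  expect_equal(h0$n_features, 0L)
})

test_that("encoding equals a brute-force nearest-centroid scan and ignores order", {
  set.seed(12)
  X <- matrix(runif(100 * 64), 100)
  C <- matrix(runif(10 * 64), 10)
  cb <- structure(list(centroids = C, k = 10L,
                       train_meta = list(seed = 1L, n_iter = 0L, inertia = 0)),
                  class = "codebook")
  h <- encode(fake_features(X), cb)
  # independent oracle: exhaustive per-feature scan
  oracle <- vapply(seq_len(nrow(X)), function(i) {
    d2 <- vapply(seq_len(nrow(C)), function(j) sum((X[i, ] - C[j, ])^2),
                 numeric(1))
    which.min(d2)
  }, integer(1))
  expect_equal(h$assignments, oracle)
  expect_equal(sum(h$counts), 100L)            # mass conservation
  perm <- sample(nrow(X))
  h2 <- encode(fake_features(X[perm, ]), cb)
  expect_equal(h2$counts, h$counts)            # order invariance
})

test_that("codebooks and histograms survive the TSV round trip with digests", {
  set.seed(8)
  feats <- list(fake_features(matrix(runif(12 * 64), 12), "a", xs = 1:12, ys = 12:1),
                fake_features(matrix(runif(9 * 64), 9), "b", xs = 1:9, ys = 1:9))
  cb <- build_codebook(build_dictionary(feats), k = 5, seed = 2)
  dir <- withr::local_tempdir()
  cbp <- file.path(dir, "codebook.tsv")
  write_codebook(cb, cbp)
  cb2 <- read_codebook(cbp)
  expect_equal(cb2$centroids, cb$centroids, tolerance = 1e-12)
  expect_equal(cb2$k, cb$k)
  enc <- encode_corpus(feats, cb)
  hp <- file.path(dir, "hist.tsv")
  write_histograms(enc, hp, codebook_digest = cb2$digest)
  H <- read_histograms(hp, expect_codebook_digest = cb2$digest)
  expect_equal(unname(H), unname(enc$histograms))
  expect_error(read_histograms(hp, expect_codebook_digest = "bogus"),
               "digest mismatch")
  fp <- file.path(dir, "features.tsv")
  write_features(feats, fp)
  back <- read_features(fp)
  expect_equal(length(back), 2L)
  expect_equal(back[["a"]]$descriptors, feats[[1]]$descriptors,
               tolerance = 1e-12, ignore_attr = TRUE)
})
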