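test_that("cosine distance: identity, orthogonality, closed form, scale invariance", {
  expect_equal(cosine_distance(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(cosine_distance(c(1, 0, 0), c(0, 2, 0)), 1)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 0)), 1 - 1 / sqrt(2))
  set.seed(6)
  for (r in 1:10) {
    h <- rpois(20, 3) + 1
    g <- rpois(20, 3)
    expect_equal(cosine_distance(h, 7 * h), 0)
    expect_equal(cosine_distance(h, g + 1), cosine_distance(3 * h, g + 1))
  }
  expect_error(cosine_distance(c(0, 0), c(1, 2)), "zero vector")
  expect_error(cosine_distance(c(1, 2), c(1, 2, 3)), "length")
})

test_that("leave-one-out retrieval: duplicates, forced misses, exhaustive oracle", {
  # every item has an exact duplicate sharing its family -> perfect at all levels
  set.seed(10)
  base <- matrix(rpois(4 * 15, 4), 4)
  H <- rbind(base, base)
  rownames(H) <- sprintf("d%02d", 1:8)
  sids <- rep(c("a.1.1.1", "b.2.1.1", "c.3.2.1", "d.4.1.2"), 2)
  for (lv in c("class", "fold", "superfamily", "family"))
    expect_equal(nearest_neighbor_accuracy(H, sids, lv)$accuracy, 1.0)
  # two items, different classes: the only neighbour is wrong
  H2 <- matrix(c(5, 1, 1, 5), 2, byrow = TRUE, dimnames = list(c("x", "y"), NULL))
  expect_equal(nearest_neighbor_accuracy(H2, c("a.1.1.1", "b.1.1.1"),
                                         "class")$accuracy, 0.0)
  # random corpus vs brute-force all-pairs oracle
  set.seed(11)
  Hr <- matrix(rpois(20 * 12, 2) + 1, 20)
  rownames(Hr) <- sprintf("q%02d", 1:20)
  sids_r <- sample(c("a.1.1.1", "a.1.2.1", "b.1.1.1", "b.2.1.1", "c.1.1.1"),
                   20, replace = TRUE)
  res <- nearest_neighbor_accuracy(Hr, sids_r, "fold")
  oracle_correct <- vapply(1:20, function(i) {
    ds <- vapply(1:20, function(j) {
      if (i == j) return(Inf)
      1 - sum(Hr[i, ] * Hr[j, ]) /
        (sqrt(sum(Hr[i, ]^2)) * sqrt(sum(Hr[j, ]^2)))
    }, numeric(1))
    nn <- which(abs(ds - min(ds)) < 1e-12)
    nn <- nn[order(rownames(Hr)[nn])][1]
    match_level(sids_r[i], sids_r[nn], "fold")
  }, logical(1))
  expect_equal(res$accuracy, mean(oracle_correct))
  expect_equal(res$detail$correct, oracle_correct)
  expect_error(nearest_neighbor_accuracy(Hr, c(sids_r[-1], NA), "fold"),
               "unlabeled")
})

test_that("relative frequency counts image presence, not occurrences", {
  H <- rbind(c(2, 0, 9), c(1, 0, 0), c(4, 0, 0),
             c(0, 0, 1), c(0, 0, 3), c(1, 0, 2),
             c(0, 0, 4), c(3, 0, 1), c(0, 0, 2), c(1, 0, 5))
  rf <- relative_frequency(H)
  expect_equal(rf[2], 0)                 # absent everywhere
  expect_equal(rf[3], 0.8)               # 8 of 10 images
  expect_equal(relative_frequency(rbind(c(1, 1), c(9, 1)))[2], 1.0)
  wf <- relative_frequency(H, weighted = TRUE)
  expect_equal(sum(wf), 1)
})

test_that("diagonal distance is the normalized corner-bounded offset", {
  for (n in c(2, 17, 150))
    expect_equal(diagonal_distance(5 %% n, 5 %% n, n), 0)
  expect_equal(diagonal_distance(0, 127, 128), sqrt(2) / 2)
  expect_equal(round(diagonal_distance(0, 99, 100), 1), 0.7)
  # (x^, y^) = (0.5, 0.25): offset 0.25 / sqrt(2)
  expect_equal(diagonal_distance(2, 1, 5), 0.25 / sqrt(2))
  # symmetry and bounds on a grid
  n <- 31
  xs <- rep(0:(n - 1), n); ys <- rep(0:(n - 1), each = n)
  d <- diagonal_distance(xs, ys, n)
  expect_equal(d, diagonal_distance(ys, xs, n))
  expect_true(all(d >= 0 & d <= sqrt(2) / 2 + 1e-15))
  expect_error(diagonal_distance(0, 0, 1), ">= 2")
  expect_error(diagonal_distance(9, 0, 8), "range")
})

test_that("codeword profile matches a flat per-feature recomputation", {
  set.seed(13)
  feats <- lapply(1:3, function(i) {
    n <- 10 + i
    fake_features(matrix(runif(n * 64), n), sprintf("im%d", i),
                  image_size = 40, xs = sample(0:39, n), ys = sample(0:39, n))
  })
  cb <- build_codebook(build_dictionary(feats), k = 6, seed = 3)
  enc <- encode_corpus(feats, cb)
  prof <- codeword_diagonal_profile(enc)
  expect_equal(nrow(prof), 6L)
  # independent aggregation over the raw feature table
  ft <- enc$feature_table
  for (w in 1:6) {
    rows <- ft[ft$codeword == w, ]
    if (nrow(rows) == 0) {
      expect_true(is.na(prof$mean_diag_dist[w]))
      next
    }
    dd <- abs(rows$x / (rows$image_size - 1) - rows$y / (rows$image_size - 1)) / sqrt(2)
    expect_equal(prof$mean_diag_dist[w], mean(dd))
    expect_equal(prof$n_feat[w], nrow(rows))
    expect_equal(prof$rel_freq[w],
                 length(unique(rows$image_id)) / 3)
  }
  expect_setequal(prof$rank_by_freq, 1:6)
  # all features of one codeword on the diagonal -> mean 0; offsets 0 and 1
  # average to sqrt(2)/4
  diag_feats <- fake_features(matrix(c(rep(1, 64), rep(0, 63), 1), 2,
                                     byrow = TRUE),
                              "d", image_size = 10,
                              xs = c(3, 0), ys = c(3, 9))
  cb2 <- structure(list(centroids = diag_feats$descriptors, k = 2L,
                        train_meta = list(seed = 1L, n_iter = 0L, inertia = 0)),
                   class = "codebook")
  prof2 <- codeword_diagonal_profile(encode_corpus(list(diag_feats), cb2))
  expect_equal(prof2$mean_diag_dist[1], 0)
  expect_equal(prof2$mean_diag_dist[2], sqrt(2) / 2)
  both <- fake_features(rbind(rep(1, 64) / 8, rep(1, 64) / 8), "e",
                        image_size = 10, xs = c(2, 0), ys = c(2, 9))
  cb3 <- structure(list(centroids = matrix(1 / 8, 1, 64), k = 1L,
                        train_meta = list(seed = 1L, n_iter = 0L, inertia = 0)),
                   class = "codebook")
  prof3 <- codeword_diagonal_profile(encode_corpus(list(both), cb3))
  expect_equal(prof3$mean_diag_dist[1], sqrt(2) / 4)
})

test_that("unique-word ratio follows its definition and bounds", {
  counts <- c(rep(2L, 100), rep(1L, 300), rep(0L, 100))  # 500 features, 400 words
  u <- unique_word_ratio(counts)
  expect_equal(u$ratio, 0.8)
  expect_equal(unique_word_ratio(rep(1L, 7))$ratio, 1.0)
  expect_equal(unique_word_ratio(c(5L, 0L, 0L))$ratio, 0.2)
  expect_error(unique_word_ratio(integer(4)), "empty")
  # ratio <= 1 always; equals 1 iff all nonzero bins have count 1
  set.seed(14)
  for (r in 1:20) {
    cnt <- rpois(30, 0.8)
    if (sum(cnt) == 0) next
    u <- unique_word_ratio(cnt)
    expect_lte(u$ratio, 1)
    expect_identical(u$ratio == 1, all(cnt[cnt > 0] == 1))
  }
})

test_that("pearson correlation matches the covariance formula and flags degeneracy", {
  x <- c(1, 2, 3, 4, 7)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  set.seed(15)
  a <- rnorm(25); b <- 0.3 * a + rnorm(25)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), oracle)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("PCA embedding reproduces an eigendecomposition oracle", {
  set.seed(16)
  H <- matrix(rpois(10 * 6, 5), 10)
  p <- pca_embed(H, 2)
  Hc <- scale(H, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(Hc), symmetric = TRUE)
  oracle <- Hc %*% eig$vectors[, 1:2]
  for (j in 1:2) {  # scores match up to the sign of each component
    expect_true(isTRUE(all.equal(unname(p$scores[, j]), unname(oracle[, j]))) ||
                isTRUE(all.equal(unname(p$scores[, j]), -unname(oracle[, j]))))
    expect_equal(p$explained_variance[j], eig$values[j])
  }
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # rank-1 data: second component variance 0
  r1 <- outer(1:6, c(1, 2, 3, 0.5)) + 2
  p1 <- pca_embed(r1, 2)
  expect_lt(p1$explained_variance[2], 1e-20)
  expect_error(pca_embed(H[1, , drop = FALSE], 2), "at least 2")
})
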