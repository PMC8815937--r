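# Quantitative codeword statistics: cosine nearest-neighbour retrieval,
# relative frequency, diagonal-distance profiles, unique-word ratio,
# correlation and PCA embedding.

hist_counts <- function(h) {
  if (inherits(h, "codeword_histogram")) h$counts else as.numeric(h)
}

#' Cosine distance between two codeword histograms
#'
#' `1 - (h1 . h2) / (|h1| |h2|)`; lies in `[0, 1]` for nonnegative vectors
#' and is invariant to positive rescaling of either histogram, so raw
#' counts and relative frequencies give identical distances.
#'
#' @param h1,h2 Codeword histograms (or numeric vectors) of equal length.
#' @return A number in `[0, 1]`.
#' @export
cosine_distance <- function(h1, h2) {
  a <- hist_counts(h1); b <- hist_counts(h2)
  if (length(a) != length(b)) stopf("histograms differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stopf("cosine distance undefined for a zero vector")
  min(max(1 - sum(a * b) / (na * nb), 0), 1)
}

cosine_distance_matrix <- function(H) {
  H <- as.matrix(H)
  nrm <- sqrt(rowSums(H^2))
  if (any(nrm == 0)) stopf("zero histogram row(s): %s",
                           paste(rownames(H)[nrm == 0], collapse = ", "))
  S <- tcrossprod(H / nrm)
  D <- 1 - S
  D[D < 0] <- 0
  D[D > 1] <- 1
  diag(D) <- 0
  D
}

#' Leave-one-out nearest-neighbour accuracy at a SCOP hierarchy level
#'
#' For every domain, the nearest other domain by cosine distance between
#' codeword histograms is retrieved (ties broken toward the
#' lexicographically smaller image id); the prediction is correct iff the
#' two labels agree at the requested hierarchy level.
#'
#' @param H n_images x k histogram matrix with image ids as rownames.
#' @param labels Vector of SCOP sids (or list of [scop_label]s), one per row.
#' @param level `"class"`, `"fold"`, `"superfamily"` or `"family"`.
#' @return List with `accuracy`, `level` and a per-query data frame
#'   `detail` (id, neighbor, distance, correct).
#' @export
nearest_neighbor_accuracy <- function(H, labels, level) {
  H <- as.matrix(H)
  if (nrow(H) < 2L) stopf("need at least 2 domains")
  if (length(labels) != nrow(H)) stopf("one label per histogram row required")
  if (anyNA(labels)) stopf("unlabeled items present")
  labels <- lapply(labels, parse_scop_sid)
  ids <- rownames(H) %||% as.character(seq_len(nrow(H)))
  D <- cosine_distance_matrix(H)
  nn <- integer(nrow(H))
  for (i in seq_len(nrow(H))) {
    d <- D[i, ]
    d[i] <- Inf
    cand <- which(d == min(d))
    nn[i] <- if (length(cand) > 1L) cand[order(ids[cand])][1L] else cand
  }
  correct <- vapply(seq_len(nrow(H)), function(i)
    match_level(labels[[i]], labels[[nn[i]]], level), logical(1))
  list(accuracy = mean(correct), level = level,
       detail = data.frame(id = ids, neighbor = ids[nn],
                           distance = D[cbind(seq_len(nrow(H)), nn)],
                           correct = correct, stringsAsFactors = FALSE))
}

#' Presence-based relative frequency of each codeword
#'
#' The fraction of corpus images in which each codeword occurs at least
#' once. With `weighted = TRUE` the occurrence-weighted variant (total
#' count share per codeword) is returned instead.
#'
#' @param H n_images x k histogram matrix.
#' @param weighted Use occurrence weighting instead of presence.
#' @return Length-k vector in `[0, 1]`.
#' @export
relative_frequency <- function(H, weighted = FALSE) {
  H <- as.matrix(H)
  if (nrow(H) == 0L) stopf("empty corpus")
  if (weighted) colSums(H) / sum(H) else colMeans(H > 0)
}

#' Normalized distance from a keypoint to the matrix diagonal
#'
#' Pixel coordinates are normalized by `n - 1` so that corners map to 0 or
#' 1 exactly; the perpendicular distance from the normalized point
#' `(x^, y^)` to the main diagonal is `|x^ - y^| / sqrt(2)`, bounded by
#' `sqrt(2)/2 ~ 0.7` (attained at the far corners, i.e. the longest-range
#' contact), with 0 meaning the feature sits on the diagonal.
#'
#' @param x,y 0-based pixel column / row (vectorized).
#' @param n Image side length (>= 2).
#' @return Distances in `[0, sqrt(2)/2]`.
#' @export
diagonal_distance <- function(x, y, n) {
  if (any(n < 2)) stopf("image side n must be >= 2")
  if (any(x < 0 | x > n - 1 | y < 0 | y > n - 1))
    stopf("pixel coordinates out of range")
  abs(x / (n - 1) - y / (n - 1)) / sqrt(2)
}

#' Per-codeword frequency and diagonal-distance profile
#'
#' For every codeword: its presence-based relative frequency, its
#' frequency rank (1 = most frequent), the number of features assigned to
#' it corpus-wide, and the mean and standard deviation of the normalized
#' diagonal distances of those features. Codewords with no assigned
#' features get `NA` distance summaries.
#'
#' @param enc A [encode_corpus()] result.
#' @return Data frame of class `codeword_stats` with columns `codeword`,
#'   `n_feat`, `rel_freq`, `rank_by_freq`, `mean_diag_dist`, `sd_diag_dist`.
#' @export
codeword_diagonal_profile <- function(enc) {
  if (!inherits(enc, "corpus_encoding")) stopf("enc must be a corpus_encoding")
  k <- enc$k
  ft <- enc$feature_table
  dd <- diagonal_distance(ft$x, ft$y, ft$image_size)
  grp <- factor(ft$codeword, levels = seq_len(k))
  out <- data.frame(
    codeword = seq_len(k),
    n_feat = as.integer(table(grp)),
    rel_freq = relative_frequency(enc$histograms),
    mean_diag_dist = as.numeric(tapply(dd, grp, mean)),
    sd_diag_dist = as.numeric(tapply(dd, grp, stats::sd)))
  out$rank_by_freq <- rank(-out$rel_freq, ties.method = "first")
  out <- out[, c("codeword", "n_feat", "rel_freq", "rank_by_freq",
                 "mean_diag_dist", "sd_diag_dist")]
  class(out) <- c("codeword_stats", "data.frame")
  out
}

#' Unique-word ratio of a codeword histogram
#'
#' The number of distinct codewords present in the image divided by its
#' total feature count. Low values indicate repetitive distance-matrix
#' texture: many features quantized to few codewords, the signature of
#' solenoid / tandem-repeat domains. 500 features over 400 distinct
#' codewords give 400/500 = 0.8; the ratio is 1 exactly when every
#' feature lands in its own codeword.
#'
#' @param h A [encode()] histogram (or nonnegative count vector).
#' @param image_id Identifier used when `h` is a bare vector.
#' @return Data frame row with `image_id`, `n_features`, `n_unique`,
#'   `ratio`.
#' @export
unique_word_ratio <- function(h, image_id = "image") {
  counts <- hist_counts(h)
  if (inherits(h, "codeword_histogram")) image_id <- h$image_id
  n_features <- if (inherits(h, "codeword_histogram")) h$n_features else sum(counts)
  if (n_features <= 0) stopf("unique-word ratio undefined for an empty histogram")
  n_unique <- sum(counts > 0)
  data.frame(image_id = image_id, n_features = as.integer(n_features),
             n_unique = as.integer(n_unique),
             ratio = n_unique / n_features, stringsAsFactors = FALSE)
}

#' Unique-word ratios for a whole corpus
#'
#' @param enc A [encode_corpus()] result (or histogram matrix).
#' @return Data frame with one [unique_word_ratio()] row per image.
#' @export
unique_word_ratios <- function(enc) {
  H <- if (inherits(enc, "corpus_encoding")) enc$histograms else as.matrix(enc)
  ids <- rownames(H) %||% as.character(seq_len(nrow(H)))
  do.call(rbind, lapply(seq_len(nrow(H)), function(i)
    unique_word_ratio(H[i, ], image_id = ids[i])))
}

#' Sample Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (length(x) < 3L) stopf("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined for constant input")
  stats::cor(x, y)
}

#' PCA embedding of a histogram corpus
#'
#' Mean-centered principal component scores of the images-by-codewords
#' count matrix; component variances are non-increasing.
#'
#' @param H n_images x k histogram matrix.
#' @param n_components Number of leading components (default 2).
#' @return List with `scores` (n_images x n_components, rownames = ids)
#'   and `explained_variance` (component variances, descending).
#' @export
pca_embed <- function(H, n_components = 2) {
  H <- as.matrix(H)
  if (nrow(H) < 2L) stopf("need at least 2 images")
  if (ncol(H) < 2L) stopf("need at least 2 codewords")
  if (n_components > nrow(H)) stopf("fewer samples than components")
  p <- stats::prcomp(H, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(p$x))
  scores <- p$x[, seq_len(nc), drop = FALSE]
  if (nc < n_components)   # rank-deficient: pad trailing zero components
    scores <- cbind(scores, matrix(0, nrow(H), n_components - nc))
  colnames(scores) <- paste0("pc", seq_len(n_components))
  vars <- numeric(n_components)
  vars[seq_len(nc)] <- p$sdev[seq_len(nc)]^2
  list(scores = scores, explained_variance = vars)
}
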