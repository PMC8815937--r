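# Bag-of-visual-words: visual dictionary, k-means codebook, hard-coded
# codeword histograms.

#' Pool per-image features into a visual dictionary
#'
#' Row-concatenates the descriptor matrices of a corpus, keeping the
#' provenance (image id, keypoint index) of every row.
#'
#' @param features_list List of [image_features] objects.
#' @return An object of class `visual_dictionary`: list with `descriptors`
#'   (M x 64), `provenance` (data frame `image_id`, `keypoint`), `M`.
#' @export
build_dictionary <- function(features_list) {
  if (inherits(features_list, "image_features"))
    features_list <- list(features_list)
  counts <- vapply(features_list, function(f) nrow(f$descriptors), integer(1))
  if (sum(counts) == 0L) stopf("corpus yielded zero features")
  descriptors <- do.call(rbind, lapply(features_list, `[[`, "descriptors"))
  provenance <- data.frame(
    image_id = rep(vapply(features_list, `[[`, character(1), "image_id"), counts),
    keypoint = unlist(lapply(counts, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE)
  structure(list(descriptors = descriptors, provenance = provenance,
                 M = nrow(descriptors)),
            class = "visual_dictionary")
}

#' @export
print.visual_dictionary <- function(x, ...) {
  cat(sprintf("<visual_dictionary> %d features from %d images\n",
              x$M, length(unique(x$provenance$image_id))))
  invisible(x)
}

kmeanspp_init <- function(X, k) {
  centers <- integer(k)
  centers[1] <- sample.int(nrow(X), 1L)
  d2 <- cross_dist2(X, X[centers[1], , drop = FALSE])[, 1]
  if (k > 1L) for (j in 2:k) {
    if (sum(d2) <= 0) {
      centers[j] <- sample.int(nrow(X), 1L)   # all points on chosen centers
    } else {
      centers[j] <- sample.int(nrow(X), 1L, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, cross_dist2(X, X[centers[j], , drop = FALSE])[, 1])
  }
  X[centers, , drop = FALSE]
}

#' Build a visual codebook by k-means clustering
#'
#' Clusters the dictionary descriptors with k-means (k-means++
#' initialization from a fixed seed, Lloyd iterations, Euclidean metric)
#' and stores the cluster centroids as codewords. Empty clusters are
#' re-seeded from the point farthest from its centroid. The per-iteration
#' inertia (total within-cluster sum of squares) trace is recorded; it is
#' non-increasing by construction.
#'
#' @param dict A [build_dictionary()] result, or a bare M x 64 matrix.
#' @param k Vocabulary size (1 <= k <= M).
#' @param seed RNG seed controlling the initialization.
#' @param max_iter Maximum Lloyd iterations.
#' @param tol Relative inertia-improvement stopping tolerance.
#' @return An object of class `codebook`: list with `centroids` (k x 64),
#'   `k`, `train_meta` (seed, n_iter, inertia, inertia_trace).
#' @export
build_codebook <- function(dict, k, seed = 1, max_iter = 100L, tol = 1e-4) {
  X <- if (inherits(dict, "visual_dictionary")) dict$descriptors else as.matrix(dict)
  M <- nrow(X)
  if (k < 1L) stopf("k must be >= 1")
  if (k > M) stopf("k (%d) exceeds the dictionary size M (%d)", k, M)
  with_local_seed(seed, {
    C <- kmeanspp_init(X, k)
    trace <- numeric(0)
    assign_prev <- NULL
    for (it in seq_len(max_iter)) {
      d2 <- cross_dist2(X, C)
      assign <- max.col(-d2, ties.method = "first")
      inertia <- sum(d2[cbind(seq_len(M), assign)])
      trace <- c(trace, inertia)
      # update step
      for (j in seq_len(k)) {
        sel <- assign == j
        if (any(sel)) {
          C[j, ] <- colMeans(X[sel, , drop = FALSE])
        } else {  # re-seed empty cluster from the farthest point
          far <- which.max(d2[cbind(seq_len(M), assign)])
          C[j, ] <- X[far, ]
          d2[far, ] <- 0   # don't pick the same point twice in this pass
        }
      }
      if (!is.null(assign_prev) && all(assign == assign_prev)) break
      if (length(trace) >= 2L) {
        prev <- trace[length(trace) - 1L]
        if (prev > 0 && (prev - inertia) / prev < tol) break
      }
      assign_prev <- assign
    }
    # final inertia against the last update
    d2 <- cross_dist2(X, C)
    assign <- max.col(-d2, ties.method = "first")
    final_inertia <- sum(d2[cbind(seq_len(M), assign)])
    structure(list(centroids = unname(C), k = as.integer(k),
                   train_meta = list(seed = as.integer(seed),
                                     n_iter = length(trace),
                                     inertia = final_inertia,
                                     inertia_trace = trace)),
              class = "codebook")
  })
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> k = %d codewords (seed %d, %d iterations, inertia %.4g)\n",
              x$k, x$train_meta$seed, x$train_meta$n_iter, x$train_meta$inertia))
  invisible(x)
}

#' Encode image features as a codeword histogram (hard coding)
#'
#' Assigns every feature to its Euclidean-nearest codeword (ties broken
#' toward the lowest codeword index) and accumulates counts. The per-feature
#' assignment indices and keypoint coordinates are retained for spatial
#' statistics. An empty feature set encodes to the all-zero histogram.
#'
#' @param features An [image_features] object.
#' @param cb A [build_codebook()] result.
#' @return An object of class `codeword_histogram`: list with `counts`
#'   (length-k integer vector), `image_id`, `n_features`, `assignments`,
#'   `keypoints`, `image_size`.
#' @export
encode <- function(features, cb) {
  if (!inherits(cb, "codebook")) stopf("cb must be a codebook")
  n <- nrow(features$descriptors)
  if (n == 0L) {
    assign <- integer(0)
  } else {
    assign <- nearest_index(features$descriptors, cb$centroids)
  }
  structure(list(counts = tabulate(assign, nbins = cb$k),
                 image_id = features$image_id,
                 n_features = n,
                 assignments = assign,
                 keypoints = features$keypoints,
                 image_size = features$image_size),
            class = "codeword_histogram")
}

#' @export
print.codeword_histogram <- function(x, ...) {
  cat(sprintf("<codeword_histogram> %s: %d features over %d bins (%d unique)\n",
              x$image_id, x$n_features, length(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Encode a whole corpus against one codebook
#'
#' @param features_list List of [image_features].
#' @param cb A codebook.
#' @return List with `histograms` (n_images x k integer matrix, rownames =
#'   image ids), `records` (list of [encode()] results) and `feature_table`
#'   (data frame: image_id, x, y, scale, image_size, codeword), class
#'   `corpus_encoding`.
#' @export
encode_corpus <- function(features_list, cb) {
  records <- lapply(features_list, encode, cb = cb)
  H <- do.call(rbind, lapply(records, `[[`, "counts"))
  rownames(H) <- vapply(records, `[[`, character(1), "image_id")
  ft <- do.call(rbind, lapply(records, function(r) {
    if (r$n_features == 0L) return(NULL)
    data.frame(image_id = r$image_id, x = r$keypoints$x, y = r$keypoints$y,
               scale = r$keypoints$scale, image_size = r$image_size,
               codeword = r$assignments, stringsAsFactors = FALSE)
  }))
  rownames(ft) <- NULL
  structure(list(histograms = H, records = records, feature_table = ft,
                 k = cb$k),
            class = "corpus_encoding")
}

# --- on-disk formats -------------------------------------------------------

#' Codebook, feature and histogram files
#'
#' Codebooks are stored as a TSV of k rows x 64 descriptor columns with a
#' JSON sidecar (`<path>.json`) recording k, seed, iterations, inertia and
#' the md5 digest of the TSV; histograms record the digest of the codebook
#' they were computed against, and readers can verify it.
#'
#' @param cb,path,features_list,enc Objects / paths as appropriate.
#' @return The written path (writers, invisibly) or the reconstructed
#'   object (readers).
#' @name bovw_io
NULL

#' @rdname bovw_io
#' @export
write_codebook <- function(cb, path) {
  utils::write.table(cb$centroids, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = paste0("d", 1:64))
  meta <- cb$train_meta
  meta$inertia_trace <- NULL
  meta$k <- cb$k
  meta$digest <- unname(tools::md5sum(path))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname bovw_io
#' @export
read_codebook <- function(path) {
  C <- as.matrix(utils::read.delim(path, check.names = FALSE))
  meta <- list(seed = NA_integer_, n_iter = NA_integer_, inertia = NA_real_)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) meta <- jsonlite::read_json(sc)
  structure(list(centroids = unname(C), k = nrow(C),
                 train_meta = meta, digest = unname(tools::md5sum(path))),
            class = "codebook")
}

#' @rdname bovw_io
#' @export
write_features <- function(features_list, path) {
  if (inherits(features_list, "image_features"))
    features_list <- list(features_list)
  rows <- do.call(rbind, lapply(features_list, function(f) {
    if (nrow(f$descriptors) == 0L) return(NULL)
    cbind(data.frame(image_id = f$image_id, x = f$keypoints$x,
                     y = f$keypoints$y, scale = f$keypoints$scale,
                     image_size = f$image_size, stringsAsFactors = FALSE),
          as.data.frame(f$descriptors) |> stats::setNames(paste0("d", 1:64)))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname bovw_io
#' @export
read_features <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  dcols <- paste0("d", 1:64)
  lapply(split(tab, factor(tab$image_id, levels = unique(tab$image_id))),
         function(g) image_features(
           keypoints = data.frame(x = g$x, y = g$y, scale = g$scale,
                                  response = NA_real_),
           descriptors = as.matrix(g[, dcols]),
           image_id = g$image_id[1], image_size = g$image_size[1]))
}

#' @rdname bovw_io
#' @export
write_histograms <- function(enc, path, codebook_digest = NULL) {
  H <- enc$histograms
  tab <- data.frame(image_id = rownames(H),
                    n_features = rowSums(H),
                    H, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[-(1:2)] <- paste0("w", seq_len(ncol(H)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(k = ncol(H), n_images = nrow(H),
                            codebook_digest = codebook_digest),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname bovw_io
#' @export
read_histograms <- function(path, expect_codebook_digest = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE)
  sc <- paste0(path, ".json")
  if (!is.null(expect_codebook_digest) && file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    if (!is.null(meta$codebook_digest) &&
        !identical(meta$codebook_digest, expect_codebook_digest))
      stopf("histograms were computed against a different codebook (digest mismatch)")
  }
  H <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(H) <- tab$image_id
  colnames(H) <- NULL
  H
}
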