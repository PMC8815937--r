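# KAZE-style multiscale keypoint detection and description.
#
# Scale space is built by Perona-Malik nonlinear diffusion (explicit
# scheme), which blurs smooth regions while preserving the sharp edges of
# the distance-matrix texture. Keypoints are scale-normalized
# determinant-of-Hessian extrema across space and scale; each keypoint is
# described by an upright 64-dimensional SURF-style descriptor (4 x 4
# subregions x (sum dx, sum dy, sum |dx|, sum |dy|)) of first-order
# derivatives sampled at the keypoint's scale. Fully deterministic.

# --- low-level image ops (replicated borders) ------------------------------

shift_n <- function(M) M[c(1L, seq_len(nrow(M) - 1L)), , drop = FALSE]
shift_s <- function(M) M[c(seq_len(nrow(M) - 1L) + 1L, nrow(M)), , drop = FALSE]
shift_w <- function(M) M[, c(1L, seq_len(ncol(M) - 1L)), drop = FALSE]
shift_e <- function(M) M[, c(seq_len(ncol(M) - 1L) + 1L, ncol(M)), drop = FALSE]

blur_cols <- function(M, kern) {
  h <- (length(kern) - 1L) %/% 2L
  Mp <- M[c(rep(1L, h), seq_len(nrow(M)), rep(nrow(M), h)), , drop = FALSE]
  out <- stats::filter(Mp, kern, sides = 2)
  matrix(out[(h + 1L):(h + nrow(M)), ], nrow(M), ncol(M))
}

gaussian_blur <- function(M, sigma) {
  if (sigma <= 0) return(M)
  h <- max(1L, ceiling(3 * sigma))
  x <- (-h):h
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  t(blur_cols(t(blur_cols(M, kern)), kern))
}

deriv_x <- function(M) (shift_e(M) - shift_w(M)) / 2   # along columns (image x)
deriv_y <- function(M) (shift_s(M) - shift_n(M)) / 2   # along rows (image y)

# one explicit Perona-Malik step, conductivity g2 = 1 / (1 + |grad|^2 / k2)
pm_step <- function(L, k2, tau) {
  gx <- deriv_x(L)
  gy <- deriv_y(L)
  g <- 1 / (1 + (gx * gx + gy * gy) / k2)
  L + tau * (
    (g + shift_n(g)) * (shift_n(L) - L) +
    (g + shift_s(g)) * (shift_s(L) - L) +
    (g + shift_w(g)) * (shift_w(L) - L) +
    (g + shift_e(g)) * (shift_e(L) - L)) / 2
}

pm_diffuse <- function(L, k2, t_from, t_to, tau) {
  dt <- t_to - t_from
  if (dt <= 0) return(L)
  nsteps <- ceiling(dt / tau)
  tau_eff <- dt / nsteps
  for (s in seq_len(nsteps)) L <- pm_step(L, k2, tau_eff)
  L
}

# contrast parameter k^2: percentile of gradient magnitudes of a lightly
# smoothed copy of the image (KAZE convention)
contrast_k2 <- function(M, percentile) {
  S <- gaussian_blur(M, 1.0)
  mag <- sqrt(deriv_x(S)^2 + deriv_y(S)^2)
  mag <- mag[mag > 0]
  if (length(mag) == 0L) return(1)
  as.numeric(stats::quantile(mag, percentile, names = FALSE))^2
}

max8 <- function(M) {  # max over the 8 spatial neighbours (replicated border)
  pmax(shift_n(M), shift_s(M), shift_w(M), shift_e(M),
       shift_n(shift_w(M)), shift_n(shift_e(M)),
       shift_s(shift_w(M)), shift_s(shift_e(M)))
}

max9 <- function(M) pmax(max8(M), M)

bilinear <- function(M, ys, xs) {  # 1-based fractional coords, clamped
  n <- nrow(M); m <- ncol(M)
  ys <- pmin(pmax(ys, 1), n)
  xs <- pmin(pmax(xs, 1), m)
  y0 <- pmin(floor(ys), n - 1L); x0 <- pmin(floor(xs), m - 1L)
  fy <- ys - y0; fx <- xs - x0
  M[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    M[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    M[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    M[cbind(y0 + 1, x0 + 1)] * fy * fx
}

# --- public interface ------------------------------------------------------

#' Detector and descriptor settings
#'
#' @param threshold Minimum scale-normalized determinant-of-Hessian
#'   response for a keypoint. The default is calibrated so that domain
#'   images of ~150 residues yield feature counts of the order observed on
#'   real domain corpora (a few hundred per image).
#' @param n_octaves Maximum number of scale-space octaves; the effective
#'   number is additionally capped by image size.
#' @param n_sublevels Sublevels per octave.
#' @param sigma0 Base smoothing scale (pixels).
#' @param k_percentile Percentile of gradient magnitudes used for the
#'   Perona-Malik contrast parameter.
#' @param tau Maximum explicit diffusion step (stability requires <= 0.25).
#' @return A list of class `kaze_params`.
#' @export
kaze_params <- function(threshold = 1e-4, n_octaves = 4, n_sublevels = 4,
                        sigma0 = 1.6, k_percentile = 0.7, tau = 0.2) {
  stopifnot(threshold >= 0, n_octaves >= 1, n_sublevels >= 1,
            sigma0 > 0, tau > 0, tau <= 0.25)
  structure(list(threshold = threshold, n_octaves = n_octaves,
                 n_sublevels = n_sublevels, sigma0 = sigma0,
                 k_percentile = k_percentile, tau = tau),
            class = "kaze_params")
}

#' Extract multiscale keypoint features from a grayscale image
#'
#' Builds a nonlinear-diffusion scale space, finds scale-normalized
#' determinant-of-Hessian extrema across space and adjacent scales, and
#' computes an upright 64-dimensional gradient-histogram descriptor per
#' keypoint. Images smaller than 16 x 16 yield an empty feature set (not
#' an error), as do images with no scale-space extrema (e.g. constant
#' images).
#'
#' @param img A [gray_image] (or square matrix in `[0, 1]`).
#' @param params A [kaze_params()] list.
#' @return An object of class `image_features`: list with `keypoints`
#'   (data frame: `x`, `y` 0-based pixel coordinates with x = column =
#'   residue j, y = row = residue i; `scale`; `response`), `descriptors`
#'   (n x 64 matrix, L2-normalized rows), `image_id` and `image_size`.
#' @export
extract_features <- function(img, params = kaze_params()) {
  if (!inherits(img, "gray_image")) img <- gray_image(img)
  M <- img$pixels
  n <- nrow(M)
  empty <- function() image_features(
    keypoints = data.frame(x = numeric(0), y = numeric(0),
                           scale = numeric(0), response = numeric(0)),
    descriptors = matrix(numeric(0), 0, 64),
    image_id = img$id, image_size = n, params = params)
  if (n < 16L) return(empty())

  n_oct <- max(1L, min(params$n_octaves, floor(log2(n / 16)) + 1L))
  S <- params$n_sublevels
  lv <- expand.grid(s = seq_len(S) - 1L, o = seq_len(n_oct) - 1L)
  sigma <- params$sigma0 * 2^(lv$o + lv$s / S)
  tev <- sigma^2 / 2
  k2 <- contrast_k2(M, params$k_percentile)

  L <- gaussian_blur(M, params$sigma0)
  levels <- vector("list", length(sigma))
  t_cur <- tev[1]
  levels[[1]] <- L
  for (i in seq_along(sigma)[-1]) {
    L <- pm_diffuse(L, k2, t_cur, tev[i], params$tau)
    t_cur <- tev[i]
    levels[[i]] <- L
  }

  resp <- vector("list", length(sigma))
  Lx <- vector("list", length(sigma))
  Ly <- vector("list", length(sigma))
  for (i in seq_along(sigma)) {
    Li <- levels[[i]]
    Lx[[i]] <- deriv_x(Li)
    Ly[[i]] <- deriv_y(Li)
    Lxx <- shift_e(Li) + shift_w(Li) - 2 * Li
    Lyy <- shift_s(Li) + shift_n(Li) - 2 * Li
    Lxy <- (shift_s(shift_e(Li)) + shift_n(shift_w(Li)) -
            shift_s(shift_w(Li)) - shift_n(shift_e(Li))) / 4
    resp[[i]] <- sigma[i]^4 * (Lxx * Lyy - Lxy * Lxy)
  }

  margin <- 3L
  kp <- list()
  for (i in seq(2L, length(sigma) - 1L)) {
    R <- resp[[i]]
    is_max <- R > params$threshold &
      R > max8(R) &
      R > max9(resp[[i - 1L]]) &
      R > max9(resp[[i + 1L]])
    is_max[c(seq_len(margin), n - seq_len(margin) + 1L), ] <- FALSE
    is_max[, c(seq_len(margin), n - seq_len(margin) + 1L)] <- FALSE
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) > 0L)
      kp[[length(kp) + 1L]] <- data.frame(
        row = idx[, 1], col = idx[, 2], level = i,
        scale = sigma[i], response = R[idx])
  }
  if (length(kp) == 0L) return(empty())
  kp <- do.call(rbind, kp)
  kp <- kp[order(kp$row, kp$col, kp$level), , drop = FALSE]

  desc <- matrix(0, nrow(kp), 64)
  off <- (seq_len(20) - 10.5)            # sample offsets in units of sigma
  grid_u <- rep(off, times = 20)         # x offset
  grid_v <- rep(off, each = 20)          # y offset
  sub_idx <- (rep(floor((off + 10) / 5), times = 20) * 4 +
              rep(floor((off + 10) / 5), each = 20)) + 1  # 1..16
  w <- exp(-(grid_u^2 + grid_v^2) / (2 * 3.3^2))
  for (f in seq_len(nrow(kp))) {
    s <- kp$scale[f]
    ys <- kp$row[f] + grid_v * s
    xs <- kp$col[f] + grid_u * s
    lvl <- kp$level[f]
    dx <- w * bilinear(Lx[[lvl]], ys, xs)
    dy <- w * bilinear(Ly[[lvl]], ys, xs)
    v <- numeric(64)
    for (b in seq_len(16)) {
      sel <- sub_idx == b
      j <- (b - 1L) * 4L
      v[j + 1L] <- sum(dx[sel]); v[j + 2L] <- sum(dy[sel])
      v[j + 3L] <- sum(abs(dx[sel])); v[j + 4L] <- sum(abs(dy[sel]))
    }
    nv <- sqrt(sum(v^2))
    if (nv > 0) desc[f, ] <- v / nv
  }
  keep <- rowSums(desc != 0) > 0
  kp <- kp[keep, , drop = FALSE]
  desc <- desc[keep, , drop = FALSE]

  image_features(
    keypoints = data.frame(x = kp$col - 1, y = kp$row - 1,
                           scale = kp$scale, response = kp$response),
    descriptors = desc, image_id = img$id, image_size = n, params = params)
}

#' Construct an image feature set
#'
#' @param keypoints Data frame with 0-based `x`, `y` pixel coordinates,
#'   `scale` and `response` columns.
#' @param descriptors Numeric matrix with one 64-vector row per keypoint.
#' @param image_id Source image identifier.
#' @param image_size Side length of the (square) source image.
#' @param params Optional detector settings used.
#' @return An object of class `image_features`.
#' @export
image_features <- function(keypoints, descriptors, image_id, image_size,
                           params = NULL) {
  descriptors <- as.matrix(descriptors)
  if (nrow(keypoints) != nrow(descriptors))
    stopf("keypoints and descriptors disagree in length")
  if (ncol(descriptors) != 64L && nrow(descriptors) > 0L)
    stopf("descriptors must have 64 columns")
  if (nrow(descriptors) > 0L) {
    if (!all(is.finite(descriptors))) stopf("descriptors must be finite")
    if (any(keypoints$x < 0 | keypoints$x >= image_size |
            keypoints$y < 0 | keypoints$y >= image_size))
      stopf("keypoint coordinates outside the image")
  }
  rownames(keypoints) <- NULL
  structure(list(keypoints = keypoints, descriptors = descriptors,
                 image_id = as.character(image_id),
                 image_size = as.integer(image_size), params = params),
            class = "image_features")
}

#' @export
print.image_features <- function(x, ...) {
  cat(sprintf("<image_features> %s: %d keypoints (image %d x %d)\n",
              x$image_id, nrow(x$descriptors), x$image_size, x$image_size))
  invisible(x)
}
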