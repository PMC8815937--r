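# Pairwise C-alpha distance matrices and their grayscale-image rendering.

#' Pairwise C-alpha distance matrix
#'
#' `values[i, j]` is the Euclidean distance (Angstrom) between residues i
#' and j. The matrix is symmetric with a zero diagonal and is invariant
#' under rigid rotation and translation of the structure.
#'
#' @param trace A [ca_trace] (or a bare N x 3 coordinate matrix).
#' @return A `distance_matrix`: an N x N numeric matrix with attribute `id`.
#' @export
distance_matrix <- function(trace) {
  if (inherits(trace, "ca_trace")) {
    coords <- trace$coords
    id <- trace$id
  } else {
    coords <- as.matrix(trace)
    id <- "trace"
  }
  if (nrow(coords) < 2L) stopf("need at least 2 residues")
  D <- as.matrix(stats::dist(coords))
  dimnames(D) <- NULL
  structure(D, id = id, class = c("distance_matrix", "matrix", "array"))
}

#' Render a distance matrix as a grayscale image
#'
#' Maps distances linearly and inversely onto intensities in `[0, 1]`:
#' `pixels[i, j] = 1 - D[i, j] / max(D)` in the default per-matrix mode, so
#' white (1) encodes short range (the diagonal is exactly 1) and black (0)
#' the longest-range pair in the domain. With `mode = "fixed_cap"` distances
#' are clamped at `cap` Angstrom and divided by `cap` instead, giving a
#' normalization comparable across domains.
#'
#' @param D A [distance_matrix] (or square nonnegative matrix).
#' @param mode `"per_matrix"` (default) or `"fixed_cap"`.
#' @param cap Distance cap in Angstrom for `mode = "fixed_cap"`.
#' @param id Image identifier; defaults to the matrix `id` attribute.
#' @return A `gray_image`: list with `pixels` (N x N in `[0, 1]`), `id`, and
#'   `normalization` metadata.
#' @export
to_gray_image <- function(D, mode = c("per_matrix", "fixed_cap"), cap = 50,
                          id = NULL) {
  mode <- match.arg(mode)
  id <- id %||% attr(D, "id") %||% "image"
  if (!is_square(unclass(D))) stopf("D must be square")
  dmax <- max(D)
  if (mode == "per_matrix") {
    if (dmax <= 0) stopf("all points identical: max distance is 0")
    px <- 1 - D / dmax
  } else {
    px <- 1 - pmin(D, cap) / cap
  }
  px <- matrix(pmin(pmax(as.numeric(px), 0), 1), nrow(D), ncol(D))
  gray_image(px, id = id,
             normalization = list(mode = mode,
                                  max_distance = if (mode == "per_matrix") dmax else cap))
}

#' Construct a grayscale image object
#'
#' @param pixels Square numeric matrix with values in `[0, 1]`. Row index is
#'   residue i (image y, top-left origin), column index residue j (image x);
#'   coordinates elsewhere in the package are 0-based.
#' @param id Identifier.
#' @param normalization Optional metadata list.
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, id = "image", normalization = NULL) {
  pixels <- as.matrix(pixels)
  if (!is_square(pixels)) stopf("pixels must be square")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stopf("pixel values must be in [0, 1]")
  structure(list(pixels = pixels, id = as.character(id),
                 normalization = normalization),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %s: %d x %d\n", x$id, nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Write / read a grayscale image as 8-bit PNG
#'
#' Values are stored as `round(value * 255)`; reading divides by 255, so a
#' write-read round trip is exact to within the 8-bit quantization bound of
#' 1/510. `write_gray_png` also writes a JSON sidecar (`<path>.json`) with
#' the image id, size and normalization metadata.
#'
#' @param img A [gray_image].
#' @param path Output (input) PNG path.
#' @param sidecar Write the JSON sidecar? Default `TRUE`.
#' @return `write_gray_png` returns `path` invisibly; `read_gray_png`
#'   returns a [gray_image].
#' @export
write_gray_png <- function(img, path, sidecar = TRUE) {
  if (!inherits(img, "gray_image")) img <- gray_image(img)
  png::writePNG(img$pixels, target = path)
  if (sidecar) {
    meta <- list(id = img$id, n_residues = nrow(img$pixels),
                 normalization = img$normalization)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  id <- sub("\\.png$", "", basename(path))
  norm <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    id <- meta$id %||% id
    norm <- meta$normalization
  }
  gray_image(px, id = id, normalization = norm)
}
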