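# Reading C-alpha traces from PDB files and SCOP-style label handling.

#' Construct a C-alpha trace
#'
#' A `ca_trace` holds the ordered 3-D coordinates (in Angstrom) of the
#' C-alpha atoms of one protein domain, plus optional classification labels.
#'
#' @param id Identifier string.
#' @param coords Numeric N x 3 matrix of coordinates in Angstrom, one row per
#'   residue, in sequence order.
#' @param label Optional [scop_label] (or a sid string, which is parsed).
#' @param binary_label Optional `"solenoid"` or `"globular"`.
#' @return An object of class `ca_trace` with elements `id`, `coords`,
#'   `label`, `binary_label`.
#' @export
ca_trace <- function(id, coords, label = NULL, binary_label = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stopf("coords must be an N x 3 matrix")
  if (nrow(coords) < 2L) stopf("a trace needs at least 2 residues")
  if (!all(is.finite(coords))) stopf("coordinates must be finite")
  storage.mode(coords) <- "double"
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  if (is.character(label)) label <- parse_scop_sid(label)
  if (!is.null(binary_label)) {
    binary_label <- match.arg(binary_label, c("solenoid", "globular"))
  }
  structure(list(id = as.character(id), coords = coords, label = label,
                 binary_label = binary_label),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %s: %d residues", x$id, nrow(x$coords)))
  if (!is.null(x$label)) cat(" [", x$label$family, "]", sep = "")
  if (!is.null(x$binary_label)) cat(" (", x$binary_label, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Read the C-alpha trace of a domain from a PDB file
#'
#' Extracts one coordinate per residue bearing a CA atom, in file order.
#' Only the first model of multi-model (NMR) files is used. Where a residue
#' has alternate locations, the first encountered altloc is kept. Insertion
#' codes and numbering gaps are ignored: sequence order is record order.
#'
#' @param path Path to a PDB-format file.
#' @param chain Optional chain identifier. Required when the file contains
#'   more than one chain.
#' @param id Identifier for the returned trace; defaults to the file name
#'   without extension.
#' @return A [ca_trace].
#' @export
read_ca_trace <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  atoms <- pdb$atom
  atoms <- atoms[atoms$elety == "CA" & atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stopf("no C-alpha atoms in %s", path)
  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stopf("%s has %d chains (%s); select one with `chain`",
            path, length(chains), paste(chains, collapse = ", "))
  } else {
    atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
    if (nrow(atoms) == 0L) stopf("no C-alpha atoms for chain %s in %s", chain, path)
  }
  # first altloc per residue, in record order
  resid_key <- paste(atoms$chain, atoms$resno, atoms$insert)
  atoms <- atoms[!duplicated(resid_key), , drop = FALSE]
  ca_trace(id %||% sub("\\.[^.]+$", "", basename(path)),
           cbind(atoms$x, atoms$y, atoms$z))
}

#' Parse a SCOP-style sid into its four hierarchy levels
#'
#' A sid such as `"a.1.1.1"` encodes class, fold, superfamily and family as
#' successively longer dot-joined prefixes: `"a"`, `"a.1"`, `"a.1.1"`,
#' `"a.1.1.1"`.
#'
#' @param sid A string of the form `letter.int.int.int`.
#' @return An object of class `scop_label` with elements `cls`, `fold`,
#'   `superfamily`, `family`.
#' @export
#' @examples
#' parse_scop_sid("a.1.1.1")
parse_scop_sid <- function(sid) {
  if (inherits(sid, "scop_label")) return(sid)
  if (length(sid) != 1L || !is.character(sid))
    stopf("sid must be a single string")
  if (!grepl("^[a-zA-Z]\\.[0-9]+\\.[0-9]+\\.[0-9]+$", sid))
    stopf("malformed SCOP sid: %s (expected letter.int.int.int)", sid)
  parts <- strsplit(sid, ".", fixed = TRUE)[[1]]
  structure(list(cls = parts[1],
                 fold = paste(parts[1:2], collapse = "."),
                 superfamily = paste(parts[1:3], collapse = "."),
                 family = paste(parts[1:4], collapse = ".")),
            class = "scop_label")
}

#' @export
print.scop_label <- function(x, ...) {
  cat("<scop_label>", x$family, "\n")
  invisible(x)
}

scop_level_field <- function(level) {
  switch(match.arg(level, c("class", "fold", "superfamily", "family")),
         class = "cls", fold = "fold",
         superfamily = "superfamily", family = "family")
}

#' Compare two SCOP labels at a hierarchy level
#'
#' @param a,b [scop_label] objects (or sid strings).
#' @param level One of `"class"`, `"fold"`, `"superfamily"`, `"family"`.
#' @return `TRUE` iff the dot-joined prefixes up to `level` are identical.
#'   A match at a level implies a match at all coarser levels.
#' @export
#' @examples
#' match_level("a.1.1.1", "a.1.2.1", "fold")        # TRUE
#' match_level("a.1.1.1", "a.1.2.1", "superfamily") # FALSE
match_level <- function(a, b, level) {
  a <- parse_scop_sid(a)
  b <- parse_scop_sid(b)
  f <- scop_level_field(level)
  identical(a[[f]], b[[f]])
}

#' Read a corpus manifest
#'
#' The manifest is a TSV with columns `id` and `path`, plus optional
#' `scop_sid` and `binary_label` columns. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path Path to the TSV manifest.
#' @return A data frame with one row per domain.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "path") %in% names(m)))
    stopf("manifest must have columns `id` and `path`")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}
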