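#' Construct a weighted 3D point model
#'
#' A `coord_set` represents a structural model as weighted scattering
#' centers: atoms (weight = electron count) or beads (uniform weight).
#' All coordinates are in Angstrom.
#'
#' @param positions numeric matrix with 3 columns (x, y, z in Angstrom),
#'   one row per point.
#' @param weights numeric vector of positive scattering weights, one per
#'   point, or a single value recycled to all points.
#' @param label free-text label.
#' @return An object of class `coord_set`: list with `positions` (n x 3
#'   matrix), `weights`, `label`.
#' @examples
#' cs <- coordinate_set(rbind(c(0, 0, 0), c(10, 0, 0)), weights = 1)
#' rg_of_coords(cs)
#' @export
coordinate_set <- function(positions, weights = 1, label = "") {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  if (nrow(positions) < 1) stop("model must contain at least 1 point")
  if (any(!is.finite(positions))) stop("non-finite coordinates")
  storage.mode(positions) <- "double"
  if (length(weights) == 1) weights <- rep(as.numeric(weights), nrow(positions))
  weights <- as.numeric(weights)
  if (length(weights) != nrow(positions))
    stop("weights must match the number of points")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("all weights must be positive and finite")
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  structure(list(positions = positions, weights = weights,
                 label = as.character(label)[1]),
            class = "coord_set")
}

#' @export
print.coord_set <- function(x, ...) {
  cat(sprintf("coord_set%s: %d points, total weight %.6g, Rg %.2f A\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$positions), sum(x$weights), rg_of_coords(x)))
  invisible(x)
}

#' @export
length.coord_set <- function(x) nrow(x$positions)

#' Radius of gyration of a coordinate model
#'
#' Weight-averaged second moment about the weighted centroid:
#' `Rg^2 = sum(w * |r - rbar|^2) / sum(w)`.  Invariant under rigid
#' motion of the model.
#'
#' @param model a [coordinate_set()].
#' @return Rg in Angstrom (0 for a single point).
#' @export
rg_of_coords <- function(model) {
  stopifnot(inherits(model, "coord_set"))
  w <- model$weights
  ctr <- colSums(model$positions * w) / sum(w)
  d2 <- rowSums(sweep(model$positions, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

## Electron counts for the elements that occur in protein/nucleic-acid
## heavy-atom models.  Unknown elements are a hard error under the
## electron-count scheme.
.electron_count <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

#' Read coordinates from a PDB file
#'
#' Parses ATOM/HETATM records (via `bio3d::read.pdb`) into a weighted
#' point model.  Only the first MODEL block is used; alternate locations
#' other than blank or 'A' are dropped; water molecules (HOH/WAT/DOD)
#' are excluded by a default solvent filter.
#'
#' @param path path to a PDB-format file.
#' @param heavy_only drop hydrogen atoms (default `TRUE`).
#' @param weight_scheme `"electron-count"` (default) assigns each atom
#'   its element's electron count (C=6, N=7, O=8, P=15, S=16; unknown
#'   elements are an error); `"uniform"` assigns weight 1 to every atom.
#' @return A [coordinate_set()].
#' @export
read_pdb_coords <- function(path, heavy_only = TRUE,
                            weight_scheme = c("electron-count", "uniform")) {
  weight_scheme <- match.arg(weight_scheme)
  if (!file.exists(path)) stop("unreadable file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("no ATOM records in ", path)
  keep <- a$alt %in% c("", "A") | is.na(a$alt)
  keep <- keep & !(toupper(a$resid) %in% c("HOH", "WAT", "DOD"))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no usable ATOM records in ", path)
  elem <- toupper(trimws(a$elesy))
  ## fall back on the first letter of the atom name when the element
  ## column is blank (common in minimal or legacy files)
  blank <- !nzchar(elem) | is.na(elem)
  if (any(blank)) {
    nm <- gsub("[^A-Za-z].*$", "", trimws(a$elety[blank]))
    elem[blank] <- toupper(substr(nm, 1, 1))
  }
  if (heavy_only) {
    hyd <- elem == "H" | grepl("^[0-9]*H", toupper(trimws(a$elety)))
    a <- a[!hyd, , drop = FALSE]
    elem <- elem[!hyd]
  }
  if (nrow(a) == 0) stop("no atoms left after hydrogen filter in ", path)
  if (weight_scheme == "electron-count") {
    w <- .electron_count[elem]
    if (any(is.na(w)))
      stop("unknown element(s) under electron-count scheme: ",
           paste(unique(elem[is.na(w)]), collapse = ", "))
    w <- unname(w)
  } else {
    w <- rep(1, nrow(a))
  }
  coordinate_set(cbind(a$x, a$y, a$z), weights = w, label = basename(path))
}

#' Write a bead model as a dummy-atom PDB file
#'
#' One ATOM record per bead, element C, residue DUM, sequential serials
#' — the conventional exchange format for ab initio bead models.  The
#' output is re-readable by [read_pdb_coords()] (positions preserved to
#' the PDB's 3-decimal precision).
#'
#' @param model a [coordinate_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bead_pdb <- function(model, path) {
  stopifnot(inherits(model, "coord_set"))
  n <- nrow(model$positions)
  if (n < 1) stop("empty bead model")
  if (any(abs(model$positions) >= 10000))
    stop("coordinates exceed PDB fixed-column range")
  i <- seq_len(n)
  rec <- sprintf(
    "ATOM  %5d  CA  DUM A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    i %% 100000, i %% 10000,
    model$positions[, 1], model$positions[, 2], model$positions[, 3])
  writeLines(c(rec, "END"), path)
  invisible(path)
}
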