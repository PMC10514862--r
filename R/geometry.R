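# Grid geometry shared by maps and synthetic volumes: voxel counts, voxel
# spacing in mm, and a 4x4 voxel-to-world affine (RAS convention, 0-based
# voxel indices, as in NIfTI).

#' Construct a voxel grid geometry
#'
#' @param shape Integer 3-vector of voxel counts.
#' @param spacing Numeric 3-vector of voxel spacing in mm (strictly positive).
#' @param affine Optional 4x4 voxel-to-world affine (RAS, 0-based indices).
#'   Defaults to a diagonal affine built from `spacing` with the origin at 0.
#' @return An object of class `ms_grid`.
#' @export
ms_grid <- function(shape, spacing = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 3L, all(is.finite(spacing)), all(spacing > 0))
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- unname(as.matrix(affine))
  stopifnot(is.numeric(affine), all(dim(affine) == c(4L, 4L)), all(is.finite(affine)))
  structure(list(shape = shape, spacing = spacing, affine = affine), class = "ms_grid")
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

#' @export
print.ms_grid <- function(x, ...) {
  cat(sprintf("<grid> %s voxels, spacing %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x")))
  invisible(x)
}

# Axis canonicalization: map voxel axes onto a right/anterior/superior-like
# ordering using the dominant direction of each affine column. Returns the
# permutation (world axis -> voxel axis) and per-axis flips needed so that
# axis 1 increases to the right, 2 to anterior, 3 to superior.
grid_canonical_axes <- function(grid) {
  M <- grid$affine[1:3, 1:3]
  dominant <- apply(abs(M), 2, which.max)   # world axis dominated by each voxel axis
  if (anyDuplicated(dominant)) {
    stop("affine is too oblique to assign anatomical plane labels; use canonical = FALSE",
         call. = FALSE)
  }
  perm <- match(1:3, dominant)              # voxel axis serving each world axis
  flips <- vapply(1:3, function(w) M[w, perm[w]] < 0, logical(1))
  list(perm = perm, flips = flips)
}
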