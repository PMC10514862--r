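# Quantitative maps and co-registered map sets.

#' Construct a quantitative map
#'
#' A named 3D scalar field with grid geometry: a relaxation map (T1, T2, in
#' ms), a proton-density map (arbitrary units), or any user map referenced by
#' a signal equation. Non-finite or non-positive voxels are permitted — they
#' mark background/air and evaluate to 0 in [evaluate_model()].
#'
#' @param name Map symbol, e.g. `"T1"`; must be a valid equation identifier.
#' @param values Numeric 3D array.
#' @param grid An [ms_grid()]; defaults to unit spacing over `dim(values)`.
#' @param units `"ms"` for relaxation maps or `"arbitrary"`.
#' @return An object of class `quant_map`.
#' @export
quantitative_map <- function(name, values, grid = NULL, units = c("ms", "arbitrary")) {
  units <- match.arg(units)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            grepl("^[A-Za-z_][A-Za-z0-9_]*$", name),
            is.numeric(values), length(dim(values)) == 3L)
  if (is.null(grid)) grid <- ms_grid(dim(values))
  stopifnot(inherits(grid, "ms_grid"), identical(as.integer(dim(values)), grid$shape))
  structure(list(name = name, values = values, grid = grid, units = units),
            class = "quant_map")
}

#' Bundle co-registered maps into a set
#'
#' All maps must share one grid (equal shape; spacing and affine equal within
#' `tol`).
#'
#' @param ... `quant_map` objects (or a single list of them).
#' @param tol Geometry comparison tolerance.
#' @return An object of class `map_set` with elements `maps` (named list) and
#'   `grid`.
#' @export
map_set <- function(..., tol = 1e-6) {
  maps <- list(...)
  if (length(maps) == 1L && !inherits(maps[[1L]], "quant_map")) maps <- maps[[1L]]
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, logical(1), "quant_map")))
  nms <- vapply(maps, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate map names: ", paste(nms[duplicated(nms)], collapse = ", "))
  grid <- maps[[1L]]$grid
  for (m in maps) {
    if (!grids_equal(grid, m$grid, tol)) {
      stop(sprintf("map '%s' is not on the shared grid (shape/spacing/affine mismatch)", m$name),
           call. = FALSE)
    }
  }
  names(maps) <- nms
  structure(list(maps = maps, grid = grid), class = "map_set")
}

#' @export
print.map_set <- function(x, ...) {
  cat(sprintf("<map set> %s on %s grid\n", paste(names(x$maps), collapse = ", "),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Simulated scanner parameters
#'
#' Concrete parameter values in milliseconds, e.g.
#' `scanner_parameters(TR = 8000, TE = 80)`. All values must be finite and
#' non-negative. Recognized symbols include at least TR, TE, TI, TI1, TI2 and
#' TSAT, but any symbol a model declares is allowed.
#'
#' @param ... Named numeric scalars (ms).
#' @return Named numeric vector of class `scanner_parameters`.
#' @export
scanner_parameters <- function(...) {
  vals <- c(...)
  if (length(vals) == 0L) vals <- numeric()
  stopifnot(is.numeric(vals))
  if (length(vals) > 0L) {
    if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
      stop("all scanner parameters must be named", call. = FALSE)
    }
    if (any(!is.finite(vals)) || any(vals < 0)) {
      stop("scanner parameter values must be finite and >= 0", call. = FALSE)
    }
  }
  structure(vals, class = "scanner_parameters")
}
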