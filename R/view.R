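# Display computations: orthogonal-plane reslicing and window/level greyscale
# mapping. These are pure functions — the interactive viewer layer is out of
# scope, but its arithmetic lives here so it can be tested.

#' Window/level specification
#'
#' @param center Window center, in signal units.
#' @param width Window width, in signal units; must be > 0.
#' @return An object of class `window_level`.
#' @export
window_level <- function(center, width) {
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(width), length(width) == 1L, is.finite(width), width > 0)
  structure(list(center = center, width = width), class = "window_level")
}

#' Extract an orthogonal slice from a volume
#'
#' Exact plane extraction (no interpolation). With `canonical = TRUE`
#' (default) the volume's axes are first relabeled/flipped into a
#' right-anterior-superior ordering using the grid affine, so `"sagittal"`
#' slices along the left-right axis, `"coronal"` along posterior-anterior and
#' `"axial"` along inferior-superior. With `canonical = FALSE` the anatomical
#' names address raw voxel axes directly (sagittal = axis 1, coronal = axis
#' 2, axial = axis 3).
#'
#' @param volume A `synth_volume` or `quant_map`.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param index 1-based slice index along the chosen axis.
#' @param canonical Reorient axes to a RAS-like layout before slicing.
#' @return A 2D numeric matrix.
#' @export
reslice <- function(volume, plane = c("axial", "coronal", "sagittal"), index,
                    canonical = TRUE) {
  plane <- match.arg(plane)
  stopifnot(inherits(volume, c("synth_volume", "quant_map")))
  values <- volume$values
  if (canonical) {
    ax <- grid_canonical_axes(volume$grid)
    values <- aperm(values, ax$perm)
    for (d in 1:3) {
      if (ax$flips[d]) {
        idx <- rev(seq_len(dim(values)[d]))
        values <- switch(d, values[idx, , , drop = FALSE],
                         values[, idx, , drop = FALSE],
                         values[, , idx, drop = FALSE])
      }
    }
  }
  axis <- switch(plane, sagittal = 1L, coronal = 2L, axial = 3L)
  nmax <- dim(values)[axis]
  if (!is.numeric(index) || length(index) != 1L || index != round(index) ||
      index < 1L || index > nmax) {
    stop(sprintf("%s index must be in [1, %d], got %s", plane, nmax,
                 format(index)), call. = FALSE)
  }
  out <- switch(axis, values[index, , ], values[, index, ], values[, , index])
  out
}

#' Map a slice to 8-bit greyscale with a window/level
#'
#' Linear map of `[center - width/2, center + width/2]` onto `[0, 255]`,
#' clipped outside the window, with deterministic half-up rounding (so a
#' value exactly at the center maps to 128).
#'
#' @param slice2d 2D numeric matrix.
#' @param wl A [window_level()].
#' @return Integer matrix with values in 0..255.
#' @export
apply_window <- function(slice2d, wl) {
  stopifnot(is.numeric(slice2d), inherits(wl, "window_level"))
  lo <- wl$center - wl$width / 2
  g <- (slice2d - lo) / wl$width * 255
  g <- pmin(pmax(g, 0), 255)
  out <- as.integer(floor(g + 0.5))   # round half up
  dim(out) <- dim(slice2d)
  out
}

#' Default window covering a volume's signal range
#'
#' @param volume A `synth_volume` or `quant_map`.
#' @param probs Lower/upper quantiles defining the window (default 1st-99th
#'   percentile, the same default the DICOM exporter writes).
#' @return A [window_level()].
#' @export
default_window <- function(volume, probs = c(0.01, 0.99)) {
  q <- stats::quantile(volume$values, probs, names = FALSE, type = 7)
  width <- max(q[2] - q[1], .Machine$double.eps)
  window_level((q[1] + q[2]) / 2, width)
}

#' Write a windowed slice as an 8-bit greyscale PNG
#'
#' @param slice2d 2D numeric matrix (a [reslice()] output).
#' @param wl A [window_level()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(slice2d, wl, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export", call. = FALSE)
  }
  g <- apply_window(slice2d, wl) / 255
  # image rows run top-to-bottom in PNG; voxel axis 2 runs bottom-to-top
  png::writePNG(t(g)[rev(seq_len(ncol(g))), , drop = FALSE], path)
  invisible(path)
}

#' Plot a slice of a synthetic volume
#'
#' @param object A `synth_volume`.
#' @param plane,index Passed to [reslice()]; `index` defaults to the middle
#'   slice.
#' @param wl Window; defaults to [default_window()] of the volume.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot synth_volume
#' @export
autoplot.synth_volume <- function(object, plane = "axial", index = NULL,
                                  wl = NULL, ...) {
  if (is.null(index)) {
    ax <- switch(plane, sagittal = 1L, coronal = 2L, axial = 3L)
    index <- max(1L, object$grid$shape[ax] %/% 2L)
  }
  if (is.null(wl)) wl <- default_window(object)
  sl <- apply_window(reslice(object, plane, index), wl)
  df <- data.frame(
    x = rep(seq_len(nrow(sl)), times = ncol(sl)),
    y = rep(seq_len(ncol(sl)), each = nrow(sl)),
    grey = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$grey)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (%s slice %d)", object$provenance$model, plane, index),
                  x = NULL, y = NULL, fill = "grey") +
    ggplot2::theme_minimal()
}

#' @export
plot.synth_volume <- function(x, ...) print(autoplot(x, ...))
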