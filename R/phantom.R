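# Digital head phantom: nested axis-aligned ellipsoids of piecewise-constant
# tissue (background / CSF shell / GM shell / WM core) with known ground
# truth, so every pipeline stage is testable without acquired data.

#' Tissue specification
#'
#' @param label Tissue label (e.g. `"WM"`).
#' @param T1,T2 Relaxation times in ms (positive; `T1 >= T2` unless
#'   `allow_implausible`).
#' @param PD Proton density in (0, 1].
#' @param radius_frac Ellipsoid semi-axes as a fraction of the half-extent of
#'   the volume (scalar or 3-vector, in (0, 1]). Tissues are listed outermost
#'   first; each successive ellipsoid overwrites the interior of the previous
#'   one, producing nested shells.
#' @param allow_implausible Permit `T1 < T2` (non-physical, for testing).
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(label, T1, T2, PD, radius_frac, allow_implausible = FALSE) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.numeric(T1), T1 > 0, is.numeric(T2), T2 > 0,
            is.numeric(PD), PD > 0, PD <= 1,
            is.numeric(radius_frac), length(radius_frac) %in% c(1L, 3L),
            all(radius_frac > 0), all(radius_frac <= 1))
  if (!allow_implausible && T1 < T2) {
    stop(sprintf("tissue '%s': T1 (%g) < T2 (%g) is not physically plausible; ",
                 label, T1, T2),
         "set allow_implausible = TRUE to override", call. = FALSE)
  }
  if (length(radius_frac) == 1L) radius_frac <- rep(radius_frac, 3L)
  structure(list(label = label, T1 = T1, T2 = T2, PD = PD,
                 radius_frac = radius_frac),
            class = "tissue_spec")
}

#' Default tissue parameters per field strength
#'
#' Literature-style white matter / grey matter / CSF relaxation values for
#' 1.5T, 3T and 7T scanners. These are synthetic testing defaults
#' (representative of published in vivo ranges), not measured values from any
#' specific dataset; override them freely.
#'
#' @param field `"1.5T"`, `"3T"` or `"7T"`.
#' @return List of [tissue_spec()]s ordered outermost (CSF) to innermost (WM),
#'   satisfying CSF T1 > GM T1 > WM T1.
#' @export
default_tissues <- function(field = c("3T", "1.5T", "7T")) {
  field <- match.arg(field)
  vals <- switch(field,
    "1.5T" = list(CSF = c(4000, 2000), GM = c(1200, 95), WM = c(650, 70)),
    "3T"   = list(CSF = c(4200, 1800), GM = c(1350, 100), WM = c(850, 70)),
    "7T"   = list(CSF = c(4400, 1000), GM = c(2100, 55), WM = c(1220, 47)))
  pd <- c(CSF = 1.0, GM = 0.8, WM = 0.65)
  frac <- list(CSF = 0.9, GM = 0.7, WM = 0.45)
  lapply(names(vals), function(lbl) {
    tissue_spec(lbl, T1 = vals[[lbl]][1], T2 = vals[[lbl]][2],
                PD = pd[[lbl]], radius_frac = frac[[lbl]])
  })
}

#' Phantom specification
#'
#' @param shape Voxel counts (3-vector); default 64 x 64 x 32.
#' @param spacing Voxel spacing in mm.
#' @param tissues Ordered list of [tissue_spec()]s, outermost first.
#' @param noise_sd Per-map additive Gaussian noise sd, named vector over map
#'   symbols (e.g. `c(T1 = 10)`) or a single value applied to all maps;
#'   0 = noiseless. Noise is only added inside tissue, so background stays 0.
#' @param seed Integer seed; the phantom is fully determined by it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 32), spacing = c(1, 1, 1),
                         tissues = default_tissues("3T"),
                         noise_sd = 0, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 2L),
            length(tissues) >= 1L,
            all(vapply(tissues, inherits, logical(1), "tissue_spec")),
            is.numeric(noise_sd), all(noise_sd >= 0), all(is.finite(noise_sd)),
            length(seed) == 1L, is.finite(seed))
  labels <- vapply(tissues, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate tissue labels", call. = FALSE)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 tissues = tissues, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a digital head phantom
#'
#' Builds nested-ellipsoid T1/T2/PD maps with a ground-truth label volume.
#' Each voxel belongs to exactly one tissue (the innermost ellipsoid that
#' contains it) or to background (label 0, all maps 0). Maps are
#' piecewise-constant at the tissue values plus optional Gaussian noise; the
#' result is fully determined by `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `maps` (a [map_set()] of T1, T2, PD), `labels` (integer
#'   array; 0 = background, i = i-th tissue in `spec$tissues`) and `tissues`
#'   (the spec's tissue table, as a tibble).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(16, 16, 8), seed = 42))
#' table(ph$labels)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  centre <- (shape + 1) / 2
  half <- shape / 2

  i <- (seq_len(shape[1]) - centre[1]) / half[1]
  j <- (seq_len(shape[2]) - centre[2]) / half[2]
  k <- (seq_len(shape[3]) - centre[3]) / half[3]

  labels <- array(0L, dim = shape)
  any_fit <- FALSE
  for (t in seq_along(spec$tissues)) {
    rf <- spec$tissues[[t]]$radius_frac
    d2 <- outer(outer((i / rf[1])^2, (j / rf[2])^2, `+`), (k / rf[3])^2, `+`)
    inside <- d2 <= 1
    if (any(inside)) any_fit <- TRUE
    labels[inside] <- t
  }
  if (!any_fit) stop("no tissue ellipsoid fits inside the phantom shape", call. = FALSE)

  noise <- spec$noise_sd
  if (is.null(names(noise)) && length(noise) == 1L) {
    noise <- c(T1 = noise, T2 = noise, PD = noise)
  }
  sd_for <- function(sym) if (sym %in% names(noise)) noise[[sym]] else 0

  grid <- ms_grid(shape, spacing = spec$spacing)
  inside <- labels > 0L
  n_inside <- sum(inside)

  build_map <- function(sym, units) {
    tissue_vals <- vapply(spec$tissues, `[[`, numeric(1), sym)
    values <- array(0, dim = shape)
    values[inside] <- tissue_vals[labels[inside]]
    s <- sd_for(sym)
    if (s > 0 && n_inside > 0) {
      values[inside] <- values[inside] + stats::rnorm(n_inside, sd = s)
    }
    quantitative_map(sym, values, grid, units = units)
  }

  maps <- with_seed(spec$seed, {
    list(build_map("T1", "ms"), build_map("T2", "ms"), build_map("PD", "arbitrary"))
  })

  tissues_tbl <- tibble::tibble(
    label = vapply(spec$tissues, `[[`, character(1), "label"),
    index = seq_along(spec$tissues),
    T1 = vapply(spec$tissues, `[[`, numeric(1), "T1"),
    T2 = vapply(spec$tissues, `[[`, numeric(1), "T2"),
    PD = vapply(spec$tissues, `[[`, numeric(1), "PD"))

  list(maps = map_set(maps), labels = labels, tissues = tissues_tbl)
}

#' Write a phantom's maps to disk
#'
#' Writes one NIfTI file per map (`T1.nii.gz`, `T2.nii.gz`, `PD.nii.gz`) into
#' `dir`, plus a JSON ground-truth sidecar (`phantom_truth.json`) recording
#' the tissue table, seed and noise level.
#'
#' @param phantom Result of [generate_phantom()].
#' @param spec The [phantom_spec()] that produced it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in phantom$maps$maps) {
    write_nifti(m, file.path(dir, paste0(m$name, ".nii.gz")))
  }
  truth <- list(
    seed = spec$seed,
    noise_sd = as.list(if (is.null(names(spec$noise_sd)) && length(spec$noise_sd) == 1L)
      c(T1 = spec$noise_sd, T2 = spec$noise_sd, PD = spec$noise_sd) else spec$noise_sd),
    tissues = lapply(spec$tissues, function(t) {
      list(label = t$label, T1 = t$T1, T2 = t$T2, PD = t$PD,
           radius_frac = as.list(t$radius_frac))
    })
  )
  writeLines(canonical_json(truth), file.path(dir, "phantom_truth.json"))
  invisible(dir)
}
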