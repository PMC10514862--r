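# Batch synthesization: discover per-subject map sets under a directory root,
# evaluate a list of models on each, export every result, and report.

#' Discover subjects under a directory root
#'
#' Each immediate subdirectory of `root` is one subject. Within a subject
#' directory, map files are matched per symbol by a filename pattern
#' (default: the symbol bounded by non-alphanumerics, so `sub01_T1.nii.gz`
#' matches `T1` but not `TI` or `T12`). A subject is `ok` when every required
#' symbol matches exactly one file; otherwise its status records what is
#' missing or ambiguous.
#'
#' @param root Directory containing one subdirectory per subject.
#' @param required_maps Map symbols every subject must provide.
#' @param patterns Optional named character vector of regular expressions,
#'   one per symbol, overriding the default matching rule.
#' @return A tibble with columns `id`, `status` (`"ok"`, `"missing_maps"`,
#'   `"io_error"`), `detail`, and `paths` (named list column symbol -> path),
#'   sorted by `id`.
#' @export
discover_subjects <- function(root, required_maps = c("T1", "T2", "PD"),
                              patterns = NULL) {
  stopifnot(dir.exists(root))
  subject_dirs <- sort(list.dirs(root, recursive = FALSE), method = "radix")
  pattern_for <- function(sym) {
    if (!is.null(patterns) && sym %in% names(patterns)) return(patterns[[sym]])
    paste0("(^|[^A-Za-z0-9])", sym, "([^A-Za-z0-9]|$)")
  }
  rows <- lapply(subject_dirs, function(d) {
    id <- basename(d)
    entries <- list.files(d, full.names = TRUE)
    paths <- list()
    missing <- character()
    ambiguous <- character()
    for (sym in required_maps) {
      hits <- entries[grepl(pattern_for(sym), basename(entries))]
      if (length(hits) == 1L) {
        paths[[sym]] <- hits
      } else if (length(hits) == 0L) {
        missing <- c(missing, sym)
      } else {
        ambiguous <- c(ambiguous, sym)
      }
    }
    if (length(missing) == 0L && length(ambiguous) == 0L) {
      status <- "ok"; detail <- ""
    } else if (length(ambiguous)) {
      status <- "io_error"
      detail <- paste0("ambiguous match for: ", paste(ambiguous, collapse = ", "))
      if (length(missing)) detail <- paste0(detail, "; missing: ", paste(missing, collapse = ", "))
    } else {
      status <- "missing_maps"
      detail <- paste0("missing: ", paste(missing, collapse = ", "))
    }
    tibble::tibble(id = id, status = status, detail = detail, paths = list(paths))
  })
  if (length(rows) == 0L) {
    return(tibble::tibble(id = character(), status = character(),
                          detail = character(), paths = list()))
  }
  dplyr::bind_rows(rows)
}

#' Batch-synthesize contrasts for many subjects
#'
#' For every `ok` subject and every model, evaluates the model at fixed
#' scanner parameters and exports one volume. Failures are isolated per
#' subject x model item: one bad subject cannot abort the run. A
#' machine-readable JSON report is always written to
#' `file.path(out_dir, "batch_report.json")`.
#'
#' Output layout: `out_dir/<subject>/<model>/` containing
#' `<subject>_<model>.nii.gz` (NIfTI) or `<subject>_<model>_<NNN>.dcm` slices
#' (DICOM).
#'
#' @param subjects Tibble from [discover_subjects()].
#' @param models List of [signal_model()]s (or a single model).
#' @param params Optional named list (by model name) of [scanner_parameters()]
#'   overriding each model's defaults.
#' @param settings An [export_settings()].
#' @param out_dir Output directory root.
#' @param quiet Suppress per-item log lines.
#' @return A `batch_report`: list with `items` (tibble: subject, model,
#'   outcome, path, message) and `totals` (subjects, volumes_written, skips,
#'   failures).
#' @export
batch_synthesize <- function(subjects, models, params = NULL,
                             settings = export_settings("nifti"),
                             out_dir, quiet = FALSE) {
  if (inherits(models, "signal_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, logical(1), "signal_model")),
            inherits(settings, "export_settings"))
  model_names <- vapply(models, `[[`, character(1), "name")
  names(models) <- model_names
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_line <- function(...) if (!quiet) message(sprintf(...))
  items <- list()
  add_item <- function(subject, model, outcome, path = "", msg = "") {
    items[[length(items) + 1L]] <<- tibble::tibble(
      subject = subject, model = model, outcome = outcome, path = path, message = msg)
    log_line("[%s] subject=%s model=%s%s", outcome, subject, model,
             if (nzchar(msg)) paste0(" (", msg, ")") else "")
  }

  all_syms <- unique(unlist(lapply(models, `[[`, "maps")))
  for (si in seq_len(nrow(subjects))) {
    sub <- subjects$id[si]
    if (subjects$status[si] != "ok") {
      for (mn in model_names) add_item(sub, mn, "skipped", msg = subjects$detail[si])
      next
    }
    paths <- subjects$paths[[si]]
    maps <- tryCatch({
      loaded <- lapply(intersect(all_syms, names(paths)), function(sym) {
        read_map(paths[[sym]], sym, units = if (sym %in% c("T1", "T2")) "ms" else "arbitrary")
      })
      map_set(loaded)
    }, error = function(e) e)
    if (inherits(maps, "error")) {
      for (mn in model_names) add_item(sub, mn, "failed", msg = conditionMessage(maps))
      next
    }
    for (mn in model_names) {
      res <- tryCatch({
        p <- if (!is.null(params) && mn %in% names(params)) params[[mn]] else NULL
        vol <- evaluate_model(models[[mn]], maps, p)
        dest <- file.path(out_dir, sub, mn)
        dir.create(dest, recursive = TRUE, showWarnings = FALSE)
        if (settings$format == "nifti") {
          fname <- gsub("{model}", mn, gsub("{subject}", sub, settings$pattern, fixed = TRUE),
                        fixed = TRUE)
          out_path <- file.path(dest, fname)
          write_nifti(vol, out_path)
        } else {
          write_dicom(vol, dicom_template(), settings, dest, subject = sub)
          out_path <- dest
        }
        out_path
      }, error = function(e) e)
      if (inherits(res, "error")) {
        add_item(sub, mn, "failed", msg = conditionMessage(res))
      } else {
        add_item(sub, mn, "written", path = res)
      }
    }
  }

  items_tbl <- if (length(items)) dplyr::bind_rows(items) else {
    tibble::tibble(subject = character(), model = character(), outcome = character(),
                   path = character(), message = character())
  }
  totals <- list(
    subjects = nrow(subjects),
    models = length(models),
    volumes_written = sum(items_tbl$outcome == "written"),
    skips = sum(items_tbl$outcome == "skipped"),
    failures = sum(items_tbl$outcome == "failed"))
  report <- structure(list(items = items_tbl, totals = totals), class = "batch_report")
  write_batch_report(report, file.path(out_dir, "batch_report.json"))
  report
}

write_batch_report <- function(report, path) {
  raw <- list(
    totals = report$totals,
    items = lapply(seq_len(nrow(report$items)), function(i) {
      as.list(report$items[i, c("subject", "model", "outcome", "path", "message")])
    })
  )
  writeLines(canonical_json(raw), path)
  invisible(path)
}

#' @export
print.batch_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<batch report> %d subject(s) x %d model(s): %d written, %d skipped, %d failed\n",
              t$subjects, t$models, t$volumes_written, t$skips, t$failures))
  invisible(x)
}

#' Tidy a batch report into per-item rows
#'
#' @param x A `batch_report`.
#' @param ... Unused.
#' @return Tibble with one row per subject x model item.
#' @importFrom generics tidy
#' @method tidy batch_report
#' @export
tidy.batch_report <- function(x, ...) x$items

#' One-row summary of a batch report
#'
#' @param x A `batch_report`.
#' @param ... Unused.
#' @return One-row tibble of the run totals.
#' @importFrom generics glance
#' @method glance batch_report
#' @export
glance.batch_report <- function(x, ...) tibble::as_tibble(x$totals)
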