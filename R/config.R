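# JSON configuration: presets -> models -> {title, equation, maps,
# parameters:{symbol:{default,min,max}}}, plus the accepted-map vocabulary.
#
# Schema (normative for this package):
# {
#   "accepted_maps": { "<symbol>": { "units": "ms" | "arbitrary" }, ... },
#   "presets": {
#     "<preset name>": {
#       "models": {
#         "<model name>": {
#           "title":      "<display string>",
#           "equation":   "<infix equation>",
#           "maps":       ["T1", ...],
#           "parameters": { "<symbol>": { "default": n, "min": n, "max": n }, ... }
#         }, ...
#       }
#     }, ...
#   }
# }
#
# Canonical serialization: UTF-8, 2-space indent, object keys sorted (C
# locale), numbers printed without trailing zeros. save -> load -> save is
# byte-identical.

#' Path of the shipped default configuration
#'
#' The default configuration contains one preset (`"3T"`) holding the seven
#' built-in models of [builtin_presets()].
#'
#' @return File path of the installed `config.json`.
#' @export
default_config_path <- function() {
  system.file("extdata", "config.json", package = "mrisynth", mustWork = TRUE)
}

#' Validate a raw configuration document
#'
#' Checks a parsed JSON document (as returned by
#' `jsonlite::fromJSON(..., simplifyVector = FALSE)`) against the
#' configuration schema and the signal-model invariants. Content problems are
#' returned as data, never raised.
#'
#' @param raw A nested list representing the JSON document.
#' @return A validation report: tibble with columns `severity`
#'   (`"error"`/`"warning"`), `path` (JSON pointer) and `message`, of class
#'   `ms_validation`. An empty report (no error rows) means the document is
#'   loadable.
#' @export
validate_config <- function(raw) {
  issues <- list()
  add <- function(severity, path, message) {
    issues[[length(issues) + 1L]] <<- list(severity = severity, path = path, message = message)
  }
  known_top <- c("accepted_maps", "presets")

  if (!is.list(raw)) {
    add("error", "/", "configuration root must be a JSON object")
    return(validation_report(issues))
  }
  for (k in setdiff(names(raw), known_top)) {
    add("warning", paste0("/", k), "unknown key (ignored)")
  }

  am <- raw[["accepted_maps"]]
  accepted <- character()
  if (is.null(am) || !is.list(am) || length(am) == 0L || is.null(names(am))) {
    add("error", "/accepted_maps", "must be a non-empty object of map symbols")
  } else {
    if (anyDuplicated(names(am))) {
      add("error", "/accepted_maps", "duplicate map symbols")
    }
    for (nm in names(am)) {
      entry <- am[[nm]]
      if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", nm)) {
        add("error", paste0("/accepted_maps/", nm), "invalid map symbol")
        next
      }
      units <- if (is.list(entry)) entry[["units"]] else NULL
      if (is.null(units) || !is.character(units) || !units %in% c("ms", "arbitrary")) {
        add("error", paste0("/accepted_maps/", nm, "/units"),
            "units must be \"ms\" or \"arbitrary\"")
      }
      if (is.list(entry)) {
        for (k in setdiff(names(entry), "units")) {
          add("warning", paste0("/accepted_maps/", nm, "/", k), "unknown key (ignored)")
        }
      }
      accepted <- c(accepted, nm)
    }
  }

  presets <- raw[["presets"]]
  used_maps <- character()
  if (is.null(presets) || !is.list(presets) || length(presets) == 0L || is.null(names(presets))) {
    add("error", "/presets", "must be a non-empty object of presets")
  } else {
    if (anyDuplicated(names(presets))) {
      add("error", "/presets", sprintf("duplicate preset names: %s",
          paste(unique(names(presets)[duplicated(names(presets))]), collapse = ", ")))
    }
    for (pn in names(presets)) {
      ppath <- paste0("/presets/", pn)
      preset <- presets[[pn]]
      if (!is.list(preset) || is.null(preset[["models"]]) || !is.list(preset[["models"]]) ||
          length(preset[["models"]]) == 0L || is.null(names(preset[["models"]]))) {
        add("error", paste0(ppath, "/models"), "preset must contain a non-empty models object")
        next
      }
      for (k in setdiff(names(preset), "models")) {
        add("warning", paste0(ppath, "/", k), "unknown key (ignored)")
      }
      models <- preset[["models"]]
      if (anyDuplicated(names(models))) {
        add("error", paste0(ppath, "/models"), sprintf("duplicate model names: %s",
            paste(unique(names(models)[duplicated(names(models))]), collapse = ", ")))
      }
      for (mn in names(models)) {
        mpath <- paste0(ppath, "/models/", mn)
        mres <- validate_model_entry(models[[mn]], mpath, accepted, add)
        used_maps <- c(used_maps, mres)
      }
    }
  }

  for (nm in setdiff(accepted, unique(used_maps))) {
    add("warning", paste0("/accepted_maps/", nm), "accepted map is not used by any model")
  }
  validation_report(issues)
}

validate_model_entry <- function(model, mpath, accepted, add) {
  used <- character()
  if (!is.list(model)) {
    add("error", mpath, "model must be a JSON object")
    return(used)
  }
  known <- c("title", "equation", "maps", "parameters")
  for (k in setdiff(names(model), known)) {
    add("warning", paste0(mpath, "/", k), "unknown key (ignored)")
  }
  eq_text <- model[["equation"]]
  ast <- NULL
  if (is.null(eq_text) || !is.character(eq_text) || length(eq_text) != 1L) {
    add("error", paste0(mpath, "/equation"), "equation must be a string")
  } else {
    ast <- tryCatch(parse_equation(eq_text), error = function(e) {
      add("error", paste0(mpath, "/equation"), conditionMessage(e))
      NULL
    })
  }
  maps <- model[["maps"]]
  maps <- if (is.null(maps)) character() else unlist(maps, use.names = FALSE)
  if (!is.character(maps) && length(maps) > 0L) {
    add("error", paste0(mpath, "/maps"), "maps must be an array of symbols")
    maps <- character()
  }
  for (nm in maps) {
    if (length(accepted) && !nm %in% accepted) {
      add("error", paste0(mpath, "/maps"),
          sprintf("map '%s' is not in accepted_maps", nm))
    }
  }
  used <- c(used, maps)

  params <- model[["parameters"]]
  pnames <- character()
  if (!is.null(params)) {
    if (!is.list(params) || (length(params) > 0L && is.null(names(params)))) {
      add("error", paste0(mpath, "/parameters"), "parameters must be an object")
      params <- NULL
    }
  }
  if (!is.null(params)) {
    pnames <- names(params)
    for (pn in pnames) {
      p <- params[[pn]]
      ppath2 <- paste0(mpath, "/parameters/", pn)
      if (!is.list(p) || is.null(p[["default"]]) || !is.numeric(p[["default"]])) {
        add("error", ppath2, "parameter must be an object with a numeric default")
        next
      }
      d <- p[["default"]]
      mn <- if (is.null(p[["min"]])) 0 else p[["min"]]
      mx <- if (is.null(p[["max"]])) (if (d > 0) 10 * d else 1) else p[["max"]]
      if (!is.numeric(mn) || !is.numeric(mx)) {
        add("error", ppath2, "min/max must be numeric")
        next
      }
      if (mn < 0) add("error", paste0(ppath2, "/min"), "min must be >= 0 (times in ms)")
      if (mn > mx) add("error", ppath2, "min > max")
      if (d < mn || d > mx) {
        add("error", paste0(ppath2, "/default"),
            sprintf("default %g outside [min,max] = [%g, %g]", d, mn, mx))
      }
      for (k in setdiff(names(p), c("default", "min", "max"))) {
        add("warning", paste0(ppath2, "/", k), "unknown key (ignored)")
      }
    }
  }

  dup <- intersect(maps, pnames)
  if (length(dup)) {
    add("error", mpath, sprintf("symbols declared as both map and parameter: %s",
                                paste(dup, collapse = ", ")))
  }
  if (!is.null(ast)) {
    undeclared <- setdiff(free_symbols(ast), c(maps, pnames))
    if (length(undeclared)) {
      add("error", paste0(mpath, "/equation"),
          sprintf("equation symbols not declared as map or parameter: %s",
                  paste(undeclared, collapse = ", ")))
    }
  }
  used
}

validation_report <- function(issues) {
  if (length(issues) == 0L) {
    rep <- tibble::tibble(severity = character(), path = character(), message = character())
  } else {
    rep <- tibble::tibble(
      severity = vapply(issues, `[[`, character(1), "severity"),
      path = vapply(issues, `[[`, character(1), "path"),
      message = vapply(issues, `[[`, character(1), "message"))
  }
  class(rep) <- c("ms_validation", class(rep))
  rep
}

#' @export
print.ms_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("configuration OK: no issues\n")
  } else {
    cat(sprintf("%d issue(s): %d error(s), %d warning(s)\n", nrow(x),
                sum(x$severity == "error"), sum(x$severity == "warning")))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$path[i], x$message[i]))
    }
  }
  invisible(x)
}

config_has_errors <- function(report) any(report$severity == "error")

#' Load and validate a JSON configuration
#'
#' Parses the file, runs [validate_config()], and on success returns a
#' `ms_config` object whose model equations are pre-parsed to ASTs.
#'
#' @param path Path to a JSON configuration file.
#' @return An object of class `ms_config` with elements `presets` (named list
#'   of presets, each holding named [signal_model()]s) and `accepted_maps`
#'   (named list of `list(units = ...)`). The validation report is attached as
#'   attribute `"report"`.
#' @examples
#' cfg <- load_config(default_config_path())
#' names(cfg$presets)
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  report <- validate_config(raw)
  if (config_has_errors(report)) {
    msg <- paste0("invalid configuration '", path, "':\n",
                  paste(sprintf("  [%s] %s: %s", report$severity, report$path, report$message),
                        collapse = "\n"))
    cond <- structure(class = c("mrisynth_config_error", "error", "condition"),
                      list(message = msg, call = NULL, report = report))
    stop(cond)
  }
  cfg <- config_from_raw(raw)
  attr(cfg, "report") <- report
  cfg
}

config_from_raw <- function(raw) {
  accepted <- lapply(raw$accepted_maps, function(e) list(units = e$units))
  presets <- lapply(names(raw$presets), function(pn) {
    models_raw <- raw$presets[[pn]]$models
    models <- lapply(names(models_raw), function(mn) {
      m <- models_raw[[mn]]
      params <- lapply(m$parameters, function(p) {
        d <- p$default
        list(default = d,
             min = if (is.null(p$min)) 0 else p$min,
             max = if (is.null(p$max)) (if (d > 0) 10 * d else 1) else p$max)
      })
      signal_model(mn, m$equation, parameters = params,
                   maps = as.character(unlist(m$maps, use.names = FALSE)),
                   title = if (is.null(m$title)) mn else m$title)
    })
    names(models) <- names(models_raw)
    list(name = pn, models = models)
  })
  names(presets) <- names(raw$presets)
  structure(list(presets = presets, accepted_maps = accepted), class = "ms_config")
}

#' @export
print.ms_config <- function(x, ...) {
  cat(sprintf("<config> %d preset(s); accepted maps: %s\n", length(x$presets),
              paste(names(x$accepted_maps), collapse = ", ")))
  for (p in x$presets) {
    cat(sprintf("  %s: %s\n", p$name, paste(names(p$models), collapse = ", ")))
  }
  invisible(x)
}

#' Save a configuration in canonical JSON
#'
#' Serialization is canonical — UTF-8, 2-space indent, keys sorted in the C
#' locale — so `save_config(load_config(p))` reproduces the file byte for
#' byte when `p` itself is canonical.
#'
#' @param config A `ms_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "ms_config"))
  raw <- config_to_raw(config)
  txt <- paste0(canonical_json(raw), "\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}

config_to_raw <- function(config) {
  list(
    accepted_maps = lapply(config$accepted_maps, function(e) list(units = e$units)),
    presets = lapply(config$presets, function(p) {
      list(models = lapply(p$models, function(m) {
        list(title = m$title,
             equation = deparse_equation(m$equation),
             maps = as.list(m$maps),
             parameters = lapply(m$parameters, function(b) {
               list(default = b$default, min = b$min, max = b$max)
             }))
      }))
    })
  )
}

#' Reload a configuration with fallback
#'
#' Re-reads `path`; if the new content fails validation the previous
#' configuration is returned unchanged, with the failure report attached, so
#' a live editing session never loses a working configuration.
#'
#' @param config The currently active `ms_config`.
#' @param path File to reload from.
#' @return A `ms_config` (new on success, `config` on failure) with the
#'   validation report in attribute `"report"`.
#' @export
reload_config <- function(config, path) {
  stopifnot(inherits(config, "ms_config"))
  res <- tryCatch(load_config(path), error = function(e) e)
  if (inherits(res, "ms_config")) return(res)
  report <- if (!is.null(res$report)) res$report else {
    validation_report(list(list(severity = "error", path = "/",
                                message = conditionMessage(res))))
  }
  attr(config, "report") <- report
  config
}

# --- canonical JSON writer -------------------------------------------------

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  paste0("\"", s, "\"")
}

json_number <- function(x) {
  if (!is.finite(x)) stop("cannot serialize non-finite number to JSON", call. = FALSE)
  if (x == round(x) && abs(x) < 1e15) {
    format(x, scientific = FALSE, trim = TRUE)
  } else {
    format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
}

canonical_json <- function(x, indent = 0L) {
  pad <- strrep(" ", indent)
  pad2 <- strrep(" ", indent + 2L)
  if (is.list(x)) {
    if (!is.null(names(x)) && length(x) > 0L) {
      keys <- sort(names(x), method = "radix")
      body <- vapply(keys, function(k) {
        paste0(pad2, json_escape(k), ": ", canonical_json(x[[k]], indent + 2L))
      }, character(1))
      paste0("{\n", paste(body, collapse = ",\n"), "\n", pad, "}")
    } else if (length(x) == 0L) {
      if (is.null(names(x))) "[]" else "{}"
    } else {
      body <- vapply(x, function(el) paste0(pad2, canonical_json(el, indent + 2L)), character(1))
      paste0("[\n", paste(body, collapse = ",\n"), "\n", pad, "]")
    }
  } else if (is.character(x)) {
    stopifnot(length(x) == 1L)
    json_escape(x)
  } else if (is.numeric(x)) {
    stopifnot(length(x) == 1L)
    json_number(x)
  } else if (is.logical(x)) {
    stopifnot(length(x) == 1L)
    if (x) "true" else "false"
  } else if (is.null(x)) {
    "null"
  } else {
    stop("cannot serialize object of class ", paste(class(x), collapse = "/"), call. = FALSE)
  }
}
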