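#' @title Route files
#'
#' @description
#' Routes are stored in a small versioned YAML schema chosen because a
#' convergent synthesis is inherently tree-shaped: a document carries
#' `format_version`, free-form `metadata`, and a recursive `route` whose
#' elements are either `{type: step, id, yield}` or
#' `{type: convergence, branches: [{weight?, elements: [...]}]}`. Yields
#' are stored as fractions; percent strings such as `"82%"` are accepted on
#' input and normalized. Unknown keys are preserved in `metadata` but
#' rejected inside elements to catch typos.
#'
#' @name route-io
NULL

FORMAT_VERSION <- "1"

io_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "syntheff_io_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)))
}

#' Create a route document
#'
#' @param route A valid `synth_route`.
#' @param metadata Named list of free-form metadata (source, literature
#'   reference, notes). Preserved verbatim on round trips.
#' @param format_version Schema version string.
#' @return An object of class `"route_document"`.
#' @export
route_document <- function(route, metadata = list(),
                           format_version = FORMAT_VERSION) {
  assert_valid_route(route)
  structure(list(format_version = format_version, metadata = metadata,
                 route = route),
            class = "route_document")
}

# ---- parsing -----------------------------------------------------------

parse_yield <- function(y, path) {
  if (is.numeric(y) && length(y) == 1L) return(as.numeric(y))
  if (is.character(y) && length(y) == 1L && grepl("%\\s*$", y)) {
    v <- suppressWarnings(as.numeric(sub("%\\s*$", "", y)))
    if (!is.na(v)) return(v / 100)
  }
  io_error("syntheff_schema_error",
           sprintf("%s: yield must be a number or a percent string, got %s",
                   path, deparse(y)))
}

check_keys <- function(x, allowed, required, path) {
  if (!is.list(x) || (length(x) && is.null(names(x)))) {
    io_error("syntheff_schema_error", sprintf("%s: expected a mapping", path))
  }
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    io_error("syntheff_schema_error",
             sprintf("%s: unknown key(s): %s", path,
                     paste(extra, collapse = ", ")))
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    io_error("syntheff_schema_error",
             sprintf("%s: missing key(s): %s", path,
                     paste(missing, collapse = ", ")))
  }
}

parse_elements <- function(els, path) {
  if (!is.list(els) || length(els) == 0L) {
    io_error("syntheff_schema_error",
             sprintf("%s: `elements` must be a non-empty list", path))
  }
  lapply(seq_along(els), function(i) {
    el <- els[[i]]
    p <- sprintf("%s.elements[%d]", path, i)
    if (!is.list(el) || is.null(el$type)) {
      io_error("syntheff_schema_error",
               sprintf("%s: element needs a `type`", p))
    }
    if (identical(el$type, "step")) {
      check_keys(el, c("type", "id", "yield", "description"),
                 c("type", "id", "yield"), p)
      synth_step(el$id, parse_yield(el$yield, p),
                 description = el$description)
    } else if (identical(el$type, "convergence")) {
      check_keys(el, c("type", "branches"), c("type", "branches"), p)
      if (!is.list(el$branches) || length(el$branches) == 0L) {
        io_error("syntheff_schema_error",
                 sprintf("%s: `branches` must be a non-empty list", p))
      }
      branches <- lapply(seq_along(el$branches), function(j) {
        b <- el$branches[[j]]
        bp <- sprintf("%s.branches[%d]", p, j)
        check_keys(b, c("weight", "elements"), "elements", bp)
        w <- if (is.null(b$weight)) NULL else as.numeric(b$weight)
        structure(list(route = synth_route(
          elements = parse_elements(b$elements, bp)), weight = w),
          class = "synth_branch")
      })
      structure(list(branches = branches), class = "convergence_point")
    } else {
      io_error("syntheff_schema_error",
               sprintf("%s: unknown element type %s", p, deparse(el$type)))
    }
  })
}

#' Parse a route document from text
#'
#' Distinguishes three failure modes, each with its own condition class:
#' `syntheff_syntax_error` (malformed YAML, with the parser's position
#' information), `syntheff_schema_error` (well-formed YAML that does not
#' match the route schema, e.g. a misspelled key), and
#' `syntheff_validation_error` (schema-conforming route violating a domain
#' invariant such as a yield above 1).
#'
#' @param text Character scalar (or vector of lines) with the document.
#' @return A `route_document`.
#' @examples
#' doc <- parse_route("
#' format_version: '1'
#' route:
#'   name: demo
#'   elements:
#'   - {type: step, id: s1, yield: 82%}
#' ")
#' doc$route$elements[[1]]$yield # 0.82
#' @export
parse_route <- function(text) {
  text <- paste(text, collapse = "\n")
  raw <- tryCatch(
    yaml::yaml.load(text),
    error = function(e) {
      io_error("syntheff_syntax_error",
               paste0("route file syntax error: ", conditionMessage(e)))
    })
  if (!is.list(raw)) {
    io_error("syntheff_syntax_error",
             "route file syntax error: document is not a mapping")
  }
  check_keys(raw, c("format_version", "metadata", "route"), "route",
             "document")
  fv <- raw$format_version
  if (!is.null(fv) && !identical(as.character(fv), FORMAT_VERSION)) {
    io_error("syntheff_schema_error",
             sprintf("unsupported format_version %s", deparse(fv)))
  }
  check_keys(raw$route, c("name", "elements"), "elements", "route")
  route <- synth_route(
    elements = parse_elements(raw$route$elements, "route"),
    name = if (is.null(raw$route$name)) "" else as.character(raw$route$name))
  v <- validate_route(route)
  if (nrow(v)) {
    stop(structure(
      class = c("syntheff_validation_error", "error", "condition"),
      list(message = paste0(
        "route file fails validation:\n",
        paste0("  ", v$path, ": ", v$problem, collapse = "\n")),
        call = sys.call(-1), violations = v)))
  }
  md <- raw$metadata
  route_document(route, metadata = if (is.null(md)) list() else md)
}

#' Read a route document from a file
#'
#' @param path Path to a route file (UTF-8).
#' @return A `route_document`.
#' @export
read_route <- function(path) {
  if (!file.exists(path)) {
    io_error("syntheff_file_error", sprintf("no such route file: %s", path))
  }
  parse_route(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

# ---- writing -----------------------------------------------------------

serialize_elements <- function(els) {
  lapply(els, function(el) {
    if (inherits(el, "synth_step")) {
      out <- list(type = "step", id = el$id, yield = el$yield)
      if (!is.null(el$description)) out$description <- el$description
      out
    } else {
      list(type = "convergence",
           branches = lapply(el$branches, function(b) {
             out <- list()
             if (!is.null(b$weight)) out$weight <- b$weight
             out$elements <- serialize_elements(b$route$elements)
             out
           }))
    }
  })
}

#' Write a route document to text (and optionally a file)
#'
#' Canonical serialization: stable key order (`format_version`, `metadata`,
#' `route`), fractions written with enough digits to round-trip, so that
#' `parse_route(write_route(doc))` reproduces the document.
#'
#' @param doc A `route_document` (a bare `synth_route` is wrapped).
#' @param path Optional file path to write to.
#' @return The serialized text, invisibly when `path` is given.
#' @export
write_route <- function(doc, path = NULL) {
  if (inherits(doc, "synth_route")) doc <- route_document(doc)
  stopifnot(inherits(doc, "route_document"))
  payload <- list(format_version = doc$format_version)
  if (length(doc$metadata)) payload$metadata <- doc$metadata
  payload$route <- list(name = doc$route$name,
                        elements = serialize_elements(doc$route$elements))
  text <- yaml::as.yaml(payload, precision = 15L)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(text, con, sep = "", useBytes = TRUE)
    return(invisible(text))
  }
  text
}

# ---- result export -----------------------------------------------------

#' Export an efficiency result as machine-readable text
#'
#' @param result An `"efficiency_result"` from [overall_yield()].
#' @param format `"json"` for a JSON record or `"tabular"` for a flat
#'   tab-separated key/value listing.
#' @return Character scalar with the serialized record.
#' @examples
#' res <- overall_yield(linear_route(c(0.9, 0.8)))
#' cat(export_result(res, "tabular"))
#' @export
export_result <- function(result, format = c("json", "tabular")) {
  stopifnot(inherits(result, "efficiency_result"))
  format <- match.arg(format)
  rec <- list(
    route_name = result$route_name,
    overall_yield = result$overall_yield,
    step_count = result$step_count,
    efficiency_pct = result$efficiency,
    convergence_means = result$convergence_means,
    modification_factors = result$modification_factors,
    rounding = result$policy
  )
  if (format == "json") {
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  dataframe = "columns"))
  } else {
    lines <- c(
      sprintf("route_name\t%s", rec$route_name),
      sprintf("overall_yield\t%.15g", rec$overall_yield),
      sprintf("step_count\t%d", rec$step_count),
      sprintf("efficiency_pct\t%.15g", rec$efficiency_pct),
      sprintf("rounding\t%s", rec$rounding),
      sprintf("convergence_mean\t%d\t%.15g",
              rec$convergence_means$index, rec$convergence_means$mean),
      sprintf("modification_factor\t%d\t%.15g",
              rec$modification_factors$index,
              rec$modification_factors$factor)
    )
    paste0(paste(lines, collapse = "\n"), "\n")
  }
}

# ---- packaged fixtures -------------------------------------------------

#' Packaged example routes
#'
#' Worked examples shipped with the package as route files: a convergent
#' case study with two convergence points and eight steps, three decapeptide
#' assembly strategies at a uniform 80% coupling yield, the Ugi
#' four-component construct toward ecteinascidin-743 with its three
#' precursor chains (plus a fully sequential variant of the same data), and
#' the two tropinone syntheses (a one-step multicomponent route and a long
#' linear route, each stored as a single aggregate-yield step with the real
#' step count in metadata).
#'
#' @param name Fixture name; see `route_fixtures()` for the available names.
#' @return `route_fixtures()` returns a character vector of names;
#'   `route_fixture_path()` the file path; `route_fixture()` the parsed
#'   `route_document`.
#' @examples
#' route_fixtures()
#' doc <- route_fixture("case_study")
#' step_count(doc$route) # 8
#' @export
route_fixtures <- function() {
  sort(sub("\\.yaml$", "",
           dir(system.file("extdata", package = "syntheff"),
               pattern = "\\.yaml$")))
}

#' @rdname route_fixtures
#' @export
route_fixture_path <- function(name) {
  p <- system.file("extdata", paste0(name, ".yaml"), package = "syntheff")
  if (!nzchar(p)) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(route_fixtures(), collapse = ", ")))
  }
  p
}

#' @rdname route_fixtures
#' @export
route_fixture <- function(name) {
  read_route(route_fixture_path(name))
}
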