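#' @title Synthesis route trees
#'
#' @description
#' A synthesis route is modelled as an ordered sequence of elements, each of
#' which is either a *step* (one one-pot working process with a fractional
#' yield) or a *convergence point* where two or more independently prepared
#' precursor chains (branches) meet. Branches are themselves routes, so
#' arbitrarily nested convergent syntheses can be expressed. Routes built
#' with these constructors are trees by construction and therefore acyclic.
#'
#' @details
#' Each branch carries a weight used in the weighted arithmetic mean at its
#' convergence point. When no weight is given it defaults to the branch's
#' total (recursive) step count, reflecting that longer precursor chains
#' contribute more synthetic work to the convergence. An explicit numeric
#' weight overrides the default.
#'
#' @name route-model
NULL

#' Create a synthesis step
#'
#' A step is a practical unit of reactions run in one pot in one working
#' process, without intermediate isolation or purification. Its yield is a
#' fraction in `(0, 1]`; a yield of exactly 1 denotes a quantitative step.
#'
#' @param id Short unique label for the step (e.g. `"A-C"`).
#' @param yield Fractional yield in `(0, 1]`.
#' @param description Optional free-text description.
#' @return An object of class `"synth_step"`.
#' @examples
#' synth_step("A-C", 0.82)
#' @export
synth_step <- function(id, yield, description = NULL) {
  structure(
    list(id = as.character(id), yield = as.numeric(yield),
         description = description),
    class = "synth_step"
  )
}

#' Create a branch feeding a convergence point
#'
#' @param ... Route elements (steps and/or convergence points) making up the
#'   branch, or a single `synth_route`.
#' @param weight Optional positive weight for the branch mean. When `NULL`
#'   (the default) the branch is weighted by its recursive step count.
#' @return An object of class `"synth_branch"`.
#' @examples
#' synth_branch(synth_step("V-D", 0.65))
#' @export
synth_branch <- function(..., weight = NULL) {
  els <- list(...)
  if (length(els) == 1L && inherits(els[[1L]], "synth_route")) {
    route <- els[[1L]]
  } else {
    route <- synth_route(elements = els)
  }
  structure(list(route = route, weight = weight), class = "synth_branch")
}

#' Create a convergence point
#'
#' A convergence point joins one or more parallel branches. Branch yields are
#' combined by a weighted arithmetic mean, not by multiplication: parallel
#' precursor chains are cumulative with respect to each other, not
#' sequential. The first-listed branch is conventionally the backbone (main
#' reaction set) branch.
#'
#' @param ... Branches (`synth_branch` objects). Bare steps or routes are
#'   promoted to single-element branches for convenience.
#' @return An object of class `"convergence_point"`.
#' @examples
#' convergence(
#'   synth_branch(synth_step("A-C", 0.82)),
#'   synth_branch(synth_step("V-D", 0.65))
#' )
#' @export
convergence <- function(...) {
  branches <- lapply(list(...), function(b) {
    if (inherits(b, "synth_branch")) b
    else if (inherits(b, c("synth_step", "synth_route"))) synth_branch(b)
    else b # left as-is; validate_route() will flag it
  })
  structure(list(branches = branches), class = "convergence_point")
}

#' Create a synthesis route
#'
#' @param ... Route elements in order: `synth_step` and/or
#'   `convergence_point` objects.
#' @param name Route name (free text).
#' @param elements Alternatively, a list of elements (overrides `...`).
#' @return An object of class `"synth_route"`.
#' @examples
#' synth_route(synth_step("S1", 0.9), synth_step("S2", 0.8), name = "demo")
#' @export
synth_route <- function(..., name = "", elements = NULL) {
  if (is.null(elements)) elements <- list(...)
  structure(list(name = as.character(name), elements = elements),
            class = "synth_route")
}

#' Build a purely sequential route from a vector of yields
#'
#' @param yields Numeric vector of step yields in `(0, 1]`.
#' @param name Route name.
#' @param ids Optional step ids; defaults to `"s1"`, `"s2"`, ...
#' @return A `synth_route` with one step per yield.
#' @examples
#' linear_route(rep(0.8, 9), name = "decapeptide (sequential)")
#' @export
linear_route <- function(yields, name = "", ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(yields))
  stopifnot(length(ids) == length(yields))
  synth_route(elements = Map(synth_step, ids, yields), name = name)
}

# ---- validation --------------------------------------------------------

new_violation <- function(path, problem) {
  data.frame(path = path, problem = problem, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(path = character(0), problem = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a synthesis route
#'
#' Walks the route tree and collects every invariant violation: step yields
#' outside `(0, 1]`, duplicate step ids, empty element lists, empty
#' branches, non-positive explicit weights, and malformed elements.
#' Violations are returned as data, not raised as errors, so a whole file
#' can be diagnosed in one pass.
#'
#' @param route A `synth_route` (or a structurally similar list).
#' @return A data frame with columns `path` and `problem`; zero rows iff the
#'   route is valid.
#' @examples
#' nrow(validate_route(linear_route(c(0.9, 0.8)))) # 0
#' nrow(validate_route(linear_route(c(1.2))))      # 1
#' @export
validate_route <- function(route) {
  v <- no_violations()
  ids <- character(0)

  check_step <- function(step, path) {
    y <- step$yield
    if (!is.numeric(y) || length(y) != 1L || is.na(y)) {
      v <<- rbind(v, new_violation(path, "step yield is not a single number"))
    } else if (y <= 0 || y > 1) {
      v <<- rbind(v, new_violation(
        path, sprintf("step '%s' yield %g outside (0, 1]", step$id, y)))
    }
    if (!is.character(step$id) || length(step$id) != 1L || !nzchar(step$id)) {
      v <<- rbind(v, new_violation(path, "step id missing or empty"))
    } else {
      if (step$id %in% ids)
        v <<- rbind(v, new_violation(
          path, sprintf("duplicate step id '%s'", step$id)))
      ids <<- c(ids, step$id)
    }
  }

  check_route <- function(rt, path) {
    els <- rt$elements
    if (!is.list(els) || length(els) == 0L) {
      v <<- rbind(v, new_violation(path, "route has no elements"))
      return(invisible())
    }
    for (i in seq_along(els)) {
      el <- els[[i]]
      p <- sprintf("%s.elements[%d]", path, i)
      if (inherits(el, "synth_step")) {
        check_step(el, p)
      } else if (inherits(el, "convergence_point")) {
        brs <- el$branches
        if (!is.list(brs) || length(brs) == 0L) {
          v <<- rbind(v, new_violation(p, "convergence point has no branches"))
        } else {
          for (j in seq_along(brs)) {
            b <- brs[[j]]
            bp <- sprintf("%s.branches[%d]", p, j)
            if (!inherits(b, "synth_branch")) {
              v <<- rbind(v, new_violation(bp, "branch is not a synth_branch"))
              next
            }
            w <- b$weight
            if (!is.null(w) &&
                (!is.numeric(w) || length(w) != 1L || is.na(w) || w <= 0)) {
              v <<- rbind(v, new_violation(
                bp, "explicit branch weight must be a positive number"))
            }
            check_route(b$route, bp)
          }
        }
      } else {
        v <<- rbind(v, new_violation(
          p, "element is neither a step nor a convergence point"))
      }
    }
  }

  if (!inherits(route, "synth_route") && !is.list(route)) {
    return(new_violation("route", "not a route object"))
  }
  check_route(route, "route")
  v
}

# stop with a classed error when a route is invalid
assert_valid_route <- function(route) {
  v <- validate_route(route)
  if (nrow(v) > 0L) {
    stop(structure(
      class = c("syntheff_validation_error", "error", "condition"),
      list(message = paste0(
        "invalid route:\n",
        paste0("  ", v$path, ": ", v$problem, collapse = "\n")),
        call = sys.call(-1), violations = v)))
  }
  invisible(route)
}

# ---- step counting -----------------------------------------------------

#' Count the synthesis steps of a route
#'
#' Counts every step in the tree, including all steps inside every branch of
#' every convergence point, recursively. This is the step number `N` used in
#' the synthesis-efficiency denominator.
#'
#' @param x A `synth_route`, `convergence_point`, `synth_branch`, or
#'   `synth_step`.
#' @return A positive integer step count.
#' @examples
#' step_count(linear_route(rep(0.8, 9))) # 9
#' @export
step_count <- function(x) UseMethod("step_count")

#' @export
step_count.synth_step <- function(x) 1L

#' @export
step_count.synth_branch <- function(x) step_count(x$route)

#' @export
step_count.convergence_point <- function(x) {
  sum(vapply(x$branches, step_count, integer(1)))
}

#' @export
step_count.synth_route <- function(x) {
  sum(vapply(x$elements, step_count, integer(1)))
}

#' Resolve the branch weights of a convergence point
#'
#' Branches with an explicit `weight` keep it; branches without one are
#' weighted by their recursive step count, so a three-step precursor chain
#' counts three times as much as a single-step chain in the convergence
#' mean.
#'
#' @param cp A `convergence_point`.
#' @return Numeric vector of positive weights, one per branch.
#' @examples
#' cp <- convergence(
#'   synth_branch(synth_step("C-E", 0.76)),
#'   synth_branch(synth_step("x1", 0.68), synth_step("x2", 0.73),
#'                synth_step("x3", 0.59))
#' )
#' default_weights(cp) # 1 3
#' @export
default_weights <- function(cp) {
  stopifnot(inherits(cp, "convergence_point"))
  vapply(cp$branches, function(b) {
    if (is.null(b$weight)) as.numeric(step_count(b)) else as.numeric(b$weight)
  }, numeric(1))
}

# ---- printing ----------------------------------------------------------

#' @export
print.synth_step <- function(x, ...) {
  cat(sprintf("<step> %s  yield %.4g\n", x$id, x$yield))
  invisible(x)
}

#' @export
print.synth_route <- function(x, ...) {
  cat(sprintf("<synthesis route> %s\n",
              if (nzchar(x$name)) x$name else "(unnamed)"))
  cat(sprintf("  %d element(s), %d step(s)\n",
              length(x$elements), step_count(x)))
  print_tree <- function(els, indent) {
    for (el in els) {
      if (inherits(el, "synth_step")) {
        cat(sprintf("%s- %s (%.4g)\n", indent, el$id, el$yield))
      } else if (inherits(el, "convergence_point")) {
        cat(sprintf("%s- convergence of %d branch(es):\n",
                    indent, length(el$branches)))
        for (j in seq_along(el$branches)) {
          b <- el$branches[[j]]
          w <- if (is.null(b$weight)) "steps" else format(b$weight)
          cat(sprintf("%s  [branch %d, weight %s]\n", indent, j, w))
          print_tree(b$route$elements, paste0(indent, "    "))
        }
      }
    }
  }
  print_tree(x$elements, "  ")
  invisible(x)
}
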