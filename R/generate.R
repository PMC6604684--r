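#' Generate a random synthesis route
#'
#' Deterministic random route generator for property testing. The tree
#' structure (element counts, convergence placement, branch counts) is drawn
#' first and the step yields are filled in afterwards in document order, so
#' the same seed yields the same structure even when `yield_range` changes.
#' Yields are rounded to four decimals, the precision at which laboratory
#' yields are realistically reported, which also guarantees lossless file
#' round trips.
#'
#' The caller's RNG state is saved and restored; the generator draws from
#' its own seeded stream.
#'
#' @param seed Integer seed; same seed, same route.
#' @param max_depth Maximum nesting depth of convergences (>= 1). At depth 1
#'   no convergence points are generated, giving a linear route.
#' @param max_branches Maximum number of branches per convergence (>= 1).
#' @param yield_range Length-2 interval within `(0, 1]` from which step
#'   yields are drawn uniformly.
#' @param max_elements Maximum number of elements per (sub-)route.
#' @return A valid `synth_route`.
#' @examples
#' r1 <- generate_random_route(1)
#' r2 <- generate_random_route(1)
#' identical(r1, r2) # TRUE
#' @export
generate_random_route <- function(seed, max_depth = 3L, max_branches = 3L,
                                  yield_range = c(0.4, 0.99),
                                  max_elements = 4L) {
  if (!is.numeric(max_depth) || max_depth < 1) {
    stop("`max_depth` must be >= 1")
  }
  if (!is.numeric(max_branches) || max_branches < 1) {
    stop("`max_branches` must be >= 1")
  }
  if (length(yield_range) != 2L || yield_range[1] <= 0 ||
      yield_range[2] > 1 || yield_range[1] > yield_range[2]) {
    stop("`yield_range` must be an interval within (0, 1]")
  }

  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(seed)

  n_steps <- 0L

  # pass 1: structure only (yields left as placeholders)
  build <- function(depth) {
    n_el <- sample.int(max_elements, 1L)
    els <- vector("list", n_el)
    for (i in seq_len(n_el)) {
      if (depth < max_depth && stats::runif(1) < 0.35) {
        nb <- sample.int(max_branches, 1L)
        branches <- lapply(seq_len(nb),
                           function(j) synth_branch(build(depth + 1L)))
        els[[i]] <- structure(list(branches = branches),
                              class = "convergence_point")
      } else {
        n_steps <<- n_steps + 1L
        els[[i]] <- synth_step(paste0("s", n_steps), NA_real_)
      }
    }
    synth_route(elements = els)
  }
  skeleton <- build(1L)

  # pass 2: yields in document order
  draw_yield <- function() {
    y <- round(stats::runif(1, yield_range[1], yield_range[2]), 4)
    max(y, 1e-4) # rounding must not push a yield to zero
  }
  fill <- function(rt) {
    rt$elements <- lapply(rt$elements, function(el) {
      if (inherits(el, "synth_step")) {
        el$yield <- draw_yield()
      } else {
        el$branches <- lapply(el$branches, function(b) {
          b$route <- fill(b$route)
          b
        })
      }
      el
    })
    rt
  }
  route <- fill(skeleton)
  route$name <- sprintf("random-route-seed-%d", as.integer(seed))
  route
}
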