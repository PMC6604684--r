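#' @title Strategy comparisons
#'
#' @description
#' Higher-level tools built on route evaluation: fragment-condensation
#' plans for linear syntheses (split a sequential chain into parallel
#' fragments and link them), exhaustive enumeration of contiguous
#' fragmentations, the average-yield/step-number efficiency grid, and
#' side-by-side route comparisons with pairwise ratios.
#'
#' @name strategy
NULL

#' Define a fragment-condensation plan
#'
#' Describes splitting a linear sequence of coupling steps into contiguous
#' fragments that are synthesized in parallel and joined by a final linking
#' step. With no cut points and no linking step the plan is the plain
#' sequential synthesis.
#'
#' @param step_yields Ordered numeric vector of step yields in `(0, 1]`.
#' @param cut_points Strictly increasing integer positions; a cut after
#'   position `i` ends a fragment. Must lie in `1 .. length(step_yields)-1`.
#' @param linking_yield Optional fractional yield of the final condensation
#'   step joining the fragments; required when there are two or more
#'   fragments.
#' @return An object of class `"fragmentation_plan"`.
#' @examples
#' # two tetrapeptide couplings fragments linked at 0.8
#' fragmentation_plan(rep(0.8, 8), cut_points = 4, linking_yield = 0.8)
#' @export
fragmentation_plan <- function(step_yields, cut_points = integer(0),
                               linking_yield = NULL) {
  n <- length(step_yields)
  if (n < 1L || !is.numeric(step_yields) ||
      any(step_yields <= 0 | step_yields > 1)) {
    stop("`step_yields` must be a non-empty vector of fractions in (0, 1]")
  }
  cut_points <- as.integer(cut_points)
  if (length(cut_points)) {
    if (any(cut_points < 1L | cut_points >= n) ||
        any(diff(cut_points) <= 0L)) {
      stop("`cut_points` must be strictly increasing and within 1..",
           n - 1L)
    }
  }
  if (!is.null(linking_yield) &&
      (!is.numeric(linking_yield) || linking_yield <= 0 ||
       linking_yield > 1)) {
    stop("`linking_yield` must be a fraction in (0, 1]")
  }
  if (length(cut_points) && is.null(linking_yield)) {
    stop("a plan with two or more fragments needs a `linking_yield`")
  }
  structure(list(step_yields = as.numeric(step_yields),
                 cut_points = cut_points,
                 linking_yield = linking_yield),
            class = "fragmentation_plan")
}

#' Build the route corresponding to a fragmentation plan
#'
#' Fragments become parallel branches of one convergence point (weighted by
#' their step counts), followed by the linking step. A plan without cuts
#' and without a linking step is the plain linear route.
#'
#' @param plan A [fragmentation_plan()].
#' @param name Route name.
#' @return A `synth_route`.
#' @export
fragmentation_route <- function(plan, name = "fragmentation") {
  stopifnot(inherits(plan, "fragmentation_plan"))
  ys <- plan$step_yields
  n <- length(ys)
  if (length(plan$cut_points) == 0L && is.null(plan$linking_yield)) {
    return(linear_route(ys, name = name))
  }
  bounds <- c(0L, plan$cut_points, n)
  branches <- lapply(seq_len(length(bounds) - 1L), function(f) {
    idx <- (bounds[f] + 1L):bounds[f + 1L]
    synth_branch(linear_route(ys[idx],
                              ids = paste0("f", f, "_s", seq_along(idx))))
  })
  els <- list(structure(list(branches = branches),
                        class = "convergence_point"))
  if (!is.null(plan$linking_yield)) {
    els <- c(els, list(synth_step("link", plan$linking_yield)))
  }
  synth_route(elements = els, name = name)
}

#' Overall yield of a fragment-condensation plan
#'
#' @param plan A [fragmentation_plan()].
#' @param policy A [rounding_policy()].
#' @return The overall yield as a fraction.
#' @examples
#' # sequential decapeptide: nine couplings at 0.8
#' evaluate_fragmentation(fragmentation_plan(rep(0.8, 9))) # 0.134
#' # two 4-step fragments, link 0.8
#' evaluate_fragmentation(
#'   fragmentation_plan(rep(0.8, 8), 4, 0.8)) # 0.328
#' @export
evaluate_fragmentation <- function(plan, policy = rounding_policy()) {
  overall_yield(fragmentation_route(plan),
                as_rounding_policy(policy))$overall_yield
}

#' Enumerate all contiguous fragmentations of a linear synthesis
#'
#' Evaluates every partition of the step sequence into at most
#' `max_fragments` contiguous fragments, each plan ending in the linking
#' step, and ranks them by overall yield. The single-fragment (no-cut) plan
#' is included; since the linking step is mandated for the enumeration, its
#' value is the plain chain yield times the linking yield.
#'
#' @param step_yields Ordered numeric vector of step yields in `(0, 1]`.
#' @param linking_yield Fractional yield of the final condensation step.
#' @param max_fragments Maximum number of fragments (>= 1).
#' @param policy A [rounding_policy()].
#' @param max_plans Safety cap on the number of enumerated plans.
#' @return A data frame with columns `n_fragments`, `cut_points` (comma
#'   string), and `overall_yield`, sorted by descending yield with ties
#'   broken lexicographically by cut points. The corresponding
#'   [fragmentation_plan()] objects are attached as attribute `"plans"` in
#'   the same order.
#' @examples
#' top <- enumerate_fragmentations(rep(0.8, 8), 0.8, max_fragments = 2)
#' top[1, ] # the symmetric 4+4 split wins
#' @export
enumerate_fragmentations <- function(step_yields, linking_yield,
                                     max_fragments = 3L,
                                     policy = rounding_policy(),
                                     max_plans = 20000L) {
  n <- length(step_yields)
  if (n < 2L) stop("need at least two steps to fragment")
  max_fragments <- min(as.integer(max_fragments), n)
  if (max_fragments < 1L) stop("`max_fragments` must be >= 1")
  total <- sum(choose(n - 1L, seq_len(max_fragments) - 1L))
  if (total > max_plans) {
    stop(sprintf("enumeration would produce %d plans (cap %d)",
                 total, max_plans))
  }
  policy <- as_rounding_policy(policy)

  plans <- vector("list", total)
  p <- 0L
  for (k in seq_len(max_fragments)) {
    cut_sets <- if (k == 1L) list(integer(0))
      else utils::combn(n - 1L, k - 1L, simplify = FALSE)
    for (cuts in cut_sets) {
      p <- p + 1L
      plans[[p]] <- fragmentation_plan(step_yields, cuts, linking_yield)
    }
  }
  yields <- vapply(plans, evaluate_fragmentation, numeric(1),
                   policy = policy)
  cut_str <- vapply(plans, function(pl)
    paste(sprintf("%03d", pl$cut_points), collapse = ","), character(1))
  ord <- order(-yields, cut_str)
  out <- data.frame(
    n_fragments = vapply(plans, function(pl)
      length(pl$cut_points) + 1L, integer(1))[ord],
    cut_points = vapply(plans, function(pl)
      paste(pl$cut_points, collapse = ","), character(1))[ord],
    overall_yield = yields[ord],
    stringsAsFactors = FALSE
  )
  attr(out, "plans") <- plans[ord]
  out
}

#' Efficiency grid over average yields and step numbers
#'
#' For each combination of a geometric average per-step yield and a step
#' number `n`, the overall yield is the average yield to the n-th power and
#' the efficiency is that overall yield divided by `n`, both in percent.
#' Full-precision values are stored; display columns apply the grid's
#' rendering convention (whole percents at or above 10, two significant
#' figures below).
#'
#' @param average_yields Numeric vector of per-step average yields in
#'   `(0, 1]`.
#' @param max_steps Largest step number `n` (>= 1).
#' @return A data frame of class `"efficiency_grid"` with columns `y_av`,
#'   `n`, `y_oa_pct`, `eff_pct`, `y_oa_display`, `eff_display`.
#' @examples
#' g <- efficiency_grid(c(0.95, 0.9), max_steps = 3)
#' subset(g, y_av == 0.9 & n == 2) # y_oa 81, Eff 40.5
#' @export
efficiency_grid <- function(average_yields = c(0.95, 0.9, 0.8, 0.7, 0.6),
                            max_steps = 10L) {
  if (any(average_yields <= 0 | average_yields > 1)) {
    stop("`average_yields` must be fractions in (0, 1]")
  }
  if (!is.numeric(max_steps) || max_steps < 1) {
    stop("`max_steps` must be >= 1")
  }
  g <- expand.grid(n = seq_len(max_steps), y_av = average_yields,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("y_av", "n")]
  g$y_oa_pct <- 100 * g$y_av^g$n
  g$eff_pct <- g$y_oa_pct / g$n
  g$y_oa_display <- grid_display(g$y_oa_pct)
  g$eff_display <- grid_display(g$eff_pct)
  rownames(g) <- NULL
  class(g) <- c("efficiency_grid", "data.frame")
  g
}

# grid rendering: whole percents >= 10 (round-half-even, matching the
# published convention where e.g. 40.5 prints as 40), else 2 significant
# figures
grid_display <- function(x) {
  vapply(x, function(v) {
    if (v >= 10) sprintf("%d", as.integer(round(v)))
    else format(signif(v, 2), scientific = FALSE)
  }, character(1))
}

#' @export
print.efficiency_grid <- function(x, ...) {
  yavs <- unique(x$y_av)
  hdr <- paste(sprintf("%6s", sprintf("%.0f", 100 * yavs)), collapse = "")
  cat("Overall yield y_oa [%] and synthesis efficiency Eff_syn [%]\n")
  cat("by geometric average step yield y_av and step number n\n\n")
  cat(sprintf("  n |%s  |%s\n", hdr, hdr))
  for (n in sort(unique(x$n))) {
    row <- x[x$n == n, ]
    row <- row[match(yavs, row$y_av), ]
    cat(sprintf("%3d |%s  |%s\n", n,
                paste(sprintf("%6s", row$y_oa_display), collapse = ""),
                paste(sprintf("%6s", row$eff_display), collapse = "")))
  }
  invisible(x)
}

#' Compare several routes side by side
#'
#' Evaluates each route, reports overall yield, step count, efficiency and
#' the fictive fully-sequential yield, and computes pairwise ratio matrices
#' of overall yields and efficiencies at full precision. Routes are ordered
#' by descending efficiency.
#'
#' @param routes List of `synth_route` objects (length >= 2).
#' @param policy A [rounding_policy()].
#' @param n_steps Optional numeric vector of step-count overrides, one per
#'   route (`NA` to use the route's own step count).
#' @return An object of class `"route_comparison"` with a `summary` data
#'   frame and `yield_ratio` / `efficiency_ratio` matrices (row over
#'   column), all in the order of the summary.
#' @examples
#' a <- linear_route(0.9, name = "one-pot")
#' b <- linear_route(rep(0.9, 5), name = "stepwise")
#' compare_routes(list(a, b))
#' @export
compare_routes <- function(routes, policy = rounding_policy(),
                           n_steps = NULL) {
  if (!is.list(routes) || length(routes) < 2L) {
    stop("`routes` must be a list of at least two routes")
  }
  policy <- as_rounding_policy(policy)
  if (is.null(n_steps)) n_steps <- rep(NA_real_, length(routes))
  stopifnot(length(n_steps) == length(routes))

  results <- Map(function(rt, ns) {
    overall_yield(rt, policy, n_steps = if (is.na(ns)) NULL else ns)
  }, routes, n_steps)

  nm <- vapply(seq_along(routes), function(i) {
    n <- routes[[i]]$name
    if (nzchar(n)) n else sprintf("route-%d", i)
  }, character(1))
  smry <- data.frame(
    name = nm,
    overall_yield = vapply(results, `[[`, numeric(1), "overall_yield"),
    n_steps = vapply(results, `[[`, integer(1), "step_count"),
    efficiency_pct = vapply(results, `[[`, numeric(1), "efficiency"),
    fictive_linear = vapply(routes, fictive_linear_yield, numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-smry$efficiency_pct)
  smry <- smry[ord, ]
  rownames(smry) <- NULL
  yr <- outer(smry$overall_yield, smry$overall_yield, `/`)
  er <- outer(smry$efficiency_pct, smry$efficiency_pct, `/`)
  dimnames(yr) <- dimnames(er) <- list(smry$name, smry$name)
  structure(list(summary = smry, yield_ratio = yr, efficiency_ratio = er,
                 policy = policy$mode),
            class = "route_comparison")
}

#' @export
print.route_comparison <- function(x, ...) {
  cat("Route comparison (ordered by synthesis efficiency)\n\n")
  s <- x$summary
  disp <- data.frame(
    route = s$name,
    `y_oa` = sprintf("%.3f", round_half_up(s$overall_yield, 3)),
    `y_oa%` = format_percent(100 * s$overall_yield),
    N = s$n_steps,
    `Eff_syn%` = format_percent(s$efficiency_pct),
    fictive = sprintf("%.3f", round_half_up(s$fictive_linear, 3)),
    check.names = FALSE
  )
  print(disp, row.names = FALSE)
  cat("\nPairwise overall-yield ratios (row / column):\n")
  print(round(x$yield_ratio, 2))
  cat("\nPairwise efficiency ratios (row / column):\n")
  print(round(x$efficiency_ratio, 2))
  invisible(x)
}
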