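#' @title Overall yield and synthesis efficiency
#'
#' @description
#' The overall yield of a purely sequential synthesis is the product of its
#' step yields. In a branched (convergent) synthesis the parallel precursor
#' chains feeding a convergence are cumulative, not sequential: their chain
#' yields are combined by a weighted arithmetic mean, weighted by the number
#' of steps in each chain, and the resulting convergence means enter the
#' sequential product of the main reaction set. Synthesis efficiency is the
#' overall yield divided by the total number of synthesis steps, expressed
#' in percent, which makes step economy a first-class criterion alongside
#' yield.
#'
#' @name efficiency
NULL

#' Overall yield of a sequential chain of steps
#'
#' @param yields Numeric vector of step yields, each in `(0, 1]`.
#' @param policy A [rounding_policy()]; under `"paper2dp"` the product is
#'   additionally rounded half-up to 2 decimals.
#' @return The chain yield as a fraction. An empty vector returns 1, the
#'   neutral element of the product.
#' @examples
#' chain_yield(c(0.89, 0.9, 0.85, 0.91, 0.97, 0.89)) # 0.535 (3 dp)
#' @export
chain_yield <- function(yields, policy = rounding_policy()) {
  policy <- as_rounding_policy(policy)
  if (length(yields) == 0L) return(1)
  if (!is.numeric(yields) || anyNA(yields) || any(yields <= 0 | yields > 1)) {
    stop("all step yields must be numbers in (0, 1]")
  }
  # sequential double-precision fold, bit-identical to the route walker,
  # so a linear route evaluates to exactly its chain yield
  y <- 1
  for (v in yields) y <- y * v
  policy_chain(y, policy)
}

#' Weighted arithmetic mean of branch yields
#'
#' Combines the chain yields of parallel branches at a convergence point.
#' Weights are typically the branches' step counts (see
#' [default_weights()]).
#'
#' @param values Numeric vector of branch yields (fractions).
#' @param weights Numeric vector of positive weights, same length.
#' @return The weighted mean, which always lies within
#'   `[min(values), max(values)]`.
#' @examples
#' weighted_yield_mean(c(0.82, 0.65), c(1, 1)) # 0.735
#' @export
weighted_yield_mean <- function(values, weights) {
  if (length(values) == 0L || length(values) != length(weights)) {
    stop("`values` and `weights` must be non-empty and of equal length")
  }
  if (!is.numeric(weights) || anyNA(weights) || any(weights <= 0)) {
    stop("all weights must be positive numbers")
  }
  stats::weighted.mean(values, weights)
}

#' Evaluate a route: overall yield, step count, efficiency
#'
#' Evaluates the route tree left to right. Each step multiplies the running
#' yield; each convergence point contributes the weighted mean of its
#' branches' recursively evaluated yields, with weights resolved by
#' [default_weights()]. Per-convergence means are recorded in pre-order
#' (document) traversal order. Modification factors (the ratio of a
#' convergence mean to its backbone branch's yield) are recorded for the
#' convergences on the backbone spine, i.e. those reached by always
#' following the first-listed branch; multiplying the linear backbone yield
#' by these factors recovers the overall yield exactly (see
#' [overall_yield_via_mf()]).
#'
#' @param route A valid `synth_route`.
#' @param policy A [rounding_policy()].
#' @param n_steps Optional override for the step count used in the
#'   efficiency denominator, for cases where the accounting of "real" steps
#'   differs from the number of yield-bearing entries in the tree.
#' @return An object of class `"efficiency_result"` with fields
#'   `overall_yield` (fraction), `step_count`, `efficiency` (percent),
#'   `convergence_means` and `modification_factors` (data frames with
#'   columns `index` and `mean`/`factor`), `policy`, and `route_name`.
#' @examples
#' r <- linear_route(c(0.9, 0.8), name = "two steps")
#' overall_yield(r)$overall_yield # 0.72
#' @export
overall_yield <- function(route, policy = rounding_policy(), n_steps = NULL) {
  policy <- as_rounding_policy(policy)
  assert_valid_route(route)

  counter <- 0L
  mean_idx <- integer(0); mean_val <- numeric(0)
  mf_idx <- integer(0); mf_val <- numeric(0)

  eval_route <- function(rt, spine) {
    y <- 1
    for (el in rt$elements) {
      if (inherits(el, "synth_step")) {
        y <- y * el$yield
        next
      }
      counter <<- counter + 1L
      idx <- counter
      w <- default_weights(el)
      branch_y <- numeric(length(el$branches))
      for (j in seq_along(el$branches)) {
        branch_y[j] <- policy_chain(
          eval_route(el$branches[[j]]$route, spine && j == 1L), policy)
      }
      m <- weighted_yield_mean(branch_y, w)
      mean_idx <<- c(mean_idx, idx); mean_val <<- c(mean_val, m)
      if (spine) {
        mf_idx <<- c(mf_idx, idx); mf_val <<- c(mf_val, m / branch_y[1L])
      }
      y <- y * m
    }
    y
  }

  y <- eval_route(route, TRUE)
  n_tree <- step_count(route)
  n_eff <- if (is.null(n_steps)) n_tree else {
    if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
      stop("`n_steps` must be a positive integer")
    as.integer(n_steps)
  }
  ord <- order(mean_idx)
  structure(
    list(
      overall_yield = y,
      step_count = n_eff,
      tree_step_count = n_tree,
      efficiency = synthesis_efficiency(y, n_eff),
      convergence_means = data.frame(index = mean_idx[ord],
                                     mean = mean_val[ord]),
      modification_factors = data.frame(index = mf_idx, factor = mf_val),
      policy = policy$mode,
      route_name = route$name
    ),
    class = "efficiency_result"
  )
}

#' Synthesis efficiency in percent
#'
#' Overall yield divided by the number of synthesis steps, on the percent
#' scale. A one-step synthesis with 90% yield has an efficiency of 90%; a
#' twenty-step synthesis with 0.75% overall yield only 0.038%.
#'
#' @param overall_yield Overall yield as a fraction in `(0, 1]`.
#' @param n_steps Total number of synthesis steps (>= 1).
#' @return Efficiency in percent.
#' @examples
#' synthesis_efficiency(0.9, 1)     # 90
#' synthesis_efficiency(0.0075, 20) # 0.0375
#' @export
synthesis_efficiency <- function(overall_yield, n_steps) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1) {
    stop("`n_steps` must be a positive integer")
  }
  if (!is.numeric(overall_yield) || overall_yield <= 0 || overall_yield > 1) {
    stop("`overall_yield` must be a fraction in (0, 1]")
  }
  100 * overall_yield / n_steps
}

#' Yield along the backbone path only
#'
#' Product of the step yields along a single linear path through the route:
#' at every convergence point exactly one branch is followed and all other
#' branches are ignored. The default follows the first-listed branch, the
#' conventional main reaction set. Note that no ordering between backbone
#' yield and overall yield is guaranteed in either direction.
#'
#' @param route A valid `synth_route`.
#' @param select Either a single branch index applied at every convergence,
#'   or a function `function(cp)` returning the index of the branch to
#'   follow for a given convergence point.
#' @return The backbone yield as a fraction.
#' @examples
#' # one-step backbone 0.82 vs a weaker parallel branch
#' r <- synth_route(convergence(synth_step("A-C", 0.82),
#'                              synth_step("V-D", 0.65)),
#'                  synth_step("C-J", 0.9))
#' backbone_yield(r) # 0.82 * 0.9
#' @export
backbone_yield <- function(route, select = 1L) {
  assert_valid_route(route)
  pick <- if (is.function(select)) select else function(cp) select
  rec <- function(rt) {
    y <- 1
    for (el in rt$elements) {
      if (inherits(el, "synth_step")) {
        y <- y * el$yield
      } else {
        j <- pick(el)
        if (j < 1L || j > length(el$branches))
          stop("backbone selection index out of range")
        y <- y * rec(el$branches[[j]]$route)
      }
    }
    y
  }
  rec(route)
}

#' Parallel reaction modification factor
#'
#' The ratio of a convergence's weighted branch mean to the backbone
#' branch's chain yield. Multiplying the backbone yield by the modification
#' factors of all convergences along the backbone gives the overall yield.
#' The factor exceeds 1 when the backbone branch is weaker than the branch
#' mean.
#'
#' @param convergence_mean Weighted mean of the convergence, in `(0, 1]`.
#' @param backbone_branch_yield Chain yield of the backbone branch, in
#'   `(0, 1]`.
#' @return The factor `convergence_mean / backbone_branch_yield`.
#' @examples
#' modification_factor(0.735, 0.82) # 0.896 (3 dp)
#' @export
modification_factor <- function(convergence_mean, backbone_branch_yield) {
  if (!is.numeric(backbone_branch_yield) || backbone_branch_yield <= 0 ||
      backbone_branch_yield > 1) {
    stop("`backbone_branch_yield` must be in (0, 1]")
  }
  if (!is.numeric(convergence_mean) || convergence_mean <= 0 ||
      convergence_mean > 1) {
    stop("`convergence_mean` must be in (0, 1]")
  }
  convergence_mean / backbone_branch_yield
}

#' Overall yield via the modification-factor method
#'
#' The second calculation method: compute the yield of the linear backbone
#' path, then multiply by the modification factor of every convergence on
#' the backbone spine. Algebraically identical to the direct weighted-mean
#' evaluation; under full precision the two agree to floating-point
#' accuracy.
#'
#' @param route A valid `synth_route`.
#' @param policy A [rounding_policy()] (applied to the branch chain yields
#'   entering the convergence means, as in [overall_yield()]).
#' @return The overall yield as a fraction.
#' @examples
#' r <- synth_route(convergence(synth_step("a", 0.82),
#'                              synth_step("b", 0.65)),
#'                  synth_step("c", 0.9))
#' all.equal(overall_yield_via_mf(r), overall_yield(r)$overall_yield)
#' @export
overall_yield_via_mf <- function(route, policy = rounding_policy()) {
  policy <- as_rounding_policy(policy)
  res <- overall_yield(route, policy)
  backbone_yield(route) * prod(res$modification_factors$factor)
}

#' Fictive yield of a fully sequential execution
#'
#' The hypothetical overall yield if every step of a branched route were
#' run strictly in sequence: the plain product of all step yields in the
#' tree, with no branch averaging. This is the baseline against which the
#' benefit of convergence is quantified; it is never larger than the
#' branched overall yield, with equality exactly when no convergence has
#' two or more branches.
#'
#' @param route A valid `synth_route`.
#' @return The fictive sequential yield as a fraction.
#' @examples
#' r <- synth_route(convergence(synth_step("a", 0.9),
#'                              synth_step("b", 0.8)),
#'                  synth_step("c", 0.9))
#' fictive_linear_yield(r) # 0.9 * 0.8 * 0.9
#' @export
fictive_linear_yield <- function(route) {
  assert_valid_route(route)
  rec <- function(rt) {
    y <- 1
    for (el in rt$elements) {
      if (inherits(el, "synth_step")) {
        y <- y * el$yield
      } else {
        for (b in el$branches) y <- y * rec(b$route)
      }
    }
    y
  }
  rec(route)
}

#' Ratio of two yields or efficiencies
#'
#' A simple quotient used to compare syntheses, e.g. a 90% single-step
#' route against a 0.75% route is 120 times better by yield. The caller
#' chooses which quantity to compare (overall yield or efficiency) and
#' passes both on the same scale.
#'
#' @param a,b Positive numbers on the same scale (two yields or two
#'   efficiencies).
#' @return `a / b`.
#' @examples
#' efficiency_ratio(90, 0.75) # 120
#' @export
efficiency_ratio <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || a <= 0) {
    stop("`a` and `b` must be positive numbers")
  }
  if (b <= 0) stop("cannot take a ratio against a non-positive denominator")
  a / b
}

#' Cost model parameters
#'
#' @param c1 Cost per synthesis step (currency units), `>= 0`.
#' @param c2 Yield scaling constant (dimensionless), `> 0`.
#' @param C Fixed cost offset (currency units), `>= 0`.
#' @return An object of class `"cost_params"`.
#' @export
cost_params <- function(c1 = 1, c2 = 1, C = 0) {
  if (!is.numeric(c2) || c2 <= 0) stop("`c2` must be > 0")
  if (!is.numeric(c1) || c1 < 0) stop("`c1` must be >= 0")
  if (!is.numeric(C) || C < 0) stop("`C` must be >= 0")
  structure(list(c1 = c1, c2 = c2, C = C), class = "cost_params")
}

#' Step-based synthesis cost estimate
#'
#' Costs grow linearly with the number of steps (each step carries similar
#' fixed labour, equipment and energy costs) and inversely with the overall
#' yield (material throughput). The functional form is
#' `(c1 * N) / (c2 * y_oa) + C`; the grouping, with both `c2` and the
#' overall yield in the denominator, is the interpretation adopted here.
#' The constants are application-specific and carry no default currency.
#'
#' @param n_steps Total number of synthesis steps (>= 1).
#' @param overall_yield Overall yield as a fraction, `> 0`.
#' @param params A [cost_params()] object.
#' @return The cost estimate in the units of `c1` and `C`.
#' @examples
#' cost_estimate(8, 0.225, cost_params(c1 = 1, c2 = 1, C = 0)) # 35.56
#' @export
cost_estimate <- function(n_steps, overall_yield, params = cost_params()) {
  stopifnot(inherits(params, "cost_params"))
  if (!is.numeric(n_steps) || n_steps < 1) {
    stop("`n_steps` must be a positive integer")
  }
  if (!is.numeric(overall_yield) || overall_yield <= 0) {
    stop("`overall_yield` must be > 0")
  }
  (params$c1 * n_steps) / (params$c2 * overall_yield) + params$C
}

# ---- display helpers ---------------------------------------------------

# percent display: 1 decimal place at or above 0.1%, else 2 significant
# figures (0.0375 -> "0.038")
format_percent <- function(p) {
  vapply(p, function(x) {
    if (x >= 0.1) sprintf("%.1f", round_half_up(x, 1))
    else format(signif(x, 2), scientific = FALSE)
  }, character(1))
}

#' @export
print.efficiency_result <- function(x, ...) {
  nm <- if (nzchar(x$route_name)) x$route_name else "(unnamed route)"
  cat(sprintf("Synthesis evaluation: %s\n", nm))
  cat(sprintf("  overall yield y_oa : %.3f (%s%%)\n",
              round_half_up(x$overall_yield, 3),
              format_percent(100 * x$overall_yield)))
  cat(sprintf("  steps N            : %d%s\n", x$step_count,
              if (x$step_count != x$tree_step_count)
                sprintf(" (tree holds %d yield-bearing steps)",
                        x$tree_step_count) else ""))
  cat(sprintf("  efficiency Eff_syn : %s%%\n", format_percent(x$efficiency)))
  if (nrow(x$convergence_means)) {
    cat("  convergence means  :",
        paste(sprintf("#%d=%.3f", x$convergence_means$index,
                      round_half_up(x$convergence_means$mean, 3)),
              collapse = ", "), "\n")
  }
  if (nrow(x$modification_factors)) {
    cat("  mod. factors (mf)  :",
        paste(sprintf("#%d=%.3f", x$modification_factors$index,
                      round_half_up(x$modification_factors$factor, 3)),
              collapse = ", "), "\n")
  }
  if (x$policy != "full") cat(sprintf("  rounding policy    : %s\n", x$policy))
  invisible(x)
}
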