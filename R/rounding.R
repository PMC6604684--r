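#' Rounding policies for route evaluation
#'
#' All computations default to full double precision. The `"paper2dp"`
#' policy reproduces hand calculations in which each branch chain yield is
#' rounded to two decimal places before entering the weighted convergence
#' mean, as is common in published worked examples. Display rounding
#' (reports, tables) is always applied separately at rendering time and
#' never feeds back into the arithmetic.
#'
#' @param mode Either `"full"` (no intermediate rounding; the default) or
#'   `"paper2dp"` (branch chain yields rounded half-up to 2 decimals before
#'   the convergence mean).
#' @return An object of class `"rounding_policy"`.
#' @examples
#' rounding_policy("full")
#' rounding_policy("paper2dp")
#' @export
rounding_policy <- function(mode = c("full", "paper2dp")) {
  mode <- match.arg(mode)
  structure(list(mode = mode), class = "rounding_policy")
}

as_rounding_policy <- function(policy) {
  if (inherits(policy, "rounding_policy")) return(policy)
  if (is.character(policy) && length(policy) == 1L) {
    # accept the CLI spelling "paper" as shorthand
    if (policy == "paper") policy <- "paper2dp"
    return(rounding_policy(policy))
  }
  stop("`policy` must be a rounding_policy or one of \"full\", \"paper2dp\"")
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding as used for displayed yields and
#' percentages, where e.g. 0.8265 at three decimals prints 0.827. Base R's
#' [round()] rounds half to even and is kept for contexts where that
#' convention is wanted.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.8265, 3) # 0.827
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# apply intermediate rounding to a chain yield under the given policy
policy_chain <- function(y, policy) {
  if (policy$mode == "paper2dp") round_half_up(y, 2) else y
}

#' @export
print.rounding_policy <- function(x, ...) {
  cat(sprintf("<rounding policy: %s>\n", x$mode))
  invisible(x)
}
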