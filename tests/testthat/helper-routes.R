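# Shared fixtures built in code (independent of the shipped files) and an
# independent brute-force evaluator used as the oracle for the weighted
# branch-averaging algorithm.

case_study_route <- function() {
  synth_route(
    convergence(
      synth_branch(synth_step("A-C", 0.82)),
      synth_branch(synth_step("V-D", 0.65))
    ),
    convergence(
      synth_branch(synth_step("C-E", 0.76)),
      synth_branch(synth_step("X-G1", 0.68), synth_step("X-G2", 0.73),
                   synth_step("X-G3", 0.59))
    ),
    synth_step("E-I", 0.9),
    synth_step("I-J", 0.83),
    name = "case-study-A-J"
  )
}

et743_chain_yields <- list(
  a = c(0.89, 0.9, 0.85, 0.91, 0.97, 0.89),
  b = c(0.79, 0.94, 0.72, 0.98, 0.93, 0.99),
  c = c(0.95, 0.87)
)

et743_route <- function() {
  ch <- et743_chain_yields
  synth_route(
    convergence(
      synth_branch(linear_route(ch$a, ids = paste0("a", 1:6))),
      synth_branch(linear_route(ch$b, ids = paste0("b", 1:6))),
      synth_branch(linear_route(ch$c, ids = paste0("c", 1:2)))
    ),
    synth_step("ugi", 0.9),
    name = "et743-ugi-4cr"
  )
}

# flatten all step yields in document order (independent leaf enumeration)
leaf_yields <- function(rt) {
  unlist(lapply(rt$elements, function(el) {
    if (inherits(el, "synth_step")) el$yield
    else unlist(lapply(el$branches, function(b) leaf_yields(b$route)))
  }))
}

# brute-force reference evaluator written directly from the definition:
# sequential product of steps and of step-count-weighted branch means
oracle_yield <- function(rt) {
  val <- 1
  for (el in rt$elements) {
    if (inherits(el, "synth_step")) {
      val <- val * el$yield
    } else {
      vs <- vapply(el$branches, function(b) oracle_yield(b$route), 0)
      ws <- vapply(el$branches, function(b) {
        if (is.null(b$weight)) length(leaf_yields(b$route))
        else b$weight
      }, 0)
      val <- val * sum(vs * ws) / sum(ws)
    }
  }
  val
}

# apply `f` to the yield of the k-th step in document order
modify_step_yield <- function(rt, k, f) {
  counter <- 0L
  rec <- function(r) {
    r$elements <- lapply(r$elements, function(el) {
      if (inherits(el, "synth_step")) {
        counter <<- counter + 1L
        if (counter == k) el$yield <- f(el$yield)
      } else {
        el$branches <- lapply(el$branches, function(b) {
          b$route <- rec(b$route)
          b
        })
      }
      el
    })
    r
  }
  rec(rt)
}

has_multi_branch_convergence <- function(rt) {
  any(vapply(rt$elements, function(el) {
    if (inherits(el, "synth_step")) return(FALSE)
    if (length(el$branches) >= 2L) return(TRUE)
    any(vapply(el$branches, function(b)
      has_multi_branch_convergence(b$route), logical(1)))
  }, logical(1)))
}
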