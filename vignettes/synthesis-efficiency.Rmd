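---
title: "Evaluating branched synthesis routes: overall yield, efficiency, and strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating branched synthesis routes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntheff)
```

## The problem

The standard figure of merit for a chemical synthesis is its overall yield
$y_{oa}$. For a purely sequential route of $N$ steps with fractional step
yields $y_n$ it is the product

$$y_{oa} = \prod_{n=1}^{N} y_n.$$

Real total syntheses, and multicomponent reactions (MCRs) in particular,
are rarely sequential: several precursor chains are prepared in parallel
and meet at convergence points. Parallel chains are *cumulative* with
respect to each other, not sequential, so multiplying their yields would
be wrong. Instead, the chain yields $y_j$ of the $J$ branches feeding a
convergence are combined by an arithmetic mean weighted by $m_j$, the
number of synthesis steps in each chain:

$$y_{am} = \frac{\sum_{j=1}^{J} y_j\, m_j}{\sum_{j=1}^{J} m_j},$$

and these convergence means enter the sequential product of the main
reaction set:

$$y_{oa} = \prod_{k=1}^{K} \left[ \frac{\sum_{j=1}^{J}
  \left(\prod_{n=1}^{N} y_n\right)_j m_j}{\sum_{j=1}^{J} m_j} \right].$$

Yield alone ignores step economy. Each synthesis step — defined here as a
one-pot working process without intermediate isolation and purification —
carries roughly constant fixed costs (labour, equipment, energy, waste
handling), so the second criterion is the total step number $N$, and the
synthesis efficiency is

$$\mathrm{Eff}_{syn} = \frac{y_{oa}}{N}$$

on the percent scale. A one-step MCR at 90% yield has
$\mathrm{Eff}_{syn} = 90\%$; a twenty-step linear route at 0.75% overall
yield has $\mathrm{Eff}_{syn} = 0.038\%$ — three to four orders of
magnitude apart, which is what makes step count a first-class criterion.

## Route model

`syntheff` represents a route as a tree: an ordered list of elements, each
a **step** (id plus fractional yield) or a **convergence point** holding
one or more **branches**, each branch being a sub-route with an optional
weight. Trees are acyclic by construction. Design choices where the
formulation left room:

* **Default weights are recursive step counts.** The worked convergences
  weight a one-step chain against a three-step chain as 1:3, and three
  chains of 6, 6 and 2 steps as 6:6:2, i.e. by the synthetic work in each
  branch. An explicit per-branch `weight` overrides the default (with
  equal-length branches the two conventions coincide).
* **Every yield-bearing entry counts exactly once** toward $N$; the
  bond-forming reaction at a convergence is a step only if it carries its
  own yield (like the Ugi step below).
* **Single-branch convergences are legal** and behave as the branch
  inlined (a mean of one value, modification factor exactly 1).
* **A yield of exactly 1 is legal** (quantitative step); 0 is not.
* Nested convergences are allowed; a branch containing its own
  convergence is weighted by its total recursive step count.

`validate_route()` returns violations as a data frame with element paths
rather than throwing on the first problem, so a whole route file can be
diagnosed in one pass; computational entry points signal a classed error
on invalid input, with no silent clamping.

## The two calculation methods

`overall_yield()` evaluates the tree directly: steps multiply, convergence
points contribute their weighted branch mean. It returns the overall
yield, the step count, the efficiency, and the per-convergence means and
modification factors:

```{r case-study}
cs <- route_fixture("case_study")$route
overall_yield(cs)
```

The **modification-factor method** is the chemist's target-molecule view
of the same number: compute the plain product along the backbone path
(first-listed branch at every convergence, `backbone_yield()`), then
multiply by each convergence's modification factor
$mf = y_{am} / y_{backbone\ branch}$:

```{r mf}
backbone_yield(cs)
overall_yield_via_mf(cs)
```

The two methods are algebraically identical; the test suite checks
agreement to $10^{-10}$ over a thousand generated routes. For nested
convergences the factors recorded are those on the backbone spine
(convergences reached by always following the first branch); convergences
inside non-backbone branches contribute through the branch values inside
the means, which is exactly what makes the identity exact.

## Rounding

Full double precision is the default everywhere; display rounding
(fractions to 3 decimals, percents to 1 decimal or 2 significant figures
below 0.1%, half-up) is applied only at rendering. One classic worked
example, the heptapeptide + tripeptide fragment condensation, carries its
hand-rounded intermediates into the arithmetic: the fragment chain yields
$0.8^6 = 0.262$ and $0.8^2 = 0.64$ enter the weighted mean as 0.26 and
0.64, giving 0.284 where full precision gives 0.285. The
`rounding_policy("paper2dp")` mode reproduces exactly that convention —
branch chain yields rounded half-up to two decimals before the weighted
mean, the mean itself carried forward at full precision (rounding the
mean too would give 0.288, which matches no hand calculation). Display
rounding never corrupts results by default; the policy exists solely to
replicate display-precision hand calculations.

A related numerical detail: sequential products are accumulated by a
plain double-precision fold (not extended-precision `prod()`), so a
branched evaluation of a linear route is bit-identical to `chain_yield()`.

## Fragment and MCR strategies

`fragmentation_plan()` / `evaluate_fragmentation()` express the classic
peptide fragment-condensation question. For a decapeptide built at a
uniform 80% coupling yield:

```{r decapeptide}
# nine sequential couplings
evaluate_fragmentation(fragmentation_plan(rep(0.8, 9)))
# two pentapeptide fragments (4 + 4 couplings), linked at 0.8
evaluate_fragmentation(fragmentation_plan(rep(0.8, 8), 4, 0.8))
# heptapeptide + tripeptide (6 + 2), display-precision arithmetic
evaluate_fragmentation(fragmentation_plan(rep(0.8, 8), 6, 0.8),
                       rounding_policy("paper2dp"))
```

The symmetric split is best — `enumerate_fragmentations()` confirms this
by exhaustive enumeration of contiguous partitions (restricted, like the
published scheme, to one final linking step; deeper fragment trees are
expressible through the route type but not enumerated). Whether the
linking step "counts" toward $N$ in efficiency comparisons is left to the
caller: the step count of the fragmented route includes it, and the
`n_steps` override reports any other accounting.

The Ugi four-component construct toward ecteinascidin-743 shows the same
effect at full scale — three precursor chains of 6, 6 and 2 steps meeting
in a 90% Ugi reaction:

```{r et743}
et <- route_fixture("et743_ugi")$route
res <- overall_yield(et, n_steps = 17)
res$overall_yield
fictive_linear_yield(et)
res$efficiency
```

The *fictive linear yield* is the hypothetical product of all step yields
run strictly in sequence — the baseline for quantifying the benefit of
convergence. It never exceeds the branched yield (a product of fractions
is at most their minimum, hence at most the weighted mean), with equality
exactly when no convergence has two or more branches. Here the convergent
architecture is worth a factor of 2.6. The efficiency denominator uses
the `n_steps = 17` override: the route tree holds 15 yield-bearing
entries, but the real precursor count is 17 (three entries are double
steps), and that is the published step accounting for this synthesis.

`efficiency_grid()` tabulates $y_{oa} = y_{av}^n$ and
$\mathrm{Eff}_{syn} = y_{oa}/n$ over average step yields and step
numbers; full precision is stored, and the display columns use whole
percents at or above 10 (round-half-even) and two significant figures
below. `compare_routes()` puts several routes
side by side with pairwise yield and efficiency ratios at full precision;
every displayed ratio is the quotient of the two full-precision
quantities, rounded only for display. One deliberate exception is
reproduced both ways: the comparison of the one-step 90% MCR with the
twenty-step 0.75% route gives 2400 at full precision, and 2368 when the
smaller efficiency is first display-rounded to 0.038% — the conventional
two-stage hand rounding.

The simple cost model
$\mathrm{cost} = c_1 N / (c_2\, y_{oa}) + C$ (`cost_estimate()`) carries
step-proportional fixed costs and yield-inverse variable costs; the
grouping, with both $c_2$ and $y_{oa}$ in the denominator, is this
package's documented reading of the inline formula, and no constants are
assumed — only the functional form is provided.

## Files, fixtures and the CLI

Routes are stored in a small versioned YAML schema (`read_route()`,
`write_route()`), chosen over a flat edge list because convergent
syntheses are inherently tree-shaped. Yields are stored as fractions;
percent strings (`"82%"`) are normalized on input. Unknown keys inside
elements are rejected (catching typos like `yeild`), while `metadata` is
free-form and preserved. Serialization is canonical, so
`write(parse(write(doc)))` is byte-identical. Eight worked-example routes
ship with the package (`route_fixtures()`); the two tropinone routes are
stored as single aggregate-yield steps because only their overall yields
are recorded, with the real step counts in metadata, and the linearized
Ugi variant is marked synthetic.

`syntheff_cli()` (and the installed `syntheff` script) exposes
`eval`, `validate`, `compare`, `table` and `random` subcommands with
stable exit codes (0 ok, 1 usage, 2 syntax/schema, 3 validation, 4
computation, 5 I/O); results go to standard output, diagnostics to the
message stream, and `--output machine` emits the same full-precision
numbers as JSON.

## The random-route generator and what the tests show

`generate_random_route()` drives the property suite: structure (element
counts, convergence placement, branch counts; up to depth 3–4) is drawn
before yields, so seeds are stable across yield ranges; yields are
uniform on (0.4, 0.99) rounded to four decimals — the precision at which
laboratory yields are realistically reported, which also makes file round
trips lossless. The suite sweeps 1000 such routes for the
direct-versus-modification-factor identity, monotonicity of the overall
yield in every single step yield, branch-mean bounds, the
fictive-vs-branched inequality, and serialization round trips.

These generated trees emulate the *arithmetic* structure of convergent
syntheses, not their chemistry: yields are independent draws, branch
shapes are uniform, and nothing models reaction feasibility,
stoichiometry, atom economy or purification losses. Passing tests
therefore certify the evaluation algebra and its invariants, not any
statement about real routes. Known limitations, by design: no structure
handling (SMILES/InChI), no retrosynthetic search or route optimization,
no uncertainty propagation on yields, and a cost model with user-supplied
constants only.
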