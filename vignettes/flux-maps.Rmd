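---
title: "Flux maps: model, validation and rendering choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux maps: model, validation and rendering choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmapr)
```

This vignette is the package's account of its science: the graph model and
the per-edge flux equation, what balance validation can and cannot prove,
the parameters that matter, how the synthetic data generator constructs its
ground truth, and the places where a design was genuinely open and a choice
had to be made.

## The bipartite model and the per-edge flux

A reaction such as `Suc -> Fru + Glc` relates more than two species, so a
plain metabolite-to-metabolite graph cannot carry it. The package therefore
uses the standard bipartite representation: one node per metabolite label,
one node per reaction, reactant edges metabolite → reaction and product
edges reaction → metabolite, each with its stoichiometric factor $s > 0$
(non-integer factors allowed). Metabolite nodes additionally carry a
*clone index* so that hub splitting (below) can coexist with the rule that
labels, not node ids, are the user-facing join key.

Flux data enter per reaction: a signed value $v$ for each
(condition, timepoint), optionally a quality $q$. The flux shown on an
edge is

$$ f = |v| \cdot s \cdot w $$

where $w$ is the metabolite's *substance weight* — the number of traced
atoms per molecule (carbon counts for a C-flux map; 1 everywhere for a
mass-flux map). The product form is the only one that makes reaction-level
balance equal to conservation of the traced element: reaction $r$ with
measurement $v$ is balanced iff

$$ \sum_{\text{reactants}} s_i w_i \;=\; \sum_{\text{products}} s_j w_j, $$

and multiplying both sides by $|v|$ gives precisely inflow = outflow of
per-edge fluxes at the reaction node. The sign of $v$ never enters $f$; it
is consumed by *direction adaptation*: a negative measurement reverses the
reaction's edges in the slice's working copy only. The base network is
immutable because different conditions may legitimately disagree about
direction (a TCA-style cycle can run forward, backward, or be broken,
depending on oxygen supply — the built-in `usecase_fba_toy()` reproduces
exactly this pattern).

Zero and missing measurements do not prune edges: the affected edges are
kept and flagged `zero`, rendered dashed at minimum thickness. Slices of a
sparse time course therefore always draw the same topology.

## Balance validation

`validate_reactions()` checks inflow = outflow per reaction node;
`validate_metabolites()` checks the steady-state condition
production = consumption per metabolite *label*, summing over clones.
Validation never throws on unbalanced data — it reports, with residual
`inflow − outflow`, sorted by `|residual|` descending (ties lexicographic).

**What a failed reaction balance means.** For substance fluxes, almost
always a template entry error: a misspelled name (the misspelling either
lacks a weight entry, caught at parse time, or carries a different weight,
caught as imbalance), a glued factor (`2Suc` parses as a *label* with
$s = 1$ — the parser's whitespace rule is deliberate so this typo class
surfaces as a factor-of-two imbalance instead of being guessed away), a
wrong factor, or a missing reactant. For mass fluxes the interpretation is
different: any reaction with unequal stoichiometry-weighted term counts
(e.g. `A + B -> C`) is structurally unbalanceable, and the validator's
verdict set equals exactly that structural set — mass-flux maps are
visualized, not balance-checked.

**Tolerance.** Flux data arrive as finite-precision decimals and the
package's own arithmetic is IEEE double, so the balanced flag uses a
*relative* tolerance: `|residual| ≤ tol · max(inflow, outflow, 1)` with
`tol = 1e-6` by default (CLI-overridable). The floor of 1 avoids a 0/0
decision for zero-flux reactions. The verdict is thus invariant under
rescaling all fluxes by any positive constant, which matters because flux
units are arbitrary (relative units, µmol·h⁻¹, …).

**Zero-flux reactions** would trivially pass 0 = 0 and hide template
errors, so they get a flux-independent structural check of
$\sum s w$ per side instead, reported as a *warning*, never a failure —
there is no measurement to contradict.

**Boundary handling.** Uptaken, excreted and stored metabolites violate
steady state by design. Nothing is auto-exempted — silent exemption rules
create false passes on real data — so exemption is an explicit
`external_labels` argument (CLI `--external`), and exempt entries are
reported but never counted as failures.

## Interaction operators

`rank_by_degree()` orders metabolite labels by total incident edge count —
the list from which currency metabolites (ATP, CO₂) are picked.
`split_label()` replaces an unsplit metabolite node by one clone per
incident reaction (clone indices assigned in ascending reaction-label
order; a metabolite that is both reactant and product of one reaction
yields a single clone carrying both edges). The edge multiset is unchanged,
so *all* flux and balance quantities are invariant — the tests assert
residuals are bitwise identical, not merely close, which holds because
splitting preserves edge enumeration order and therefore floating-point
summation order. `unsplit_label()` is the exact inverse;
`reconnect_label()` builds a connector overlay (one green node plus one
edge per clone) that is a separate object: the base network is never
touched, overlays for several labels coexist, carry no flux, and are
omitted from exports unless explicitly requested.

## Layout

`layout_dot()` emits DOT text and delegates to Graphviz `dot` when it is
on the `PATH`; otherwise (and always under `engine = "builtin"`) it uses a
deterministic layered layout: longest-path ranks on the DAG obtained by
ignoring DFS back edges (deterministic because roots and neighbors are
visited in sorted id order), then three barycenter sweeps for within-layer
order with ties broken by node id. Determinism is a hard requirement — identical
inputs must give byte-identical SVG — which is why the fallback avoids any
randomized refinement. Coordinates follow the screen convention (origin
top-left, y downward, units points), recorded as `x`/`y` attributes in
annotated exports so no flipping step sits between layout and SVG.

## Rendering

* **Thickness** is linear: `max(min_thickness, multiplicator · f)`, with
  `min_thickness = 0.5` pt and `multiplicator = 1` by default. The
  multiplicator is a global gain the user turns until the map reads well;
  linearity keeps ratios of thicknesses equal to ratios of fluxes, which
  is the quantity a flux map is supposed to convey. Log/sqrt scaling is
  deliberately not offered.
* **Quality** maps onto a linear black → red RGB ramp:
  `t = clamp((q − q_low)/(q_high − q_low), 0, 1)`, channel
  `round_half_up(255 t)`, so `q_low` is exactly black and `q_high` exactly
  `rgb(255,0,0)`. Larger quality value = redder, because in both intended
  data kinds the quality is a badness measure (confidence-interval width;
  flux-variability range, where 0 means a fully determined flux and is
  drawn black). `invert_quality` covers score-like data where larger is
  better. Absent qualities render black. Edges inherit the owning
  reaction's color so an `invisible` reaction-node style still conveys
  quality.
* **Arrowheads** are `arrow_ratio` (default 1.5) times the line thickness —
  raising the ratio emphasizes direction over magnitude.
* **Determinism and parse-back.** SVG lengths are printed with exactly 3
  decimals and no timestamps are emitted, so re-export is byte-identical
  and a test can parse stroke widths, dash arrays and fills back out of
  the file and compare them to the styled values (the worst-case
  quantization error is 0.0005 pt). Half-up rounding for color channels
  keeps goldens platform-stable.
* PNG export rasterizes the same geometry at `dpi/72` pixels per point.

## The flux template

The on-disk template is a sectioned CSV (`#METADATA`, `#CONDITIONS`,
`#TIMEPOINTS`, `#WEIGHTS`, `#REACTIONS`, `#FLUXES`) — machine-checkable,
diff-friendly, and carrying all six data groups of a flux experiment; an
equivalent single-sheet xlsx is read through `readxl`. CSV is the
canonical dialect and the only one written. Declaration order of
conditions and timepoints is preserved end-to-end (it is the user's
ordering of slices). Decimals use `.` only; thousands separators are
rejected rather than guessed, and numbers are written in shortest
round-trip plain-decimal form (never exponent notation, which would
collide with the `+` term separator in equations), so write → parse is the
identity to the bit. Substance weight 0 is permitted — a metabolite
carrying none of the traced element, such as ATP in an N-flux map — and
flagged with a warning; its edges then carry zero substance flux.

## The synthetic data generator

`generate_fixture()` is first-class, tested code: it is the package's
ground-truth machine. Balanced fixtures are balanced *by construction*,
not by rejection sampling: weights are drawn (integers 1–12 in
`carbon_like` mode), stoichiometries are derived as weight ratios
($s_p = w_r / w_p$ for a 1→1 conversion, making $\sum s w$ equal on both
sides identically), and measurements are propagated along the topology
(chain, two-branch tree with a drawn split fraction in 0.25–0.75, or
cycle) so that the atom flux through every segment is consistent and every
internal metabolite is exactly at steady state. Residuals on such fixtures
are pure floating-point noise (~10⁻¹⁵ relative), far below the 10⁻⁶
verdict tolerance. Mass-mode fixtures set all weights to 1 and give the
terminal reaction a byproduct so at least one reaction has unequal term
counts, exercising the mass-flux theorem.

Corrupted fixtures inject exactly one error into one reaction and record
the ground truth: `misspell_label`, `glued_stoichiometry` (the generator
first forces that reaction's product factor to exactly 2 so the glue has
something to destroy), `wrong_stoichiometry` (factor doubled), or
`missing_reactant` (the target first gains a balanced ATP/ADP-style
cofactor couple, then loses the ATP term). For the misspelling the
corrupted template also carries a weight entry for the wrong name, with a
different weight — the harder case that parses silently and must be caught
by balance validation; the variant without a weight entry is caught at
parse time and tested separately. The master property tying the modules
together: balanced fixtures always validate clean, corrupted fixtures fail
at exactly the recorded reaction — the test suite asserts this over 200
seeded fixtures of 3–30 reactions, and `scripts/acceptance.R` recomputes
it from scratch.

Two fixed toys emulate the intended use-case shapes: `usecase_seed_toy()`
(two conditions, carbon weights, confidence qualities, yellow starch/lipid
sinks receiving 70/30 vs 30/70 of the entering hexose-phosphate carbon —
the 70/30 choice is a designed-in contrast, large enough to be obvious in
a rendered comparison) and `usecase_fba_toy()` (three oxygen conditions,
unit weights, variability qualities, a cycle that reverses and breaks
across conditions, and an uptake reaction with quality exactly 0).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: realistic network size and connectivity (real
central-metabolism maps have hundreds of reactions and much higher hub
degrees), measurement noise (generated fluxes are exactly consistent;
real ¹³C fits are not, and will show small nonzero residuals everywhere
rather than a clean single-reaction signal), compartment semantics beyond
label suffixes, and cofactor-rich stoichiometry. The validator's
*localization* of an error to one reaction is crisp on fixtures because
exactly one error is injected; multiple interacting template errors can
mask or smear each other.

## Numerical and degenerate-input choices

* Relative balance tolerance `1e-6`, floor `max(·, ·, 1)`; verdicts are
  scale-invariant.
* Color channels round half-up; SVG lengths 3 decimals; template numbers
  shortest-round-trip decimals.
* Degenerate quality range (`q_low = q_high`) renders all black with a
  warning rather than dividing by zero; an all-equal automatic range falls
  back to `(0, 1)`.
* Empty experiments cannot build networks (`empty_network`); a cycle needs
  ≥ 2 reactions, a branch ≥ 3 (`spec_error`).
* Kind-less network input (plain GML) is classified only when a
  two-coloring exists *and* supplied reaction labels identify one side;
  anything else is a `bipartite_inference_error` — misclassification would
  silently corrupt balance validation, so the package never guesses.
* Missing stoichiometries default to 1 with a warning for GML/SIF (the
  equation parser's default); for SBML the default of 1 is the standard's
  own and is applied silently.
* GraphML output is checked as well-formed XML with the correct namespace
  and for re-readability; full XSD validation is not attempted because the
  official schema pulls in remote imports.

## Test and acceptance problem sizes

The randomized suites use chains, branched trees and cycles of 3–30
reactions, 200 seeds for the balanced/corrupted master property, 50 for
the mass-flux theorem, and a few dozen for splitting, direction and
round-trip properties — sizes chosen so the whole suite exercises every
code path many times while remaining a sub-minute, single-CPU run.

## Known limitations

* No flux estimation: the package visualizes and validates given fluxes;
  it does not compute them.
* Label-based matching between template and network reactions; set-based
  (reactant/product) matching would catch renamed-but-identical reactions
  and is a possible extension. Conflicting topologies under one name are
  at least detected (`topology_conflict`).
* One substance weight per metabolite per experiment (no per-timepoint
  weights).
* xlsx templates are read, not written; CSV is the canonical dialect.
* The built-in layout is serviceable, not Graphviz-quality; for
  publication figures install Graphviz and use `engine = "dot"`.
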