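# fluxmapr

Flux maps on bipartite metabolic networks: structured flux-data import,
reaction- and metabolite-level balance validation, and quantitative network
rendering.

## The problem

Metabolic flux studies — ¹³C labelling experiments, computed carbon flux
distributions, flux balance analysis (FBA) predictions — produce one signed
rate *v* per biochemical reaction, per experimental condition and time
point, often with a per-reaction quality value *q* (a confidence interval
width, or the flux range from flux variability analysis). Interpreting such
data requires seeing it on the network: which routes carry material, in
which direction, how routes differ between conditions, and where the
numbers cannot be trusted. It also requires catching the entry errors that
plague hand-built flux templates — misspelled substance names (`Sucr` for
`Suc`), stoichiometric factors glued to a name (`2Suc` for `2 Suc`),
missing factors or missing reactants.

`fluxmapr` is a toolkit for exactly this workflow, aimed at systems
biologists who have flux values (measured or simulated) and want validated,
quantitative, comparable flux maps without a GUI: everything is a plain R
function plus a thin `fluxmap` command-line front end.

## The model

Reactions are hyperedges, so the network is the standard **directed
bipartite graph**: one node per metabolite, one node per reaction, reactant
edges metabolite → reaction and product edges reaction → metabolite, each
edge carrying its stoichiometric factor *s*. Each metabolite has a
**substance weight** *w* — the number of traced atoms per molecule (e.g.
carbon count); setting every *w* = 1 turns the map into a **mass-flux**
map (molecules per time instead of atoms per time).

The per-edge flux drawn as edge thickness is

```
f = |v| · s · w
```

and the sign of *v* sets the direction: a negative measurement reverses all
edges of its reaction within that slice of the data. Reactions measured as
0, or not measured in a given (condition, timepoint) slice, keep their
edges as dashed zero-flux lines, so sparse data never changes the drawn
topology.

With this definition, **reaction balance** — the sum of ingoing per-edge
fluxes into a reaction node equals the sum of outgoing ones — is exactly
conservation of the traced element, and a violated balance localizes a
template error to one reaction. **Metabolite balance** is the steady-state
condition production = consumption per metabolite label; boundary
metabolites (nutrient uptake, excreted or stored products) are exempted via
an explicit external list. In mass-flux maps any reaction whose
stoichiometry-weighted substrate and product counts differ can never
balance; the validator reports exactly that set.

Beyond mapping and validation the package provides the interaction
operators of flux-map exploration as pure graph transformations: splitting
of high-degree currency metabolites (ATP, CO₂, …) into one clone per
reaction, temporary green connector overlays re-linking the clones of a
label, a deterministic layered (DOT-style) layout with optional delegation
to Graphviz, and rendering to SVG/PNG plus attribute-annotated GML/GraphML.

## Worked example

A built-in two-condition ¹³C-style toy models seed metabolism: condition
`A` stores mainly starch, condition `B` mainly lipids.

```r
library(fluxmapr)

toy <- usecase_seed_toy(1)
toy$experiment
#> <flux_experiment>
#>   conditions: A, B
#>   timepoints: t1
#>   9 metabolites (weights in [1, 12]), 7 reactions, 14 measurements

s <- map_slice(toy$network, toy$experiment, "A", "t1")
s
#> <flux_map_slice> condition 'A', timepoint 't1': 16 edges (0 zero-flux)

validate_slice(s, external_labels = toy$external_labels)
#> balance report: condition 'A', timepoint 't1' (tolerance 1e-06)
#> all balanced

rank_by_degree(toy$network)
#>    label degree
#> 1   HexP      4
#> 2  AcCoA      2
#> ...
```

Every reaction conserves carbon (`all balanced`): e.g. sucrose cleavage
`Suc -> Fru + Glc` carries 12 carbons in and 6 + 6 out. The degree ranking
identifies `HexP` as the hub you might pass to `split_label()` before
layout. Rendering the two conditions:

```r
lay <- layout_dot(toy$network, engine = "builtin")
sty <- flux_style(multiplicator = 3, quality_mode = "red_graduation")
for (cond in c("A", "B")) {
  sl <- map_slice(toy$network, toy$experiment, cond, "t1")
  export_svg(style_slice(sl, lay, sty), paste0("map_", cond, ".svg"))
}
```

In `map_A.svg` the edge into the yellow `starch` sink is 2.33× thicker
than in `map_B.svg` (8.4 vs 3.6 carbon-flux units: 70% vs 30% of the 12
entering carbons), and the lipid route shows the reverse contrast. Redder
edges mark less certain measurements (black = certain, pure red = the
upper end of the configured quality range).

The same pipeline runs from a shell:

```sh
fluxmap=inst/cli/fluxmap.R
Rscript $fluxmap fixtures --spec seed-toy --seed 1 --out toy/
Rscript $fluxmap validate --network toy/network.gml --data toy/template.csv \
        --all-slices --external "$(paste -sd, toy/external.txt)"   # exit 0
Rscript $fluxmap render --network toy/network.gml --data toy/template.csv \
        --condition A --timepoint t1 --multiplicator 3 --quality red --out map_A.svg
```

`fluxmap validate` exits 0 when everything balances and 3 otherwise, so it
drops straight into shell pipelines and CI checks of curated datasets.

## File formats

* **Flux template** — a sectioned UTF-8 CSV (or single-sheet xlsx, read
  via `readxl`) with header rows `#METADATA`, `#CONDITIONS`,
  `#TIMEPOINTS`, `#WEIGHTS`, `#REACTIONS` (name, equation), `#FLUXES`
  (reaction, condition, timepoint, value, quality; quality optional).
  Reaction equations use `->`/`=>`/`→` arrows, `+`-separated terms and
  whitespace-separated stoichiometries.
* **Networks in** — SBML (Level 2/3 core subset), GML, GraphML, and a SIF
  dialect with one tab-separated edge per line, interaction `rp`
  (reactant → reaction) or `pr` (reaction → product) and an optional
  fourth stoichiometry column.
* **Out** — GML/GraphML with all visual attributes, deterministic SVG,
  PNG.

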