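---
title: "A plain-text language for reaction-network models and its SBML mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A plain-text language for reaction-network models and its SBML mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnscript)
```

## Why a text language

SBML is the exchange standard for biochemical network models, but its XML
serialization is verbose and painful to inspect or edit by hand. rxnscript
implements a compact, line-oriented text language in which one line expresses
one modelling concept, together with a lossless bidirectional bridge to SBML
Level 3 Version 2 (Core plus the Flux Balance Constraints and Distributions
packages, and a minimal subset of Layout). The pipeline is the classic
parser / internal-representation / serializer design: text is parsed into an
in-memory model, which can be serialized back to canonical text or exported
to SBML; SBML documents import into the same representation.

```{r}
res <- rxn_parse("S1 -> S2; k1*S1")
res$model
```

## Implicit declaration

The defining convenience of the language is that explicit type declarations
are optional. A single reaction line declares everything it mentions: ids on
reaction sides become species, ids referenced only in math become
parameters, an id in coefficient position becomes a named stoichiometry, and
`in <id>` declares a compartment. Promotion is deterministic: an id's final
kind depends only on the set of structural roles it appears in, never on
statement order, because a math reference (the weakest role) never demotes a
structural kind, and two conflicting structural roles are an error rather
than a race. Explicit declarations (`species`, `compartment`, `parameter`,
`const`, a `$` boundary prefix) pin a kind; promoting away from an explicit
declaration is an error.

## Statement forms

* Reactions: `[id:] reactants -> products [; rate]`, sides are
  `+`-separated `[coefficient] species` terms; coefficients are positive
  numbers or named-stoichiometry ids. Unlabeled reactions receive generated
  ids `_J0, _J1, ...` (events `_E0, ...`); generated labels are ignored by
  the semantic-equality oracle.
* Events: `[id:] at <trigger>[, priority = <expr>]: target = expr, ...`.
* Rules: `x := expr` (assignment), `x' = expr` (rate),
  `[id:] 0 = expr` (algebraic — recognized only by the literal `0` on the
  left).
* Initialization: `x = <number>` sets an initial value; `x = <expr>`
  with anything non-constant (including distribution draws) becomes an
  initial assignment.
* Inequalities: `10 < J2 < 50` declares a parameter constraint; the same
  syntax on a reaction id is a flux bound (`0 <= R1 <= 1000`; equal bounds
  fix a flux). This is deliberately the only constraint/flux-bound surface.
  A bound written before its reaction is declared is reclassified after the
  parse, so statement order stays immaterial. Strict inequalities on flux
  bounds are accepted with a warning and treated as non-strict.
* Dot properties: `x.mean = 10`, `x.standardDeviation`, `x.variance`,
  `x.confidenceInterval = {lo, hi}` attach uncertainty statistics;
  `x.position = {50, 40}`, `x.size`, reaction `centroid` and `curvePoints`,
  `model.layout = on` and `model.styleTemplate = "name"` carry diagram
  geometry. Uncertainty statistics are metadata only — they are not
  referencable inside math and do not affect any computation.
* Annotations: `S1 is "http://identifiers.org/..."` attaches a CV term;
  `model notes "markdown"` attaches human-readable notes (at most one per
  element; a later one wins with a warning).
* `substanceOnly S1, S2` marks species as amounts; it may appear before or
  after first use, and flips the meaning of `S1 = 10` from initial
  concentration to initial amount.

Comments are `//` and `/* ... */`. Statements end at newlines or `;`, except
the `;` separating a reaction from its rate law, which is disambiguated by
the presence of an arrow in the clause. Both the ASCII `->` and the
typographic minus arrow are accepted on input; output always uses `->`.

## Expressions

Expression trees cover arithmetic with conventional precedence
(`^` right-associative and tighter than unary minus), comparisons, boolean
connectives (`and/or/not` canonical on output, `&&/||/!` accepted),
standard math functions, the `time` csymbol, `rateOf(<id>)` (argument must
be a bare identifier), and distribution draws with pinned two-parameter
forms: `normal(mean, sd)`, `uniform(lo, hi)`, `lognormal(mu, sigma)` on the
log scale, `exponential(rate)`, `gamma(shape, scale)`, `poisson(rate)`,
`binomial(n, p)`. Numbers render as the shortest decimal that round-trips
to the same double, so serialization is byte-stable.

`math_eval()` evaluates trees under bindings; draws consume R's RNG stream,
so `set.seed()` gives reproducible samples, and parameter domains are
checked at evaluation time. The two-event priority race is the executable
demonstration: with priorities drawn from `uniform(0,1)` and `uniform(0,2)`,
the wider-distribution event wins with probability
$1 - \tfrac12\cdot\tfrac12 = \tfrac34$ (the narrow draw wins only when the
wide draw lands below 1 *and* below the narrow draw):

```{r}
priority_race(20000, seed = 1)
```

## SBML mapping choices

Where the language is silent, the exporter applies fixed, documented
defaults so that translation is deterministic and round-trips are exact:

* Reactions are exported `reversible="true"`; the arrow carries no
  reversibility marker and no alternate arrow is provided.
* Event attributes default to `persistent="true"`, `initialValue="true"`,
  `useValuesFromTriggerTime="true"`; there is no surface syntax to change
  them.
* Species without a compartment are placed in an auto-created
  `default_compartment` (size 1), which the importer removes again.
* Flux bounds become constant parameters `<rid>_lb` / `<rid>_ub`
  (collisions resolved by numeric suffix) referenced from the reaction's
  fbc attributes; one-sided bounds import as infinite.
* Constraints encode as the conjunction of two comparisons, `lt` vs `leq`
  preserving strictness.
* Objectives fill the fbc objective list with the first objective active.
* Named stoichiometries become identified species references; their numeric
  value travels as an initial assignment.
* Uncertainty statistics become distrib `uncertParameter` children
  (`uncertSpan` for confidence intervals, which require both ends).
* CV terms become RDF bags under biology qualifiers for elements and model
  qualifiers for the model; the provenance keywords `origin`, `created`
  and `creator` are emitted in the model-qualifier namespace as well, a
  pragmatic extension of that vocabulary.
* Notes are embedded verbatim inside a preformatted XHTML block; no
  markdown conversion is attempted, so the importer recovers the exact
  text.
* Package namespaces are declared only when used; a model touching no fbc,
  distrib or layout feature exports as pure Core.

Layout is stored, not computed: positions and sizes map to glyph bounding
boxes (species, compartment and reaction glyphs, general glyphs for other
elements) and `curvePoints` to line segments. A missing size defaults to an
80×40 box, and `model.layout = on` with no coordinates places species on a
deterministic grid (150-unit pitch, five per row, declaration order). Both
defaults are applied when the model is finalized — at parse or import time,
not at export — so that a model and its SBML round-trip compare equal and
the generated geometry is itself subject to the losslessness checks. The
style template name is pass-through text stored in a small annotation on the
layout.

## Canonical serialization and the losslessness oracle

The serializer emits a fixed section order with canonical whitespace, and
orders the sections that the SBML bridge regroups (flux bounds, uncertainty,
annotations, layout) by symbol-table position rather than statement order.
Consequently `serialize(parse(serialize(parse(t))))` is byte-identical to
`serialize(parse(t))` for every accepted `t`, and the second-generation text
after a full text→SBML→text trip equals the first. Comments are dropped on
canonicalization. Semantic equality — the oracle behind all round-trip
claims — compares every collection as a multiset, ignoring statement order,
generated labels and the explicit/implicit declaration distinction.

## The fixture generator

`rxn_generate()` produces seeded random models across a feature-flag lattice
(events, rules, constraints, fbc, distrib, layout, annotations, named
stoichiometries, substanceOnly), with small species/reaction counts and
bounded expression depth. It emulates the *structural* variety of hand
written models — every construct the language supports, in random
combination — but not their numerical realism: rate constants are arbitrary
positive decimals, networks are random hypergraphs without conservation
structure, and no kinetic plausibility is attempted. Passing round-trip
suites on this corpus therefore demonstrates syntactic and structural
losslessness, not simulation correctness; simulation is explicitly out of
scope (there is no ODE or FBA solver here). The generator avoids strict
flux-bound inequalities and quotes inside notes so that round-trips stay
byte-stable.

The shipped suites use problem sizes chosen to exercise the space densely
while staying desk-scale: 500 generated models for the text and SBML
round-trip properties, 1000 random trees for the MathML identity, 100,000
draws per distribution for the moment checks (asserted within four standard
errors of the closed forms), 100,000 trials for the priority race, and 1000
mutated inputs for parser crash-freedom.

## Numerical and degenerate-input choices

* Shortest-round-trip decimal formatting everywhere; integers print without
  a decimal point.
* `Inf` is accepted as a numeric literal so that one-sided flux bounds
  imported from SBML (`INF` parameter values) re-serialize losslessly.
* Duplicate flux bounds for one reaction: the later statement wins.
* Duplicate notes for one element: the later wins, with a warning.
* Empty or whitespace-only input is a valid empty model; a malformed
  statement yields a diagnostic (`severity`, 1-based `line`, message) and
  the parser continues with the next statement. Arbitrary byte input —
  including invalid UTF-8 — never crashes the parser.
* `time` is reserved and cannot be declared as a symbol.

## Known limitations

Submodel instantiation, unit definitions, modifier species, local
parameters, event delays, `piecewise`/`lambda`/`factorial` math, SBML
Levels 1–2 and the qual/comp/multi/groups packages are out of scope; on
import every such construct is recorded in the `dropped` table rather than
silently lost. Render-package styling beyond the template name is not
stored. The importer assumes documents roughly follow the L3V2 schema; it
is forgiving about missing optional attributes (applying the same defaults
as the parser, so text-origin and SBML-origin models compare equal) but is
not a validator — `sbml_check()` covers structural essentials only.
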