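---
title: "Visualizing multi-row omics tables on networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing multi-row omics tables on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovglyph)
library(tibble)
```

## The data model

Omics measurements are frequently *site-level*: a phosphoproteomics
experiment reports one row per phosphorylation site, so one protein — one
network node — owns several rows. `ovglyph` keeps that structure intact.
An `ov_table` is an ordered, typed table (types restricted to integer,
float, boolean, string; cells may be missing) in which a key column links
any number of rows to one node. Filtering only *hides* rows: the visible
row set is an index vector alongside the full data, so operations that must
ignore filtering (per-node connected-row counts) read the full table while
visual operations can restrict themselves to visible rows.

A connection binds one table to one network through a pair of key columns.
The asymmetry is deliberate: one table may decorate several networks, but a
network is decorated by at most one table — reconnecting requires an
explicit `replace`, so a network's glyphs always have a single provenance.

## Glyph semantics

A **pie** draws the values of one column as equal-angle slices inside the
node, one slice per connected row, in table row order (no sorting, ever —
row order is the one the scientist curated). A **donut** draws concentric
rings around the node. Under the default *ring is column* orientation there
is one ring per value column — the first listed column is the innermost
ring — and one slice per connected row; *ring is row* transposes the
layout (one ring per row, one slice per column). The transposition is exact:
slice $(r, s)$ of one orientation equals slice $(s, r)$ of the other, a
property the test suite asserts on randomized cases.

Angles: slice $i$ of $k$ spans
$[\,a + 360(i{-}1)/k,\; a + 360i/k\,)$ degrees, where $a$ is `arcstart`
(default 0 = the 3 o'clock position; angles increase clockwise — screen
coordinates have the y axis pointing down, so this is the usual reading
direction). Computing each boundary directly from $i/k$ rather than
accumulating widths makes the final slice close the ring at exactly
$a + 360$ and per-ring spans telescope to exactly 360°.

Degenerate inputs: a node with zero connected (or zero visible, under
`filtered_only`) rows gets no chart at all rather than an empty one; a
missing cell keeps its angular span and takes the missing-value color
(default `#CCCCCC`), so rings of one donut never shift out of alignment.

## The filter engine

Filters are trees of typed criteria under `AND`/`OR`. The textual grammar —
`(column,OPERATOR[,operand])` for leaves, `(AND,expr,expr,...)` /
`(OR,...)` for connectives — is deliberately comma-and-parenthesis only,
so column names with spaces need no quoting (a column name runs to the
first comma). Three semantic decisions were genuinely open and are fixed
here as follows:

* **Missing cells compare false.** Every operator except `NULL`/`NOT_NULL`
  evaluates to false on a missing cell — three-valued logic collapsed to
  false at the leaf. `NOT_EQUALS` on a missing cell is therefore *false*,
  not true; `NULL` and `NOT_NULL` are the only detectors of missingness.
  This keeps negation pairs (`LOWER` vs `GREATER_EQUALS`, …) exact
  complements on complete rows, which the test suite checks as a De
  Morgan-style duality.
* **`CONTAINS` is case-sensitive**, a fixed substring test.
* **`MATCHES` is anchored**: the regular expression must match the whole
  cell. Unanchored behavior is recoverable by writing `.*pat.*`; the
  converse would not be expressible.

There is no `NOT` connective; negation lives in the operator pairs. The
engine is validated against a brute-force recursive evaluator that
materializes truth values row by row.

## Type inference and coercion

File import inspects at most the first 100 non-missing cells of a column
(the `sample_limit` parameter) and picks the narrowest type — in the order
integer, float, boolean, string — that parses all of them. The bounded
sample is a feature, not a shortcut: it makes import time independent of
file length. Its cost is visible and intentional: a column whose first 100
cells are integers is an integer column even if cell 120 is not, and that
cell becomes missing during coercion. Aborting the import instead would
discard an entire multi-site table for one stray cell. Missing values on
input are the empty string and `"NA"` (configurable).

Keys match by *canonical text rendering*: integers (and whole doubles)
render without a decimal point, booleans as `true`/`false`, other doubles
with 17 significant digits (the shortest form that survives a text round
trip exactly). So an integer key `1` matches a node key `"1"`, and
serialized tables re-import bit-identically. When a key value occurs on
several nodes, all of them receive the same connected rows — the symmetric
choice, since nothing distinguishes the duplicates.

## Color mapping

The continuous mapping takes three anchors (minimum, middle, maximum
values, each with a color) and interpolates linearly **per sRGB channel**
within each segment. sRGB is the space chart renderers blend in; a
perceptually uniform variant could be added behind the same interface, but
matching the downstream renderer exactly was judged more important than
perceptual linearity. Ordering of the checks matters at the edges and is
fixed as: clamp first (`v ≤ min`, `v ≥ max`), middle anchor second
(`v = mid` returns the middle color bit-exactly), interpolation last. With
a degenerate segment (`min = mid` or `mid = max`) the empty segment is
unreachable and its boundary maps to the shared anchor color via the clamp.

Default bounds are symmetric about zero:
$M = \max(|\min v|, |\max v|)$, bounds $(-M, 0, M)$ — the natural scale
for log-ratios, where equal color intensity should mean equal fold change
in either direction. All-missing or all-zero input has no usable scale and
raises an error prompting explicit bounds.

Downstream chart renderers anchor their gradients at zero. To serve them,
emitted value lists are shifted by the middle anchor
($v' = v - \mathrm{mid}$, bounds likewise), which composes exactly with a
zero-centered colorer — the tests assert
`color(v, mapping) == color(v - mid, shifted mapping)` on random cases.
Only the emitted copies shift; the source table never changes.

Bundled palettes (qualitative `Paired`, `Set1`, `Dark2`; diverging `RdBu`,
`BlueWhiteRed`; sequential `Viridis`) are literal hex lists, so color
output is reproducible with no runtime palette dependency. A qualitative
palette shorter than the value set cycles, with a warning rather than an
error — a 13th category in a 12-color palette should degrade gracefully
during exploration.

## Chart strings, node columns, sessions

Each chart serializes to a one-line description string (documented in the
README) stored in the node table, alongside one value-list column per ring
— the attribute layout a declarative chart renderer consumes. All derived
columns live under the `ov::` namespace prefix so they are easy to
recognize and to strip; disconnecting a network removes exactly these
columns and provably restores the prior node table. Re-applying a
visualization first removes its namespace columns, then writes fresh ones:
emission is idempotent, never additive.

Angles are *not* stored in the chart string; the parser recomputes them
from `arcstart` and the slice count by the same closed form the builder
uses, which is what makes the round trip structurally exact. Reserved
characters in labels and node ids are percent-encoded; an empty field
decodes to a missing value (a label that is literally the empty string is
therefore not distinguishable from an absent one — a documented
limitation).

Sessions persist as versioned JSON with tables embedded as TSV blocks (so
session files diff cleanly under version control). Connections and
visualizations are stored as *records*, not materialized state: loading a
session re-runs the connect and visualization steps, which both recreates
the derived columns and re-validates referential integrity — a session
file in which one network is connected to two tables fails to load.
Legends are likewise rebuilt from their stored parameters and the active
visualizations, so a loaded legend can never disagree with the charts.

## Rendering

SVG output was chosen over raster as the primary format: it is lossless,
text-diffable, and lets tests assert structure (exactly one `<path>` per
slice; the legend group contains all and only legend primitives). Node
positions come from, in order of precedence: an explicit layout table,
`x`/`y` node attributes, or a seeded force-directed layout
(`igraph::layout_with_fr`). Every coordinate is formatted with a fixed
`%.3f`, so a fixed seed yields byte-identical documents — determinism is
asserted by rendering twice and comparing bytes. Arc spans of 180° or more
are split into sub-arcs, so a single-slice ring (a full circle) still
renders as one path element and the slice-count invariant holds. Label
collisions are not resolved; labels sit at the slice mid-angle just
outside the outermost ring.

Legend geometry (swatch size, margins, block width) is a set of fixed
constants; only title, font, font size and position (eight compass
placements, `EAST_TOP` by default) are user-facing. Gradient-bar tick
labels print the anchor values to at most 4 significant digits and
otherwise verbatim.

## The command surface

Every subcommand (`load`, `filter`, `connect`, `retrieve`,
`viz apply {inner|outer} {continuous|discrete}`, `legend draw`, `render`,
`session save/load`) is a thin adapter over exactly one library operation;
no logic exists only in the command layer, which the end-to-end tests
exercise by driving the complete workflow through printed command strings.
Flags are `key=value` (matching automation-style invocations; `--key
value` also works). `inner` denotes the pie (drawn inside the node),
`outer` the donut (drawn around it). Network retrieval goes through a
client interface — `map(identifiers, taxon)` then `network(ids, cutoff)` —
with an HTTP implementation for live use and a deterministic offline mock
that records the arguments it receives; all tests use the mock, so the
suite runs without any network access, and live retrieval results (which
depend on the remote database version) are deliberately outside the tested
surface.

## The synthetic-data generator

`ov_fixture_table()` emulates the *shape* of a site-level quantitative
comparison table: accession-like keys (`P` + five digits, exercising the
case-insensitive "uniprot" column detection), integer site positions,
two log-ratio columns named like disease-versus-healthy comparisons drawn
from a centered normal (sd 2 by default — log\(_2\)-ratios of that spread
are typical for strong differential phosphorylation), an adjusted p-value
column in which half the rows sit at or below 0.01, and a three-level
cluster label. Site counts per protein follow a shifted Poisson (minimum
1), so every protein has at least one row and the multi-row-per-node
property is always exercised. The default of 40 proteins with a mean of 2
sites keeps every test and the acceptance script comfortably fast while
still producing nodes with 1–6 slices.

What the generator does **not** emulate — and what passing tests therefore
do not show — includes: correlation between the two comparisons (real
disease-versus-two-controls designs are strongly correlated), realistic
p-value/effect-size dependence, heavy-tailed site counts, and identifier
mapping failures. The matched network generator is Erdős–Rényi with one
node per distinct key; real interaction networks are scale-free and
incomplete. These fixtures validate the *mechanics* (joins, filtering,
geometry, serialization), not biological plausibility.

## Problem sizes and determinism in the test suite

The randomized suites run on the order of $10^4$ elementary cases: ~100
random tables of 12–15 rows against the brute-force filter evaluator,
~45 random key sets against the nested-loop join, ~260 random rings for
angle closure, ~110 random chart strings for round-trip identity, and a
few thousand random values for clamping, monotonicity and bound symmetry —
all under fixed seeds, so failures are reproducible. The full command
workflow runs on generated fixtures in a temporary directory and finishes
in seconds.

## Known limitations

* Filter operands cannot contain commas or parentheses (the grammar has no
  quoting); such values can still be matched with `MATCHES` and character
  classes.
* `CONTAINS` case sensitivity and anchored `MATCHES` are this package's
  documented choices; other tools' filter dialects may differ.
* Slice direction (clockwise) and the sRGB interpolation space are
  documented conventions, not universal standards.
* Labels are drawn without collision handling; dense nodes overlap.
* The session format embeds full tables; very large tables make large
  session files (streaming or referencing external files is future work).
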