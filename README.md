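# ovglyph

Per-node pie and donut glyphs for long-format omics tables on molecular
networks.

## The problem

Standard network tools attach **one** row of data to each node. Omics data
rarely come that way: a phosphoproteomics experiment yields several rows per
protein — one per modification site — and the same happens with peptides,
splice isoforms, or repeated conditions. `ovglyph` keeps such tables in
their natural long format (several rows sharing one node key), connects
them to networks, and draws every connected row as one slice of a glyph on
its node:

* **pie** (inner) — slices inside the node, one value column, one slice per
  connected row;
* **donut** (outer) — concentric rings around the node; by default one ring
  per value column (the first listed column is the innermost ring) and one
  slice per connected row ("ring is column"); "ring is row" transposes
  this.

It is aimed at anyone who wants per-site/per-condition values visible *on*
a protein-interaction or other molecular network, scriptably and offline.

## The method

* **Typed import.** Column types are inferred from the first 100
  non-missing cells, narrowest first (integer → float → boolean → string);
  cells that later fail the inferred type become missing, never dropping a
  row.
* **Filtering hides, never deletes.** A filter is a boolean formula over
  typed criteria — `EQUALS`, `NOT_EQUALS`, `NULL`, `NOT_NULL` for all
  types; `CONTAINS`, `NOT_CONTAINS`, `MATCHES` for strings; `LOWER`,
  `LOWER_EQUALS`, `GREATER`, `GREATER_EQUALS` for numbers — combined with
  `AND`/`OR`. Rows failing the filter are hidden; all bookkeeping that
  should ignore filtering (per-node connected-row counts) does.
* **Connections.** A table row links to a node when its key column equals
  the node's key attribute (text equality after canonical rendering). A
  table may serve several networks; a network is connected to at most one
  table. A pluggable client can retrieve a protein network for the table's
  identifiers (defaults: human, taxon 9606, confidence cutoff 0.40, query
  column found by a case-insensitive search for "uniprot").
* **Color mapping.** Discrete value→color assignments, or a continuous
  three-anchor gradient: values *v* map linearly per sRGB channel within
  [min, mid] or [mid, max]; `v ≤ min` and `v ≥ max` clamp to the boundary
  colors; `v = mid` hits the middle color exactly. Default bounds are
  symmetric: `max = max(|data min|, |data max|)`, `min = −max`, centered on
  zero. For emission to zero-anchored chart renderers, values and bounds
  are shifted by the middle anchor (`v′ = v − mid`); source tables are
  never modified.
* **Charts and legends.** Slices partition the circle into equal angles
  starting at `arcstart` (0° = 3 o'clock, clockwise); per-ring spans sum to
  exactly 360°. Chart descriptions are stored as one-line strings (grammar
  below) plus per-ring value columns, all in the `ov::` node-table
  namespace. Legends are grouped primitives — swatches, a min/mid/max
  gradient bar, the donut ring-order list — rendered into the SVG.

## Worked example

```r
library(ovglyph)

tab <- ov_fixture_table(n_proteins = 8, seed = 42)   # synthetic site table
tab <- ov_apply_filter(tab, "(Adj p-value,LOWER_EQUALS,0.01)")
#> rows: 22 before filtering, 9 after

conn <- ov_retrieve_string_network(tab, ov_string_query(filtered_only = TRUE))
conn
#> <ov_connection> table 'synthetic sites' (UniProt) <-> network
#>   'retrieved network' (query term): 6/6 nodes with rows

cfg <- ov_viz_config("donut", c("EOC vs FTE", "EOC vs OSE"),
                     ov_continuous_mapping(-8, 0, 8),
                     label_column = "AA position", filtered_only = TRUE)
conn <- ov_apply_viz(conn, cfg)
glance(conn$charts$donut[[1]])
#> # A tibble: 1 × 5
#>   node       style n_rings n_slices arc_start
#>   <chr>      <chr>   <int>    <int>     <dbl>
#> 1 str.P61413 donut       2        2         0

leg <- ov_build_legend(cfg, title = "log-ratios", position = "EAST_TOP")
svg <- ov_render_svg(conn$network, charts = conn$charts$donut,
                     legend = leg, seed = 1)
```

The filter message says 9 of the 22 sites pass the significance cutoff;
the connection report says all 6 retrieved nodes carry table rows; the
glance shows one node's donut: two rings (one per comparison column, the
first listed innermost), one slice per significant site of that protein.
`ov_default_continuous_bounds(c(-3, 5))` returns `(-5, 0, 5)` — the
symmetric zero-centered default scale.

The same workflow is scriptable through the `ov` command surface
(`exec/ov`, or `ov_run_command()` in R):

```sh
ov load file=sites.tsv
ov filter filter="(Adj p-value,LOWER_EQUALS,0.01)"
ov retrieve taxonID=9606 filteredOnly=true queryColumn="UniProt"
ov viz apply outer continuous attributes="EOC vs FTE,EOC vs OSE" \
   labels="AA position" filteredOnly=true rangeMin=-8 rangeMax=8 \
   chartSettings="arcstart:0,labelsize:15"
ov viz apply inner discrete attributes="Cluster" labels="AA position" \
   colorMapping="A:#1F78B4,B:#FF7F00,C:#E31A1C" filteredOnly=true \
   chartSettings="arcstart:0,labelsize:15"
ov legend draw position="EAST_TOP" title=""
ov render file=out.svg
```

State persists between invocations in a versioned JSON session file
(`--session path`, default `ov_session.json`).

## Chart-string grammar

One line per chart, stored in the `ov::<style> chart` node column:

```
style:<pie|donut>|node:<enc>|arcstart:<num>|labelsize:<num|empty>|ring:<slices>|ring:...
slice := <#RRGGBB>;<value,enc>;<label,enc>     slices separated by ","
```

`enc` percent-encodes `| , ; : %` and space; an empty field is a missing
value. Slice angles are not stored: they are recomputed from `arcstart`
and the slice count, exactly as they were derived. `ov_parse_chart_string()`
inverts `ov_emit_chart_string()`.

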