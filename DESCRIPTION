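Package: ovglyph
Title: Per-Node Pie and Donut Glyphs for Long-Format Omics Tables on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Import delimited data tables in which several rows refer to the
    same gene or protein (phosphorylation sites, peptides, isoforms, or
    conditions), filter them with a typed boolean-formula engine, connect them
    to molecular networks via matching key columns, and render the connected
    values as pie (in-node) and donut (around-node) glyphs with automatically
    generated legends. Values map to colors through discrete assignments or
    continuous minimum/middle/maximum gradients with clamping and
    mid-centering. Networks can be read from SIF or GraphML files or retrieved
    from a STRING-like service through a pluggable client. Outputs are SVG
    images, chart description strings compatible in spirit with Cytoscape
    enhancedGraphics, and a JSON session file; an 'ov' command interface makes
    multi-step workflows scriptable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
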