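Package: templater
Title: Automated Extraction of Reaction Templates from Reaction Databases
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines reaction templates from heterogeneous reaction-database
    inputs: structured identifier lists (SMILES/InChI), directories of MDL RXN
    (V2000) files, and CHEMKIN-format mechanisms with identifier comments.
    Reactions are balanced-filtered, atom-atom mappings are computed by a
    built-in minimal-change maximum-common-substructure mapper (or imported
    from pre-mapped RXN files), resonance-structure combinations are selected
    to minimize the reactive-atom count, and symmetric mapping gaps are
    completed heuristically. Per-atom and per-bond changes are detected,
    reactive centers are connected via shortest-path minimum spanning trees,
    and deduplicated, reversibility-annotated templates are formalized as
    SMARTS patterns with recipes and molecular constraints. A template
    application engine supports round-trip validation against the source
    reactions, and a synthetic corpus generator covers the common radical
    pyrolysis and simple organic reaction families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
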