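# templater

Automated extraction of reaction templates from reaction databases and
kinetic networks, in R.

Kinetic model generators (pyrolysis/combustion networks) and retro-synthesis
tools are driven by **reaction templates**: the substructures the reactants
must contain plus a **recipe** of graph edits — bond formations and
scissions, bond-order changes, radical/charge/stereo changes — that turn
matched reactants into products. `templater` mines such templates
automatically from:

* structured identifier lists (one reaction per line, SMILES/InChI),
* directories of MDL RXN (V2000) files, with or without atom-map indices,
* CHEMKIN-format mechanisms whose species carry an identifier comment
  (`C2H5 ! [CH2]C`).

The pipeline is the classic four-block scheme: **database interpretation**
(readers, balance and arity filters) → **atom–atom mapping** (pre-mapped
input, or a built-in exact minimal-change mapper with resonance-combination
selection and symmetry-based gap completion) → **extraction** (per-atom /
per-bond change detection; reactive centers connected by shortest-path
minimum spanning trees; mechanism plausibility; the hydroperoxyl-elimination
four-ring → five-ring mapping correction) → **formalization** (deduplicated,
reversibility-annotated templates as SMARTS with `X`/`v` atom annotations,
recipe, molecular constraints and an empty kinetics placeholder). An
application engine replays any template on new reactants, which is also how
every extracted template is validated round-trip against its source
reaction.

## Worked example

```r
library(templater)

cp  <- generate_synthetic_corpus(60, seed = 42)   # 8 reaction families, mapped
res <- run_pipeline(cp, mapper = "premapped", outdir = "out")
```

The manifest line this prints:

```
parsed 60 | unbalanced 0 | arity 0 | templates 16 (1 reverse, 0 identical)
```

60 balanced reactions collapse to 16 unique templates; one template pair is
linked as mutually reverse (beta scission / radical addition: id 7 and 8
below), and the self-inverse hydrogen transfers link to themselves without
counting as "reverse". The distribution table (`out/distribution.csv`):

```
   id                    class count status reverse_of
1   1 h_abstraction/h_centered     2     ok         NA
2   2 h_abstraction/c_centered     4     ok          2
...
7   7            beta_scission     8     ok          8
8   8                 addition     3     ok          7
...
16 16          hoo_elimination     7     ok         NA
```

One record and its template:

```r
rec <- cp$records[[1]]
#> <rxn_record synth_00001> C + [H] >> [CH3] + [H][H]  [map: 6/6]
tpl <- extract_template(rec)
generate_center_smarts(tpl)
#> [1] "[CX4v4]-[#1X1v1]" "[#1X0v0]"
classify_template(tpl)
#> [1] "h_abstraction/h_centered"
apply_template(tpl, rec$reactants)   # round trip
#> products: [CH3] [H][H]
```

`[CX4v4]` reads "carbon with four neighbors and valence four" (a saturated,
non-radical carbon); `[#1X0v0]` is a free hydrogen atom — the abstracting
radical. The recipe breaks the C–H bond, forms the new H–H bond and swaps
the radical, so applied to `CC + [H]` the same template yields
`[CH2]C + [H][H]`.

A CHEMKIN mechanism goes through the same driver:

```r
res <- run_pipeline(system.file("extdata", "mini_pyrolysis.inp", package = "templater"),
                    format = "chemkin", mapper = "baseline")
```

## Command line

```sh
Rscript inst/cli/templater.R run      --input mech.inp --format chemkin --out out/
Rscript inst/cli/templater.R synth    --n 500 --seed 42 --out corpus/
Rscript inst/cli/templater.R validate --input corpus/
```

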