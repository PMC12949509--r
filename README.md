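# rdm2dpo

Double-pushout reaction rules and atom-to-atom maps from KEGG RCLASS data.

The KEGG reaction database describes the chemical change of a reaction not
by an atom-to-atom map (AAM) but by RCLASS entries: per reactant/product
compound pair, a set of *RDM codes* of the form `R:D:M` listing the
Reaction-center atom, the Difference atoms and the Matched atoms as pairs of
KEGG atom types (`C1a` = the carbon in R–CH3, `C1b` = the carbon in
R–CH2–R, ...), reactant and product side separated by a hyphen. This
encoding is convenient for classification and hard to use for anything
else. `rdm2dpo` reconstructs from it what atom-level models actually need:

* explicit chemical **DPO rules** `L <- K -> R` — spans of labelled graphs
  in which only bonds change, `beta: V(L) -> V(R)` is a bijection and `K`
  is the maximal common context;
* complete **atom-to-atom maps** `alpha: V(G) -> V(H)` for the full
  reaction, together with the **ITS graph** (the union of reactant and
  product graphs under `alpha`, with paired edge labels whose disagreements
  are the reaction center).

Everything is enumerated exhaustively: ambiguous type graphs, alternative
embeddings, and multiple surviving rules or maps are all reported, never
silently resolved. Inconsistent inputs yield a conflict report naming the
clashing atoms. The package is aimed at people building atom transition
networks, isotope-tracing models or graph-grammar models of metabolism who
need KEGG's curated reaction knowledge in an executable form.

The pipeline has five stages, available as R functions and as a thin
command line (`exec/rdm2dpo`): RDM parsing and type-graph expansion
(`parse_rdm()`, `expand_tree()`, `make_pattern_graphs()`), embedding and
pairwise-pattern assembly (`enumerate_embeddings()`, `orient_sides()`,
`assemble_pairwise()`), cross-RCLASS rule reconstruction
(`combine_reaction()`, `balance_test()`), completion of reactions whose
RCLASS coverage is incomplete (`d_subgraphs()`, `match_d_subgraphs()`,
`carboxy_special_case()`, `complete_small_molecule_rule()`), and AAM
completion (`seeded_extension()`, `complete_via_rule_embeddings()`), all on
top of a self-contained DPO rewriting engine (`apply_rule()`,
`its_graph()`, `extract_rule()`). Molecule structures are read from MDL MOL
V2000 or KEGG KCF text; rules are serialized in the three-section GML rule
dialect; maps are written as mapped reaction SMILES plus a JSON pair list.
The 68-entry KEGG atom-type dictionary, including all documented
alternative interpretations, ships as a plain data file
(`inst/extdata/kegg_atom_types.tsv`).

## A worked example

A synthetic cleavage reaction (seed 7): one six-carbon/sulfur molecule
splits into two products, described by two RCLASSes.

```r
library(rdm2dpo)
fx <- make_fixture(7, template = "cleavage")
fx$record
#> <reaction RXN_cleavage: S001 => P001 + P002; 2 RCLASS link(s)>
fx$codes
#> $RCX_S001_P001: "C2b-C2a:C1b-*:C2c-C2c"
#> $RCX_S001_P002: "C1b-C1a:C2b-*:C1a-C1a"
```

The first code says: the reaction-center atom is a vinylic CH (`C2b`) that
becomes a terminal CH2= (`C2a`); it loses a CH2 neighbor (`C1b`, absent on
the product side, hence the `*`); its substituted vinylic neighbor (`C2c`)
is matched and unchanged. Running the pipeline:

```r
res <- run_pipeline(fx$record, fx$molecules, fx$codes)
res$status
#> "aam_complete"
res$rules[[1]]
#> <dpo_rule RXN_cleavage: 4 atoms, L 3 bonds / K 2 bonds / R 2 bonds>
cat(write_rule_gml(res$rules[[1]]))
#> rule [
#>   ruleID "RXN_cleavage"
#>   left [
#>     node [ id 3 label "CH" ]
#>     node [ id 4 label "CH2" ]
#>     edge [ source 3 target 4 label "-" ]
#>   ]
#>   context [
#>     node [ id 2 label "C" ]
#>     node [ id 5 label "CH3" ]
#>     edge [ source 2 target 3 label "=" ]
#>     edge [ source 4 target 5 label "-" ]
#>   ]
#>   right [
#>     node [ id 3 label "CH2" ]
#>     node [ id 4 label "CH3" ]
#>   ]
#> ]
```

The rule deletes the single bond 3–4 (it appears only in the `left`
section) and books the freed valences as hydrogens (`CH` becomes `CH2`,
`CH2` becomes `CH3`); the two unchanged bonds around the cut form the
context `K`. Applying the rule and extending the map over the unchanged
remainder yields one AAM class:

```r
a <- res$aams[[1]]
a$changing_bonds; a$multiplicity
#> 1
#> 4        # four symmetry-equivalent embeddings, all ITS-isomorphic
cat(a$smiles)
#> [CH3:1][C:2](=[CH:3][CH2:4][CH3:5])[SH:6]>>[CH3:1][C:2](=[CH2:3])[SH:6].[CH3:4][CH3:5]
```

The atom-map numbers are the reactant atom ids; `its_isomorphic(a$its,
fx$truth$its)` confirms the recovered map equals the generator's ground
truth. The same run is available from a shell:

```sh
rdm2dpo fixture --dir demo --seed 7 --template cleavage
rdm2dpo run --dir demo        # writes rules/*.gml, aams/*.smi, status.tsv
```

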