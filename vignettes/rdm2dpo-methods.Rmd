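---
title: "From RCLASS codes to DPO rules and atom maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RCLASS codes to DPO rules and atom maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdm2dpo)
```

## The problem

The KEGG reaction database does not publish atom-to-atom maps (AAMs).
Instead, each reaction links to RCLASS entries that describe the chemical
change between one reactant and one product compound through *RDM codes*:
strings of the form `R:D:M` listing the Reaction-center atom, the Difference
atoms and the Matched atoms as pairs of KEGG atom types, reactant side and
product side separated by a hyphen. This is a lossy, pattern-based encoding.
`rdm2dpo` inverts it as far as the data allow: it reconstructs explicit
double-pushout (DPO) graph transformation rules `L <- K -> R` and complete
AAMs, exhaustively enumerating every solution consistent with the input and
never repairing or amending the data.

The reconstruction is an instance of the graph reconstruction problem —
inferring a graph (here, the imaginary transition state graph of the
reaction) from a collection of local subgraph patterns. Uniqueness is not
guaranteed, so every stage carries all alternatives forward and ambiguity is
reported, not resolved.

## Molecules, rules and the ITS graph

Molecules are vertex- and edge-labelled simple graphs: elements on vertices,
bond orders (`single`, `double`, `triple`, `aromatic`) plus a ring flag on
edges, and charge/radical annotations on loops so that vertex labels never
change under a rule. Hydrogens are implicit: each heavy atom carries a
hydrogen count, which we treat as part of its vertex label. This keeps
pattern embedding spaces small (explicit hydrogens multiply embeddings
without adding information, because RDM atom types encode hydrogen counts
compositionally), at the price that a pattern atom only matches host atoms
with the same implicit hydrogen count; the count is relaxed to "at least as
many" at context atoms, where the type graph understates the environment.

A chemical DPO rule preserves atoms, so it is a span `L <- K -> R` with a
total bijection `beta` between the atoms of `L` and `R`; only edges are
deleted, inserted or relabelled. For fixed `L`, `R` and `beta` the context is
not unique, but there is a unique *maximal* context: the edges on which `L`
and `R` agree. `rule_context()` always returns this maximal `K`, the
canonical representative — any smaller context deletes and re-inserts an
unchanged edge and produces the same result.

The ITS graph of a reaction has an edge wherever a bond exists on at least
one side, labelled with the pair of bond labels; edges with unequal labels
are *reaction edges*. Any subgraph of the ITS that covers all reaction edges
(and, in our implicit-hydrogen convention, all atoms whose hydrogen count
changes) is equivalent to a DPO rule that regenerates the products when
applied at its defining match. This round-trip is the package's central
correctness property and is exercised over hundreds of extracted subgraph
rules in the test suite.

## The atom-type dictionary

Each of the 68 KEGG atom types denotes a small rooted *type graph*: the
focal atom with its implicit hydrogens and immediate neighborhood, unnamed
heavy neighbors appearing as wildcard "R-residues". The dictionary ships as
a plain table (`inst/extdata/kegg_atom_types.tsv`) rather than code, one row
per (code, alternative), each tagged with its provenance (`kegg`,
`kegg_documented`, `inferred`). KEGG itself documents alternatives for five
codes (C2y, N1a, N1b, N1c, N2a); twenty further codes need alternative
readings — ring-fusion variants, protonation states, tautomers — and P1a
attains the maximum of four. Three sources of softness are *not* stored as
alternatives but implemented as matching predicates, which keeps the table
small and the search space tight:

* bonds involving oxygen do not distinguish single from double order;
* a within-ring bond may be read as aromatic and vice versa;
* charge loops never block a lenient match.

These predicates apply when RDM-derived patterns are embedded into
molecules. They do *not* apply when concrete molecule fragments are matched
against each other (the D-subgraph stage below); there, bond orders are
compared exactly — which is precisely why the carboxy/CO2 special case
exists.

## From codes to pattern graphs

`parse_rdm()` enforces the grammar (three sections, positional
reactant–product pairs, `+` separators, `*` absence markers; `*` never in
the R or M sections). Each side becomes a depth-1 tree rooted at the R-atom.
`expand_tree()` replaces every node by its type graph(s) and merges children
progressively into the root: if two adjacent type graphs share a pair of
atoms (O1c, H–O–P, and P1b, P–O, share the P–O motif), the shared pair is
the merge point; otherwise a wildcard of each fragment is consumed, which
requires exactly matching bond orders and compatible ring/aromatic context.
Merging two C2b fragments (R–CH=R) illustrates the inherent ambiguity: both
R–HC=CH–R and R=CH–HC=R are legal, and only the first survives extension by
C1a (R–CH3). Since non-extensible combinations may only become recognisable
at later merge steps, the search explores all branches and prunes dead ones
(branch and bound). Where a shared motif and a wildcard consumption both
exist, both branches are kept and the embedding stage decides — the merge
preference is treated as a priority, not a filter. On merged vertices the
focal atom's own type definition wins over neighbor-implied attributes;
conflicting non-focal attributes prune the branch. Results are deduplicated
up to rooted labelled isomorphism with every tree-node position pinned and
ordered deterministically by a canonical invariant, so repeated runs give
identical variant lists.

`make_pattern_graphs()` pairs every reactant-side expansion with every
product-side expansion; the partial correspondence `corr` links the R-atom
and each M-atom to its positional partner, never a D-atom. Positional
pairing across the hyphen is assumed (KEGG does not state it); a pairing
that fails to preserve element labels is dropped with a warning.

## Embedding and pairwise patterns

All subgraph monomorphisms of each pattern side into the candidate
molecules are enumerated with a backtracking (VF2-style) search under the
leniency predicates. Hydrogen counts must agree exactly at R/D/M atoms and
may only be exceeded by the host at context atoms; wildcards match any
heavy atom, injectively — which is exactly why three-membered rings
(epoxides) defeat path-shaped patterns: both wildcards would have to land on
the same ring atom. Since KEGG stores patterns without naming which side is
the reactant, the embeddings decide the orientation first.

Overlapping embeddings of two codes must be consistent: a shared host atom
must either be a D-atom in both codes, or matched in both with coinciding
partners on the opposite side. Context and wildcard atoms carry no matching
information and never conflict (a design choice; the source condition is
stated only for D-atoms versus matched atoms). All combinations of
(type-graph variant, left embedding, right embedding) across the RCLASS's
codes are enumerated, filtered by these conditions, and united into
*pairwise pattern graphs* — the embedded subgraphs plus the bipartite
matching of their atoms, with every contributing code's R/D/M annotation
recorded per atom. Enumeration order is lexicographic in (code index,
variant, embedding key), so output order is reproducible.

## Rule reconstruction

For each reaction, one pairwise pattern per RCLASS link is chosen, in all
combinations. A combination survives if the union of the bipartite
matchings is again a matching — a clash is reported as a *conflict*, naming
the atoms with contradictory images — and if every D-atom is matched by
some other pairwise pattern (a departing atom must reappear somewhere).
Role precedence is R > M > D: an atom marked R anywhere is an R-atom; atoms
marked both M and D are treated first as M-atoms, and incorrectly declared
M-atoms are removed by the balance test, which compares effective role
counts per chemical element between the two sides (the per-role-and-element
arithmetic is our choice; the source does not print the exact arithmetic).
`L` and `R` are then the unions of the embedded patterns restricted to
matched atoms, `beta` is the union matching, `K` the maximal context, and
the candidate is validated by applying it at its defining match and
comparing the resulting components, as a multiset and respecting
stoichiometric multiplicities, against the expected products. Candidate
rules that differ only in how many implicit hydrogens they shuffle are
collapsed to the representatives with the fewest hydrogen-count edits.

When stoichiometric multiplicities exceed one, RCLASS links are applied to
the first instance of their compound pair; distinguishing instances would
require information KEGG does not provide.

## Missing RCLASSes

When not all exchanging compound pairs carry an RCLASS, some D-atoms stay
unmatched after the union. The connected subgraphs induced by the unmatched
D-atoms on each side are matched, largest first, against the opposite side
of the reaction by exact (element and bond-order) subgraph isomorphism.
A counterpart is a candidate only if (1) it is not one of the original
pairwise pattern images, (2) where it overlaps integrated pattern atoms the
overlap contains an R-atom (we read the source's condition as applying to
the overlap region, and only to non-D overlaps), (3) it maps onto D-atoms
of other patterns only if it consists exclusively of D-atoms, and (4)
hydrogen atoms are excluded. Single-atom D-subgraphs (a lone oxygen, say)
typically admit several candidates; the balance test and rule validation
cut them down — in the bundled synthetic configuration shaped like a
phosphate-transfer reaction, three candidates reduce to exactly one.

Two repairs cover small molecules that RCLASS data never describe: carboxy
groups leaving as CO2 are recognised structurally (internal bond changes
defeat plain isomorphism matching), and after any candidate extension the
rule is *completed* by adding every bond that changes under the extended
atom map, with its incident atoms and hydrogen-count updates. Completion is
idempotent; if a changed bond has an endpoint with no image, the rule is
flagged incomplete rather than guessed at.

## Completing the atom map

A complete rule yields the AAM directly: the map defined by the rule's
embedding is extended over the unchanged remainder by a seeded isomorphism
search that *declares* the seed consistent and appends a pair only if all
edges and labels to previously matched atoms are preserved. A seed that
cannot be extended to a bijection cannot belong to a correct rule — this is
the filter that removes surviving wrong variants. For incomplete rules, all
combinations of educt- and product-side rule embeddings are seeded and
completed by an exact branch-and-bound minimization of the number of bonds
that change outside the rule (the objective is what matters; at this scale
an exact search replaces an integer program). The minimization is applied
per reaction: of all admissible maps across all candidate rules, the ones
with the fewest changing bonds are reported. Maps are deduplicated by ITS
isomorphism, with the residual multiplicity recorded — symmetric molecules
legitimately admit several equivalent maps. Rules are filtered to minimal
hydrogen exchanges first, then maps are minimized; the two objectives are
not interleaved.

## The synthetic fixture generator

`make_fixture()` builds the study conditions for download-free testing: a
random connected molecule of about six heavy atoms (C/N/O/S, mostly carbon,
single and double bonds, optionally one ring), a reaction template (bond
cleavage, condensation, group transfer, or a bond-order change) applied
with implicit-hydrogen bookkeeping, and the RDM codes KEGG would write for
each exchanging pair — case (i) with R/D/M atoms where the pair has
unmatched heavy atoms, case (ii) with an empty D section where only atom
types change. The true AAM and ITS graph are retained, so end-to-end
recovery is checkable: every completed map's ITS must be isomorphic to the
generated truth.

Three generator choices matter. Rings below five atoms are never closed:
radius-2 type graphs cannot represent them (the wildcards of adjacent ring
types would collide — the same reason epoxide RCLASSes fail on real data),
so such draws would only test the failure path. Phosphorus and aromatic
systems are exercised through hand-built fixtures and the dictionary tests
rather than the random generator, whose typing rules cover the C/N/O/S
environments it can produce; a draw is rejected unless every atom's
assigned type graph embeds back at its atom. And hypersymmetric draws
(e.g. a doubly methylated double bond) can exceed the default combination
cap of 1000 per side and are then reported as combinatorics skips, exactly
as on real data — the end-to-end suite therefore asserts that completed
maps are never wrong, not that every draw completes.

What passing these tests shows is that the reconstruction machinery is
faithful on data whose generating process is known. What it cannot show is
robustness to the quirks of curated data — inconsistent hydrogen
annotations, abbreviated residues, unbalanced reactions — which the
pipeline only detects and reports (`no_structure`, `undefined_atoms`,
`conflict`, `combinatorics_skip`, ...), never repairs.

## Numerical and procedural choices

* Combination cap: 1000 per reaction side (configurable); exceeding it is a
  reported skip, not an error. Per-rule application time limit: 7200 s.
* All enumerations sort by atom id and canonical fragment invariants;
  repeated runs are bit-identical.
* Isomorphism everywhere is exact label-preserving search (elements,
  hydrogen counts, loops, bond orders; ring flags for declared pattern
  context), screened by cheap invariants.
* Degenerate inputs: a reaction with no change yields no codes and no rule;
  empty embedding sets, conflicting codes and over-cap combinations each
  map to a distinct status so that batch runs can account for every input.
* The problem sizes used by the test and acceptance suites — about 100
  fixtures of 5–13 heavy atoms, exhaustive subgraph enumeration up to 6
  context edges with 25-subset sampling beyond — were chosen so the full
  enumeration properties remain exactly checkable at desk scale.

## Known limitations

* Three-membered rings cannot be reconstructed from RDM data (they appear
  as paths whose wildcards collide); this is inherent to the encoding.
* RCLASSes with "undefined atom" types are non-convertible and reported as
  such.
* Multiple non-isomorphic solutions can survive for genuinely ambiguous
  data; the package reports all of them with a multiplicity tag and makes
  no chemical plausibility judgement beyond the changing-bond objective.
* The RDM encoding of intra-pair bond *deletions* (rather than order
  changes) is not well specified by the source material; the generator does
  not emit such cases and the pipeline handles them only insofar as the
  embedding stage succeeds.
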