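# Synthetic reaction configurations built by hand (no KEGG data involved).

## Water-elimination analogue of a reaction whose free small molecule is not
## covered by any RCLASS: A1 (a methylated diol) + A2 (a mercapto alcohol)
## react to a thioether product plus free water; the water pair has no
## RCLASS, so its oxygen must be recovered from the D-subgraph machinery.
## The single-oxygen D-subgraph admits several isomorphic counterparts of
## which exactly one survives rule validation.
synthetic_missing_rclass <- function() {
  A1 <- molgraph(data.frame(id = 1:5,
                            element = c("O", "C", "C", "O", "C"),
                            hcount = c(1L, 1L, 2L, 1L, 3L)),
                 bond_df(c(1, 2, "single"), c(2, 3, "single"),
                         c(3, 4, "single"), c(2, 5, "single")),
                 compound_id = "A1")
  A2 <- molgraph(data.frame(id = 1:3, element = c("S", "C", "O"),
                            hcount = c(1L, 2L, 1L)),
                 bond_df(c(1, 2, "single"), c(2, 3, "single")),
                 compound_id = "A2")
  B1 <- molgraph(data.frame(id = 1:7,
                            element = c("O", "C", "C", "C", "S", "C", "O"),
                            hcount = c(1L, 1L, 2L, 3L, 0L, 2L, 1L)),
                 bond_df(c(1, 2, "single"), c(2, 3, "single"),
                         c(2, 4, "single"), c(3, 5, "single"),
                         c(5, 6, "single"), c(6, 7, "single")),
                 compound_id = "B1")
  B2 <- molgraph(data.frame(id = 1L, element = "O", hcount = 2L),
                 compound_id = "B2")
  record <- reaction_record(
    "RXN_synthetic_missing",
    c("A1", "A2"), c("B1", "B2"),
    list(list(rclass_id = "RCS1", reactant = "A1", product = "B1"),
         list(rclass_id = "RCS2", reactant = "A2", product = "B1")))
  codes <- list(RCS1 = "C1b-C1b:O1a-S2a:C1c-C1c",
                RCS2 = "S1a-S2a:*-C1b:C1b-C1b")
  list(molecules = list(A1 = A1, A2 = A2, B1 = B1, B2 = B2),
       record = record, codes = codes)
}

## decarboxylation analogue: a carboxy group leaves as CO2, whose internal
## bond changes defeat plain isomorphism matching of the D-subgraph
synthetic_decarboxylation <- function(n_co2 = 1L) {
  ## reactant: CH3-CH2-COOH; products: CH3-CH3 (h-filled) + CO2
  G <- molgraph(data.frame(id = 1:6,
                           element = c("C", "C", "C", "O", "O", "C"),
                           hcount = c(3L, 2L, 0L, 0L, 1L, 3L)),
                bond_df(c(1, 2, "single"), c(2, 3, "single"),
                        c(3, 4, "double"), c(3, 5, "single"),
                        c(1, 6, "single")))
  comps <- list(data.frame(id = 1:3, element = c("C", "C", "O"),
                           hcount = c(0L, 0L, 0L)))
  H_atoms <- data.frame(id = 1:6,
                        element = c("C", "C", "C", "O", "O", "C"),
                        hcount = c(3L, 3L, 0L, 0L, 0L, 3L))
  H_bonds <- bond_df(c(1, 2, "single"), c(3, 4, "double"),
                     c(3, 5, "double"), c(1, 6, "single"))
  H <- molgraph(H_atoms, H_bonds)
  if (n_co2 == 2L) {
    extra <- data.frame(id = 7:9, element = c("C", "O", "O"),
                        hcount = 0L)
    H <- molgraph(rbind(H_atoms, extra),
                  rbind(H_bonds, bond_df(c(7, 8, "double"),
                                         c(7, 9, "double"))))
    G2 <- G  # a second carboxy source is not modelled; candidates only
  }
  list(G = G, H = H)
}
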