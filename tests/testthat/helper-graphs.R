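# shorthand molecule builders used across the suite

mg <- function(elements, hcounts, bonds = NULL, ...) {
  molgraph(data.frame(id = seq_along(elements), element = elements,
                      hcount = hcounts, stringsAsFactors = FALSE),
           bonds, ...)
}

bond_df <- function(...) {
  ## bond_df(c(1,2,"single"), c(2,3,"double"))
  rows <- list(...)
  data.frame(a = vapply(rows, function(r) as.integer(r[1]), integer(1)),
             b = vapply(rows, function(r) as.integer(r[2]), integer(1)),
             order = vapply(rows, function(r) r[3], character(1)),
             stringsAsFactors = FALSE)
}

ethane <- function() mg(c("C", "C"), c(3, 3), bond_df(c(1, 2, "single")))

ethanol <- function() mg(c("C", "C", "O"), c(3, 2, 1),
                         bond_df(c(1, 2, "single"), c(2, 3, "single")))

propane <- function() mg(c("C", "C", "C"), c(3, 2, 3),
                         bond_df(c(1, 2, "single"), c(2, 3, "single")))

cyclopropane <- function() mg(c("C", "C", "C"), c(2, 2, 2),
                              bond_df(c(1, 2, "single"), c(2, 3, "single"),
                                      c(1, 3, "single")))

ethanol_mol <- paste0(
  "ethanol\n  test\n\n  3  2  0  0  0  0  0  0  0  0999 V2000\n",
  "    0.0000    0.0000    0.0000 C   0  0\n",
  "    0.0000    0.0000    0.0000 C   0  0\n",
  "    0.0000    0.0000    0.0000 O   0  0\n",
  "  1  2  1  0\n  2  3  1  0\nM  END")

benzene_mol <- paste0(
  "benzene\n\n\n  6  6  0  0  0  0  0  0  0  0999 V2000\n",
  paste(rep("    0.0000    0.0000    0.0000 C   0  0", 6), collapse = "\n"),
  "\n  1  2  2  0\n  2  3  1  0\n  3  4  2  0\n  4  5  1  0\n  5  6  2  0\n",
  "  1  6  1  0\nM  END")

## one identity rule and one bond-deletion rule, as reusable fixtures
identity_rule <- function() {
  m <- mg("C", 4)
  dpo_rule(m, m, c("1" = 1L), rule_id = "identity")
}

cleave_cc_rule <- function() {
  L <- mg(c("C", "C"), c(3, 3), bond_df(c(1, 2, "single")))
  R <- mg(c("C", "C"), c(4, 4))
  dpo_rule(L, R, c("1" = 1L, "2" = 2L), rule_id = "cleave")
}

## deterministic fixture seeds shared by property suites
fixture_templates <- c("cleavage", "condensation", "transfer", "order_change")

fixture_for <- function(seed) {
  make_fixture(seed, template = fixture_templates[(seed %% 4L) + 1L],
               n_atoms = 6L)
}
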