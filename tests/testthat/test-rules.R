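# hand-built minimal pairwise pattern (one matched atom) for conflict tests
tiny_pp <- function(a_local, b_local, role = "R") {
  structure(list(
    lhat = mg("O", 2),
    rhat = mg("O", 2),
    matching = data.frame(a = a_local, b = b_local),
    roles_a = stats::setNames(list(role), as.character(a_local)),
    roles_b = stats::setNames(list(role), as.character(b_local)),
    provenance = list()), class = "pairwise_pattern")
}

test_that("contradictory atom maps yield zero rules and a conflict naming the atom", {
  water <- mg("O", 2, compound_id = "W")
  record <- reaction_record("Rconflict", c("W"), c("W1", "W2"),
                            list(list(rclass_id = "RC1", reactant = "W",
                                      product = "W1"),
                                 list(rclass_id = "RC2", reactant = "W",
                                      product = "W2")))
  mols <- list(W = water, W1 = water, W2 = water)
  out <- combine_reaction(record, mols, list(list(tiny_pp(1L, 1L)),
                                             list(tiny_pp(1L, 1L))))
  expect_length(out$rules, 0L)
  expect_equal(out$status, "conflict")
  expect_length(out$conflicts, 1L)
  ## the clashing reactant atom (the single O, global id 1) is named
  expect_equal(out$conflicts[[1]]$reactant_atoms, 1L)
})

test_that("balance test counts effective roles per element on both sides", {
  mk <- function(ra, rb, ea, eb) {
    list(roles_a = ra, roles_b = rb, elem_a = ea, elem_b = eb)
  }
  ## symmetric toy rule
  expect_true(balance_test(mk(
    list(`1` = "R", `2` = "M"), list(`1` = "R", `2` = "M"),
    c(`1` = "C", `2` = "O"), c(`1` = "C", `2` = "O"))))
  ## one extra unpaired D on one side
  expect_false(balance_test(mk(
    list(`1` = "R", `2` = "D"), list(`1` = "R"),
    c(`1` = "C", `2` = "O"), c(`1` = "C"))))
  ## an M-vertex whose partner was consumed as D elsewhere: per the hand
  ## count, side a has {R:C, M:O}, side b has {R:C, D:O} -- unbalanced
  expect_false(balance_test(mk(
    list(`1` = "R", `2` = "M"), list(`1` = "R", `2` = "D"),
    c(`1` = "C", `2` = "O"), c(`1` = "C", `2` = "O"))))
  ## R-precedence: a vertex labelled R anywhere counts as R
  expect_true(balance_test(mk(
    list(`1` = c("R", "M")), list(`1` = "R"),
    c(`1` = "C"), c(`1` = "C"))))
  ## M-before-D precedence for doubly labelled atoms
  expect_true(balance_test(mk(
    list(`1` = c("M", "D")), list(`1` = "M"),
    c(`1` = "C"), c(`1` = "C"))))
})

test_that("a single-RCLASS reaction gives a rule whose K drops exactly the changed edges", {
  fx <- make_fixture(2, template = "order_change", n_atoms = 6)
  expect_false(is.null(fx))
  res <- run_pipeline(fx$record, fx$molecules, fx$codes)
  expect_equal(res$status, "aam_complete")
  rule <- res$rules[[1]]
  K <- rule_context(rule)
  ridx <- rdm2dpo:::mg_bond_index(rule$right)
  for (k in seq_len(nrow(rule$left$bonds))) {
    a <- rule$left$bonds$a[k]; b <- rule$left$bonds$b[k]
    rr <- rdm2dpo:::mg_bond_row(ridx, rule$beta[[as.character(a)]],
                                rule$beta[[as.character(b)]])
    unchanged <- !is.na(rr) &&
      rule$right$bonds$order[rr] == rule$left$bonds$order[k]
    in_k <- !is.na(rdm2dpo:::mg_bond_row(rdm2dpo:::mg_bond_index(K), a, b))
    expect_equal(in_k, unchanged)   # K is the maximal context
  }
})

test_that("two RCLASSes whose D-atoms cross-match produce one complete rule", {
  fx <- make_fixture(1, template = "cleavage", n_atoms = 6)
  expect_false(is.null(fx))
  res <- run_pipeline(fx$record, fx$molecules, fx$codes)
  expect_equal(res$status, "aam_complete")
  expect_gte(length(res$rules), 1L)
  rule <- res$rules[[1]]
  ## every D-role atom ends up matched (present in the rule's atom map)
  roles_a <- rule$provenance$roles_a
  d_atoms <- names(roles_a)[vapply(roles_a, function(r) "D" %in% r,
                                   logical(1))]
  expect_true(all(d_atoms %in% names(rule$beta)))
})

test_that("emitted rules regenerate the products at their defining match", {
  for (seed in c(3, 8, 13, 22)) {
    fx <- fixture_for(seed)
    expect_false(is.null(fx))
    res <- run_pipeline(fx$record, fx$molecules, fx$codes)
    expect_equal(res$status, "aam_complete")
    rg <- res$graphs
    expected <- lapply(rdm2dpo:::mg_components(rg$H), function(ids)
      mg_subgraph(rg$H, ids))
    for (rule in res$rules) {
      expect_true(validate_rule(rule, rg$G, expected)$valid)
    }
  }
})

test_that("rules differing only in hydrogen exchanges collapse to the minimum", {
  ## same heavy-bond change, one rule shuffles an extra hydrogen pair
  L1 <- mg(c("C", "C"), c(3, 3), bond_df(c(1, 2, "single")))
  R1 <- mg(c("C", "C"), c(4, 4))
  r_min <- dpo_rule(L1, R1, c(`1` = 1L, `2` = 2L))
  L2 <- mg(c("C", "C", "C"), c(3, 3, 2), bond_df(c(1, 2, "single")))
  R2 <- mg(c("C", "C", "C"), c(4, 4, 2))
  r_min2 <- dpo_rule(L2, R2, c(`1` = 1L, `2` = 2L, `3` = 3L))
  L3 <- mg(c("C", "C", "C"), c(3, 3, 3), bond_df(c(1, 2, "single")))
  R3 <- mg(c("C", "C", "C"), c(4, 4, 2))
  r_extra <- dpo_rule(L3, R3, c(`1` = 1L, `2` = 2L, `3` = 3L))
  kept <- filter_min_h_rules(list(r_min2, r_extra))
  expect_length(kept, 1L)
  expect_equal(rdm2dpo:::rule_h_edits(kept[[1]]), 2)
  ## structurally different rules are never collapsed
  kept2 <- filter_min_h_rules(list(r_min, r_extra))
  expect_length(kept2, 2L)
})
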