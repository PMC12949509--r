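test_that("unmatched D-atoms are extracted as connected subgraphs per side", {
  ## cleavage fixture with its second RCLASS dropped: the departing fragment
  ## stays uncovered and its D-atoms stay unmatched
  fx <- make_fixture(1, template = "cleavage", n_atoms = 6, drop_link = 2)
  expect_false(is.null(fx))
  pw <- lapply(fx$record$rclass_links, function(link) {
    assemble_pairwise(lapply(fx$codes[[link$rclass_id]], parse_rdm),
                      fx$molecules[[link$reactant]],
                      fx$molecules[[link$product]])
  })
  comb <- combine_reaction(fx$record, fx$molecules, pw)
  expect_gt(length(comb$partials), 0L)
  ds <- d_subgraphs(comb$partials[[1]], comb$graphs)
  expect_gt(length(ds), 0L)
  for (d in ds) {
    expect_true(rdm2dpo:::mg_is_connected(d$graph))
    expect_true(all(d$side %in% c("reactant", "product")))
  }
  ## ordered largest-first
  sizes <- vapply(ds, function(d) length(d$ids), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the synthetic missing-RCLASS configuration yields several candidates, one survivor", {
  ## labelled synthetic: mirrors the shape of a KEGG reaction whose free
  ## phosphate is uncovered (three isomorphic counterparts for a
  ## single-oxygen D-subgraph; exactly one passes DPO validation)
  syn <- synthetic_missing_rclass()
  res <- run_pipeline(syn$record, syn$molecules, syn$codes)
  expect_equal(res$status, "aam_complete")
  expect_gt(res$completion$candidates, 1L)
  expect_equal(res$completion$surviving, 1L)
  ## the recovered map sends the leaving O onto the free water oxygen
  rg <- res$graphs
  water_gid <- rg$hmap$gid[rg$hmap$compound_id == "B2"]
  o4_gid <- rg$gmap$gid[rg$gmap$compound_id == "A1" & rg$gmap$local == 4L]
  expect_equal(unname(res$aams[[1]]$alpha[[as.character(o4_gid)]]), water_gid)
})

test_that("D-subgraph candidates respect the four matching conditions", {
  syn <- synthetic_missing_rclass()
  pw <- lapply(syn$record$rclass_links, function(link) {
    assemble_pairwise(lapply(syn$codes[[link$rclass_id]], parse_rdm,
                             rclass_id = link$rclass_id),
                      syn$molecules[[link$reactant]],
                      syn$molecules[[link$product]])
  })
  comb <- combine_reaction(syn$record, syn$molecules, pw)
  cand <- comb$partials[[1]]
  rg <- comb$graphs
  ds <- d_subgraphs(cand, rg)
  got <- match_d_subgraphs(ds, cand, rg)
  expect_equal(length(got[[1]]), 3L)   # three isomorphic single-O counterparts

  ## brute-force oracle: every injective element-preserving image, filtered
  ## by the explicitly stated conditions
  d <- ds[[1]]
  host <- rg$H
  matched <- cand$matching$b
  roles <- cand$roles_b
  oracle <- 0L
  for (v in host$atoms$id) {
    if (host$atoms$element[match(v, host$atoms$id)] != "O") next
    if (host$atoms$element[match(v, host$atoms$id)] == "H") next  # cond (4)
    if (v %in% matched) next
    img <- v
    sets <- attr(cand, "part_images")$vb
    if (any(vapply(sets, function(s) setequal(img, s), logical(1)))) next # (1)
    on_d <- vapply(as.character(img), function(k)
      "D" %in% (roles[[k]] %||% character()), logical(1))
    if (any(on_d) && !all(on_d)) next                                     # (3)
    if (!any(on_d)) {
      overlap <- intersect(img, cand$core_b)
      if (length(overlap) &&
          !any(vapply(as.character(overlap), function(k)
            "R" %in% (roles[[k]] %||% character()), logical(1)))) next    # (2)
    }
    oracle <- oracle + 1L
  }
  expect_equal(length(got[[1]]), oracle)
})

test_that("a candidate overlapping pattern atoms needs an R-atom in the overlap", {
  ## hand-built state: one unmatched D oxygen; the opposite side has two
  ## oxygens inside pattern images, one next to an R-atom and one not
  G <- mg(c("C", "O"), c(3, 1), bond_df(c(1, 2, "single")))
  H <- mg(c("C", "O", "O"), c(3, 1, 1), bond_df(c(1, 2, "single")))
  rg <- list(G = G, H = H)
  cand <- list(matching = data.frame(a = 1L, b = 1L),
               va = c(1L, 2L), vb = c(1L, 2L, 3L),
               roles_a = list(`1` = "R", `2` = "D"),
               roles_b = list(`1` = "R", `2` = "R", `3` = "M"))
  attr(cand, "part_images") <- list(va = list(c(1L, 2L)), vb = list(c(1L, 2L)))
  ds <- list(list(side = "reactant", ids = 2L, graph = mg_subgraph(G, 2L)))
  got <- match_d_subgraphs(ds, cand, rg)[[1]]
  ## O2's overlap contains an R-atom: allowed;
  ## O3 carries only an M role, no R-atom in the overlap: excluded
  expect_length(got, 1L)
  expect_equal(got[[1]]$b, 2L)

  ## condition (3): an image consisting exclusively of D-atoms is allowed,
  ## without requiring an R-atom in the overlap
  cand2 <- cand
  cand2$roles_b <- list(`1` = "R", `2` = "D", `3` = "M")
  got2 <- match_d_subgraphs(ds, cand2, rg)[[1]]
  expect_length(got2, 1L)
  expect_equal(got2[[1]]$b, 2L)
})

test_that("carboxy groups are matched onto CO2 despite internal bond changes", {
  dec <- synthetic_decarboxylation()
  d <- list(side = "reactant", ids = c(3L, 4L, 5L),
            graph = mg_subgraph(dec$G, c(3, 4, 5)))
  cand <- list(matching = data.frame(a = integer(), b = integer()))
  rg <- list(G = dec$G, H = dec$H)
  got <- carboxy_special_case(d, cand, rg)
  expect_length(got, 1L)
  expect_setequal(got[[1]]$a, c(3L, 4L, 5L))
  expect_setequal(got[[1]]$b, c(3L, 4L, 5L))
  ## plain isomorphism matching indeed fails here (bond orders changed)
  expect_length(match_d_subgraphs(list(d), c(cand, list(
    va = integer(), vb = integer(), roles_a = list(), roles_b = list())),
    rg)[[1]], 0L)

  ## no CO2 on the opposite side: no candidate
  no_co2 <- rg; no_co2$H <- dec$G
  expect_length(carboxy_special_case(d, cand, no_co2), 0L)

  ## two CO2 products: both enumerated
  dec2 <- synthetic_decarboxylation(n_co2 = 2L)
  rg2 <- list(G = dec2$G, H = dec2$H)
  expect_length(carboxy_special_case(d, cand, rg2), 2L)
})

test_that("small-molecule completion adds changed bonds and is idempotent", {
  ## hydration: the rule covers the C=C order change but not the new C-O
  ## bond of the incoming water
  G <- mg(c("C", "C", "O"), c(2, 2, 2), bond_df(c(1, 2, "double")))
  H <- mg(c("C", "C", "O"), c(3, 2, 1),
          bond_df(c(1, 2, "single"), c(2, 3, "single")))
  L0 <- mg_subgraph(G, c(1, 2))
  R0 <- mg_subgraph(H, c(1, 2))
  rule <- dpo_rule(L0, R0, c(`1` = 1L, `2` = 2L))
  alpha <- c(`1` = 1L, `2` = 2L, `3` = 3L)
  done <- complete_small_molecule_rule(rule, G, H, alpha = alpha)
  expect_true(done$complete)
  expect_true(3L %in% done$left$atoms$id)
  expect_true(any(done$right$bonds$a == 2L & done$right$bonds$b == 3L))
  ## idempotence
  again <- complete_small_molecule_rule(done, G, H, alpha = alpha)
  expect_true(its_isomorphic(rdm2dpo:::rule_psi(again),
                             rdm2dpo:::rule_psi(done)))
  ## an already complete rule is unchanged
  full <- extract_rule(its_graph(G, H, alpha), c(1L, 2L, 3L))
  full2 <- complete_small_molecule_rule(full, G, H)
  expect_true(its_isomorphic(rdm2dpo:::rule_psi(full2),
                             rdm2dpo:::rule_psi(full)))
  ## a changed bond with an unmapped endpoint cannot be completed
  part <- complete_small_molecule_rule(rule, G, H,
                                       alpha = c(`1` = 1L, `2` = 2L))
  expect_false(part$complete)
})

test_that("the missing-RCLASS path completes a dropped-link fixture end to end", {
  fx <- make_fixture(1, template = "cleavage", n_atoms = 6, drop_link = 2)
  expect_false(is.null(fx))
  res <- run_pipeline(fx$record, fx$molecules, fx$codes)
  expect_true(res$status %in% c("aam_complete", "aam_partial"))
  if (res$status == "aam_complete") {
    expect_true(any(vapply(res$aams, function(a)
      its_isomorphic(a$its, fx$truth$its), logical(1))))
  }
})
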