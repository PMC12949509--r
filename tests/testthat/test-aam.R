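test_that("seeded extension behaves as declared-consistent VF2", {
  G <- propane(); H <- propane()
  full <- c(`1` = 1L, `2` = 2L, `3` = 3L)
  expect_identical(seeded_extension(G, H, full), list(full))
  ## an unchanged symmetric tail admits both extensions
  got <- seeded_extension(G, H, c(`2` = 2L))
  expect_length(got, 2L)
  ## a seed that forces an edge or element mismatch is filtered out
  expect_length(seeded_extension(ethanol(), ethanol(), c(`1` = 3L)), 0L)
})

test_that("bond-change minimization matches the exhaustive bijection oracle", {
  ## exhaustive oracle: minimum number of changed bonds over every
  ## element-preserving bijection V(G) -> V(H)
  oracle_min <- function(G, H) {
    stopifnot(mg_n(G) <= 8)
    gi <- rdm2dpo:::mg_bond_index(G); hi <- rdm2dpo:::mg_bond_index(H)
    cost_of <- function(alpha) {
      cost <- 0L
      ids <- G$atoms$id
      for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
        r1 <- rdm2dpo:::mg_bond_row(gi, ids[i], ids[j])
        r2 <- rdm2dpo:::mg_bond_row(hi, alpha[[as.character(ids[i])]],
                                    alpha[[as.character(ids[j])]])
        if (is.na(r1) != is.na(r2)) cost <- cost + 1L
        else if (!is.na(r1) && G$bonds$order[r1] != H$bonds$order[r2])
          cost <- cost + 1L
      }
      cost
    }
    best <- Inf
    classes <- split(H$atoms$id, H$atoms$element)
    gids_by_el <- split(G$atoms$id, G$atoms$element)
    if (!identical(lapply(classes, length)[sort(names(classes))],
                   lapply(gids_by_el, length)[sort(names(gids_by_el))]))
      return(NA_integer_)
    ## enumerate per-element permutations
    perms_of <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      }
      out
    }
    grids <- lapply(sort(names(gids_by_el)), function(el)
      perms_of(classes[[el]]))
    idx <- rdm2dpo:::cartesian_index(lengths(grids))
    for (cb in idx) {
      alpha <- stats::setNames(
        unlist(Map(function(g, k) g[[k]], grids, cb)),
        as.character(unlist(gids_by_el[sort(names(gids_by_el))])))
      best <- min(best, cost_of(alpha))
    }
    best
  }

  for (seed in c(2, 7, 12, 21)) {
    fx <- make_fixture(seed, template = if (seed %% 2) "order_change"
                       else "cleavage", n_atoms = 6)
    expect_false(is.null(fx))
    res <- run_pipeline(fx$record, fx$molecules, fx$codes)
    expect_equal(res$status, "aam_complete")
    rg <- res$graphs
    got <- complete_via_rule_embeddings(res$rules[[1]], rg$G, rg$H)
    expect_equal(attr(got, "minimum"), oracle_min(rg$G, rg$H))
  }
})

test_that("a complete rule's minimum equals its own reaction-edge count", {
  fx <- make_fixture(4, template = "order_change", n_atoms = 6)
  res <- run_pipeline(fx$record, fx$molecules, fx$codes)
  rule <- res$rules[[1]]
  rg <- res$graphs
  got <- complete_via_rule_embeddings(rule, rg$G, rg$H)
  expect_equal(attr(got, "minimum"),
               nrow(its_reaction_edges(rdm2dpo:::rule_psi(rule))))
})

test_that("an incomplete rule is completed by minimizing the residual changes", {
  ## hydration with the rule covering only the C=C order change; the C-O
  ## bond formation is recovered by the minimization
  G <- mg(c("C", "C", "O"), c(2, 2, 2), bond_df(c(1, 2, "double")))
  H <- mg(c("C", "C", "O"), c(3, 2, 1),
          bond_df(c(1, 2, "single"), c(2, 3, "single")))
  rule <- dpo_rule(mg_subgraph(G, c(1, 2)), mg_subgraph(H, c(1, 2)),
                   c(`1` = 1L, `2` = 2L))
  got <- complete_via_rule_embeddings(rule, G, H)
  expect_equal(attr(got, "minimum"), 2)   # order change + one new bond
  truth <- its_graph(G, H, c(`1` = 1L, `2` = 2L, `3` = 3L))
  expect_true(any(vapply(got, function(a) its_isomorphic(a$its, truth),
                         logical(1))))
})

test_that("repetitive molecules admit many isomorphic atom maps", {
  ## polymer-like chain with a small reaction center: the mirror symmetry
  ## doubles the number of admissible maps
  n <- 6
  chain <- mg(rep("C", n), c(3, rep(2, n - 2), 3),
              do.call(bond_df, lapply(seq_len(n - 1), function(i)
                c(i, i + 1, "single"))))
  H <- chain
  k <- 3  # middle bond becomes double
  H$bonds$order[k] <- "double"
  H$atoms$hcount[c(3, 4)] <- H$atoms$hcount[c(3, 4)] - 1L
  its <- its_graph(chain, H, stats::setNames(1:n, as.character(1:n)))
  keep <- c(3L, 4L)
  rule <- extract_rule(its, keep, edge_rows = which(its$edges$a == 3 &
                                                      its$edges$b == 4))
  got <- complete_via_rule_embeddings(rule, chain, H)
  expect_gte(sum(vapply(got, `[[`, integer(1), "multiplicity")), 2L)
  expect_length(got, 1L)   # all maps share one ITS class
})

test_that("mapped reaction SMILES and the JSON pair list are well-formed", {
  fx <- make_fixture(1, template = "cleavage", n_atoms = 6)
  res <- run_pipeline(fx$record, fx$molecules, fx$codes)
  a <- res$aams[[1]]
  expect_match(a$smiles, ">>", fixed = TRUE)
  ## every reactant atom id appears as an atom-map number on both sides
  sides <- strsplit(a$smiles, ">>", fixed = TRUE)[[1]]
  for (s in sides) {
    nums <- as.integer(unlist(regmatches(s, gregexpr(":([0-9]+)\\]", s)) |>
                                lapply(gsub, pattern = "[^0-9]", replacement = "")))
    expect_setequal(nums, res$graphs$G$atoms$id)
  }
  js <- jsonlite::fromJSON(write_aam_json(a$alpha))
  expect_identical(js$pairs$reactant, sort(res$graphs$G$atoms$id))
  expect_identical(stats::setNames(js$pairs$product,
                                   as.character(js$pairs$reactant)),
                   a$alpha[order(as.integer(names(a$alpha)))])
})
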