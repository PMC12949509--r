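# exact equality of two graphs over the same atom-id space
graphs_equal <- function(g1, g2) {
  a1 <- g1$atoms[order(g1$atoms$id), c("id", "element", "hcount")]
  a2 <- g2$atoms[order(g2$atoms$id), c("id", "element", "hcount")]
  key <- function(b) sort(paste(b$a, b$b, b$order))
  identical(unname(as.list(a1)), unname(as.list(a2))) &&
    identical(key(g1$bonds), key(g2$bonds))
}

test_that("identity rule reproduces the host, bond deletion splits it", {
  G <- cyclopropane()
  id_rule <- dpo_rule(mg("C", 2), mg("C", 2), c(`1` = 1L))
  res <- apply_rule(id_rule, G, c(`1` = 1L))
  expect_true(graphs_equal(res$H, G))
  expect_identical(unname(res$alpha), G$atoms$id)

  split <- apply_rule(cleave_cc_rule(), ethane(), c(`1` = 1L, `2` = 2L))
  comps <- rdm2dpo:::mg_components(split$H)
  expect_length(comps, 2L)
  expect_true(all(split$H$atoms$hcount == 4L))
})

test_that("match enumeration counts symmetry orbits; conflicts are per-match", {
  ch3 <- dpo_rule(mg("C", 3), mg("C", 3), c(`1` = 1L))
  expect_length(enumerate_matches(ch3, propane()), 2L)
  ch2 <- dpo_rule(mg("C", 2), mg("C", 2), c(`1` = 1L))
  expect_length(enumerate_matches(ch2, cyclopropane()), 3L)

  ## brute-force oracle: count label-preserving monomorphisms by enumerating
  ## all injections directly
  oracle_monos <- function(rule, G) {
    pat <- rule$left
    n <- 0L
    ids <- G$atoms$id
    for (perm in asplit(gtools_perms(length(ids), mg_n(pat)), 1)) {
      img <- ids[perm]
      ok <- TRUE
      for (i in seq_len(mg_n(pat))) {
        if (pat$atoms$element[i] != G$atoms$element[match(img[i], ids)] ||
            pat$atoms$hcount[i] != G$atoms$hcount[match(img[i], ids)]) {
          ok <- FALSE; break
        }
      }
      if (ok && nrow(pat$bonds)) {
        gidx <- rdm2dpo:::mg_bond_index(G)
        for (k in seq_len(nrow(pat$bonds))) {
          r <- rdm2dpo:::mg_bond_row(gidx,
                                     img[match(pat$bonds$a[k], pat$atoms$id)],
                                     img[match(pat$bonds$b[k], pat$atoms$id)])
          if (is.na(r) || G$bonds$order[r] != pat$bonds$order[k]) {
            ok <- FALSE; break
          }
        }
      }
      if (ok) n <- n + 1L
    }
    n
  }
  expect_equal(length(enumerate_matches(ch3, propane())),
               oracle_monos(ch3, propane()))
  cc <- cleave_cc_rule()
  expect_equal(length(enumerate_matches(cc, propane())),
               oracle_monos(cc, propane()))

  ## a match that would create a parallel edge is rejected; others survive
  join <- dpo_rule(mg(c("C", "C"), c(1, 1)),
                   mg(c("C", "C"), c(1, 1), bond_df(c(1, 2, "single"))),
                   c(`1` = 1L, `2` = 2L))
  G <- mg(c("C", "C", "C", "C"), c(1, 1, 1, 1), bond_df(c(1, 2, "single")))
  out <- enumerate_matches(join, G)
  applied <- vapply(out, `[[`, logical(1), "applied")
  onto_bond <- vapply(out, function(e)
    setequal(unname(e$match), c(1L, 2L)), logical(1))
  expect_true(all(!applied[onto_bond]))
  expect_true(all(applied[!onto_bond]))
})

test_that("ITS construction and rule extraction follow the definitions", {
  G <- ethanol()
  id_alpha <- stats::setNames(G$atoms$id, as.character(G$atoms$id))
  its0 <- its_graph(G, G, id_alpha)
  expect_equal(nrow(its_reaction_edges(its0)), 0L)

  ## one bond-order change: exactly one reaction edge labelled (single,double)
  H <- G; H$bonds$order[1] <- "double"
  H$atoms$hcount[1:2] <- H$atoms$hcount[1:2] - 1L
  its1 <- its_graph(G, H, id_alpha)
  re <- its_reaction_edges(its1)
  expect_equal(nrow(re), 1L)
  expect_equal(re$order_g, "single")
  expect_equal(re$order_h, "double")

  ## keep = all vertices: the extracted rule is the full span G <- D -> H
  full <- extract_rule(its1, its1$atoms$id)
  out <- apply_rule(full, G,
                    stats::setNames(G$atoms$id, as.character(G$atoms$id)))
  expect_true(graphs_equal(out$H, H))

  ## a keep set missing a reaction-edge endpoint is rejected
  expect_error(extract_rule(its1, c(2L, 3L)), "cover")
})

test_that("any reaction-edge-covering ITS subgraph defines a rule regenerating H", {
  ## the core round-trip property, spot-checked here on a few seeds (the
  ## full suite runs in the acceptance tests)
  for (seed in c(4, 9, 17)) {
    fx <- fixture_for(seed)
    expect_false(is.null(fx))
    its <- fx$truth$its
    req <- union(unique(unlist(its_reaction_edges(its)[, c("a", "b")])),
                 rdm2dpo:::its_changed_vertices(its))
    ctx_rows <- which(!(is.na(its$edges$order_g) | is.na(its$edges$order_h) |
                          its$edges$order_g != its$edges$order_h))
    re_rows <- setdiff(seq_len(nrow(its$edges)), ctx_rows)
    subsets <- if (length(ctx_rows) <= 5) {
      unlist(lapply(0:length(ctx_rows), function(k)
        utils::combn(ctx_rows, k, simplify = FALSE)), recursive = FALSE)
    } else {
      lapply(1:10, function(i) {
        set.seed(seed * 100 + i)
        sample(ctx_rows, sample(0:length(ctx_rows), 1))
      })
    }
    for (rows in subsets) {
      keep <- union(req, unique(unlist(its$edges[c(re_rows, rows),
                                                 c("a", "b")])))
      rule <- extract_rule(its, keep, edge_rows = c(re_rows, rows))
      out <- apply_rule(rule, fx$truth$G,
                        stats::setNames(sort(keep), as.character(sort(keep))))
      expect_false(is.null(out))
      expect_true(graphs_equal(out$H, fx$truth$H))
      expect_identical(out$alpha, stats::setNames(fx$truth$G$atoms$id,
                                                  as.character(fx$truth$G$atoms$id)))
    }
  }
})

test_that("maximal and reduced contexts yield the same product", {
  fx <- fixture_for(5)
  its <- fx$truth$its
  req <- union(unique(unlist(its_reaction_edges(its)[, c("a", "b")])),
               rdm2dpo:::its_changed_vertices(its))
  full <- extract_rule(its, its$atoms$id)
  re_rows <- which(is.na(its$edges$order_g) | is.na(its$edges$order_h) |
                     its$edges$order_g != its$edges$order_h)
  keep <- union(req, unique(unlist(its$edges[re_rows, c("a", "b")])))
  minimal <- extract_rule(its, keep, edge_rows = re_rows)
  idm <- function(ids) stats::setNames(ids, as.character(ids))
  h_full <- apply_rule(full, fx$truth$G, idm(sort(full$left$atoms$id)))$H
  h_min <- apply_rule(minimal, fx$truth$G, idm(sort(minimal$left$atoms$id)))$H
  expect_true(graphs_equal(h_full, h_min))
})

test_that("rule application conserves atoms and elements", {
  for (seed in c(6, 11)) {
    fx <- fixture_for(seed)
    res <- run_pipeline(fx$record, fx$molecules, fx$codes)
    rg <- res$graphs
    for (rule in res$rules) {
      v <- validate_rule(rule, rg$G, lapply(rdm2dpo:::mg_components(rg$H),
                                            function(i) mg_subgraph(rg$H, i)))
      expect_identical(sort(v$H$atoms$id), sort(rg$G$atoms$id))
      expect_identical(sort(v$H$atoms$element), sort(rg$G$atoms$element))
    }
  }
})
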