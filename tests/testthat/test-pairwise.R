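test_that("embedding counts follow symmetry and forcing", {
  single_c <- mg("C", 3)
  single_c$atoms$role <- "R"
  expect_length(enumerate_embeddings(single_c, ethane()), 2L)

  cco <- mg(c("C", "C", "O"), c(3, 2, 1),
            bond_df(c(1, 2, "single"), c(2, 3, "single")))
  cco$atoms$role <- c("R", "M", "M")
  expect_length(enumerate_embeddings(cco, ethanol()), 1L)
})

test_that("3-ring hosts defeat path-shaped patterns whose wildcards collide", {
  ## epoxide heavy atoms: a C-C-O triangle
  epoxide <- mg(c("C", "C", "O"), c(2, 2, 0),
                bond_df(c(1, 2, "single"), c(2, 3, "single"),
                        c(1, 3, "single")))
  ## RDM-derived pattern: the ring is encoded as a path R-CH2-CH2-R, so both
  ## wildcards would need to land on the same third ring atom
  path <- mg(c("*", "C", "C", "*"), c(0, 2, 2, 0),
             bond_df(c(1, 2, "single"), c(2, 3, "single"), c(3, 4, "single")))
  path$atoms$wildcard <- c(TRUE, FALSE, FALSE, TRUE)
  path$atoms$role <- c(NA, "R", "M", NA)
  expect_length(enumerate_embeddings(path, epoxide), 0L)
  ## the same pattern embeds fine once the ring is large enough
  cyclopentane <- mg(rep("C", 5), rep(2, 5),
                     bond_df(c(1, 2, "single"), c(2, 3, "single"),
                             c(3, 4, "single"), c(4, 5, "single"),
                             c(1, 5, "single")))
  expect_gt(length(enumerate_embeddings(path, cyclopentane)), 0L)
})

test_that("orientation is decided by which sides embed", {
  ## asymmetric: the left side needs C(-O)(-C), only ethanol has it
  pat <- make_pattern_graphs(parse_rdm("C1b-C1a:O1a-*:C1a-C1a"))
  A <- ethanol(); B <- ethane()
  expect_equal(orient_sides(list(pat), A, B), "as-is")
  expect_equal(orient_sides(list(pat), B, A), "swapped")
  ## fully symmetric molecules admit both orientations
  pat2 <- make_pattern_graphs(parse_rdm("C1a-C1a:*-*:C1b-C1b"))
  expect_equal(orient_sides(list(pat2), propane(), propane()), "both")
  ## neither side embeds
  expect_equal(orient_sides(list(pat), cyclopropane(), cyclopropane()),
               "neither")
})

test_that("overlap consistency follows the shared-vertex role condition", {
  p <- make_pattern_graphs(parse_rdm("C1a-C1a:*-*:*-*"))[[1]]
  mk <- function(lmap, rmap) list(pattern = p, left = lmap, right = rmap)
  root <- names(p$corr)[1]
  ## disjoint images: vacuously consistent
  e1 <- mk(stats::setNames(1L, root), stats::setNames(1L, as.character(p$corr[[root]])))
  e2 <- mk(stats::setNames(2L, root), stats::setNames(2L, as.character(p$corr[[root]])))
  expect_true(check_overlap_consistency(e1, e2))
  ## shared vertex, both matched to the same product atom: consistent
  e3 <- mk(stats::setNames(1L, root), stats::setNames(1L, as.character(p$corr[[root]])))
  expect_true(check_overlap_consistency(e1, e3))
  ## shared vertex matched to different product atoms: inconsistent
  e4 <- mk(stats::setNames(1L, root), stats::setNames(5L, as.character(p$corr[[root]])))
  expect_false(check_overlap_consistency(e1, e4))
  ## shared vertex matched in one code but D in the other: inconsistent
  pd <- make_pattern_graphs(parse_rdm("C1b-C1a:C1a-*:C1a-C1a"))[[1]]
  roles <- stats::setNames(pd$left$atoms$role, pd$left$atoms$id)
  d_id <- pd$left$atoms$id[roles %in% "D"]
  r_id <- as.integer(names(pd$corr))[roles[names(pd$corr)] == "R"]
  m_id <- as.integer(names(pd$corr))[roles[names(pd$corr)] == "M"]
  e5 <- list(
    pattern = pd,
    left = stats::setNames(c(3L, 1L, 2L), as.character(c(r_id, d_id, m_id))),
    right = stats::setNames(c(30L, 20L),
                            as.character(c(pd$corr[[as.character(r_id)]],
                                           pd$corr[[as.character(m_id)]]))))
  ## host atom 1 is a D-atom in e5 but a matched R-atom in e1
  expect_false(check_overlap_consistency(e5, e1))
})

test_that("pairwise assembly equals the brute-force combination oracle", {
  ## symmetric diol: two codes, multiply embeddable, with both consistent
  ## and inconsistent pairings
  diol <- mg(c("O", "C", "C", "O"), c(1, 2, 2, 1),
             bond_df(c(1, 2, "single"), c(2, 3, "single"), c(3, 4, "single")))
  codes <- list(parse_rdm("C1b-C1b:*-*:O1a+C1b-O1a+C1b", "RCt"),
                parse_rdm("C1b-C1b:*-*:O1a+C1b-O1a+C1b", "RCt"))
  got <- assemble_pairwise(codes, diol, diol)
  expect_equal(attr(got, "status"), "ok")

  ## oracle: enumerate every (variant, left, right) combination per code,
  ## filter by the union matching being a matching and by the role condition
  opts <- lapply(seq_along(codes), function(i) {
    out <- list()
    for (p in make_pattern_graphs(codes[[i]], code_index = i)) {
      for (le in enumerate_embeddings(p$left, diol))
        for (re in enumerate_embeddings(p$right, diol))
          out[[length(out) + 1L]] <- list(pattern = p, left = le, right = re)
    }
    out
  })
  n_ok <- 0L; keys <- character()
  for (i1 in seq_along(opts[[1]])) for (i2 in seq_along(opts[[2]])) {
    es <- list(opts[[1]][[i1]], opts[[2]][[i2]])
    pairs <- do.call(rbind, lapply(es, function(e) {
      data.frame(a = unname(e$left[names(e$pattern$corr)]),
                 b = unname(e$right[as.character(e$pattern$corr)]))
    }))
    pairs <- unique(pairs)
    if (anyDuplicated(pairs$a) || anyDuplicated(pairs$b)) next
    ## role condition at shared vertices
    role_at <- function(e, v, side) {
      m <- if (side == "l") e$left else e$right
      g <- if (side == "l") e$pattern$left else e$pattern$right
      x <- as.integer(names(m)[match(v, m)])
      if (is.na(x)) return(NA_character_)
      g$atoms$role[match(x, g$atoms$id)]
    }
    bad <- FALSE
    for (side in c("l", "r")) {
      ms <- lapply(es, function(e) if (side == "l") e$left else e$right)
      for (v in intersect(unname(ms[[1]]), unname(ms[[2]]))) {
        r1 <- role_at(es[[1]], v, side); r2 <- role_at(es[[2]], v, side)
        if (is.na(r1) || is.na(r2) || !(r1 %in% c("R", "D", "M")) ||
              !(r2 %in% c("R", "D", "M"))) next
        if ((r1 == "D") != (r2 == "D")) { bad <- TRUE; break }
      }
    }
    if (bad) next
    key <- paste(sort(paste(pairs$a, pairs$b)), collapse = ";")
    if (!(key %in% keys)) { keys <- c(keys, key); n_ok <- n_ok + 1L }
  }
  expect_equal(length(got), n_ok)
  ## at least one combination was rejected by the consistency conditions
  expect_lt(length(got), length(opts[[1]]) * length(opts[[2]]))
})

test_that("assembly output satisfies the pairwise-pattern invariants", {
  fx <- fixture_for(7)
  link <- fx$record$rclass_links[[1]]
  codes <- lapply(fx$codes[[link$rclass_id]], parse_rdm)
  pw <- assemble_pairwise(codes, fx$molecules[[link$reactant]],
                          fx$molecules[[link$product]])
  expect_gt(length(pw), 0L)
  for (pp in pw) {
    expect_false(anyDuplicated(pp$matching$a) > 0)
    expect_false(anyDuplicated(pp$matching$b) > 0)
    for (v in names(pp$roles_a)) {
      r <- pp$roles_a[[v]]
      if ("D" %in% r && !any(c("R", "M") %in% r)) {
        expect_false(as.integer(v) %in% pp$matching$a)
      }
      if (any(c("R", "M") %in% r)) {
        expect_true(as.integer(v) %in% pp$matching$a)
      }
    }
  }
})

test_that("atoms disconnected from all images never change the assembly", {
  diol <- mg(c("O", "C", "C", "O"), c(1, 2, 2, 1),
             bond_df(c(1, 2, "single"), c(2, 3, "single"), c(3, 4, "single")))
  codes <- list(parse_rdm("C1b-C1b:*-*:O1a+C1b-O1a+C1b", "RCt"))
  base <- assemble_pairwise(codes, diol, diol)
  bigger <- molgraph(rbind(diol$atoms,
                           data.frame(id = 99L, element = "N", hcount = 2L,
                                      wildcard = FALSE, role = NA_character_)),
                     diol$bonds)
  more <- assemble_pairwise(codes, bigger, diol)
  expect_equal(length(more), length(base))
  expect_identical(lapply(more, function(p) p$matching),
                   lapply(base, function(p) p$matching))
})

test_that("the combination cap triggers a combinatorics skip", {
  decane <- mg(rep("C", 10), c(3, rep(2, 8), 3),
               do.call(bond_df, lapply(1:9, function(i)
                 c(i, i + 1, "single"))))
  codes <- list(parse_rdm("C1b-C1b:*-*:C1b+C1b-C1b+C1b", "RCd"))
  res <- assemble_pairwise(codes, decane, decane, cap = 10)
  expect_equal(attr(res, "status"), "combinatorics")
  expect_length(res, 0L)
})
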