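#' KEGG atom type of one atom in a molecule
#'
#' Rule-based classifier covering the atom environments the synthetic
#' fixture generator can produce (C/N/O/S skeletons, single and double
#' bonds, all-carbon rings). Consistent with the bundled type-graph table:
#' the returned code's first type graph always embeds rooted at the atom.
#'
#' @param mol a `molgraph`.
#' @param v atom id.
#' @return atom-type code string.
#' @export
kegg_atom_type <- function(mol, v) {
  i <- base::match(v, mol$atoms$id)
  el <- mol$atoms$element[i]; h <- mol$atoms$hcount[i]
  idx <- mg_bond_index(mol)
  nb <- sort(mg_nbrs(mol)[[as.character(v)]])
  ords <- vapply(nb, function(u) mol$bonds$order[mg_bond_row(idx, v, u)],
                 character(1))
  rings <- vapply(nb, function(u) mol$bonds$ring[mg_bond_row(idx, v, u)],
                  logical(1))
  nels <- mol$atoms$element[base::match(nb, mol$atoms$id)]
  deg <- length(nb)
  in_ring <- any(rings)
  has_double <- any(ords == "double")
  has_triple <- any(ords == "triple")
  has_arom <- any(ords == "aromatic")
  pick <- function(...) {
    x <- c(...)
    if (is.na(x[1])) stop("no atom type for ", el, " (h=", h, ", deg=", deg, ")")
    x[1]
  }
  if (el == "C") {
    if (has_arom) return(if (h >= 1) "C8x" else "C8y")
    if (has_triple) return(if (h >= 1) "C3a" else "C3b")
    if (has_double && "O" %in% nels[ords == "double"]) {
      others <- nb[!(ords == "double" & nels == "O")]
      oels <- nels[ords == "single"]
      osingle <- nb[ords == "single" & nels == "O"]
      if (length(osingle)) {
        oh <- mol$atoms$hcount[base::match(osingle, mol$atoms$id)]
        if (any(oh >= 1)) return("C6a")
        return(if (any(rings)) "C7x" else "C7a")
      }
      if (h >= 1) return("C4a")
      return(if (any(rings)) "C5x" else "C5a")
    }
    if (has_double) {
      return(pick(switch(as.character(h), "2" = "C2a", "1" = if (in_ring) "C2x" else "C2b",
                         "0" = if (in_ring) "C2y" else "C2c", NA_character_)))
    }
    if (in_ring) {
      return(pick(switch(as.character(h), "2" = "C1x", "1" = "C1y",
                         "0" = "C1z", NA_character_)))
    }
    return(pick(switch(as.character(h), "3" = "C1a", "2" = "C1b",
                       "1" = "C1c", "0" = "C1d", NA_character_)))
  }
  if (el == "N") {
    if (has_arom) return(if (h >= 1) "N4x" else if (deg >= 3) "N4y" else "N5x")
    if (has_triple) return("N3a")
    if (has_double) {
      if (in_ring) return("N2x")
      return(if (h >= 1) "N2a" else "N2b")
    }
    if (in_ring) return(if (h >= 1) "N1x" else "N1y")
    if (deg >= 4) return("N1d")
    return(pick(switch(as.character(h), "2" = "N1a", "1" = "N1b",
                       "0" = "N1c", NA_character_)))
  }
  if (el == "O") {
    if (deg == 0L) return("O0")
    if (has_double) {
      cc <- nb[ords == "double"][1]
      if (nels[ords == "double"][1] == "C") {
        cnb <- sort(mg_nbrs(mol)[[as.character(cc)]])
        cords <- vapply(cnb, function(u) mol$bonds$order[mg_bond_row(idx, cc, u)],
                        character(1))
        cnels <- mol$atoms$element[base::match(cnb, mol$atoms$id)]
        osing <- cnb[cords == "single" & cnels == "O"]
        ci <- base::match(cc, mol$atoms$id)
        if (length(osing)) {
          oh <- mol$atoms$hcount[base::match(osing, mol$atoms$id)]
          if (any(oh >= 1)) return("O6a")
          return(if (any(mol$bonds$ring[vapply(cnb, function(u)
            mg_bond_row(idx, cc, u), integer(1))])) "O7x" else "O7a")
        }
        if (mol$atoms$hcount[ci] >= 1) return("O4a")
        return(if (any(mol$bonds$ring[vapply(cnb, function(u)
          mg_bond_row(idx, cc, u), integer(1))])) "O5x" else "O5a")
      }
      return("O0")
    }
    if (deg == 1L) {
      return(switch(nels[1], P = "O1c", S = "O1d", "O1a"))
    }
    if (in_ring) return("O2x")
    np <- sum(nels == "P"); ns <- sum(nels == "S")
    if (np >= 2) return("O2c")
    if (np == 1) return("O2b")
    if (ns >= 2) return("O3c")
    if (ns == 1) return("O3a")
    return("O2a")
  }
  if (el == "S") {
    if (h >= 1 && deg == 1L) return("S1a")
    if (any(nels == "S")) return(if (in_ring) "S3x" else "S3a")
    if (in_ring) return("S2x")
    return(if (deg >= 1) "S2a" else "S0")
  }
  if (el == "P") {
    return(if (any(nels == "O")) "P1b" else "P1a")
  }
  if (el %in% HALOGENS) return("X")
  "Z"
}

ELEMENT_CAPACITY <- c(C = 4L, N = 3L, O = 2L, S = 2L)

## random connected molecule: tree skeleton, optional C-C double bonds on
## bridges, optional one all-carbon single-bond ring
random_molecule <- function(n, compound_id, ring_prob = 0.3,
                            double_prob = 0.25) {
  elements <- c("C", sample(names(ELEMENT_CAPACITY), n - 1, replace = TRUE,
                            prob = c(0.7, 0.1, 0.15, 0.05)))
  cap <- ELEMENT_CAPACITY[elements]
  used <- integer(n)
  bonds <- NULL
  for (i in seq_len(n)[-1]) {
    cand <- which(seq_len(n) < i & used < cap[seq_len(n)] - (elements == "C"))
    if (!length(cand)) cand <- which(seq_len(n) < i & used < cap[seq_len(n)])
    if (!length(cand)) return(NULL)
    j <- if (length(cand) == 1L) cand else sample(cand, 1)
    bonds <- rbind(bonds, data.frame(a = j, b = i, order = "single",
                                     stringsAsFactors = FALSE))
    used[i] <- used[i] + 1L; used[j] <- used[j] + 1L
  }
  ## upgrade some C-C bonds to double where capacity allows
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    if (elements[a] == "C" && elements[b] == "C" &&
        used[a] < cap[a] && used[b] < cap[b] &&
        stats::runif(1) < double_prob) {
      bonds$order[k] <- "double"
      used[a] <- used[a] + 1L; used[b] <- used[b] + 1L
    }
  }
  ## close one all-carbon ring with a single bond, if possible
  if (stats::runif(1) < ring_prob) {
    cs <- which(elements == "C" & used < cap)
    cs <- cs[!vapply(cs, function(v) any(
      (bonds$a == v | bonds$b == v) & bonds$order != "single"), logical(1))]
    if (length(cs) >= 2L) {
      ## tree distances: rings below 5 atoms are not representable by
      ## radius-2 type graphs (wildcards would collide, the 3-ring failure
      ## class), so only close rings of size >= 5
      adj <- lapply(seq_len(n), function(v)
        c(bonds$b[bonds$a == v], bonds$a[bonds$b == v]))
      tree_dist <- function(s, t) {
        d <- rep(NA_integer_, n); d[s] <- 0L; q <- s
        while (length(q)) {
          v <- q[1]; q <- q[-1]
          for (u in adj[[v]]) if (is.na(d[u])) { d[u] <- d[v] + 1L; q <- c(q, u) }
        }
        d[t]
      }
      pairs <- utils::combn(cs, 2)
      ok <- apply(pairs, 2, function(p) tree_dist(p[1], p[2]) >= 4L)
      pairs <- pairs[, ok, drop = FALSE]
      if (ncol(pairs)) {
        p <- pairs[, sample(ncol(pairs), 1)]
        ## only close if the ring path is all-carbon and single-bonded
        bonds <- rbind(bonds, data.frame(a = p[1], b = p[2], order = "single",
                                         stringsAsFactors = FALSE))
        used[p[1]] <- used[p[1]] + 1L; used[p[2]] <- used[p[2]] + 1L
      }
    }
  }
  hc <- cap - used
  molgraph(data.frame(id = seq_len(n), element = elements, hcount = hc,
                      stringsAsFactors = FALSE),
           bonds, compound_id = compound_id)
}

#' Generate a synthetic reaction fixture with ground truth
#'
#' Builds random small molecules, applies a reaction template (bond
#' cleavage, condensation, group transfer, or a bond-order change), derives
#' the true ITS graph, and emits the RDM codes that KEGG would write for
#' every exchanging reactant/product pair — case (i) when the pair has
#' unmatched non-hydrogen atoms (R-atom adjacent to an unmatched D-atom,
#' matched neighbors as M-atoms), case (ii) when only atom types change.
#' The ground-truth atom map is retained for end-to-end recovery tests.
#'
#' @param seed integer seed; all randomness is derived from it.
#' @param template one of `"cleavage"`, `"condensation"`, `"transfer"`,
#'   `"order_change"`, or `"none"` (a degenerate no-change reaction).
#' @param n_atoms heavy-atom count of the (first) reactant.
#' @param drop_link optionally drop the RCLASS link with this index from the
#'   record (to exercise the missing-RCLASS path).
#' @return list with `molecules` (named list of `molgraph`s), `record`
#'   ([reaction_record()]), `codes` (named list: rclass id -> character
#'   vector of RDM code strings), `truth` (`list(G, H, alpha, its)`), or
#'   `NULL` if the random draw admits no legal edit.
#' @export
make_fixture <- function(seed, template = c("transfer", "cleavage",
                                            "condensation", "order_change",
                                            "none"),
                         n_atoms = 6L, drop_link = NULL) {
  template <- match.arg(template)
  set.seed(seed)
  for (attempt in 1:25) {
    fx <- try_make_fixture(template, n_atoms, drop_link)
    if (!is.null(fx)) return(fx)
  }
  NULL
}

try_make_fixture <- function(template, n_atoms, drop_link) {
  mols_in <- list()
  edits <- NULL
  if (template %in% c("cleavage", "order_change", "none")) {
    m <- random_molecule(n_atoms, "S001")
    if (is.null(m)) return(NULL)
    mols_in <- list(S001 = m)
  } else {
    m1 <- random_molecule(n_atoms, "S001")
    m2 <- random_molecule(max(2L, n_atoms - 3L), "S002", ring_prob = 0)
    if (is.null(m1) || is.null(m2)) return(NULL)
    mols_in <- list(S001 = m1, S002 = m2)
  }
  side <- data.frame(compound_id = names(mols_in), n = 1L,
                     stringsAsFactors = FALSE)
  u <- mg_disjoint_union(mols_in)
  G <- u$graph
  bridges <- function(g) {
    g2 <- mg_recompute_rings(g)
    which(!g2$bonds$ring)
  }
  H <- G
  if (template == "cleavage") {
    k <- bridges(G)
    if (!length(k)) return(NULL)
    k <- k[sample(length(k), 1)]
    a <- G$bonds$a[k]; b <- G$bonds$b[k]
    if (G$bonds$order[k] != "single") return(NULL)
    H$bonds <- H$bonds[-k, , drop = FALSE]
    H$atoms$hcount[base::match(c(a, b), H$atoms$id)] <-
      H$atoms$hcount[base::match(c(a, b), H$atoms$id)] + 1L
  } else if (template == "condensation") {
    ids1 <- unname(u$maps[[1]]); ids2 <- unname(u$maps[[2]])
    x <- ids1[G$atoms$hcount[base::match(ids1, G$atoms$id)] >= 1L]
    y <- ids2[G$atoms$hcount[base::match(ids2, G$atoms$id)] >= 1L]
    if (!length(x) || !length(y)) return(NULL)
    x <- x[sample(length(x), 1)]; y <- y[sample(length(y), 1)]
    H$bonds <- rbind(H$bonds, data.frame(a = min(x, y), b = max(x, y),
                                         order = "single", ring = FALSE,
                                         stringsAsFactors = FALSE))
    H$atoms$hcount[base::match(c(x, y), H$atoms$id)] <-
      H$atoms$hcount[base::match(c(x, y), H$atoms$id)] - 1L
  } else if (template == "transfer") {
    ids1 <- unname(u$maps[[1]]); ids2 <- unname(u$maps[[2]])
    k <- bridges(G)
    k <- k[G$bonds$a[k] %in% ids1 & G$bonds$b[k] %in% ids1 &
             G$bonds$order[k] == "single"]
    if (!length(k)) return(NULL)
    k <- k[sample(length(k), 1)]
    xy <- c(G$bonds$a[k], G$bonds$b[k])
    y <- xy[sample(2, 1)]; x <- setdiff(xy, y)
    z <- ids2[G$atoms$hcount[base::match(ids2, G$atoms$id)] >= 1L]
    if (!length(z)) return(NULL)
    z <- z[sample(length(z), 1)]
    H$bonds <- H$bonds[-k, , drop = FALSE]
    H$bonds <- rbind(H$bonds, data.frame(a = min(y, z), b = max(y, z),
                                         order = "single", ring = FALSE,
                                         stringsAsFactors = FALSE))
    H$atoms$hcount[base::match(x, H$atoms$id)] <-
      H$atoms$hcount[base::match(x, H$atoms$id)] + 1L
    H$atoms$hcount[base::match(z, H$atoms$id)] <-
      H$atoms$hcount[base::match(z, H$atoms$id)] - 1L
  } else if (template == "order_change") {
    k <- bridges(G)
    ch <- vapply(k, function(kk) {
      a <- G$bonds$a[kk]; b <- G$bonds$b[kk]
      els <- G$atoms$element[base::match(c(a, b), G$atoms$id)]
      hs <- G$atoms$hcount[base::match(c(a, b), G$atoms$id)]
      all(els == "C") &&
        ((G$bonds$order[kk] == "single" && all(hs >= 1)) ||
           G$bonds$order[kk] == "double")
    }, logical(1))
    k <- k[ch]
    if (!length(k)) return(NULL)
    k <- k[sample(length(k), 1)]
    a <- G$bonds$a[k]; b <- G$bonds$b[k]
    if (G$bonds$order[k] == "single") {
      H$bonds$order[k] <- "double"
      H$atoms$hcount[base::match(c(a, b), H$atoms$id)] <-
        H$atoms$hcount[base::match(c(a, b), H$atoms$id)] - 1L
    } else {
      H$bonds$order[k] <- "single"
      H$atoms$hcount[base::match(c(a, b), H$atoms$id)] <-
        H$atoms$hcount[base::match(c(a, b), H$atoms$id)] + 1L
    }
  }
  H <- mg_recompute_rings(H)
  G <- mg_recompute_rings(G)
  alpha <- stats::setNames(G$atoms$id, as.character(G$atoms$id))
  ## product molecules: components of H, renumbered locally
  comps <- mg_components(H)
  products <- list(); hmap_rows <- list()
  for (ci in seq_along(comps)) {
    ids <- comps[[ci]]
    sub <- mg_subgraph(H, ids)
    local <- stats::setNames(seq_along(ids), as.character(ids))
    sub$atoms$id <- unname(local[as.character(sub$atoms$id)])
    if (nrow(sub$bonds)) {
      sub$bonds$a <- unname(local[as.character(sub$bonds$a)])
      sub$bonds$b <- unname(local[as.character(sub$bonds$b)])
      sw <- sub$bonds$a > sub$bonds$b
      tmp <- sub$bonds$a[sw]; sub$bonds$a[sw] <- sub$bonds$b[sw]
      sub$bonds$b[sw] <- tmp
    }
    if (length(sub$loops)) names(sub$loops) <-
      as.character(unname(local[names(sub$loops)]))
    cid <- sprintf("P%03d", ci)
    sub$compound_id <- cid
    sub <- mg_recompute_rings(sub)
    products[[cid]] <- sub
    hmap_rows[[ci]] <- data.frame(gid = ids, compound_id = cid, instance = 1L,
                                  local = unname(local), stringsAsFactors = FALSE)
  }
  hmap <- do.call(rbind, hmap_rows)
  gmap <- do.call(rbind, lapply(seq_along(mols_in), function(i) {
    m <- u$maps[[i]]
    data.frame(gid = unname(m), compound_id = names(mols_in)[i], instance = 1L,
               local = as.integer(names(m)), stringsAsFactors = FALSE)
  }))
  ## every atom's assigned type graph must embed back at that atom, else the
  ## draw is rejected (keeps generator and dictionary mutually consistent)
  for (m in c(mols_in, products)) {
    if (!typing_consistent(m)) return(NULL)
  }
  emitted <- emit_rdm_codes(G, H, alpha, gmap, hmap, mols_in, products)
  if (template != "none" && !length(emitted$codes)) return(NULL)
  links <- emitted$links
  if (!is.null(drop_link)) {
    if (drop_link > length(links)) return(NULL)
    dropped <- links[[drop_link]]
    links <- links[-drop_link]
    emitted$codes[[dropped$rclass_id]] <- NULL
    if (!length(links)) return(NULL)
  }
  record <- reaction_record(sprintf("RXN_%s", template),
                            side, data.frame(
                              compound_id = names(products), n = 1L,
                              stringsAsFactors = FALSE),
                            links)
  list(molecules = c(mols_in, products), record = record,
       codes = emitted$codes,
       truth = list(G = G, H = H, alpha = alpha,
                    its = its_graph(G, H, alpha),
                    gmap = gmap, hmap = hmap))
}

## TRUE iff every atom's assigned type admits a rooted embedding at the atom
typing_consistent <- function(mol, table = atom_type_table()) {
  for (v in mol$atoms$id) {
    code <- tryCatch(kegg_atom_type(mol, v), error = function(e) NULL)
    if (is.null(code)) return(FALSE)
    alts <- tryCatch(atom_type_lookup(code, table), error = function(e) NULL)
    if (is.null(alts) || !length(alts)) return(FALSE)
    ok <- any(vapply(alts, function(a) {
      pat <- a$graph
      pat$atoms$role[pat$atoms$id == a$focal] <- "R"  # exact hcount at focal
      length(graph_match(pat, mol, mode = "mono", lenient = TRUE,
                         seed = stats::setNames(v, as.character(a$focal)),
                         max_results = 1)) > 0
    }, logical(1)))
    if (!ok) return(FALSE)
  }
  TRUE
}

## RDM codes per exchanging reactant/product pair, from the ground truth
emit_rdm_codes <- function(G, H, alpha, gmap, hmap, reactants, products) {
  codes <- list(); links <- list()
  type_in <- function(side_map, mols, gid, host) {
    row <- side_map[side_map$gid == gid, ]
    kegg_atom_type(mols[[row$compound_id]], row$local)
  }
  gn <- mg_nbrs(G); hn <- mg_nbrs(H)
  for (rc in unique(gmap$compound_id)) {
    for (pc in unique(hmap$compound_id)) {
      aids <- gmap$gid[gmap$compound_id == rc]
      bids <- hmap$gid[hmap$compound_id == pc]
      matched <- aids[unname(alpha[as.character(aids)]) %in% bids]
      if (!length(matched)) next
      unA <- setdiff(aids, matched)
      unB <- setdiff(bids, unname(alpha[as.character(matched)]))
      tA <- function(v) type_in(gmap, reactants, v, G)
      tB <- function(v) type_in(hmap, products, v, H)
      pair_codes <- character()
      if (length(unA) || length(unB)) {
        ## case (i): R-atoms are matched atoms adjacent to an unmatched atom
        r_atoms <- matched[vapply(matched, function(x) {
          any(gn[[as.character(x)]] %in% unA) ||
            any(hn[[as.character(alpha[[as.character(x)]])]] %in% unB)
        }, logical(1))]
        for (r in sort(r_atoms)) {
          dr <- sort(intersect(gn[[as.character(r)]], unA))
          dp <- sort(intersect(hn[[as.character(alpha[[as.character(r)]])]], unB))
          mm <- sort(intersect(gn[[as.character(r)]], matched))
          drt <- sort(vapply(dr, tA, character(1)))
          dpt <- sort(vapply(dp, function(v) tB(v), character(1)))
          npad <- max(length(drt), length(dpt), 1L)
          drt <- c(drt, rep("*", npad - length(drt)))
          dpt <- c(dpt, rep("*", npad - length(dpt)))
          msec <- if (length(mm)) {
            paste(paste(vapply(mm, tA, character(1)), collapse = "+"),
                  paste(vapply(mm, function(v)
                    tB(alpha[[as.character(v)]]), character(1)),
                    collapse = "+"), sep = "-")
          } else "*-*"
          pair_codes <- c(pair_codes, paste(
            paste(tA(r), tB(alpha[[as.character(r)]]), sep = "-"),
            paste(paste(drt, collapse = "+"), paste(dpt, collapse = "+"),
                  sep = "-"),
            msec, sep = ":"))
        }
      } else {
        ## case (ii): R-atoms are matched atoms whose type changes
        changed <- matched[vapply(matched, function(x)
          tA(x) != tB(alpha[[as.character(x)]]), logical(1))]
        for (r in sort(changed)) {
          mm <- sort(gn[[as.character(r)]])
          msec <- if (length(mm)) {
            paste(paste(vapply(mm, tA, character(1)), collapse = "+"),
                  paste(vapply(mm, function(v)
                    tB(alpha[[as.character(v)]]), character(1)),
                    collapse = "+"), sep = "-")
          } else "*-*"
          pair_codes <- c(pair_codes, paste(
            paste(tA(r), tB(alpha[[as.character(r)]]), sep = "-"),
            "*-*", msec, sep = ":"))
        }
      }
      if (length(pair_codes)) {
        rid <- sprintf("RCX_%s_%s", rc, pc)
        codes[[rid]] <- unique(pair_codes)
        links[[length(links) + 1L]] <- list(rclass_id = rid, reactant = rc,
                                            product = pc)
      }
    }
  }
  list(codes = codes, links = links)
}
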