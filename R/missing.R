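#' D-subgraphs of a partially matched reaction state
#'
#' When RCLASSes are missing, some D-atoms stay unmatched after rule
#' assembly. The connected subgraphs induced by the unmatched D-atoms on
#' each reaction side are the handles used to complete the atom map: each
#' must reappear as an isomorphic subgraph on the opposite side.
#'
#' @param cand a partial candidate state from [combine_reaction()].
#' @param rg reaction graphs (`combine_reaction()$graphs`).
#' @return list of `list(side, ids, graph)` with `side` `"reactant"` or
#'   `"product"`, ordered largest-first (larger subgraphs constrain more).
#' @export
d_subgraphs <- function(cand, rg) {
  out <- list()
  for (side in c("reactant", "product")) {
    host <- if (side == "reactant") rg$G else rg$H
    matched <- if (side == "reactant") cand$matching$a else cand$matching$b
    roles <- if (side == "reactant") cand$roles_a else cand$roles_b
    dids <- as.integer(names(roles)[vapply(roles, function(r) "D" %in% r,
                                           logical(1))])
    dids <- setdiff(dids, matched)
    if (!length(dids)) next
    sub <- mg_subgraph(host, dids)
    for (comp in mg_components(sub)) {
      out[[length(out) + 1L]] <- list(side = side, ids = comp,
                                      graph = mg_subgraph(sub, comp))
    }
  }
  if (length(out) > 1L) {
    out <- out[order(-vapply(out, function(d) length(d$ids), integer(1)),
                     vapply(out, function(d) paste(d$ids, collapse = ","),
                            character(1)))]
  }
  out
}

#' Candidate matches for unmatched D-subgraphs
#'
#' For every D-subgraph, all isomorphic counterparts on the opposite side of
#' the reaction are enumerated (VF2-style subgraph search on element and
#' bond labels; hydrogen counts are not constrained). A counterpart is a
#' candidate only if: (1) it is not one of the original pairwise pattern
#' images; (2) where it overlaps atoms of an integrated pairwise pattern,
#' the overlap contains at least one R-atom; (3) it maps onto D-atoms of
#' other pairwise patterns only if it consists exclusively of D-atoms;
#' (4) hydrogen atoms are excluded. Candidates may not re-use atoms that
#' are already matched.
#'
#' @param ds output of [d_subgraphs()].
#' @param cand the partial candidate state.
#' @param rg reaction graphs.
#' @return list parallel to `ds`; each element a list of extensions, i.e.
#'   data.frames with columns `a` (reactant atom) and `b` (product atom).
#' @export
match_d_subgraphs <- function(ds, cand, rg) {
  lapply(ds, function(d) {
    host <- if (d$side == "reactant") rg$H else rg$G
    covered <- if (d$side == "reactant") cand$core_b %||% cand$vb
    else cand$core_a %||% cand$va
    roles <- if (d$side == "reactant") cand$roles_b else cand$roles_a
    matched <- if (d$side == "reactant") cand$matching$b else cand$matching$a
    pat <- d$graph
    pat$atoms$hcount <- 0L
    pat$atoms$role <- NA_character_
    cands <- list()
    ## images of the individual contributing pairwise patterns (condition 1)
    part_images <- attr(cand, "part_images")
    ## element and exact bond-order isomorphism: the oxygen bond-order
    ## tolerance is an RDM-pattern convention and does not apply between
    ## concrete molecule fragments (which is why carboxy/CO2 needs its own
    ## special case)
    for (m in graph_match(pat, host, mode = "mono", lenient = TRUE,
                          bond_exact = TRUE)) {
      img <- sort(unname(m))
      if (any(host$atoms$element[base::match(img, host$atoms$id)] == "H")) next
      if (any(img %in% matched)) next
      if (!is.null(part_images)) {
        sets <- if (d$side == "reactant") part_images$vb else part_images$va
        if (any(vapply(sets, function(s) setequal(img, s), logical(1)))) next
      }
      on_d <- vapply(as.character(img), function(k)
        "D" %in% (roles[[k]] %||% character()), logical(1))
      if (any(on_d) && !all(on_d)) next     # condition (3)
      if (!any(on_d)) {
        ## condition (2): a non-D overlap with integrated pattern atoms
        ## must contain at least one R-atom
        overlap <- intersect(img, covered)
        if (length(overlap)) {
          has_r <- any(vapply(as.character(overlap), function(k)
            "R" %in% (roles[[k]] %||% character()), logical(1)))
          if (!has_r) next
        }
      }
      ext <- if (d$side == "reactant") {
        data.frame(a = as.integer(names(m)), b = unname(m))
      } else {
        data.frame(a = unname(m), b = as.integer(names(m)))
      }
      cands[[length(cands) + 1L]] <- ext
    }
    cands
  })
}

#' Carboxy/CO2 special case
#'
#' Decarboxylation turns a carboxy group (R-COOH) into O=C=O; the internal
#' bond changes defeat plain isomorphism matching of the D-subgraph. This
#' recogniser matches a carboxy-shaped D-subgraph (one carbon bonded to two
#' oxygens) onto every free CO2 component on the opposite side, ignoring
#' the bond-order changes.
#'
#' @param d one [d_subgraphs()] entry.
#' @param cand the partial candidate state.
#' @param rg reaction graphs.
#' @return list of extensions (data.frames with columns `a`, `b`); empty if
#'   the subgraph is not carboxy-shaped or no CO2 is present opposite.
#' @export
carboxy_special_case <- function(d, cand, rg) {
  g <- d$graph
  if (mg_n(g) != 3L) return(list())
  els <- sort(g$atoms$element)
  if (!identical(els, c("C", "O", "O"))) return(list())
  cid <- g$atoms$id[g$atoms$element == "C"]
  nb <- mg_nbrs(g)[[as.character(cid)]]
  if (length(nb) != 2L) return(list())
  host <- if (d$side == "reactant") rg$H else rg$G
  matched <- if (d$side == "reactant") cand$matching$b else cand$matching$a
  out <- list()
  for (comp in mg_components(host)) {
    if (length(comp) != 3L) next
    sub <- mg_subgraph(host, comp)
    if (!identical(sort(sub$atoms$element), c("C", "O", "O"))) next
    hc <- sub$atoms$id[sub$atoms$element == "C"]
    hnb <- mg_nbrs(sub)[[as.character(hc)]]
    if (length(hnb) != 2L ||
        !all(sub$bonds$order == "double")) next  # O=C=O
    if (any(comp %in% matched)) next
    os <- sort(g$atoms$id[g$atoms$element == "O"])
    hos <- sort(sub$atoms$id[sub$atoms$element == "O"])
    pairs <- data.frame(ds = c(cid, os), opp = c(hc, hos))
    ext <- if (d$side == "reactant") {
      data.frame(a = pairs$ds, b = pairs$opp)
    } else {
      data.frame(a = pairs$opp, b = pairs$ds)
    }
    out[[length(out) + 1L]] <- ext
  }
  out
}

#' Complete a rule over the rest of its small molecules
#'
#' Adds to `L` and `R` every bond that changes according to the (possibly
#' extended) atom-to-atom map but is not yet part of the rule, together with
#' its incident atoms, and updates atoms whose implicit hydrogen counts
#' change. Idempotent. If the rule still fails to regenerate the products
#' (e.g. a changed bond has an endpoint with no image under the map), the
#' returned rule carries `complete = FALSE`.
#'
#' @param rule a [dpo_rule()] in the id spaces of `G` and `H`.
#' @param G,H reactant and product union graphs.
#' @param alpha optional partial map `V(G) -> V(H)` extending `rule$beta`.
#' @return the completed [dpo_rule()] with its `complete` flag set.
#' @export
complete_small_molecule_rule <- function(rule, G, H, alpha = NULL) {
  if (is.null(alpha)) alpha <- rule$beta
  alpha <- alpha[order(as.integer(names(alpha)))]
  gidx <- mg_bond_index(G); hidx <- mg_bond_index(H)
  addL <- list(); addR <- list(); verts <- integer()
  dom <- as.integer(names(alpha))
  for (k in seq_len(nrow(G$bonds))) {
    a <- G$bonds$a[k]; b <- G$bonds$b[k]
    if (!(a %in% dom && b %in% dom)) next
    hr <- mg_bond_row(hidx, alpha[[as.character(a)]], alpha[[as.character(b)]])
    if (is.na(hr) || H$bonds$order[hr] != G$bonds$order[k]) {
      addL[[length(addL) + 1L]] <- c(a, b); verts <- union(verts, c(a, b))
    }
  }
  inv <- stats::setNames(as.integer(names(alpha)), alpha)
  for (k in seq_len(nrow(H$bonds))) {
    u <- H$bonds$a[k]; v <- H$bonds$b[k]
    if (!(u %in% alpha && v %in% alpha)) next
    a <- inv[[as.character(u)]]; b <- inv[[as.character(v)]]
    gr <- mg_bond_row(gidx, a, b)
    if (is.na(gr) || G$bonds$order[gr] != H$bonds$order[k]) {
      addR[[length(addR) + 1L]] <- c(a, b); verts <- union(verts, c(a, b))
    }
  }
  ## atoms whose implicit hydrogen count changes must be covered too
  for (x in dom) {
    gi <- base::match(x, G$atoms$id)
    hi <- base::match(alpha[[as.character(x)]], H$atoms$id)
    if (G$atoms$hcount[gi] != H$atoms$hcount[hi]) verts <- union(verts, x)
  }
  vl <- sort(union(rule$left$atoms$id, verts))
  keyset <- function(bonds) paste(bonds$a, bonds$b, sep = "|")
  pick_bonds <- function(host, old, pairs, keep) {
    rows <- old
    have <- keyset(old)
    for (p in pairs) {
      key <- paste(min(p), max(p), sep = "|")
      r <- base::match(key, keyset(host$bonds))
      if (!is.na(r) && !(key %in% have)) {
        rows <- rbind(rows, host$bonds[r, , drop = FALSE])
        have <- c(have, key)
      }
    }
    rows[rows$a %in% keep & rows$b %in% keep, , drop = FALSE]
  }
  beta2 <- stats::setNames(unname(alpha[as.character(vl)]), as.character(vl))
  if (anyNA(beta2)) {
    ## a changed edge touches an atom with no image: cannot complete
    rule$complete <- FALSE
    return(rule)
  }
  vr <- sort(unname(beta2))
  L2 <- mg_subgraph(G, vl, edges = pick_bonds(G, rule$left$bonds, addL, vl))
  hpairs <- lapply(addR, function(p)
    c(alpha[[as.character(p[1])]], alpha[[as.character(p[2])]]))
  R2 <- mg_subgraph(H, vr, edges = pick_bonds(H, rule$right$bonds, hpairs, vr))
  out <- dpo_rule(L2, R2, beta2, rule_id = rule$rule_id,
                  provenance = rule$provenance)
  val <- validate_rule(out, G, lapply(mg_components(H), function(ids)
    mg_subgraph(H, ids)))
  out$complete <- isTRUE(val$valid)
  out
}
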