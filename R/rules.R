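#' Combine pairwise pattern graphs of all RCLASSes into DPO rules
#'
#' All cross-RCLASS combinations of pairwise pattern graphs are enumerated.
#' A combination survives if (1) the union of the bipartite matchings is
#' again a matching, and (2) every D-atom is matched by some other pairwise
#' pattern (a D-atom leaves its molecule and must reappear as a matched atom
#' of another reactant/product pair). For each survivor, `L` and `R` are the
#' unions of the embedded patterns restricted to matched atoms, the atom map
#' is the union matching, and the context `K` is maximal. Role precedence:
#' an atom labelled R anywhere is an R-atom; atoms labelled both M and D are
#' treated first as M-atoms and then as D-atoms; imbalances are removed by
#' the balance test.
#'
#' @param record a [reaction_record()].
#' @param molecules named list of `molgraph`s keyed by compound id.
#' @param pairwise list parallel to `record$rclass_links`: each entry the
#'   [assemble_pairwise()] result for that link.
#' @param cap combination limit.
#' @return list with `rules` (validated-candidate [dpo_rule()]s carrying the
#'   defining match in `provenance`), `partials` (consistent combinations
#'   with unmatched D-atoms, for the missing-RCLASS path), `conflicts`
#'   (reports naming clashing atoms) and `status`.
#' @export
combine_reaction <- function(record, molecules, pairwise, cap = 1000) {
  rg <- reaction_graphs(record, molecules)
  nlink <- length(record$rclass_links)
  stopifnot(length(pairwise) == nlink)
  if (any(!lengths(pairwise))) {
    return(list(rules = list(), partials = list(), conflicts = list(),
                status = "no_pairwise", graphs = rg))
  }
  ncomb <- prod(lengths(pairwise))
  if (ncomb > cap) {
    return(list(rules = list(), partials = list(), conflicts = list(),
                status = "combinatorics", graphs = rg))
  }
  lifted <- lapply(seq_len(nlink), function(i) {
    link <- record$rclass_links[[i]]
    lapply(pairwise[[i]], lift_pairwise, link = link, rg = rg)
  })
  rules <- list(); partials <- list(); conflicts <- list()
  for (combo in cartesian_index(lengths(lifted))) {
    cand <- merge_lifted(Map(function(l, k) l[[k]], lifted, combo))
    if (!is.null(cand$clash)) {
      conflicts[[length(conflicts) + 1L]] <- cand$clash
      next
    }
    cand <- with_elements(cand, rg)
    if (length(cand$unmatched_d)) {
      ## balance is deferred: it is re-checked once the D-completion stage
      ## has proposed partners for the unmatched D-atoms
      partials[[length(partials) + 1L]] <- cand
      next
    }
    if (!balance_test(cand)) next
    rule <- state_to_rule(cand, rg, record$reaction_id)
    if (!is.null(rule)) rules[[length(rules) + 1L]] <- rule
  }
  status <- if (length(rules)) "ok"
  else if (length(partials)) "incomplete"
  else if (length(conflicts)) "conflict"
  else "no_rule"
  list(rules = rules, partials = partials, conflicts = conflicts,
       status = status, graphs = rg)
}

## express a pairwise pattern in the global id space of the reaction graphs
lift_pairwise <- function(pp, link, rg) {
  amap <- stats::setNames(instance_ids(rg$gmap, link$reactant),
                          sort(rg$gmap$local[rg$gmap$compound_id == link$reactant &
                                               rg$gmap$instance == 1L]))
  bmap <- stats::setNames(instance_ids(rg$hmap, link$product),
                          sort(rg$hmap$local[rg$hmap$compound_id == link$product &
                                               rg$hmap$instance == 1L]))
  lift_ids <- function(ids, m) unname(m[as.character(ids)])
  lift_roles <- function(roles, m) {
    out <- roles
    if (length(out)) names(out) <- as.character(unname(m[names(roles)]))
    out
  }
  lift_bonds <- function(bonds, m) {
    if (nrow(bonds)) {
      bonds$a <- lift_ids(bonds$a, m); bonds$b <- lift_ids(bonds$b, m)
      sw <- bonds$a > bonds$b
      tmp <- bonds$a[sw]; bonds$a[sw] <- bonds$b[sw]; bonds$b[sw] <- tmp
    }
    bonds
  }
  list(
    va = lift_ids(pp$lhat$atoms$id, amap),
    vb = lift_ids(pp$rhat$atoms$id, bmap),
    core_a = lift_ids(pp$core_a %||% pp$lhat$atoms$id, amap),
    core_b = lift_ids(pp$core_b %||% pp$rhat$atoms$id, bmap),
    ea = lift_bonds(pp$lhat$bonds, amap),
    eb = lift_bonds(pp$rhat$bonds, bmap),
    matching = data.frame(a = lift_ids(pp$matching$a, amap),
                          b = lift_ids(pp$matching$b, bmap)),
    roles_a = lift_roles(pp$roles_a, amap),
    roles_b = lift_roles(pp$roles_b, bmap),
    provenance = pp$provenance)
}

## union of lifted pairwise patterns; detects matching clashes and
## collects unmatched D-atoms (condition (2) failures)
merge_lifted <- function(parts) {
  matching <- unique(do.call(rbind, lapply(parts, `[[`, "matching")))
  dup_a <- matching$a[duplicated(matching$a)]
  dup_b <- matching$b[duplicated(matching$b)]
  if (length(dup_a) || length(dup_b)) {
    clash <- list(reactant_atoms = sort(unique(dup_a)),
                  product_atoms = sort(unique(dup_b)))
    return(list(clash = clash))
  }
  merge_roles <- function(field) {
    acc <- list()
    for (p in parts) {
      for (k in names(p[[field]])) acc[[k]] <- union(acc[[k]], p[[field]][[k]])
    }
    acc
  }
  roles_a <- merge_roles("roles_a"); roles_b <- merge_roles("roles_b")
  d_a <- as.integer(names(roles_a)[vapply(roles_a, function(r)
    "D" %in% r, logical(1))])
  d_b <- as.integer(names(roles_b)[vapply(roles_b, function(r)
    "D" %in% r, logical(1))])
  unmatched_d <- c(setdiff(d_a, matching$a), setdiff(d_b, matching$b))
  out <- list(va = sort(unique(unlist(lapply(parts, `[[`, "va")))),
              vb = sort(unique(unlist(lapply(parts, `[[`, "vb")))),
              core_a = sort(unique(unlist(lapply(parts, `[[`, "core_a")))),
              core_b = sort(unique(unlist(lapply(parts, `[[`, "core_b")))),
              ea = unique(do.call(rbind, lapply(parts, `[[`, "ea"))),
              eb = unique(do.call(rbind, lapply(parts, `[[`, "eb"))),
              matching = matching[order(matching$a), , drop = FALSE],
              roles_a = roles_a, roles_b = roles_b,
              unmatched_d = unmatched_d,
              provenance = do.call(c, lapply(parts, `[[`, "provenance")),
              clash = NULL)
  ## per-part image vertex sets (condition (1) of the D-subgraph matching)
  attr(out, "part_images") <- list(va = lapply(parts, `[[`, "core_a"),
                                   vb = lapply(parts, `[[`, "core_b"))
  out
}

#' Balance test of accumulated atom roles
#'
#' Counts the effective roles per chemical element on the two reaction
#' sides. Precedence R > M > D resolves multiple labels per atom; this is
#' what filters incorrectly declared M-atoms. The candidate passes iff R-
#' and M-counts agree per element between the sides and every effective
#' D-atom has a partner of the same element on the opposite side: either a
#' D-labelled atom, or — when the candidate carries a matching, as after
#' the D-completion stage — the unlabelled atom its matching pair assigns.
#'
#' @param cand a candidate state with `roles_a`, `roles_b`, `elem_a`,
#'   `elem_b` (named element lookups) and optionally `matching` — as
#'   produced inside [combine_reaction()], which attaches the element maps.
#' @return `TRUE` iff balanced.
#' @export
balance_test <- function(cand) {
  eff <- function(roles) {
    stats::setNames(vapply(roles, function(r) {
      if ("R" %in% r) "R" else if ("M" %in% r) "M" else "D"
    }, character(1)), names(roles))
  }
  ea <- eff(cand$roles_a); eb <- eff(cand$roles_b)
  da <- names(ea)[ea == "D"]; db <- names(eb)[eb == "D"]
  ## a matched D-atom whose partner carries no role: the matching declares
  ## the partner its D-counterpart
  if (!is.null(cand$matching) && nrow(cand$matching)) {
    m <- cand$matching
    for (v in da) {
      w <- m$b[m$a == as.integer(v)]
      if (length(w) == 1L && !(as.character(w) %in% names(eb))) {
        db <- unique(c(db, as.character(w)))
      }
    }
    for (w in names(eb)[eb == "D"]) {
      v <- m$a[m$b == as.integer(w)]
      if (length(v) == 1L && !(as.character(v) %in% names(ea))) {
        da <- unique(c(da, as.character(v)))
      }
    }
  }
  count_tab <- function(roles_eff, elems, dset) {
    ef <- c(roles_eff[roles_eff != "D"],
            stats::setNames(rep("D", length(dset)), dset))
    table(paste(ef, elems[names(ef)]))
  }
  ta <- count_tab(ea, cand$elem_a, da)
  tb <- count_tab(eb, cand$elem_b, db)
  keys <- union(names(ta), names(tb))
  all(vapply(keys, function(k) {
    a <- if (k %in% names(ta)) ta[[k]] else 0L
    b <- if (k %in% names(tb)) tb[[k]] else 0L
    a == b
  }, logical(1)))
}

## build the DPO rule from a fully matched candidate state
state_to_rule <- function(cand, rg, reaction_id) {
  m <- cand$matching
  va <- intersect(cand$va, m$a)            # unmatched context atoms drop out
  vb <- intersect(cand$vb, m$b)
  m <- m[m$a %in% va & m$b %in% vb, , drop = FALSE]
  keep_edges <- function(ed, keep) {
    ed[ed$a %in% keep & ed$b %in% keep, , drop = FALSE]
  }
  L <- mg_subgraph(rg$G, va, edges = keep_edges(cand$ea, va))
  R <- mg_subgraph(rg$H, vb, edges = keep_edges(cand$eb, vb))
  L$atoms$role <- NA_character_; R$atoms$role <- NA_character_
  L$atoms$wildcard <- FALSE; R$atoms$wildcard <- FALSE
  beta <- stats::setNames(m$b, as.character(m$a))
  rule <- tryCatch(dpo_rule(L, R, beta, rule_id = reaction_id,
                            provenance = list(pairwise = cand$provenance,
                                              roles_a = cand$roles_a,
                                              roles_b = cand$roles_b)),
                   error = function(e) NULL)
  rule
}

## attach element lookups needed by the balance test
with_elements <- function(cand, rg) {
  cand$elem_a <- stats::setNames(rg$G$atoms$element, as.character(rg$G$atoms$id))
  cand$elem_b <- stats::setNames(rg$H$atoms$element, as.character(rg$H$atoms$id))
  cand
}

#' Validate a rule by regenerating the products
#'
#' The rule is applied at its defining match (the identity embedding of `L`
#' into the reactant union graph); it is valid if the resulting components
#' are isomorphic, as a multiset, to the expected products.
#'
#' @param rule a [dpo_rule()] whose `L` lives in the id space of `G`.
#' @param G reactant union graph.
#' @param expected list of expected product components.
#' @return `list(valid, H, alpha)`.
#' @export
validate_rule <- function(rule, G, expected) {
  m <- stats::setNames(rule$left$atoms$id, as.character(rule$left$atoms$id))
  res <- apply_rule(rule, G, m)
  if (is.null(res)) return(list(valid = FALSE))
  comps <- lapply(mg_components(res$H), function(ids) mg_subgraph(res$H, ids))
  list(valid = mols_multiset_iso(comps, expected), H = res$H,
       alpha = res$alpha)
}

#' Keep only rules with the minimum number of hydrogen exchanges
#'
#' Rules that differ only in how many implicit hydrogens they shuffle are
#' collapsed to the representative(s) with the fewest hydrogen-count edits.
#'
#' @param rules list of [dpo_rule()]s.
#' @return filtered list.
#' @export
filter_min_h_rules <- function(rules) {
  if (length(rules) <= 1L) return(rules)
  ## group by the heavy-bond structure of the rule graph (hydrogens zeroed)
  zero_h <- function(rule) {
    rule$left$atoms$hcount <- 0L; rule$right$atoms$hcount <- 0L
    rule
  }
  n <- length(rules)
  grp <- rep(NA_integer_, n)
  psis <- lapply(rules, function(r) rule_psi(zero_h(r)))
  g <- 0L
  for (i in seq_len(n)) {
    if (!is.na(grp[i])) next
    g <- g + 1L; grp[i] <- g
    for (j in seq_len(n)) {
      if (j > i && is.na(grp[j]) && its_isomorphic(psis[[i]], psis[[j]])) grp[j] <- g
    }
  }
  hed <- vapply(rules, rule_h_edits, numeric(1))
  keep <- logical(n)
  for (gg in seq_len(g)) {
    idx <- which(grp == gg)
    keep[idx[hed[idx] == min(hed[idx])]] <- TRUE
  }
  rules[keep]
}
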