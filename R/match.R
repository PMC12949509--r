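#' Labelled subgraph matching
#'
#' Backtracking (VF2-style) enumeration of label-preserving monomorphisms or
#' isomorphisms between `molgraph`s, with the bond-compatibility predicates
#' used throughout the pipeline:
#'
#' * wildcard pattern atoms ("R-residues") match any non-hydrogen host atom;
#' * bonds involving oxygen do not distinguish single and double order;
#' * a within-ring bond may be interpreted as an aromatic bond and vice versa;
#' * charge/radical loop annotations never block a lenient match;
#' * implicit hydrogen counts must agree exactly at R/D/M-role pattern atoms
#'   and may only be exceeded by the host elsewhere.
#'
#' With `lenient = FALSE` all labels (element, hcount, loops, bond order)
#' must agree exactly; this is the regime used when applying a DPO rule.
#'
#' @param pat pattern `molgraph` (may contain wildcards and roles).
#' @param host host `molgraph`.
#' @param mode `"mono"`: every pattern bond must be present in the host
#'   (non-induced embedding); `"iso"`: bijection with exact correspondence of
#'   bond sets (requires equal vertex counts). `"iso"` is always strict.
#' @param seed named integer vector (names: pattern atom ids, values: host
#'   atom ids) fixed in advance; must be injective.
#' @param lenient apply the chemical compatibility predicates.
#' @param bond_exact with `lenient = TRUE`, still require exact bond orders
#'   (used when matching concrete molecule fragments rather than RDM
#'   patterns, where the oxygen bond-order tolerance does not apply).
#' @param max_results stop after this many matches.
#' @return list of named integer vectors mapping pattern atom ids to host
#'   atom ids, in deterministic order.
#' @export
graph_match <- function(pat, host, mode = c("mono", "iso"), seed = NULL,
                        lenient = NULL, bond_exact = FALSE,
                        max_results = Inf) {
  mode <- match.arg(mode)
  if (is.null(lenient)) lenient <- (mode == "mono")
  if (mode == "iso") lenient <- FALSE
  p <- mg_prep(pat); h <- mg_prep(host)
  if (mode == "iso" && p$n != h$n) return(list())
  match_engine(p, h, mode, seed, lenient, max_results, bond_exact)
}

HALOGENS <- c("F", "Cl", "Br", "I")

## prepared view of a molgraph for the matcher
mg_prep <- function(mol) {
  n <- mg_n(mol)
  adj <- matrix(0L, nrow = max(n, 1L), ncol = max(n, 1L))
  pos <- stats::setNames(seq_len(n), as.character(mol$atoms$id))
  nb <- nrow(mol$bonds)
  if (nb) {
    for (k in seq_len(nb)) {
      i <- pos[[as.character(mol$bonds$a[k])]]
      j <- pos[[as.character(mol$bonds$b[k])]]
      adj[i, j] <- k; adj[j, i] <- k
    }
  }
  wc <- mol$atoms$wildcard
  if (is.null(wc)) wc <- rep(FALSE, n)
  role <- mol$atoms$role
  if (is.null(role)) role <- rep(NA_character_, n)
  list(ids = mol$atoms$id, pos = pos, n = n,
       element = mol$atoms$element, hcount = mol$atoms$hcount,
       wildcard = wc %in% TRUE, role = role,
       loops = lapply(mol$atoms$id, function(id) mg_loops_of(mol, id)),
       adj = adj, order = mol$bonds$order, ring = mol$bonds$ring,
       nbrs = lapply(seq_len(n), function(i) which(adj[i, seq_len(n)] > 0L)))
}

## lenient bond-label compatibility (pattern edge k1 vs host edge k2)
bond_compatible <- function(p, k1, h, k2, elems, bond_exact = FALSE) {
  po <- p$order[k1]; ho <- h$order[k2]
  pr <- p$ring[k1]; hr <- h$ring[k2]
  ok <- (po == ho) ||
    (!bond_exact &&
       ((any(elems == "O") && po %in% c("single", "double") &&
           ho %in% c("single", "double")) ||
          (po == "aromatic" && hr) ||
          (pr && ho == "aromatic")))
  ok && (!pr || hr || ho == "aromatic")
}

match_engine <- function(p, h, mode, seed, lenient, max_results,
                         bond_exact = FALSE) {
  vertex_ok <- function(pi, hi) {
    if (lenient && p$wildcard[pi]) return(h$element[hi] != "H")
    el_ok <- p$element[pi] == h$element[hi] ||
      (lenient && p$element[pi] == "X" && h$element[hi] %in% HALOGENS)
    if (!el_ok) return(FALSE)
    if (lenient) {
      if (!is.na(p$role[pi]) && p$role[pi] %in% c("R", "D", "M")) {
        if (p$hcount[pi] != h$hcount[hi]) return(FALSE)
      } else if (h$hcount[hi] < p$hcount[pi]) return(FALSE)
      TRUE
    } else {
      p$hcount[pi] == h$hcount[hi] &&
        identical(p$loops[[pi]], h$loops[[hi]])
    }
  }
  edge_ok <- function(pi, pj, k1, k2) {
    if (lenient) {
      bond_compatible(p, k1, h, k2, c(p$element[pi], p$element[pj]),
                      bond_exact)
    } else {
      ## ring context is a declared part of a fragment's label (compared in
      ## "iso" mode); at rule-application time it is derived, not a label
      p$order[k1] == h$order[k2] &&
        (mode != "iso" || p$ring[k1] == h$ring[k2])
    }
  }

  n <- p$n
  if (n == 0L) return(list(stats::setNames(integer(), character())))
  map <- rep(NA_integer_, n)       # pattern pos -> host pos
  used <- rep(FALSE, h$n)
  if (!is.null(seed) && length(seed)) {
    if (anyDuplicated(seed)) stop("seed is not injective")
    for (nm in names(seed)) {
      pi <- p$pos[[nm]]; hi <- h$pos[[as.character(seed[[nm]])]]
      if (is.null(pi) || is.null(hi)) stop("seed references unknown atom id")
      map[pi] <- hi; used[hi] <- TRUE
    }
  }
  ## static expansion order: seeded first, then most-connected-first
  ordered <- which(!is.na(map))
  remaining <- setdiff(seq_len(n), ordered)
  while (length(remaining)) {
    nconn <- vapply(remaining, function(v)
      sum(p$nbrs[[v]] %in% ordered), integer(1))
    sel <- remaining[order(-nconn, p$wildcard[remaining],
                           -lengths(p$nbrs[remaining]), p$ids[remaining])][1]
    ordered <- c(ordered, sel)
    remaining <- setdiff(remaining, sel)
  }
  free_order <- ordered[is.na(map[ordered])]

  results <- list()
  consistent <- function(pi, hi) {
    if (!vertex_ok(pi, hi)) return(FALSE)
    if (mode == "iso") {
      for (pj in which(!is.na(map))) {
        k1 <- p$adj[pi, pj]; k2 <- h$adj[hi, map[pj]]
        if ((k1 > 0L) != (k2 > 0L)) return(FALSE)
        if (k1 > 0L && !edge_ok(pi, pj, k1, k2)) return(FALSE)
      }
    } else {
      for (pj in p$nbrs[[pi]]) {
        if (is.na(map[pj])) next
        k2 <- h$adj[hi, map[pj]]
        if (k2 == 0L) return(FALSE)
        if (!edge_ok(pi, pj, p$adj[pi, pj], k2)) return(FALSE)
      }
    }
    TRUE
  }
  recurse <- function(step) {
    if (length(results) >= max_results) return()
    if (step > length(free_order)) {
      m <- stats::setNames(h$ids[map], as.character(p$ids))
      results[[length(results) + 1L]] <<- m[order(as.integer(names(m)))]
      return()
    }
    pi <- free_order[step]
    mapped_nb <- p$nbrs[[pi]][!is.na(map[p$nbrs[[pi]]])]
    cand <- if (length(mapped_nb)) {
      unique(unlist(lapply(mapped_nb, function(pj) h$nbrs[[map[pj]]])))
    } else seq_len(h$n)
    cand <- cand[!used[cand]]
    cand <- cand[order(h$ids[cand])]
    for (hi in cand) {
      if (consistent(pi, hi)) {
        map[pi] <<- hi; used[hi] <<- TRUE
        recurse(step + 1L)
        map[pi] <<- NA_integer_; used[hi] <<- FALSE
        if (length(results) >= max_results) return()
      }
    }
  }
  ## In "iso" mode a seed is *declared* a consistent set of matches (it may
  ## span the reaction center, where labels legitimately differ); only newly
  ## added pairs are checked against it. In "mono" mode the seed must itself
  ## satisfy the embedding conditions.
  if (mode == "mono") {
    seeded <- which(!is.na(map))
    for (a in seeded) {
      if (!vertex_ok(a, map[a])) return(list())
      for (b in seeded) {
        if (b <= a) next
        k1 <- p$adj[a, b]
        if (k1 > 0L) {
          k2 <- h$adj[map[a], map[b]]
          if (k2 == 0L || !edge_ok(a, b, k1, k2)) return(list())
        }
      }
    }
  }
  recurse(1L)
  results
}

#' Test two molecule graphs for label-preserving isomorphism
#'
#' @param m1,m2 `molgraph`s.
#' @param pin optional named integer vector pinning atoms of `m1` to atoms of
#'   `m2` (e.g. a focal/root atom for rooted isomorphism).
#' @return `TRUE` or `FALSE`.
#' @export
mg_isomorphic <- function(m1, m2, pin = NULL) {
  if (mg_n(m1) != mg_n(m2) || nrow(m1$bonds) != nrow(m2$bonds)) return(FALSE)
  ## cheap invariant screen before the exact search
  if (is.null(pin) && mg_invariant(strip_marks(m1)) != mg_invariant(strip_marks(m2)))
    return(FALSE)
  ## seeded pairs are exempt from label checks in the engine (they may span a
  ## reaction center); for rooted isomorphism the pins are ordinary vertices,
  ## so compare their labels here
  if (!is.null(pin)) {
    for (nm in names(pin)) {
      i1 <- base::match(as.integer(nm), m1$atoms$id)
      i2 <- base::match(pin[[nm]], m2$atoms$id)
      if (is.na(i1) || is.na(i2)) return(FALSE)
      if (m1$atoms$element[i1] != m2$atoms$element[i2] ||
          m1$atoms$hcount[i1] != m2$atoms$hcount[i2] ||
          !identical(m1$atoms$wildcard[i1] %in% TRUE,
                     m2$atoms$wildcard[i2] %in% TRUE) ||
          !identical(mg_loops_of(m1, as.integer(nm)),
                     mg_loops_of(m2, pin[[nm]]))) return(FALSE)
    }
    ## edge labels between two pinned vertices are skipped by the engine too
    idx2 <- mg_bond_index(m2)
    for (k in seq_len(nrow(m1$bonds))) {
      a <- as.character(m1$bonds$a[k]); b <- as.character(m1$bonds$b[k])
      if (a %in% names(pin) && b %in% names(pin)) {
        r2 <- mg_bond_row(idx2, pin[[a]], pin[[b]])
        if (is.na(r2) || m2$bonds$order[r2] != m1$bonds$order[k] ||
            m2$bonds$ring[r2] != m1$bonds$ring[k]) return(FALSE)
      }
    }
  }
  length(graph_match(strip_marks(m1), strip_marks(m2), mode = "iso",
                     seed = pin, max_results = 1)) > 0
}

## drop role markings (they are bookkeeping, not labels) but keep wildcards,
## which are genuine labels of pattern fragments
strip_marks <- function(mol) {
  mol$atoms$role <- NA_character_
  ## wildcard atoms compare by their wildcard label: encode into element
  if (any(mol$atoms$wildcard %in% TRUE)) {
    mol$atoms$element[mol$atoms$wildcard %in% TRUE] <- "*"
  }
  mol
}

## isomorphism of two multisets of molgraphs (componentwise, multiplicity-aware)
mols_multiset_iso <- function(l1, l2) {
  if (length(l1) != length(l2)) return(FALSE)
  unused <- rep(TRUE, length(l2))
  for (a in l1) {
    found <- FALSE
    for (j in seq_along(l2)) {
      if (unused[j] && mg_isomorphic(a, l2[[j]])) {
        unused[j] <- FALSE; found <- TRUE; break
      }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

## indices of first representatives of a fragment list up to (optionally
## rooted) isomorphism; roots = vector of root ids parallel to frags
dedup_indices <- function(frags, roots = NULL) {
  keep <- logical(length(frags))
  for (i in seq_along(frags)) {
    dup <- FALSE
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      pin <- NULL
      if (!is.null(roots)) {
        pin <- stats::setNames(as.integer(roots[j]), as.character(roots[i]))
      }
      if (mg_isomorphic(frags[[i]], frags[[j]], pin = pin)) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  which(keep)
}
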