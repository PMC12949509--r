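#' Expand one RDM tree into connected pattern fragments
#'
#' Each tree node's atom-type code is replaced by its type graph(s) and the
#' children are merged progressively into the root. Two adjacent type graphs
#' that share a common pair of atoms (e.g. O1c, H-O-P, and P1b, P-O, share
#' the P-O motif) are merged at that pair; otherwise a wildcard R-residue of
#' each side is consumed, which requires the bond orders to match exactly
#' and the ring/aromatic context to be compatible. Every combination of
#' type-graph alternatives and merge points is explored; combinations with
#' no legal merge are pruned (branch and bound — non-extensible combinations
#' may only become recognisable in later merge steps). The result list is
#' deduplicated up to rooted labelled isomorphism (all tree-node positions
#' pinned) and deterministically ordered.
#'
#' @param tree one side of [build_trees()].
#' @param table atom-type dictionary.
#' @return list of expansions, each `list(graph, node_map)` where `node_map`
#'   is a named integer vector from tree node id to fragment vertex id.
#'   Fragments carry role markings (`R`/`D`/`M`/`context`) and wildcards.
#' @export
expand_tree <- function(tree, table = atom_type_table()) {
  stopifnot(is.data.frame(tree), nrow(tree) >= 1L, tree$role[1] == "R")
  alts <- lapply(tree$code, function(cd) {
    a <- atom_type_lookup(cd, table)
    if (any(vapply(a, `[[`, logical(1), "undefined"))) {
      stop("atom-type code ", sQuote(cd), " contains undefined atoms and is ",
           "non-convertible")
    }
    a
  })
  ## states: list(graph, node_map)
  states <- lapply(alts[[1]], function(a) {
    g <- type_fragment(a, role = "R")
    list(graph = g$graph, node_map = stats::setNames(g$focal, "1"))
  })
  for (ci in seq_len(nrow(tree))[-1]) {
    node <- tree$node[ci]; role <- tree$role[ci]
    nxt <- list()
    for (st in states) {
      for (a in alts[[ci]]) {
        child <- type_fragment(a, role = role)
        nxt <- c(nxt, merge_child(st, child, node))
      }
    }
    if (!length(nxt)) return(list())
    states <- dedup_states(nxt)
  }
  dedup_states(states)
}

## instantiate one type-graph alternative as a fragment with role markings
type_fragment <- function(alt, role) {
  g <- alt$graph
  g$atoms$role <- ifelse(g$atoms$id == alt$focal, role,
                         ifelse(g$atoms$wildcard, NA_character_, "context"))
  list(graph = g, focal = alt$focal)
}

## all legal merges of a child fragment into an accumulated state along the
## tree edge root--child; returns list of new states
merge_child <- function(st, child, node) {
  A <- st$graph
  r <- st$node_map[["1"]]
  C <- child$graph
  ## renumber child vertices above the accumulated fragment's id range
  off <- max(A$atoms$id)
  C$atoms$id <- C$atoms$id + off
  if (nrow(C$bonds)) { C$bonds$a <- C$bonds$a + off; C$bonds$b <- C$bonds$b + off }
  if (length(C$loops)) names(C$loops) <- as.character(as.integer(names(C$loops)) + off)
  cf <- child$focal + off

  aidx <- mg_bond_index(A); cidx <- mg_bond_index(C)
  anb <- mg_nbrs(A); cnb <- mg_nbrs(C)
  arow <- function(v) match(v, A$atoms$id); crow <- function(v) match(v, C$atoms$id)
  elem_a <- function(v) A$atoms$element[arow(v)]
  elem_c <- function(v) C$atoms$element[crow(v)]
  wc_a <- function(v) isTRUE(A$atoms$wildcard[arow(v)])
  wc_c <- function(v) isTRUE(C$atoms$wildcard[crow(v)])

  out <- list()
  for (u in sort(anb[[as.character(r)]])) {        # u in A: becomes the child focal
    if (!wc_a(u) && elem_a(u) != elem_c(cf)) next
    ## a vertex already standing for another tree node cannot be re-used
    if (!wc_a(u) && u %in% st$node_map) next
    ka <- mg_bond_row(aidx, r, u)
    for (v in sort(cnb[[as.character(cf)]])) {     # v in C: stands for the root
      if (!wc_c(v) && elem_c(v) != elem_a(r)) next
      kc <- mg_bond_row(cidx, cf, v)
      if (A$bonds$order[ka] != C$bonds$order[kc]) next
      if (!ring_ctx_compatible(A$bonds$ring[ka], A$bonds$order[ka],
                               C$bonds$ring[kc], C$bonds$order[kc])) next
      m <- glue_fragments(A, st$node_map, r, u, C, cf, v, node)
      if (!is.null(m)) out <- c(out, list(m))
    }
  }
  out
}

ring_ctx_compatible <- function(r1, o1, r2, o2) {
  r1 == r2 || o1 == "aromatic" || o2 == "aromatic"
}

## identify u (in A) with cf (focal of C) and v (in C) with r; union the rest
glue_fragments <- function(A, node_map, r, u, C, cf, v, node) {
  ## child vertex id -> id in the merged graph
  remap <- stats::setNames(C$atoms$id, as.character(C$atoms$id))
  remap[[as.character(cf)]] <- u
  remap[[as.character(v)]] <- r

  atoms <- A$atoms
  au <- match(u, atoms$id); ac <- match(cf, C$atoms$id)
  ## u takes the child focal's definition (the focal definition wins)
  atoms$element[au] <- C$atoms$element[ac]
  atoms$hcount[au] <- C$atoms$hcount[ac]
  atoms$wildcard[au] <- FALSE
  atoms$role[au] <- C$atoms$role[ac]
  ## the child's view of the root (v): the root focal's definition wins; if v
  ## is a non-wildcard whose element clashes we never get here (checked)
  keepC <- !(C$atoms$id %in% c(cf, v))
  newatoms <- C$atoms[keepC, , drop = FALSE]
  newatoms$id <- unname(remap[as.character(newatoms$id)])
  atoms <- rbind(atoms, newatoms)

  loops <- A$loops
  ## u takes the child focal's loop annotations (focal definition wins);
  ## the root focal keeps its own (the child's view of it is discarded)
  loops[[as.character(u)]] <- C$loops[[as.character(cf)]]
  for (nm in setdiff(names(C$loops), as.character(c(cf, v)))) {
    loops[[as.character(remap[[nm]])]] <- C$loops[[nm]]
  }
  loops <- loops[!vapply(loops, is.null, logical(1))]

  bonds <- A$bonds
  bidx <- mg_bond_index(A)
  if (nrow(C$bonds)) {
    for (k in seq_len(nrow(C$bonds))) {
      a2 <- remap[[as.character(C$bonds$a[k])]]
      b2 <- remap[[as.character(C$bonds$b[k])]]
      ex <- mg_bond_row(bidx, a2, b2)
      if (!is.na(ex)) {
        ## unified edge (the tree edge): labels already checked compatible;
        ## a ring context on either side is kept
        bonds$ring[ex] <- bonds$ring[ex] || C$bonds$ring[k]
        next
      }
      bonds <- rbind(bonds, data.frame(a = min(a2, b2), b = max(a2, b2),
                                       order = C$bonds$order[k],
                                       ring = C$bonds$ring[k],
                                       stringsAsFactors = FALSE))
    }
  }
  g <- tryCatch(molgraph(atoms, bonds, loops = loops, recompute_rings = FALSE),
                error = function(e) NULL)
  if (is.null(g)) return(NULL)
  nm <- c(node_map, stats::setNames(u, as.character(node)))
  list(graph = g, node_map = nm)
}

## deduplicate states up to labelled isomorphism with every tree-node
## position pinned; deterministic order by fragment invariant
dedup_states <- function(states) {
  if (length(states) <= 1L) return(states)
  keys <- vapply(states, function(s) mg_invariant(strip_marks(s$graph)),
                 character(1))
  ord <- order(keys)
  states <- states[ord]; keys <- keys[ord]
  keep <- logical(length(states))
  for (i in seq_along(states)) {
    dup <- FALSE
    for (j in seq_len(i - 1L)) {
      if (!keep[j] || keys[i] != keys[j]) next
      nmi <- states[[i]]$node_map; nmj <- states[[j]]$node_map
      pin <- stats::setNames(as.integer(nmj[names(nmi)]), as.character(nmi))
      if (mg_isomorphic(states[[i]]$graph, states[[j]]$graph, pin = pin)) {
        dup <- TRUE; break
      }
    }
    keep[i] <- !dup
  }
  states[keep]
}

#' Compile an RDM code into RDM pattern graphs
#'
#' Expands the reactant- and product-side trees and pairs every reactant
#' expansion with every product expansion. The partial correspondence `corr`
#' links the R-atom and each M-atom to its positional partner; D-atoms stay
#' unmatched. All alternatives are carried forward.
#'
#' @param code an [parse_rdm()] result.
#' @param table atom-type dictionary.
#' @param code_index provenance index of this code within its RCLASS.
#' @return list of `rdm_pattern` objects: `list(left, right, corr,
#'   variant_id, rclass_id, code_index)`. An empty list means the code is
#'   non-convertible (one side has no expansion).
#' @export
make_pattern_graphs <- function(code, table = atom_type_table(),
                                code_index = 1L) {
  trees <- build_trees(code)
  lexp <- expand_tree(trees$reactant, table)
  rexp <- expand_tree(trees$product, table)
  if (!length(lexp) || !length(rexp)) return(list())
  shared <- intersect(names(lexp[[1]]$node_map), names(rexp[[1]]$node_map))
  ## matched nodes: the R-atom and the M-atoms (never D)
  roles <- stats::setNames(c("R", vapply(code$d_pairs, function(p) "D", ""),
                             vapply(code$m_pairs, function(p) "M", "")),
                           as.character(seq_len(1 + length(code$d_pairs) +
                                                  length(code$m_pairs))))
  matched_nodes <- shared[roles[shared] %in% c("R", "M")]
  out <- list()
  vid <- 0L
  for (le in lexp) {
    for (re in rexp) {
      corr <- stats::setNames(as.integer(re$node_map[matched_nodes]),
                              as.character(le$node_map[matched_nodes]))
      el_l <- le$graph$atoms$element[match(as.integer(names(corr)),
                                           le$graph$atoms$id)]
      el_r <- re$graph$atoms$element[match(unname(corr), re$graph$atoms$id)]
      if (!all(el_l == el_r)) {
        warning("RDM code ", code$code_string,
                ": positional R/M pairing does not preserve element labels; ",
                "variant dropped")
        next
      }
      vid <- vid + 1L
      out[[vid]] <- structure(
        list(left = le$graph, right = re$graph, corr = corr,
             left_node_map = le$node_map, right_node_map = re$node_map,
             variant_id = vid, rclass_id = code$rclass_id,
             code_index = code_index),
        class = "rdm_pattern")
    }
  }
  out
}

#' @export
print.rdm_pattern <- function(x, ...) {
  cat(sprintf("<rdm_pattern %s#%d variant %d: left %d atoms, right %d atoms, %d matched>\n",
              if (is.na(x$rclass_id)) "" else x$rclass_id, x$code_index,
              x$variant_id, mg_n(x$left), mg_n(x$right), length(x$corr)))
  invisible(x)
}
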