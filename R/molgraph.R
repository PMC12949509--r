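#' Molecule graphs
#'
#' A `molgraph` is a labelled simple graph representing one compound (or a
#' disjoint union of compounds): vertices are heavy atoms carrying an element
#' symbol and an implicit hydrogen count, edges are bonds labelled with one of
#' `"single"`, `"double"`, `"triple"`, `"aromatic"` plus a ring flag, and
#' per-vertex *loops* carry annotations such as charges or unpaired electrons
#' so that vertex labels never have to change under a transformation rule.
#' Pattern fragments reuse the same container with two extra per-vertex
#' columns: `wildcard` (an "R-residue", matching any non-hydrogen atom) and
#' `role` (one of `"R"`, `"D"`, `"M"`, `"context"`).
#'
#' @param atoms data.frame with columns `id` (integer, unique), `element`
#'   (character), `hcount` (non-negative integer). Optional columns:
#'   `wildcard` (logical), `role` (character), `kcf_type` (character).
#' @param bonds data.frame with columns `a`, `b` (atom ids), `order`
#'   (bond label) and optionally `ring` (logical; recomputed unless
#'   `recompute_rings = FALSE`).
#' @param compound_id external identifier string.
#' @param loops named list (names = atom ids as character) of character
#'   vectors of loop annotations, e.g. `"charge:+1"`.
#' @param recompute_rings if `TRUE` (default) the per-edge ring flag is
#'   derived from cycle membership; pattern fragments keep their declared
#'   ring-context flags by passing `FALSE`.
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds = NULL, compound_id = NA_character_,
                     loops = list(), recompute_rings = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "element", "hcount") %in% names(atoms)))
  atoms$id <- as.integer(atoms$id)
  atoms$hcount <- as.integer(atoms$hcount)
  if (anyDuplicated(atoms$id)) stop("duplicate atom ids")
  if (any(atoms$hcount < 0)) stop("negative implicit hydrogen count")
  if (is.null(atoms$wildcard)) atoms$wildcard <- FALSE
  if (is.null(atoms$role)) atoms$role <- NA_character_
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a = integer(), b = integer(),
                        order = character(), ring = logical(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    stopifnot(all(c("a", "b", "order") %in% names(bonds)))
    bonds$a <- as.integer(bonds$a)
    bonds$b <- as.integer(bonds$b)
    if (is.null(bonds$ring)) bonds$ring <- FALSE
    if (any(bonds$a == bonds$b)) {
      stop("loops may not carry bond orders; use the 'loops' annotation list")
    }
    swap <- bonds$a > bonds$b
    tmp <- bonds$a[swap]; bonds$a[swap] <- bonds$b[swap]; bonds$b[swap] <- tmp
    if (anyDuplicated(paste(bonds$a, bonds$b))) stop("parallel bonds")
    if (!all(bonds$order %in% BOND_ORDERS)) {
      stop("unknown bond order: ", paste(setdiff(bonds$order, BOND_ORDERS),
                                         collapse = ", "))
    }
    if (!all(c(bonds$a, bonds$b) %in% atoms$id)) stop("bond references unknown atom")
    bonds <- bonds[, c("a", "b", "order", "ring")]
  }
  mol <- structure(
    list(atoms = atoms, bonds = bonds, loops = loops,
         compound_id = compound_id),
    class = "molgraph")
  if (recompute_rings) mol <- mg_recompute_rings(mol)
  mol
}

BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph %s: %d atoms, %d bonds>\n",
              if (is.na(x$compound_id)) "?" else x$compound_id,
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

mg_n <- function(mol) nrow(mol$atoms)

#' Recompute ring membership flags
#'
#' A bond lies in a ring iff it is not a bridge of the graph. Idempotent.
#' @param mol a `molgraph`.
#' @return the graph with refreshed per-bond `ring` flags.
#' @export
mg_recompute_rings <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(mol)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(mol$bonds$a), to = as.character(mol$bonds$b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(mol$atoms$id)))
  br <- igraph::bridges(g)
  ring <- rep(TRUE, nrow(mol$bonds))
  ring[as.integer(br)] <- FALSE
  mol$bonds$ring <- ring
  mol
}

## neighbour list keyed by atom id (names are ids as character)
mg_nbrs <- function(mol) {
  ids <- mol$atoms$id
  out <- stats::setNames(vector("list", length(ids)), as.character(ids))
  for (i in seq_along(ids)) out[[i]] <- integer()
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- as.character(mol$bonds$a[k]); b <- as.character(mol$bonds$b[k])
      out[[a]] <- c(out[[a]], mol$bonds$b[k])
      out[[b]] <- c(out[[b]], mol$bonds$a[k])
    }
  }
  out
}

## fast bond lookup: environment keyed "a|b" (a < b) -> row index
mg_bond_index <- function(mol) {
  env <- new.env(parent = emptyenv(), size = max(16L, nrow(mol$bonds) * 2L))
  if (nrow(mol$bonds)) {
    keys <- paste(mol$bonds$a, mol$bonds$b, sep = "|")
    for (k in seq_along(keys)) assign(keys[k], k, envir = env)
  }
  env
}

mg_bond_key <- function(a, b) {
  if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

## bond row index between ids a,b or NA
mg_bond_row <- function(idx, a, b) {
  k <- mg_bond_key(a, b)
  if (exists(k, envir = idx, inherits = FALSE)) get(k, envir = idx) else NA_integer_
}

#' Induced subgraph on a set of atom ids
#'
#' Atom ids are preserved, so subgraphs of a host graph stay addressable in
#' the host's id space. Ring flags are inherited, not recomputed.
#' @param mol a `molgraph`.
#' @param ids atom ids to keep.
#' @param edges optionally a data.frame of bonds (subset of `mol$bonds`) to
#'   keep instead of all induced bonds.
#' @return a `molgraph`.
#' @export
mg_subgraph <- function(mol, ids, edges = NULL) {
  ids <- as.integer(ids)
  atoms <- mol$atoms[mol$atoms$id %in% ids, , drop = FALSE]
  if (is.null(edges)) {
    keep <- mol$bonds$a %in% ids & mol$bonds$b %in% ids
    bonds <- mol$bonds[keep, , drop = FALSE]
  } else {
    bonds <- edges
  }
  loops <- mol$loops[names(mol$loops) %in% as.character(ids)]
  molgraph(atoms, bonds, compound_id = mol$compound_id, loops = loops,
           recompute_rings = FALSE)
}

## connected components as list of id vectors (deterministic order)
mg_components <- function(mol) {
  n <- mg_n(mol)
  if (n == 0L) return(list())
  nbrs <- mg_nbrs(mol)
  seen <- stats::setNames(rep(FALSE, n), as.character(mol$atoms$id))
  comps <- list()
  for (v in sort(mol$atoms$id)) {
    if (seen[[as.character(v)]]) next
    stack <- v; comp <- integer()
    while (length(stack)) {
      u <- stack[[1]]; stack <- stack[-1]
      cu <- as.character(u)
      if (seen[[cu]]) next
      seen[[cu]] <- TRUE
      comp <- c(comp, u)
      stack <- c(stack, nbrs[[cu]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

mg_is_connected <- function(mol) length(mg_components(mol)) <= 1L

## disjoint union with id offsets; returns list(graph, maps) where maps[[i]]
## is a named map old id -> new id for input i
mg_disjoint_union <- function(mols) {
  offset <- 0L
  atoms <- list(); bonds <- list(); loops <- list(); maps <- list()
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    map <- stats::setNames(seq_len(mg_n(m)) + offset, as.character(m$atoms$id))
    a <- m$atoms; a$id <- unname(map[as.character(a$id)])
    b <- m$bonds
    if (nrow(b)) {
      b$a <- unname(map[as.character(b$a)])
      b$b <- unname(map[as.character(b$b)])
    }
    lp <- m$loops
    if (length(lp)) names(lp) <- as.character(unname(map[names(lp)]))
    atoms[[i]] <- a; bonds[[i]] <- b; loops <- c(loops, lp); maps[[i]] <- map
    offset <- offset + mg_n(m)
  }
  g <- molgraph(do.call(rbind, atoms), do.call(rbind, bonds),
                loops = loops, recompute_rings = FALSE)
  list(graph = g, maps = maps)
}

## loop annotations of one vertex (sorted multiset)
mg_loops_of <- function(mol, id) {
  l <- mol$loops[[as.character(id)]]
  if (is.null(l)) character() else sort(l)
}

## canonical comparable key of a molgraph up to reindexing (brute force over
## automorphism-reduced permutations is avoided: we use a cheap invariant
## refinement followed by exact isomorphism grouping at the call sites)
mg_invariant <- function(mol) {
  at <- mol$atoms
  vdesc <- character(nrow(at))
  idx <- mg_bond_index(mol)
  nbrs <- mg_nbrs(mol)
  for (i in seq_len(nrow(at))) {
    id <- at$id[i]
    incident <- sort(vapply(nbrs[[as.character(id)]], function(u) {
      r <- mg_bond_row(idx, id, u)
      paste0(mol$bonds$order[r], if (mol$bonds$ring[r]) "r" else "")
    }, character(1)))
    vdesc[i] <- paste(at$element[i], at$hcount[i],
                      if (isTRUE(at$wildcard[i])) "w" else "",
                      paste(mg_loops_of(mol, id), collapse = ","),
                      paste(incident, collapse = "+"), sep = ":")
  }
  paste(sort(vdesc), collapse = ";")
}
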