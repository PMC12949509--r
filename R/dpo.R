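#' Imaginary transition state (ITS) graphs
#'
#' The ITS graph of a reaction with reactant graph `G`, product graph `H`
#' and atom-to-atom map `alpha` has the vertices of `G` and an edge wherever
#' a bond exists in at least one of `G` and `H`, labelled with the pair of
#' bond labels (one side may be absent). Edges whose two labels differ (or
#' exist on one side only) are *reaction edges*; the equal-labelled edges
#' form the unchanged context `D`. Implicit-hydrogen changes are carried on
#' the vertices as an `(h_G, h_H)` pair.
#'
#' @param G,H `molgraph`s with equal atom counts.
#' @param alpha named integer vector: `G` atom id -> `H` atom id,
#'   label-preserving bijection.
#' @return an object of class `itsgraph`.
#' @export
its_graph <- function(G, H, alpha) {
  alpha <- alpha[order(as.integer(names(alpha)))]
  if (!identical(as.integer(names(alpha)), sort(G$atoms$id)) ||
      !identical(sort(unname(alpha)), sort(H$atoms$id))) {
    stop("alpha must be a bijection V(G) -> V(H)")
  }
  gi <- match(as.integer(names(alpha)), G$atoms$id)
  hi <- match(unname(alpha), H$atoms$id)
  if (!all(G$atoms$element[gi] == H$atoms$element[hi])) {
    stop("alpha does not preserve element labels")
  }
  atoms <- data.frame(id = as.integer(names(alpha)),
                      element = G$atoms$element[gi],
                      h_g = G$atoms$hcount[gi], h_h = H$atoms$hcount[hi],
                      stringsAsFactors = FALSE)
  loops_g <- lapply(atoms$id, function(v) mg_loops_of(G, v))
  loops_h <- lapply(atoms$id, function(v) mg_loops_of(H, unname(alpha[[as.character(v)]])))
  hidx <- mg_bond_index(H)
  edges <- list()
  seen <- character()
  if (nrow(G$bonds)) for (k in seq_len(nrow(G$bonds))) {
    a <- G$bonds$a[k]; b <- G$bonds$b[k]
    hr <- mg_bond_row(hidx, alpha[[as.character(a)]], alpha[[as.character(b)]])
    edges[[length(edges) + 1L]] <- data.frame(
      a = a, b = b, order_g = G$bonds$order[k],
      order_h = if (is.na(hr)) NA_character_ else H$bonds$order[hr],
      stringsAsFactors = FALSE)
    seen <- c(seen, paste(a, b, sep = "|"))
  }
  inv <- stats::setNames(as.integer(names(alpha)), alpha)
  if (nrow(H$bonds)) for (k in seq_len(nrow(H$bonds))) {
    a <- inv[[as.character(H$bonds$a[k])]]
    b <- inv[[as.character(H$bonds$b[k])]]
    key <- if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
    if (key %in% seen) next
    edges[[length(edges) + 1L]] <- data.frame(
      a = min(a, b), b = max(a, b), order_g = NA_character_,
      order_h = H$bonds$order[k], stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = integer(), b = integer(), order_g = character(),
               order_h = character(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(atoms = atoms, edges = edges,
                 loops_g = loops_g, loops_h = loops_h, alpha = alpha),
            class = "itsgraph")
}

#' @export
print.itsgraph <- function(x, ...) {
  re <- its_reaction_edges(x)
  cat(sprintf("<itsgraph: %d atoms, %d edges (%d reaction edges)>\n",
              nrow(x$atoms), nrow(x$edges), nrow(re)))
  invisible(x)
}

#' Reaction edges of an ITS graph
#'
#' @param its an [its_graph()].
#' @return the rows of `its$edges` whose labels differ between the sides.
#' @export
its_reaction_edges <- function(its) {
  d <- is.na(its$edges$order_g) | is.na(its$edges$order_h) |
    its$edges$order_g != its$edges$order_h
  its$edges[d, , drop = FALSE]
}

## vertices whose labels (implicit H or loops) change
its_changed_vertices <- function(its) {
  ch <- its$atoms$h_g != its$atoms$h_h |
    !mapply(identical, its$loops_g, its$loops_h)
  its$atoms$id[ch]
}

#' Extract a DPO rule from a subgraph of an ITS graph
#'
#' Any subgraph of the ITS graph that covers all reaction edges (and all
#' vertices with label changes) defines a unique chemical DPO rule: deleting
#' the edges absent on one side and splitting each label pair gives `L`, `K`
#' and `R` on the common vertex set.
#'
#' @param its an [its_graph()].
#' @param keep atom ids to retain; must include every reaction-edge endpoint
#'   and every changed vertex.
#' @param edge_rows optional row indices into `its$edges` selecting the
#'   subgraph's edges (default: all edges induced on `keep`); must include
#'   every reaction edge.
#' @return a [dpo_rule()] whose `beta` is the identity on `keep`.
#' @export
extract_rule <- function(its, keep, edge_rows = NULL) {
  keep <- sort(as.integer(keep))
  re <- its_reaction_edges(its)
  need <- union(unique(c(re$a, re$b)), its_changed_vertices(its))
  if (!all(need %in% keep)) {
    stop("rule subgraph must cover all reaction edges and changed vertices")
  }
  induced <- which(its$edges$a %in% keep & its$edges$b %in% keep)
  if (is.null(edge_rows)) edge_rows <- induced
  edge_rows <- sort(intersect(edge_rows, induced))
  rekeys <- paste(re$a, re$b)
  if (!all(rekeys %in% paste(its$edges$a[edge_rows], its$edges$b[edge_rows]))) {
    stop("rule subgraph must cover all reaction edges")
  }
  ed <- its$edges[edge_rows, , drop = FALSE]
  side <- function(col, hcol, loops) {
    ai <- match(keep, its$atoms$id)
    atoms <- data.frame(id = keep, element = its$atoms$element[ai],
                        hcount = its$atoms[[hcol]][ai], stringsAsFactors = FALSE)
    sel <- !is.na(ed[[col]])
    bonds <- data.frame(a = ed$a[sel], b = ed$b[sel], order = ed[[col]][sel],
                        stringsAsFactors = FALSE)
    lp <- loops[ai]
    names(lp) <- as.character(keep)
    lp <- lp[lengths(lp) > 0]
    molgraph(atoms, bonds, loops = lp)
  }
  L <- side("order_g", "h_g", its$loops_g)
  R <- side("order_h", "h_h", its$loops_h)
  dpo_rule(L, R, stats::setNames(keep, as.character(keep)))
}

## the rule graph Psi of a DPO rule, i.e. the ITS of L -> R under beta
rule_psi <- function(rule) its_graph(rule$left, rule$right, rule$beta)

#' Apply a DPO rule to a reactant graph at a given match
#'
#' First the parts of `L` not preserved in `K` are removed, then the parts
#' of `R` missing in `K` are glued in; the vertex set is unchanged (atoms
#' are preserved). The match must be a label-preserving monomorphism under
#' strict label equality. If the rule tries to insert a bond where the
#' intermediate graph retains one, the result would have parallel edges and
#' the application is rejected.
#'
#' @param rule a [dpo_rule()].
#' @param G reactant `molgraph`.
#' @param match named integer map, `L` atom id -> `G` atom id.
#' @return `list(H, alpha)` with `alpha` the identity-induced atom map on
#'   `V(G)` ids, or `NULL` if the application is rejected (parallel-edge
#'   conflict).
#' @export
apply_rule <- function(rule, G, match) {
  L <- rule$left; R <- rule$right
  K <- rule_context(rule)
  kidx <- mg_bond_index(K)
  bonds <- G$bonds
  gidx <- mg_bond_index(G)
  drop <- integer()
  if (nrow(L$bonds)) for (k in seq_len(nrow(L$bonds))) {
    a <- L$bonds$a[k]; b <- L$bonds$b[k]
    kr <- mg_bond_row(kidx, a, b)
    in_k <- !is.na(kr) && K$bonds$order[kr] == L$bonds$order[k]
    if (!in_k) {
      gr <- mg_bond_row(gidx, match[[as.character(a)]], match[[as.character(b)]])
      stopifnot(!is.na(gr))
      drop <- c(drop, gr)
    }
  }
  if (length(drop)) bonds <- bonds[-drop, , drop = FALSE]
  didx_keys <- paste(bonds$a, bonds$b, sep = "|")
  inv_beta <- stats::setNames(as.integer(names(rule$beta)), rule$beta)
  if (nrow(R$bonds)) for (k in seq_len(nrow(R$bonds))) {
    la <- inv_beta[[as.character(R$bonds$a[k])]]
    lb <- inv_beta[[as.character(R$bonds$b[k])]]
    kr <- mg_bond_row(kidx, la, lb)
    if (!is.na(kr) && K$bonds$order[kr] == R$bonds$order[k]) next
    ga <- match[[as.character(la)]]; gb <- match[[as.character(lb)]]
    key <- if (ga < gb) paste(ga, gb, sep = "|") else paste(gb, ga, sep = "|")
    if (key %in% didx_keys) return(NULL)   # parallel-edge conflict
    bonds <- rbind(bonds, data.frame(a = min(ga, gb), b = max(ga, gb),
                                     order = R$bonds$order[k], ring = FALSE,
                                     stringsAsFactors = FALSE))
    didx_keys <- c(didx_keys, key)
  }
  atoms <- G$atoms
  loops <- G$loops
  for (x in names(rule$beta)) {
    gx <- match[[x]]
    ri <- base::match(rule$beta[[x]], R$atoms$id)
    atoms$hcount[base::match(gx, atoms$id)] <- R$atoms$hcount[ri]
    lp <- mg_loops_of(R, rule$beta[[x]])
    if (length(lp)) loops[[as.character(gx)]] <- lp
    else loops[[as.character(gx)]] <- NULL
  }
  H <- molgraph(atoms, bonds, compound_id = G$compound_id, loops = loops)
  list(H = H, alpha = stats::setNames(G$atoms$id, as.character(G$atoms$id)))
}

#' Enumerate all applications of a rule to a reactant graph
#'
#' All strict label-preserving monomorphisms of `L` into `G` are listed;
#' each is applied, and if expected products are supplied, the resulting
#' components are compared against them (componentwise isomorphism,
#' respecting multiplicities). Alternative matches that produce other
#' products are recorded but do not invalidate the rule.
#'
#' @param rule a [dpo_rule()].
#' @param G reactant `molgraph` (disjoint union of all reactants).
#' @param expected optional list of product `molgraph`s (one per product
#'   component, with multiplicity).
#' @param time_limit seconds; exceeding it returns the matches found so far
#'   with attribute `timeout = TRUE`.
#' @return list of `list(match, applied, products_ok, H, alpha)` entries.
#' @export
enumerate_matches <- function(rule, G, expected = NULL, time_limit = Inf) {
  t0 <- Sys.time()
  matches <- graph_match(rule$left, G, mode = "mono", lenient = FALSE)
  out <- list()
  timeout <- FALSE
  for (m in matches) {
    if (as.numeric(Sys.time() - t0, units = "secs") > time_limit) {
      timeout <- TRUE; break
    }
    res <- apply_rule(rule, G, m)
    entry <- list(match = m, applied = !is.null(res), products_ok = NA)
    if (!is.null(res)) {
      entry$H <- res$H; entry$alpha <- res$alpha
      if (!is.null(expected)) {
        comps <- lapply(mg_components(res$H), function(ids)
          mg_subgraph(res$H, ids))
        entry$products_ok <- mols_multiset_iso(comps, expected)
      }
    }
    out[[length(out) + 1L]] <- entry
  }
  structure(out, timeout = timeout)
}

## prepared view of an ITS graph for the matching engine (labels encoded)
its_prep <- function(its) {
  n <- nrow(its$atoms)
  elem <- vapply(seq_len(n), function(i) {
    paste(its$atoms$element[i], its$atoms$h_g[i], its$atoms$h_h[i],
          paste(its$loops_g[[i]], collapse = ","),
          paste(its$loops_h[[i]], collapse = ","), sep = "#")
  }, character(1))
  adj <- matrix(0L, nrow = max(n, 1L), ncol = max(n, 1L))
  pos <- stats::setNames(seq_len(n), as.character(its$atoms$id))
  ord <- character(nrow(its$edges))
  if (nrow(its$edges)) for (k in seq_len(nrow(its$edges))) {
    i <- pos[[as.character(its$edges$a[k])]]
    j <- pos[[as.character(its$edges$b[k])]]
    adj[i, j] <- k; adj[j, i] <- k
    ord[k] <- paste(its$edges$order_g[k], its$edges$order_h[k], sep = ">")
  }
  list(ids = its$atoms$id, pos = pos, n = n, element = elem,
       hcount = rep(0L, n), wildcard = rep(FALSE, n),
       role = rep(NA_character_, n),
       loops = rep(list(character()), n),
       adj = adj, order = ord, ring = rep(FALSE, length(ord)),
       nbrs = lapply(seq_len(n), function(i) which(adj[i, seq_len(n)] > 0L)))
}

#' Test two ITS graphs for isomorphism
#'
#' Vertex labels (element plus both hydrogen counts and loop annotations)
#' and paired edge labels must be preserved. This is the equivalence used to
#' deduplicate atom-to-atom maps: two AAMs with isomorphic ITS graphs
#' describe the same reaction mechanism.
#'
#' @param i1,i2 [its_graph()]s.
#' @return `TRUE` or `FALSE`.
#' @export
its_isomorphic <- function(i1, i2) {
  if (nrow(i1$atoms) != nrow(i2$atoms) || nrow(i1$edges) != nrow(i2$edges))
    return(FALSE)
  p1 <- its_prep(i1); p2 <- its_prep(i2)
  if (!identical(sort(p1$element), sort(p2$element)) ||
      !identical(sort(p1$order), sort(p2$order))) return(FALSE)
  length(match_engine(p1, p2, mode = "iso", seed = NULL, lenient = FALSE,
                      max_results = 1)) > 0
}
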