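# Independent brute-force oracles used by the derived-value tests.
# Deliberately separate implementations: plain data-frame gluing plus
# igraph VF2 for isomorphism, so they share no code path with the package
# internals they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

## all ordered selections of k indices from n (tiny n only)
gtools_perms <- function(n, k) {
  if (k == 1L) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- gtools_perms(n - 1L, k - 1L)
    rest <- matrix(setdiff(seq_len(n), i)[rest], nrow = nrow(rest))
    out <- rbind(out, cbind(i, rest))
  }
  out
}

frag_vlabels <- function(frag, pins) {
  vlab <- paste(frag$atoms$element, frag$atoms$hcount,
                ifelse(frag$atoms$wildcard %in% TRUE, "w", ""),
                vapply(frag$atoms$id, function(v)
                  paste(sort(frag$loops[[as.character(v)]] %||% character()),
                        collapse = ","), character(1)))
  pidx <- match(frag$atoms$id, pins)
  ifelse(is.na(pidx), vlab, paste0("PIN", pidx, ":", vlab))
}

frag_iso <- function(f1, f2, pins1 = integer(), pins2 = integer()) {
  if (nrow(f1$atoms) != nrow(f2$atoms) || nrow(f1$bonds) != nrow(f2$bonds))
    return(FALSE)
  v1 <- frag_vlabels(f1, pins1); v2 <- frag_vlabels(f2, pins2)
  e1 <- paste(f1$bonds$order, f1$bonds$ring)
  e2 <- paste(f2$bonds$order, f2$bonds$ring)
  vlev <- unique(c(v1, v2)); elev <- unique(c(e1, e2))
  mk <- function(frag) igraph::graph_from_data_frame(
    if (nrow(frag$bonds)) data.frame(from = as.character(frag$bonds$a),
                                     to = as.character(frag$bonds$b))
    else data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = as.character(frag$atoms$id)))
  isTRUE(igraph::isomorphic(
    mk(f1), mk(f2), method = "vf2",
    vertex.color1 = as.integer(factor(v1, levels = vlev)),
    vertex.color2 = as.integer(factor(v2, levels = vlev)),
    edge.color1 = as.integer(factor(e1, levels = elev)),
    edge.color2 = as.integer(factor(e2, levels = elev))))
}

## brute-force expansion oracle: every alternative combination x every
## attachment pairing, glued by direct table manipulation
oracle_expand <- function(tree, table = atom_type_table()) {
  alts <- lapply(tree$code, atom_type_lookup, table = table)
  states <- lapply(alts[[1]], function(a) {
    g <- a$graph
    list(graph = g, nodes = stats::setNames(a$focal, "1"), nextid = max(g$atoms$id))
  })
  for (ci in seq_len(nrow(tree))[-1]) {
    node <- tree$node[ci]
    nxt <- list()
    for (st in states) for (a in alts[[ci]]) {
      A <- st$graph; r <- st$nodes[["1"]]
      C <- a$graph
      off <- st$nextid
      C$atoms$id <- C$atoms$id + off
      if (nrow(C$bonds)) { C$bonds$a <- C$bonds$a + off; C$bonds$b <- C$bonds$b + off }
      if (length(C$loops)) names(C$loops) <-
        as.character(as.integer(names(C$loops)) + off)
      cf <- a$focal + off
      r_nb <- unique(c(A$bonds$b[A$bonds$a == r], A$bonds$a[A$bonds$b == r]))
      c_nb <- unique(c(C$bonds$b[C$bonds$a == cf], C$bonds$a[C$bonds$b == cf]))
      for (u in r_nb) for (v in c_nb) {
        au <- A$atoms[A$atoms$id == u, ]; cv <- C$atoms[C$atoms$id == v, ]
        cfa <- C$atoms[C$atoms$id == cf, ]; ra <- A$atoms[A$atoms$id == r, ]
        if (!au$wildcard && au$element != cfa$element) next
        if (!cv$wildcard && cv$element != ra$element) next
        if (!au$wildcard && u %in% st$nodes) next
        eA <- A$bonds[(A$bonds$a == r & A$bonds$b == u) |
                        (A$bonds$a == u & A$bonds$b == r), ]
        eC <- C$bonds[(C$bonds$a == cf & C$bonds$b == v) |
                        (C$bonds$a == v & C$bonds$b == cf), ]
        if (eA$order != eC$order) next
        if (!(eA$ring == eC$ring || eA$order == "aromatic" ||
                eC$order == "aromatic")) next
        ## glue: u := cf (child focal definition), v := r
        atoms <- A$atoms
        atoms[atoms$id == u, c("element", "hcount", "wildcard")] <-
          cfa[, c("element", "hcount", "wildcard")]
        keep <- C$atoms[!(C$atoms$id %in% c(cf, v)), , drop = FALSE]
        atoms <- rbind(atoms, keep)
        bonds <- A$bonds
        bonds$ring[(bonds$a == r & bonds$b == u) | (bonds$a == u & bonds$b == r)] <-
          eA$ring | eC$ring
        if (nrow(C$bonds)) for (k in seq_len(nrow(C$bonds))) {
          a2 <- C$bonds$a[k]; b2 <- C$bonds$b[k]
          a2 <- if (a2 == cf) u else if (a2 == v) r else a2
          b2 <- if (b2 == cf) u else if (b2 == v) r else b2
          if (any((bonds$a == min(a2, b2) & bonds$b == max(a2, b2)))) next
          bonds <- rbind(bonds, data.frame(a = min(a2, b2), b = max(a2, b2),
                                           order = C$bonds$order[k],
                                           ring = C$bonds$ring[k],
                                           stringsAsFactors = FALSE))
        }
        loops <- A$loops
        loops[[as.character(u)]] <- C$loops[[as.character(cf)]]
        for (nm in setdiff(names(C$loops), as.character(c(cf, v)))) {
          loops[[nm]] <- C$loops[[nm]]
        }
        loops <- loops[!vapply(loops, is.null, logical(1))]
        g2 <- tryCatch(molgraph(atoms, bonds, loops = loops,
                                recompute_rings = FALSE),
                       error = function(e) NULL)
        if (is.null(g2)) next
        nxt[[length(nxt) + 1L]] <- list(
          graph = g2, nodes = c(st$nodes, stats::setNames(u, as.character(node))),
          nextid = max(g2$atoms$id))
      }
    }
    states <- nxt
    if (!length(states)) return(list())
  }
  ## dedup with all node positions pinned, via the igraph route
  keep <- logical(length(states))
  for (i in seq_along(states)) {
    dup <- FALSE
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (frag_iso(states[[i]]$graph, states[[j]]$graph,
                   pins1 = unname(states[[i]]$nodes),
                   pins2 = unname(states[[j]]$nodes[names(states[[i]]$nodes)]))) {
        dup <- TRUE; break
      }
    }
    keep[i] <- !dup
  }
  states[keep]
}
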