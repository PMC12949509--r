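#' Enumerate embeddings of a pattern fragment into a molecule
#'
#' All subgraph monomorphisms of one side of an RDM pattern graph into a
#' host molecule, under the chemical leniency predicates (oxygen bond-order
#' tolerance, ring/aromatic interchange, charge-insensitive vertices,
#' wildcards matching any heavy atom). Implicit hydrogen counts must agree
#' exactly at R/D/M-role atoms and may only be exceeded by the host at
#' context atoms.
#'
#' @param pattern a `molgraph` fragment (one side of an `rdm_pattern`).
#' @param host a `molgraph` molecule.
#' @return list of named integer maps (pattern atom id -> host atom id),
#'   deterministically ordered; empty if the pattern cannot be embedded.
#' @export
enumerate_embeddings <- function(pattern, host) {
  graph_match(pattern, host, mode = "mono", lenient = TRUE)
}

#' Determine which molecule is the reactant and which the product side
#'
#' KEGG stores RDM pattern graphs without an explicit reactant/product
#' distinction; the embeddings decide. An orientation is admissible if every
#' code of the RCLASS has at least one variant whose left side embeds into
#' the first molecule and whose right side embeds into the second.
#'
#' @param patterns list (one entry per RDM code) of lists of `rdm_pattern`
#'   variants.
#' @param A,B `molgraph` molecules.
#' @return one of `"as-is"`, `"swapped"`, `"both"`, `"neither"`.
#' @export
orient_sides <- function(patterns, A, B) {
  admits <- function(X, Y) {
    all(vapply(patterns, function(variants) {
      any(vapply(variants, function(p) {
        length(graph_match(p$left, X, max_results = 1)) > 0 &&
          length(graph_match(p$right, Y, max_results = 1)) > 0
      }, logical(1)))
    }, logical(1)))
  }
  asis <- admits(A, B); swapped <- admits(B, A)
  if (asis && swapped) "both" else if (asis) "as-is"
  else if (swapped) "swapped" else "neither"
}

#' Consistency of two overlapping embedded codes
#'
#' If the left embeddings of two RDM codes share a host vertex, then either
#' both pattern vertices are D-atoms, or both are matched and their partners
#' coincide in the product-side embedding (and symmetrically for shared
#' product vertices). Context and wildcard atoms carry no matching
#' information and never conflict.
#'
#' @param e1,e2 embedded codes: `list(pattern, left, right)` with `left`,
#'   `right` named maps from pattern atom ids to host atom ids.
#' @return `TRUE` iff the pair is consistent.
#' @export
check_overlap_consistency <- function(e1, e2) {
  side_ok <- function(m1, m2, p1, p2, corr1, corr2, o1, o2) {
    shared <- intersect(unname(m1), unname(m2))
    for (v in shared) {
      x1 <- as.integer(names(m1)[match(v, m1)])
      x2 <- as.integer(names(m2)[match(v, m2)])
      r1 <- vertex_role(p1, x1); r2 <- vertex_role(p2, x2)
      info1 <- !is.na(r1) && r1 %in% c("R", "D", "M")
      info2 <- !is.na(r2) && r2 %in% c("R", "D", "M")
      if (!info1 || !info2) next           # context/wildcard: no constraint
      m1d <- r1 == "D"; m2d <- r2 == "D"
      if (m1d != m2d) return(FALSE)
      if (!m1d) {
        w1 <- o1[[as.character(corr1[[as.character(x1)]])]]
        w2 <- o2[[as.character(corr2[[as.character(x2)]])]]
        if (w1 != w2) return(FALSE)
      }
    }
    TRUE
  }
  side_ok(e1$left, e2$left, e1$pattern$left, e2$pattern$left,
          e1$pattern$corr, e2$pattern$corr, e1$right, e2$right) &&
    side_ok(e1$right, e2$right, e1$pattern$right, e2$pattern$right,
            inv_map(e1$pattern$corr), inv_map(e2$pattern$corr),
            e1$left, e2$left)
}

vertex_role <- function(mol, id) mol$atoms$role[match(id, mol$atoms$id)]

inv_map <- function(m) stats::setNames(as.integer(names(m)), m)

#' Assemble the pairwise pattern graphs of one RCLASS on one molecule pair
#'
#' Every combination of (type-graph variant, left embedding, right
#' embedding) across the RCLASS's codes is enumerated; combinations whose
#' embedded codes violate the overlap-consistency conditions, or whose
#' united correspondence fails to be a bipartite matching, are rejected. The
#' surviving combinations are united into pairwise pattern graphs: the
#' embedded subgraphs of reactant and product plus the matching of their
#' vertices, with the R/D/M annotations of every contributing code recorded
#' per vertex.
#'
#' @param codes list of [parse_rdm()] results (the codes of one RCLASS).
#' @param A,B reactant and product `molgraph`s (already oriented).
#' @param table atom-type dictionary.
#' @param cap combination limit per side; exceeding it records a
#'   "combinatorics" failure instead of enumerating.
#' @param patterns optionally precomputed pattern variants per code.
#' @return list of `pairwise_pattern` objects with attribute `status` one of
#'   `"ok"`, `"cannot_embed"`, `"combinatorics"`, `"no_pattern"`.
#' @export
assemble_pairwise <- function(codes, A, B, table = atom_type_table(),
                              cap = 1000, patterns = NULL) {
  if (is.null(patterns)) {
    patterns <- lapply(seq_along(codes), function(i)
      make_pattern_graphs(codes[[i]], table, code_index = i))
  }
  if (any(!lengths(patterns))) {
    return(structure(list(), status = "no_pattern"))
  }
  ## options per code: one (variant, left embedding, right embedding) each
  options <- vector("list", length(patterns))
  for (i in seq_along(patterns)) {
    opts <- list()
    for (p in patterns[[i]]) {
      les <- enumerate_embeddings(p$left, A)
      res <- enumerate_embeddings(p$right, B)
      for (le in les) for (re in res) {
        opts[[length(opts) + 1L]] <- list(pattern = p, left = le, right = re)
      }
    }
    if (!length(opts)) return(structure(list(), status = "cannot_embed"))
    options[[i]] <- opts
  }
  ncomb <- prod(lengths(options))
  if (ncomb > cap) return(structure(list(), status = "combinatorics"))

  out <- list(); seen <- character()
  for (combo in cartesian_index(lengths(options))) {
    es <- Map(function(opts, k) opts[[k]], options, combo)
    ok <- TRUE
    if (length(es) > 1) {
      for (i in seq_along(es)) {
        for (j in seq_len(i - 1L)) {
          if (!check_overlap_consistency(es[[i]], es[[j]])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (!ok) next
    pp <- union_embedded_codes(es, A, B)
    if (is.null(pp)) next
    key <- pairwise_key(pp)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- pp
  }
  structure(out, status = if (length(out)) "ok" else "inconsistent")
}

## all index combinations, first index fastest; deterministic
cartesian_index <- function(lens) {
  if (!length(lens)) return(list(integer()))
  grid <- do.call(expand.grid, lapply(lens, seq_len))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

## union one consistent combination of embedded codes into a pairwise pattern
union_embedded_codes <- function(es, A, B) {
  va <- integer(); vb <- integer()
  ea <- list(); eb <- list()
  roles_a <- list(); roles_b <- list()
  match_pairs <- list()
  prov <- list()
  add_role <- function(env, v, role) {
    k <- as.character(v)
    env[[k]] <- union(env[[k]], role)
    env
  }
  core_a <- integer(); core_b <- integer()
  for (e in es) {
    p <- e$pattern
    va <- union(va, unname(e$left)); vb <- union(vb, unname(e$right))
    ## images of the non-wildcard pattern atoms (wildcard R-residues are
    ## placeholders, not integrated pattern atoms)
    core_a <- union(core_a, unname(
      e$left[as.character(p$left$atoms$id[!p$left$atoms$wildcard])]))
    core_b <- union(core_b, unname(
      e$right[as.character(p$right$atoms$id[!p$right$atoms$wildcard])]))
    ## image edges of the embedded pattern bonds
    for (k in seq_len(nrow(p$left$bonds))) {
      ea[[length(ea) + 1L]] <- sort(c(e$left[[as.character(p$left$bonds$a[k])]],
                                      e$left[[as.character(p$left$bonds$b[k])]]))
    }
    for (k in seq_len(nrow(p$right$bonds))) {
      eb[[length(eb) + 1L]] <- sort(c(e$right[[as.character(p$right$bonds$a[k])]],
                                      e$right[[as.character(p$right$bonds$b[k])]]))
    }
    for (i in seq_len(mg_n(p$left))) {
      role <- p$left$atoms$role[i]
      if (!is.na(role) && role %in% c("R", "D", "M")) {
        roles_a <- add_role(roles_a, e$left[[as.character(p$left$atoms$id[i])]], role)
      }
    }
    for (i in seq_len(mg_n(p$right))) {
      role <- p$right$atoms$role[i]
      if (!is.na(role) && role %in% c("R", "D", "M")) {
        roles_b <- add_role(roles_b, e$right[[as.character(p$right$atoms$id[i])]], role)
      }
    }
    for (x in names(p$corr)) {
      match_pairs[[length(match_pairs) + 1L]] <-
        c(e$left[[x]], e$right[[as.character(p$corr[[x]])]])
    }
    prov[[length(prov) + 1L]] <- list(rclass_id = p$rclass_id,
                                      code_index = p$code_index,
                                      variant_id = p$variant_id)
  }
  mm <- unique(do.call(rbind, match_pairs))
  matching <- data.frame(a = mm[, 1], b = mm[, 2])
  matching <- matching[order(matching$a), , drop = FALSE]
  if (anyDuplicated(matching$a) || anyDuplicated(matching$b)) return(NULL)
  host_edges <- function(host, pairs) {
    if (!length(pairs)) {
      return(host$bonds[0, , drop = FALSE])
    }
    keys <- unique(vapply(pairs, function(e) paste(e[1], e[2], sep = "|"),
                          character(1)))
    host$bonds[paste(host$bonds$a, host$bonds$b, sep = "|") %in% keys, ,
               drop = FALSE]
  }
  lhat <- mg_subgraph(A, sort(va), edges = host_edges(A, ea))
  rhat <- mg_subgraph(B, sort(vb), edges = host_edges(B, eb))
  structure(list(lhat = lhat, rhat = rhat, matching = matching,
                 roles_a = roles_a, roles_b = roles_b,
                 core_a = sort(core_a), core_b = sort(core_b),
                 provenance = prov),
            class = "pairwise_pattern")
}

pairwise_key <- function(pp) {
  paste(paste(pp$lhat$atoms$id, collapse = ","),
        paste(pp$rhat$atoms$id, collapse = ","),
        paste(pp$lhat$bonds$a, pp$lhat$bonds$b, collapse = ","),
        paste(pp$rhat$bonds$a, pp$rhat$bonds$b, collapse = ","),
        paste(pp$matching$a, pp$matching$b, collapse = ","),
        paste(vapply(sort(names(pp$roles_a)), function(k)
          paste0(k, "=", paste(sort(pp$roles_a[[k]]), collapse = "")),
          character(1)), collapse = ";"),
        sep = " / ")
}

#' @export
print.pairwise_pattern <- function(x, ...) {
  cat(sprintf("<pairwise_pattern: L^ %d atoms, R^ %d atoms, %d matched pairs>\n",
              mg_n(x$lhat), mg_n(x$rhat), nrow(x$matching)))
  invisible(x)
}
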