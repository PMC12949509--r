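#' Extend a partial atom map by seeded isomorphism search
#'
#' A VF2-style search initialised by *declaring* the seed a consistent set
#' of matches: a new vertex pair can be appended only if all edges and edge
#' labels to previously matched vertices are preserved. If the seed covers
#' every atom incident to a bond change, the remainder of the molecules is
#' unchanged and the search terminates with full bijections; a seed with no
#' extension cannot belong to a correct DPO rule, which makes extensibility
#' a filter criterion.
#'
#' @param G,H reactant and product `molgraph`s (equal atom counts).
#' @param seed named integer map `V(G)` id -> `V(H)` id (injective).
#' @return list of full bijections (named integer vectors); empty if the
#'   seed cannot be extended.
#' @export
seeded_extension <- function(G, H, seed) {
  graph_match(G, H, mode = "iso", seed = seed)
}

#' Complete atom maps from rule embeddings, minimizing changing bonds
#'
#' All strict embeddings of the rule's educt side `L` into `G` and of its
#' product side `R` into `H` are combined into partial atom maps; each is
#' extended to a full label-preserving bijection by exact branch-and-bound
#' minimization of the number of bonds that change outside the rule. For a
#' complete rule the minimum equals the rule's own reaction-edge count; for
#' an incomplete rule the minimization supplies precisely the uncovered
#' changes. Results are deduplicated by ITS isomorphism with the residual
#' multiplicity recorded.
#'
#' @param rule a [dpo_rule()].
#' @param G,H reactant and product union graphs.
#' @param minimal_only drop AAMs above the minimal changing-bond count.
#' @return list of `list(alpha, changing_bonds, its, multiplicity)`, minimal
#'   count first; empty if no combination extends. The attribute
#'   `minimum` carries the minimal changing-bond count.
#' @export
complete_via_rule_embeddings <- function(rule, G, H, minimal_only = TRUE) {
  if (mg_n(G) != mg_n(H)) return(structure(list(), minimum = NA_integer_))
  l_embs <- graph_match(rule$left, G, mode = "mono", lenient = FALSE)
  r_embs <- graph_match(rule$right, H, mode = "mono", lenient = FALSE)
  seeds <- list(); seen <- character()
  for (ml in l_embs) for (mr in r_embs) {
    seed <- stats::setNames(
      unname(mr[as.character(rule$beta[names(ml)])]), unname(ml))
    seed <- seed[order(as.integer(names(seed)))]
    if (anyDuplicated(unname(seed))) next
    key <- paste(names(seed), seed, collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key); seeds[[length(seeds) + 1L]] <- seed
  }
  results <- list()
  for (seed in seeds) {
    for (ext in min_change_extension(G, H, seed)) {
      results[[length(results) + 1L]] <- ext
    }
  }
  if (!length(results)) return(structure(list(), minimum = NA_integer_))
  costs <- vapply(results, `[[`, numeric(1), "cost")
  results <- results[order(costs)]
  costs <- sort(costs)
  if (minimal_only) {
    results <- results[costs == costs[1]]
  }
  ## deduplicate by ITS isomorphism, tagging residual multiplicity
  out <- list()
  for (res in results) {
    its <- its_graph(G, H, res$alpha)
    dup <- FALSE
    for (i in seq_along(out)) {
      if (out[[i]]$changing_bonds == res$cost &&
          its_isomorphic(out[[i]]$its, its)) {
        out[[i]]$multiplicity <- out[[i]]$multiplicity + 1L
        dup <- TRUE; break
      }
    }
    if (!dup) {
      out[[length(out) + 1L]] <- list(alpha = res$alpha,
                                      changing_bonds = res$cost,
                                      its = its, multiplicity = 1L)
    }
  }
  structure(out, minimum = min(vapply(out, `[[`, numeric(1), "changing_bonds")))
}

## exact branch-and-bound completion of a partial map to full bijections
## minimizing the number of changed bonds; returns all optima as
## list(alpha, cost)
min_change_extension <- function(G, H, seed) {
  p <- mg_prep(G); h <- mg_prep(H)
  if (p$n != h$n) return(list())
  map <- rep(NA_integer_, p$n); used <- rep(FALSE, h$n)
  for (nm in names(seed)) {
    pi <- p$pos[[nm]]; hi <- h$pos[[as.character(seed[[nm]])]]
    map[pi] <- hi; used[hi] <- TRUE
  }
  pair_cost <- function(pi, hi) {
    cost <- 0L
    for (pj in which(!is.na(map))) {
      if (pj == pi) next
      k1 <- p$adj[pi, pj]; k2 <- h$adj[hi, map[pj]]
      if (k1 > 0L || k2 > 0L) {
        if (k1 == 0L || k2 == 0L || p$order[k1] != h$order[k2]) cost <- cost + 1L
      }
    }
    cost
  }
  ## cost already incurred within the seed
  base_cost <- 0L
  seeded <- which(!is.na(map))
  for (a in seeded) for (b in seeded) {
    if (b <= a) next
    k1 <- p$adj[a, b]; k2 <- h$adj[map[a], map[b]]
    if (k1 > 0L || k2 > 0L) {
      if (k1 == 0L || k2 == 0L || p$order[k1] != h$order[k2])
        base_cost <- base_cost + 1L
    }
  }
  free <- setdiff(seq_len(p$n), seeded)
  ## connected-first deterministic order
  ordered <- integer()
  remaining <- free
  anchor <- seeded
  while (length(remaining)) {
    nconn <- vapply(remaining, function(v)
      sum(p$nbrs[[v]] %in% c(anchor, ordered)), integer(1))
    sel <- remaining[order(-nconn, p$ids[remaining])][1]
    ordered <- c(ordered, sel); remaining <- setdiff(remaining, sel)
  }
  best <- Inf; results <- list()
  recurse <- function(step, cost) {
    if (cost > best) return()
    if (step > length(ordered)) {
      alpha <- stats::setNames(h$ids[map], as.character(p$ids))
      alpha <- alpha[order(as.integer(names(alpha)))]
      if (cost < best) { best <<- cost; results <<- list() }
      results[[length(results) + 1L]] <<- list(alpha = alpha, cost = cost)
      return()
    }
    pi <- ordered[step]
    cand <- which(!used & h$element == p$element[pi])
    cand <- cand[order(h$ids[cand])]
    for (hi in cand) {
      dc <- pair_cost(pi, hi)
      if (cost + dc <= best) {
        map[pi] <<- hi; used[hi] <<- TRUE
        recurse(step + 1L, cost + dc)
        map[pi] <<- NA_integer_; used[hi] <<- FALSE
      }
    }
  }
  recurse(1L, base_cost)
  results
}

#' Mapped reaction SMILES of an atom-to-atom map
#'
#' Writes every atom in brackets with its atom-map number (the reactant atom
#' id), reactant components joined by `.`, then `>>`, then the product
#' components. Intended for interchange and eyeballing, alongside the
#' bit-exact JSON pair list from [write_aam_json()].
#'
#' @param G,H reactant and product union graphs.
#' @param alpha named integer map `V(G)` id -> `V(H)` id.
#' @return a character scalar.
#' @export
aam_smiles <- function(G, H, alpha) {
  mapnum_g <- stats::setNames(G$atoms$id, as.character(G$atoms$id))
  inv <- stats::setNames(as.integer(names(alpha)), alpha)
  mapnum_h <- stats::setNames(as.integer(inv[as.character(H$atoms$id)]),
                              as.character(H$atoms$id))
  side <- function(mol, mapnum) {
    paste(vapply(mg_components(mol), function(ids)
      smiles_component(mg_subgraph(mol, ids), mapnum), character(1)),
      collapse = ".")
  }
  paste0(side(G, mapnum_g), ">>", side(H, mapnum_h))
}

smiles_component <- function(mol, mapnum) {
  idx <- mg_bond_index(mol)
  nbrs <- mg_nbrs(mol)
  start <- min(mol$atoms$id)
  bond_sym <- function(a, b) {
    r <- mg_bond_row(idx, a, b)
    c(single = "", double = "=", triple = "#", aromatic = ":")[[mol$bonds$order[r]]]
  }
  atom_str <- function(v) {
    i <- base::match(v, mol$atoms$id)
    h <- mol$atoms$hcount[i]
    chg <- ""
    for (lp in mg_loops_of(mol, v)) {
      if (startsWith(lp, "charge:")) {
        c0 <- as.integer(sub("charge:", "", lp))
        chg <- paste0(if (c0 > 0) "+" else "-",
                      if (abs(c0) > 1) abs(c0) else "")
      }
    }
    paste0("[", mol$atoms$element[i],
           if (h > 0) paste0("H", if (h > 1) h else ""),
           chg, ":", mapnum[[as.character(v)]], "]")
  }
  ## first pass: DFS tree and back edges (ring closures)
  visited <- character()
  children <- list(); back <- character()
  walk <- function(v, parent) {
    visited <<- c(visited, as.character(v))
    kids <- integer()
    for (u in sort(nbrs[[as.character(v)]])) {
      if (!is.null(parent) && u == parent) next
      if (as.character(u) %in% visited) {
        back <<- union(back, mg_bond_key(v, u))
      } else {
        kids <- c(kids, u)
        walk(u, v)
      }
    }
    children[[as.character(v)]] <<- kids
  }
  walk(start, NULL)
  ring_digit <- function(n) if (n > 9) paste0("%", n) else as.character(n)
  closures_of <- function(v) {
    s <- ""
    for (i in seq_along(back)) {
      ends <- as.integer(strsplit(back[i], "|", fixed = TRUE)[[1]])
      if (v %in% ends) s <- paste0(s, ring_digit(i))
    }
    s
  }
  ## second pass: DFS emission re-using the recorded tree
  emit <- function(v) {
    ## children may have been claimed by an earlier branch of the DFS
    kids <- children[[as.character(v)]]
    s <- paste0(atom_str(v), closures_of(v))
    parts <- vapply(kids, function(u) paste0(bond_sym(v, u), emit(u)),
                    character(1))
    if (length(parts) > 1L) {
      s <- paste0(s, paste0("(", parts[-length(parts)], ")", collapse = ""),
                  parts[length(parts)])
    } else if (length(parts) == 1L) s <- paste0(s, parts)
    s
  }
  emit(start)
}

#' Write an atom-to-atom map as a JSON pair list
#'
#' @param alpha named integer map (reactant atom id -> product atom id).
#' @param path optional output file; if `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to a file).
#' @export
write_aam_json <- function(alpha, path = NULL) {
  alpha <- alpha[order(as.integer(names(alpha)))]
  js <- jsonlite::toJSON(
    list(pairs = data.frame(reactant = as.integer(names(alpha)),
                            product = unname(alpha))),
    dataframe = "rows", auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
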