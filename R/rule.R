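#' DPO transformation rules
#'
#' A chemical DPO rule is a span `L <- K -> R`: `L` and `R` are molecule-graph
#' fragments over vertex sets linked by the label-preserving bijection `beta`,
#' and the context `K` is the *maximal* context: the graph on `V(L)` whose
#' edges are exactly those on which `L` and `R` agree (same bond, same label).
#' Atoms are always preserved, so `beta` is total; only edges change.
#'
#' @param left,right `molgraph` fragments.
#' @param beta named integer vector: names are `left` atom ids, values the
#'   corresponding `right` atom ids.
#' @param rule_id identifier string.
#' @param provenance free-form list recording contributing patterns.
#' @return an object of class `dpo_rule`.
#' @export
dpo_rule <- function(left, right, beta, rule_id = NA_character_,
                     provenance = NULL) {
  beta <- beta[order(as.integer(names(beta)))]
  lid <- sort(left$atoms$id); rid <- sort(right$atoms$id)
  if (!identical(as.integer(names(beta)), lid)) {
    stop("beta must cover every atom of L (chemical rules preserve atoms)")
  }
  if (!identical(sort(unname(beta)), rid)) {
    stop("beta must be a bijection onto the atoms of R")
  }
  el_l <- left$atoms$element[match(as.integer(names(beta)), left$atoms$id)]
  el_r <- right$atoms$element[match(unname(beta), right$atoms$id)]
  if (!all(el_l == el_r)) stop("beta does not preserve element labels")
  structure(list(left = left, right = right, beta = beta,
                 rule_id = rule_id, provenance = provenance,
                 complete = NA),
            class = "dpo_rule")
}

#' @export
print.dpo_rule <- function(x, ...) {
  K <- rule_context(x)
  cat(sprintf("<dpo_rule %s: %d atoms, L %d bonds / K %d bonds / R %d bonds>\n",
              if (is.na(x$rule_id)) "?" else x$rule_id,
              mg_n(x$left), nrow(x$left$bonds), nrow(K$bonds),
              nrow(x$right$bonds)))
  invisible(x)
}

#' Maximal context K of a rule
#'
#' `xx'` is an edge of `K` iff it is an edge of `L`, its image under `beta`
#' is an edge of `R`, and the two labels agree. Any smaller context yields
#' the same transformation, so the maximal one is the canonical
#' representative.
#'
#' @param rule a [dpo_rule()].
#' @return a `molgraph` on the vertex set of `L`.
#' @export
rule_context <- function(rule) {
  L <- rule$left; R <- rule$right
  ridx <- mg_bond_index(R)
  keep <- logical(nrow(L$bonds))
  if (nrow(L$bonds)) {
    for (k in seq_len(nrow(L$bonds))) {
      ra <- rule$beta[[as.character(L$bonds$a[k])]]
      rb <- rule$beta[[as.character(L$bonds$b[k])]]
      r <- mg_bond_row(ridx, ra, rb)
      keep[k] <- !is.na(r) && R$bonds$order[r] == L$bonds$order[k]
    }
  }
  mg_subgraph(L, L$atoms$id, edges = L$bonds[keep, , drop = FALSE])
}

## per-vertex label changes (hcount or loops) between L and R under beta
rule_vertex_changed <- function(rule) {
  L <- rule$left; R <- rule$right
  vapply(as.character(L$atoms$id), function(v) {
    rv <- rule$beta[[v]]
    li <- match(as.integer(v), L$atoms$id); ri <- match(rv, R$atoms$id)
    L$atoms$hcount[li] != R$atoms$hcount[ri] ||
      !identical(mg_loops_of(L, as.integer(v)), mg_loops_of(R, rv))
  }, logical(1))
}

## total number of implicit-hydrogen changes of a rule (for the
## minimum-hydrogen-exchange filter)
rule_h_edits <- function(rule) {
  L <- rule$left; R <- rule$right
  sum(vapply(seq_len(mg_n(L)), function(i) {
    rv <- rule$beta[[as.character(L$atoms$id[i])]]
    abs(L$atoms$hcount[i] - R$atoms$hcount[match(rv, R$atoms$id)])
  }, numeric(1)))
}

## two rules equivalent up to isomorphism of their rule graphs Psi
rules_isomorphic <- function(r1, r2) {
  its_isomorphic(rule_psi(r1), rule_psi(r2))
}
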