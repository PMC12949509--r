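#' Run the full RDM-to-DPO workflow for one reaction
#'
#' Executes the five stages consecutively: RDM code expansion, side
#' orientation and embedding, pairwise pattern assembly, cross-RCLASS rule
#' reconstruction (with missing-RCLASS completion where D-atoms stay
#' unmatched), and atom-to-atom map completion. Every stage enumerates all
#' solutions consistent with the input; nothing is guessed or repaired.
#'
#' @param record a [reaction_record()].
#' @param molecules named list of `molgraph`s for every compound.
#' @param codes named list: rclass id -> character vector of RDM codes.
#' @param table atom-type dictionary.
#' @param cap combination limit per enumeration stage (default 1000).
#' @param time_limit overall time budget in seconds (default 7200).
#' @return list with `status` (one of `aam_complete`, `aam_partial`,
#'   `rule_only`, `conflict`, `combinatorics_skip`, `timeout`,
#'   `no_structure`, `undefined_atoms`, `no_pattern`, `cannot_embed`,
#'   `no_rule`), `rules` (validated [dpo_rule()]s), `aams`, `conflicts`,
#'   `completion` (candidate statistics of the missing-RCLASS stage) and
#'   `graphs`.
#' @export
run_pipeline <- function(record, molecules, codes, table = atom_type_table(),
                         cap = 1000, time_limit = 7200) {
  t0 <- Sys.time()
  over_time <- function() as.numeric(Sys.time() - t0, units = "secs") > time_limit
  res <- list(status = "no_rule", rules = list(), aams = list(),
              conflicts = list(), completion = list(candidates = 0L,
                                                    surviving = 0L))
  ## stage 0: structures
  needed <- unique(c(record$reactants$compound_id, record$products$compound_id))
  for (cid in needed) {
    m <- molecules[[cid]]
    if (is.null(m) || !is.null(m$nonconvertible)) {
      res$status <- "no_structure"
      return(res)
    }
  }
  if (!length(record$rclass_links)) return(res)

  ## stage 1: expand RDM codes into pattern graphs
  link_patterns <- vector("list", length(record$rclass_links))
  for (i in seq_along(record$rclass_links)) {
    link <- record$rclass_links[[i]]
    code_strs <- codes[[link$rclass_id]]
    if (is.null(code_strs)) { res$status <- "no_pattern"; return(res) }
    parsed <- lapply(code_strs, parse_rdm, rclass_id = link$rclass_id,
                     table = table)
    pats <- tryCatch(
      lapply(seq_along(parsed), function(k)
        make_pattern_graphs(parsed[[k]], table, code_index = k)),
      error = function(e) {
        if (grepl("undefined atoms", conditionMessage(e))) "undefined" else stop(e)
      })
    if (identical(pats, "undefined")) {
      res$status <- "undefined_atoms"; return(res)
    }
    if (any(!lengths(pats))) { res$status <- "no_pattern"; return(res) }
    link_patterns[[i]] <- list(link = link, codes = parsed, patterns = pats)
  }

  ## stages 2-3: orientation and pairwise assembly
  pairwise <- vector("list", length(link_patterns))
  for (i in seq_along(link_patterns)) {
    lp <- link_patterns[[i]]
    A <- molecules[[lp$link$reactant]]; B <- molecules[[lp$link$product]]
    ori <- orient_sides(lp$patterns, A, B)
    if (ori == "neither") { res$status <- "cannot_embed"; return(res) }
    pats <- lp$patterns
    if (ori == "swapped") pats <- lapply(pats, function(vs)
      lapply(vs, swap_pattern))
    pw <- assemble_pairwise(lp$codes, A, B, table = table, cap = cap,
                            patterns = pats)
    st <- attr(pw, "status")
    if (st == "combinatorics") { res$status <- "combinatorics_skip"; return(res) }
    if (st %in% c("cannot_embed", "no_pattern")) {
      res$status <- if (st == "no_pattern") "no_pattern" else "cannot_embed"
      return(res)
    }
    if (!length(pw)) { res$status <- "conflict"; return(res) }
    pairwise[[i]] <- pw
    if (over_time()) { res$status <- "timeout"; return(res) }
  }

  ## stage 4: rule reconstruction
  comb <- combine_reaction(record, molecules, pairwise, cap = cap)
  rg <- comb$graphs
  res$graphs <- rg
  res$conflicts <- comb$conflicts
  if (comb$status == "combinatorics") { res$status <- "combinatorics_skip"; return(res) }
  expected <- lapply(mg_components(rg$H), function(ids) mg_subgraph(rg$H, ids))
  valid <- list()
  for (rule in comb$rules) {
    v <- validate_rule(rule, rg$G, expected)
    if (isTRUE(v$valid)) { rule$complete <- TRUE; valid[[length(valid) + 1L]] <- rule }
  }
  ## missing-RCLASS completion for consistent but partially matched states
  for (cand in comb$partials) {
    if (over_time()) { res$status <- "timeout"; return(res) }
    ds <- d_subgraphs(cand, rg)
    if (!length(ds)) next
    cand_lists <- match_d_subgraphs(ds, cand, rg)
    for (k in seq_along(ds)) {
      if (!length(cand_lists[[k]])) {
        cand_lists[[k]] <- carboxy_special_case(ds[[k]], cand, rg)
      }
    }
    res$completion$candidates <- res$completion$candidates +
      sum(lengths(cand_lists))
    if (any(!lengths(cand_lists))) next        # rule stays incomplete
    for (ext in combine_extensions(cand_lists)) {
      cand2 <- cand
      cand2$matching <- rbind(cand$matching, ext)
      cand2$matching <- cand2$matching[order(cand2$matching$a), , drop = FALSE]
      cand2$va <- sort(union(cand$va, ext$a))
      cand2$vb <- sort(union(cand$vb, ext$b))
      cand2 <- with_elements(cand2, rg)
      if (!balance_test(cand2)) next
      rule <- state_to_rule(cand2, rg, record$reaction_id)
      if (is.null(rule)) next
      alpha_full <- stats::setNames(cand2$matching$b,
                                    as.character(cand2$matching$a))
      rule <- complete_small_molecule_rule(rule, rg$G, rg$H, alpha = alpha_full)
      if (isTRUE(rule$complete)) {
        res$completion$surviving <- res$completion$surviving + 1L
        valid[[length(valid) + 1L]] <- rule
      }
    }
  }
  if (!length(valid)) {
    res$status <- if (length(comb$conflicts)) "conflict"
    else if (length(comb$partials)) "aam_partial"
    else "no_rule"
    return(res)
  }
  valid <- filter_min_h_rules(valid)
  res$rules <- valid

  ## stage 5: AAM completion
  if (mg_n(rg$G) != mg_n(rg$H)) { res$status <- "aam_partial"; return(res) }
  aams <- list()
  for (rule in valid) {
    if (over_time()) { res$status <- "timeout"; return(res) }
    for (a in complete_via_rule_embeddings(rule, rg$G, rg$H)) {
      dup <- FALSE
      for (i in seq_along(aams)) {
        if (its_isomorphic(aams[[i]]$its, a$its)) {
          aams[[i]]$multiplicity <- aams[[i]]$multiplicity + a$multiplicity
          dup <- TRUE; break
        }
      }
      if (!dup) {
        a$smiles <- aam_smiles(rg$G, rg$H, a$alpha)
        aams[[length(aams) + 1L]] <- a
      }
    }
  }
  ## the minimization objective is per reaction: of all admissible maps,
  ## keep those with the fewest changing bonds
  if (length(aams)) {
    cb <- vapply(aams, `[[`, integer(1), "changing_bonds")
    aams <- aams[cb == min(cb)]
  }
  res$aams <- aams
  res$status <- if (length(aams)) "aam_complete" else "rule_only"
  res
}

## exchange the two sides of an rdm_pattern (orientation "swapped")
swap_pattern <- function(p) {
  structure(list(left = p$right, right = p$left, corr = inv_map(p$corr),
                 left_node_map = p$right_node_map,
                 right_node_map = p$left_node_map,
                 variant_id = p$variant_id, rclass_id = p$rclass_id,
                 code_index = p$code_index),
            class = "rdm_pattern")
}

## all disjoint unions of per-D-subgraph candidate extensions
combine_extensions <- function(cand_lists) {
  if (!length(cand_lists) || any(!lengths(cand_lists))) return(list())
  out <- list()
  for (cb in cartesian_index(lengths(cand_lists))) {
    ext <- do.call(rbind, Map(function(l, k) l[[k]], cand_lists, cb))
    if (anyDuplicated(ext$a) || anyDuplicated(ext$b)) next
    out[[length(out) + 1L]] <- ext
  }
  out
}

#' One-line status summary of a pipeline result
#'
#' @param record the [reaction_record()] that was run.
#' @param result the [run_pipeline()] return value.
#' @return data.frame row for a machine-readable status table.
#' @export
pipeline_status_row <- function(record, result) {
  data.frame(reaction_id = record$reaction_id, status = result$status,
             n_rules = length(result$rules), n_aams = length(result$aams),
             n_conflicts = length(result$conflicts),
             stringsAsFactors = FALSE)
}
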