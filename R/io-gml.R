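#' Serialize a DPO rule in the GML rule dialect
#'
#' Emits the three-section (`left`/`context`/`right`) GML format used by DPO
#' rewriting tools: nodes and edges shared by both sides (with identical
#' labels) go to `context`; parts that differ go to `left` and `right`,
#' sharing vertex ids (the ids of `L`; `beta` is applied to express `R` in
#' that id space). Node labels encode element, implicit hydrogens and loop
#' annotations (e.g. `"CH3"`, `"O{charge:-1}"`); edge labels use `-`, `=`,
#' `#`, `:` for single/double/triple/aromatic, with an extra `ring 1` key on
#' ring bonds. Round-trips through [read_rule_gml()].
#'
#' @param rule a [dpo_rule()].
#' @return a character scalar of GML text.
#' @export
write_rule_gml <- function(rule) {
  L <- rule$left; R <- rule$right
  K <- rule_context(rule)
  inv_beta <- stats::setNames(as.integer(names(rule$beta)), rule$beta)
  vlab_l <- function(v) node_label(L, v)
  vlab_r <- function(v) node_label(R, rule$beta[[as.character(v)]])
  changed <- rule_vertex_changed(rule)
  kidx <- mg_bond_index(K)

  node_line <- function(v, lab) sprintf('    node [ id %d label "%s" ]', v, lab)
  edge_line <- function(a, b, order, ring) {
    sprintf('    edge [ source %d target %d label "%s"%s ]', a, b,
            c(single = "-", double = "=", triple = "#", aromatic = ":")[[order]],
            if (ring) " ring 1" else "")
  }
  left <- character(); ctx <- character(); right <- character()
  for (i in seq_len(mg_n(L))) {
    v <- L$atoms$id[i]
    if (changed[[as.character(v)]]) {
      left <- c(left, node_line(v, vlab_l(v)))
      right <- c(right, node_line(v, vlab_r(v)))
    } else ctx <- c(ctx, node_line(v, vlab_l(v)))
  }
  if (nrow(L$bonds)) for (k in seq_len(nrow(L$bonds))) {
    a <- L$bonds$a[k]; b <- L$bonds$b[k]
    if (!is.na(mg_bond_row(kidx, a, b))) {
      ctx <- c(ctx, edge_line(a, b, L$bonds$order[k], L$bonds$ring[k]))
    } else {
      left <- c(left, edge_line(a, b, L$bonds$order[k], L$bonds$ring[k]))
    }
  }
  if (nrow(R$bonds)) for (k in seq_len(nrow(R$bonds))) {
    a <- inv_beta[[as.character(R$bonds$a[k])]]
    b <- inv_beta[[as.character(R$bonds$b[k])]]
    kr <- mg_bond_row(kidx, a, b)
    if (is.na(kr) || K$bonds$order[kr] != R$bonds$order[k]) {
      right <- c(right, edge_line(a, b, R$bonds$order[k], R$bonds$ring[k]))
    }
  }
  paste(c("rule [",
          sprintf('  ruleID "%s"',
                  if (is.na(rule$rule_id)) "rule" else rule$rule_id),
          "  left [", left, "  ]",
          "  context [", ctx, "  ]",
          "  right [", right, "  ]",
          "]"), collapse = "\n")
}

node_label <- function(mol, v) {
  i <- match(v, mol$atoms$id)
  h <- mol$atoms$hcount[i]
  lab <- mol$atoms$element[i]
  if (isTRUE(mol$atoms$wildcard[i])) lab <- "*"
  if (h > 0) lab <- paste0(lab, "H", if (h > 1) h else "")
  lp <- mg_loops_of(mol, v)
  if (length(lp)) lab <- paste0(lab, "{", paste(lp, collapse = ";"), "}")
  lab
}

parse_node_label <- function(lab) {
  loops <- character()
  if (grepl("\\{", lab)) {
    loops <- strsplit(sub("^.*\\{(.*)\\}.*$", "\\1", lab), ";", fixed = TRUE)[[1]]
    lab <- sub("\\{.*\\}", "", lab)
  }
  m <- regmatches(lab, regexec("^(\\*|[A-Z][a-z]?)(H([0-9]*))?$", lab))[[1]]
  if (!length(m)) stop("GML parse error: bad node label ", sQuote(lab))
  h <- if (m[3] == "") 0L else if (m[4] == "") 1L else as.integer(m[4])
  list(element = m[2], hcount = h, loops = loops, wildcard = m[2] == "*")
}

#' Read a DPO rule from its GML serialization
#'
#' @param text GML text as produced by [write_rule_gml()].
#' @return a [dpo_rule()].
#' @export
read_rule_gml <- function(text) {
  toks <- gml_tokens(text)
  tree <- gml_parse(toks)
  rule <- gml_find(tree, "rule")
  if (is.null(rule)) stop("GML parse error: no rule block")
  sect <- function(name) gml_find(rule$children, name)
  get_nodes <- function(blk) {
    out <- list()
    for (ch in blk$children) {
      if (ch$key == "node") {
        id <- gml_scalar(ch, "id"); lab <- gml_scalar(ch, "label")
        out[[length(out) + 1L]] <- c(list(id = as.integer(id)),
                                     parse_node_label(lab))
      }
    }
    out
  }
  get_edges <- function(blk) {
    out <- list()
    for (ch in blk$children) {
      if (ch$key == "edge") {
        ring <- gml_scalar(ch, "ring", optional = TRUE)
        out[[length(out) + 1L]] <- list(
          a = as.integer(gml_scalar(ch, "source")),
          b = as.integer(gml_scalar(ch, "target")),
          order = c("-" = "single", "=" = "double", "#" = "triple",
                    ":" = "aromatic")[[gml_scalar(ch, "label")]],
          ring = !is.null(ring) && ring == "1")
      }
    }
    out
  }
  l_blk <- sect("left"); c_blk <- sect("context"); r_blk <- sect("right")
  ln <- get_nodes(l_blk); cn <- get_nodes(c_blk); rn <- get_nodes(r_blk)
  build_side <- function(own_nodes) {
    nodes <- c(cn, own_nodes)
    atoms <- data.frame(
      id = vapply(nodes, `[[`, integer(1), "id"),
      element = vapply(nodes, `[[`, character(1), "element"),
      hcount = vapply(nodes, `[[`, integer(1), "hcount"),
      wildcard = vapply(nodes, `[[`, logical(1), "wildcard"),
      stringsAsFactors = FALSE)
    loops <- list()
    for (nd in nodes) if (length(nd$loops)) loops[[as.character(nd$id)]] <- nd$loops
    list(atoms = atoms, loops = loops)
  }
  mk_bonds <- function(edge_lists) {
    if (!length(edge_lists)) {
      return(data.frame(a = integer(), b = integer(), order = character(),
                        ring = logical(), stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(edge_lists, function(e)
      data.frame(a = e$a, b = e$b, order = e$order, ring = e$ring,
                 stringsAsFactors = FALSE)))
  }
  ce <- get_edges(c_blk)
  sl <- build_side(ln); sr <- build_side(rn)
  L <- molgraph(sl$atoms, mk_bonds(c(ce, get_edges(l_blk))), loops = sl$loops,
                recompute_rings = FALSE)
  R <- molgraph(sr$atoms, mk_bonds(c(ce, get_edges(r_blk))), loops = sr$loops,
                recompute_rings = FALSE)
  rid <- gml_scalar(rule, "ruleID", optional = TRUE)
  dpo_rule(L, R, stats::setNames(L$atoms$id, as.character(L$atoms$id)),
           rule_id = rid %||% NA_character_)
}

## ---- minimal GML tokenizer/parser -----------------------------------------

gml_tokens <- function(text) {
  text <- paste(text, collapse = "\n")
  pat <- '"[^"]*"|\\[|\\]|[^\\s\\[\\]"]+'
  regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
}

gml_parse <- function(toks) {
  i <- 1L
  parse_list <- function() {
    items <- list()
    while (i <= length(toks) && toks[i] != "]") {
      key <- toks[i]; i <<- i + 1L
      if (i > length(toks)) stop("GML parse error: dangling key ", key)
      val <- toks[i]; i <<- i + 1L
      if (val == "[") {
        children <- parse_list()
        if (i > length(toks) || toks[i] != "]") stop("GML parse error: missing ]")
        i <<- i + 1L
        items[[length(items) + 1L]] <- list(key = key, children = children)
      } else {
        items[[length(items) + 1L]] <- list(key = key,
                                            value = gsub('^"|"$', "", val))
      }
    }
    items
  }
  parse_list()
}

gml_find <- function(items, key) {
  for (it in items) if (it$key == key) return(it)
  NULL
}

gml_scalar <- function(block, key, optional = FALSE) {
  it <- gml_find(block$children, key)
  if (is.null(it)) {
    if (optional) return(NULL)
    stop("GML parse error: missing key ", sQuote(key))
  }
  it$value
}
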