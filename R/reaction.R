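#' Reaction records
#'
#' A reaction record lists the reactant and product compounds of one reaction
#' (with stoichiometric multiplicities) and the RCLASS links: which reaction
#' class connects which reactant/product compound pair.
#'
#' @param reaction_id identifier string.
#' @param reactants,products data.frames with columns `compound_id` and `n`
#'   (multiplicity), or character vectors of compound ids (multiplicity 1).
#' @param rclass_links list of entries `list(rclass_id =, reactant =,
#'   product =)` naming one reactant and one product compound id.
#' @return an object of class `reaction_record`.
#' @export
reaction_record <- function(reaction_id, reactants, products, rclass_links) {
  norm <- function(x) {
    if (is.character(x)) x <- data.frame(compound_id = x, n = 1L,
                                         stringsAsFactors = FALSE)
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if (is.null(x$n)) x$n <- 1L
    x$n <- as.integer(x$n)
    x
  }
  reactants <- norm(reactants); products <- norm(products)
  for (lk in rclass_links) {
    if (!lk$reactant %in% reactants$compound_id ||
        !lk$product %in% products$compound_id) {
      stop("rclass link ", lk$rclass_id,
           " references a compound absent from the reaction sides")
    }
  }
  structure(list(reaction_id = reaction_id, reactants = reactants,
                 products = products, rclass_links = rclass_links),
            class = "reaction_record")
}

#' @export
print.reaction_record <- function(x, ...) {
  side <- function(s) paste(ifelse(s$n > 1, paste0(s$n, " "), ""),
                            s$compound_id, sep = "", collapse = " + ")
  cat(sprintf("<reaction %s: %s => %s; %d RCLASS link(s)>\n", x$reaction_id,
              side(x$reactants), side(x$products), length(x$rclass_links)))
  invisible(x)
}

#' Read reaction records from a JSON config
#'
#' The format is an array of objects with fields `reaction_id`, `reactants`,
#' `products` (arrays of `{compound_id, n}` or plain id strings) and
#' `rclass_links` (array of `{rclass_id, reactant, product}`).
#'
#' @param path file path or JSON text.
#' @return list of [reaction_record()]s.
#' @export
read_reaction_records <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(js, function(r) {
    side <- function(s) {
      if (is.character(s)) return(s)
      data.frame(
        compound_id = vapply(s, function(e)
          if (is.character(e)) e else e$compound_id, character(1)),
        n = vapply(s, function(e)
          if (is.character(e)) 1L else as.integer(e$n %||% 1L), integer(1)),
        stringsAsFactors = FALSE)
    }
    reaction_record(r$reaction_id, side(r$reactants), side(r$products),
                    r$rclass_links)
  })
}

## Instantiate the reactant graph G and product graph H of a reaction as
## disjoint unions of compound instances (one copy per multiplicity).
## Returns list(G, H, gmap, hmap) where the maps are data.frames
## (gid, compound_id, instance, local).
reaction_graphs <- function(record, molecules) {
  instantiate <- function(side) {
    mols <- list(); meta <- list()
    for (i in seq_len(nrow(side))) {
      cid <- side$compound_id[i]
      mol <- molecules[[cid]]
      if (is.null(mol)) stop("no structure for compound ", cid)
      for (k in seq_len(side$n[i])) {
        mols[[length(mols) + 1L]] <- mol
        meta[[length(meta) + 1L]] <- list(cid = cid, instance = k)
      }
    }
    u <- mg_disjoint_union(mols)
    map <- do.call(rbind, lapply(seq_along(mols), function(j) {
      m <- u$maps[[j]]
      data.frame(gid = unname(m), compound_id = meta[[j]]$cid,
                 instance = meta[[j]]$instance,
                 local = as.integer(names(m)), stringsAsFactors = FALSE)
    }))
    list(graph = u$graph, map = map)
  }
  g <- instantiate(record$reactants); h <- instantiate(record$products)
  list(G = g$graph, H = h$graph, gmap = g$map, hmap = h$map)
}

## global ids of one compound instance within a reaction-side map
instance_ids <- function(map, compound_id, instance = 1L) {
  map$gid[map$compound_id == compound_id & map$instance == instance]
}
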