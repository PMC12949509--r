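#' The KEGG atom-type dictionary
#'
#' KEGG classifies every heavy atom into one of 68 neighborhood classes
#' ("atom types"); each class denotes a small rooted *type graph*: the focal
#' atom with its implicit hydrogens and its immediate chemical environment,
#' where unspecified heavy neighbors are wildcard "R-residues". For example,
#' the carbon in R-CH3 has type `C1a` and the carbon in R-CH2-R has type
#' `C1b`. Several codes admit more than one structural interpretation: KEGG
#' itself documents alternatives for five codes (C2y, N1a, N1b, N1c, N2a),
#' and a further twenty codes need alternative readings (ring-fusion
#' variants, charge states, tautomers); `P1a` attains the maximum of four.
#' The dictionary ships as a human-auditable table in
#' `inst/extdata/kegg_atom_types.tsv` with a per-entry source tag.
#'
#' @param path optional path to an alternative table file.
#' @return the parsed dictionary (an object of class `atom_type_table`):
#'   a named list mapping each code to its ordered list of type graphs.
#' @export
atom_type_table <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("table", envir = .atomtype_cache)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "kegg_atom_types.tsv", package = "rdm2dpo")
    if (path == "") path <- file.path("inst", "extdata", "kegg_atom_types.tsv")
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  entries <- list()
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    tg <- parse_type_graph(row$atoms, row$bonds, row$loops, row$code)
    tg$code <- row$code
    tg$alt <- as.integer(row$alt)
    tg$source <- row$source
    tg$undefined <- row$undefined == 1
    tg$note <- row$note
    entries[[row$code]] <- c(entries[[row$code]], list(tg))
  }
  entries <- lapply(entries, function(alts)
    alts[order(vapply(alts, `[[`, integer(1), "alt"))])
  tbl <- structure(entries, class = "atom_type_table")
  assign("table", tbl, envir = .atomtype_cache)
  tbl
}

.atomtype_cache <- new.env(parent = emptyenv())

## one type graph: list(code, focal = 1L, graph = molgraph fragment)
parse_type_graph <- function(atoms_str, bonds_str, loops_str, code) {
  arecs <- strsplit(strsplit(atoms_str, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  atoms <- data.frame(
    id = vapply(arecs, function(r) as.integer(r[1]), integer(1)),
    element = vapply(arecs, function(r) r[2], character(1)),
    hcount = vapply(arecs, function(r)
      if (length(r) >= 3) as.integer(r[3]) else 0L, integer(1)),
    stringsAsFactors = FALSE)
  atoms$wildcard <- atoms$element == "*"
  bonds <- NULL
  if (!is.na(bonds_str) && bonds_str != "-") {
    brecs <- strsplit(strsplit(bonds_str, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    bonds <- data.frame(
      a = vapply(brecs, function(r) as.integer(strsplit(r[1], "-")[[1]][1]),
                 integer(1)),
      b = vapply(brecs, function(r) as.integer(strsplit(r[1], "-")[[1]][2]),
                 integer(1)),
      order = vapply(brecs, function(r)
        c(s = "single", d = "double", t = "triple", a = "aromatic")[[r[2]]],
        character(1)),
      ring = vapply(brecs, function(r) length(r) >= 3 && r[3] == "r",
                    logical(1)),
      stringsAsFactors = FALSE)
  }
  loops <- list()
  if (!is.na(loops_str) && loops_str != "-") {
    for (rec in strsplit(loops_str, ";", fixed = TRUE)[[1]]) {
      kv <- strsplit(rec, "=", fixed = TRUE)[[1]]
      loops[[kv[1]]] <- c(loops[[kv[1]]], kv[2])
    }
  }
  if (atoms$wildcard[atoms$id == 1L]) {
    stop("type graph for ", code, ": focal vertex may not be a wildcard")
  }
  list(focal = 1L,
       graph = molgraph(atoms, bonds, loops = loops, recompute_rings = FALSE))
}

#' Look up the type graph(s) of a KEGG atom-type code
#'
#' @param code one of the 68 atom-type codes, or `"*"` (the absence marker,
#'   which returns an empty list).
#' @param table dictionary from [atom_type_table()].
#' @return ordered list of type graphs (each `list(code, focal, graph, ...)`).
#'   Codes of the non-convertible "undefined atom" class return their entries
#'   with `undefined = TRUE`; downstream stages must refuse them.
#' @export
atom_type_lookup <- function(code, table = atom_type_table()) {
  if (code == "*") return(list())
  alts <- table[[code]]
  if (is.null(alts)) {
    stop("unknown atom-type code ", sQuote(code), "; valid codes: ",
         paste(names(table), collapse = ", "))
  }
  alts
}

#' Summary statistics of the atom-type dictionary
#'
#' @param table dictionary from [atom_type_table()].
#' @return list with `n_codes`, `n_kegg_ambiguous` (codes whose alternatives
#'   KEGG itself documents), `n_extra_ambiguous` (additional ambiguous codes)
#'   and `max_alternatives`.
#' @export
atom_type_stats <- function(table = atom_type_table()) {
  nalts <- vapply(table, length, integer(1))
  documented <- vapply(table, function(alts)
    any(vapply(alts, function(a) a$source == "kegg_documented", logical(1))),
    logical(1))
  list(n_codes = length(table),
       n_kegg_ambiguous = sum(nalts > 1 & documented),
       n_extra_ambiguous = sum(nalts > 1 & !documented),
       max_alternatives = max(nalts))
}
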