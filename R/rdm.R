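#' Parse a KEGG RDM code string
#'
#' An RDM code has three colon-separated sections — the Reaction-center
#' atom, the Difference atoms and the Matched atoms, in this order. Within
#' each section the reactant-side and product-side atom types are separated
#' by a hyphen, multiple D- or M-atoms by `+`, and an asterisk denotes the
#' absence of a non-hydrogen atom. The R-atom and all M-atoms are matched
#' between the two sides by definition, so `*` may only appear on one side
#' of a D-pair.
#'
#' @param code RDM code string, e.g. `"C1a-C1b:*-C1a:C1b-C1b"`.
#' @param rclass_id provenance identifier.
#' @param table atom-type dictionary used to validate the codes.
#' @return an object of class `rdm_code` with fields `r_pair`, `d_pairs`,
#'   `m_pairs`.
#' @export
parse_rdm <- function(code, rclass_id = NA_character_,
                      table = atom_type_table()) {
  sections <- strsplit(code, ":", fixed = TRUE)[[1]]
  if (length(sections) != 3L) {
    stop("RDM parse error in ", sQuote(code), ": expected 3 sections (R:D:M), found ",
         length(sections))
  }
  known <- function(x) x == "*" || x %in% names(table)
  split_section <- function(sec, name, idx) {
    halves <- strsplit(sec, "-", fixed = TRUE)[[1]]
    if (length(halves) != 2L) {
      stop("RDM parse error in section ", idx, " (", name, ") of ",
           sQuote(code), ": expected reactant-product pair separated by '-'")
    }
    lhs <- strsplit(halves[1], "+", fixed = TRUE)[[1]]
    rhs <- strsplit(halves[2], "+", fixed = TRUE)[[1]]
    if (length(lhs) != length(rhs)) {
      stop("RDM parse error in section ", idx, " (", name, ") of ",
           sQuote(code), ": unequal numbers of reactant and product types")
    }
    bad <- c(lhs, rhs)[!vapply(c(lhs, rhs), known, logical(1))]
    if (length(bad)) {
      stop("RDM parse error in section ", idx, " (", name, ") of ",
           sQuote(code), ": unknown atom-type code ",
           paste(sQuote(bad), collapse = ", "))
    }
    Map(c, lhs, rhs, USE.NAMES = FALSE)
  }
  r <- split_section(sections[1], "R", 1L)
  d <- split_section(sections[2], "D", 2L)
  m <- split_section(sections[3], "M", 3L)
  if (length(r) != 1L || any(r[[1]] == "*")) {
    stop("RDM parse error in section 1 (R) of ", sQuote(code),
         ": exactly one R-atom pair required and '*' is not allowed")
  }
  ## a pair that is absent on both sides denotes an empty section
  d <- Filter(function(p) !all(p == "*"), d)
  m <- Filter(function(p) !all(p == "*"), m)
  if (any(vapply(m, function(p) any(p == "*"), logical(1)))) {
    stop("RDM parse error in section 3 (M) of ", sQuote(code),
         ": M-atoms are matched by definition; '*' is not allowed")
  }
  structure(list(r_pair = r[[1]], d_pairs = d, m_pairs = m,
                 rclass_id = rclass_id, code_string = code),
            class = "rdm_code")
}

#' @export
print.rdm_code <- function(x, ...) {
  cat(sprintf("<rdm_code %s: R %s-%s, %d D pair(s), %d M pair(s)>\n",
              if (is.na(x$rclass_id)) "" else x$rclass_id,
              x$r_pair[1], x$r_pair[2],
              length(x$d_pairs), length(x$m_pairs)))
  invisible(x)
}

#' Expand an RDM code into its reactant and product trees
#'
#' Each side of an RDM code corresponds to a depth-1 tree rooted at the
#' R-atom, with one child per D- or M-atom (all of which are by definition
#' adjacent to the R-atom). Nodes absent on a side (`*`) are omitted from
#' that side's tree. Node ids are shared between the two trees, which
#' records the positional correspondence of R- and M-atoms.
#'
#' @param code an [parse_rdm()] result.
#' @return list with elements `reactant` and `product`, each a data.frame
#'   with columns `node`, `role` (`"R"`, `"D"`, `"M"`) and `code`.
#' @export
build_trees <- function(code) {
  nodes <- data.frame(node = 1L, role = "R",
                      reactant = code$r_pair[1], product = code$r_pair[2],
                      stringsAsFactors = FALSE)
  nid <- 1L
  for (p in code$d_pairs) {
    nid <- nid + 1L
    nodes <- rbind(nodes, data.frame(node = nid, role = "D",
                                     reactant = p[1], product = p[2],
                                     stringsAsFactors = FALSE))
  }
  for (p in code$m_pairs) {
    nid <- nid + 1L
    nodes <- rbind(nodes, data.frame(node = nid, role = "M",
                                     reactant = p[1], product = p[2],
                                     stringsAsFactors = FALSE))
  }
  side <- function(col) {
    df <- nodes[nodes[[col]] != "*", c("node", "role")]
    df$code <- nodes[[col]][nodes[[col]] != "*"]
    rownames(df) <- NULL
    df
  }
  list(reactant = side("reactant"), product = side("product"))
}
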