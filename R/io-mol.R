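#' Read an MDL MOL (V2000) block into a molecule graph
#'
#' Charges (`M  CHG`) and radicals (`M  RAD`) are mapped onto loop
#' annotations, implicit hydrogen counts are computed from standard valences,
#' and ring flags are derived from cycle membership. Element symbols that are
#' not recognised pass through verbatim (with zero implicit hydrogens).
#' Structures containing abbreviated "R"-residue pseudo-atoms are returned
#' with the `nonconvertible` field set: they cannot be used for rule
#' construction.
#'
#' @param text a character scalar (or vector of lines) with one V2000 block.
#' @param compound_id identifier to attach; defaults to the MOL title line.
#' @return a [molgraph()].
#' @export
read_mol <- function(text, compound_id = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 4L) stop("MOL parse error: fewer than 4 header lines")
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) {
    stop("MOL parse error in counts line (line 4): ", sQuote(counts))
  }
  if (length(lines) < 4L + natoms + nbonds) {
    stop("MOL parse error: file truncated before bond block")
  }
  elements <- character(natoms)
  for (i in seq_len(natoms)) {
    ln <- lines[4L + i]
    el <- trimws(substr(ln, 32, 34))
    if (el == "") {  # whitespace-separated fallback
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(tok) < 4L) {
        stop("MOL parse error in atom block (line ", 4L + i, "): ", sQuote(ln))
      }
      el <- tok[4]
    }
    elements[i] <- el
  }
  bonds <- data.frame(a = integer(nbonds), b = integer(nbonds),
                      order = character(nbonds), stringsAsFactors = FALSE)
  for (i in seq_len(nbonds)) {
    ln <- lines[4L + natoms + i]
    a <- suppressWarnings(as.integer(substr(ln, 1, 3)))
    b <- suppressWarnings(as.integer(substr(ln, 4, 6)))
    o <- suppressWarnings(as.integer(substr(ln, 7, 9)))
    if (any(is.na(c(a, b, o)))) {
      tok <- suppressWarnings(as.integer(strsplit(trimws(ln), "\\s+")[[1]]))
      if (length(tok) < 3L || any(is.na(tok[1:3]))) {
        stop("MOL parse error in bond block (line ", 4L + natoms + i, "): ",
             sQuote(ln))
      }
      a <- tok[1]; b <- tok[2]; o <- tok[3]
    }
    bonds$a[i] <- a; bonds$b[i] <- b
    bonds$order[i] <- switch(as.character(o), "1" = "single", "2" = "double",
                             "3" = "triple", "4" = "aromatic",
                             stop("MOL parse error: unsupported bond order ", o,
                                  " (line ", 4L + natoms + i, ")"))
  }
  charges <- integer(natoms); radicals <- integer(natoms)
  for (ln in lines[-seq_len(4L + natoms + nbonds)]) {
    if (grepl("^M  (CHG|RAD)", ln)) {
      tok <- strsplit(trimws(sub("^M  (CHG|RAD)", "", ln)), "\\s+")[[1]]
      vals <- suppressWarnings(as.integer(tok))
      n <- vals[1]
      for (k in seq_len(n)) {
        aid <- vals[2 * k]; v <- vals[2 * k + 1]
        if (grepl("CHG", ln)) charges[aid] <- v else radicals[aid] <- v
      }
    }
    if (grepl("^M  END", ln)) break
  }
  loops <- list()
  for (i in seq_len(natoms)) {
    ann <- character()
    if (charges[i] != 0) ann <- c(ann, paste0("charge:", sprintf("%+d", charges[i])))
    if (radicals[i] != 0) ann <- c(ann, paste0("radical:", radicals[i]))
    if (length(ann)) loops[[as.character(i)]] <- ann
  }
  hcount <- vapply(seq_len(natoms), function(i) {
    implicit_h(elements[i], bond_order_sum(bonds, i), charges[i])
  }, integer(1))
  mol <- molgraph(
    data.frame(id = seq_len(natoms), element = elements, hcount = hcount,
               stringsAsFactors = FALSE),
    bonds, compound_id = compound_id %||%
      (if (nzchar(trimws(lines[1]))) trimws(lines[1]) else NA_character_),
    loops = loops)
  if (any(elements %in% c("R", "R#", "*", "A", "Q"))) {
    mol$nonconvertible <- "abbreviated residue (R pseudo-atom) in structure"
  }
  mol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bond_order_sum <- function(bonds, i) {
  if (!nrow(bonds)) return(0)
  k <- bonds$a == i | bonds$b == i
  sum(c(single = 1, double = 2, triple = 3, aromatic = 1.5)[bonds$order[k]])
}

## allowed valence lists per element; implicit H fills to the smallest
## allowed valence that is >= the (charge-adjusted) bond order sum
VALENCES <- list(C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
                 F = 1, Cl = 1, Br = 1, I = 1, B = 3, H = 1, Si = 4)

implicit_h <- function(element, order_sum, charge = 0) {
  vals <- VALENCES[[element]]
  if (is.null(vals)) return(0L)
  adj <- if (element %in% c("N", "P", "O", "S")) charge else -abs(charge)
  vals <- vals + adj
  order_sum <- ceiling(order_sum)
  for (v in vals) if (v >= order_sum) return(as.integer(v - order_sum))
  0L
}

#' Read a KEGG KCF block into a molecule graph
#'
#' As [read_mol()], with the KCF atom-type label of every atom retained as an
#' advisory annotation in the `kcf_type` column.
#'
#' @param text a character scalar (or vector of lines) with one KCF entry.
#' @return a [molgraph()].
#' @export
read_kcf <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  section <- ""
  entry <- NA_character_
  atom_lines <- character(); bond_lines <- character()
  for (ln in lines) {
    key <- trimws(substr(ln, 1, 12))
    if (nzchar(key)) section <- key
    body <- trimws(substr(ln, 13, nchar(ln)))
    if (section == "ENTRY" && nzchar(key)) {
      entry <- strsplit(body, "\\s+")[[1]][1]
    } else if (section == "ATOM" && !nzchar(key)) {
      atom_lines <- c(atom_lines, body)
    } else if (section == "BOND" && !nzchar(key)) {
      bond_lines <- c(bond_lines, body)
    }
  }
  if (!any(grepl("^ATOM", lines))) stop("KCF parse error: missing ATOM section")
  if (!any(grepl("^BOND", lines))) stop("KCF parse error: missing BOND section")
  natoms <- length(atom_lines)
  atoms <- data.frame(id = integer(natoms), element = character(natoms),
                      hcount = 0L, kcf_type = character(natoms),
                      stringsAsFactors = FALSE)
  for (i in seq_len(natoms)) {
    tok <- strsplit(atom_lines[i], "\\s+")[[1]]
    if (length(tok) < 3L) stop("KCF parse error in ATOM section: ",
                               sQuote(atom_lines[i]))
    atoms$id[i] <- as.integer(tok[1])
    atoms$kcf_type[i] <- tok[2]
    atoms$element[i] <- tok[3]
  }
  bonds <- data.frame(a = integer(), b = integer(), order = character(),
                      stringsAsFactors = FALSE)
  for (ln in bond_lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 4L) stop("KCF parse error in BOND section: ", sQuote(ln))
    bonds <- rbind(bonds, data.frame(
      a = as.integer(tok[2]), b = as.integer(tok[3]),
      order = switch(tok[4], "1" = "single", "2" = "double", "3" = "triple",
                     "4" = "aromatic",
                     stop("KCF parse error: unsupported bond order ", tok[4])),
      stringsAsFactors = FALSE))
  }
  atoms$hcount <- vapply(atoms$id, function(i) {
    implicit_h(atoms$element[atoms$id == i], bond_order_sum(bonds, i))
  }, integer(1))
  molgraph(atoms, bonds, compound_id = entry)
}
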