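# SMILES subset parser producing annotated molecular graphs.
#
# Covers what reaction datasets in this domain use: organic-subset atoms
# (B C N O P S F Cl Br I and aromatic b c n o s p), bracket atoms with
# isotope / chirality (@, @@) / explicit H count / charge / atom-map number,
# bond symbols - = # : / \ (directional bonds are read as single bonds; the
# matching pipeline is stereochemistry-unaware by design), branches, ring
# closures including %nn, and dot-separated components.  Bond orders are kept
# for hydrogen-count and hybridization bookkeeping; graph matching itself
# ignores them.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)

#' Parse a single-molecule SMILES string
#'
#' @param s SMILES string (one molecule; no dots).
#' @return object of class `smigraph`: `atoms` data.frame (element, aromatic,
#'   charge, n_h, map, chirality, bracket) and `bonds` data.frame (i, j,
#'   order; aromatic bonds have order 1.5).  `n_h` counts implicit hydrogens
#'   (valence rule) for organic-subset atoms and the bracket H count otherwise.
#' @export
parse_smiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  chars <- strsplit(s, "")[[1]]
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NA_real_  # bond order carried by the last bond symbol
  ring_open <- list()  # closure digit -> list(atom, order)

  add_atom <- function(element, aromatic, charge = 0L, n_h = NA_integer_,
                       map = NA_integer_, chirality = 0L, bracket = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, charge = charge, n_h = n_h,
      map = map, chirality = chirality, bracket = bracket)
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord)) {
        ord <- if (aromatic && atoms[[prev]]$aromatic) 1.5 else 1
      }
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx, order = ord)
    }
    prev <<- idx
    pending <<- NA_real_
    idx
  }

  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("invalid SMILES: unterminated bracket atom in ", s)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parse_bracket_atom(body, s)
      add_atom(at$element, at$aromatic, at$charge, at$n_h, at$map,
               at$chirality, bracket = TRUE)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), aromatic = FALSE)
      i <- i + 2L
    } else if (ch %in% .ORGANIC_SUBSET) {
      add_atom(ch, aromatic = FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), aromatic = TRUE)
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- 1; i <- i + 1L
    } else if (ch == "=") {
      pending <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending <- 3; i <- i + 1L
    } else if (ch == ":") {
      pending <- 1.5; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("invalid SMILES: branch before any atom in ", s)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("invalid SMILES: unmatched ')' in ", s)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stop("invalid SMILES: truncated %nn closure in ", s)
        lab <- paste(chars[(i + 1L):(i + 2L)], collapse = "")
        i <- i + 3L
      } else {
        lab <- ch; i <- i + 1L
      }
      if (is.na(prev)) stop("invalid SMILES: ring closure before any atom in ", s)
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        ord <- if (!is.na(pending)) pending else if (!is.na(op$order)) op$order
               else if (atoms[[prev]]$aromatic && atoms[[op$atom]]$aromatic) 1.5 else 1
        bonds[[length(bonds) + 1L]] <- list(i = op$atom, j = prev, order = ord)
        ring_open[[lab]] <- NULL
      } else {
        ring_open[[lab]] <- list(atom = prev, order = pending)
      }
      pending <- NA_real_
    } else if (ch == ".") {
      stop("parse_smiles handles one molecule; split components on '.' first")
    } else {
      stop("invalid SMILES: unexpected character '", ch, "' in ", s)
    }
  }
  if (length(ring_open)) stop("invalid SMILES: unclosed ring bond in ", s)
  if (length(stack)) stop("invalid SMILES: unmatched '(' in ", s)
  if (!length(atoms)) stop("invalid SMILES: no atoms in ", s)

  at <- do.call(rbind, lapply(atoms, function(a) {
    data.frame(element = a$element, aromatic = a$aromatic, charge = a$charge,
               n_h = a$n_h, map = a$map, chirality = a$chirality,
               bracket = a$bracket)
  }))
  bd <- if (length(bonds)) {
    do.call(rbind, lapply(bonds, function(b) {
      data.frame(i = b$i, j = b$j, order = b$order)
    }))
  } else {
    data.frame(i = integer(0), j = integer(0), order = numeric(0))
  }
  # implicit hydrogens for organic-subset atoms (bracket atoms are explicit)
  for (k in seq_len(nrow(at))) {
    if (!at$bracket[k]) {
      ord_sum <- sum(bd$order[bd$i == k | bd$j == k])
      if (at$aromatic[k]) ord_sum <- ceiling(ord_sum)
      val <- .DEFAULT_VALENCE[[at$element[k]]]
      at$n_h[k] <- max(0L, as.integer(val - ord_sum))
    } else if (is.na(at$n_h[k])) {
      at$n_h[k] <- 0L
    }
  }
  structure(list(atoms = at, bonds = bd, smiles = s), class = "smigraph")
}

.parse_bracket_atom <- function(body, s) {
  rest <- body
  grab <- function(pattern) {
    m <- regmatches(rest, regexpr(pattern, rest))
    if (length(m) && nzchar(m)) {
      rest <<- sub(pattern, "", rest)
      m
    } else {
      ""
    }
  }
  grab("^[0-9]+")  # isotope label: accepted and ignored
  sym <- grab("^([A-Z][a-z]?|[bcnops]|\\*)")
  if (!nzchar(sym)) stop("invalid SMILES: bad bracket atom [", body, "] in ", s)
  if (sym == "*") stop("wildcard atoms are not supported: [", body, "]")
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  element <- if (aromatic) toupper(sym) else sym
  chi <- grab("^@{1,2}")
  chirality <- if (nzchar(chi)) 1L else 0L
  hh <- grab("^H[0-9]*")
  n_h <- if (!nzchar(hh)) 0L else if (hh == "H") 1L else as.integer(sub("H", "", hh))
  chg <- grab("^(\\+[0-9]+|-[0-9]+|\\++|-+)")
  charge <- if (!nzchar(chg)) 0L else if (grepl("[0-9]", chg)) {
    as.integer(chg)
  } else {
    (if (substr(chg, 1, 1) == "+") 1L else -1L) * nchar(chg)
  }
  mp <- grab("^:[0-9]+")
  map <- if (nzchar(mp)) as.integer(sub(":", "", mp)) else NA_integer_
  if (nzchar(rest)) stop("invalid SMILES: trailing '", rest, "' in [", body, "]")
  list(element = element, aromatic = aromatic, charge = charge, n_h = n_h,
       map = map, chirality = chirality)
}

#' Parse an atom-mapped reaction SMILES
#'
#' Splits `reactants>>products` on top-level dots, parses each molecule, and
#' checks atom-map consistency.  Map numbers are optional (regime "None");
#' when present they must be unique within each side.
#'
#' @param rxn reaction SMILES string, e.g. `"[C:1][C:2].[O:3]>>[C:1][C:2][O:3]"`.
#' @return list with `reactants` and `products` (lists of [parse_smiles()]
#'   graphs in input order) and `mapped` (TRUE if any atom carries a map).
#' @export
parse_mapped_reaction_smiles <- function(rxn) {
  parts <- strsplit(rxn, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("reaction SMILES must contain exactly one '>>': ", rxn)
  }
  parse_side <- function(side, label) {
    mols <- lapply(strsplit(side, ".", fixed = TRUE)[[1]], parse_smiles)
    maps <- unlist(lapply(mols, function(g) g$atoms$map))
    maps <- maps[!is.na(maps)]
    if (anyDuplicated(maps)) {
      stop("duplicate atom-map number on the ", label, " side of ", rxn)
    }
    mols
  }
  reactants <- parse_side(parts[1], "reactant")
  products <- parse_side(parts[2], "product")
  any_map <- function(mols) any(!is.na(unlist(lapply(mols, function(g) g$atoms$map))))
  list(reactants = reactants, products = products,
       mapped = any_map(reactants) || any_map(products))
}
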