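# Labelled molecular graphs, covalent-radius bond perception, SMILES-xyz
# matching by graph isomorphism, and reaction-type signatures.

#' Covalent radii table
#'
#' Single-bond covalent radii in angstroms (Cordero-style consensus values)
#' for the elements the package handles.
#'
#' @return named numeric vector, element symbol -> radius.
#' @export
covalent_radii <- function() {
  c(H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
    O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21,
    Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03,
    Ca = 1.76, Br = 1.20, I = 1.39)
}

#' Construct a labelled graph
#'
#' Node labels are element symbols; adjacency records bond presence only,
#' without orders.  Edges are stored once with `i < j`; self-loops are
#' rejected.
#'
#' @param labels character vector of node labels.
#' @param edges two-column integer matrix of undirected edges (may have 0 rows).
#' @return object of class `labeled_graph`.
#' @export
labeled_graph <- function(labels, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    if (any(edges < 1L) || any(edges > length(labels))) stop("edge index out of range")
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(labels = as.character(labels), edges = edges),
            class = "labeled_graph")
}

lg_n <- function(g) length(g$labels)

lg_degree <- function(g) {
  tabulate(c(g$edges[, 1], g$edges[, 2]), nbins = lg_n(g))
}

lg_adjacency <- function(g) {
  n <- lg_n(g)
  A <- matrix(0L, n, n)
  if (nrow(g$edges)) {
    A[g$edges] <- 1L
    A[g$edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  A
}

lg_igraph <- function(g) {
  igraph::graph_from_edgelist(g$edges, directed = FALSE) |>
    (\(x) igraph::add_vertices(x, max(0L, lg_n(g) - igraph::vcount(x))))()
}

#' Molecular graph from 3D coordinates via covalent radii
#'
#' Atoms a and b are bonded iff their distance does not exceed
#' `radii[a] + radii[b] + tolerance`.
#'
#' @param mol a [molecule3d()].
#' @param radii named radius table in angstroms, see [covalent_radii()].
#' @param tolerance additive slack in angstroms.
#' @return a [labeled_graph()].
#' @export
graph_from_xyz <- function(mol, radii = covalent_radii(), tolerance = 0.4) {
  missing <- setdiff(mol$elements, names(radii))
  if (length(missing)) {
    stop("no covalent radius for element(s): ", paste(missing, collapse = ", "))
  }
  n <- n_atoms(mol)
  r <- radii[mol$elements]
  D <- as.matrix(stats::dist(mol$coords))
  thr <- outer(r, r, "+") + tolerance
  A <- D <= thr
  diag(A) <- FALSE
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  labeled_graph(mol$elements, idx)
}

#' Labelled graph of the explicit atoms of a parsed SMILES
#'
#' @param g an object from [parse_smiles()].
#' @param drop_h drop explicit hydrogen nodes (their counts are folded into
#'   the annotation table, not the matching graph).
#' @return a [labeled_graph()].
#' @export
labeled_graph_from_smiles <- function(g, drop_h = FALSE) {
  keep <- if (drop_h) which(g$atoms$element != "H") else seq_len(nrow(g$atoms))
  remap <- match(seq_len(nrow(g$atoms)), keep)
  e <- g$bonds[g$bonds$i %in% keep & g$bonds$j %in% keep, , drop = FALSE]
  labeled_graph(g$atoms$element[keep], cbind(remap[e$i], remap[e$j]))
}

#' Match two labelled graphs by isomorphism
#'
#' Finds a bijection `perm` such that reindexing `g_xyz` by `perm` reproduces
#' `g_smiles` exactly: `g_xyz$labels[perm] == g_smiles$labels` and the
#' permuted adjacency is identical.  When several isomorphisms exist
#' (symmetric molecules) the first found under the deterministic VF2 ordering
#' is returned, so runs are reproducible.  The procedure is unaware of
#' chirality and double-bond stereochemistry.
#'
#' @param g_xyz,g_smiles two [labeled_graph()]s with equal atom counts and
#'   element multisets.
#' @param extra_colors1,extra_colors2 optional integer refinements added to
#'   the element colors (e.g. attached-hydrogen counts).
#' @return integer vector: `perm[k]` is the `g_xyz` node matched to
#'   `g_smiles` node `k`.
#' @export
match_smiles_to_xyz <- function(g_xyz, g_smiles,
                                extra_colors1 = NULL, extra_colors2 = NULL) {
  if (lg_n(g_xyz) != lg_n(g_smiles)) {
    stop("SMILES/xyz mismatch: different atom counts (",
         lg_n(g_xyz), " vs ", lg_n(g_smiles), ")")
  }
  if (!identical(sort(g_xyz$labels), sort(g_smiles$labels))) {
    stop("SMILES/xyz mismatch: different element multisets")
  }
  all_labels <- sort(unique(c(g_xyz$labels, g_smiles$labels)))
  col1 <- match(g_xyz$labels, all_labels)
  col2 <- match(g_smiles$labels, all_labels)
  if (!is.null(extra_colors1)) {
    k <- max(c(extra_colors1, extra_colors2)) + 1L
    col1 <- col1 * k + as.integer(extra_colors1)
    col2 <- col2 * k + as.integer(extra_colors2)
  }
  iso <- igraph::graph.get.isomorphisms.vf2(
    lg_igraph(g_xyz), lg_igraph(g_smiles),
    vertex.color1 = col1, vertex.color2 = col2)
  if (!length(iso)) stop("SMILES/xyz mismatch: no labelled isomorphism exists")
  perm <- as.integer(iso[[1]])
  if (!.perm_valid(g_xyz, g_smiles, perm)) perm <- order(perm)
  if (!.perm_valid(g_xyz, g_smiles, perm)) {
    stop("internal error: VF2 mapping failed verification")
  }
  perm
}

# perm[k] = xyz node matched to smiles node k; exact check of labels+adjacency
.perm_valid <- function(g_xyz, g_smiles, perm) {
  identical(g_xyz$labels[perm], g_smiles$labels) &&
    identical(lg_adjacency(g_xyz)[perm, perm, drop = FALSE],
              lg_adjacency(g_smiles))
}

# ---- reaction-type signatures ----------------------------------------------

#' Reaction-type signature from mapped reaction graphs
#'
#' Compares the connectivity matrices of reactants and products over mapped
#' atoms, ignoring bond orders.  A bond present only in the products
#' contributes a formed label `+X-Y`; present only in the reactants, a broken
#' label `-X-Y`; element pairs are ordered alphabetically within a label.
#' The canonical string lists formed labels first, each group sorted
#' lexicographically, comma-joined (e.g. `+C-H,-C-C,-C-H`).
#'
#' @param reactants,products lists of [parse_smiles()] graphs whose atoms
#'   carry map numbers.  Unmapped hydrogens are ignored (hydrogens are not
#'   always mapped); any other unmapped atom is an error.
#' @return object of class `rxn_signature` with fields `formed`, `broken`
#'   (character multisets) and `string` (canonical form).
#' @export
reaction_type_signature <- function(reactants, products) {
  side_bonds <- function(mols, side) {
    elem <- character(0); bonds <- character(0)
    pair_list <- list()
    for (g in mols) {
      unmapped <- is.na(g$atoms$map)
      if (any(unmapped & g$atoms$element != "H")) {
        stop("unmapped non-hydrogen atom on the ", side, " side")
      }
      elem[as.character(g$atoms$map[!unmapped])] <- g$atoms$element[!unmapped]
      b <- g$bonds
      mi <- g$atoms$map[b$i]; mj <- g$atoms$map[b$j]
      ok <- !is.na(mi) & !is.na(mj)
      if (any(ok)) {
        pair_list[[length(pair_list) + 1L]] <-
          paste(pmin(mi[ok], mj[ok]), pmax(mi[ok], mj[ok]), sep = "~")
      }
    }
    list(elem = elem, bonds = unlist(pair_list))
  }
  r <- side_bonds(reactants, "reactant")
  p <- side_bonds(products, "product")
  label <- function(pairs, elem) {
    if (!length(pairs)) return(character(0))
    parts <- strsplit(pairs, "~", fixed = TRUE)
    vapply(parts, function(ij) {
      ab <- sort(c(elem[[ij[1]]], elem[[ij[2]]]))
      paste0(ab[1], "-", ab[2])
    }, "")
  }
  # multiset difference on map-number pairs
  formed_pairs <- .multiset_diff(p$bonds, r$bonds)
  broken_pairs <- .multiset_diff(r$bonds, p$bonds)
  formed <- sort(label(formed_pairs, p$elem))
  broken <- sort(label(broken_pairs, r$elem))
  string <- paste(c(if (length(formed)) paste0("+", formed),
                    if (length(broken)) paste0("-", broken)), collapse = ",")
  structure(list(formed = formed, broken = broken, string = string),
            class = "rxn_signature")
}

.multiset_diff <- function(a, b) {
  for (x in b) {
    hit <- match(x, a)
    if (!is.na(hit)) a <- a[-hit]
  }
  a
}

#' @export
print.rxn_signature <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @param x an `rxn_signature`.
#' @param dash `"ascii"` for `C-H` labels or `"endash"` for the typographic
#'   display form.
#' @param ... unused.
#' @rdname reaction_type_signature
#' @export
format.rxn_signature <- function(x, dash = c("ascii", "endash"), ...) {
  dash <- match.arg(dash)
  s <- if (nzchar(x$string)) x$string else "(no bond changes)"
  if (dash == "endash") s <- gsub("-(?=[A-Z])", "–", s, perl = TRUE)
  s
}

# ---- ring perception and atom annotations -----------------------------------

# Small-ring info from an approximate minimum cycle basis: for every non-tree
# edge, the shortest cycle through it.  Good enough for ring-membership
# descriptors on molecule-sized graphs.
ring_info <- function(g) {
  n <- lg_n(g)
  out <- list(n_rings = integer(n),
              flags = matrix(0L, n, 5, dimnames = list(NULL, paste0("ring", 3:7))),
              in_ring = integer(n))
  if (!nrow(g$edges)) return(out)
  ig <- lg_igraph(g)
  mst <- igraph::mst(ig)
  tree_keys <- apply(igraph::as_edgelist(mst), 1, function(e)
    paste(sort(as.integer(e)), collapse = "~"))
  all_e <- igraph::as_edgelist(ig)
  keys <- apply(all_e, 1, function(e) paste(sort(as.integer(e)), collapse = "~"))
  extra <- which(!(keys %in% tree_keys) | duplicated(keys))
  seen <- character(0)
  for (k in extra) {
    u <- as.integer(all_e[k, 1]); v <- as.integer(all_e[k, 2])
    g2 <- igraph::delete_edges(ig, igraph::E(ig)[k])
    sp <- suppressWarnings(igraph::shortest_paths(g2, u, v)$vpath[[1]])
    if (!length(sp)) next
    cyc <- sort(as.integer(sp))
    key <- paste(cyc, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    size <- length(cyc)
    out$n_rings[cyc] <- out$n_rings[cyc] + 1L
    out$in_ring[cyc] <- 1L
    if (size >= 3 && size <= 7) out$flags[cyc, size - 2L] <- 1L
  }
  out
}

#' Per-atom annotation table from a parsed SMILES
#'
#' Produces the descriptor source consumed by [initial_node_features()]:
#' element, atomic number, chirality class, heavy-atom degree, ring counts
#' and size flags, implicit valence, formal charge, total attached hydrogens,
#' unpaired electrons, hybridization class (1 sp, 2 sp2, 3 sp3, 0 other) and
#' aromaticity.
#'
#' @param g a [parse_smiles()] graph.
#' @return data.frame with one row per explicit non-hydrogen atom... one row
#'   per explicit atom; hydrogen rows are retained so callers can exclude
#'   them consistently.
#' @export
annotate_smiles <- function(g) {
  n <- nrow(g$atoms)
  lgh <- labeled_graph(g$atoms$element,
                       cbind(g$bonds$i, g$bonds$j))
  ri <- ring_info(lgh)
  is_h_nbr <- function(k) {
    nb <- c(g$bonds$j[g$bonds$i == k], g$bonds$i[g$bonds$j == k])
    sum(g$atoms$element[nb] == "H")
  }
  deg_all <- lg_degree(lgh)
  hyb <- integer(n)
  for (k in seq_len(n)) {
    b <- g$bonds[g$bonds$i == k | g$bonds$j == k, ]
    if (g$atoms$aromatic[k] || any(b$order == 1.5)) hyb[k] <- 2L
    else if (any(b$order == 3) || sum(b$order == 2) >= 2) hyb[k] <- 1L
    else if (any(b$order == 2)) hyb[k] <- 2L
    else hyb[k] <- 3L
  }
  expl_h <- vapply(seq_len(n), is_h_nbr, 0L)
  data.frame(
    element = g$atoms$element,
    atomic_number = unname(ELEMENT_NUMBERS[g$atoms$element]),
    chirality = g$atoms$chirality,
    degree_heavy = deg_all - expl_h,
    degree_all = deg_all,
    n_rings = ri$n_rings,
    implicit_valence = ifelse(g$atoms$bracket, 0L, g$atoms$n_h),
    formal_charge = g$atoms$charge,
    n_h = g$atoms$n_h + expl_h,
    n_radical = 0L,
    hybridization = hyb,
    aromatic = as.integer(g$atoms$aromatic),
    ring3 = ri$flags[, 1], ring4 = ri$flags[, 2], ring5 = ri$flags[, 3],
    ring6 = ri$flags[, 4], ring7 = ri$flags[, 5],
    in_ring = ri$in_ring,
    map = g$atoms$map
  )
}

#' Per-atom annotation table from geometry alone
#'
#' Fallback descriptor source when no SMILES is available (e.g. synthetic
#' point-cloud molecules): bonds are perceived from covalent radii;
#' chirality, charge, aromaticity and hybridization are set to their
#' unspecified/neutral classes.
#'
#' @param mol a [molecule3d()].
#' @param radii,tolerance bond-perception parameters, see [graph_from_xyz()].
#' @return data.frame with the same columns as [annotate_smiles()].
#' @export
annotate_geometry <- function(mol, radii = covalent_radii(), tolerance = 0.4) {
  g <- graph_from_xyz(mol, radii, tolerance)
  ri <- ring_info(g)
  deg_all <- lg_degree(g)
  n <- lg_n(g)
  n_h <- integer(n)
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      i <- g$edges[r, 1]; j <- g$edges[r, 2]
      if (mol$elements[j] == "H") n_h[i] <- n_h[i] + 1L
      if (mol$elements[i] == "H") n_h[j] <- n_h[j] + 1L
    }
  }
  data.frame(
    element = mol$elements,
    atomic_number = unname(ELEMENT_NUMBERS[mol$elements]),
    chirality = 0L,
    degree_heavy = deg_all - n_h,
    degree_all = deg_all,
    n_rings = ri$n_rings,
    implicit_valence = 0L,
    formal_charge = 0L,
    n_h = n_h,
    n_radical = 0L,
    hybridization = 0L,
    aromatic = 0L,
    ring3 = ri$flags[, 1], ring4 = ri$flags[, 2], ring5 = ri$flags[, 3],
    ring6 = ri$flags[, 4], ring7 = ri$flags[, 5],
    in_ring = ri$in_ring,
    map = if (is.null(mol$map_numbers)) NA_integer_ else mol$map_numbers
  )
}
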