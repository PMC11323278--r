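# Distance-based molecular graph with initial node descriptors, radial edge
# features, and spherical-harmonic filters.

#' Graph construction configuration
#'
#' @param r_max radial cutoff in angstroms (hyperparameter space 2.5/5/10).
#' @param n_neigh maximum number of neighbors per atom before symmetrization.
#' @param n_g number of radial edge features.
#' @param l_max highest spherical-harmonic filter degree: 0 for the invariant
#'   variant, 2 for the equivariant one.
#' @param exclude_h drop hydrogen atoms as graph nodes; hydrogen information
#'   then survives only through the attached-hydrogen count descriptor of the
#'   heavy atoms.
#' @return object of class `graph_config`.
#' @export
graph_config <- function(r_max = 2.5, n_neigh = 25L, n_g = 16L,
                         l_max = 0L, exclude_h = TRUE) {
  stopifnot(r_max > 0, n_neigh >= 1, n_g >= 1, l_max %in% 0:2)
  structure(list(r_max = r_max, n_neigh = as.integer(n_neigh),
                 n_g = as.integer(n_g), l_max = as.integer(l_max),
                 exclude_h = isTRUE(exclude_h)),
            class = "graph_config")
}

#' Radius graph with neighbor cap
#'
#' Directed edges run from every atom within `r_max` to the receiving atom,
#' truncated to the `n_neigh` nearest (ties broken by atom index), then
#' symmetrized by union with the reversed edge set so edge (a,b) is present
#' iff (b,a) is.
#'
#' @param coords numeric matrix (n x 3).
#' @param r_max cutoff in angstroms.
#' @param n_neigh neighbor cap.
#' @return list with `src`, `dst` integer vectors (messages flow src -> dst)
#'   and `dist` edge lengths.
#' @export
build_radius_graph <- function(coords, r_max, n_neigh = Inf) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  stopifnot(n >= 1, all(is.finite(coords)))
  if (n == 1L) return(list(src = integer(0), dst = integer(0), dist = numeric(0)))
  D <- as.matrix(stats::dist(coords))
  if (any(D[upper.tri(D)] < 1e-8)) stop("coincident atoms in radius graph")
  pairs <- matrix(0L, 0, 2)
  for (a in seq_len(n)) {
    nb <- setdiff(which(D[a, ] <= r_max), a)
    if (length(nb) > n_neigh) {
      nb <- nb[order(D[a, nb], nb)][seq_len(n_neigh)]
    }
    if (length(nb)) pairs <- rbind(pairs, cbind(nb, a))
  }
  # symmetrize: union with reversal
  if (nrow(pairs)) {
    pairs <- unique(rbind(pairs, pairs[, c(2, 1), drop = FALSE]))
    pairs <- pairs[order(pairs[, 2], pairs[, 1]), , drop = FALSE]
  }
  list(src = pairs[, 1], dst = pairs[, 2],
       dist = D[pairs])
}

#' Radial edge features
#'
#' Smooth basis expansion of an interatomic distance: `n_g` Gaussians with
#' centers uniformly spaced on `[0, r_max]` and width equal to the spacing,
#' multiplied by the smooth [cutoff_envelope()] so features (and hence all
#' downstream messages) vanish continuously as an atom crosses the cutoff.
#' Placing the envelope on the basis keeps it upstream of the learned
#' radial filters, which can re-amplify attenuated shells during training.
#' Symmetric by construction (a function of the distance only).
#'
#' @param d numeric vector of distances, each in `(0, r_max]`.
#' @param cfg a [graph_config()].
#' @return matrix `length(d)` x `n_g`.
#' @export
radial_edge_features <- function(d, cfg) {
  stopifnot(inherits(cfg, "graph_config"))
  if (any(d <= 0) || any(d > cfg$r_max + 1e-9)) {
    stop("edge length outside (0, r_max]: edges beyond the cutoff must not exist")
  }
  centers <- seq(0, cfg$r_max, length.out = cfg$n_g)
  width <- if (cfg$n_g > 1) centers[2] - centers[1] else cfg$r_max
  exp(-outer(d, centers, "-")^2 / (2 * width^2)) *
    cutoff_envelope(d, cfg$r_max)
}

#' Smooth cutoff envelope
#'
#' Cosine envelope `0.5 (cos(pi d / r_max) + 1)`: 1 at zero distance,
#' vanishing smoothly at the cutoff.  Multiplies the radial basis so
#' messages switch off continuously at `r_max`.
#'
#' @param d numeric vector of distances.
#' @param r_max cutoff in angstroms.
#' @return numeric vector of factors in `[0, 1]`.
#' @export
cutoff_envelope <- function(d, r_max) {
  0.5 * (cos(pi * pmin(d, r_max) / r_max) + 1)
}

#' Spherical-harmonic filters for edge direction vectors
#'
#' @param rel_vec matrix (E x 3) of relative position vectors (dst - src).
#' @param l_max highest degree (0, 1 or 2).
#' @return matrix E x (l_max+1)^2; see [sph_harmonics()] for the basis.
#' @export
sph_filters <- function(rel_vec, l_max) sph_harmonics(rel_vec, l_max)

#' Initial node feature matrix
#'
#' Sixteen cheminformatics descriptors per atom, in fixed order: atomic
#' number; chirality class; number of directly bonded neighbors; number of
#' rings containing the atom; implicit valence; formal charge; attached
#' hydrogens; unpaired electrons; hybridization class; aromaticity flag;
#' membership flags for rings of size 3-7; and a generic in-ring flag (the
#' reserved sixteenth slot).
#'
#' @param ann annotation data.frame from [annotate_smiles()] or
#'   [annotate_geometry()].
#' @param exclude_h whether hydrogens are excluded as nodes (switches the
#'   degree descriptor to heavy-atom degree).
#' @return numeric matrix n x 16.
#' @export
initial_node_features <- function(ann, exclude_h = TRUE) {
  if (is.null(ann) || !nrow(ann)) stop("annotation source missing")
  deg <- if (exclude_h) ann$degree_heavy else ann$degree_all
  m <- cbind(
    ann$atomic_number, ann$chirality, deg, ann$n_rings,
    ann$implicit_valence, ann$formal_charge, ann$n_h, ann$n_radical,
    ann$hybridization, ann$aromatic,
    ann$ring3, ann$ring4, ann$ring5, ann$ring6, ann$ring7,
    ann$in_ring
  )
  colnames(m) <- c("atomic_number", "chirality", "degree", "n_rings",
                   "implicit_valence", "formal_charge", "n_h", "n_radical",
                   "hybridization", "aromatic", "ring3", "ring4", "ring5",
                   "ring6", "ring7", "in_ring")
  storage.mode(m) <- "double"
  m
}

#' Assemble the full molecular graph
#'
#' Builds the radius graph, initial node descriptors, radial edge features
#' and spherical-harmonic filters for one molecule.  With `exclude_h` set,
#' hydrogen atoms are removed as nodes first.
#'
#' @param mol a [molecule3d()].
#' @param cfg a [graph_config()].
#' @param ann optional annotation table (one row per atom of `mol`); computed
#'   with [annotate_geometry()] when absent.
#' @return object of class `mol_graph`: `coords`, `node_feats0`, `src`,
#'   `dst`, `dist`, `edge_feats0`, `sph`, `keep` (indices of retained atoms
#'   in the original molecule).
#' @export
mol_graph <- function(mol, cfg = graph_config(), ann = NULL) {
  if (is.null(ann)) ann <- if (!is.null(mol$ann)) mol$ann else annotate_geometry(mol)
  stopifnot(nrow(ann) == n_atoms(mol))
  keep <- if (cfg$exclude_h) which(mol$elements != "H") else seq_len(n_atoms(mol))
  if (!length(keep)) stop("no atoms left after hydrogen exclusion")
  coords <- mol$coords[keep, , drop = FALSE]
  rg <- build_radius_graph(coords, cfg$r_max, cfg$n_neigh)
  rel <- coords[rg$dst, , drop = FALSE] - coords[rg$src, , drop = FALSE]
  structure(list(
    coords = coords,
    node_feats0 = initial_node_features(ann[keep, , drop = FALSE], cfg$exclude_h),
    src = rg$src, dst = rg$dst, dist = rg$dist,
    edge_feats0 = if (length(rg$dist)) radial_edge_features(rg$dist, cfg)
                  else matrix(0, 0, cfg$n_g),
    sph = if (length(rg$dist)) sph_filters(rel, cfg$l_max)
          else matrix(0, 0, (cfg$l_max + 1)^2),
    keep = keep, n = length(keep)
  ), class = "mol_graph")
}

# Concatenate several mol_graphs into one block-diagonal batch graph.
# `mol_id` records the source molecule of every node.
batch_graphs <- function(graphs) {
  ns <- vapply(graphs, function(g) g$n, 1L)
  offs <- cumsum(c(0L, ns[-length(ns)]))
  list(
    coords = do.call(rbind, lapply(graphs, function(g) g$coords)),
    node_feats0 = do.call(rbind, lapply(graphs, function(g) g$node_feats0)),
    src = unlist(mapply(function(g, o) g$src + o, graphs, offs, SIMPLIFY = FALSE)),
    dst = unlist(mapply(function(g, o) g$dst + o, graphs, offs, SIMPLIFY = FALSE)),
    dist = unlist(lapply(graphs, function(g) g$dist)),
    edge_feats0 = do.call(rbind, lapply(graphs, function(g) g$edge_feats0)),
    sph = do.call(rbind, lapply(graphs, function(g) g$sph)),
    mol_id = rep(seq_along(graphs), ns),
    n = sum(ns)
  )
}
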