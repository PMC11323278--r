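# Data splits: random interpolation splits and the three extrapolation
# splits (scaffold, molecular size, property value).

#' Split specification
#'
#' @param type `"random"`, `"scaffold"`, `"size"` or `"property"`.
#' @param fractions train/val/test fractions summing to 1.
#' @param seed RNG seed fixing the fold.
#' @param scaffold_side which side's molecules define the scaffold key
#'   (reactants for chemically diverse sets; products e.g. for cycloaddition
#'   sets whose products carry the ring system).
#' @param reverse size/property splits in reverse order (largest molecules /
#'   lowest barriers in train).
#' @return object of class `split_spec`.
#' @export
split_spec <- function(type = c("random", "scaffold", "size", "property"),
                       fractions = c(0.8, 0.1, 0.1), seed = 1L,
                       scaffold_side = c("reactant", "product"),
                       reverse = FALSE) {
  type <- match.arg(type)
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            all(fractions > 0))
  structure(list(type = type, fractions = fractions, seed = as.integer(seed),
                 scaffold_side = match.arg(scaffold_side),
                 reverse = isTRUE(reverse)),
            class = "split_spec")
}

.part_sizes <- function(n, fractions) {
  n_val <- max(1L, floor(fractions[2] * n))
  n_test <- max(1L, n - floor(fractions[1] * n) - n_val)
  c(train = n - n_val - n_test, val = n_val, test = n_test)
}

.partition_order <- function(ord, sizes) {
  list(train = sort(ord[seq_len(sizes[1])]),
       val = sort(ord[sizes[1] + seq_len(sizes[2])]),
       test = sort(ord[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

#' Random split
#'
#' @param n number of records.
#' @param spec a [split_spec()].
#' @return list of sorted index vectors `train`, `val`, `test`: disjoint,
#'   exhaustive, reproducible per seed.
#' @export
random_split <- function(n, spec = split_spec("random")) {
  if (n < 3) stop("need at least 3 records to split")
  sizes <- .part_sizes(n, spec$fractions)
  ord <- withr::with_seed(spec$seed, sample.int(n))
  .partition_order(ord, sizes)
}

#' Scaffold key of a molecule
#'
#' Element-retaining ring-system framework: terminal atoms (degree <= 1) are
#' pruned iteratively from the heavy-atom graph, leaving rings and the
#' linkers between them; the remainder is canonicalized (BLISS canonical
#' permutation with element colors) into a string key.  Acyclic molecules
#' yield the empty key and are grouped together.
#'
#' @param mol a [molecule3d()], or a [labeled_graph()].
#' @return character scaffold key.
#' @export
scaffold_key <- function(mol) {
  g <- if (inherits(mol, "labeled_graph")) mol else {
    if (!is.null(mol$source_smiles)) {
      labeled_graph_from_smiles(parse_smiles(mol$source_smiles), drop_h = TRUE)
    } else {
      full <- graph_from_xyz(mol)
      keep <- which(mol$elements != "H")
      remap <- match(seq_along(mol$elements), keep)
      e <- full$edges[full$edges[, 1] %in% keep & full$edges[, 2] %in% keep, ,
                      drop = FALSE]
      labeled_graph(mol$elements[keep], cbind(remap[e[, 1]], remap[e[, 2]]))
    }
  }
  repeat {
    deg <- lg_degree(g)
    drop <- which(deg <= 1L)
    if (!length(drop) || length(drop) == lg_n(g)) {
      if (length(drop) == lg_n(g)) return("")
      break
    }
    keep <- setdiff(seq_len(lg_n(g)), drop)
    remap <- match(seq_len(lg_n(g)), keep)
    e <- g$edges[g$edges[, 1] %in% keep & g$edges[, 2] %in% keep, , drop = FALSE]
    g <- labeled_graph(g$labels[keep], cbind(remap[e[, 1]], remap[e[, 2]]))
  }
  if (!lg_n(g)) return("")
  labs <- sort(unique(g$labels))
  cp <- igraph::canonical_permutation(lg_igraph(g),
                                      colors = match(g$labels, labs))$labeling
  perm <- as.integer(cp)                 # node i -> canonical index
  inv <- order(perm)
  labels_c <- g$labels[inv]
  e <- cbind(perm[g$edges[, 1]], perm[g$edges[, 2]])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  paste0(paste(labels_c, collapse = ""), "|",
         paste(e[, 1], e[, 2], sep = "-", collapse = ","))
}

# Scaffold key of a record: sorted concatenation of per-molecule keys of the
# designated side.
record_scaffold_key <- function(rec, side = "reactant") {
  mols <- if (side == "reactant") rec$reactants else rec$products
  paste(sort(vapply(mols, scaffold_key, "")), collapse = ";")
}

#' Scaffold split
#'
#' Whole scaffold groups are assigned to partitions so no scaffold key ever
#' appears in two partitions: group order is shuffled by the seed, then
#' train, val and test are filled greedily to their capacities.
#'
#' @param records list of [reaction_record()].
#' @param spec a [split_spec()].
#' @return index partition as in [random_split()].
#' @export
scaffold_split <- function(records, spec = split_spec("scaffold")) {
  n <- length(records)
  keys <- vapply(records, record_scaffold_key, "", side = spec$scaffold_side)
  groups <- split(seq_len(n), keys)
  sizes <- .part_sizes(n, spec$fractions)
  if (max(lengths(groups)) > sizes[1]) {
    big <- names(which.max(lengths(groups)))
    stop(sprintf(
      "scaffold group '%s' holds %d of %d records, more than the train capacity %d",
      big, max(lengths(groups)), n, sizes[1]))
  }
  ord <- withr::with_seed(spec$seed, sample(length(groups)))
  part <- list(train = integer(0), val = integer(0), test = integer(0))
  for (g in groups[ord]) {
    tgt <- if (length(part$train) + length(g) <= sizes[1]) "train"
           else if (length(part$val) + length(g) <= sizes[2]) "val"
           else "test"
    part[[tgt]] <- c(part[[tgt]], g)
  }
  lapply(part, sort)
}

# heavy-atom count of the designated side
record_size <- function(rec, side = "reactant") {
  mols <- if (side == "reactant") rec$reactants else rec$products
  sum(vapply(mols, function(m) sum(m$elements != "H"), 1L))
}

#' Size-based extrapolation split
#'
#' Reactions of the smallest molecules (reactant-side heavy-atom count) go to
#' train, the largest to validation and test; a seeded initial shuffle breaks
#' ties, so equal-size data reduce to a random split.
#'
#' @inheritParams scaffold_split
#' @return index partition as in [random_split()].
#' @export
size_split <- function(records, spec = split_spec("size")) {
  n <- length(records)
  sizes_v <- vapply(records, record_size, 1L, side = spec$scaffold_side)
  if (spec$reverse) sizes_v <- -sizes_v
  shuf <- withr::with_seed(spec$seed, sample.int(n))
  ord <- shuf[order(sizes_v[shuf])]
  .partition_order(ord, .part_sizes(n, spec$fractions))
}

#' Property-based extrapolation split
#'
#' Trains on reactions with higher targets (barriers) and tests on the
#' lowest ones; seeded shuffle breaks ties.
#'
#' @inheritParams scaffold_split
#' @return index partition as in [random_split()].
#' @export
property_split <- function(records, spec = split_spec("property")) {
  n <- length(records)
  y <- vapply(records, function(r) r$target, 1)
  if (spec$reverse) y <- -y
  shuf <- withr::with_seed(spec$seed, sample.int(n))
  ord <- shuf[order(-y[shuf])]
  .partition_order(ord, .part_sizes(n, spec$fractions))
}

#' Dispatch a split by its specification
#'
#' @param records list of records (only `n` is used for random splits).
#' @param spec a [split_spec()].
#' @return index partition.
#' @export
make_split <- function(records, spec) {
  switch(spec$type,
         random = random_split(length(records), spec),
         scaffold = scaffold_split(records, spec),
         size = size_split(records, spec),
         property = property_split(records, spec))
}

#' Write k folds of a split to CSV
#'
#' @param records list of records with `id` fields.
#' @param spec base [split_spec()]; fold f uses seed `spec$seed + f - 1`.
#' @param k number of folds.
#' @param path output CSV path (columns id, fold, partition).
#' @return the data.frame, invisibly.
#' @export
write_splits <- function(records, spec, k = 10L, path) {
  ids <- vapply(records, function(r) r$id, "")
  rows <- do.call(rbind, lapply(seq_len(k), function(f) {
    sp <- spec; sp$seed <- spec$seed + f - 1L
    part <- make_split(records, sp)
    do.call(rbind, lapply(names(part), function(p) {
      if (!length(part[[p]])) return(NULL)
      data.frame(id = ids[part[[p]]], fold = f, partition = p)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
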