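# Dataset curation: read manifests, match every molecule's SMILES graph to
# its xyz structure, compose reaction atom maps, and report exclusions.

#' Match one molecule's SMILES to its xyz structure
#'
#' Builds the covalent-radius graph of the structure and matches it to the
#' SMILES graph by labelled isomorphism.  When the SMILES carries fewer
#' explicit atoms than the structure (implicit hydrogens), matching runs on
#' the heavy-atom skeletons with attached-hydrogen counts as an extra color
#' and hydrogens are assigned per heavy atom by count, not individually.
#'
#' @param mol a [molecule3d()].
#' @param smi a [parse_smiles()] graph.
#' @param radii,tolerance bond-perception parameters.
#' @return list: `map_numbers` (per xyz atom; `NA` where unmapped), `ann`
#'   (annotation table aligned to xyz atom order), `perm` (the heavy or full
#'   atom permutation found).
#' @export
match_molecule_to_smiles <- function(mol, smi, radii = covalent_radii(),
                                     tolerance = 0.4) {
  g_xyz <- graph_from_xyz(mol, radii, tolerance)
  ann_smi <- annotate_smiles(smi)
  n_x <- n_atoms(mol)
  n_s <- nrow(smi$atoms)
  if (n_s == n_x) {
    g_smi <- labeled_graph_from_smiles(smi)
    perm <- match_smiles_to_xyz(g_xyz, g_smi)
    map_numbers <- rep(NA_integer_, n_x)
    map_numbers[perm] <- smi$atoms$map
    ann <- ann_smi
    ann[perm, ] <- ann_smi
    return(list(map_numbers = map_numbers, ann = ann, perm = perm))
  }
  # heavy-skeleton matching with hydrogen counts as color refinement
  hx <- which(mol$elements != "H")
  hs <- which(smi$atoms$element != "H")
  if (length(hs) != length(hx)) {
    stop("SMILES/xyz mismatch: ", length(hx), " heavy atoms in xyz vs ",
         length(hs), " in SMILES")
  }
  sub_lg <- function(labels, edges, keep) {
    remap <- match(seq_along(labels), keep)
    e <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    labeled_graph(labels[keep], cbind(remap[e[, 1]], remap[e[, 2]]))
  }
  gxh <- sub_lg(mol$elements, g_xyz$edges, hx)
  gsh <- sub_lg(smi$atoms$element, as.matrix(smi$bonds[, c("i", "j")]), hs)
  # hydrogens in the structure must sit on exactly one heavy atom
  h_at <- setdiff(seq_len(n_x), hx)
  h_host <- integer(length(h_at))
  hx_cnt <- integer(length(hx))
  for (k in seq_along(h_at)) {
    nb <- c(g_xyz$edges[g_xyz$edges[, 1] == h_at[k], 2],
            g_xyz$edges[g_xyz$edges[, 2] == h_at[k], 1])
    nb <- nb[mol$elements[nb] != "H"]
    if (length(nb) != 1L) {
      stop("SMILES/xyz mismatch: hydrogen atom ", h_at[k],
           " bonded to ", length(nb), " heavy atoms")
    }
    h_host[k] <- nb
    hx_cnt[match(nb, hx)] <- hx_cnt[match(nb, hx)] + 1L
  }
  hs_cnt <- ann_smi$n_h[hs]
  if (!identical(sort(hx_cnt), sort(as.integer(hs_cnt)))) {
    stop("SMILES/xyz mismatch: hydrogen-count multisets differ")
  }
  perm <- match_smiles_to_xyz(gxh, gsh, extra_colors1 = hx_cnt,
                              extra_colors2 = as.integer(hs_cnt))
  map_numbers <- rep(NA_integer_, n_x)
  map_numbers[hx[perm]] <- smi$atoms$map[hs]
  # distribute maps of explicit SMILES hydrogens per matched heavy atom
  h_rows <- .h_annotation_row()
  ann <- ann_smi[rep(1L, n_x), ]
  ann[hx[perm], ] <- ann_smi[hs, ]
  for (k in seq_along(hs)) {
    host_x <- hx[perm[k]]
    smi_h <- c(smi$bonds$j[smi$bonds$i == hs[k]], smi$bonds$i[smi$bonds$j == hs[k]])
    smi_h <- smi_h[smi$atoms$element[smi_h] == "H"]
    xyz_h <- h_at[h_host == host_x]
    if (length(smi_h)) {
      take <- seq_len(min(length(smi_h), length(xyz_h)))
      map_numbers[xyz_h[take]] <- smi$atoms$map[smi_h[take]]
    }
  }
  ann[h_at, ] <- h_rows[rep(1L, length(h_at)), ]
  ann$map <- map_numbers
  rownames(ann) <- NULL
  list(map_numbers = map_numbers, ann = ann, perm = perm)
}

.h_annotation_row <- function() {
  data.frame(element = "H", atomic_number = 1, chirality = 0L,
             degree_heavy = 1L, degree_all = 1L, n_rings = 0L,
             implicit_valence = 0L, formal_charge = 0L, n_h = 0L,
             n_radical = 0L, hybridization = 0L, aromatic = 0L,
             ring3 = 0L, ring4 = 0L, ring5 = 0L, ring6 = 0L, ring7 = 0L,
             in_ring = 0L, map = NA_integer_)
}

#' Read a reaction manifest
#'
#' Columns: `id`, `reactant_xyz` and `product_xyz` (";"-joined paths
#' relative to the manifest), `rxn_smiles` (may be empty), `target`, and
#' optionally `atom_map` (";"-joined product indices for SMILES-free
#' records).
#'
#' @param path manifest CSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(id = "character"))
}

#' Curate a reaction dataset
#'
#' For every manifest row, reads the xyz structures, parses the reaction
#' SMILES, matches each molecule's SMILES graph to its structure, and
#' composes the reaction atom map from the SMILES map numbers and the
#' per-molecule permutations.  Records whose molecules all match are kept;
#' failures (I/O, parse, or SMILES/xyz mismatch) are collected per record
#' with their reason and never abort the batch.
#'
#' @param manifest data.frame from [read_manifest()] (or compatible).
#' @param dir directory the xyz paths are relative to.
#' @param regime atom-mapping regime recorded on the kept records.
#' @param radii,tolerance bond-perception parameters.
#' @return list of class `curation`: `records`, `exclusions` (data.frame id,
#'   reason), `n_kept`, `n_excluded`.
#' @export
curate_dataset <- function(manifest, dir = ".", regime = "True",
                           radii = covalent_radii(), tolerance = 0.4) {
  records <- list()
  excl <- list()
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    res <- tryCatch({
      rmols <- lapply(strsplit(row$reactant_xyz, ";")[[1]],
                      function(p) read_xyz(file.path(dir, p)))
      pmols <- lapply(strsplit(row$product_xyz, ";")[[1]],
                      function(p) read_xyz(file.path(dir, p)))
      target <- as.numeric(row$target)
      if (!is.finite(target)) stop("non-finite target")
      atom_map <- NULL
      if (nzchar(row$rxn_smiles %||% "")) {
        rx <- parse_mapped_reaction_smiles(row$rxn_smiles)
        if (length(rx$reactants) != length(rmols)) {
          stop("molecule count mismatch on reactant side (",
               length(rx$reactants), " SMILES vs ", length(rmols), " xyz)")
        }
        if (length(rx$products) != length(pmols)) {
          stop("molecule count mismatch on product side (",
               length(rx$products), " SMILES vs ", length(pmols), " xyz)")
        }
        attach_side <- function(mols, smis) {
          maps <- integer(0)
          for (j in seq_along(mols)) {
            m <- match_molecule_to_smiles(mols[[j]], smis[[j]], radii, tolerance)
            mols[[j]]$ann <- m$ann
            mols[[j]]$map_numbers <- m$map_numbers
            mols[[j]]$source_smiles <- smis[[j]]$smiles
            maps <- c(maps, m$map_numbers)
          }
          list(mols = mols, maps = maps)
        }
        rs <- attach_side(rmols, rx$reactants)
        ps <- attach_side(pmols, rx$products)
        rmols <- rs$mols; pmols <- ps$mols
        if (rx$mapped) {
          common <- intersect(rs$maps[!is.na(rs$maps)], ps$maps[!is.na(ps$maps)])
          atom_map <- rep(NA_integer_, length(rs$maps))
          atom_map[match(common, rs$maps)] <- match(common, ps$maps)
        }
      } else if (!is.null(row$atom_map) && nzchar(row$atom_map %||% "")) {
        atom_map <- as.integer(strsplit(row$atom_map, ";")[[1]])
      }
      reaction_record(rmols, pmols, regime = regime, atom_map = atom_map,
                      target = target, id = row$id)
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "reaction_record")) {
      records[[length(records) + 1L]] <- res
    } else {
      excl[[length(excl) + 1L]] <- data.frame(id = row$id, reason = res)
    }
  }
  structure(list(
    records = records,
    exclusions = if (length(excl)) do.call(rbind, excl)
                 else data.frame(id = character(0), reason = character(0)),
    n_kept = length(records), n_excluded = length(excl)
  ), class = "curation")
}

#' @export
print.curation <- function(x, ...) {
  cat("<curation> kept", x$n_kept, "records, excluded", x$n_excluded, "\n")
  if (x$n_excluded) print(x$exclusions)
  invisible(x)
}

#' Write the exclusion report
#'
#' @param curation result of [curate_dataset()].
#' @param path output CSV (columns id, reason).
#' @export
write_exclusion_report <- function(curation, path) {
  utils::write.csv(curation$exclusions, path, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
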