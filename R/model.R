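# Full model: shared molecular encoder applied to both sides of each
# reaction (one set of weights, per the symmetric-channel design), plus the
# mapping/readout head.  Reactions are processed in batches as block-diagonal
# graphs; predictions are independent of batch composition because every
# operation is per-atom, per-edge or a per-reaction pool.

#' Construct a reaction record
#'
#' @param reactants,products lists of [molecule3d()] (multi-molecule sides
#'   concatenate in list order for atom indexing).
#' @param regime atom-mapping regime: `"True"`, `"RXNMapper"` or `"None"`.
#' @param atom_map optional integer vector over the concatenated reactant
#'   atoms: `atom_map[i]` is the concatenated product-atom index aligned with
#'   reactant atom `i`; `NA` marks unmapped atoms (typically hydrogens).
#' @param target scalar reaction property (kcal/mol).
#' @param id record identifier.
#' @return object of class `reaction_record`.
#' @export
reaction_record <- function(reactants, products, regime = "None",
                            atom_map = NULL, target = NA_real_, id = "") {
  stopifnot(regime %in% c("True", "RXNMapper", "None"))
  nr <- sum(vapply(reactants, n_atoms, 1L))
  np <- sum(vapply(products, n_atoms, 1L))
  if (!is.null(atom_map)) {
    stopifnot(length(atom_map) == nr)
    mapped <- atom_map[!is.na(atom_map)]
    if (length(mapped) && (any(mapped < 1) || any(mapped > np) ||
                           anyDuplicated(mapped))) {
      stop("atom_map values must be distinct product-atom indices")
    }
  }
  if (!is.na(target) && !is.finite(target)) stop("target must be finite")
  structure(list(id = id, reactants = reactants, products = products,
                 regime = regime, atom_map = atom_map, target = target),
            class = "reaction_record")
}

# Featurize one side of a record: mol_graphs per molecule plus the retained
# (post hydrogen-exclusion) concatenated atom index.
.prep_side <- function(mols, gcfg, anns = NULL) {
  graphs <- lapply(seq_along(mols), function(i) {
    mol_graph(mols[[i]], gcfg, ann = if (is.null(anns)) NULL else anns[[i]])
  })
  ns <- vapply(mols, n_atoms, 1L)
  offs <- cumsum(c(0L, ns[-length(ns)]))
  keep <- unlist(mapply(function(g, o) g$keep + o, graphs, offs,
                        SIMPLIFY = FALSE))
  list(graphs = graphs, keep = keep)
}

#' Featurize reaction records for the model
#'
#' Builds per-molecule graphs (with the configured hydrogen exclusion) and
#' reduces each record's atom map to the retained atoms.
#'
#' @param records list of [reaction_record()].
#' @param gcfg a [graph_config()].
#' @param need_map require a complete map over retained atoms (variant M).
#' @return list of prepared records (class `rxn_prep`).
#' @export
prepare_reactions <- function(records, gcfg = graph_config(),
                              need_map = FALSE) {
  prep <- lapply(records, function(rec) {
    pr <- .prep_side(rec$reactants, gcfg)
    pp <- .prep_side(rec$products, gcfg)
    align <- NULL
    if (!is.null(rec$atom_map)) {
      if (length(pr$keep) != length(pp$keep)) {
        stop("unbalanced reaction ", rec$id, ": ", length(pr$keep),
             " vs ", length(pp$keep), " retained atoms")
      }
      mapped <- rec$atom_map[pr$keep]
      align <- match(mapped, pp$keep)
      if (anyNA(align)) {
        if (need_map) stop("record ", rec$id,
                           ": retained atom without a map (variant M needs one)")
        align <- NULL
      }
    } else if (need_map) {
      stop("record ", rec$id, " has no atom map (variant M needs one)")
    }
    list(id = rec$id, gr = pr$graphs, gp = pp$graphs,
         nr = length(pr$keep), np = length(pp$keep),
         align = align, target = rec$target)
  })
  structure(prep, class = "rxn_prep")
}

#' @export
`[.rxn_prep` <- function(x, i) {
  structure(unclass(x)[i], class = "rxn_prep")
}

# Assemble a subset of prepared records into one batched forward problem.
assemble_batch <- function(prep, idx = seq_along(prep)) {
  sub <- prep[idx]
  br <- batch_graphs(unlist(lapply(sub, function(p) p$gr), recursive = FALSE))
  bp <- batch_graphs(unlist(lapply(sub, function(p) p$gp), recursive = FALSE))
  nr <- vapply(sub, function(p) p$nr, 1L)
  np <- vapply(sub, function(p) p$np, 1L)
  rid_r <- rep(seq_along(sub), nr)
  rid_p <- rep(seq_along(sub), np)
  offs_p <- cumsum(c(0L, np[-length(np)]))
  align <- NULL
  if (!any(vapply(sub, function(p) is.null(p$align), TRUE))) {
    align <- unlist(mapply(function(p, o) p$align + o, sub, offs_p,
                           SIMPLIFY = FALSE))
  }
  list(br = br, bp = bp, rid_r = rid_r, rid_p = rid_p,
       n_rxn = length(sub), align = align,
       targets = vapply(sub, function(p) p$target, 1))
}

#' Initialize a model
#'
#' Draws all parameters from the current RNG state (seed with `set.seed()`
#' for reproducibility).
#'
#' @param gcfg,ccfg,hcfg configuration objects.
#' @param target_mean,target_sd target standardization constants (z-score on
#'   the training set; predictions are returned on the original scale).
#' @return object of class `rxn3d_model`.
#' @export
rxn3d_model <- function(gcfg = graph_config(), ccfg = channel_config(),
                        hcfg = head_config(), target_mean = 0,
                        target_sd = 1) {
  if (gcfg$l_max < channel_l_max(ccfg)) {
    gcfg$l_max <- channel_l_max(ccfg)
  }
  D <- local_rep_dim(ccfg, gcfg)
  structure(list(
    params = list(encoder = init_encoder(gcfg, ccfg),
                  head = init_head(hcfg, D)),
    gcfg = gcfg, ccfg = ccfg, hcfg = hcfg, D = D,
    target_mean = target_mean, target_sd = target_sd,
    version = tryCatch(as.character(utils::packageVersion("rxn3d")),
                       error = function(e) "0.0.0")
  ), class = "rxn3d_model")
}

# Forward pass on an assembled batch; predictions on the standardized scale.
model_fwd <- function(model, batch, train = FALSE) {
  er <- encode_fwd(model$params$encoder, batch$br, model$gcfg, model$ccfg, train)
  ep <- encode_fwd(model$params$encoder, batch$bp, model$gcfg, model$ccfg, train)
  hf <- head_fwd(model$params$head, model$hcfg, er$X, ep$X,
                 batch$rid_r, batch$rid_p, batch$n_rxn, batch$align)
  list(pred = hf$pred, er = er, ep = ep, hcache = hf$cache)
}

# Backward pass: d_pred is the gradient of the loss w.r.t. each prediction.
model_bwd <- function(model, batch, fw, d_pred) {
  hb <- head_bwd(model$params$head, model$hcfg, fw$hcache, fw$er$X, fw$ep$X,
                 batch$rid_r, batch$rid_p, batch$n_rxn, d_pred)
  gr <- encode_bwd(model$params$encoder, fw$er$cache, batch$br,
                   model$gcfg, model$ccfg, hb$dXr)
  gp <- encode_bwd(model$params$encoder, fw$ep$cache, batch$bp,
                   model$gcfg, model$ccfg, hb$dXp)
  list(encoder = params_add(gr, gp), head = hb$grads)
}

#' Predict reaction properties
#'
#' Runs the full pipeline (featurization, shared molecular channels, head)
#' and returns predictions in original target units.
#'
#' @param model a trained or freshly initialized [rxn3d_model()].
#' @param records list of [reaction_record()], or an `rxn_prep` from
#'   [prepare_reactions()].
#' @return numeric vector of predictions.
#' @export
predict_reactions <- function(model, records) {
  prep <- if (inherits(records, "rxn_prep")) records else {
    prepare_reactions(records, model$gcfg,
                      need_map = model$hcfg$mapping_variant == "M")
  }
  batch <- assemble_batch(prep)
  fw <- model_fwd(model, batch, train = FALSE)
  fw$pred * model$target_sd + model$target_mean
}
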