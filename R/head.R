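# Reaction head: combines reactant and product local representations into a
# reaction representation and predicts the scalar target.
#
# Mapping variants: "M" (atom-mapped: product rows reordered by the atom map),
# "X" (cross-attention surrogate for the map), "S" (mapping-free: per-side
# global pooling).  Readouts: "vector" (pooled global reaction vector through
# an MLP) and "energy" (summed per-atom contributions through a centered MLP
# whose output vanishes exactly at the zero representation, so identity
# reactions give exactly zero under the diff combine rule).

#' Head configuration
#'
#' @param mapping_variant `"M"`, `"X"` or `"S"`.
#' @param combine_mode `"diff"`, `"sum"`, `"mean"` or `"mlp"`.
#' @param graph_mode `"vector"` or `"energy"`.
#' @return object of class `head_config`.
#' @export
head_config <- function(mapping_variant = c("S", "M", "X"),
                        combine_mode = c("diff", "sum", "mean", "mlp"),
                        graph_mode = c("energy", "vector")) {
  structure(list(mapping_variant = match.arg(mapping_variant),
                 combine_mode = match.arg(combine_mode),
                 graph_mode = match.arg(graph_mode)),
            class = "head_config")
}

#' @keywords internal
init_head <- function(hcfg, D) {
  p <- list()
  Dc <- D
  if (hcfg$mapping_variant %in% c("M", "X")) {
    if (hcfg$combine_mode == "mlp") {
      p$combine_mlp <- nn_init_mlp(2L * D, D, D)
      Dc <- D
    }
    if (hcfg$mapping_variant == "X") {
      p$attn <- list(Wq = nn_init_linear(D, D, bias = FALSE)$W,
                     Wk = nn_init_linear(D, D, bias = FALSE)$W,
                     Wv = nn_init_linear(D, D, bias = FALSE)$W)
    }
    if (hcfg$graph_mode == "vector") {
      p$atom_mlp <- nn_init_mlp(Dc, c(D, D), D)
      p$final_mlp <- nn_init_mlp(D, c(D, D), 1L)
    } else {
      p$energy_mlp <- nn_init_mlp(Dc, c(D, D), 1L)
    }
  } else {  # S
    if (hcfg$graph_mode == "vector") {
      p$atom_mlp <- nn_init_mlp(D, c(D, D), D)
      if (hcfg$combine_mode == "mlp") p$combine_mlp <- nn_init_mlp(2L * D, D, D)
      p$final_mlp <- nn_init_mlp(D, c(D, D), 1L)
    } else {
      p$energy_mlp <- nn_init_mlp(D, c(D, D), 1L)
      if (hcfg$combine_mode == "mlp") p$combine_mlp <- nn_init_mlp(2L, D, 1L)
    }
  }
  p
}

# Centered per-atom energy readout: contribution(x) = g(x) - g(0), so the
# zero reaction representation maps to an exactly zero contribution (the
# final-layer-has-no-effective-bias guarantee) while the MLP keeps its
# hidden biases for optimization.
energy_head_fwd <- function(mlp, X) {
  fx <- nn_mlp_fwd(mlp, X)
  f0 <- nn_mlp_fwd(mlp, matrix(0, 1, ncol(X)))
  list(out = fx$out - as.numeric(f0$out), fx = fx, f0 = f0)
}

energy_head_bwd <- function(mlp, cache, dY) {
  bx <- nn_mlp_bwd(mlp, cache$fx, dY)
  b0 <- nn_mlp_bwd(mlp, cache$f0, matrix(-sum(dY), 1, 1))
  list(dX = bx$dX, grad = params_add(bx$grad, b0$grad))
}

#' Reorder product-atom representations by an atom map
#'
#' Row `i` of the result is the product-atom representation mapped to
#' reactant atom `i`.
#'
#' @param X_product matrix of product-atom representations.
#' @param atom_map integer vector: `atom_map[i]` is the product atom aligned
#'   with reactant atom `i`; must be a bijection.
#' @return reordered matrix with `length(atom_map)` rows.
#' @export
reorder_by_mapping <- function(X_product, atom_map) {
  if (length(atom_map) != nrow(X_product)) {
    stop("unbalanced reaction: ", length(atom_map), " reactant atoms vs ",
         nrow(X_product), " product atoms")
  }
  if (anyNA(atom_map) || !setequal(atom_map, seq_len(nrow(X_product)))) {
    stop("atom_map must be a bijection onto the product atoms")
  }
  X_product[atom_map, , drop = FALSE]
}

#' Align product atoms to reactant atoms by cross-attention
#'
#' Single-head scaled dot-product attention with reactant queries over
#' product keys/values: output row `i` is the attention-weighted combination
#' of product value vectors for reactant atom `i`.
#'
#' @param X_reactant,X_product representation matrices sharing feature
#'   dimension D.
#' @param attn list with projection matrices `Wq`, `Wk`, `Wv` (D x D).
#' @return list: `aligned` (n_reactant x D), `A` attention matrix (rows sum
#'   to 1), plus intermediates used by the backward pass.
#' @export
cross_attention_align <- function(X_reactant, X_product, attn) {
  if (!nrow(X_product)) stop("empty product side")
  D <- ncol(X_reactant)
  Q <- X_reactant %*% attn$Wq
  K <- X_product %*% attn$Wk
  V <- X_product %*% attn$Wv
  S <- Q %*% t(K) / sqrt(D)
  S <- S - apply(S, 1, max)
  A <- exp(S)
  A <- A / rowSums(A)
  list(aligned = A %*% V, A = A, Q = Q, K = K, V = V)
}

.cross_attention_bwd <- function(Xr, Xp, attn, cache, d_aligned) {
  D <- ncol(Xr)
  dV <- t(cache$A) %*% d_aligned
  dA <- d_aligned %*% t(cache$V)
  dS <- cache$A * (dA - rowSums(dA * cache$A))
  dQ <- dS %*% cache$K / sqrt(D)
  dK <- t(dS) %*% cache$Q / sqrt(D)
  list(dXr = dQ %*% t(attn$Wq),
       dXp = dK %*% t(attn$Wk) + dV %*% t(attn$Wv),
       grads = list(Wq = crossprod(Xr, dQ), Wk = crossprod(Xp, dK),
                    Wv = crossprod(Xp, dV)))
}

#' Combine aligned reactant and product representations
#'
#' @param X_reactant,X_product_aligned equal-shape matrices (atoms x D).
#' @param combine_mode `"diff"` (product minus reactant), `"sum"`, `"mean"`,
#'   or `"mlp"` (learned map on the rowwise concatenation; requires
#'   `combine_mlp`).
#' @param combine_mlp MLP parameter list for `combine_mode = "mlp"`.
#' @return list with `X_rxn` and a backward cache.
#' @export
combine_local <- function(X_reactant, X_product_aligned,
                          combine_mode = "diff", combine_mlp = NULL) {
  stopifnot(all(dim(X_reactant) == dim(X_product_aligned)))
  switch(combine_mode,
    diff = list(X_rxn = X_product_aligned - X_reactant, cache = NULL),
    sum  = list(X_rxn = X_product_aligned + X_reactant, cache = NULL),
    mean = list(X_rxn = (X_product_aligned + X_reactant) / 2, cache = NULL),
    mlp  = {
      fw <- nn_mlp_fwd(combine_mlp, cbind(X_reactant, X_product_aligned))
      list(X_rxn = fw$out, cache = fw)
    },
    stop("unknown combine_mode: ", combine_mode))
}

.combine_bwd <- function(combine_mode, combine_mlp, cache, dX, D) {
  switch(combine_mode,
    diff = list(dXr = -dX, dXp = dX, grads = NULL),
    sum  = list(dXr = dX, dXp = dX, grads = NULL),
    mean = list(dXr = dX / 2, dXp = dX / 2, grads = NULL),
    mlp  = {
      bw <- nn_mlp_bwd(combine_mlp, cache, dX)
      list(dXr = bw$dX[, seq_len(D), drop = FALSE],
           dXp = bw$dX[, D + seq_len(D), drop = FALSE],
           grads = bw$grad)
    })
}

# ---- batched head forward/backward ------------------------------------------
#
# Inputs: Xr (Nr x D), Xp (Np x D), per-atom reaction ids rid_r / rid_p,
# n_rxn, and for variant M a global alignment index `align` (length Nr,
# giving the Xp row aligned with each Xr row).

head_fwd <- function(hp, hcfg, Xr, Xp, rid_r, rid_p, n_rxn, align = NULL) {
  D <- ncol(Xr)
  cache <- list()
  if (hcfg$mapping_variant == "S") {
    if (hcfg$graph_mode == "vector") {
      fr <- nn_mlp_fwd(hp$atom_mlp, Xr)
      fp <- nn_mlp_fwd(hp$atom_mlp, Xp)
      Gr <- scatter_sum(fr$out, rid_r, n_rxn)
      Gp <- scatter_sum(fp$out, rid_p, n_rxn)
      cmb <- combine_local(Gr, Gp, hcfg$combine_mode, hp$combine_mlp)
      ff <- nn_mlp_fwd(hp$final_mlp, cmb$X_rxn)
      pred <- as.numeric(ff$out)
      cache <- list(fr = fr, fp = fp, Gr = Gr, Gp = Gp, cmb = cmb, ff = ff)
    } else {
      fr <- energy_head_fwd(hp$energy_mlp, Xr)
      fp <- energy_head_fwd(hp$energy_mlp, Xp)
      Er <- scatter_sum(fr$out, rid_r, n_rxn)
      Ep <- scatter_sum(fp$out, rid_p, n_rxn)
      if (hcfg$combine_mode == "mlp") {
        cf <- nn_mlp_fwd(hp$combine_mlp, cbind(Er, Ep))
        pred <- as.numeric(cf$out)
        cache$cf <- cf
      } else {
        pred <- switch(hcfg$combine_mode,
                       diff = Ep - Er, sum = Ep + Er, mean = (Ep + Er) / 2)
        pred <- as.numeric(pred)
      }
      cache <- c(cache, list(fr = fr, fp = fp, Er = Er, Ep = Ep))
    }
    return(list(pred = pred, cache = cache))
  }
  # variants M and X share the local-combination pipeline
  if (hcfg$mapping_variant == "M") {
    Xpa <- Xp[align, , drop = FALSE]
    cache$align <- align
  } else {
    at <- vector("list", n_rxn)
    Xpa <- matrix(0, nrow(Xr), D)
    for (r in seq_len(n_rxn)) {
      ir <- which(rid_r == r); ip <- which(rid_p == r)
      ca <- cross_attention_align(Xr[ir, , drop = FALSE],
                                  Xp[ip, , drop = FALSE], hp$attn)
      Xpa[ir, ] <- ca$aligned
      at[[r]] <- ca
    }
    cache$at <- at
  }
  cmb <- combine_local(Xr, Xpa, hcfg$combine_mode, hp$combine_mlp)
  cache$cmb <- cmb
  cache$Xpa <- Xpa
  if (hcfg$graph_mode == "vector") {
    fa <- nn_mlp_fwd(hp$atom_mlp, cmb$X_rxn)
    G <- scatter_sum(fa$out, rid_r, n_rxn)
    ff <- nn_mlp_fwd(hp$final_mlp, G)
    pred <- as.numeric(ff$out)
    cache <- c(cache, list(fa = fa, G = G, ff = ff))
  } else {
    fe <- energy_head_fwd(hp$energy_mlp, cmb$X_rxn)
    pred <- as.numeric(scatter_sum(fe$out, rid_r, n_rxn))
    cache$fe <- fe
  }
  list(pred = pred, cache = cache)
}

head_bwd <- function(hp, hcfg, cache, Xr, Xp, rid_r, rid_p, n_rxn, d_pred) {
  D <- ncol(Xr)
  grads <- list()
  if (hcfg$mapping_variant == "S") {
    if (hcfg$graph_mode == "vector") {
      bf <- nn_mlp_bwd(hp$final_mlp, cache$ff, matrix(d_pred, ncol = 1))
      grads$final_mlp <- bf$grad
      cb <- .combine_bwd(hcfg$combine_mode, hp$combine_mlp, cache$cmb$cache,
                         bf$dX, D)
      if (!is.null(cb$grads)) grads$combine_mlp <- cb$grads
      br <- nn_mlp_bwd(hp$atom_mlp, cache$fr, cb$dXr[rid_r, , drop = FALSE])
      bp <- nn_mlp_bwd(hp$atom_mlp, cache$fp, cb$dXp[rid_p, , drop = FALSE])
      grads$atom_mlp <- params_add(br$grad, bp$grad)
      return(list(dXr = br$dX, dXp = bp$dX, grads = grads))
    }
    if (hcfg$combine_mode == "mlp") {
      bc <- nn_mlp_bwd(hp$combine_mlp, cache$cf, matrix(d_pred, ncol = 1))
      grads$combine_mlp <- bc$grad
      dEr <- bc$dX[, 1]; dEp <- bc$dX[, 2]
    } else {
      dEr <- switch(hcfg$combine_mode, diff = -d_pred, sum = d_pred,
                    mean = d_pred / 2)
      dEp <- switch(hcfg$combine_mode, diff = d_pred, sum = d_pred,
                    mean = d_pred / 2)
    }
    br <- energy_head_bwd(hp$energy_mlp, cache$fr, matrix(dEr[rid_r], ncol = 1))
    bp <- energy_head_bwd(hp$energy_mlp, cache$fp, matrix(dEp[rid_p], ncol = 1))
    grads$energy_mlp <- params_add(br$grad, bp$grad)
    return(list(dXr = br$dX, dXp = bp$dX, grads = grads))
  }
  # M / X
  if (hcfg$graph_mode == "vector") {
    bf <- nn_mlp_bwd(hp$final_mlp, cache$ff, matrix(d_pred, ncol = 1))
    grads$final_mlp <- bf$grad
    ba <- nn_mlp_bwd(hp$atom_mlp, cache$fa, bf$dX[rid_r, , drop = FALSE])
    grads$atom_mlp <- ba$grad
    dXrxn <- ba$dX
  } else {
    be <- energy_head_bwd(hp$energy_mlp, cache$fe, matrix(d_pred[rid_r], ncol = 1))
    grads$energy_mlp <- be$grad
    dXrxn <- be$dX
  }
  cb <- .combine_bwd(hcfg$combine_mode, hp$combine_mlp, cache$cmb$cache,
                     dXrxn, D)
  if (!is.null(cb$grads)) grads$combine_mlp <- cb$grads
  dXr <- cb$dXr
  if (hcfg$mapping_variant == "M") {
    dXp <- matrix(0, nrow(Xp), D)
    dXp[cache$align, ] <- cb$dXp
  } else {
    dXp <- matrix(0, nrow(Xp), D)
    ga <- NULL
    for (r in seq_len(n_rxn)) {
      ir <- which(rid_r == r); ip <- which(rid_p == r)
      ab <- .cross_attention_bwd(Xr[ir, , drop = FALSE],
                                 Xp[ip, , drop = FALSE], hp$attn,
                                 cache$at[[r]], cb$dXp[ir, , drop = FALSE])
      dXr[ir, ] <- dXr[ir, ] + ab$dXr
      dXp[ip, ] <- dXp[ip, ] + ab$dXp
      ga <- params_add(ga, ab$grads)
    }
    grads$attn <- ga
  }
  list(dXr = dXr, dXp = dXp, grads = grads)
}
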