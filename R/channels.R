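# Symmetry-adapted molecular channels: embeddings plus n_conv tensor-product
# convolution layers turning a batched molecular graph into a per-atom local
# representation X.  Forward passes cache everything the analytic backward
# passes need; both variants (invariant l=0-only and equivariant with l=1
# internal features and filters up to l=2) share one code path driven by the
# path table below.

#' Channel (encoder) configuration
#'
#' @param variant `"invariant"` (scalar features and filters only; the
#'   network reduces to a continuous-filter distance-based model) or
#'   `"equivariant"` (internal l=1 features, filters up to l=2).
#' @param n_s scalar (l=0) channel count / embedding size.
#' @param n_v l=1 channel count (equivariant variant only).
#' @param n_conv number of convolution layers (2 or 3 in the search space).
#' @param dropout dropout probability on scalar channels after each layer.
#' @param sum_mode `"node"` (X is the final scalar node block) or `"both"`
#'   (scalar node block concatenated with mean-pooled incident edge
#'   embeddings).
#' @return object of class `channel_config`.
#' @export
channel_config <- function(variant = c("invariant", "equivariant"),
                           n_s = 32L, n_v = 16L, n_conv = 3L,
                           dropout = 0, sum_mode = c("node", "both"),
                           aggregation = c("sumnorm", "mean")) {
  variant <- match.arg(variant)
  sum_mode <- match.arg(sum_mode)
  aggregation <- match.arg(aggregation)
  stopifnot(n_conv >= 1, dropout >= 0, dropout < 1)
  structure(list(variant = variant, n_s = as.integer(n_s),
                 n_v = as.integer(n_v), n_conv = as.integer(n_conv),
                 dropout = dropout, sum_mode = sum_mode,
                 aggregation = aggregation),
            class = "channel_config")
}

# Message aggregation scaling per receiving node.  "sumnorm" divides the
# message sum by a fixed constant (sqrt of a typical neighbor count), which
# keeps activations O(1) while preserving neighbor-count information —
# additive per-atom targets depend on counts, which a per-node mean erases.
# "mean" (divide by the in-degree) is available for comparison.
.AGG_CONST <- sqrt(10)

agg_inv_scale <- function(ccfg, deg) {
  if (identical(ccfg$aggregation, "mean")) {
    ifelse(deg > 0, 1 / deg, 0)
  } else {
    rep(1 / .AGG_CONST, length(deg))
  }
}

# Required l_max of the spherical filters for a channel config.
channel_l_max <- function(ccfg) if (ccfg$variant == "equivariant") 2L else 0L

# Representation width D of the local representation X.
local_rep_dim <- function(ccfg, gcfg) {
  ccfg$n_s + if (ccfg$sum_mode == "both") gcfg$n_g else 0L
}

# Path table for one layer: every (l_in, l_f, l_out) combination allowed by
# the triangle inequality between the input irreps, filter degrees and output
# degrees, channelwise (multiplicity carried over from the input block).
conv_paths <- function(in_degs, in_muls, l_max, out_degs) {
  rows <- list()
  for (k in seq_along(in_degs)) {
    for (lf in 0:l_max) {
      for (lo in out_degs) {
        li <- in_degs[k]
        if (lo >= abs(li - lf) && lo <= li + lf) {
          rows[[length(rows) + 1L]] <-
            data.frame(l_in = li, l_f = lf, l_out = lo, mul = in_muls[k])
        }
      }
    }
  }
  p <- do.call(rbind, rows)
  p$w_off <- cumsum(c(0L, p$mul[-nrow(p)]))
  p
}

# column indices of m-th component block for a degree-l feature matrix
.blk <- function(m, mul) (m - 1L) * mul + seq_len(mul)

# Precompiled per-layer path plan: plain lists with cached Clebsch-Gordan
# entry matrices, so the conv inner loops do no data.frame work.
.plan_cache <- new.env(parent = emptyenv())

conv_plan <- function(paths) {
  key <- paste(paths$l_in, paths$l_f, paths$l_out, paths$mul, paths$w_off,
               collapse = "|")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  plan <- lapply(seq_len(nrow(paths)), function(i) {
    p <- as.list(paths[i, ])
    ent <- cg_entries(p$l_in, p$l_f, p$l_out)
    list(l_in = p$l_in, l_f = p$l_f, l_out = p$l_out, mul = p$mul,
         w_off = p$w_off, d3 = 2L * p$l_out + 1L,
         scalar_path = p$l_in == 0L && p$l_f == 0L && p$l_out == 0L,
         sph_cols = .sph_cols(p$l_f),
         ent = as.matrix(ent[, c("m1", "m2", "m3")]),
         cg = ent$c)
  })
  .plan_cache[[key]] <- plan
  plan
}

# sph filter column range for degree l (layout of sph_harmonics)
.sph_cols <- function(l) (l^2 + 1L):((l + 1L)^2)

#' @keywords internal
init_encoder <- function(gcfg, ccfg) {
  out_degs <- if (ccfg$variant == "equivariant") c(0L, 1L) else 0L
  layers <- vector("list", ccfg$n_conv)
  for (i in seq_len(ccfg$n_conv)) {
    in_degs <- if (i == 1L || ccfg$variant == "invariant") 0L else c(0L, 1L)
    in_muls <- if (length(in_degs) == 2L) c(ccfg$n_s, ccfg$n_v) else ccfg$n_s
    paths <- conv_paths(in_degs, in_muls, channel_l_max(ccfg), out_degs)
    tot0 <- sum(paths$mul[paths$l_out == 0L])
    tot1 <- sum(paths$mul[paths$l_out == 1L])
    lp <- list(
      edge_mlp = nn_init_mlp(gcfg$n_g, gcfg$n_g, sum(paths$mul)),
      mix0 = nn_init_linear(tot0, ccfg$n_s),
      self0 = nn_init_linear(ccfg$n_s, ccfg$n_s, bias = FALSE)
    )
    if (tot1 > 0L) {
      lp$mix1 <- nn_init_linear(tot1, ccfg$n_v, bias = FALSE)
      if (1L %in% in_degs) lp$self1 <- nn_init_linear(ccfg$n_v, ccfg$n_v, bias = FALSE)
      lp$gate <- nn_init_linear(ccfg$n_s, ccfg$n_v)
    }
    layers[[i]] <- lp
  }
  list(
    node_embed = nn_init_linear(16L, ccfg$n_s),
    edge_embed = nn_init_linear(gcfg$n_g, gcfg$n_g),
    layers = layers
  )
}

# ---- single convolution layer ----------------------------------------------

conv_layer_fwd <- function(lp, feats, e, batch, ccfg, paths, n,
                           train = FALSE) {
  E <- length(batch$src)
  deg <- tabulate(batch$dst, nbins = n)
  inv_deg <- agg_inv_scale(ccfg, deg)
  wfw <- nn_mlp_fwd(lp$edge_mlp, e)
  W <- wfw$out                       # E x sum(mul)
  plan <- conv_plan(paths)
  lo <- vapply(plan, function(p) p$l_out, 1L)
  muls <- vapply(plan, function(p) p$mul, 1L)
  tot0 <- sum(muls[lo == 0L])
  tot1 <- sum(muls[lo == 1L])
  msg0 <- matrix(0, E, tot0)
  msg1 <- if (tot1) matrix(0, E, 3L * tot1) else NULL
  tp_cache <- vector("list", length(plan))
  off0 <- 0L; off1 <- 0L
  pos0 <- integer(length(plan)); pos1 <- integer(length(plan))
  for (pidx in seq_along(plan)) {
    p <- plan[[pidx]]
    mul <- p$mul
    Xin <- if (p$l_in == 0L) feats$l0 else feats$l1
    Xs <- Xin[batch$src, , drop = FALSE]
    d3 <- p$d3
    if (p$scalar_path) {
      tp <- Xs
      Z <- NULL
    } else {
      Z <- batch$sph[, p$sph_cols, drop = FALSE]
      tp <- matrix(0, E, d3 * mul)
      for (r in seq_along(p$cg)) {
        m1 <- p$ent[r, 1L]; m2 <- p$ent[r, 2L]; m3 <- p$ent[r, 3L]
        tp[, .blk(m3, mul)] <- tp[, .blk(m3, mul)] +
          p$cg[r] * Xs[, .blk(m1, mul), drop = FALSE] * Z[, m2]
      }
    }
    w <- W[, p$w_off + seq_len(mul), drop = FALSE]
    wm <- tp * 0
    for (m in seq_len(d3)) wm[, .blk(m, mul)] <- tp[, .blk(m, mul)] * w
    tp_cache[[pidx]] <- list(tp = tp, Xs = Xs, Z = Z, w = w)
    if (p$l_out == 0L) {
      pos0[pidx] <- off0
      msg0[, off0 + seq_len(mul)] <- wm
      off0 <- off0 + mul
    } else {
      pos1[pidx] <- off1
      for (m in 1:3) {
        msg1[, (m - 1L) * tot1 + off1 + seq_len(mul)] <- wm[, .blk(m, mul)]
      }
      off1 <- off1 + mul
    }
  }
  agg0 <- scatter_sum(msg0, batch$dst, n) * inv_deg
  out0_pre <- agg0 %*% lp$mix0$W + feats$l0 %*% lp$self0$W
  out0_pre <- add_bias(out0_pre, lp$mix0$b)
  act0 <- silu(out0_pre)
  mask <- NULL
  if (train && ccfg$dropout > 0) {
    mask <- matrix(stats::rbinom(length(act0), 1, 1 - ccfg$dropout),
                   nrow(act0)) / (1 - ccfg$dropout)
    act0 <- act0 * mask
  }
  out <- list(l0 = act0, l1 = NULL)
  gates <- NULL; out1_pre <- NULL; agg1 <- NULL
  if (tot1) {
    agg1 <- scatter_sum(msg1, batch$dst, n) * inv_deg
    nv <- ccfg$n_v
    out1_pre <- matrix(0, n, 3L * nv)
    for (m in 1:3) {
      blk_in <- (m - 1L) * tot1 + seq_len(tot1)
      out1_pre[, .blk(m, nv)] <- agg1[, blk_in, drop = FALSE] %*% lp$mix1$W
      if (!is.null(lp$self1)) {
        out1_pre[, .blk(m, nv)] <- out1_pre[, .blk(m, nv)] +
          feats$l1[, .blk(m, nv), drop = FALSE] %*% lp$self1$W
      }
    }
    gates_pre <- add_bias(out0_pre %*% lp$gate$W, lp$gate$b)
    gates <- sigmoid(gates_pre)
    out$l1 <- out1_pre
    for (m in 1:3) out$l1[, .blk(m, nv)] <- out$l1[, .blk(m, nv)] * gates
  }
  list(out = out,
       cache = list(feats = feats, W = W, wfw = wfw, tp = tp_cache,
                    msg_dims = c(tot0 = tot0, tot1 = tot1),
                    pos0 = pos0, pos1 = pos1,
                    agg0 = agg0, agg1 = agg1, out0_pre = out0_pre,
                    out1_pre = out1_pre, gates = gates, mask = mask,
                    inv_deg = inv_deg, plan = plan, n = n))
}

conv_layer_bwd <- function(lp, cache, batch, ccfg, d_out0, d_out1) {
  n <- cache$n
  plan <- cache$plan
  tot0 <- cache$msg_dims[["tot0"]]; tot1 <- cache$msg_dims[["tot1"]]
  grads <- list()
  d_out0_pre <- NULL
  d_feats <- list(l0 = NULL, l1 = NULL)
  nv <- ccfg$n_v
  d_agg1 <- NULL
  if (tot1) {
    if (is.null(d_out1)) d_out1 <- matrix(0, n, 3L * nv)
    gates <- cache$gates
    d_out1_pre <- d_out1
    d_gates <- matrix(0, n, nv)
    for (m in 1:3) {
      d_out1_pre[, .blk(m, nv)] <- d_out1[, .blk(m, nv)] * gates
      d_gates <- d_gates + d_out1[, .blk(m, nv)] * cache$out1_pre[, .blk(m, nv)]
    }
    d_gates_pre <- d_gates * gates * (1 - gates)
    grads$gate <- list(W = crossprod(cache$out0_pre, d_gates_pre),
                       b = colSums(d_gates_pre))
    d_out0_pre <- d_gates_pre %*% t(lp$gate$W)
    # l1 mixing backward
    d_agg1 <- matrix(0, n, 3L * tot1)
    gW1 <- matrix(0, tot1, nv)
    gS1 <- if (!is.null(lp$self1)) matrix(0, nv, nv) else NULL
    d_feats$l1 <- if (!is.null(lp$self1)) matrix(0, n, 3L * nv) else NULL
    for (m in 1:3) {
      blk_in <- (m - 1L) * tot1 + seq_len(tot1)
      d_agg1[, blk_in] <- d_out1_pre[, .blk(m, nv), drop = FALSE] %*% t(lp$mix1$W)
      gW1 <- gW1 + crossprod(cache$agg1[, blk_in, drop = FALSE],
                             d_out1_pre[, .blk(m, nv), drop = FALSE])
      if (!is.null(lp$self1)) {
        gS1 <- gS1 + crossprod(cache$feats$l1[, .blk(m, nv), drop = FALSE],
                               d_out1_pre[, .blk(m, nv), drop = FALSE])
        d_feats$l1[, .blk(m, nv)] <- d_out1_pre[, .blk(m, nv), drop = FALSE] %*%
          t(lp$self1$W)
      }
    }
    grads$mix1 <- list(W = gW1, b = NULL)
    if (!is.null(gS1)) grads$self1 <- list(W = gS1, b = NULL)
  }
  d_act0 <- d_out0
  if (!is.null(cache$mask)) d_act0 <- d_act0 * cache$mask
  d0 <- d_act0 * silu_grad(cache$out0_pre)
  d_out0_pre <- if (is.null(d_out0_pre)) d0 else d_out0_pre + d0
  grads$mix0 <- list(W = crossprod(cache$agg0, d_out0_pre),
                     b = colSums(d_out0_pre))
  grads$self0 <- list(W = crossprod(cache$feats$l0, d_out0_pre), b = NULL)
  d_feats$l0 <- d_out0_pre %*% t(lp$self0$W)
  d_agg0 <- d_out0_pre %*% t(lp$mix0$W)

  # aggregation backward: gather to edges with the mean scaling
  sc <- cache$inv_deg[batch$dst]
  d_msg0 <- d_agg0[batch$dst, , drop = FALSE] * sc
  d_msg1 <- if (tot1) d_agg1[batch$dst, , drop = FALSE] * sc else NULL

  dW <- matrix(0, length(batch$src), ncol(cache$W))
  for (pidx in seq_along(plan)) {
    p <- plan[[pidx]]
    mul <- p$mul
    d3 <- p$d3
    pc <- cache$tp[[pidx]]
    if (p$l_out == 0L) {
      d_wm <- d_msg0[, cache$pos0[pidx] + seq_len(mul), drop = FALSE]
    } else {
      d_wm <- matrix(0, length(batch$src), d3 * mul)
      for (m in 1:3) {
        d_wm[, .blk(m, mul)] <-
          d_msg1[, (m - 1L) * tot1 + cache$pos1[pidx] + seq_len(mul), drop = FALSE]
      }
    }
    # wm = tp * w (per m-block): backward to both factors
    d_w <- matrix(0, length(batch$src), mul)
    d_tp <- d_wm
    for (m in seq_len(d3)) {
      d_w <- d_w + d_wm[, .blk(m, mul), drop = FALSE] * pc$tp[, .blk(m, mul), drop = FALSE]
      d_tp[, .blk(m, mul)] <- d_wm[, .blk(m, mul), drop = FALSE] * pc$w
    }
    dW[, p$w_off + seq_len(mul)] <- d_w
    # tp backward to the gathered source features
    if (p$scalar_path) {
      d_Xs <- d_tp
    } else {
      d_Xs <- matrix(0, nrow(pc$Xs), ncol(pc$Xs))
      for (r in seq_along(p$cg)) {
        m1 <- p$ent[r, 1L]; m2 <- p$ent[r, 2L]; m3 <- p$ent[r, 3L]
        d_Xs[, .blk(m1, mul)] <- d_Xs[, .blk(m1, mul)] +
          p$cg[r] * d_tp[, .blk(m3, mul), drop = FALSE] * pc$Z[, m2]
      }
    }
    tgt <- if (p$l_in == 0L) "l0" else "l1"
    add <- scatter_sum(d_Xs, batch$src, n)
    d_feats[[tgt]] <- if (is.null(d_feats[[tgt]])) add else d_feats[[tgt]] + add
  }
  mb <- nn_mlp_bwd(lp$edge_mlp, cache$wfw, dW)
  grads$edge_mlp <- mb$grad
  list(d_feats = d_feats, d_e = mb$dX, grads = grads)
}

# ---- full encoder -----------------------------------------------------------

# Forward over a batched graph; returns local representation X (N x D) and a
# cache for encode_bwd.
encode_fwd <- function(enc, batch, gcfg, ccfg, train = FALSE) {
  nf <- nn_linear_fwd(enc$node_embed, batch$node_feats0)
  x0 <- silu(nf$out)
  ef <- nn_linear_fwd(enc$edge_embed, batch$edge_feats0)
  e <- silu(ef$out)
  feats <- list(l0 = x0, l1 = NULL)
  n <- batch$n
  lcaches <- vector("list", ccfg$n_conv)
  lpaths <- vector("list", ccfg$n_conv)
  for (i in seq_len(ccfg$n_conv)) {
    in_degs <- if (is.null(feats$l1)) 0L else c(0L, 1L)
    in_muls <- if (length(in_degs) == 2L) c(ccfg$n_s, ccfg$n_v) else ccfg$n_s
    out_degs <- if (ccfg$variant == "equivariant") c(0L, 1L) else 0L
    paths <- conv_paths(in_degs, in_muls, channel_l_max(ccfg), out_degs)
    cf <- conv_layer_fwd(enc$layers[[i]], feats, e, batch, ccfg, paths, n, train)
    feats <- cf$out
    lcaches[[i]] <- cf$cache
    lpaths[[i]] <- paths
  }
  pool <- NULL; inv_deg_pool <- NULL
  X <- feats$l0
  if (ccfg$sum_mode == "both") {
    deg <- tabulate(batch$dst, nbins = n)
    inv_deg_pool <- agg_inv_scale(ccfg, deg)
    pool <- scatter_sum(e, batch$dst, n) * inv_deg_pool
    X <- cbind(feats$l0, pool)
  }
  list(X = X, feats = feats,
       cache = list(nf = nf, ef = ef, x0 = x0, e = e, lcaches = lcaches,
                    inv_deg_pool = inv_deg_pool, n = n))
}

# Backward from dX (N x D); returns encoder parameter gradients.
encode_bwd <- function(enc, cache, batch, gcfg, ccfg, dX,
                       d_feats_extra = NULL) {
  n <- cache$n
  grads <- list(layers = vector("list", ccfg$n_conv))
  if (ccfg$sum_mode == "both") {
    d_l0 <- dX[, seq_len(ccfg$n_s), drop = FALSE]
    d_pool <- dX[, ccfg$n_s + seq_len(ncol(cache$e)), drop = FALSE]
    d_e <- d_pool[batch$dst, , drop = FALSE] * cache$inv_deg_pool[batch$dst]
  } else {
    d_l0 <- dX
    d_e <- matrix(0, length(batch$src), ncol(cache$e))
  }
  d_feats <- list(l0 = d_l0, l1 = NULL)
  if (!is.null(d_feats_extra)) {
    d_feats$l0 <- d_feats$l0 + d_feats_extra$l0
    d_feats$l1 <- d_feats_extra$l1
  }
  for (i in rev(seq_len(ccfg$n_conv))) {
    cb <- conv_layer_bwd(enc$layers[[i]], cache$lcaches[[i]], batch, ccfg,
                         d_feats$l0, d_feats$l1)
    grads$layers[[i]] <- cb$grads
    d_feats <- cb$d_feats
    d_e <- d_e + cb$d_e
  }
  # embeddings
  d_x0pre <- d_feats$l0 * silu_grad(cache$nf$out)
  nb <- nn_linear_bwd(enc$node_embed, cache$nf, d_x0pre)
  grads$node_embed <- nb$grad
  d_epre <- d_e * silu_grad(cache$ef$out)
  eb <- nn_linear_bwd(enc$edge_embed, cache$ef, d_epre)
  grads$edge_embed <- eb$grad
  grads
}
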