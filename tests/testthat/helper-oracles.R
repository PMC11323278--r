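# Independent oracles used across the test suite.  These deliberately share
# no code with the implementation paths they check.

# Optimal rigid superposition residual (Kabsch, including reflections when
# allow_reflection) minimized over all atom correspondences of like elements.
# Returns the smallest RMSD over correspondences; > threshold means the two
# structures are not congruent.
best_superposition_rmsd <- function(m1, m2, allow_reflection = TRUE) {
  stopifnot(length(m1$elements) == length(m2$elements))
  n <- length(m1$elements)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  kabsch_rmsd <- function(A, B, reflect) {
    A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
    s <- svd(t(B) %*% A)
    d <- sign(det(s$u %*% t(s$v)))
    if (!reflect && d < 0) {
      s$u[, 3] <- -s$u[, 3]
    }
    R <- s$u %*% t(s$v)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    if (!identical(m1$elements, m2$elements[p])) next
    for (refl in if (allow_reflection) c(FALSE, TRUE) else FALSE) {
      best <- min(best, kabsch_rmsd(m1$coords, m2$coords[p, , drop = FALSE], refl))
    }
  }
  best
}

# Brute-force tensor-product convolution layer: explicit scalar loops over
# edges, paths, Clebsch-Gordan entries and channels, then dense linear
# algebra for the mixing/self-interaction/gate stage written directly from
# the layer definition.  Used as the oracle for the vectorized conv layer.
ref_conv_layer <- function(lp, feats, e, batch, ccfg, paths) {
  n <- nrow(feats$l0)
  E <- length(batch$src)
  W <- e
  for (i in seq_along(lp$edge_mlp)) {
    W <- W %*% lp$edge_mlp[[i]]$W
    W <- W + matrix(lp$edge_mlp[[i]]$b, nrow(W), length(lp$edge_mlp[[i]]$b),
                    byrow = TRUE)
    if (i < length(lp$edge_mlp)) W <- W / (1 + exp(-W))  # silu
  }
  tot0 <- sum(paths$mul[paths$l_out == 0L])
  tot1 <- sum(paths$mul[paths$l_out == 1L])
  agg0 <- matrix(0, n, tot0)
  agg1 <- if (tot1) matrix(0, n, 3L * tot1) else NULL
  deg <- tabulate(batch$dst, nbins = n)
  scale_of <- function(a) {
    if (identical(ccfg$aggregation, "mean")) 1 / deg[a] else 1 / sqrt(10)
  }
  for (ed in seq_len(E)) {
    a <- batch$dst[ed]; b <- batch$src[ed]
    off0 <- 0L; off1 <- 0L
    for (pidx in seq_len(nrow(paths))) {
      p <- paths[pidx, ]
      C <- rxn3d::cg_real(p$l_in, p$l_f, p$l_out)
      d1 <- 2L * p$l_in + 1L; d3 <- 2L * p$l_out + 1L
      Xin <- if (p$l_in == 0L) feats$l0 else feats$l1
      for (ch in seq_len(p$mul)) {
        w <- W[ed, p$w_off + ch]
        for (m3 in seq_len(d3)) {
          acc <- 0
          for (m1 in seq_len(d1)) {
            for (m2 in seq_len(2L * p$l_f + 1L)) {
              z <- batch$sph[ed, p$l_f^2 + m2]
              acc <- acc + C[m1, m2, m3] * Xin[b, (m1 - 1L) * p$mul + ch] * z
            }
          }
          msg <- w * acc * scale_of(a)
          if (p$l_out == 0L) {
            agg0[a, off0 + ch] <- agg0[a, off0 + ch] + msg
          } else {
            agg1[a, (m3 - 1L) * tot1 + off1 + ch] <-
              agg1[a, (m3 - 1L) * tot1 + off1 + ch] + msg
          }
        }
      }
      if (p$l_out == 0L) off0 <- off0 + p$mul else off1 <- off1 + p$mul
    }
  }
  out0_pre <- agg0 %*% lp$mix0$W + feats$l0 %*% lp$self0$W
  out0_pre <- out0_pre + matrix(lp$mix0$b, n, length(lp$mix0$b), byrow = TRUE)
  out0 <- out0_pre / (1 + exp(-out0_pre))
  out <- list(l0 = out0, l1 = NULL)
  if (tot1) {
    nv <- ccfg$n_v
    out1 <- matrix(0, n, 3L * nv)
    for (m in 1:3) {
      blk_in <- (m - 1L) * tot1 + seq_len(tot1)
      out1[, (m - 1L) * nv + seq_len(nv)] <-
        agg1[, blk_in, drop = FALSE] %*% lp$mix1$W
      if (!is.null(lp$self1)) {
        out1[, (m - 1L) * nv + seq_len(nv)] <-
          out1[, (m - 1L) * nv + seq_len(nv)] +
          feats$l1[, (m - 1L) * nv + seq_len(nv), drop = FALSE] %*% lp$self1$W
      }
    }
    gpre <- out0_pre %*% lp$gate$W +
      matrix(lp$gate$b, n, length(lp$gate$b), byrow = TRUE)
    gate <- 1 / (1 + exp(-gpre))
    for (m in 1:3) {
      out1[, (m - 1L) * nv + seq_len(nv)] <-
        out1[, (m - 1L) * nv + seq_len(nv)] * gate
    }
    out$l1 <- out1
  }
  out
}

# Run a python RDKit snippet and return its parsed JSON output, as an
# independent cheminformatics oracle.
rdkit_oracle <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  }
  jsonlite::fromJSON(paste(out, collapse = "\n"))
}

# silu nonlinearity, written out independently for expected-value arithmetic
silu <- function(x) x / (1 + exp(-x))

# Random small molecule for property-style loops.
random_test_molecule <- function(n, elements = c("C", "N", "O")) {
  repeat {
    coords <- matrix(stats::rnorm(3 * n, sd = 1.6), n, 3)
    if (n == 1 || min(stats::dist(coords)) > 0.9) break
  }
  molecule3d(sample(elements, n, replace = TRUE), coords)
}

# Tiny model helper with small widths for fast exact checks.
small_model <- function(variant = "invariant", mapping = "S",
                        combine = "diff", graph_mode = "energy",
                        n_s = 6L, n_v = 4L, n_conv = 2L, n_g = 8L,
                        sum_mode = "node", seed = 7) {
  withr::with_seed(seed, rxn3d_model(
    graph_config(r_max = 5, n_g = n_g,
                 l_max = if (variant == "equivariant") 2L else 0L),
    channel_config(variant, n_s = n_s, n_v = n_v, n_conv = n_conv,
                   sum_mode = sum_mode),
    head_config(mapping, combine, graph_mode)))
}
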