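make_batch <- function(mols, gcfg) {
  rxn3d:::batch_graphs(lapply(mols, mol_graph, cfg = gcfg))
}

test_that("embeddings are a pure function of the descriptors", {
  withr::local_seed(31)
  gcfg <- graph_config(n_g = 8, exclude_h = FALSE)
  ccfg <- channel_config("invariant", n_s = 12, n_conv = 1)
  enc <- rxn3d:::init_encoder(gcfg, ccfg)
  # two atoms with identical descriptor rows embed identically
  X <- rbind(c(6, 0, 1, 0, 0, 0, 3, 0, 3, 0, rep(0, 6)),
             c(6, 0, 1, 0, 0, 0, 3, 0, 3, 0, rep(0, 6)))
  out <- silu(X %*% enc$node_embed$W + rep(enc$node_embed$b, each = 2))
  expect_equal(out[1, ], out[2, ])
  expect_equal(ncol(out), 12L)
  # all-zero weights: embedding equals the bias everywhere
  enc$node_embed$W[] <- 0
  out0 <- X %*% enc$node_embed$W + rep(enc$node_embed$b, each = 2)
  expect_equal(out0[1, ], enc$node_embed$b)
})

test_that("conv layer matches the brute-force Clebsch-Gordan path sum", {
  withr::local_seed(32)
  for (variant in c("invariant", "equivariant")) {
    gcfg <- graph_config(r_max = 5, n_g = 6, exclude_h = FALSE,
                         l_max = if (variant == "equivariant") 2L else 0L)
    ccfg <- channel_config(variant, n_s = 2, n_v = 2, n_conv = 2)
    enc <- rxn3d:::init_encoder(gcfg, ccfg)
    mol <- random_test_molecule(3)
    batch <- make_batch(list(mol), gcfg)
    ef <- rxn3d:::encode_fwd(enc, batch, gcfg, ccfg)
    # check layer 2 (whose input carries l=1 structure in equivariant mode)
    feats_in <- ef$cache$lcaches[[2]]$feats
    paths <- rxn3d:::conv_paths(
      if (is.null(feats_in$l1)) 0L else c(0L, 1L),
      if (is.null(feats_in$l1)) ccfg$n_s else c(ccfg$n_s, ccfg$n_v),
      rxn3d:::channel_l_max(ccfg),
      if (variant == "equivariant") c(0L, 1L) else 0L)
    got <- rxn3d:::conv_layer_fwd(enc$layers[[2]], feats_in, ef$cache$e,
                                  batch, ccfg, paths, batch$n)
    want <- ref_conv_layer(enc$layers[[2]], feats_in, ef$cache$e,
                           batch, ccfg, paths)
    expect_lt(max(abs(got$out$l0 - want$l0)), 1e-6)
    if (variant == "equivariant") {
      expect_lt(max(abs(got$out$l1 - want$l1)), 1e-6)
    }
  }
})

test_that("invariant features ignore rotations; equivariant ones transform", {
  withr::local_seed(33)
  mol <- random_test_molecule(5)
  R <- random_rotation()
  rotated <- mol
  rotated$coords <- mol$coords %*% t(R) + rep(1, 5) %o% c(1, -2, 0.5)

  for (variant in c("invariant", "equivariant")) {
    gcfg <- graph_config(r_max = 5, n_g = 8, exclude_h = FALSE,
                         l_max = if (variant == "equivariant") 2L else 0L)
    ccfg <- channel_config(variant, n_s = 6, n_v = 4, n_conv = 2)
    enc <- withr::with_seed(5, rxn3d:::init_encoder(gcfg, ccfg))
    f1 <- rxn3d:::encode_fwd(enc, make_batch(list(mol), gcfg), gcfg, ccfg)
    f2 <- rxn3d:::encode_fwd(enc, make_batch(list(rotated), gcfg), gcfg, ccfg)
    expect_lt(max(abs(f1$X - f2$X)), 1e-6)   # scalar output invariant
    if (variant == "equivariant") {
      nv <- ccfg$n_v
      for (ch in seq_len(nv)) {
        va <- f1$feats$l1[, ch + nv * (0:2)]
        vb <- f2$feats$l1[, ch + nv * (0:2)]
        expect_lt(max(abs(vb - va %*% t(R))), 1e-5)
      }
    }
  }
})

test_that("a node with no edges reduces to its self-interaction", {
  withr::local_seed(34)
  gcfg <- graph_config(r_max = 2.5, n_g = 8, exclude_h = FALSE)
  ccfg <- channel_config("invariant", n_s = 6, n_conv = 1)
  enc <- rxn3d:::init_encoder(gcfg, ccfg)
  lone <- molecule3d("He", matrix(0, 1, 3))
  batch <- make_batch(list(lone), gcfg)
  f <- rxn3d:::encode_fwd(enc, batch, gcfg, ccfg)
  x1 <- silu(batch$node_feats0 %*% enc$node_embed$W +
             rep(enc$node_embed$b, each = 1))
  want <- silu(x1 %*% enc$layers[[1]]$self0$W +
               rep(enc$layers[[1]]$mix0$b, each = 1))
  expect_equal(f$X, want, tolerance = 1e-10)
})

test_that("local representation modes have the documented shapes", {
  withr::local_seed(35)
  mol <- random_test_molecule(4)
  for (sm in c("node", "both")) {
    gcfg <- graph_config(r_max = 5, n_g = 8, exclude_h = FALSE)
    ccfg <- channel_config("invariant", n_s = 6, n_conv = 2, sum_mode = sm)
    enc <- rxn3d:::init_encoder(gcfg, ccfg)
    f <- rxn3d:::encode_fwd(enc, make_batch(list(mol), gcfg), gcfg, ccfg)
    expect_equal(ncol(f$X), rxn3d:::local_rep_dim(ccfg, gcfg))
    expect_equal(nrow(f$X), 4L)
  }
  # both mode on an edgeless graph: pooled edge block is zeros
  lone <- molecule3d("He", matrix(0, 1, 3))
  gcfg <- graph_config(r_max = 2.5, n_g = 8, exclude_h = FALSE)
  ccfg <- channel_config("invariant", n_s = 6, n_conv = 1, sum_mode = "both")
  enc <- rxn3d:::init_encoder(gcfg, ccfg)
  f <- rxn3d:::encode_fwd(enc, make_batch(list(lone), gcfg), gcfg, ccfg)
  expect_true(all(f$X[, 7:14] == 0))

  # permuting atoms permutes rows of X identically
  gcfg2 <- graph_config(r_max = 5, n_g = 8, exclude_h = FALSE)
  ccfg2 <- channel_config("invariant", n_s = 6, n_conv = 2)
  enc2 <- rxn3d:::init_encoder(gcfg2, ccfg2)
  perm <- c(3, 1, 4, 2)
  mp <- molecule3d(mol$elements[perm], mol$coords[perm, ])
  fa <- rxn3d:::encode_fwd(enc2, make_batch(list(mol), gcfg2), gcfg2, ccfg2)
  fb <- rxn3d:::encode_fwd(enc2, make_batch(list(mp), gcfg2), gcfg2, ccfg2)
  expect_equal(fb$X, fa$X[perm, ], tolerance = 1e-10)
})
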