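test_that("mapping reorder is exact and rejects unbalanced reactions", {
  X <- matrix(1:8, 4, 2)
  expect_identical(reorder_by_mapping(X, 1:4), X)
  expect_identical(reorder_by_mapping(X[1:2, ], c(2L, 1L)), X[c(2, 1), ])
  expect_error(reorder_by_mapping(X[1:2, ], 1:3), "unbalanced")
  expect_error(reorder_by_mapping(X, c(1L, 1L, 2L, 3L)), "bijection")
})

test_that("cross-attention is row-stochastic with the right limits", {
  withr::local_seed(41)
  D <- 5
  attn <- list(Wq = matrix(rnorm(D * D), D), Wk = matrix(rnorm(D * D), D),
               Wv = matrix(rnorm(D * D), D))
  Xr <- matrix(rnorm(3 * D), 3, D)
  # single product atom: every output row equals its value vector
  Xp1 <- matrix(rnorm(D), 1, D)
  ca <- cross_attention_align(Xr, Xp1, attn)
  for (i in 1:3) expect_equal(ca$aligned[i, ], as.numeric(Xp1 %*% attn$Wv))
  # rows always sum to one
  Xp <- matrix(rnorm(4 * D), 4, D)
  ca2 <- cross_attention_align(Xr, Xp, attn)
  expect_equal(unname(rowSums(ca2$A)), rep(1, 3), tolerance = 1e-6)
  # identical product features: output is their average, independent of query
  Xp_same <- matrix(rep(rnorm(D), each = 2), 2, D)
  ca3 <- cross_attention_align(Xr, Xp_same, attn)
  avg <- colMeans(Xp_same %*% attn$Wv)
  for (i in 1:3) expect_equal(ca3$aligned[i, ], avg)
  expect_error(cross_attention_align(Xr, Xp[0, , drop = FALSE], attn), "empty")
})

test_that("combine modes satisfy their arithmetic identities", {
  withr::local_seed(42)
  A <- matrix(rnorm(12), 4, 3)
  B <- matrix(rnorm(12), 4, 3)
  expect_equal(combine_local(A, A, "diff")$X_rxn, matrix(0, 4, 3))
  expect_equal(combine_local(A, B, "sum")$X_rxn,
               2 * combine_local(A, B, "mean")$X_rxn)
  expect_equal(combine_local(A, B, "diff")$X_rxn,
               -combine_local(B, A, "diff")$X_rxn)
  expect_error(combine_local(A, B[1:2, ], "diff"), "dim")
})

test_that("readouts are permutation invariant and additive", {
  withr::local_seed(43)
  m <- small_model(mapping = "M", graph_mode = "vector", combine = "diff")
  mol_r <- random_test_molecule(5)
  mol_p <- random_test_molecule(5)
  rec <- reaction_record(list(mol_r), list(mol_p), "True", atom_map = 1:5,
                         target = 0, id = "x")
  p0 <- predict_reactions(m, list(rec))
  # jointly relabel mapped atoms: predictions unchanged
  perm <- c(4, 2, 5, 1, 3)
  rec2 <- reaction_record(
    list(molecule3d(mol_r$elements[perm], mol_r$coords[perm, ])),
    list(molecule3d(mol_p$elements[perm], mol_p$coords[perm, ])),
    "True", atom_map = order(perm)[perm][order(1:5)] * 0 + match(1:5, perm)[perm],
    target = 0, id = "x2")
  # simpler: permute both sides identically, map i -> same position
  rec2 <- reaction_record(
    list(molecule3d(mol_r$elements[perm], mol_r$coords[perm, ])),
    list(molecule3d(mol_p$elements[perm], mol_p$coords[perm, ])),
    "True", atom_map = 1:5, target = 0, id = "x2")
  expect_equal(predict_reactions(m, list(rec2)), p0, tolerance = 1e-6)

  # doubling the reaction doubles the pooled reaction vector
  rec_dbl <- reaction_record(list(mol_r, mol_r), list(mol_p, mol_p), "True",
                             atom_map = c(1:5, 6:10), target = 0, id = "dbl")
  prep1 <- prepare_reactions(list(rec), m$gcfg, need_map = TRUE)
  prep2 <- prepare_reactions(list(rec_dbl), m$gcfg, need_map = TRUE)
  b1 <- rxn3d:::assemble_batch(prep1)
  b2 <- rxn3d:::assemble_batch(prep2)
  f1 <- rxn3d:::model_fwd(m, b1)
  f2 <- rxn3d:::model_fwd(m, b2)
  expect_equal(f2$hcache$G, 2 * f1$hcache$G, tolerance = 1e-8)
})

test_that("identity reactions give exactly zero in bias-free energy mode", {
  withr::local_seed(44)
  mol <- random_test_molecule(6)
  rec <- reaction_record(list(mol), list(mol), "True",
                         atom_map = seq_len(6), target = 0, id = "ident")
  # M variant, diff combine, energy readout
  mM <- small_model(mapping = "M", combine = "diff", graph_mode = "energy")
  expect_identical(predict_reactions(mM, list(rec)), 0)
  # S variant, diff combine, energy readout
  mS <- small_model(mapping = "S", combine = "diff", graph_mode = "energy")
  expect_identical(predict_reactions(mS, list(rec)), 0)
  # molecule order within a side does not matter for S
  mol2 <- random_test_molecule(4)
  recA <- reaction_record(list(mol, mol2), list(mol, mol2), "None",
                          target = 0, id = "a")
  recB <- reaction_record(list(mol2, mol), list(mol, mol2), "None",
                          target = 0, id = "b")
  expect_equal(predict_reactions(mS, list(recA)),
               predict_reactions(mS, list(recB)), tolerance = 1e-9)
})

test_that("diff combine is antisymmetric through the energy readout", {
  withr::local_seed(45)
  mol_r <- random_test_molecule(5)
  mol_p <- random_test_molecule(5)
  mS <- small_model(mapping = "S", combine = "diff", graph_mode = "energy")
  fwd <- predict_reactions(mS, list(reaction_record(
    list(mol_r), list(mol_p), "None", target = 0, id = "f")))
  rev <- predict_reactions(mS, list(reaction_record(
    list(mol_p), list(mol_r), "None", target = 0, id = "r")))
  expect_equal(fwd, -rev, tolerance = 1e-9)
})
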