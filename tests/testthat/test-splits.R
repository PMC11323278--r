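make_records <- function(n, smiles = NULL, targets = NULL, sizes = NULL) {
  lapply(seq_len(n), function(i) {
    na <- if (is.null(sizes)) 4L else sizes[i]
    mol <- withr::with_seed(1000 + i, random_test_molecule(na))
    if (!is.null(smiles)) mol$source_smiles <- smiles[i]
    reaction_record(list(mol), list(mol), "None",
                    target = if (is.null(targets)) 0 else targets[i],
                    id = paste0("r", i))
  })
}

test_that("random splits are sized, disjoint, exhaustive and reproducible", {
  sp <- split_spec("random", seed = 7)
  part <- random_split(10, sp)
  expect_length(part$train, 8)
  expect_length(part$val, 1)
  expect_length(part$test, 1)
  all_idx <- sort(c(part$train, part$val, part$test))
  expect_identical(all_idx, 1:10)
  expect_identical(random_split(10, sp), part)
  expect_false(identical(random_split(10, split_spec("random", seed = 8)), part))
  expect_error(random_split(2, sp), "at least 3")
})

test_that("scaffold keys capture the ring framework, not the decoration", {
  expect_identical(scaffold_key(parse_xyz("1\n\nHe 0 0 0")), "")
  benzene <- "c1ccccc1"
  toluene <- "Cc1ccccc1"
  pyridine <- "c1ccncc1"
  key <- function(s) {
    mol <- molecule3d("C", matrix(0, 1, 3), source_smiles = s)
    scaffold_key(mol)
  }
  expect_identical(key(benzene), key(toluene))   # side chain pruned
  expect_false(identical(key(benzene), key(pyridine)))  # element-retaining
  expect_false(identical(key(benzene), ""))
})

test_that("scaffold splits never share a scaffold across partitions", {
  smiles <- c(rep("c1ccccc1", 8), rep("c1ccncc1", 5), rep("C1CC1", 4),
              rep("CCC", 3))   # last group acyclic: empty scaffold
  recs <- make_records(20, smiles = smiles)
  sp <- split_spec("scaffold", seed = 3)
  part <- scaffold_split(recs, sp)
  expect_identical(sort(c(part$train, part$val, part$test)), 1:20)
  keys <- vapply(recs, rxn3d:::record_scaffold_key, "")
  for (a in c("train", "val")) {
    for (b in c("val", "test")) {
      if (a == b) next
      expect_length(intersect(keys[part[[a]]], keys[part[[b]]]), 0)
    }
  }
  expect_identical(scaffold_split(recs, sp), part)

  # two scaffolds at 80/20: the large one fills train, no overlap
  smiles2 <- c(rep("c1ccccc1", 16), rep("C1CC1", 4))
  recs2 <- make_records(20, smiles = smiles2)
  part2 <- scaffold_split(recs2, split_spec("scaffold", seed = 1))
  keys2 <- vapply(recs2, rxn3d:::record_scaffold_key, "")
  expect_length(unique(keys2[part2$train]), 1L)
  expect_length(intersect(keys2[part2$train],
                          keys2[c(part2$val, part2$test)]), 0)

  # a scaffold larger than the train capacity is a hard error
  recs3 <- make_records(10, smiles = rep("c1ccccc1", 10))
  expect_error(scaffold_split(recs3, split_spec("scaffold")), "capacity")
})

test_that("size splits order by reactant heavy-atom count", {
  sizes <- c(10L, 3L, 7L, 4L, 9L, 5L, 8L, 2L, 6L, 1L)
  recs <- make_records(10, sizes = sizes)
  part <- size_split(recs, split_spec("size", seed = 2))
  expect_lte(max(sizes[part$train]), min(sizes[part$test]))
  expect_identical(part$test, which(sizes == 10L))  # single largest record
  expect_identical(sort(unname(unlist(part))), 1:10)
  # all-equal sizes reduce to the seeded random assignment
  recs_eq <- make_records(10)
  pa <- size_split(recs_eq, split_spec("size", seed = 5))
  pb <- random_split(10, split_spec("random", seed = 5))
  expect_identical(pa, pb)
  # reverse order puts the largest molecules in train
  prev <- size_split(recs, split_spec("size", seed = 2, reverse = TRUE))
  expect_gte(min(sizes[prev$train]), max(sizes[prev$test]))
})

test_that("property splits train high and test low", {
  targets <- c(5.2, 1.1, 9.8, 3.3, 7.5, 2.2, 8.8, 4.4, 6.6, 0.5)
  recs <- make_records(10, targets = targets)
  part <- property_split(recs, split_spec("property", seed = 2))
  expect_gte(min(targets[part$train]), max(targets[part$test]))
  expect_identical(part$test, which.min(targets))
  expect_identical(sort(unname(unlist(part))), 1:10)
  # constant targets reduce to the seeded random assignment
  recs_c <- make_records(10, targets = rep(1, 10))
  expect_identical(property_split(recs_c, split_spec("property", seed = 9)),
                   random_split(10, split_spec("random", seed = 9)))
})

test_that("fold files enumerate every record exactly once per fold", {
  recs <- make_records(12, targets = stats::rnorm(12))
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- write_splits(recs, split_spec("random", seed = 1), k = 3, path = f)
  expect_equal(nrow(rows), 36)
  back <- utils::read.csv(f)
  for (fold in 1:3) {
    sub <- back[back$fold == fold, ]
    expect_setequal(sub$id, paste0("r", 1:12))
  }
})
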