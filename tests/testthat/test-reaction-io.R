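test_that("xyz parsing handles minimal files and round-trips", {
  he <- parse_xyz("1\n\nHe 0 0 0")
  expect_equal(he$elements, "He")
  expect_equal(he$coords, matrix(0, 1, 3))

  water <- molecule3d(c("O", "H", "H"),
                      rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                            c(0, -0.7572, -0.4692)))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(water, f, comment = "water")
  back <- read_xyz(f)
  expect_identical(back$elements, water$elements)
  expect_equal(back$coords, water$coords, tolerance = 1e-9)
})

test_that("malformed xyz inputs are rejected", {
  expect_error(parse_xyz("3\n\nH 0 0 0\nH 1 0 0"), "3 atoms but only 2")
  expect_error(parse_xyz("1\n\nH 0 zero 0"), "unparsable coordinate")
  expect_error(parse_xyz("1\n\nQq 0 0 0"), "unknown element")
  expect_error(parse_xyz("x\n\nH 0 0 0"), "atom count")
})

test_that("mapped reaction SMILES parse into per-molecule graphs", {
  rx <- parse_mapped_reaction_smiles("[CH4:1]>>[CH4:1]")
  expect_length(rx$reactants, 1)
  expect_length(rx$products, 1)
  expect_true(rx$mapped)
  expect_equal(rx$reactants[[1]]$atoms$map, 1L)
  expect_equal(rx$products[[1]]$atoms$map, 1L)

  rx2 <- parse_mapped_reaction_smiles("CC>>CC")
  expect_false(rx2$mapped)
  expect_true(all(is.na(rx2$reactants[[1]]$atoms$map)))

  expect_error(parse_mapped_reaction_smiles("[CH3:1][CH3:1]>>CC"),
               "duplicate atom-map")
  expect_error(parse_mapped_reaction_smiles("CC"), ">>")
  expect_error(parse_smiles("C(C"), "unmatched")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
})

test_that("multi-molecule mapped reaction agrees with an RDKit oracle", {
  rxn <- "[C:1][C:2].[O:3]>>[C:1][C:2][O:3]"
  rx <- parse_mapped_reaction_smiles(rxn)
  expect_length(rx$reactants, 2)
  expect_length(rx$products, 1)
  expect_equal(rx$reactants[[1]]$atoms$map, c(1L, 2L))
  expect_equal(rx$reactants[[2]]$atoms$map, 3L)
  expect_equal(rx$products[[1]]$atoms$map, c(1L, 2L, 3L))
  expect_equal(nrow(rx$products[[1]]$bonds), 2L)

  oracle <- rdkit_oracle(sprintf('
import json
from rdkit import Chem
rxn = "%s"
lhs, rhs = rxn.split(">>")
def info(s):
    out = []
    for part in s.split("."):
        m = Chem.MolFromSmiles(part)
        out.append({
            "n": m.GetNumAtoms(),
            "maps": [a.GetAtomMapNum() for a in m.GetAtoms()],
            "elems": [a.GetSymbol() for a in m.GetAtoms()],
            "bonds": sorted([sorted([b.GetBeginAtomIdx(), b.GetEndAtomIdx()])
                             for b in m.GetBonds()]),
        })
    return out
print(json.dumps({"r": info(lhs), "p": info(rhs)}))
', rxn))
  for (j in 1:2) {
    expect_equal(nrow(rx$reactants[[j]]$atoms), oracle$r$n[j])
    expect_equal(rx$reactants[[j]]$atoms$element, oracle$r$elems[[j]])
    expect_equal(rx$reactants[[j]]$atoms$map, as.integer(oracle$r$maps[[j]]))
  }
  got_bonds <- rx$products[[1]]$bonds
  got <- sort(paste(pmin(got_bonds$i, got_bonds$j) - 1L,
                    pmax(got_bonds$i, got_bonds$j) - 1L))
  want <- sort(paste(oracle$p$bonds[[1]][, 1], oracle$p$bonds[[1]][, 2]))
  expect_equal(got, want)
})

test_that("SMILES hydrogen counts and descriptors match an RDKit oracle", {
  oracle <- rdkit_oracle('
import json
from rdkit import Chem
out = {}
for name, smi in [("ch4", "C"), ("benzene", "c1ccccc1"), ("ammonium", "[NH4+]")]:
    m = Chem.MolFromSmiles(smi)
    a = m.GetAtomWithIdx(0)
    out[name] = {"nH": a.GetTotalNumHs(), "degree": a.GetDegree(),
                 "aromatic": int(a.GetIsAromatic()),
                 "charge": a.GetFormalCharge(),
                 "in_ring6": int(a.IsInRingSize(6))}
print(json.dumps(out))
')
  ch4 <- annotate_smiles(parse_smiles("C"))
  expect_equal(ch4$n_h, oracle$ch4$nH)
  expect_equal(ch4$degree_heavy, oracle$ch4$degree)
  benz <- annotate_smiles(parse_smiles("c1ccccc1"))
  expect_equal(benz$n_h[1], oracle$benzene$nH)
  expect_equal(benz$degree_heavy[1], oracle$benzene$degree)
  expect_equal(benz$aromatic[1], oracle$benzene$aromatic)
  expect_equal(benz$ring6[1], oracle$benzene$in_ring6)
  amm <- annotate_smiles(parse_smiles("[NH4+]"))
  expect_equal(amm$n_h, oracle$ammonium$nH)
  expect_equal(amm$formal_charge, oracle$ammonium$charge)
})

test_that("covalent-radius graphs follow the distance criterion", {
  h2 <- molecule3d(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  g <- graph_from_xyz(h2, tolerance = 0.4)
  expect_equal(nrow(g$edges), 1L)   # 0.74 <= 0.31 + 0.31 + 0.4

  far <- molecule3d(c("He", "He"), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(nrow(graph_from_xyz(far)$edges), 0L)

  water <- molecule3d(c("O", "H", "H"),
                      rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                            c(0, -0.7572, -0.4692)))
  gw <- graph_from_xyz(water)
  expect_equal(nrow(gw$edges), 2L)  # two O-H bonds, no H-H bond
  expect_true(all(gw$edges[, 1] == 1L))

  expect_error(graph_from_xyz(molecule3d("K", matrix(0, 1, 3)),
                              radii = c(H = 0.31)), "no covalent radius")
})

test_that("labelled-graph matching agrees with exhaustive search", {
  gx <- labeled_graph(c("H", "H", "O"), rbind(c(1, 3), c(2, 3)))
  gs <- labeled_graph(c("O", "H", "H"), rbind(c(1, 2), c(1, 3)))
  perm <- match_smiles_to_xyz(gx, gs)
  expect_identical(gx$labels[perm], gs$labels)
  Ax <- rxn3d:::lg_adjacency(gx)
  expect_identical(Ax[perm, perm], rxn3d:::lg_adjacency(gs))
  # brute force over all 3! permutations: the valid set must contain perm
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  valid <- Filter(function(p) {
    identical(gx$labels[p], gs$labels) &&
      identical(Ax[p, p], rxn3d:::lg_adjacency(gs))
  }, perms)
  expect_true(any(vapply(valid, function(p) all(p == perm), TRUE)))

  # identity ordering admits the identity permutation
  expect_true(rxn3d:::.perm_valid(gs, gs, match_smiles_to_xyz(gs, gs)))

  expect_error(
    match_smiles_to_xyz(labeled_graph(c("C", "C"), matrix(0L, 0, 2)),
                        labeled_graph(c("C", "O"), matrix(0L, 0, 2))),
    "mismatch")
  expect_error(
    match_smiles_to_xyz(labeled_graph("C", matrix(0L, 0, 2)),
                        labeled_graph(c("C", "C"), matrix(0L, 0, 2))),
    "atom counts")
})

test_that("reaction-type signatures are canonical and order invariant", {
  ident <- parse_mapped_reaction_smiles("[CH4:1]>>[CH4:1]")
  sig0 <- reaction_type_signature(ident$reactants, ident$products)
  expect_equal(sig0$string, "")

  # hydrogen transfer from C to O on a mapped 4-atom example
  r <- list(parse_smiles("[CH3:1][H:2]"), parse_smiles("[OH2:3]"))
  p <- list(parse_smiles("[CH3:1]"), parse_smiles("[H:2][OH2:3]"))
  sig <- reaction_type_signature(r, p)
  expect_equal(sig$string, "+H-O,-C-H")

  # canonical form matches the documented convention: formed first, sorted
  # (break C-C and C-H, form C-H)
  r2 <- list(parse_smiles("[CH3:1][CH2:2][H:3]"))
  p2 <- list(parse_smiles("[CH3:1][H:3]"), parse_smiles("[CH2:2]"))
  sig2 <- reaction_type_signature(r2, p2)
  expect_equal(sig2$string, "+C-H,-C-C,-C-H")
  expect_equal(format(sig2, dash = "endash"), "+C–H,–C–C,–C–H")

  # invariant to molecule order within a side
  sigA <- reaction_type_signature(r, p)
  sigB <- reaction_type_signature(rev(r), rev(p))
  expect_equal(sigA$string, sigB$string)

  # invariant to a map relabeling that preserves the correspondence
  r3 <- list(parse_smiles("[CH3:7][H:9]"), parse_smiles("[OH2:5]"))
  p3 <- list(parse_smiles("[CH3:7]"), parse_smiles("[H:9][OH2:5]"))
  expect_equal(reaction_type_signature(r3, p3)$string, sig$string)

  expect_error(reaction_type_signature(list(parse_smiles("[CH3:1]C")),
                                       list(parse_smiles("[CH3:1]C"))),
               "unmapped")
})
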