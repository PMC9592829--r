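test_that("fingerprint dimensions match their specifications", {
  smi <- c("c1ccccc1CCO", "CCO")
  expect_equal(dim(compute_maccs(smi)), c(2L, 166L))
  expect_equal(dim(compute_pubchem(smi)), c(2L, 881L))
  expect_equal(dim(compute_morgan(smi)), c(2L, 1024L))
  expect_equal(dim(compute_erg(smi)), c(2L, 315L))
  blk <- fingerprint_block(smi)
  expect_equal(ncol(blk), 166L + 881L + 315L)
  expect_equal(table(attr(blk, "family"))[c("maccs", "pubchem", "erg")],
               table(rep(c("maccs", "pubchem", "erg"),
                         c(166, 881, 315)))[c("maccs", "pubchem", "erg")])
  expect_true(all(blk %in% c(0L, 1L)))
})

test_that("fingerprints are invariant to SMILES respelling and atom order", {
  spellings <- c("c1ccccc1O", "Oc1ccccc1", "C1=CC=CC=C1O")
  m <- compute_maccs(spellings)
  expect_true(all(m[1, ] == m[2, ]) && all(m[1, ] == m[3, ]))
  p <- compute_pubchem(spellings)
  expect_true(all(p[1, ] == p[2, ]) && all(p[1, ] == p[3, ]))
  g <- compute_morgan(spellings)
  expect_true(all(g[1, ] == g[2, ]) && all(g[1, ] == g[3, ]))
  e <- compute_erg(spellings)
  expect_true(all(e[1, ] == e[2, ]) && all(e[1, ] == e[3, ]))
})

test_that("featurizers are pure: repeated calls give identical output", {
  lib <- fixture_library(20, seed = 21)
  expect_identical(compute_maccs(lib), compute_maccs(lib))
  expect_identical(compute_erg(lib), compute_erg(lib))
})

test_that("fingerprints separate structurally distinct molecules", {
  g <- compute_morgan(c("C", "CC"))
  expect_true(any(g[1, ] != g[2, ]))
  # methane has no pharmacophore points
  expect_true(all(compute_erg("C") == 0))
  # nitrile introduces an acceptor absent in benzene
  e <- compute_erg(c("c1ccccc1C#N", "c1ccccc1"))
  expect_true(any(e[1, ] != e[2, ]))
  # ring-composition keys distinguish cyclohexane from hexane
  p <- compute_pubchem(c("C1CCCCC1", "CCCCCC"))
  expect_true(any(p[1, ] != p[2, ]))
  # ethanol sets an oxygen-dependent MACCS key that ethane lacks, while
  # the nitrogen keys its amine analogue turns on stay off
  m <- compute_maccs(c("CCO", "CC", "CCN"))
  expect_true(any(m[1, ] == 1 & m[2, ] == 0))
  expect_true(any(m[3, ] == 1 & m[1, ] == 0))
})

test_that("molecular graphs have the fixed heavy-atom schema", {
  g <- mol_to_graph("CCO")
  expect_s3_class(g, "mol_graph")
  expect_equal(g$n_atoms, 3L)
  expect_equal(nrow(g$edges), 4L)          # 2 bonds, both directions
  expect_equal(ncol(g$atom_features), 28L)
  expect_equal(ncol(g$bond_features), 6L)
  b <- mol_to_graph("c1ccccc1")
  expect_equal(b$n_atoms, 6L)
  expect_equal(nrow(b$edges), 12L)
  expect_equal(ncol(b$atom_features), ncol(g$atom_features))
  # edge list is symmetric
  key <- paste(g$edges[, 1], g$edges[, 2])
  rev_key <- paste(g$edges[, 2], g$edges[, 1])
  expect_setequal(key, rev_key)
  expect_error(mol_to_graph("not_a_smiles"), "cannot build graph")
})

test_that("atom-order permutation yields an isomorphic graph", {
  a <- mol_to_graph("OCCc1ccccc1")
  b <- mol_to_graph("c1ccccc1CCO")
  expect_equal(a$n_atoms, b$n_atoms)
  expect_equal(nrow(a$edges), nrow(b$edges))
  deg_a <- sort(tabulate(a$edges[, 1], a$n_atoms))
  deg_b <- sort(tabulate(b$edges[, 1], b$n_atoms))
  expect_equal(deg_a, deg_b)
  # same multiset of atom feature rows
  expect_equal(sort(apply(a$atom_features, 1, paste, collapse = ",")),
               sort(apply(b$atom_features, 1, paste, collapse = ",")))
})

test_that("SMARTS matching flags substructures and matched atoms", {
  m <- match_smarts(c("c1ccccc1C#N", "CCO"), c("C#N", "[OX2H]"))
  expect_identical(unname(m[1, ]), c(TRUE, FALSE))
  expect_identical(unname(m[2, ]), c(FALSE, TRUE))
  atoms <- match_smarts_atoms(c("CC#N", "CCO"), "C#N")
  expect_equal(atoms[[1]], c(2L, 3L))
  expect_length(atoms[[2]], 0)
})
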