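# Molecular graph core: canonical keys, resonance, subgraph radius,
# identical-environment test.

test_that("canonical keys distinguish radicals and ignore atom order", {
  expect_false(mol_key(parse_smiles("C")) == mol_key(parse_smiles("[CH3]")))
  k <- canonical_key(parse_smiles("C"))
  expect_equal(k$scheme, "inchi")

  set.seed(101)
  for (s in c("CC(C)CO", "C1CCCCC1", "[CH2]C=CC", "CC(=O)O")) {
    m <- parse_smiles(s)
    keys <- vapply(1:10, function(i) mol_key(perm_mol(m, sample(n_atoms(m)))), "")
    expect_length(unique(c(mol_key(m), keys)), 1L)
  }
})

test_that("the nine heptane isomers get nine distinct keys", {
  mols <- lapply(heptane_isomers, parse_smiles)
  keys <- vapply(mols, mol_key, "")
  expect_length(unique(keys), length(mols))
  # oracle: brute-force pairwise isomorphism agrees with key equality
  for (i in seq_along(mols)) for (j in seq_along(mols)) {
    expect_equal(keys[i] == keys[j], brute_isomorphic(mols[[i]], mols[[j]]),
                 info = paste(heptane_isomers[i], "vs", heptane_isomers[j]))
  }
})

test_that("resonance enumeration finds radical delocalization", {
  # 1-buten-3-yl: secondary and primary localization
  rs <- enumerate_resonance(parse_smiles("C=C[CH]C"))
  expect_length(rs, 2L)
  rads <- vapply(rs, function(m) which(m$atoms$radical > 0L), 0L)
  expect_setequal(rads, c(1L, 3L))
  # no delocalizable system
  expect_length(enumerate_resonance(parse_smiles("CC")), 1L)
  # allyl: two mirror-equivalent localizations
  al <- enumerate_resonance(parse_smiles("[CH2]C=C"))
  expect_length(al, 2L)
  expect_true(mol_isomorphic(al[[1]], al[[2]]))
})

test_that("resonance outputs contain the input and share a delocalized key", {
  for (s in c("C=C[CH]C", "[CH2]C=C", "CC", "C=CC=C[CH2]")) {
    m <- parse_smiles(s)
    rs <- enumerate_resonance(m)
    expect_true(any(vapply(rs, function(x)
      templater:::mol_identical_labeled(x, m), TRUE)), info = s)
    dkeys <- vapply(rs, function(x) canonical_key(x, delocalized = TRUE)$key, "")
    expect_length(unique(dkeys), 1L)
    skel <- vapply(rs, function(x) paste(x$atoms$element, collapse = ""), "")
    expect_length(unique(skel), 1L)
  }
})

test_that("subgraph_radius equals the BFS eccentricity oracle", {
  expect_equal(subgraph_radius(parse_smiles("[H]"), 1L), 0L)
  # n-butane heavy-skeleton intuition carries over to the explicit-H graph
  but <- parse_smiles("CCCC")
  expect_equal(subgraph_radius(but, 1L), 4L)   # terminal C: farthest H on C4
  expect_equal(subgraph_radius(but, 2L), 3L)
  set.seed(7)
  for (q in 1:100) {
    m <- random_test_mol()
    d <- igraph::distances(templater:::mol_igraph(m))
    root <- sample.int(n_atoms(m), 1L)
    expect_equal(subgraph_radius(m, root), max(d[root, ]))
  }
})

test_that("environments_identical implements the shell criterion", {
  e <- parse_smiles("CC")
  expect_true(environments_identical(e, 1L, e, 2L))
  p <- parse_smiles("CCC")
  expect_false(environments_identical(p, 1L, p, 2L))
  expect_true(environments_identical(p, 1L, p, 3L))
  # two separate (value-equal) molecules: same chemical position
  e2 <- parse_smiles("CC")
  expect_true(environments_identical(e, 1L, e2, 2L, same_molecule = FALSE))
  expect_false(environments_identical(e, 1L, p, 1L, same_molecule = FALSE))
  # different elements are never identical
  co <- parse_smiles("CO")
  expect_false(environments_identical(co, 1L, co, 2L))
})

test_that("environments_identical is an equivalence relation on a small corpus", {
  mols <- lapply(c("CC", "CCC", "CC(C)C", "CCO", "C"), parse_smiles)
  univ <- do.call(rbind, lapply(seq_along(mols), function(mi)
    cbind(mi, seq_len(n_atoms(mols[[mi]])))))
  n <- nrow(univ)
  M <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    M[i, j] <- environments_identical(
      mols[[univ[i, 1]]], univ[i, 2], mols[[univ[j, 1]]], univ[j, 2],
      same_molecule = univ[i, 1] == univ[j, 1])
  }
  expect_true(all(diag(M)))
  expect_identical(M, t(M))
  viol <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) if (M[i, j])
    viol <- viol + sum(M[j, ] & !M[i, ])
  expect_equal(viol, 0L)
})

test_that("molecule validation catches inconsistent graphs", {
  expect_error(molecule(c("C", "C")), "not connected")
  expect_error(molecule("C", radical = 5L), "valence")
  expect_error(molecule(c("C", "Xx"),
                        data.frame(a1 = 1, a2 = 2, order = 1)), "element")
  # valence accounting: CH3 radical is fine, CH4 with a radical is not
  expect_silent(validate_molecule(parse_smiles("[CH3]")))
  m <- parse_smiles("C")
  m$atoms$radical[1] <- 1L
  expect_error(validate_molecule(m), "valence")
})

test_that("SMILES and InChI readers agree and round-trip", {
  pairs <- list(
    c("CCO", "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3"),
    c("C", "InChI=1S/CH4/h1H4"),
    c("[CH3]", "InChI=1S/CH3/h1H3"),
    c("O=C=O", "InChI=1S/CO2/c2-1-3"),
    c("c1ccccc1", "InChI=1S/C6H6/c1-2-4-6-5-3-1/h1-6H"))
  for (p in pairs) {
    expect_equal(mol_key(parse_smiles(p[1])), mol_key(parse_inchi(p[2])),
                 info = p[2])
  }
  set.seed(21)
  for (q in 1:20) {
    m <- random_test_mol()
    m2 <- parse_smiles(write_smiles(m))
    expect_true(mol_isomorphic(m, m2))
  }
})
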