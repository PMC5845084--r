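# Template identity, dedup, reverse pairs, SMARTS, constraints, application
# and classification.

habs_template <- function(substrate = "CC", abstractor = "[H]") {
  sub <- parse_smiles(substrate)
  abs_ <- parse_smiles(abstractor)
  rec <- reaction_record(list(sub, abs_), list(sub, abs_), source_id = "x")
  # build the reaction properly: abstract the first C-H
  rs <- side_info(list(sub, abs_))
  donor <- which(rs$element == "C")[1]
  h <- templater:::h_on(rs, donor)[1]
  rad <- which(rs$mol_of == 2L & rs$radical > 0L)[1]
  templater:::record_from_edit(list(sub, abs_), function(atoms, bonds) {
    bonds <- templater:::del_bond(bonds, donor, h)
    bonds <- templater:::add_bond(bonds, rad, h)
    atoms$radical[donor] <- atoms$radical[donor] + 1L
    atoms$radical[rad] <- atoms$radical[rad] - 1L
    list(atoms = atoms, bonds = bonds)
  }, "x", "h_abstraction")
}

test_that("template equality is center + recipe isomorphism", {
  # same family from two different substrates (same local environment)
  t1 <- extract_template(habs_template("CC"))
  t2 <- extract_template(habs_template("CCC"))
  expect_true(template_equals(t1, t2))
  expect_true(template_equals(t1, t1))
  # abstraction by H radical vs by C radical: different centers
  t3 <- extract_template(habs_template("CC", "[CH3]"))
  expect_false(template_equals(t1, t3))
  # equality is invariant under atom-order permutation of the inputs
  rec <- habs_record()
  p <- c(1L, 3L, 2L, 5L, 4L)             # permute methane atoms
  rec2 <- reaction_record(list(perm_mol(rec$reactants[[1]], p), rec$reactants[[2]]),
                          rec$products,
                          map = rec$map[order(c(p, 6L))], source_id = "perm")
  expect_true(template_equals(extract_template(rec), extract_template(rec2)))
})

test_that("deduplication counts representatives and is order-independent", {
  set.seed(3)
  tpls <- lapply(1:10, function(i)
    extract_template(habs_template(c("CC", "CCC", "CCCC")[1 + i %% 3])))
  tab <- deduplicate_and_count(tpls)
  expect_length(tab, 1L)
  expect_equal(tab[[1]]$count, 10L)
  expect_length(tab[[1]]$source_ids, 10L)
  # empty stream
  expect_length(deduplicate_and_count(list()), 0L)
  # shuffling the stream leaves counts and signatures unchanged
  cp <- generate_synthetic_corpus(30, seed = 8)
  tt <- lapply(cp$records, extract_template)
  tab1 <- deduplicate_and_count(tt)
  tab2 <- deduplicate_and_count(tt[sample(length(tt))])
  sig1 <- sort(vapply(tab1, function(t) paste(t$sig, t$count), ""))
  sig2 <- sort(vapply(tab2, function(t) paste(t$sig, t$count), ""))
  expect_identical(sig1, sig2)
  # sum of counts equals the number of processed reactions
  expect_equal(sum(vapply(tab1, function(t) t$count, 0L)), 30L)
})

test_that("reverse templates are detected, including self-inverse ones", {
  # beta scission of 1-propyl vs the addition regenerating it
  prop <- templater:::primary_radical_chain(3L)
  beta <- templater:::record_from_edit(list(prop), function(atoms, bonds) {
    bonds <- templater:::del_bond(bonds, 2L, 3L)
    bonds <- templater:::set_order(bonds, 1L, 2L, 2L)
    atoms$radical[1L] <- 0L; atoms$radical[3L] <- 1L
    list(atoms = atoms, bonds = bonds)
  }, "beta", "beta_scission")
  tb <- extract_template(beta)
  add_rec <- reaction_record(beta$products, beta$reactants,
                             map = order(beta$map), source_id = "add")
  ta <- extract_template(add_rec)
  expect_true(is_reverse_pair(tb, ta))
  expect_true(is_reverse_pair(ta, tb))
  # self-inverse hydrogen transfer: CH4 + CH3. -> CH3. + CH4
  selfrec <- habs_template("C", "[CH3]")
  ts <- extract_template(selfrec)
  expect_true(is_reverse_pair(ts, ts))
  # the documented species-level false positive: 1-2 shift in 1-pentyl vs
  # 1-4 shift in 2-pentyl link as reverse although the centers differ
  pent <- templater:::primary_radical_chain(5L)
  mk_shift <- function(from, to, id) {
    rs <- side_info(list(pent))
    h <- templater:::h_on(rs, from)[1]
    templater:::record_from_edit(list(pent), function(atoms, bonds) {
      bonds <- templater:::del_bond(bonds, from, h)
      bonds <- templater:::add_bond(bonds, to, h)
      atoms$radical[to] <- 0L
      atoms$radical[from] <- 1L
      list(atoms = atoms, bonds = bonds)
    }, id, "h_shift")
  }
  s12 <- mk_shift(2L, 1L, "s12")     # 1-pentyl -> 2-pentyl
  t12 <- extract_template(s12)
  # 1-4 shift in 2-pentyl: start from the 2-pentyl product
  pent2 <- s12$products[[1]]
  rs2 <- side_info(list(pent2))
  rad2 <- which(rs2$radical > 0L)
  h2 <- templater:::h_on(rs2, 5L)[1]
  s14 <- templater:::record_from_edit(list(pent2), function(atoms, bonds) {
    bonds <- templater:::del_bond(bonds, 5L, h2)
    bonds <- templater:::add_bond(bonds, rad2, h2)
    atoms$radical[rad2] <- 0L
    atoms$radical[5L] <- 1L
    list(atoms = atoms, bonds = bonds)
  }, "s14", "h_shift")
  t14 <- extract_template(s14)
  expect_false(template_equals(t12, t14))
  expect_true(is_reverse_pair(t12, t14))   # preserved false positive
})

test_that("center SMARTS carries X/v annotations and matches its source", {
  # propene pi carbons: three neighbors, valence four
  prop <- parse_smiles("C=CC")
  add <- reaction_record(list(prop, parse_smiles("[H]")),
                         list(parse_smiles("CC[CH2]")), source_id = "ad")
  res <- compute_mapping(add)
  tpl <- extract_template(add, res$map)
  sm <- generate_center_smarts(tpl)
  expect_true(any(grepl("\\[CX3v4\\]", sm)))
  # methyl radical carbon: three neighbors, valence three
  rec <- habs_record()
  tpl2 <- extract_template(reaction_record(rec$products, rec$reactants,
                                           map = order(rec$map),
                                           source_id = "rev"))
  sm2 <- generate_center_smarts(tpl2)
  expect_true(any(grepl("\\[CX3v3\\]", sm2)))
  # every emitted pattern matches its own source molecule exactly at the
  # center atoms
  rs <- side_info(add$reactants)
  for (fi in seq_along(tpl$fragments)) {
    f <- tpl$fragments[[fi]]
    mol <- add$reactants[[f$src_mol]]
    embs <- templater:::fragment_embeddings(f, mol)
    expect_gte(length(embs), 1L)
    want <- rs$atom_of[tpl$center_atoms[f$labels]]
    hit <- vapply(embs, function(e) all(e == want), TRUE)
    expect_true(any(hit))
  }
})

test_that("atom-first SMARTS all describe the same match sets", {
  rec <- shift15_record()
  tpl <- extract_template(rec)
  nlab <- sum(vapply(tpl$fragments, function(f) length(f$labels), 0L))
  mol <- rec$reactants[[1]]
  base <- templater:::fragment_embeddings(tpl$fragments[[1]], mol)
  base_sets <- unique(lapply(base, sort))
  for (l in seq_len(nlab)) {
    s <- generate_atom_first_smarts(tpl, l)
    expect_match(s, "^\\[")
    # the pattern string starts with the target atom's own token
    f <- tpl$fragments[[1]]
    q <- match(l, f$labels)
    tok <- templater:::smarts_atom_token(f$element[q], f$charge[q], f$X[q],
                                         f$v[q], f$arom[q])
    expect_equal(substr(s, 1, nchar(tok)), tok)
  }
  expect_error(generate_atom_first_smarts(tpl, nlab + 10L), "not in template")
})

test_that("constraints mirror corpus size and reactant electron counts", {
  cp <- generate_synthetic_corpus(15, seed = 4)
  maxheavy <- max(vapply(cp$records, function(r)
    max(vapply(c(r$reactants, r$products), heavy_atom_count, 0L)), 0L))
  tpl <- extract_template(cp$records[[1]])
  cons <- generate_constraints(cp, tpl)
  g <- cons[cons$scope == "global", ]
  expect_equal(g$value, maxheavy)
  pr <- cons[cons$scope == "per_reactant", ]
  expect_equal(nrow(pr), tpl$nfrag)
  for (k in seq_len(nrow(pr))) {
    m <- tpl$rep_record$reactants[[tpl$fragments[[pr$reactant[k]]]$src_mol]]
    expect_equal(pr$value[k], radical_count(m))
  }
})

test_that("apply_template regenerates and generalizes reactions", {
  rec <- habs_record()
  tpl <- extract_template(rec)
  out <- apply_template(tpl, rec$reactants)
  keys <- vapply(out, function(ps) paste(side_keys(ps), collapse = "|"), "")
  expect_true(paste(side_keys(rec$products), collapse = "|") %in% keys)
  # generalization: ethane + H gives ethyl + H2
  out2 <- apply_template(tpl, list(parse_smiles("CC"), parse_smiles("[H]")))
  expect_length(out2, 1L)
  expect_setequal(vapply(out2[[1]], mol_formula, ""), c("C2H5", "H2"))
  # constraint violation rejects
  cons <- data.frame(scope = "global", kind = "max_heavy_atoms", value = 1,
                     reactant = NA)
  expect_length(apply_template(tpl, list(parse_smiles("CC"), parse_smiles("[H]")),
                               constraints = cons), 0L)
  # no embedding: water has no C-H
  expect_length(apply_template(tpl, list(parse_smiles("O"), parse_smiles("[H]"))),
                0L)
  # Diels-Alder applied to butadiene + ethene yields cyclohexene
  da <- reaction_record(list(parse_smiles("C=CC=C"), parse_smiles("C=C")),
                        list(parse_smiles("C1=CCCCC1")), source_id = "da")
  r <- compute_mapping(da)
  tplda <- extract_template(da, r$map)
  outda <- apply_template(tplda, list(parse_smiles("C=CC=C"), parse_smiles("C=C")))
  expect_true(any(vapply(outda, function(ps)
    identical(side_keys(ps), side_keys(da$products)), TRUE)))
})

test_that("classification labels the family recipes", {
  t_habs <- extract_template(habs_template("CC", "[CH3]"))
  expect_equal(classify_template(t_habs), "h_abstraction/c_centered")
  t_habs_h <- extract_template(habs_template("CC", "[H]"))
  expect_equal(classify_template(t_habs_h), "h_abstraction/h_centered")
  t_shift <- extract_template(shift15_record())
  expect_equal(classify_template(t_shift), "h_shift/c_centered")
  # stereo-only template is identical with an empty formalized recipe
  a <- parse_smiles("C"); b <- parse_smiles("C")
  a$atoms$stereo[1] <- "@"; b$atoms$stereo[1] <- "@@"
  iso <- reaction_record(list(a), list(b), map = 1:5, source_id = "iso")
  t_iso <- extract_template(iso)
  expect_equal(t_iso$status, "identical")
  expect_equal(classify_template(t_iso), "identical")
  # the stereo change items survive internally
  expect_true(any(t_iso$recipe$action == "CHANGE_STEREO"))
})
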