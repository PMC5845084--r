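# Change detection, reactive centers, connectors, mechanism check and the
# hydroperoxyl-elimination correction.

test_that("detect_changes reproduces the change taxonomy", {
  rec <- habs_record()
  ch <- detect_changes(rec, rec$map)
  expect_setequal(ch$reactive_atoms, c(1L, 5L, 6L))  # C, leaving H, radical H
  kinds <- sort(ch$items$kind)
  expect_setequal(unique(kinds),
                  c("neighbor_loss", "neighbor_gain", "radical_gain", "radical_loss"))
  # identity map on identical sides: empty change set
  m <- parse_smiles("CCO")
  idrec <- reaction_record(list(m), list(m), map = seq_len(n_atoms(m)),
                           source_id = "id")
  idch <- detect_changes(idrec, idrec$map)
  expect_equal(nrow(idch$items), 0L)
  expect_length(idch$reactive_atoms, 0L)
  # incomplete map is an error
  bad <- rec$map; bad[2] <- NA
  expect_error(detect_changes(rec, bad), "complete")
})

test_that("Diels-Alder changes: two new sigma bonds, four pi order changes", {
  da <- reaction_record(list(parse_smiles("C=CC"), parse_smiles("C=CC(C)=C")),
                        list(parse_smiles("CC1CCC(C)=CC1")), source_id = "da")
  res <- compute_mapping(da)
  ch <- detect_changes(da, res$map)
  expect_equal(sum(ch$items$kind == "neighbor_gain"), 2L)
  expect_equal(sum(ch$items$kind == "bond_order_change"), 4L)
  expect_length(ch$reactive_atoms, 6L)
})

test_that("stereo gain/loss of an undefined descriptor is not a change", {
  a <- parse_smiles("C")
  b <- parse_smiles("C")
  b$atoms$stereo[1] <- "@"
  rec <- reaction_record(list(a), list(b), map = 1:5, source_id = "st")
  ch <- detect_changes(rec, rec$map)
  expect_equal(nrow(ch$items), 0L)
  # but a flip between two defined descriptors is
  a$atoms$stereo[1] <- "@@"
  rec2 <- reaction_record(list(a), list(b), map = 1:5, source_id = "st2")
  ch2 <- detect_changes(rec2, rec2$map)
  expect_equal(ch2$items$kind, "stereo_change")
})

test_that("connect_center realizes minimal connecting paths", {
  pent <- parse_smiles("CCCCC")
  # two reactive atoms three bonds apart -> the two intermediate carbons
  expect_equal(connect_center(pent, c(1L, 4L)), c(2L, 3L))
  # adjacent reactive atoms -> nothing to add
  expect_equal(connect_center(pent, c(2L, 3L)), integer(0))
  # Y-shaped case: three terminal methyls of isopentane meet at the branch
  iso <- parse_smiles("CC(C)CC")            # C1, C3, C5 terminals
  conn <- connect_center(iso, c(1L, 3L, 5L))
  expect_setequal(conn, c(2L, 4L))
})

test_that("connector sets are minimal: removing any connector disconnects", {
  mols <- lapply(c("CCCCC", "CC(C)CC", "CC(C)(C)CC", "C1CCCCC1", "CC1CCC(C)C1",
                   "CCOCC"), parse_smiles)
  set.seed(13)
  for (m in mols) {
    heavy <- which(m$atoms$element != "H")
    for (q in 1:20) {
      k <- resample_int(2:min(4, length(heavy)))
      reactive <- sort(sample(heavy, k))
      conn <- connect_center(m, reactive)
      all_atoms <- c(reactive, conn)
      expect_true(is_connected_subset(m, all_atoms))
      for (c_ in conn) {
        expect_false(is_connected_subset(m, setdiff(all_atoms, c_)),
                     info = paste(write_smiles(m), paste(reactive, collapse = ","), c_))
      }
    }
  }
})

test_that("reactive centers connect per molecule and expand to heteroatoms", {
  rec <- habs_record()
  ch <- detect_changes(rec, rec$map)
  rc <- build_reactive_center(rec, ch)
  expect_equal(nrow(rc), 3L)
  expect_true(all(rc$role == "reactive"))
  # 1-5 hydrogen shift: three connectors along the chain
  sh <- shift15_record()
  ch2 <- detect_changes(sh, sh$map)
  rc2 <- build_reactive_center(sh, ch2)
  expect_setequal(rc2$atom[rc2$role == "connector"], c(2L, 3L, 4L))
  # abstraction alpha to an ether oxygen: O joins with hetero_expansion
  ether <- parse_smiles("COC")
  habs <- reaction_record(list(ether, parse_smiles("[H]")),
                          list(parse_smiles("[CH2]OC"), parse_smiles("[H][H]")),
                          source_id = "eth")
  res <- compute_mapping(habs)
  ch3 <- detect_changes(habs, res$map)
  rc_on <- build_reactive_center(habs, ch3, include_hetero = TRUE)
  rc_off <- build_reactive_center(habs, ch3, include_hetero = FALSE)
  expect_true(any(rc_on$role == "hetero_expansion"))
  expect_false(any(rc_off$role == "hetero_expansion"))
  rs <- side_info(habs$reactants)
  expect_equal(rs$element[rc_on$atom[rc_on$role == "hetero_expansion"]], "O")
  # hetero expansion only grows the center
  expect_true(all(rc_off$atom %in% rc_on$atom))
  sub <- rc_on[rc_on$atom %in% rc_off$atom, ]
  expect_identical(sub$role, rc_off$role)
})

test_that("mechanism acceptability flags spectator radicals", {
  # spectator mapping: CH3. + C2H6 -> C2H6 + CH3. with the radical idle
  ch3 <- parse_smiles("[CH3]")
  eth <- parse_smiles("CC")
  rec <- reaction_record(list(ch3, eth), list(eth, ch3),
                         map = c(9:12, 1:8), source_id = "spec")
  ch <- detect_changes(rec, rec$map)
  acc <- mechanism_acceptable(rec, ch)
  expect_false(as.logical(acc))
  expect_match(attr(acc, "reason"), "radical")
  # participating radical passes
  rec2 <- habs_record()
  acc2 <- mechanism_acceptable(rec2, detect_changes(rec2, rec2$map))
  expect_true(as.logical(acc2))
  # closed-shell reactions have nothing to check
  da <- reaction_record(list(parse_smiles("C=CC=C"), parse_smiles("C=C")),
                        list(parse_smiles("C1=CCCCC1")), source_id = "da")
  r <- compute_mapping(da)
  expect_true(as.logical(mechanism_acceptable(da, detect_changes(da, r$map))))
})

test_that("four-ring hydroperoxyl eliminations are remapped to five rings", {
  cp <- generate_synthetic_corpus(
    10, proportions = c(hoo_elimination = 1), seed = 23,
    peroxide_wrong_mapping = TRUE)
  for (rec in cp$records) {
    expect_equal(implied_ts_ring_size(rec, rec$map), 4L)
    fixed <- correct_peroxide_elimination(rec, rec$map)
    expect_equal(implied_ts_ring_size(rec, fixed), 5L)
    # idempotent on the corrected mapping
    again <- correct_peroxide_elimination(rec, fixed)
    expect_equal(implied_ts_ring_size(rec, again), 5L)
  }
  # non-peroxide records pass through untouched
  rec <- habs_record()
  expect_identical(correct_peroxide_elimination(rec, rec$map), rec$map)
})
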