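# Readers/writers and corpus filters.

test_that("identifier lists parse mixed SMILES/InChI and skip bad lines", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "C=CC + C=CC(C)=C >> CC1CCC(C)=CC1",
    "# a comment line",
    "",
    "InChI=1S/CH4/h1H4 + [OH] >> [CH3] + O",
    "C + [H] >> [CH3] + [H][H]",
    "notasmiles >> C"), f)
  cp <- suppressMessages(read_identifier_list(f))
  expect_equal(n_records(cp), 3L)
  expect_equal(attr(cp, "skipped")$line, 6L)
  da <- cp$records[[1]]
  expect_length(da$reactants, 2L)
  expect_length(da$products, 1L)
  expect_null(da$map)

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), empty)
  expect_equal(n_records(read_identifier_list(empty)), 0L)
})

test_that("RXN files round-trip molecules and mappings", {
  rec <- habs_record()
  f <- withr::local_tempfile(fileext = ".rxn")
  write_rxn(rec, f)
  rec2 <- read_rxn(f)
  expect_identical(rec2$map, rec$map)
  for (i in 1:2) {
    expect_true(mol_isomorphic(rec$reactants[[i]], rec2$reactants[[i]]))
    expect_true(mol_isomorphic(rec$products[[i]], rec2$products[[i]]))
  }
  # radical species carry a RAD property line
  expect_true(any(grepl("^M  RAD", readLines(f))))
  # unmapped record: all indices zero, mapping absent on read
  rec$map <- NULL
  write_rxn(rec, f)
  expect_null(read_rxn(f)$map)

  # directory reader skips malformed files
  d <- withr::local_tempdir()
  write_rxn(habs_record(id = "a"), file.path(d, "a.rxn"))
  writeLines("garbage", file.path(d, "b.rxn"))
  cp <- suppressMessages(read_rxn_directory(d))
  expect_equal(n_records(cp), 1L)
  expect_equal(attr(cp, "skipped"), "b.rxn")
})

test_that("CHEMKIN mechanisms parse via identifier comments only", {
  f <- withr::local_tempfile(fileext = ".inp")
  writeLines(c(
    "ELEMENTS", "C H O", "END",
    "SPECIES",
    "CH4   ! C",
    "H     ! [H]",
    "CH3   ! [CH3]",
    "H2    ! [H][H]",
    "C2H6  ! InChI=1S/C2H6/c1-2/h1-2H3",
    "END",
    "REACTIONS",
    "CH4+H=CH3+H2        1.0E13  0.0  10000",
    "H+H+M=H2+M          1.0E13  0.0  0",
    "CH3+CH3(+M)=C2H6(+M)  1.0E13 0.0 0",
    "  LOW / 1.0E10 0.0 0.0 /",
    "END"), f)
  cp <- read_chemkin(f)
  expect_equal(n_records(cp), 3L)
  # third bodies stripped
  r2 <- cp$records[[2]]
  expect_length(r2$reactants, 2L)
  expect_length(r2$products, 1L)
  expect_equal(mol_formula(r2$products[[1]]), "H2")
  # the species name is opaque: resolution is by the comment
  expect_equal(radical_count(cp$records[[1]]$reactants[[2]]), 1L)

  # species without an identifier comment is a hard error naming it
  f2 <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("SPECIES", "CH4 ! C", "MYSTERY", "END",
               "REACTIONS", "CH4=CH4 1 0 0", "END"), f2)
  expect_error(read_chemkin(f2), "MYSTERY")
})

test_that("unknown species in a reaction line are skipped, not fatal", {
  f <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("SPECIES", "CH4 ! C", "END",
               "REACTIONS",
               "CH4=CH4 1 0 0",
               "CH4+BOGUS=CH4 1 0 0",
               "END"), f)
  cp <- suppressMessages(read_chemkin(f))
  expect_equal(n_records(cp), 1L)
  expect_length(attr(cp, "skipped"), 1L)
})

test_that("balance filter keeps element- and charge-balanced records", {
  bad <- reaction_record(list(parse_smiles("[H][H]"), parse_smiles("O=O")),
                         list(parse_smiles("O")), source_id = "bad")
  good <- habs_record(map = NULL, id = "good")
  cp <- corpus(list(bad, good))
  out <- filter_unbalanced(cp)
  expect_equal(n_records(out), 1L)
  expect_equal(attr(out, "rejected")$source_id, "bad")
  expect_match(attr(out, "rejected")$tally, "O|H")
  # idempotent
  again <- filter_unbalanced(out)
  expect_equal(n_records(again), 1L)
})

test_that("arity filter and filter-order invariance", {
  m <- parse_smiles("C")
  h2 <- parse_smiles("[H][H]")
  hh <- parse_smiles("[H]")
  tri <- reaction_record(list(m, hh, hh), list(parse_smiles("C"), hh, hh),
                         source_id = "tri")
  bi <- habs_record(map = NULL, id = "bi")
  unbal <- reaction_record(list(m), list(h2), source_id = "unbal")
  cp <- corpus(list(tri, bi, unbal))
  a <- filter_arity(filter_unbalanced(cp), 2L)
  b <- filter_unbalanced(filter_arity(cp, 2L))
  ids <- function(x) vapply(x$records, function(r) r$source_id, "")
  expect_identical(ids(a), ids(b))
  expect_identical(ids(a), "bi")
})

test_that("arity filter reproduces the 1110/263/847 profile", {
  m <- parse_smiles("C")
  mk <- function(i, nreact) reaction_record(rep(list(m), nreact), list(m),
                                            source_id = paste0("r", i))
  set.seed(5)
  arity <- c(rep(3L, 263L), rep(sample(1:2, 847, replace = TRUE)))
  cp <- corpus(lapply(seq_len(1110L), function(i) mk(i, arity[i])))
  expect_equal(n_records(cp), 1110L)
  out <- filter_arity(cp, 2L)
  expect_equal(n_records(out), 847L)
  expect_length(attr(out, "rejected"), 263L)
})
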