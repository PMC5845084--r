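# Synthetic corpus generation (small-radical pyrolysis chemistry plus simple
# organic transformations) and the test-reaction validation scheme: variants
# of a mapped reaction obtained by adding/removing substituent fragments
# outside the reactive center, which must share the base reaction's template.

.FAMILIES <- c("h_abstraction", "h_shift", "beta_scission", "addition",
               "recombination", "substitution", "diels_alder",
               "hoo_elimination")

# -- small building blocks ---------------------------------------------------

# sample() misbehaves on length-1 vectors; always index explicitly
resample <- function(x, size = 1L) x[sample.int(length(x), size)]

# fill open valences with explicit hydrogens
fill_hydrogens <- function(elements, bonds, charge = 0L, radical = 0L) {
  n <- length(elements)
  charge <- rep_len(as.integer(charge), n)
  radical <- rep_len(as.integer(radical), n)
  bsum <- integer(n)
  if (!is.null(bonds) && nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + bonds$order[k]
    bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + bonds$order[k]
  }
  el <- elements; chg <- charge; rad <- radical
  bb <- if (is.null(bonds)) data.frame(a1 = integer(), a2 = integer(),
                                       order = integer()) else bonds
  if (is.null(bb$arom)) bb$arom <- rep(FALSE, nrow(bb))
  if (is.null(bb$stereo)) bb$stereo <- rep(NA_character_, nrow(bb))
  for (i in seq_len(n)) {
    need <- min(allowed_valences(elements[i], charge[i])) - bsum[i] - radical[i]
    if (need < 0L) stop("over-valent atom in skeleton")
    for (q in seq_len(need)) {
      el <- c(el, "H"); chg <- c(chg, 0L); rad <- c(rad, 0L)
      bb <- rbind(bb, data.frame(a1 = i, a2 = length(el), order = 1L,
                                 arom = FALSE, stereo = NA_character_))
    }
  }
  molecule(el, bb, charge = chg, radical = rad)
}

# random alkyl skeleton (tree of nc carbons), optionally decorated with one
# hetero substituent (OH or Cl); returns heavy-atom skeleton descriptors
random_alkyl_skeleton <- function(nc, hetero_prob = 0) {
  el <- rep("C", nc)
  bonds <- NULL
  if (nc > 1L) {
    a1 <- integer(nc - 1L)
    for (i in 2:nc) a1[i - 1L] <- sample.int(i - 1L, 1L)
    bonds <- data.frame(a1 = a1, a2 = 2:nc, order = 1L)
  }
  if (stats::runif(1) < hetero_prob) {
    het <- sample(c("O", "Cl"), 1L)
    at <- sample.int(nc, 1L)
    el <- c(el, het)
    bonds <- rbind(bonds, data.frame(a1 = at, a2 = length(el), order = 1L))
  }
  list(elements = el, bonds = bonds)
}

random_alkane <- function(nc, hetero_prob = 0) {
  sk <- random_alkyl_skeleton(nc, hetero_prob)
  fill_hydrogens(sk$elements, sk$bonds)
}

# primary radical on carbon 1 of a chain of nc carbons
primary_radical_chain <- function(nc) {
  bonds <- if (nc > 1L) data.frame(a1 = 1:(nc - 1L), a2 = 2:nc, order = 1L) else NULL
  fill_hydrogens(rep("C", nc), bonds, radical = c(1L, rep(0L, nc - 1L)))
}

random_radical <- function() {
  pick <- sample.int(4L, 1L)
  switch(pick,
         molecule("H", radical = 1L),                               # H.
         fill_hydrogens("C", NULL, radical = 1L),                   # CH3.
         fill_hydrogens(c("O"), NULL, radical = 1L),                # OH.
         fill_hydrogens(c("C", "C"),
                        data.frame(a1 = 1L, a2 = 2L, order = 1L),
                        radical = c(1L, 0L)))                       # C2H5.
}

# -- record assembly ---------------------------------------------------------

# Build a record from reactant molecules and an edit on their flattened
# union; the product molecules are the connected components after the edit
# and the map follows the atoms through it.
record_from_edit <- function(reactants, edit, source_id, family) {
  rs <- side_info(reactants)
  atoms <- do.call(rbind, lapply(reactants, function(m) m$atoms))
  rownames(atoms) <- NULL
  bonds <- rs$bonds
  ed <- edit(atoms, bonds)
  sp <- split_components(ed$atoms, ed$bonds)
  # product molecule order: by first-atom occurrence (stable)
  offs <- c(0L, cumsum(vapply(sp$mols, n_atoms, 0L)))
  map <- offs[sp$index[, 1]] + sp$index[, 2]
  reaction_record(reactants, sp$mols, map = map, source_id = source_id,
                  origin_format = "synthetic", family = family)
}

del_bond <- function(bonds, i, j) {
  e <- which(bonds$a1 == min(i, j) & bonds$a2 == max(i, j))
  stopifnot(length(e) == 1L)
  bonds[-e, , drop = FALSE]
}
add_bond <- function(bonds, i, j, order = 1L) {
  rbind(bonds, data.frame(a1 = min(i, j), a2 = max(i, j), order = order,
                          arom = FALSE, stereo = NA_character_))
}
set_order <- function(bonds, i, j, order) {
  e <- which(bonds$a1 == min(i, j) & bonds$a2 == max(i, j))
  stopifnot(length(e) == 1L)
  bonds$order[e] <- order
  bonds
}
h_on <- function(side, heavy) {
  nb <- which(side$adj[heavy, ] > 0L)
  nb[side$element[nb] == "H"]
}

# -- family generators (each uses the current RNG stream) --------------------

gen_h_abstraction <- function(id, hetero_prob) {
  substrate <- random_alkane(sample.int(4L, 1L), hetero_prob)
  abstractor <- random_radical()
  reactants <- list(substrate, abstractor)
  rs <- side_info(reactants)
  carbons <- which(rs$mol_of == 1L & rs$element == "C")
  donor <- resample(carbons)
  hs <- h_on(rs, donor)
  if (!length(hs)) return(NULL)
  h <- hs[1L]
  rad <- which(rs$mol_of == 2L & rs$radical > 0L)[1L]
  record_from_edit(reactants, function(atoms, bonds) {
    bonds <- del_bond(bonds, donor, h)
    bonds <- add_bond(bonds, rad, h)
    atoms$radical[donor] <- atoms$radical[donor] + 1L
    atoms$radical[rad] <- atoms$radical[rad] - 1L
    list(atoms = atoms, bonds = bonds)
  }, id, "h_abstraction")
}

gen_h_shift <- function(id, ...) {
  nc <- resample(3:5)
  m <- primary_radical_chain(nc)
  reactants <- list(m)
  rs <- side_info(reactants)
  donor <- resample(3:nc)
  h <- h_on(rs, donor)[1L]
  record_from_edit(reactants, function(atoms, bonds) {
    bonds <- del_bond(bonds, donor, h)
    bonds <- add_bond(bonds, 1L, h)
    atoms$radical[1L] <- 0L
    atoms$radical[donor] <- 1L
    list(atoms = atoms, bonds = bonds)
  }, id, "h_shift")
}

gen_beta_scission <- function(id, ...) {
  nc <- resample(3:5)
  m <- primary_radical_chain(nc)
  record_from_edit(list(m), function(atoms, bonds) {
    bonds <- del_bond(bonds, 2L, 3L)
    bonds <- set_order(bonds, 1L, 2L, 2L)
    atoms$radical[1L] <- 0L
    atoms$radical[3L] <- 1L
    list(atoms = atoms, bonds = bonds)
  }, id, "beta_scission")
}

gen_addition <- function(id, ...) {
  nc <- resample(2:4)       # alkene carbons
  bonds <- data.frame(a1 = 1:(nc - 1L), a2 = 2:nc, order = c(2L, rep(1L, nc - 2L)))
  alkene <- fill_hydrogens(rep("C", nc), bonds)
  radical <- random_radical()
  reactants <- list(alkene, radical)
  rs <- side_info(reactants)
  rad <- which(rs$mol_of == 2L & rs$radical > 0L)[1L]
  record_from_edit(reactants, function(atoms, bonds) {
    bonds <- set_order(bonds, 1L, 2L, 1L)
    bonds <- add_bond(bonds, rad, 1L)
    atoms$radical[rad] <- atoms$radical[rad] - 1L
    atoms$radical[2L] <- atoms$radical[2L] + 1L
    list(atoms = atoms, bonds = bonds)
  }, id, "addition")
}

gen_recombination <- function(id, ...) {
  r1 <- random_radical(); r2 <- random_radical()
  reactants <- list(r1, r2)
  rs <- side_info(reactants)
  a1 <- which(rs$mol_of == 1L & rs$radical > 0L)[1L]
  a2 <- which(rs$mol_of == 2L & rs$radical > 0L)[1L]
  record_from_edit(reactants, function(atoms, bonds) {
    bonds <- add_bond(bonds, a1, a2)
    atoms$radical[a1] <- atoms$radical[a1] - 1L
    atoms$radical[a2] <- atoms$radical[a2] - 1L
    list(atoms = atoms, bonds = bonds)
  }, id, "recombination")
}

gen_substitution <- function(id, ...) {
  nc <- resample(1:3)
  sk <- random_alkyl_skeleton(nc, 0)
  sk$elements <- c(sk$elements, "Cl")
  sk$bonds <- rbind(sk$bonds, data.frame(a1 = 1L, a2 = length(sk$elements),
                                         order = 1L))
  rcl <- fill_hydrogens(sk$elements, sk$bonds)
  water <- fill_hydrogens("O", NULL)
  reactants <- list(rcl, water)
  rs <- side_info(reactants)
  cl <- which(rs$mol_of == 1L & rs$element == "Cl")[1L]
  o <- which(rs$mol_of == 2L & rs$element == "O")[1L]
  oh <- h_on(rs, o)[1L]
  record_from_edit(reactants, function(atoms, bonds) {
    bonds <- del_bond(bonds, 1L, cl)
    bonds <- del_bond(bonds, o, oh)
    bonds <- add_bond(bonds, 1L, o)
    bonds <- add_bond(bonds, cl, oh)
    list(atoms = atoms, bonds = bonds)
  }, id, "substitution")
}

gen_diels_alder <- function(id, ...) {
  # diene C1=C2-C3=C4 with optional methyl on C2; dienophile C5=C6 with
  # optional methyl
  dmethyl <- stats::runif(1) < 0.5
  del <- c("C", "C", "C", "C", if (dmethyl) "C")
  db <- data.frame(a1 = c(1L, 2L, 3L), a2 = c(2L, 3L, 4L), order = c(2L, 1L, 2L))
  if (dmethyl) db <- rbind(db, data.frame(a1 = 2L, a2 = 5L, order = 1L))
  diene <- fill_hydrogens(del, db)
  emethyl <- stats::runif(1) < 0.5
  eel <- c("C", "C", if (emethyl) "C")
  eb <- data.frame(a1 = 1L, a2 = 2L, order = 2L)
  if (emethyl) eb <- rbind(eb, data.frame(a1 = 2L, a2 = 3L, order = 1L))
  dienophile <- fill_hydrogens(eel, eb)
  reactants <- list(diene, dienophile)
  n1 <- n_atoms(diene)
  c5 <- n1 + 1L; c6 <- n1 + 2L
  record_from_edit(reactants, function(atoms, bonds) {
    bonds <- set_order(bonds, 1L, 2L, 1L)
    bonds <- set_order(bonds, 2L, 3L, 2L)
    bonds <- set_order(bonds, 3L, 4L, 1L)
    bonds <- set_order(bonds, c5, c6, 1L)
    bonds <- add_bond(bonds, 1L, c5)
    bonds <- add_bond(bonds, 4L, c6)
    list(atoms = atoms, bonds = bonds)
  }, id, "diels_alder")
}

gen_hoo_elimination <- function(id, wrong_mapping = FALSE, ...) {
  nc <- resample(2:4)   # C1 (beta) - C2 (alpha) chain; O-O on C2... use
  # chain C1..Cnc with peroxy on C(nc): beta = C(nc-1)
  el <- c(rep("C", nc), "O", "O")
  bonds <- data.frame(a1 = c(1:(nc - 1L), nc, nc + 1L),
                      a2 = c(2:nc, nc + 1L, nc + 2L), order = 1L)
  roo <- fill_hydrogens(el, bonds, radical = c(rep(0L, nc + 1L), 1L))
  alpha <- nc; beta <- nc - 1L; o1 <- nc + 1L; o2 <- nc + 2L
  rs <- side_info(list(roo))
  hb <- h_on(rs, beta)[1L]
  rec <- record_from_edit(list(roo), function(atoms, bonds) {
    bonds <- del_bond(bonds, beta, hb)
    bonds <- del_bond(bonds, alpha, o1)
    bonds <- set_order(bonds, beta, alpha, 2L)
    bonds <- add_bond(bonds, o2, hb)
    atoms$radical[o2] <- 0L
    atoms$radical[o1] <- 1L
    list(atoms = atoms, bonds = bonds)
  }, id, "hoo_elimination")
  if (wrong_mapping) {
    # emit the four-ring misinterpretation: the hydrogen leaving with the
    # HOO is taken from the alpha carbon instead
    ha <- h_on(rs, alpha)[1L]
    m <- rec$map
    m[c(hb, ha)] <- m[c(ha, hb)]
    rec$map <- m
  }
  rec
}

#' Generate a synthetic, pre-mapped reaction corpus
#'
#' Families cover small-radical pyrolysis chemistry (hydrogen abstractions,
#' intramolecular hydrogen shifts, beta scissions, radical additions and
#' recombinations, hydroperoxyl eliminations) and simple organic
#' transformations (hydrolysis-type substitutions, Diels-Alder
#' cycloadditions). Every record is balanced, fully mapped, and labeled with
#' its ground-truth family.
#'
#' @param n Number of reactions.
#' @param proportions Named numeric vector over the families (default
#'   uniform); must be non-negative and sum to a positive value.
#' @param seed RNG seed (default 42).
#' @param hetero_prob Probability of a hetero substituent (OH/Cl) on
#'   abstraction substrates (default 0.25).
#' @param peroxide_wrong_mapping Emit hydroperoxyl eliminations with the
#'   four-ring mapping (to exercise [correct_peroxide_elimination()]).
#' @return An `rxn_corpus`.
#' @export
generate_synthetic_corpus <- function(n, proportions = NULL, seed = 42L,
                                      hetero_prob = 0.25,
                                      peroxide_wrong_mapping = FALSE) {
  if (is.null(proportions))
    proportions <- stats::setNames(rep(1, length(.FAMILIES)), .FAMILIES)
  if (is.null(names(proportions)) || !all(names(proportions) %in% .FAMILIES))
    stop("proportions must be named by families: ",
         paste(.FAMILIES, collapse = ", "))
  if (any(proportions < 0) || sum(proportions) <= 0)
    stop("invalid proportions")
  if (n == 0L) return(corpus(list()))
  set.seed(as.integer(seed))
  p <- proportions / sum(proportions)
  counts <- floor(p * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(p * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  gens <- list(h_abstraction = gen_h_abstraction, h_shift = gen_h_shift,
               beta_scission = gen_beta_scission, addition = gen_addition,
               recombination = gen_recombination,
               substitution = gen_substitution,
               diels_alder = gen_diels_alder,
               hoo_elimination = gen_hoo_elimination)
  records <- list(); k <- 0L
  for (fam in names(counts)) {
    for (q in seq_len(counts[[fam]])) {
      rec <- NULL
      while (is.null(rec)) {
        k <- k + 1L
        rec <- gens[[fam]](sprintf("synth_%05d", k),
                           if (fam == "hoo_elimination") peroxide_wrong_mapping
                           else hetero_prob)
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  corpus(records, provenance = sprintf("synthetic(seed=%d)", seed))
}

# -- test reactions (variants sharing the reactive center) -------------------

.FRAGMENTS <- list(
  methyl = list(elements = "C", bonds = NULL),
  ethyl = list(elements = c("C", "C"),
               bonds = data.frame(a1 = 1L, a2 = 2L, order = 1L)),
  vinyl = list(elements = c("C", "C"),
               bonds = data.frame(a1 = 1L, a2 = 2L, order = 2L)),
  hydroxyl = list(elements = "O", bonds = NULL),
  chloride = list(elements = "Cl", bonds = NULL)
)

#' Generate test reactions sharing a base reaction's reactive center
#'
#' Random substituent fragments (methyl, ethyl, vinyl, hydroxyl, chloride)
#' replace hydrogens outside the reactive center, symmetrically on both
#' sides via the mapping (and previously added fragments may be removed
#' again), so each variant is a different reaction with the same center.
#' Hetero fragments are never attached adjacent to the center, keeping the
#' hetero-expanded template invariant too.
#'
#' @param record An `rxn_record` with a complete, accepted mapping.
#' @param map Atom map (defaults to `record$map`).
#' @param n Number of variants requested (default 25).
#' @param seed RNG seed.
#' @param include_hetero Center definition used for the untouchable atom set.
#' @return List of `rxn_record` variants (may be fewer than `n` for very
#'   small substrates, with a message).
#' @export
generate_test_reactions <- function(record, map = record$map, n = 25L,
                                    seed = 42L, include_hetero = TRUE) {
  set.seed(as.integer(seed))
  changes <- detect_changes(record, map)
  center <- build_reactive_center(record, changes, include_hetero)
  out <- list()
  seen <- character()
  base_key <- reaction_key(record)
  attempts <- 0L
  while (length(out) < n && attempts < n * 20L) {
    attempts <- attempts + 1L
    var <- tryCatch(make_variant(record, map, center$atom),
                    error = function(e) NULL)
    if (is.null(var)) next
    key <- reaction_key(var$record)
    if (key == base_key || key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- structure(var$record,
                                         added_fragments = var$added)
  }
  if (length(out) < n)
    message("generated ", length(out), " of ", n, " requested test reactions")
  out
}

reaction_key <- function(record) {
  paste(paste(side_keys(record$reactants), collapse = "|"),
        paste(side_keys(record$products), collapse = "||"))
}

# one variant: 1-3 random fragment additions (a later edit may remove an
# earlier fragment again)
make_variant <- function(record, map, center_atoms) {
  rmols <- record$reactants; pmols <- record$products
  cur_map <- map
  added <- list()          # each: list(r_atoms, p_atoms) global indices
  nedit <- sample.int(3L, 1L)
  for (q in seq_len(nedit)) {
    do_remove <- length(added) > 0L && stats::runif(1) < 0.25
    if (do_remove) {
      pick <- sample.int(length(added), 1L)
      res <- remove_fragment(rmols, pmols, cur_map, added[[pick]], center_atoms)
      rmols <- res$rmols; pmols <- res$pmols; cur_map <- res$map
      # indices of the other added fragments shift; drop their tracking
      added <- list()
    } else {
      res <- add_fragment(rmols, pmols, cur_map, center_atoms)
      if (is.null(res)) next
      rmols <- res$rmols; pmols <- res$pmols; cur_map <- res$map
      added[[length(added) + 1L]] <- res$added
    }
    center_atoms <- res$center_atoms
  }
  if (!length(added) && identical(reaction_key_mols(rmols, pmols),
                                  reaction_key_mols(record$reactants,
                                                    record$products)))
    return(NULL)
  list(record = reaction_record(rmols, pmols, map = cur_map,
                                source_id = paste0(record$source_id, "_v"),
                                origin_format = "synthetic",
                                family = record$family),
       added = added)
}

reaction_key_mols <- function(r, p)
  paste(paste(side_keys(r), collapse = "|"), paste(side_keys(p), collapse = "||"))

# replace a non-center hydrogen (and its image) by a fragment
add_fragment <- function(rmols, pmols, map, center_atoms) {
  rs <- side_info(rmols); ps <- side_info(pmols)
  frag_name <- sample(names(.FRAGMENTS), 1L)
  frag <- .FRAGMENTS[[frag_name]]
  hetero <- any(!frag$elements %in% c("C", "H"))
  # candidate hydrogens: outside the center, anchored at a heavy atom that
  # is outside the center too when the fragment is hetero (keeps
  # hetero-expanded centers invariant); image anchor consistent
  hs <- setdiff(which(rs$element == "H"), center_atoms)
  cand <- integer(0)
  for (h in hs) {
    anchor <- which(rs$adj[h, ] > 0L)
    if (length(anchor) != 1L || rs$element[anchor] == "H") next
    if (hetero && anchor %in% center_atoms) next
    p_h <- map[h]
    p_anchor <- which(ps$adj[p_h, ] > 0L)
    if (length(p_anchor) != 1L || ps$element[p_anchor] == "H") next
    if (map[anchor] != p_anchor) next    # hydrogen must ride with its anchor
    cand <- c(cand, h)
  }
  if (!length(cand)) return(NULL)
  h <- cand[sample.int(length(cand), 1L)]
  anchor <- which(rs$adj[h, ] > 0L)
  # perform symmetric replacement through the flattened sides
  rres <- splice_fragment(rmols, h, anchor, frag)
  pres <- splice_fragment(pmols, map[h], map[anchor], frag)
  # rebuild map: old atoms keep their correspondence via the index tables
  nnew <- sum(vapply(rres$mols, n_atoms, 0L))
  new_map <- rep(NA_integer_, nnew)
  for (i in seq_along(rres$old2new)) {
    if (is.na(rres$old2new[i]) || is.na(map[i])) next
    new_map[rres$old2new[i]] <- pres$old2new[map[i]]
  }
  for (k in seq_along(rres$new_atoms))
    new_map[rres$new_atoms[k]] <- pres$new_atoms[k]
  if (anyNA(new_map)) return(NULL)
  center_new <- rres$old2new[center_atoms]
  list(rmols = rres$mols, pmols = pres$mols, map = new_map,
       added = list(r_atoms = rres$new_atoms, p_atoms = pres$new_atoms,
                    anchor = rres$old2new[anchor]),
       center_atoms = center_new)
}

# splice one fragment in place of hydrogen h (anchored at heavy atom) on a
# molecule list; returns new molecule list plus index translations
splice_fragment <- function(mols, h, anchor, frag) {
  s <- side_info(mols)
  atoms <- do.call(rbind, lapply(mols, function(m) m$atoms))
  rownames(atoms) <- NULL
  bonds <- s$bonds
  # delete h
  keep <- setdiff(seq_len(s$n), h)
  old2mid <- rep(NA_integer_, s$n); old2mid[keep] <- seq_along(keep)
  bonds <- bonds[!(bonds$a1 == h | bonds$a2 == h), , drop = FALSE]
  bonds$a1 <- old2mid[bonds$a1]; bonds$a2 <- old2mid[bonds$a2]
  atoms <- atoms[keep, , drop = FALSE]
  # add fragment heavy atoms + their hydrogens
  base <- nrow(atoms)
  k <- length(frag$elements)
  frag_heavy <- base + seq_len(k)
  atoms <- rbind(atoms, data.frame(element = frag$elements,
                                   charge = 0L, radical = 0L,
                                   stereo = NA_character_,
                                   stringsAsFactors = FALSE))
  if (!is.null(frag$bonds)) {
    fb <- frag$bonds
    bonds <- rbind(bonds, data.frame(a1 = fb$a1 + base, a2 = fb$a2 + base,
                                     order = fb$order, arom = FALSE,
                                     stereo = NA_character_))
  }
  bonds <- rbind(bonds, data.frame(a1 = old2mid[anchor], a2 = frag_heavy[1],
                                   order = 1L, arom = FALSE,
                                   stereo = NA_character_))
  # fill fragment hydrogens
  bsum <- integer(nrow(atoms))
  for (e in seq_len(nrow(bonds))) {
    bsum[bonds$a1[e]] <- bsum[bonds$a1[e]] + bonds$order[e]
    bsum[bonds$a2[e]] <- bsum[bonds$a2[e]] + bonds$order[e]
  }
  new_atoms <- frag_heavy
  for (i in frag_heavy) {
    need <- min(allowed_valences(atoms$element[i], 0L)) - bsum[i]
    for (q in seq_len(max(need, 0L))) {
      atoms <- rbind(atoms, data.frame(element = "H", charge = 0L,
                                       radical = 0L, stereo = NA_character_,
                                       stringsAsFactors = FALSE))
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = nrow(atoms), order = 1L,
                                       arom = FALSE, stereo = NA_character_))
      new_atoms <- c(new_atoms, nrow(atoms))
    }
  }
  sp <- split_components(atoms, bonds)
  offs <- c(0L, cumsum(vapply(sp$mols, n_atoms, 0L)))
  mid2new <- offs[sp$index[, 1]] + sp$index[, 2]
  old2new <- rep(NA_integer_, s$n)
  old2new[keep] <- mid2new[seq_along(keep)]
  list(mols = sp$mols, old2new = old2new, new_atoms = mid2new[new_atoms])
}

# remove a previously added fragment (replace it by a hydrogen again)
remove_fragment <- function(rmols, pmols, map, added, center_atoms) {
  rres <- unsplice_fragment(rmols, added$r_atoms, added$anchor)
  p_anchor <- map[added$anchor]
  pres <- unsplice_fragment(pmols, map[added$r_atoms], p_anchor)
  nnew <- sum(vapply(rres$mols, n_atoms, 0L))
  new_map <- rep(NA_integer_, nnew)
  old <- setdiff(seq_along(rres$old2new), added$r_atoms)
  for (i in old) {
    if (is.na(rres$old2new[i])) next
    new_map[rres$old2new[i]] <- pres$old2new[map[i]]
  }
  new_map[rres$new_h] <- pres$new_h
  if (anyNA(new_map)) stop("fragment removal broke the map")
  list(rmols = rres$mols, pmols = pres$mols, map = new_map,
       center_atoms = rres$old2new[center_atoms])
}

unsplice_fragment <- function(mols, frag_atoms, anchor) {
  s <- side_info(mols)
  atoms <- do.call(rbind, lapply(mols, function(m) m$atoms))
  rownames(atoms) <- NULL
  bonds <- s$bonds
  keep <- setdiff(seq_len(s$n), frag_atoms)
  old2mid <- rep(NA_integer_, s$n); old2mid[keep] <- seq_along(keep)
  bonds <- bonds[!(bonds$a1 %in% frag_atoms | bonds$a2 %in% frag_atoms), , drop = FALSE]
  bonds$a1 <- old2mid[bonds$a1]; bonds$a2 <- old2mid[bonds$a2]
  atoms <- atoms[keep, , drop = FALSE]
  atoms <- rbind(atoms, data.frame(element = "H", charge = 0L, radical = 0L,
                                   stereo = NA_character_,
                                   stringsAsFactors = FALSE))
  bonds <- rbind(bonds, data.frame(a1 = old2mid[anchor], a2 = nrow(atoms),
                                   order = 1L, arom = FALSE,
                                   stereo = NA_character_))
  sp <- split_components(atoms, bonds)
  offs <- c(0L, cumsum(vapply(sp$mols, n_atoms, 0L)))
  mid2new <- offs[sp$index[, 1]] + sp$index[, 2]
  old2new <- rep(NA_integer_, s$n)
  old2new[keep] <- mid2new[seq_along(keep)]
  list(mols = sp$mols, old2new = old2new, new_h = mid2new[nrow(atoms)])
}

#' Round-trip validation of a processed corpus
#'
#' For every record with a complete accepted mapping, the template is
#' extracted and applied back to the record's reactants; the record passes
#' when its products appear among the generated product sets.
#'
#' @param corpus An `rxn_corpus` of mapped records.
#' @param include_hetero Passed to [extract_template()].
#' @return Data frame: source_id, family, pass, reason.
#' @export
round_trip_check <- function(corpus, include_hetero = TRUE) {
  out <- data.frame(source_id = character(), family = character(),
                    pass = logical(), reason = character(),
                    stringsAsFactors = FALSE)
  for (rec in corpus$records) {
    row <- list(rec$source_id, if (is.null(rec$family)) NA_character_ else rec$family,
                FALSE, "")
    res <- tryCatch({
      st <- validate_mapping(rec, rec$map)
      if (st$state != "complete") stop("mapping ", st$state)
      tpl <- extract_template(rec, include_hetero = include_hetero)
      if (template_round_trips(tpl)) list(TRUE, "")
      else list(FALSE, "products not regenerated")
    }, error = function(e) list(FALSE, conditionMessage(e)))
    row[[3]] <- res[[1]]; row[[4]] <- res[[2]]
    out[nrow(out) + 1L, ] <- row
  }
  out
}
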