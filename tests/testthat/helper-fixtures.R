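# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: eccentricity via igraph::distances,
# isomorphism and minimal-change mapping by exhaustive permutation.

# CH4 + H. -> CH3. + H2, the canonical hydrogen abstraction, mapped
habs_record <- function(map = 1:6, id = "habs") {
  reaction_record(list(parse_smiles("C"), parse_smiles("[H]")),
                  list(parse_smiles("[CH3]"), parse_smiles("[H][H]")),
                  map = map, source_id = id)
}

# apply an atom permutation to a molecule (new index of atom i = p[i])
perm_mol <- function(m, p) {
  inv <- order(p)
  b <- m$bonds
  b$a1 <- p[b$a1]; b$a2 <- p[b$a2]
  molecule(m$atoms$element[inv], b,
           charge = m$atoms$charge[inv], radical = m$atoms$radical[inv],
           stereo = m$atoms$stereo[inv])
}

all_perms <- function(n) {
  if (n == 0L) return(matrix(integer(), 1, 0))
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
}

# Brute-force isomorphism over heavy-atom bijections; hydrogens enter as a
# per-heavy-atom count attribute (enumerating H permutations would be
# astronomically wasteful and cannot change the answer).
brute_isomorphic <- function(a, b) {
  if (n_atoms(a) != n_atoms(b)) return(FALSE)
  sa <- side_info(list(a)); sb <- side_info(list(b))
  if (!identical(sort(sa$element), sort(sb$element))) return(FALSE)
  ha <- which(sa$element != "H"); hb <- which(sb$element != "H")
  hc <- function(s, idx) vapply(idx, function(i)
    sum(s$adj[i, ] > 0L & s$element == "H"), 0L)
  attr_a <- paste(sa$element[ha], sa$charge[ha], sa$radical[ha], hc(sa, ha))
  attr_b <- paste(sb$element[hb], sb$charge[hb], sb$radical[hb], hc(sb, hb))
  if (!identical(sort(attr_a), sort(attr_b))) return(FALSE)
  if (!length(ha)) return(TRUE)
  Aa <- sa$adj[ha, ha, drop = FALSE]; Ab <- sb$adj[hb, hb, drop = FALSE]
  perms <- all_perms(length(ha))
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (all(attr_a == attr_b[p]) && all(Aa == Ab[p, p])) return(TRUE)
  }
  FALSE
}

# exhaustive minimal-change mapping oracle: every element-preserving
# bijection between the two sides, counting atoms whose neighborhood
# (by mapped index and bond order), radical or charge state changed
brute_min_changes <- function(record) {
  rs <- side_info(record$reactants); ps <- side_info(record$products)
  els <- unique(rs$element)
  gr <- lapply(els, function(e) which(rs$element == e))
  gp <- lapply(els, function(e) which(ps$element == e))
  perms <- lapply(gr, function(g) all_perms(length(g)))
  counts <- vapply(perms, nrow, 0L)
  best <- Inf
  for (ci in seq_len(prod(counts))) {
    idx <- arrayInd(ci, counts)[1, ]
    map <- integer(rs$n)
    for (k in seq_along(els)) map[gr[[k]]] <- gp[[k]][perms[[k]][idx[k], ]]
    B <- ps$adj[map, map, drop = FALSE]
    cc <- sum((rowSums(rs$adj != B) > 0L) |
                (rs$radical != ps$radical[map]) |
                (rs$charge != ps$charge[map]))
    if (cc < best) best <- cc
  }
  best
}

# random small molecule for property tests: carbon tree skeleton (degree
# respected) optionally capped with one oxygen, then explicit H fill
random_test_mol <- function(max_heavy = 5L) {
  nh <- sample.int(max_heavy, 1L)
  els <- rep("C", nh)
  bonds <- NULL
  deg <- integer(nh)
  if (nh > 1L) {
    a1 <- integer(nh - 1L)
    for (i in 2:nh) {
      open <- which(deg[seq_len(i - 1L)] < 4L)
      a1[i - 1L] <- open[sample.int(length(open), 1L)]
      deg[a1[i - 1L]] <- deg[a1[i - 1L]] + 1L
      deg[i] <- 1L
    }
    bonds <- data.frame(a1 = a1, a2 = 2:nh, order = 1L)
  }
  if (stats::runif(1) < 0.4) {
    open <- which(deg < 4L)
    at <- open[sample.int(length(open), 1L)]
    els <- c(els, "O")
    bonds <- rbind(bonds, data.frame(a1 = at, a2 = length(els), order = 1L))
  }
  templater:::fill_hydrogens(els, bonds)
}

# the nine constitutional isomers of heptane
heptane_isomers <- c(
  "CCCCCCC", "CC(C)CCCC", "CCC(C)CCC", "CC(C)(C)CCC", "CCC(C)(C)CC",
  "CC(C)C(C)CC", "CC(C)CC(C)C", "CC(C)(C)C(C)C", "CCC(CC)CC")

# a 1-pentyl radical 1-5 hydrogen shift record (center C1, C5, H)
shift15_record <- function() {
  m <- templater:::primary_radical_chain(5L)
  rs <- side_info(list(m))
  h <- templater:::h_on(rs, 5L)[1L]
  templater:::record_from_edit(list(m), function(atoms, bonds) {
    bonds <- templater:::del_bond(bonds, 5L, h)
    bonds <- templater:::add_bond(bonds, 1L, h)
    atoms$radical[1L] <- 0L
    atoms$radical[5L] <- 1L
    list(atoms = atoms, bonds = bonds)
  }, "shift15", "h_shift")
}

resample_int <- function(x) x[sample.int(length(x), 1L)]

# connectivity of an induced subset (independent simple BFS)
is_connected_subset <- function(mol, atoms) {
  atoms <- unique(atoms)
  if (length(atoms) <= 1L) return(TRUE)
  b <- mol$bonds
  b <- b[b$a1 %in% atoms & b$a2 %in% atoms, , drop = FALSE]
  seen <- atoms[1]
  repeat {
    grow <- unique(c(b$a2[b$a1 %in% seen], b$a1[b$a2 %in% seen]))
    new <- setdiff(grow, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  length(seen) == length(atoms)
}
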