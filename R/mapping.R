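# Atom-atom mapping: the pluggable mapper contract, the built-in baseline
# mapper (MCS-flavoured branch-and-bound minimizing the number of atoms
# whose bonding changed), resonance-combination selection, heuristic
# completion of symmetric gaps, and mapping validation.

#' Count atoms changed by a complete mapping
#'
#' Number of reactant atoms whose environment differs from their mapped
#' counterpart: different neighbor set (by mapping index), different bond
#' order to a neighbor, or different unpaired-electron / charge state.
#' Stereo is not counted here (mapper objective; see [detect_changes()] for
#' the full change taxonomy).
#'
#' @param record An `rxn_record`.
#' @param map Complete atom map (integer vector, no NA).
#' @return Integer count.
#' @export
map_change_count <- function(record, map) {
  rs <- side_info(record$reactants); ps <- side_info(record$products)
  change_count_fast(rs, ps, map)
}

change_count_fast <- function(rs, ps, map) {
  B <- ps$adj[map, map, drop = FALSE]
  changed <- (rowSums(rs$adj != B) > 0L) |
    (rs$radical != ps$radical[map]) | (rs$charge != ps$charge[map])
  sum(changed)
}

# secondary mapper objective: number of changed bonds (broken, formed or
# order-changed), mirroring "minimal structural- and bond changes"
bond_change_count <- function(rs, ps, map) {
  B <- ps$adj[map, map, drop = FALSE]
  sum(rs$adj != B) %/% 2L
}

#' Compute an atom-atom mapping
#'
#' @param record A balanced `rxn_record` without a mapping.
#' @param mapper `"baseline"` for the built-in minimal-change mapper, or a
#'   function `record -> integer map (NA allowed)` implementing the plug-in
#'   contract (e.g. an adapter around externally mapped RXN files).
#' @return List with `map` (integer vector, possibly with NAs) and `status`
#'   (a `mapping_status`: state + detail).
#' @export
compute_mapping <- function(record, mapper = "baseline") {
  if (is.function(mapper)) {
    map <- tryCatch(mapper(record), error = function(e) {
      return(structure(rep(NA_integer_, sum(vapply(record$reactants, n_atoms, 0L))),
                       failed = conditionMessage(e)))
    })
    fail <- attr(map, "failed")
    st <- if (!is.null(fail)) mapping_status("failed", fail)
          else validate_mapping(record, map)
    return(list(map = as.integer(map), status = st))
  }
  stopifnot(identical(mapper, "baseline"))
  if (!isTRUE(as.logical(is_balanced(record))))
    stop("baseline mapper requires a balanced reaction")
  map <- baseline_map(record)
  list(map = map, status = validate_mapping(record, map))
}

# ---- baseline mapper -------------------------------------------------------

# exact search over heavy-atom bijections (branch and bound on per-pair
# definite-change costs), then optimal hydrogen completion
baseline_map <- function(record) {
  rs <- side_info(record$reactants); ps <- side_info(record$products)
  rheavy <- which(rs$element != "H"); pheavy <- which(ps$element != "H")
  if (length(rheavy) != length(pheavy)) stop("unbalanced heavy atoms")

  # neighborhood profile: multiset of (element, order) pairs incl. H
  profile <- function(s, i) {
    nb <- which(s$adj[i, ] > 0L)
    paste(sort(paste(s$element[nb], s$adj[i, nb], sep = ":")), collapse = ",")
  }
  rprof <- vapply(rheavy, function(i) profile(rs, i), "")
  pprof <- vapply(pheavy, function(i) profile(ps, i), "")

  # definite per-pair cost: 1 if this reactant/product pair must differ
  nh <- length(rheavy)
  if (nh) {
    pc <- matrix(0L, nh, nh)
    for (i in seq_len(nh)) for (j in seq_len(nh)) {
      pc[i, j] <- as.integer(
        rs$radical[rheavy[i]] != ps$radical[pheavy[j]] ||
        rs$charge[rheavy[i]] != ps$charge[pheavy[j]] ||
        rprof[i] != pprof[j])
    }
    allowed <- outer(rs$element[rheavy], ps$element[pheavy], "==")
    if (any(rowSums(allowed) == 0L)) stop("element mismatch between sides")
  }

  # deterministic atom orders: per-molecule canonical rank
  rank_of <- function(mols, s) {
    rk <- numeric(s$n)
    for (m in seq_along(mols)) {
      cr <- canonical_atom_ranks(mols[[m]])
      rk[s$offsets[m] + seq_len(n_atoms(mols[[m]]))] <- cr
    }
    order(s$mol_of * 1e6 + rk)   # global deterministic order
  }
  rord <- rank_of(record$reactants, rs)

  best_map <- NULL
  best_cost <- Inf
  best_bonds <- Inf

  if (nh == 0L) {
    cand <- hydrogen_completion(rs, ps, integer(0), integer(0))
    return(cand$map)
  }

  # order heavy atoms: scarcer elements first, then deterministic order
  scarcity <- table(rs$element[rheavy])
  hord <- rheavy[order(scarcity[rs$element[rheavy]], match(rheavy, rord))]
  hpos <- match(hord, rheavy)

  assigned_p <- rep(FALSE, nh)
  cur <- integer(nh)                 # cur[i]: product heavy slot for rheavy slot i

  rec_search <- function(k, lb) {
    if (lb > best_cost) return()
    if (k > nh) {
      comp <- hydrogen_completion(rs, ps, rheavy[hpos], pheavy[cur[hpos]])
      if (comp$cost < best_cost ||
          (comp$cost == best_cost && comp$bonds < best_bonds)) {
        best_cost <<- comp$cost
        best_bonds <<- comp$bonds
        best_map <<- comp$map
      }
      return()
    }
    i <- hpos[k]
    cands <- which(!assigned_p & allowed[i, ])
    # deterministic candidate order; try definite-match pairs first
    cands <- cands[order(pc[i, cands], cands)]
    for (j in cands) {
      cur[i] <<- j; assigned_p[j] <<- TRUE
      rec_search(k + 1L, lb + pc[i, j])
      assigned_p[j] <<- FALSE
    }
  }
  rec_search(1L, 0L)
  best_map
}

# Given the heavy-atom assignment, map hydrogens: along their anchors first
# (each heavy pair keeps min(#H, #H') of its hydrogens), the few leftovers by
# exhaustive permutation (they are the migrating/free hydrogens). Returns the
# full map and its exact change count.
hydrogen_completion <- function(rs, ps, rh, ph) {
  n <- rs$n
  map <- rep(NA_integer_, n)
  map[rh] <- ph
  h_r <- setdiff(which(rs$element == "H"), rh)
  h_p <- setdiff(which(ps$element == "H"), ph)
  # anchored assignment
  left_r <- integer(0)
  used_p <- logical(ps$n)
  used_p[ph] <- TRUE
  anchor <- function(s, i) {
    nb <- which(s$adj[i, ] > 0L)
    hv <- nb[s$element[nb] != "H"]
    if (length(hv) == 1L) hv else NA_integer_
  }
  ra <- vapply(h_r, function(i) anchor(rs, i), 0L)
  pa <- vapply(h_p, function(i) anchor(ps, i), 0L)
  for (t in seq_along(rh)) {
    hr <- h_r[!is.na(ra) & ra == rh[t]]
    hp <- h_p[!is.na(pa) & pa == ph[t]]
    k <- min(length(hr), length(hp))
    if (k) {
      map[hr[seq_len(k)]] <- hp[seq_len(k)]
      used_p[hp[seq_len(k)]] <- TRUE
    }
    if (length(hr) > k) left_r <- c(left_r, hr[(k + 1L):length(hr)])
  }
  left_r <- c(left_r, h_r[is.na(ra)])
  left_p <- setdiff(h_p, which(used_p))
  nl <- length(left_r)
  stopifnot(nl == length(left_p))
  if (nl == 0L) {
    return(list(map = map, cost = change_count_fast(rs, ps, map),
                bonds = bond_change_count(rs, ps, map)))
  }
  if (nl <= 5L) {
    perms <- permutations_of(nl)
    best <- NULL; bc <- Inf; bb <- Inf
    for (r in seq_len(nrow(perms))) {
      m2 <- map; m2[left_r] <- left_p[perms[r, ]]
      cc <- change_count_fast(rs, ps, m2)
      if (cc > bc) next
      b2 <- bond_change_count(rs, ps, m2)
      if (cc < bc || b2 < bb) { bc <- cc; bb <- b2; best <- m2 }
    }
    return(list(map = best, cost = bc, bonds = bb))
  }
  # many leftover hydrogens: first-fit (they are all changed anyway in the
  # chemistry this mapper targets)
  map[left_r] <- left_p
  list(map = map, cost = change_count_fast(rs, ps, map),
       bonds = bond_change_count(rs, ps, map))
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# ---- resonance combination selection ---------------------------------------

#' Select the resonance-structure combination with the fewest reactive atoms
#'
#' Every molecule (both sides) is expanded into its localized resonance
#' structures; the Cartesian product of combinations (capped) is mapped and
#' the combination minimizing the number of changed atoms is retained.
#' Ties go to the first combination in deterministic enumeration order
#' (input structures first).
#'
#' @param record A balanced `rxn_record` without mapping.
#' @param mapper Passed to [compute_mapping()].
#' @param cap Maximum number of combinations (default 64); on overflow the
#'   input structures are used as-is with a logged message.
#' @return List with `record` (chosen variant, map filled in), `map`,
#'   `status`, `cost` (reactive-atom count).
#' @export
select_resonance_combination <- function(record, mapper = "baseline", cap = 64L) {
  rres <- lapply(record$reactants, enumerate_resonance)
  pres <- lapply(record$products, enumerate_resonance)
  counts <- c(vapply(rres, length, 0L), vapply(pres, length, 0L))
  ncomb <- prod(counts)
  if (ncomb > cap) {
    message("resonance combination cap exceeded (", ncomb, " > ", cap,
            "); using input structures")
    rres <- lapply(rres, `[`, 1L); pres <- lapply(pres, `[`, 1L)
    counts <- rep(1L, length(counts))
    ncomb <- 1L
  }
  nr <- length(rres)
  best <- NULL
  for (ci in seq_len(ncomb)) {
    idx <- arrayInd(ci, counts)[1, ]
    var <- record
    var$reactants <- lapply(seq_len(nr), function(m) rres[[m]][[idx[m]]])
    var$products <- lapply(seq_along(pres), function(m) pres[[m]][[idx[nr + m]]])
    res <- compute_mapping(var, mapper)
    if (res$status$state != "complete") next
    cost <- map_change_count(var, res$map)
    if (is.null(best) || cost < best$cost) {
      var$map <- res$map
      best <- list(record = var, map = res$map, status = res$status, cost = cost)
    }
  }
  if (is.null(best)) {
    res <- compute_mapping(record, mapper)
    best <- list(record = record, map = res$map, status = res$status, cost = NA_integer_)
  }
  best
}

# ---- mapping status / validation / heuristic completion --------------------

#' Mapping status
#' @param state One of `"complete"`, `"heuristically_completed"`,
#'   `"incomplete"`, `"failed"`.
#' @param detail Free-text detail.
#' @return A `mapping_status` list.
#' @export
mapping_status <- function(state, detail = "") {
  stopifnot(state %in% c("complete", "heuristically_completed", "incomplete", "failed"))
  structure(list(state = state, detail = detail), class = "mapping_status")
}

#' Validate an atom map
#'
#' Complete iff every atom on both sides is in exactly one pair; an
#' element-mismatched pair makes the mapping `failed`.
#'
#' @param record An `rxn_record`.
#' @param map Integer map (NA = unmapped) or NULL.
#' @return A `mapping_status`.
#' @export
validate_mapping <- function(record, map) {
  rs <- side_info(record$reactants); ps <- side_info(record$products)
  if (is.null(map) || all(is.na(map)))
    return(mapping_status("failed", "no atoms mapped"))
  mapped <- which(!is.na(map))
  tgt <- map[mapped]
  if (anyDuplicated(tgt))
    return(mapping_status("failed", "map not injective"))
  bad <- mapped[rs$element[mapped] != ps$element[tgt]]
  if (length(bad))
    return(mapping_status("failed", paste0("element mismatch at reactant atom ",
                                           bad[1])))
  if (length(mapped) == rs$n && rs$n == ps$n) mapping_status("complete")
  else mapping_status("incomplete",
                      sprintf("%d of %d reactant atoms mapped", length(mapped), rs$n))
}

#' Heuristically complete a symmetric mapping gap
#'
#' Fires only when exactly two reactant atoms and two product atoms of one
#' element are unmapped and the two unmapped atoms on at least one side
#' (reactants checked first) sit in identical chemical environments. The pair
#' assignment retaining the most mapped (neighbor, bond) relations from the
#' reactant molecule wins; remaining ties go to the assignment pairing the
#' lower reactant index with the lower product index. Forbidden patterns
#' (nothing mapped; extra lone atoms; no symmetry on either side) leave the
#' input untouched.
#'
#' @param record An `rxn_record`.
#' @param partial Integer map with NAs.
#' @return List with `map` and `status`.
#' @export
complete_symmetric_gap <- function(record, partial) {
  rs <- side_info(record$reactants); ps <- side_info(record$products)
  st <- validate_mapping(record, partial)
  if (st$state %in% c("complete", "failed"))
    return(list(map = partial, status = st))
  if (all(is.na(partial)))
    return(list(map = partial, status = mapping_status("failed", "no atoms mapped")))
  ur <- which(is.na(partial))
  up <- setdiff(seq_len(ps$n), partial[!is.na(partial)])
  if (length(ur) != 2L || length(up) != 2L)
    return(list(map = partial,
                status = mapping_status("incomplete",
                                        "more than two atoms unmapped")))
  els <- unique(c(rs$element[ur], ps$element[up]))
  if (length(els) != 1L)
    return(list(map = partial,
                status = mapping_status("incomplete", "unmapped atoms of mixed elements")))
  sym_r <- environments_identical(
    record$reactants[[rs$mol_of[ur[1]]]], rs$atom_of[ur[1]],
    record$reactants[[rs$mol_of[ur[2]]]], rs$atom_of[ur[2]],
    same_molecule = rs$mol_of[ur[1]] == rs$mol_of[ur[2]])
  sym_p <- sym_r || environments_identical(
    record$products[[ps$mol_of[up[1]]]], ps$atom_of[up[1]],
    record$products[[ps$mol_of[up[2]]]], ps$atom_of[up[2]],
    same_molecule = ps$mol_of[up[1]] == ps$mol_of[up[2]])
  if (!sym_p)
    return(list(map = partial,
                status = mapping_status("incomplete",
                                        "unmapped atoms not in identical environments")))
  retained <- function(assign) {
    m2 <- partial; m2[ur] <- assign
    tot <- 0L
    for (i in ur) {
      nb <- which(rs$adj[i, ] > 0L)
      for (v in nb) {
        if (is.na(m2[v])) next
        if (ps$adj[m2[i], m2[v]] == rs$adj[i, v]) tot <- tot + 1L
      }
    }
    tot
  }
  opts <- list(up, rev(up))
  sc <- vapply(opts, retained, 0L)
  pick <- opts[[which.max(sc)]]        # ties: first option (lower index pairing)
  m2 <- partial; m2[ur] <- pick
  list(map = m2,
       status = mapping_status("heuristically_completed",
                               sprintf("completed %s pair by symmetry", els)))
}
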