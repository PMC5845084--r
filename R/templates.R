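# Reaction templates: extraction from a mapped reaction, canonical identity,
# deduplication with counts, reverse-pair detection, SMARTS formalization,
# constraints, application to new reactants, and rule-based classification.

.ACTION_ORDER <- c(BREAK_BOND = 1L, CHANGE_BOND_ORDER = 2L, FORM_BOND = 3L,
                   GAIN_RADICAL = 4L, LOSE_RADICAL = 5L, CHANGE_CHARGE = 6L,
                   CHANGE_STEREO = 7L)

#' Extract a reaction template from a mapped reaction
#'
#' @param record An `rxn_record`.
#' @param map Complete atom map (defaults to `record$map`).
#' @param include_hetero Expand the center with adjacent hetero atoms.
#' @return A `rxn_template`: center fragments (atoms annotated with element,
#'   charge, unpaired electrons, neighbor count X, valence v, role and
#'   label), the recipe (ordered actions over labels), a canonical signature
#'   used for equality/dedup, status (`"ok"` or `"identical"`), and
#'   provenance (source id, reactant/product key signatures).
#' @export
extract_template <- function(record, map = record$map, include_hetero = TRUE) {
  changes <- detect_changes(record, map)
  center <- build_reactive_center(record, changes, include_hetero = include_hetero)
  rs <- side_info(record$reactants)
  ps <- side_info(record$products)

  atoms <- center$atom                     # flattened reactant indices, sorted
  label_of <- integer(rs$n); label_of[atoms] <- seq_along(atoms)
  deg <- rowSums(rs$adj > 0L)
  val <- rowSums(rs$adj)

  frag_ids <- sort(unique(center$mol))
  fragments <- lapply(frag_ids, function(m) {
    sel <- which(center$mol == m)
    ga <- atoms[sel]
    loc <- match(ga, ga)                    # 1..k local
    b <- rs$bonds[rs$bonds$a1 %in% ga & rs$bonds$a2 %in% ga, , drop = FALSE]
    list(src_mol = m,
         labels = label_of[ga],
         element = rs$element[ga], charge = rs$charge[ga],
         radical = rs$radical[ga], stereo = rs$stereo[ga],
         X = as.integer(deg[ga]), v = as.integer(val[ga]),
         role = center$role[sel],
         arom = vapply(ga, function(i) {
           any(rs$bonds$arom[rs$bonds$a1 == i | rs$bonds$a2 == i]) }, TRUE),
         bonds = data.frame(l1 = label_of[b$a1], l2 = label_of[b$a2],
                            order = b$order, arom = b$arom,
                            stringsAsFactors = FALSE))
  })

  it <- changes$items
  kind2action <- c(neighbor_loss = "BREAK_BOND", neighbor_gain = "FORM_BOND",
                   bond_order_change = "CHANGE_BOND_ORDER",
                   radical_gain = "GAIN_RADICAL", radical_loss = "LOSE_RADICAL",
                   charge_change = "CHANGE_CHARGE", stereo_change = "CHANGE_STEREO")
  recipe <- data.frame(action = unname(kind2action[it$kind]),
                       l1 = label_of[it$a1],
                       l2 = ifelse(is.na(it$a2), NA_integer_, label_of[it$a2]),
                       before = it$before, after = it$after,
                       stringsAsFactors = FALSE)
  recipe <- recipe[order(.ACTION_ORDER[recipe$action], recipe$l1, recipe$l2), ,
                   drop = FALSE]
  rownames(recipe) <- NULL
  status <- if (all(recipe$action == "CHANGE_STEREO")) "identical" else "ok"

  tpl <- structure(list(
    fragments = fragments,
    recipe = recipe,
    nfrag = length(fragments),
    status = status,
    count = 1L,
    source_ids = record$source_id,
    side_sigs = list(c(r = paste(side_keys(record$reactants), collapse = "|"),
                       p = paste(side_keys(record$products), collapse = "|"))),
    reverse_of = NA_integer_,
    rep_record = record,
    center_atoms = atoms                 # flattened reactant indices, by label
  ), class = "rxn_template")
  tpl$sig <- template_signature(tpl)
  tpl
}

#' @export
print.rxn_template <- function(x, ...) {
  cat(sprintf("<rxn_template> %d fragment(s): %s | %d action(s) | status %s | count %d\n",
              x$nfrag, paste(generate_center_smarts(x), collapse = " + "),
              nrow(x$recipe), x$status, x$count))
  invisible(x)
}

# canonical signature: colored-graph canonical serialization of the labeled
# center (atoms: element/charge/radical/X/v/role + atom-level recipe actions;
# edges: real bonds with order/arom plus their bond-level actions, and
# virtual FORM_BOND edges). The formalized signature drops stereo actions so
# stereo-only templates collapse to "identical" consistently.
template_signature <- function(tpl) {
  nall <- sum(vapply(tpl$fragments, function(f) length(f$labels), 0L))
  vt <- character(nall); fragof <- integer(nall)
  for (fi in seq_along(tpl$fragments)) {
    f <- tpl$fragments[[fi]]
    vt[f$labels] <- paste(f$element, f$charge, f$radical, f$X, f$v, f$role,
                          f$arom, sep = "|")
    fragof[f$labels] <- fi
  }
  r <- tpl$recipe
  atom_act <- vapply(seq_len(nall), function(l) {
    sel <- which(is.na(r$l2) & r$l1 == l & r$action != "CHANGE_STEREO")
    paste(sprintf("%s:%s>%s", r$action[sel], r$before[sel], r$after[sel]),
          collapse = ",")
  }, "")
  vt <- paste(vt, atom_act, sep = "||")
  edges <- matrix(integer(), ncol = 2); et <- character()
  for (f in tpl$fragments) {
    if (nrow(f$bonds)) {
      edges <- rbind(edges, cbind(f$bonds$l1, f$bonds$l2))
      et <- c(et, paste("bond", f$bonds$order, f$bonds$arom, sep = "|"))
    }
  }
  bond_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ekey <- bond_key(edges[, 1], edges[, 2])
  for (k in which(!is.na(r$l2))) {
    if (r$action[k] == "FORM_BOND") {
      edges <- rbind(edges, c(r$l1[k], r$l2[k]))
      et <- c(et, sprintf("form|%s", r$after[k]))
      ekey <- c(ekey, bond_key(r$l1[k], r$l2[k]))
    } else {
      hit <- which(ekey == bond_key(r$l1[k], r$l2[k]))
      if (length(hit)) et[hit[1]] <- paste0(et[hit[1]], sprintf(
        "|%s:%s>%s", r$action[k], r$before[k], r$after[k]))
    }
  }
  canonical_serial(nall, vt, edges, et)
}

#' Are two templates equal?
#'
#' True iff the labeled reactive centers are isomorphic under a
#' label-preserving mapping that also identifies the recipes item-for-item
#' (implemented via canonical signature equality).
#'
#' @param a,b `rxn_template` objects.
#' @return Logical.
#' @export
template_equals <- function(a, b) identical(a$sig, b$sig)

#' Are two templates the reverse of each other?
#'
#' Implements the two-part species-level check: some representative reaction
#' of one template has products equal to the reactants of a representative of
#' the other and vice versa; additionally each template must regenerate its
#' own products when applied to its representative reactants (recipe
#' consistency). The check is symmetric and deliberately species-level,
#' reproducing the documented false positive for hydrogen shifts of
#' different spans between the same two species.
#'
#' @param a,b `rxn_template` objects.
#' @param check_application Verify recipe application (default TRUE; the
#'   table-level linker caches this per template).
#' @return Logical.
#' @export
is_reverse_pair <- function(a, b, check_application = TRUE) {
  cross <- function(x, y) {
    for (sx in x$side_sigs) for (sy in y$side_sigs) {
      if (identical(sx[["r"]], sy[["p"]]) && identical(sx[["p"]], sy[["r"]]))
        return(TRUE)
    }
    FALSE
  }
  if (!cross(a, b)) return(FALSE)
  if (check_application) {
    if (!template_round_trips(a) || !template_round_trips(b)) return(FALSE)
  }
  TRUE
}

#' Does a template regenerate its own source products?
#' @param tpl An `rxn_template`.
#' @return Logical.
#' @export
template_round_trips <- function(tpl) {
  rec <- tpl$rep_record
  out <- apply_template(tpl, rec$reactants, check_constraints = FALSE)
  want <- side_keys(rec$products)
  for (ps in out) if (identical(side_keys(ps), want)) return(TRUE)
  FALSE
}

#' Deduplicate a stream of templates and count representatives
#'
#' @param templates List of `rxn_template`s (one per source reaction).
#' @return List of unique templates; each carries `count`, merged
#'   `source_ids` / `side_sigs`, `reverse_of` (index of its reverse partner
#'   in the returned list, NA if none; self-inverse templates link to
#'   themselves) and `is_reverse` (TRUE for the later member of a reverse
#'   pair, mirroring the "labeled reverse" bookkeeping).
#' @export
deduplicate_and_count <- function(templates) {
  if (!length(templates)) return(list())
  sigs <- vapply(templates, function(t) t$sig, "")
  ord <- order(match(sigs, unique(sigs)))    # stable: first occurrence order
  table_ <- list()
  idx_of <- integer(0)
  for (i in seq_along(templates)) {
    t <- templates[[i]]
    hit <- match(t$sig, names(idx_of))
    if (is.na(hit)) {
      table_[[length(table_) + 1L]] <- t
      idx_of[t$sig] <- length(table_)
    } else {
      j <- idx_of[[t$sig]]
      table_[[j]]$count <- table_[[j]]$count + 1L
      table_[[j]]$source_ids <- c(table_[[j]]$source_ids, t$source_ids)
      ss <- table_[[j]]$side_sigs
      if (!any(vapply(ss, identical, TRUE, t$side_sigs[[1]])))
        table_[[j]]$side_sigs <- c(ss, t$side_sigs)
    }
  }
  # reverse links (application validity cached per template)
  n <- length(table_)
  valid <- vapply(table_, function(t)
    tryCatch(template_round_trips(t), error = function(e) FALSE), TRUE)
  for (j in seq_len(n)) {
    table_[[j]]$is_reverse <- FALSE
    for (i in seq_len(j)) {
      if (!(valid[i] && valid[j])) next
      if (is_reverse_pair(table_[[i]], table_[[j]], check_application = FALSE)) {
        table_[[j]]$reverse_of <- i
        table_[[j]]$is_reverse <- i < j
        if (is.na(table_[[i]]$reverse_of)) table_[[i]]$reverse_of <- j
        break
      }
    }
  }
  table_
}

# ---- SMARTS ----------------------------------------------------------------

smarts_atom_token <- function(el, charge, X, v, arom) {
  # hydrogen as an element must be written #1 in SMARTS ([H...] would read
  # as a hydrogen-count primitive)
  sym <- if (el == "H") "#1" else if (arom) tolower(el) else el
  chg <- if (charge > 0L) paste0("+", if (charge > 1L) charge else "")
         else if (charge < 0L) paste0("-", if (charge < -1L) -charge else "")
         else ""
  sprintf("[%sX%dv%d%s]", sym, X, v, chg)
}

# DFS SMARTS over one fragment, optionally rooted at a given local atom
fragment_smarts <- function(frag, root_local = 1L) {
  k <- length(frag$labels)
  adj <- vector("list", k)
  b <- frag$bonds
  lmap <- match(seq_along(frag$labels), order(frag$labels)) # local positions
  # local indices: fragment arrays are ordered by label; bonds use labels
  l2loc <- integer(max(frag$labels)); l2loc[frag$labels] <- seq_len(k)
  if (nrow(b)) for (e in seq_len(nrow(b))) {
    i <- l2loc[b$l1[e]]; j <- l2loc[b$l2[e]]
    adj[[i]] <- rbind(adj[[i]], c(j, b$order[e], b$arom[e]))
    adj[[j]] <- rbind(adj[[j]], c(i, b$order[e], b$arom[e]))
  }
  bsym <- function(o, ar) if (ar) ":" else switch(o, "-", "=", "#")
  tok <- vapply(seq_len(k), function(i) smarts_atom_token(
    frag$element[i], frag$charge[i], frag$X[i], frag$v[i], frag$arom[i]), "")
  seen <- rep(FALSE, k)
  tree_children <- vector("list", k)
  back_edges <- list()
  dfs <- function(i, parent) {
    seen[i] <<- TRUE
    nb <- adj[[i]]
    skipped <- FALSE
    if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
      j <- nb[r, 1]
      if (j == parent && !skipped) { skipped <- TRUE; next }
      if (seen[j]) {
        key <- paste(min(i, j), max(i, j))
        if (is.null(back_edges[[key]])) back_edges[[key]] <<- c(i, j, nb[r, 2], nb[r, 3])
      } else {
        tree_children[[i]] <<- rbind(tree_children[[i]], nb[r, , drop = FALSE])
        dfs(j, i)
      }
    }
  }
  dfs(root_local, 0L)
  if (!all(seen)) stop("fragment not connected")
  ring_at <- vector("list", k); dig <- 0L
  for (key in names(back_edges)) {
    dig <- dig + 1L
    e <- back_edges[[key]]
    lab <- if (dig < 10L) as.character(dig) else paste0("%", dig)
    ring_at[[e[1]]] <- rbind(ring_at[[e[1]]], c(lab, bsym(e[3], e[4] == 1)))
    ring_at[[e[2]]] <- rbind(ring_at[[e[2]]], c(lab, ""))
  }
  build <- function(i) {
    parts <- tok[i]
    ra <- ring_at[[i]]
    if (!is.null(ra)) for (r in seq_len(nrow(ra))) parts <- paste0(parts, ra[r, 2], ra[r, 1])
    ch <- tree_children[[i]]
    if (!is.null(ch)) {
      nc <- nrow(ch)
      for (r in seq_len(nc)) {
        sub <- paste0(bsym(ch[r, 2], ch[r, 3] == 1), build(ch[r, 1]))
        parts <- paste0(parts, if (r < nc) paste0("(", sub, ")") else sub)
      }
    }
    parts
  }
  build(root_local)
}

#' Center SMARTS patterns of a template
#'
#' One pattern per reactant fragment: every atom carries its neighbor count
#' (`X`) and valence (`v`) as measured in the source molecule (hydrogens
#' included), all bonds are explicit, and atoms of aromatic systems are
#' re-marked aromatic.
#'
#' @param tpl An `rxn_template`.
#' @return Character vector of SMARTS patterns.
#' @export
generate_center_smarts <- function(tpl) {
  vapply(tpl$fragments, fragment_smarts, "")
}

#' Atom-first SMARTS for a labeled center atom
#'
#' The pattern of the whole fragment containing the target atom, written so
#' the target atom comes first (the atom order is permuted until the
#' identifier starts with the desired atom); matching semantics are identical
#' to the center pattern.
#'
#' @param tpl An `rxn_template`.
#' @param label Center atom label (1-based over all center atoms).
#' @return SMARTS string.
#' @export
generate_atom_first_smarts <- function(tpl, label) {
  for (f in tpl$fragments) {
    loc <- match(label, f$labels)
    if (!is.na(loc)) return(fragment_smarts(f, loc))
  }
  stop("label ", label, " not in template center")
}

#' Generate the molecular constraints of a template
#'
#' A global constraint limits molecule size to the largest molecule in the
#' analyzed corpus (heavy atoms); per reactant, the number of single
#' electrons is limited to that of the template's source reactant.
#'
#' @param corpus An `rxn_corpus` (non-empty).
#' @param tpl An `rxn_template`.
#' @return Data frame with columns scope, kind, value, reactant.
#' @export
generate_constraints <- function(corpus, tpl) {
  stopifnot(n_records(corpus) >= 1L)
  maxheavy <- max(vapply(corpus$records, function(r)
    max(vapply(c(r$reactants, r$products), heavy_atom_count, 0L)), 0L))
  out <- data.frame(scope = "global", kind = "max_heavy_atoms",
                    value = maxheavy, reactant = NA_integer_,
                    stringsAsFactors = FALSE)
  for (fi in seq_along(tpl$fragments)) {
    m <- tpl$rep_record$reactants[[tpl$fragments[[fi]]$src_mol]]
    out <- rbind(out, data.frame(scope = "per_reactant",
                                 kind = "max_single_electrons",
                                 value = radical_count(m), reactant = fi,
                                 stringsAsFactors = FALSE))
  }
  out
}

# ---- application -----------------------------------------------------------

# all embeddings of a fragment pattern into a molecule: list of integer
# vectors (target atom per fragment label position)
fragment_embeddings <- function(frag, mol) {
  k <- length(frag$labels)
  deg <- degrees(mol); val <- bond_order_sums(mol)
  ttup <- paste(mol$atoms$element, mol$atoms$charge, deg, val)
  ptup <- paste(frag$element, frag$charge, frag$X, frag$v)
  lev <- sort(unique(c(ttup, ptup)))
  if (!all(ptup %in% ttup)) return(list())
  l2loc <- integer(max(frag$labels)); l2loc[frag$labels] <- seq_len(k)
  pg <- igraph::make_empty_graph(n = k, directed = FALSE)
  eords <- integer(0)
  if (nrow(frag$bonds)) {
    pg <- igraph::add_edges(pg, rbind(l2loc[frag$bonds$l1], l2loc[frag$bonds$l2]))
    eords <- frag$bonds$order
  }
  tg <- mol_igraph(mol)
  elev <- sort(unique(c(eords, mol$bonds$order)))
  # igraph's vf2 backend takes (target, pattern): color1 = target, color2 =
  # pattern; each returned map is pattern position -> target vertex
  maps <- igraph::subgraph_isomorphisms(
    pg, tg, method = "vf2",
    vertex.color1 = as.integer(factor(ttup, lev)),
    vertex.color2 = as.integer(factor(ptup, lev)),
    edge.color1 = as.integer(factor(mol$bonds$order, elev)),
    edge.color2 = as.integer(factor(eords, elev)))
  out <- list()
  A <- matrix(0L, n_atoms(mol), n_atoms(mol))
  if (nrow(mol$bonds)) {
    A[cbind(mol$bonds$a1, mol$bonds$a2)] <- mol$bonds$order
    A[cbind(mol$bonds$a2, mol$bonds$a1)] <- mol$bonds$order
  }
  P <- matrix(0L, k, k)
  if (nrow(frag$bonds)) {
    P[cbind(l2loc[frag$bonds$l1], l2loc[frag$bonds$l2])] <- frag$bonds$order
    P[cbind(l2loc[frag$bonds$l2], l2loc[frag$bonds$l1])] <- frag$bonds$order
  }
  for (mm in maps) {
    v <- as.integer(mm)
    # induced check: non-bonded pattern atoms must stay non-bonded
    if (any((P == 0L) & (A[v, v, drop = FALSE] != 0L) &
            upper.tri(P))) next
    out[[length(out) + 1L]] <- v
  }
  out
}

#' Apply a template to reactant molecules
#'
#' Finds every embedding of the center patterns into the supplied molecules
#' (over all assignments of patterns to molecules), applies the recipe and
#' returns the valence-valid product molecule sets, deduplicated by
#' canonical key.
#'
#' @param tpl An `rxn_template`.
#' @param mols List of `mol` objects, one per template reactant.
#' @param check_constraints Enforce `constraints` when supplied.
#' @param constraints Optional data frame from [generate_constraints()].
#' @return List of product molecule lists (possibly empty).
#' @export
apply_template <- function(tpl, mols, check_constraints = TRUE,
                           constraints = NULL) {
  if (length(mols) != tpl$nfrag)
    stop("template expects ", tpl$nfrag, " reactant(s)")
  if (check_constraints && !is.null(constraints)) {
    g <- constraints[constraints$scope == "global", ]
    if (nrow(g) && any(vapply(mols, heavy_atom_count, 0L) > g$value[1]))
      return(list())
    pr <- constraints[constraints$scope == "per_reactant", ]
    for (k in seq_len(nrow(pr)))
      if (radical_count(mols[[pr$reactant[k]]]) > pr$value[k]) return(list())
  }
  perms <- unique_perms(tpl$nfrag)
  results <- list()
  seen <- character()
  for (p in perms) {
    embs <- lapply(seq_len(tpl$nfrag), function(fi)
      fragment_embeddings(tpl$fragments[[fi]], mols[[p[fi]]]))
    if (any(vapply(embs, length, 0L) == 0L)) next
    counts <- vapply(embs, length, 0L)
    for (ci in seq_len(prod(counts))) {
      idx <- arrayInd(ci, counts)[1, ]
      prods <- tryCatch(
        apply_recipe(tpl, mols, p, lapply(seq_along(idx),
                                          function(fi) embs[[fi]][[idx[fi]]])),
        error = function(e) NULL)
      if (is.null(prods)) next
      key <- paste(side_keys(prods), collapse = "|")
      if (!key %in% seen) {
        seen <- c(seen, key)
        results[[length(results) + 1L]] <- prods
      }
    }
  }
  results
}

unique_perms <- function(n) {
  if (n == 1L) return(list(1L))
  pm <- permutations_of(n)
  lapply(seq_len(nrow(pm)), function(i) pm[i, ])
}

# build the edited union graph and split into product molecules
apply_recipe <- function(tpl, mols, perm, embeddings) {
  offs <- c(0L, cumsum(vapply(mols[perm], n_atoms, 0L)))
  atoms <- do.call(rbind, lapply(mols[perm], function(m) m$atoms))
  rownames(atoms) <- NULL
  bonds <- do.call(rbind, lapply(seq_along(perm), function(i) {
    b <- mols[[perm[i]]]$bonds
    if (nrow(b)) { b$a1 <- b$a1 + offs[i]; b$a2 <- b$a2 + offs[i] }
    b
  }))
  # label -> union atom index
  nlab <- sum(vapply(tpl$fragments, function(f) length(f$labels), 0L))
  lab2atom <- integer(nlab)
  for (fi in seq_along(tpl$fragments)) {
    f <- tpl$fragments[[fi]]
    lab2atom[f$labels] <- embeddings[[fi]] + offs[fi]
  }
  bfind <- function(i, j) which(bonds$a1 == min(i, j) & bonds$a2 == max(i, j))
  r <- tpl$recipe
  for (k in seq_len(nrow(r))) {
    act <- r$action[k]
    i <- lab2atom[r$l1[k]]
    j <- if (!is.na(r$l2[k])) lab2atom[r$l2[k]] else NA_integer_
    if (act == "BREAK_BOND") {
      e <- bfind(i, j); if (!length(e)) stop("no bond to break")
      bonds <- bonds[-e, , drop = FALSE]
    } else if (act == "FORM_BOND") {
      if (length(bfind(i, j))) stop("bond already present")
      bonds <- rbind(bonds, data.frame(a1 = min(i, j), a2 = max(i, j),
                                       order = as.integer(r$after[k]),
                                       arom = FALSE, stereo = NA_character_,
                                       stringsAsFactors = FALSE))
    } else if (act == "CHANGE_BOND_ORDER") {
      e <- bfind(i, j); if (!length(e)) stop("no bond to change")
      bonds$order[e] <- as.integer(r$after[k])
    } else if (act %in% c("GAIN_RADICAL", "LOSE_RADICAL")) {
      atoms$radical[i] <- atoms$radical[i] +
        as.integer(r$after[k]) - as.integer(r$before[k])
    } else if (act == "CHANGE_CHARGE") {
      atoms$charge[i] <- atoms$charge[i] +
        as.integer(r$after[k]) - as.integer(r$before[k])
    } else if (act == "CHANGE_STEREO") {
      if (is.na(r$l2[k])) atoms$stereo[i] <- r$after[k]
    }
  }
  split_components(atoms, bonds, validate = TRUE)$mols
}

# ---- classification --------------------------------------------------------

#' Classify a template into a reaction-family label path
#'
#' Rule-based on the recipe shape and molecularity:
#' hydrogen abstraction (intermolecular H transfer with radical swap, sub-
#' labeled by the element of the abstracting atom), hydrogen shift
#' (intramolecular), beta scission / radical addition (bond scission or
#' formation coupled to a pi-bond order change and radical migration),
#' recombination, hydroperoxyl elimination, Diels-Alder cycloaddition,
#' closed-shell substitution, identical (empty formalized recipe), other.
#'
#' @param tpl An `rxn_template`.
#' @return Label path string, components separated by `/`.
#' @export
classify_template <- function(tpl) {
  r <- tpl$recipe[tpl$recipe$action != "CHANGE_STEREO", , drop = FALSE]
  if (!nrow(r)) return("identical")
  el <- template_label_elements(tpl)
  frag_of_lab <- template_label_frags(tpl)
  nb <- sum(r$action == "BREAK_BOND"); nf <- sum(r$action == "FORM_BOND")
  no <- sum(r$action == "CHANGE_BOND_ORDER")
  ng <- sum(r$action == "GAIN_RADICAL"); nl <- sum(r$action == "LOSE_RADICAL")
  nc <- sum(r$action == "CHANGE_CHARGE")
  bonds_of <- function(a) r[r$action == a, , drop = FALSE]

  is_h_pair <- function(row) el[row$l1] == "H" || el[row$l2] == "H"
  # hydrogen transfer: one C/O/..-H break, one X-H form over the same H
  if (nb == 1L && nf == 1L && no == 0L && ng == 1L && nl == 1L && nc == 0L) {
    br <- bonds_of("BREAK_BOND"); fo <- bonds_of("FORM_BOND")
    hb <- c(br$l1, br$l2)[el[c(br$l1, br$l2)] == "H"]
    hf <- c(fo$l1, fo$l2)[el[c(fo$l1, fo$l2)] == "H"]
    if (length(hb) && length(hf) && any(hb %in% hf)) {
      acceptor <- setdiff(c(fo$l1, fo$l2), hb)
      acc_el <- tolower(el[acceptor[1]])
      if (tpl$nfrag >= 2L)
        return(paste0("h_abstraction/", acc_el, "_centered"))
      return(paste0("h_shift/", acc_el, "_centered"))
    }
  }
  # recombination: a single bond formed between two radicals, nothing else
  if (nf == 1L && nb == 0L && no == 0L && nl == 2L && ng == 0L)
    return(if (tpl$nfrag >= 2L) "recombination" else "ring_closure")
  # beta scission: unimolecular; one bond broken, one pi formed, radical moves
  if (tpl$nfrag == 1L && nb == 1L && nf == 0L && no == 1L &&
      ng == 1L && nl == 1L) {
    oc <- bonds_of("CHANGE_BOND_ORDER")
    if (as.integer(oc$after[1]) > as.integer(oc$before[1]))
      return("beta_scission")
  }
  # radical addition: bimolecular reverse of beta scission
  if (tpl$nfrag >= 2L && nf == 1L && nb == 0L && no == 1L &&
      ng == 1L && nl == 1L) {
    oc <- bonds_of("CHANGE_BOND_ORDER")
    if (as.integer(oc$after[1]) < as.integer(oc$before[1]))
      return("addition")
  }
  # hydroperoxyl elimination: unimolecular, 2 breaks, 1 form (H->O),
  # pi bond formed, radical migrates between oxygens
  if (tpl$nfrag == 1L && nb == 2L && nf == 1L && no == 1L &&
      ng == 1L && nl == 1L && any(el == "O")) {
    fo <- bonds_of("FORM_BOND")
    if (any(el[c(fo$l1, fo$l2)] == "H") && any(el[c(fo$l1, fo$l2)] == "O"))
      return("hoo_elimination")
  }
  # Diels-Alder: closed shell, two sigma bonds formed, four pi-order changes
  # (three along the diene, one on the dienophile)
  if (ng == 0L && nl == 0L && nb == 0L && nf == 2L && no == 4L &&
      tpl$nfrag >= 2L)
    return("diels_alder")
  # substitution: closed shell, bonds broken and formed, no pi changes
  if (ng == 0L && nl == 0L && nb >= 1L && nf >= 1L && no == 0L &&
      tpl$nfrag >= 2L)
    return("substitution")
  "other"
}

template_label_elements <- function(tpl) {
  nall <- sum(vapply(tpl$fragments, function(f) length(f$labels), 0L))
  el <- character(nall)
  for (f in tpl$fragments) el[f$labels] <- f$element
  el
}

template_label_frags <- function(tpl) {
  nall <- sum(vapply(tpl$fragments, function(f) length(f$labels), 0L))
  fo <- integer(nall)
  for (fi in seq_along(tpl$fragments)) fo[tpl$fragments[[fi]]$labels] <- fi
  fo
}
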