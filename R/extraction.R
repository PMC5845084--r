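# Change detection (per-atom/per-bond taxonomy), reactive-center
# construction with shortest-path/minimum-spanning-tree connectors and
# optional hetero-atom expansion, mechanism acceptability, and the
# hydroperoxyl-elimination mapping correction.

#' Detect the changes implied by a complete mapping
#'
#' Compares every mapped atom pair: neighbors and their bonds (a match needs
#' equal neighboring elements and equal neighboring mapping indices), bond
#' orders, unpaired-electron counts, charges and stereo descriptors. Stereo
#' is compared only when both counterparts carry a descriptor (an atom
#' gaining or losing an undefined descriptor is not a change).
#'
#' @param record An `rxn_record`.
#' @param map Complete atom map.
#' @return A `change_set`: list with `items` (data frame: kind, a1, a2,
#'   before, after; atom indices are flattened reactant indices, a2 NA for
#'   atom-level items) and `reactive_atoms` (integer vector).
#' @export
detect_changes <- function(record, map) {
  st <- validate_mapping(record, map)
  if (st$state != "complete")
    stop("detect_changes requires a complete mapping (", st$state, ")")
  rs <- side_info(record$reactants); ps <- side_info(record$products)
  items <- data.frame(kind = character(), a1 = integer(), a2 = integer(),
                      before = character(), after = character(),
                      stringsAsFactors = FALSE)
  add <- function(kind, a1, a2, before, after) {
    items[nrow(items) + 1L, ] <<- list(kind, a1, a2, as.character(before),
                                       as.character(after))
  }
  inv <- integer(ps$n); inv[map] <- seq_len(rs$n)
  # bond-level comparison over the union of reactant and mapped product bonds
  A <- rs$adj; B <- ps$adj[map, map, drop = FALSE]
  for (i in seq_len(rs$n - 1L)) for (j in (i + 1L):rs$n) {
    if (A[i, j] == B[i, j]) next
    if (A[i, j] > 0L && B[i, j] == 0L) add("neighbor_loss", i, j, A[i, j], 0)
    else if (A[i, j] == 0L && B[i, j] > 0L) add("neighbor_gain", i, j, 0, B[i, j])
    else add("bond_order_change", i, j, A[i, j], B[i, j])
  }
  for (i in seq_len(rs$n)) {
    p <- map[i]
    dr <- ps$radical[p] - rs$radical[i]
    if (dr > 0L) add("radical_gain", i, NA, rs$radical[i], ps$radical[p])
    if (dr < 0L) add("radical_loss", i, NA, rs$radical[i], ps$radical[p])
    if (rs$charge[i] != ps$charge[p])
      add("charge_change", i, NA, rs$charge[i], ps$charge[p])
    if (!is.na(rs$stereo[i]) && !is.na(ps$stereo[p]) &&
        rs$stereo[i] != ps$stereo[p])
      add("stereo_change", i, NA, rs$stereo[i], ps$stereo[p])
  }
  # bond stereo (E/Z) on bonds surviving the reaction
  rb <- rs$bonds
  if (nrow(rb)) for (k in seq_len(nrow(rb))) {
    if (is.na(rb$stereo[k])) next
    pi1 <- map[rb$a1[k]]; pi2 <- map[rb$a2[k]]
    pb <- ps$bonds[(ps$bonds$a1 == min(pi1, pi2) & ps$bonds$a2 == max(pi1, pi2)), ]
    if (nrow(pb) == 1L && !is.na(pb$stereo[1]) && pb$stereo[1] != rb$stereo[k])
      add("stereo_change", rb$a1[k], rb$a2[k], rb$stereo[k], pb$stereo[1])
  }
  reactive <- sort(unique(c(items$a1, items$a2[!is.na(items$a2)])))
  structure(list(items = items, reactive_atoms = reactive), class = "change_set")
}

#' @export
print.change_set <- function(x, ...) {
  cat(sprintf("<change_set> %d items, %d reactive atoms\n",
              nrow(x$items), length(x$reactive_atoms)))
  if (nrow(x$items)) print(x$items)
  invisible(x)
}

#' Connector atoms making a reactive-atom set connected
#'
#' Shortest paths between all pairs of reactive atoms (breadth-first search)
#' define a complete weighted graph; its minimum spanning tree (Kruskal,
#' edges pre-sorted by weight then canonical endpoint ranks) selects which
#' paths to realize. The concrete shortest path for each chosen tree edge is
#' the lexicographically smallest by canonical atom rank. Atoms on the
#' selected paths, minus the reactive atoms, are the connectors.
#'
#' @param mol A `mol` object.
#' @param reactive Atom indices within `mol` (all in this molecule).
#' @return Integer vector of connector atom indices (possibly empty).
#' @export
connect_center <- function(mol, reactive) {
  reactive <- sort(unique(as.integer(reactive)))
  if (length(reactive) <= 1L) return(integer(0))
  adj <- adjacency_list(mol)
  n <- n_atoms(mol)
  crank <- canonical_atom_ranks(mol)
  # all-pairs shortest path lengths among reactive atoms
  k <- length(reactive)
  dists <- matrix(0L, k, k)
  dmaps <- lapply(reactive, function(r) bfs_dist(adj, r, n))
  for (i in seq_len(k)) for (j in seq_len(k))
    dists[i, j] <- dmaps[[i]][reactive[j]]
  # Kruskal MST with deterministic tie-breaks
  edges <- data.frame(i = integer(), j = integer(), w = integer())
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    edges[nrow(edges) + 1L, ] <- list(i, j, dists[i, j])
  r1 <- pmin(crank[reactive[edges$i]], crank[reactive[edges$j]])
  r2 <- pmax(crank[reactive[edges$i]], crank[reactive[edges$j]])
  edges <- edges[order(edges$w, r1, r2), , drop = FALSE]
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  chosen <- integer(0)
  for (e in seq_len(nrow(edges))) {
    a <- find(edges$i[e]); b <- find(edges$j[e])
    if (a != b) { parent[a] <- b; chosen <- c(chosen, e) }
  }
  conn <- integer(0)
  for (e in chosen) {
    p <- smallest_shortest_path(adj, reactive[edges$i[e]], reactive[edges$j[e]],
                                dmaps[[edges$j[e]]], crank)
    conn <- c(conn, p)
  }
  sort(setdiff(unique(conn), reactive))
}

# lexicographically smallest (by canonical rank) shortest path from a to b;
# dist_b = BFS distances from b
smallest_shortest_path <- function(adj, a, b, dist_b, crank) {
  path <- a
  cur <- a
  while (cur != b) {
    nb <- adj[[cur]][, 1L]
    nxt <- nb[dist_b[nb] == dist_b[cur] - 1L]
    nxt <- nxt[order(crank[nxt])][1L]
    path <- c(path, nxt)
    cur <- nxt
  }
  path
}

#' Build the reactive center of a reaction
#'
#' The center holds every atom whose environment changed; per reactant
#' molecule, disconnected centers are connected via [connect_center()]
#' (label `connector`); optionally every non-C, non-H atom bonded to a
#' reactive atom is added with label `hetero_expansion`.
#'
#' @param record An `rxn_record`.
#' @param changes A `change_set` from [detect_changes()].
#' @param include_hetero Add adjacent hetero atoms (default TRUE).
#' @return A `reactive_center`: data frame with columns `atom` (flattened
#'   reactant index), `mol`, `role`.
#' @export
build_reactive_center <- function(record, changes, include_hetero = TRUE) {
  rs <- side_info(record$reactants)
  atoms <- changes$reactive_atoms
  role <- rep("reactive", length(atoms))
  # connect per molecule
  for (m in unique(rs$mol_of[atoms])) {
    sel <- atoms[rs$mol_of[atoms] == m]
    local <- rs$atom_of[sel]
    conn <- connect_center(record$reactants[[m]], local)
    if (length(conn)) {
      atoms <- c(atoms, rs$offsets[m] + conn)
      role <- c(role, rep("connector", length(conn)))
    }
  }
  if (include_hetero) {
    reactive <- atoms[role == "reactive"]
    het <- integer(0)
    for (i in reactive) {
      nb <- which(rs$adj[i, ] > 0L)
      het <- c(het, nb[!rs$element[nb] %in% c("C", "H")])
    }
    het <- setdiff(unique(het), atoms)
    if (length(het)) {
      atoms <- c(atoms, het)
      role <- c(role, rep("hetero_expansion", length(het)))
    }
  }
  ord <- order(atoms)
  structure(data.frame(atom = atoms[ord], mol = rs$mol_of[atoms[ord]],
                       role = role[ord], stringsAsFactors = FALSE),
            class = c("reactive_center", "data.frame"))
}

#' Mechanism acceptability of a mapping
#'
#' Radical-bearing reactant molecules must participate via at least one of
#' their radical atoms; a mapping in which every radical is a spectator is
#' construed incorrect (with the hydroperoxyl-elimination exception handled
#' by [correct_peroxide_elimination()] before this check).
#'
#' @param record An `rxn_record`.
#' @param changes A `change_set`.
#' @return Logical; attribute `"reason"` explains a FALSE.
#' @export
mechanism_acceptable <- function(record, changes) {
  rs <- side_info(record$reactants)
  for (m in seq_along(record$reactants)) {
    rad_atoms <- which(rs$mol_of == m & rs$radical > 0L)
    if (!length(rad_atoms)) next
    if (!any(rad_atoms %in% changes$reactive_atoms))
      return(structure(FALSE, reason = sprintf(
        "radical of reactant %d does not participate in the mechanism", m)))
  }
  structure(TRUE, reason = "")
}

#' Correct the hydroperoxyl-elimination mapping
#'
#' The elimination of HOO• from a peroxyl radical ROO• to form an olefin is
#' consistently mapped through a four-membered cyclic transition state
#' (H transferred from the carbon bearing the peroxy group). The reaction is
#' far more likely to pass through a five-membered ring, so when the pattern
#' ROO• -> olefin + HOO• is detected with a four-ring mapping, the
#' transferred hydrogen is remapped to originate from the adjacent (beta)
#' carbon. Anything else is returned unchanged.
#'
#' @param record An `rxn_record`.
#' @param map Complete atom map.
#' @return Corrected (or unchanged) atom map.
#' @export
correct_peroxide_elimination <- function(record, map) {
  if (length(record$reactants) != 1L || length(record$products) != 2L) return(map)
  rs <- side_info(record$reactants); ps <- side_info(record$products)
  r <- record$reactants[[1]]
  # pattern: terminal peroxy radical C-O-O(rad) in the reactant,
  # HOO radical among the products
  is_hoo <- vapply(record$products, function(p)
    mol_formula(p) == "HO2" && radical_count(p) == 1L, TRUE)
  if (sum(is_hoo) != 1L) return(map)
  o2 <- which(rs$element == "O" & rs$radical > 0L)
  if (length(o2) != 1L) return(map)
  nb2 <- which(rs$adj[o2, ] > 0L)
  o1 <- nb2[rs$element[nb2] == "O"]
  if (length(o1) != 1L) return(map)
  nb1 <- which(rs$adj[o1, ] > 0L)
  ca <- nb1[rs$element[nb1] == "C"]
  if (length(ca) != 1L) return(map)
  rsize <- implied_ts_ring_size(record, map)
  if (is.na(rsize) || rsize == 5L) return(map)
  # Four-ring mapping detected (either the alpha-hydrogen transfer or the
  # oxygen-swapped variant): rebuild the canonical five-ring mapping. The
  # carbon assignment is kept; the carbon-bearing oxygen maps onto the
  # product radical oxygen (it gains the radical), the terminal radical
  # oxygen onto the hydrogen-bearing one, and the hydrogens are re-completed
  # -- the leaving hydrogen is then forced to come from the beta carbon.
  hoo_mol <- which(is_hoo)
  p_o <- which(ps$mol_of == hoo_mol & ps$element == "O")
  p_orad <- p_o[ps$radical[p_o] > 0L][1L]
  p_oh <- setdiff(p_o, p_orad)[1L]
  if (is.na(p_orad) || is.na(p_oh)) return(map)
  m2 <- map
  m2[o1] <- p_orad
  m2[o2] <- p_oh
  rheavy <- which(rs$element != "H")
  comp <- hydrogen_completion(rs, ps, rheavy, m2[rheavy])
  comp$map
}

#' Size of the cyclic transition state implied by an H transfer
#'
#' For a mapped intramolecular hydrogen transfer (e.g. hydroperoxyl
#' elimination), the implied ring contains the transferred hydrogen, its
#' donor atom, the acceptor atom and the atoms on the reactant shortest path
#' between donor and acceptor.
#'
#' @param record An `rxn_record`.
#' @param map Complete atom map.
#' @return Integer ring size, or NA when no single transferred hydrogen is
#'   found.
#' @export
implied_ts_ring_size <- function(record, map) {
  rs <- side_info(record$reactants); ps <- side_info(record$products)
  cand <- integer(0)
  for (i in which(rs$element == "H")) {
    nb_r <- which(rs$adj[i, ] > 0L)
    if (length(nb_r) != 1L) next
    p <- map[i]
    nb_p <- which(ps$adj[p, ] > 0L)
    if (length(nb_p) != 1L) next
    acceptor_pre <- which(map == nb_p[1L])   # reactant preimage of new anchor
    if (acceptor_pre != nb_r[1L]) cand <- c(cand, i)
  }
  if (!length(cand)) return(NA_integer_)
  # several hydrogens can migrate for bookkeeping reasons; the transfer of
  # interest is the one changing anchor element (e.g. C -> O), if any
  el_change <- vapply(cand, function(i) {
    rs$element[which(rs$adj[i, ] > 0L)[1L]] !=
      ps$element[which(ps$adj[map[i], ] > 0L)[1L]]
  }, TRUE)
  trans <- if (any(el_change)) cand[el_change][1L] else cand[1L]
  donor <- which(rs$adj[trans, ] > 0L)[1L]
  p <- map[trans]
  acceptor <- which(map == which(ps$adj[p, ] > 0L)[1L])
  # shortest path donor -> acceptor in the flattened reactant graph
  adj <- apply(rs$adj > 0L, 1L, which, simplify = FALSE)
  adjl <- lapply(adj, function(v) cbind(nbr = v, order = 1L))
  d <- bfs_dist(adjl, donor, rs$n)
  if (is.na(d[acceptor])) return(NA_integer_)
  d[acceptor] + 2L        # path atoms (d+1) plus the hydrogen
}
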