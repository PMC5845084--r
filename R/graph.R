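# Graph machinery: igraph conversion, canonical labeling (BLISS, with bond
# orders encoded as colored edge-subdivision vertices), canonical molecule
# keys, colored isomorphism, subgraph radius and the identical-environment
# test used by the heuristic mapping completion.

mol_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  b <- mol$bonds
  if (nrow(b)) g <- igraph::add_edges(g, rbind(b$a1, b$a2))
  g
}

# vertex attribute tuple strings; what counts as "the same atom" everywhere
atom_tuples <- function(mol, stereo = TRUE) {
  a <- mol$atoms
  st <- if (stereo) ifelse(is.na(a$stereo), "", a$stereo) else ""
  paste(a$element, a$charge, a$radical, st, sep = "|")
}

bond_tuples <- function(mol, stereo = TRUE) {
  b <- mol$bonds
  st <- if (stereo) ifelse(is.na(b$stereo), "", b$stereo) else ""
  paste(b$order, st, sep = "|")
}

# Canonical labeling of a vertex/edge-colored graph. BLISS only colors
# vertices, so each edge is subdivided by a dummy vertex carrying the edge
# color. Colors must be assigned identically for isomorphic graphs, hence
# integer codes come from the sorted unique tuple strings.
#
# edges: matrix with columns (v1, v2); returns canonical rank per real vertex
# (1 = first in canonical order).
canonical_ranks <- function(n, vtuples, edges, etuples) {
  stopifnot(length(vtuples) == n)
  ne <- nrow(edges)
  all_tup <- c(paste0("V|", vtuples), if (ne) paste0("E|", etuples))
  codes <- as.integer(factor(all_tup, levels = sort(unique(all_tup))))
  g <- igraph::make_empty_graph(n = n + ne, directed = FALSE)
  if (ne) {
    dummy <- n + seq_len(ne)
    g <- igraph::add_edges(g, rbind(c(edges[, 1L], edges[, 2L]), c(dummy, dummy)))
  }
  cp <- igraph::canonical_permutation(g, colors = codes)
  lab <- cp$labeling[seq_len(n)]          # canonical label of each real vertex
  rank(lab)                                # 1..n, smallest label first
}

#' Canonical atom ranks of a molecule
#'
#' Deterministic, permutation-invariant atom ordering (BLISS canonical form
#' over element/charge/radical/stereo vertex colors and bond-order edge
#' colors). Used wherever the algorithms need a reproducible tie-break.
#'
#' @param mol A `mol` object.
#' @param stereo Include stereo descriptors in the colors.
#' @return Integer vector: rank of each atom in the canonical order.
#' @export
canonical_atom_ranks <- function(mol, stereo = TRUE) {
  canonical_ranks(n_atoms(mol), atom_tuples(mol, stereo),
                  as.matrix(mol$bonds[, c("a1", "a2"), drop = FALSE]),
                  bond_tuples(mol, stereo))
}

# canonical serialization string of a molecule-like colored graph
canonical_serial <- function(n, vtuples, edges, etuples) {
  if (n == 0L) return("empty")
  r <- canonical_ranks(n, vtuples, edges, etuples)
  ord <- order(r)
  vpart <- paste(vtuples[ord], collapse = ";")
  ne <- nrow(edges)
  if (ne) {
    e1 <- pmin(r[edges[, 1L]], r[edges[, 2L]])
    e2 <- pmax(r[edges[, 1L]], r[edges[, 2L]])
    eo <- order(e1, e2)
    epart <- paste(sprintf("%d-%d:%s", e1[eo], e2[eo], etuples[eo]), collapse = ";")
  } else epart <- ""
  paste(vpart, epart, sep = "//")
}

#' Canonical molecule key
#'
#' Layered InChI-style canonical identifier: formula layer, canonical
#' connection layer, charge layer and an explicit unpaired-electron layer so a
#' radical never shares a key with its closed-shell parent. Two molecules are
#' graph-isomorphic (respecting element, charge, unpaired electrons and bond
#' orders) iff their keys are equal. If canonical labeling fails, a coarse
#' fingerprint key (formula + degree/valence histogram) is returned with
#' `scheme = "fingerprint_fallback"`.
#'
#' @param mol A `mol` object.
#' @param delocalized Compute a resonance-insensitive key: bond orders and
#'   radical positions are dropped from the colors; total unpaired electrons
#'   and the molecular formula are kept. All resonance structures of one
#'   molecule share their delocalized key.
#' @return List with `key` (string) and `scheme` (`"inchi"` or
#'   `"fingerprint_fallback"`).
#' @export
canonical_key <- function(mol, delocalized = FALSE) {
  res <- tryCatch({
    a <- mol$atoms
    edges <- as.matrix(mol$bonds[, c("a1", "a2"), drop = FALSE])
    if (delocalized) {
      vt <- paste(a$element, a$charge, sep = "|")
      et <- rep("1", nrow(edges))
    } else {
      vt <- atom_tuples(mol)
      et <- bond_tuples(mol)
    }
    ser <- canonical_serial(n_atoms(mol), vt, edges, et)
    key <- sprintf("TK=1%s/%s/q%d/e%d/x%s",
                   if (delocalized) "D" else "", mol_formula(mol),
                   sum(a$charge), sum(a$radical), ser)
    list(key = key, scheme = "inchi")
  }, error = function(e) NULL)
  if (is.null(res)) {
    a <- mol$atoms
    fp <- sprintf("FP/%s/q%d/e%d/d%s", mol_formula(mol), sum(a$charge),
                  sum(a$radical),
                  paste(sort(table(degrees(mol))), collapse = ","))
    res <- list(key = fp, scheme = "fingerprint_fallback")
  }
  res
}

#' Key string of a molecule (convenience)
#' @param mol A `mol` object.
#' @return Character key.
#' @export
mol_key <- function(mol) canonical_key(mol)$key

#' Test molecule isomorphism
#'
#' Colored VF2 isomorphism respecting element, charge, unpaired electrons and
#' bond order.
#'
#' @param a,b `mol` objects.
#' @param stereo Include stereo descriptors.
#' @return Logical.
#' @export
mol_isomorphic <- function(a, b, stereo = TRUE) {
  if (n_atoms(a) != n_atoms(b) || nrow(a$bonds) != nrow(b$bonds)) return(FALSE)
  ta <- atom_tuples(a, stereo); tb <- atom_tuples(b, stereo)
  ea <- bond_tuples(a, stereo); eb <- bond_tuples(b, stereo)
  lev <- sort(unique(c(ta, tb)))
  elev <- sort(unique(c(ea, eb)))
  if (!setequal(ta, tb)) return(FALSE)
  igraph::isomorphic(mol_igraph(a), mol_igraph(b), method = "vf2",
                     vertex.color1 = as.integer(factor(ta, lev)),
                     vertex.color2 = as.integer(factor(tb, lev)),
                     edge.color1 = as.integer(factor(ea, elev)),
                     edge.color2 = as.integer(factor(eb, elev)))
}

# BFS distances from one atom (implementation kept independent of
# igraph::distances, which serves as the oracle in the tests)
bfs_dist <- function(adj, root, n) {
  d <- rep(NA_integer_, n)
  d[root] <- 0L
  queue <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]][, 1L]) if (is.na(d[w])) { d[w] <- d[v] + 1L; queue <- c(queue, w) }
  }
  d
}

#' Subgraph radius of an atom
#'
#' The radius at which the subgraph grown from the root atom stops growing,
#' i.e. the graph eccentricity of the root: the minimal number of bonds
#' between the root and the atoms farthest from it.
#'
#' @param mol A `mol` object.
#' @param root Atom index.
#' @return Integer radius (0 for a single-atom molecule).
#' @export
subgraph_radius <- function(mol, root) {
  stopifnot(root >= 1L, root <= n_atoms(mol))
  d <- bfs_dist(adjacency_list(mol), root, n_atoms(mol))
  max(d)
}

# induced submolecule on an atom set; relaxed validation (fragments may have
# dangling valences). Returns mol-like object plus the original indices.
induced_fragment <- function(mol, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  remap <- integer(n_atoms(mol)); remap[atoms] <- seq_along(atoms)
  b <- mol$bonds[mol$bonds$a1 %in% atoms & mol$bonds$a2 %in% atoms, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  frag <- structure(list(
    atoms = mol$atoms[atoms, , drop = FALSE],
    bonds = b
  ), class = "mol")
  rownames(frag$atoms) <- NULL
  attr(frag, "orig") <- atoms
  frag
}

# shell of radius r around root: atoms at BFS distance <= r
shell_atoms <- function(mol, root, r) {
  d <- bfs_dist(adjacency_list(mol), root, n_atoms(mol))
  which(d <= r)
}

# isomorphism of two rooted fragments where the roots must correspond
rooted_fragments_isomorphic <- function(molA, atomsA, rootA, molB, atomsB, rootB) {
  fa <- induced_fragment(molA, atomsA)
  fb <- induced_fragment(molB, atomsB)
  if (n_atoms(fa) != n_atoms(fb) || nrow(fa$bonds) != nrow(fb$bonds)) return(FALSE)
  ra <- match(rootA, attr(fa, "orig"))
  rb <- match(rootB, attr(fb, "orig"))
  ta <- atom_tuples(fa); tb <- atom_tuples(fb)
  ta[ra] <- paste0("ROOT|", ta[ra]); tb[rb] <- paste0("ROOT|", tb[rb])
  ea <- bond_tuples(fa); eb <- bond_tuples(fb)
  lev <- sort(unique(c(ta, tb))); elev <- sort(unique(c(ea, eb)))
  if (!setequal(ta, tb)) return(FALSE)
  igraph::isomorphic(mol_igraph(fa), mol_igraph(fb), method = "vf2",
                     vertex.color1 = as.integer(factor(ta, lev)),
                     vertex.color2 = as.integer(factor(tb, lev)),
                     edge.color1 = as.integer(factor(ea, elev)),
                     edge.color2 = as.integer(factor(eb, elev)))
}

#' Are two atoms in identical chemical environments?
#'
#' Same molecule object: true iff the molecule has the same subgraph radius r
#' relative to both atoms and all rooted subgraphs of radius r - i
#' (i = 1..r) are isomorphic (an axis of symmetry between the atoms).
#' Different molecule objects: true iff all rooted subgraphs of radius r - i
#' (i = 0..r) around both atoms are isomorphic (same chemical position in two
#' identical molecules). Subgraph isomorphism respects element, charge,
#' unpaired electrons and bond orders, with the two roots required to
#' correspond.
#'
#' @param molA,molB `mol` objects (may be the same object).
#' @param a,b Atom indices in `molA` / `molB`.
#' @param same_molecule Force the same-molecule/different-molecule case split;
#'   default decides by object identity.
#' @return Logical.
#' @export
environments_identical <- function(molA, a, molB, b, same_molecule = NULL) {
  if (molA$atoms$element[a] != molB$atoms$element[b]) return(FALSE)
  same <- if (is.null(same_molecule)) identical(molA, molB) else same_molecule
  ra <- subgraph_radius(molA, a)
  rb <- subgraph_radius(molB, b)
  if (ra != rb) return(FALSE)
  i0 <- if (same) 1L else 0L
  if (i0 > ra) return(TRUE)
  for (i in seq(i0, ra)) {
    r <- ra - i
    sa <- shell_atoms(molA, a, r)
    sb <- shell_atoms(molB, b, r)
    if (!rooted_fragments_isomorphic(molA, sa, a, molB, sb, b)) return(FALSE)
  }
  TRUE
}
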