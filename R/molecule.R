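# Molecular graph model: atoms with formal charge / unpaired-electron counts /
# optional stereo descriptors, bonds with integer (Kekule) orders plus an
# aromaticity flag. All hydrogens are explicit; one molecule = one connected
# component.

# Default valences. A vector per element means several allowed states
# (e.g. sulfur 2/4/6). Used for validation, implicit-H assignment on SMILES
# import and bond-order reconstruction from InChI connection layers.
.VALENCES <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L
)

#' Allowed valences of an element at a formal charge
#'
#' For N, P, O and S a positive charge raises and a negative charge lowers the
#' allowed valence (ammonium N is tetravalent, alkoxide O monovalent); for all
#' other elements charge removes bonding capacity.
#'
#' @param element Element symbol.
#' @param charge Formal charge (integer).
#' @return Integer vector of allowed valences (bond order sum + unpaired
#'   electrons), non-negative.
#' @keywords internal
allowed_valences <- function(element, charge = 0L) {
  base <- .VALENCES[[element]]
  if (is.null(base)) stop("unknown element: ", element)
  v <- if (element %in% c("N", "P", "O", "S")) base + charge else base - abs(charge)
  v[v >= 0L]
}

#' Construct a molecule
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param bonds Data frame (or NULL) with columns `a1`, `a2` (1-based atom
#'   indices), `order` (1, 2, 3) and optionally `arom` (logical) and `stereo`
#'   (character, `"E"`/`"Z"` or NA).
#' @param charge,radical Integer vectors (recycled) of formal charges and
#'   unpaired-electron counts per atom.
#' @param stereo Character vector of atom stereo descriptors (NA = undefined).
#' @param validate Check valences and connectivity.
#' @return An object of class `mol`.
#' @export
molecule <- function(elements, bonds = NULL, charge = 0L, radical = 0L,
                     stereo = NA_character_, validate = TRUE) {
  n <- length(elements)
  atoms <- data.frame(
    element = as.character(elements),
    charge = as.integer(rep_len(charge, n)),
    radical = as.integer(rep_len(radical, n)),
    stereo = as.character(rep_len(stereo, n)),
    stringsAsFactors = FALSE
  )
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        arom = logical(), stereo = character(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds)
    if (is.null(bonds$arom)) bonds$arom <- FALSE
    if (is.null(bonds$stereo)) bonds$stereo <- NA_character_
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]; bonds$a1[swap] <- bonds$a2[swap]; bonds$a2[swap] <- tmp
    bonds <- bonds[, c("a1", "a2", "order", "arom", "stereo")]
    bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.integer(bonds$order)
  }
  m <- structure(list(atoms = atoms, bonds = bonds), class = "mol")
  if (validate) validate_molecule(m)
  m
}

#' Number of atoms in a molecule
#' @param mol A `mol` object.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' @export
print.mol <- function(x, ...) {
  cat(sprintf("<mol> %s  (%d atoms, %d bonds)\n",
              mol_formula(x), n_atoms(x), nrow(x$bonds)))
  invisible(x)
}

#' Hill-order molecular formula
#' @param mol A `mol` object.
#' @return Formula string, e.g. `"C2H6O"`.
#' @export
mol_formula <- function(mol) {
  tab <- table(mol$atoms$element)
  els <- names(tab)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    k <- tab[[e]]
    if (k == 1L) e else paste0(e, k)
  }, ""), collapse = "")
}

# per-atom sum of bond orders (Kekule)
bond_order_sums <- function(mol) {
  v <- integer(n_atoms(mol))
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      v[b$a1[k]] <- v[b$a1[k]] + b$order[k]
      v[b$a2[k]] <- v[b$a2[k]] + b$order[k]
    }
  }
  v
}

# per-atom neighbor counts (explicit H included)
degrees <- function(mol) {
  d <- integer(n_atoms(mol))
  b <- mol$bonds
  if (nrow(b)) {
    t1 <- table(factor(b$a1, levels = seq_len(n_atoms(mol))))
    t2 <- table(factor(b$a2, levels = seq_len(n_atoms(mol))))
    d <- as.integer(t1 + t2)
  }
  d
}

# adjacency list: for atom i, matrix with columns (nbr, order)
adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- cbind(nbr = integer(), order = integer())
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- rbind(adj[[b$a1[k]]], c(b$a2[k], b$order[k]))
    adj[[b$a2[k]]] <- rbind(adj[[b$a2[k]]], c(b$a1[k], b$order[k]))
  }
  adj
}

#' Validate a molecule
#'
#' Checks element symbols, non-negative unpaired-electron counts, distinct
#' bond endpoints, single connected component, and that every atom's
#' bond-order sum plus unpaired electrons matches an allowed valence for its
#' element and charge.
#'
#' @param mol A `mol` object.
#' @return Invisibly TRUE; otherwise an error.
#' @export
validate_molecule <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  if (!all(a$element %in% names(.VALENCES)))
    stop("unsupported element(s): ",
         paste(setdiff(a$element, names(.VALENCES)), collapse = ", "))
  if (any(a$radical < 0L)) stop("negative unpaired electron count")
  if (nrow(b)) {
    if (any(b$a1 == b$a2)) stop("bond with identical endpoints")
    if (any(b$a1 < 1L | b$a2 > n_atoms(mol))) stop("bond endpoint out of range")
    if (anyDuplicated(b[, c("a1", "a2")])) stop("duplicate bond")
    if (!all(b$order %in% 1:3)) stop("bond order must be 1, 2 or 3")
  }
  if (n_atoms(mol) > 1L) {
    comp <- mol_components(mol)
    if (max(comp) > 1L) stop("molecule graph is not connected")
  }
  vs <- bond_order_sums(mol) + a$radical
  for (i in seq_len(n_atoms(mol))) {
    if (!vs[i] %in% allowed_valences(a$element[i], a$charge[i]))
      stop(sprintf("atom %d (%s, charge %d): valence %d not allowed",
                   i, a$element[i], a$charge[i], vs[i]))
  }
  invisible(TRUE)
}

# connected component id per atom (no igraph needed; used during validation)
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  adj <- adjacency_list(mol)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]][, 1L]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

#' Split a possibly disconnected atom/bond set into molecules
#'
#' Used after recipe application, where bond edits may fragment a molecule.
#'
#' @param atoms Atom data frame (columns as in `mol$atoms`).
#' @param bonds Bond data frame.
#' @param validate Validate each component.
#' @return List with `mols` (list of `mol`) and `index` (for each input atom,
#'   `c(mol, atom)` locating it in the output).
#' @keywords internal
split_components <- function(atoms, bonds, validate = TRUE) {
  tmp <- structure(list(atoms = atoms, bonds = bonds), class = "mol")
  comp <- mol_components(tmp)
  k <- max(comp, 1L)
  mols <- vector("list", k)
  index <- matrix(0L, nrow = nrow(atoms), ncol = 2L)
  for (c_ in seq_len(k)) {
    sel <- which(comp == c_)
    remap <- integer(nrow(atoms)); remap[sel] <- seq_along(sel)
    bsel <- bonds[bonds$a1 %in% sel & bonds$a2 %in% sel, , drop = FALSE]
    bsel$a1 <- remap[bsel$a1]; bsel$a2 <- remap[bsel$a2]
    mols[[c_]] <- molecule(atoms$element[sel], bsel,
                           charge = atoms$charge[sel],
                           radical = atoms$radical[sel],
                           stereo = atoms$stereo[sel],
                           validate = validate)
    index[sel, ] <- cbind(c_, seq_along(sel))
  }
  list(mols = mols, index = index)
}

#' Count heavy (non-hydrogen) atoms
#' @param mol A `mol` object.
#' @return Integer.
#' @export
heavy_atom_count <- function(mol) sum(mol$atoms$element != "H")

#' Total unpaired electrons of a molecule
#' @param mol A `mol` object.
#' @return Integer.
#' @export
radical_count <- function(mol) sum(mol$atoms$radical)

# structural equality on labeled atoms (same indices); used by resonance
# enumeration to deduplicate electron placements over a fixed skeleton
mol_identical_labeled <- function(a, b) {
  ba <- a$bonds[order(a$bonds$a1, a$bonds$a2), c("a1", "a2", "order")]
  bb <- b$bonds[order(b$bonds$a1, b$bonds$a2), c("a1", "a2", "order")]
  identical(a$atoms$element, b$atoms$element) &&
    identical(a$atoms$charge, b$atoms$charge) &&
    identical(a$atoms$radical, b$atoms$radical) &&
    nrow(ba) == nrow(bb) &&
    all(ba == bb)
}
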