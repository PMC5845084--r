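# Resonance enumeration for neutral radical delocalization.
#
# The localized electron arrangements reachable by allylic shifts are
# enumerated: a radical on atom X adjacent to a single bond X-Y where Y
# carries a multiple bond Y=Z moves to Z while the bonds re-localize
# (X=Y, Y-Z). Closure of this move set over the molecule gives all localized
# structures of e.g. allyl (2, mirror images) or 1-buten-3-yl (2: secondary
# and primary radical). Charged resonance (ions, zwitterions) is out of
# scope; aromatic rings are kept Kekule-localized and not re-enumerated here.

.RESONANCE_CAP <- 16L

#' Enumerate resonance structures
#'
#' Returns all distinct localized structures over the fixed atom skeleton,
#' input first, then the others in deterministic (discovery, key-sorted)
#' order. Structures are distinct as labeled graphs: the two mirror forms of
#' the allyl radical count separately.
#'
#' @param mol A `mol` object.
#' @param cap Maximum number of structures; if exceeded, the input alone is
#'   returned with attribute `overflow = TRUE` and a warning.
#' @return List of `mol` objects (length >= 1, contains the input).
#' @export
enumerate_resonance <- function(mol, cap = .RESONANCE_CAP) {
  found <- list(mol)
  queue <- list(mol)
  overflow <- FALSE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (nxt in resonance_moves(cur)) {
      if (any(vapply(found, mol_identical_labeled, TRUE, nxt))) next
      if (length(found) >= cap) { overflow <- TRUE; break }
      found[[length(found) + 1L]] <- nxt
      queue[[length(queue) + 1L]] <- nxt
    }
    if (overflow) break
  }
  if (overflow) {
    warning("resonance enumeration cap (", cap, ") exceeded; using input structure")
    found <- list(mol)
    attr(found, "overflow") <- TRUE
  }
  found
}

# all single allylic radical shifts applicable to mol
resonance_moves <- function(mol) {
  out <- list()
  a <- mol$atoms
  radical_atoms <- which(a$radical > 0L)
  if (!length(radical_atoms)) return(out)
  b <- mol$bonds
  bidx <- function(i, j) which((b$a1 == min(i, j)) & (b$a2 == max(i, j)))
  adj <- adjacency_list(mol)
  for (x in radical_atoms) {
    nbx <- adj[[x]]
    for (r in seq_len(nrow(nbx))) {
      y <- nbx[r, 1]
      if (nbx[r, 2] != 1L) next              # X-Y must be single
      nby <- adj[[y]]
      for (r2 in seq_len(nrow(nby))) {
        z <- nby[r2, 1]
        if (z == x || nby[r2, 2] < 2L) next  # Y=Z multiple bond
        m2 <- mol
        m2$bonds$order[bidx(x, y)] <- m2$bonds$order[bidx(x, y)] + 1L
        m2$bonds$order[bidx(y, z)] <- m2$bonds$order[bidx(y, z)] - 1L
        m2$atoms$radical[x] <- m2$atoms$radical[x] - 1L
        m2$atoms$radical[z] <- m2$atoms$radical[z] + 1L
        ok <- tryCatch({ validate_molecule(m2); TRUE }, error = function(e) FALSE)
        if (ok) out[[length(out) + 1L]] <- m2
      }
    }
  }
  out
}
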