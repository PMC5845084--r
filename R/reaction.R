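# Reaction records, corpora and atom-map plumbing.
#
# An atom map is stored as an integer vector over the flattened reactant
# atoms (all reactant molecules concatenated in order), giving for each
# reactant atom the flattened product atom index, NA where unmapped.

#' Construct a reaction record
#'
#' @param reactants,products Lists of `mol` objects (at least one each).
#' @param map Optional integer atom map over flattened atom indices
#'   (NA = unmapped), or NULL.
#' @param source_id Identifier of the database entry.
#' @param origin_format One of `"identifier_list"`, `"rxn"`, `"chemkin"`,
#'   `"synthetic"`.
#' @param family Optional ground-truth family label (synthetic corpora).
#' @return Object of class `rxn_record`.
#' @export
reaction_record <- function(reactants, products, map = NULL,
                            source_id = "", origin_format = "identifier_list",
                            family = NA_character_) {
  stopifnot(length(reactants) >= 1L, length(products) >= 1L)
  nr <- sum(vapply(reactants, n_atoms, 0L))
  np <- sum(vapply(products, n_atoms, 0L))
  if (!is.null(map)) {
    map <- as.integer(map)
    stopifnot(length(map) == nr)
    mm <- map[!is.na(map)]
    if (length(mm) && (any(mm < 1L | mm > np) || anyDuplicated(mm)))
      stop("invalid atom map")
  }
  structure(list(reactants = reactants, products = products, map = map,
                 source_id = source_id, origin_format = origin_format,
                 family = family),
            class = "rxn_record")
}

#' @export
print.rxn_record <- function(x, ...) {
  cat(sprintf("<rxn_record %s> %s >> %s  [map: %s]\n", x$source_id,
              paste(vapply(x$reactants, write_smiles, ""), collapse = " + "),
              paste(vapply(x$products, write_smiles, ""), collapse = " + "),
              if (is.null(x$map)) "absent"
              else sprintf("%d/%d", sum(!is.na(x$map)), length(x$map))))
  invisible(x)
}

#' Construct a corpus of reaction records
#'
#' @param records List of `rxn_record`s; source ids must be unique.
#' @param provenance Character vector of source paths.
#' @return Object of class `rxn_corpus`.
#' @export
corpus <- function(records = list(), provenance = character()) {
  ids <- vapply(records, function(r) r$source_id, "")
  if (anyDuplicated(ids[nzchar(ids)])) stop("duplicate source_id in corpus")
  structure(list(records = records, provenance = provenance),
            class = "rxn_corpus")
}

#' @export
print.rxn_corpus <- function(x, ...) {
  cat(sprintf("<rxn_corpus> %d records\n", length(x$records)))
  invisible(x)
}

#' Number of records in a corpus
#' @param corpus An `rxn_corpus`.
#' @return Integer.
#' @export
n_records <- function(corpus) length(corpus$records)

# flattened view of one reaction side
side_info <- function(mols) {
  na <- vapply(mols, n_atoms, 0L)
  off <- c(0L, cumsum(na))[seq_along(mols)]
  n <- sum(na)
  element <- character(n); chargev <- integer(n); radicalv <- integer(n)
  stereov <- character(n); mol_of <- integer(n); atom_of <- integer(n)
  b1 <- integer(); b2 <- integer(); bord <- integer(); barom <- logical(); bst <- character()
  for (m in seq_along(mols)) {
    idx <- off[m] + seq_len(na[m])
    element[idx] <- mols[[m]]$atoms$element
    chargev[idx] <- mols[[m]]$atoms$charge
    radicalv[idx] <- mols[[m]]$atoms$radical
    stereov[idx] <- mols[[m]]$atoms$stereo
    mol_of[idx] <- m
    atom_of[idx] <- seq_len(na[m])
    bb <- mols[[m]]$bonds
    if (nrow(bb)) {
      b1 <- c(b1, bb$a1 + off[m]); b2 <- c(b2, bb$a2 + off[m])
      bord <- c(bord, bb$order); barom <- c(barom, bb$arom); bst <- c(bst, bb$stereo)
    }
  }
  adjm <- matrix(0L, n, n)
  if (length(b1)) {
    adjm[cbind(b1, b2)] <- bord
    adjm[cbind(b2, b1)] <- bord
  }
  list(n = n, offsets = off, mol_of = mol_of, atom_of = atom_of,
       element = element, charge = chargev, radical = radicalv,
       stereo = stereov,
       bonds = data.frame(a1 = b1, a2 = b2, order = bord, arom = barom,
                          stereo = bst, stringsAsFactors = FALSE),
       adj = adjm)
}

# global index from (mol, atom) and back
global_index <- function(side, m, a) side$offsets[m] + a

#' Is a reaction balanced?
#'
#' Identical element multisets (explicit hydrogens included) and equal net
#' charge on both sides.
#'
#' @param record An `rxn_record`.
#' @return Logical; attribute `"tally"` carries the per-element imbalance
#'   when FALSE.
#' @export
is_balanced <- function(record) {
  r <- side_info(record$reactants); p <- side_info(record$products)
  tr <- table(r$element); tp <- table(p$element)
  els <- union(names(tr), names(tp))
  diff <- vapply(els, function(e) {
    (if (e %in% names(tr)) tr[[e]] else 0L) -
      (if (e %in% names(tp)) tp[[e]] else 0L)
  }, 0L)
  ok <- all(diff == 0L) && sum(r$charge) == sum(p$charge)
  structure(ok, tally = diff[diff != 0L])
}

#' Sorted canonical keys of a molecule list
#' @param mols List of `mol`.
#' @return Character vector (sorted).
#' @export
side_keys <- function(mols) sort(vapply(mols, mol_key, ""))

#' Filter out unbalanced reactions
#'
#' @param corpus An `rxn_corpus`.
#' @return The retained corpus; attribute `"rejected"` is a data frame with
#'   the source ids and offending element tallies of dropped records.
#' @export
filter_unbalanced <- function(corpus) {
  keep <- logical(n_records(corpus))
  rej_id <- character(); rej_tally <- character()
  for (i in seq_along(corpus$records)) {
    b <- is_balanced(corpus$records[[i]])
    keep[i] <- isTRUE(as.logical(b))
    if (!keep[i]) {
      rej_id <- c(rej_id, corpus$records[[i]]$source_id)
      t <- attr(b, "tally")
      rej_tally <- c(rej_tally, paste(names(t), t, sep = ":", collapse = ","))
    }
  }
  out <- corpus
  out$records <- corpus$records[keep]
  attr(out, "rejected") <- data.frame(source_id = rej_id, tally = rej_tally,
                                      stringsAsFactors = FALSE)
  out
}

#' Filter reactions by reactant count
#'
#' @param corpus An `rxn_corpus`.
#' @param max_reactants Maximum number of reactant molecules (default 2).
#' @return Corpus of retained records; attribute `"rejected"` lists dropped
#'   source ids.
#' @export
filter_arity <- function(corpus, max_reactants = 2L) {
  stopifnot(max_reactants >= 1L)
  keep <- vapply(corpus$records, function(r) length(r$reactants) <= max_reactants, TRUE)
  out <- corpus
  out$records <- corpus$records[keep]
  attr(out, "rejected") <- vapply(corpus$records[!keep], function(r) r$source_id, "")
  out
}
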