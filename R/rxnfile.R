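# MDL RXN (V2000) reading and writing. Atom-atom map indices live in the
# atom block (field 11 after the symbol); radicals and charges are carried in
# M  RAD / M  CHG property lines. Coordinates are written as zeros (the
# pipeline is 2D/3D-agnostic).

fmt_molblock <- function(mol, mapidx = NULL, title = "") {
  a <- mol$atoms; b <- mol$bonds
  n <- n_atoms(mol)
  if (is.null(mapidx)) mapidx <- integer(n)
  lines <- c(title, "  templater", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0%3d  0  0",
      0, 0, 0, a$element[i], mapidx[i]))
  }
  for (k in seq_len(nrow(b))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", b$a1[k], b$a2[k], b$order[k]))
  }
  chg <- which(a$charge != 0L)
  if (length(chg)) lines <- c(lines, paste0(
    sprintf("M  CHG%3d", length(chg)),
    paste0(sprintf("%4d%4d", chg, a$charge[chg]), collapse = "")))
  rad <- which(a$radical > 0L)
  if (length(rad)) {
    code <- ifelse(a$radical[rad] == 1L, 2L, 3L)   # doublet / triplet
    lines <- c(lines, paste0(
      sprintf("M  RAD%3d", length(rad)),
      paste0(sprintf("%4d%4d", rad, code), collapse = "")))
  }
  c(lines, "M  END")
}

#' Write a reaction record as an MDL RXN (V2000) file
#'
#' Atom-map indices are written 1-based when the record's mapping is
#' complete; partial maps keep their mapped indices and unmapped atoms get 0.
#'
#' @param record An `rxn_record`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_rxn <- function(record, path) {
  r <- record$reactants; p <- record$products
  nr <- sum(vapply(r, n_atoms, 0L))
  rmapidx <- integer(nr); pmapsrc <- integer(sum(vapply(p, n_atoms, 0L)))
  if (!is.null(record$map)) {
    mapped <- which(!is.na(record$map))
    rmapidx[mapped] <- mapped            # reactant atom i gets label i
    pmapsrc[record$map[mapped]] <- mapped
  }
  roff <- c(0L, cumsum(vapply(r, n_atoms, 0L)))
  poff <- c(0L, cumsum(vapply(p, n_atoms, 0L)))
  lines <- c("$RXN", "", " templater", record$source_id,
             sprintf("%3d%3d", length(r), length(p)))
  for (i in seq_along(r)) {
    idx <- rmapidx[roff[i] + seq_len(n_atoms(r[[i]]))]
    lines <- c(lines, "$MOL", fmt_molblock(r[[i]], idx, sprintf("reactant_%d", i)))
  }
  for (i in seq_along(p)) {
    idx <- pmapsrc[poff[i] + seq_len(n_atoms(p[[i]]))]
    lines <- c(lines, "$MOL", fmt_molblock(p[[i]], idx, sprintf("product_%d", i)))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_molblock <- function(lines) {
  counts <- lines[4]
  n <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(n) || is.na(nb)) stop("malformed counts line")
  el <- character(n); mapidx <- integer(n)
  for (i in seq_len(n)) {
    ln <- lines[4 + i]
    el[i] <- trimws(substr(ln, 32, 34))
    flds <- strsplit(trimws(substr(ln, 35, nchar(ln))), "\\s+")[[1]]
    mapidx[i] <- if (length(flds) >= 10L) suppressWarnings(as.integer(flds[10])) else 0L
    if (is.na(mapidx[i])) mapidx[i] <- 0L
  }
  b1 <- integer(nb); b2 <- integer(nb); bo <- integer(nb)
  for (k in seq_len(nb)) {
    ln <- lines[4 + n + k]
    b1[k] <- as.integer(substr(ln, 1, 3))
    b2[k] <- as.integer(substr(ln, 4, 6))
    bo[k] <- as.integer(substr(ln, 7, 9))
  }
  arom <- bo == 4L
  bo[arom] <- 1L
  chg <- integer(n); rad <- integer(n)
  for (ln in lines[-seq_len(4 + n + nb)]) {
    if (startsWith(ln, "M  CHG") || startsWith(ln, "M  RAD")) {
      typ <- substr(ln, 4, 6)
      k <- as.integer(substr(ln, 7, 9))
      for (q in seq_len(k)) {
        at <- as.integer(substr(ln, 10 + (q - 1) * 8, 13 + (q - 1) * 8))
        vl <- as.integer(substr(ln, 14 + (q - 1) * 8, 17 + (q - 1) * 8))
        if (typ == "CHG") chg[at] <- vl
        else rad[at] <- switch(vl, 2L, 1L, 2L)   # codes 1,2,3
      }
    }
    if (identical(trimws(ln), "M  END")) break
  }
  bonds <- data.frame(a1 = b1, a2 = b2, order = bo, arom = arom,
                      stereo = rep(NA_character_, nb), stringsAsFactors = FALSE)
  if (any(arom)) {
    atom_arom <- rep(FALSE, n)
    atom_arom[c(bonds$a1[bonds$arom], bonds$a2[bonds$arom])] <- TRUE
    res <- kekulize(el, chg, rep(0L, n), atom_arom, bonds, "molblock")
    bonds <- res$bonds
  }
  mol <- molecule(el, bonds, charge = chg, radical = rad)
  list(mol = mol, mapidx = mapidx)
}

#' Read one MDL RXN (V2000) file
#'
#' @param path File path.
#' @param source_id Record id (defaults to the file name).
#' @return An `rxn_record`; mapping present when at least one atom-map index
#'   is non-zero (complete when all are).
#' @export
read_rxn <- function(path, source_id = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "$RXN")) stop("not an RXN file: ", path)
  cnt <- lines[5]
  nr <- as.integer(substr(cnt, 1, 3)); np <- as.integer(substr(cnt, 4, 6))
  mol_starts <- which(trimws(lines) == "$MOL")
  if (length(mol_starts) != nr + np) stop("wrong number of $MOL blocks in ", path)
  ends <- c(mol_starts[-1] - 1L, length(lines))
  blocks <- lapply(seq_along(mol_starts), function(i)
    parse_molblock(lines[(mol_starts[i] + 1L):ends[i]]))
  rs <- blocks[seq_len(nr)]
  ps <- blocks[nr + seq_len(np)]
  rmols <- lapply(rs, `[[`, "mol"); pmols <- lapply(ps, `[[`, "mol")
  rlab <- unlist(lapply(rs, `[[`, "mapidx"))
  plab <- unlist(lapply(ps, `[[`, "mapidx"))
  map <- NULL
  if (any(rlab > 0L)) {
    map <- rep(NA_integer_, length(rlab))
    for (i in which(rlab > 0L)) {
      j <- which(plab == rlab[i])
      if (length(j) == 1L) map[i] <- j
      else if (length(j) > 1L) stop("duplicate atom-map index in ", path)
    }
  }
  reaction_record(rmols, pmols, map = map, source_id = source_id,
                  origin_format = "rxn")
}

#' Read a directory of MDL RXN files
#'
#' Malformed files are skipped with a logged message.
#'
#' @param path Directory containing `.rxn` files.
#' @return An `rxn_corpus`; attribute `"skipped"` lists unreadable files.
#' @export
read_rxn_directory <- function(path) {
  files <- sort(list.files(path, pattern = "\\.rxn$", full.names = TRUE))
  records <- list(); skipped <- character()
  for (f in files) {
    rec <- tryCatch(read_rxn(f), error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) skipped <- c(skipped, basename(f))
    else records[[length(records) + 1L]] <- rec
  }
  structure(corpus(records, provenance = path), skipped = skipped)
}
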