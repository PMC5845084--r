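# SMILES reader and writer.
#
# The reader covers the organic subset (B C N O P S F Cl Br I), aromatic
# lowercase atoms (kekulized on import), bracket atoms with H counts, charges
# and chirality tags, ring closures (including %nn), branches, bond symbols
# - = # : / \ and dot-separated components. Implicit hydrogens are added as
# explicit atoms; bracket atoms with unfilled valence become radicals
# (e.g. [CH3] is the methyl radical). Directional bonds around a double bond
# are folded into an E/Z descriptor on the bond.
#
# The writer always emits Kekule structures (uppercase atoms, explicit = / #)
# and suppresses hydrogens bound to ordinary heavy atoms; radical, charged or
# stereo atoms are bracketed with explicit H counts.

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string
#'
#' @param s SMILES string. A dot (`.`) separates components; with
#'   `multi = TRUE` a list of molecules is returned, otherwise a dot is an
#'   error.
#' @param multi Allow multiple components.
#' @return A `mol` object, or a list of them when `multi = TRUE`.
#' @export
parse_smiles <- function(s, multi = FALSE) {
  s <- trimws(s)
  if (!nzchar(s)) stop("empty SMILES")
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  if (length(parts) > 1L && !multi) stop("multi-component SMILES: ", s)
  mols <- lapply(parts, parse_smiles_one)
  if (multi) mols else mols[[1]]
}

parse_smiles_one <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  el <- character(); chg <- integer(); hcount <- integer(); arom <- logical()
  stereo <- character(); explicit_h <- logical()
  b1 <- integer(); b2 <- integer(); bord <- integer(); barom <- logical(); bdir <- character()
  ring <- list()      # open ring closures: digit -> list(atom, bond, dir)
  prev <- 0L          # previous atom index
  stack <- integer()
  pend_bond <- ""     # pending bond symbol
  i <- 1L

  add_atom <- function(sym, aromatic, charge = 0L, h = NA_integer_,
                       chiral = NA_character_) {
    el[length(el) + 1L] <<- sym
    chg[length(chg) + 1L] <<- charge
    hcount[length(hcount) + 1L] <<- h
    arom[length(arom) + 1L] <<- aromatic
    stereo[length(stereo) + 1L] <<- chiral
    explicit_h[length(explicit_h) + 1L] <<- !is.na(h)
    length(el)
  }
  add_bond <- function(a, b, sym) {
    ord <- switch(sym, "=" = 2L, "#" = 3L, 1L)
    ar <- FALSE
    if (sym == ":" || (sym == "" && arom[a] && arom[b])) { ar <- TRUE; ord <- 1L }
    b1[length(b1) + 1L] <<- a; b2[length(b2) + 1L] <<- b
    bord[length(bord) + 1L] <<- ord; barom[length(barom) + 1L] <<- ar
    bdir[length(bdir) + 1L] <<- if (sym %in% c("/", "\\")) sym else ""
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend_bond <- ch; i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES: ", s)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stop("bad %% ring closure in: ", s)
        d <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { d <- ch; i <- i + 1L }
      if (is.null(ring[[d]])) {
        ring[[d]] <- list(atom = prev, bond = pend_bond)
      } else {
        op <- ring[[d]]
        sym <- if (nzchar(pend_bond)) pend_bond else op$bond
        add_bond(op$atom, prev, sym)
        ring[[d]] <- NULL
      }
      pend_bond <- ""
    } else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in: ", s)
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, s)
      a <- add_atom(at$element, at$arom, at$charge, at$h, at$chiral)
      if (prev) add_bond(prev, a, pend_bond)
      prev <- a; pend_bond <- ""
      i <- j + 1L
    } else {
      # organic subset atom, aromatic or aliphatic; two-letter Cl/Br
      sym <- ch
      if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
        two <- paste0(ch, chars[i + 1L])
        if (two %in% c("Cl", "Br")) { sym <- two; i <- i + 1L }
      }
      aromatic <- sym %in% .AROMATIC_OK
      if (aromatic) sym <- toupper(sym)
      if (!sym %in% .ORGANIC) stop("unexpected character '", ch, "' in SMILES: ", s)
      a <- add_atom(sym, aromatic)
      if (prev) add_bond(prev, a, pend_bond)
      prev <- a; pend_bond <- ""
      i <- i + 1L
    }
  }
  open <- names(ring)[!vapply(ring, is.null, TRUE)]
  if (length(open)) stop("unclosed ring bond(s) ", paste(open, collapse = ","), " in: ", s)

  bonds <- data.frame(a1 = b1, a2 = b2, order = bord, arom = barom,
                      dir = bdir, stringsAsFactors = FALSE)
  res <- kekulize(el, chg, hcount, arom, bonds, s)
  bonds <- res$bonds; hcount <- res$hcount

  # E/Z from directional single bonds flanking a double bond
  bstereo <- rep(NA_character_, nrow(bonds))
  dirb <- which(nzchar(bonds$dir))
  if (length(dirb)) {
    for (k in which(bonds$order == 2L)) {
      ends <- c(bonds$a1[k], bonds$a2[k])
      d1 <- dirb[bonds$a1[dirb] %in% ends[1] | bonds$a2[dirb] %in% ends[1]]
      d2 <- dirb[bonds$a1[dirb] %in% ends[2] | bonds$a2[dirb] %in% ends[2]]
      d1 <- setdiff(d1, k); d2 <- setdiff(d2, k)
      if (length(d1) && length(d2)) {
        s1 <- bonds$dir[d1[1]]; s2 <- bonds$dir[d2[1]]
        # like symbols on both sides: substituents trans (E); unlike: cis (Z)
        bstereo[k] <- if (s1 == s2) "E" else "Z"
      }
    }
  }
  bonds$stereo <- bstereo; bonds$dir <- NULL

  # implicit hydrogens -> explicit atoms
  bsum <- integer(length(el))
  for (k in seq_len(nrow(bonds))) {
    bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + bonds$order[k]
    bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + bonds$order[k]
  }
  rad <- integer(length(el))
  nh <- integer(length(el))
  for (a in seq_along(el)) {
    av <- allowed_valences(el[a], chg[a])
    if (is.na(hcount[a])) {           # organic subset: fill to lowest valence
      fit <- av[av >= bsum[a]]
      if (!length(fit)) stop("valence of atom ", a, " (", el[a], ") exceeds allowed in: ", s)
      nh[a] <- min(fit) - bsum[a]
    } else {                           # bracket atom: H as written, rest radical
      nh[a] <- hcount[a]
      tot <- bsum[a] + nh[a]
      fit <- av[av >= tot]
      if (!length(fit)) stop("valence of atom ", a, " (", el[a], ") exceeds allowed in: ", s)
      rad[a] <- min(fit) - tot
    }
  }
  st <- stereo
  nat <- length(el)
  for (a in seq_len(nat)) {
    if (nh[a] > 0L) {
      for (q in seq_len(nh[a])) {
        el <- c(el, "H"); chg <- c(chg, 0L); rad <- c(rad, 0L); st <- c(st, NA_character_)
        bonds <- rbind(bonds, data.frame(a1 = a, a2 = length(el), order = 1L,
                                         arom = FALSE, stereo = NA_character_,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  molecule(el, bonds, charge = chg, radical = rad, stereo = st)
}

parse_bracket_atom <- function(body, s) {
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Z][a-z]?|[a-z])(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\+*|-*)?(:[0-9]+)?$",
    body))[[1]]
  if (!length(m)) stop("cannot parse bracket atom [", body, "] in: ", s)
  sym <- m[3]
  aromatic <- sym %in% .AROMATIC_OK
  if (aromatic) sym <- toupper(sym)
  chiral <- if (nzchar(m[4])) m[4] else NA_character_
  h <- if (nzchar(m[5])) {
    if (m[5] == "H") 1L else as.integer(sub("H", "", m[5]))
  } else 0L
  chg <- 0L
  cs <- m[6]
  if (nzchar(cs)) {
    if (grepl("^[+-][0-9]+$", cs)) {
      chg <- as.integer(cs)
    } else {
      chg <- nchar(cs) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
    }
  }
  list(element = sym, arom = aromatic, charge = chg, h = h, chiral = chiral)
}

# Kekulize aromatic atoms/bonds: every aromatic atom with a valence deficit
# must get exactly one double bond within the aromatic bond set (perfect
# matching by backtracking). hcount of aromatic organic-subset atoms is
# resolved before matching (lowest valence).
kekulize <- function(el, chg, hcount, arom, bonds, s) {
  aidx <- which(arom)
  if (!length(aidx)) return(list(bonds = bonds, hcount = hcount))
  abonds <- which(bonds$arom)
  deg <- integer(length(el)); bsum <- integer(length(el))
  for (k in seq_len(nrow(bonds))) {
    for (a in c(bonds$a1[k], bonds$a2[k])) {
      deg[a] <- deg[a] + 1L
      bsum[a] <- bsum[a] + bonds$order[k]
    }
  }
  need <- logical(length(el))
  for (a in aidx) {
    base <- min(allowed_valences(el[a], chg[a]))
    h <- hcount[a]
    if (is.na(h)) h <- max(base - bsum[a] - 1L, 0L)  # reserve 1 for pi if possible
    tot <- bsum[a] + h
    if (tot + 1L <= base) {
      need[a] <- TRUE
    } else if (tot != base) stop("cannot kekulize atom ", a, " in: ", s)
    if (is.na(hcount[a])) hcount[a] <- h
  }
  todo <- which(need)
  cand <- abonds[need[bonds$a1[abonds]] & need[bonds$a2[abonds]]]
  match_try <- function(unsat, chosen) {
    if (!length(unsat)) return(chosen)
    a <- unsat[1L]
    for (k in cand) {
      e <- c(bonds$a1[k], bonds$a2[k])
      if (!a %in% e) next
      o <- setdiff(e, a)
      if (!o %in% unsat) next
      r <- match_try(setdiff(unsat, e), c(chosen, k))
      if (!is.null(r)) return(r)
    }
    NULL
  }
  sel <- match_try(todo, integer())
  if (is.null(sel) && length(todo)) stop("kekulization failed for: ", s)
  bonds$order[sel] <- 2L
  list(bonds = bonds, hcount = hcount)
}

#' Write a SMILES string
#'
#' Kekule output; hydrogens attached to unexceptional heavy atoms are folded
#' into implicit/bracket H counts. Radical, charged and stereo-tagged atoms
#' are written in brackets. Bond E/Z descriptors are not serialized.
#'
#' @param mol A `mol` object.
#' @return SMILES string.
#' @export
write_smiles <- function(mol) {
  a <- mol$atoms
  adj <- adjacency_list(mol)
  n <- n_atoms(mol)
  # hydrogens to fold away: plain H with a single non-H neighbor
  suppress <- rep(FALSE, n)
  nh <- integer(n)
  for (i in seq_len(n)) {
    if (a$element[i] != "H") next
    nb <- adj[[i]]
    if (nrow(nb) == 1L && a$element[nb[1, 1]] != "H" &&
        a$charge[i] == 0L && a$radical[i] == 0L && is.na(a$stereo[i]) &&
        nb[1, 2] == 1L) {
      suppress[i] <- TRUE
      nh[nb[1, 1]] <- nh[nb[1, 1]] + 1L
    }
  }
  keep <- which(!suppress)
  if (!length(keep)) { keep <- seq_len(n); nh[] <- 0L; suppress[] <- FALSE }

  heavy_bsum <- integer(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (suppress[b$a1[k]] || suppress[b$a2[k]]) next
    heavy_bsum[b$a1[k]] <- heavy_bsum[b$a1[k]] + b$order[k]
    heavy_bsum[b$a2[k]] <- heavy_bsum[b$a2[k]] + b$order[k]
  }
  bsym <- function(o) switch(o, "", "=", "#")
  atom_token <- function(i) {
    el <- a$element[i]
    bracket <- a$charge[i] != 0L || a$radical[i] > 0L || !is.na(a$stereo[i]) ||
      !el %in% .ORGANIC || el == "H"
    if (!bracket) {
      av <- allowed_valences(el, 0L)
      fit <- av[av >= heavy_bsum[i]]
      if (!length(fit) || min(fit) - heavy_bsum[i] != nh[i]) bracket <- TRUE
    }
    if (!bracket) return(el)
    chgs <- if (a$charge[i] > 0L) paste0("+", if (a$charge[i] > 1L) a$charge[i] else "")
            else if (a$charge[i] < 0L) paste0("-", if (a$charge[i] < -1L) -a$charge[i] else "")
            else ""
    hs <- if (nh[i] == 1L) "H" else if (nh[i] > 1L) paste0("H", nh[i]) else ""
    stq <- if (!is.na(a$stereo[i]) && a$stereo[i] %in% c("@", "@@")) a$stereo[i] else ""
    paste0("[", el, stq, hs, chgs, "]")
  }

  # DFS spanning tree over kept atoms; back edges become ring closures
  adj2 <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    if (suppress[b$a1[k]] || suppress[b$a2[k]]) next
    adj2[[b$a1[k]]] <- rbind(adj2[[b$a1[k]]], c(b$a2[k], b$order[k]))
    adj2[[b$a2[k]]] <- rbind(adj2[[b$a2[k]]], c(b$a1[k], b$order[k]))
  }
  tree_children <- vector("list", n)
  back_edges <- list()
  seen <- rep(FALSE, n)
  dfs <- function(i, parent) {
    seen[i] <<- TRUE
    nb <- adj2[[i]]
    skipped_parent <- FALSE
    if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
      j <- nb[r, 1]
      if (j == parent && !skipped_parent) { skipped_parent <- TRUE; next }
      if (seen[j]) {
        key <- paste(min(i, j), max(i, j))
        if (is.null(back_edges[[key]])) back_edges[[key]] <<- c(i, j, nb[r, 2])
      } else {
        tree_children[[i]] <<- rbind(tree_children[[i]], c(j, nb[r, 2]))
        dfs(j, i)
      }
    }
  }
  environment(dfs) <- environment()
  roots <- c()
  for (i in keep) if (!seen[i]) { roots <- c(roots, i); dfs(i, 0L) }
  if (length(roots) > 1L) stop("write_smiles: molecule not connected")

  ring_at <- vector("list", n)
  dig <- 0L
  for (key in names(back_edges)) {
    dig <- dig + 1L
    e <- back_edges[[key]]
    lab <- if (dig < 10L) as.character(dig) else paste0("%", dig)
    ring_at[[e[1]]] <- rbind(ring_at[[e[1]]], c(lab, bsym(e[3])))
    ring_at[[e[2]]] <- rbind(ring_at[[e[2]]], c(lab, ""))
  }
  build <- function(i) {
    parts <- atom_token(i)
    ra <- ring_at[[i]]
    if (!is.null(ra)) for (r in seq_len(nrow(ra))) parts <- paste0(parts, ra[r, 2], ra[r, 1])
    ch <- tree_children[[i]]
    if (!is.null(ch)) {
      nc <- nrow(ch)
      for (r in seq_len(nc)) {
        sub <- paste0(bsym(ch[r, 2]), build(ch[r, 1]))
        parts <- paste0(parts, if (r < nc) paste0("(", sub, ")") else sub)
      }
    }
    parts
  }
  build(roots[1])
}
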