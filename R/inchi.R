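# Minimal InChI reader.
#
# Supported: single-component standard InChIs with formula, c (connection)
# and h (fixed hydrogen) layers, e.g. InChI=1S/C2H6O/c1-3-2/h3H2,1-2H3 —
# no mobile-H groups, no q/p/b/t/m/s layers. Bond orders are not stored in an
# InChI; they are reconstructed by a saturation solver that distributes the
# valence deficit over the heavy-atom skeleton, minimizing leftover unpaired
# electrons (so closed-shell inputs come back closed-shell and a genuinely
# radical formula, e.g. InChI=1S/CH3/h1H3, comes back as a radical).

#' Parse an InChI string (restricted subset)
#'
#' @param s InChI string starting with `InChI=`.
#' @return A `mol` object.
#' @export
parse_inchi <- function(s) {
  s <- trimws(s)
  if (!startsWith(s, "InChI=")) stop("not an InChI: ", s)
  body <- sub("^InChI=1S?/", "", s)
  layers <- strsplit(body, "/", fixed = TRUE)[[1]]
  formula <- layers[1]
  if (grepl("[.;]", formula)) stop("multi-component InChI not supported: ", s)
  rest <- layers[-1]
  lget <- function(prefix) {
    hit <- rest[startsWith(rest, prefix)]
    if (length(hit)) sub(paste0("^", prefix), "", hit[1]) else NULL
  }
  if (any(startsWith(rest, "q") | startsWith(rest, "p")))
    stop("charged InChI not supported: ", s)
  if (!is.null(lget("h")) && grepl("\\(", lget("h")))
    stop("mobile-H InChI layer not supported: ", s)

  # formula -> heavy atom list in InChI numbering (C first, then alphabetical)
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  counts <- list()
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    k <- sub("^[A-Za-z]+", "", t)
    counts[[el]] <- if (nzchar(k)) as.integer(k) else 1L
  }
  nH <- if (!is.null(counts[["H"]])) counts[["H"]] else 0L
  counts[["H"]] <- NULL
  heavy_els <- c(if (!is.null(counts[["C"]])) rep("C", counts[["C"]]),
                 unlist(lapply(sort(setdiff(names(counts), "C")),
                               function(e) rep(e, counts[[e]]))))
  nheavy <- length(heavy_els)
  if (nheavy == 0L) {
    if (nH == 1L) return(molecule("H", radical = 1L))
    if (nH == 2L) return(molecule(c("H", "H"),
                                  data.frame(a1 = 1L, a2 = 2L, order = 1L)))
    stop("cannot interpret all-hydrogen formula: ", s)
  }

  # c layer -> heavy-atom edges
  edges <- matrix(integer(), ncol = 2)
  clayer <- lget("c")
  if (!is.null(clayer) && nzchar(clayer)) {
    chars <- strsplit(clayer, "")[[1]]
    i <- 1L; cur <- NA_integer_; stk <- integer()
    while (i <= length(chars)) {
      ch <- chars[i]
      if (grepl("[0-9]", ch)) {
        j <- i
        while (j <= length(chars) && grepl("[0-9]", chars[j])) j <- j + 1L
        num <- as.integer(paste0(chars[i:(j - 1L)], collapse = ""))
        if (!is.na(cur)) edges <- rbind(edges, c(cur, num))
        cur <- num
        i <- j
      } else if (ch == "-") { i <- i + 1L
      } else if (ch == "(") { stk <- c(stk, cur); i <- i + 1L
      } else if (ch == ",") { cur <- stk[length(stk)]; i <- i + 1L
      } else if (ch == ")") { cur <- stk[length(stk)]; stk <- stk[-length(stk)]; i <- i + 1L
      } else stop("bad c layer character '", ch, "' in: ", s)
    }
  } else if (nheavy > 1L) stop("missing c layer for multi-atom molecule: ", s)

  # h layer -> per-heavy-atom hydrogen counts
  hc <- integer(nheavy)
  hlayer <- lget("h")
  if (!is.null(hlayer) && nzchar(hlayer)) {
    for (grp in strsplit(hlayer, ",", fixed = TRUE)[[1]]) {
      m <- regmatches(grp, regexec("^([0-9-]+)H([0-9]*)$", grp))[[1]]
      if (!length(m)) stop("unsupported h layer group '", grp, "' in: ", s)
      cnt <- if (nzchar(m[3])) as.integer(m[3]) else 1L
      for (span in strsplit(m[2], "-", fixed = TRUE)[[1]]) { } # validated below
      nums <- integer()
      for (span in strsplit(m[2], "-", fixed = TRUE)[[1]]) nums <- c(nums, as.integer(span))
      idx <- if (grepl("-", m[2])) seq(nums[1], nums[2]) else nums
      hc[idx] <- cnt
    }
  }
  if (sum(hc) != nH) stop("h layer does not account for formula hydrogens in: ", s)

  # reconstruct bond orders: maximize total order increments over skeleton
  deg <- integer(nheavy)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    deg[edges[k, 1]] <- deg[edges[k, 1]] + 1L
    deg[edges[k, 2]] <- deg[edges[k, 2]] + 1L
  }
  deficit <- vapply(seq_len(nheavy), function(i)
    min(allowed_valences(heavy_els[i])) - deg[i] - hc[i], 0L)
  if (any(deficit < 0L)) stop("connection layer exceeds valence in: ", s)
  inc <- saturate_deficits(deficit, edges)

  el <- heavy_els; chg <- integer(nheavy); st <- rep(NA_character_, nheavy)
  bonds <- if (nrow(edges))
    data.frame(a1 = edges[, 1], a2 = edges[, 2], order = 1L + inc,
               arom = FALSE, stereo = NA_character_) else NULL
  rad <- deficit - deficit_used(inc, edges, nheavy)
  # explicit hydrogens
  extra <- list()
  for (i in seq_len(nheavy)) if (hc[i] > 0L) for (q in seq_len(hc[i])) {
    el <- c(el, "H"); chg <- c(chg, 0L); st <- c(st, NA_character_)
    rad <- c(rad, 0L)
    bonds <- rbind(bonds, data.frame(a1 = i, a2 = length(el), order = 1L,
                                     arom = FALSE, stereo = NA_character_))
  }
  molecule(el, bonds, charge = chg, radical = rad, stereo = st)
}

# how much of each atom's deficit the chosen increments consume
deficit_used <- function(inc, edges, n) {
  used <- integer(n)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    used[edges[k, 1]] <- used[edges[k, 1]] + inc[k]
    used[edges[k, 2]] <- used[edges[k, 2]] + inc[k]
  }
  used
}

# backtracking: choose per-edge order increments (0..2) maximizing the total
# consumed deficit; deterministic (first optimum in edge order)
saturate_deficits <- function(deficit, edges) {
  ne <- nrow(edges)
  inc <- integer(ne)
  if (!ne || all(deficit == 0L)) return(inc)
  best <- integer(ne); best_used <- -1L
  rec <- function(k, rem, cur) {
    if (sum(rem) == 0L || k > ne) {
      used <- sum(deficit) - sum(rem)
      if (used > best_used) { best_used <<- used; best <<- cur }
      return()
    }
    if (sum(deficit) - sum(rem) + sum(rem) %/% 1L <= best_used) { }
    a <- edges[k, 1]; b <- edges[k, 2]
    for (d in min(rem[a], rem[b], 2L):0L) {
      cur[k] <- d
      rem2 <- rem; rem2[a] <- rem2[a] - d; rem2[b] <- rem2[b] - d
      rec(k + 1L, rem2, cur)
      if (best_used == sum(deficit)) return()   # perfect saturation found
    }
  }
  rec(1L, deficit, inc)
  best
}

#' Parse a molecular identifier (SMILES or InChI)
#'
#' Strings starting with `InChI=` go to [parse_inchi()], everything else to
#' [parse_smiles()].
#'
#' @param s Identifier string.
#' @return A `mol` object.
#' @export
parse_identifier <- function(s) {
  s <- trimws(s)
  if (startsWith(s, "InChI=")) parse_inchi(s) else parse_smiles(s)
}
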