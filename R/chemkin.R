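# CHEMKIN mechanism reader. Species declarations must carry a SMILES or
# InChI as "!" comment; reaction lines are interpreted in the written
# (forward) direction, rate coefficients are ignored, third bodies (+M /
# (+M)) are stripped and stoichiometric multipliers expand to repeated
# molecules. Auxiliary keyword lines (LOW/TROE/PLOG/REV/DUPLICATE/...) are
# skipped.

#' Read a CHEMKIN mechanism file
#'
#' @param path Mechanism file. Each species in the SPECIES block must be
#'   declared on its own line with an identifier comment,
#'   e.g. `C2H5 ! CC[CH2]`.
#' @return An `rxn_corpus`; attribute `"skipped"` is a character vector of
#'   reaction lines that referenced unknown species or failed to parse.
#' @export
read_chemkin <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # block boundaries (keywords may carry ELEMENTS/SPECIES/REACTIONS or END)
  upper <- toupper(trimws(lines))
  blk_start <- function(kw) which(startsWith(upper, kw))[1]
  sp0 <- blk_start("SPECIES"); rx0 <- blk_start("REACTIONS")
  if (is.na(sp0) || is.na(rx0)) stop("missing SPECIES or REACTIONS block in ", path)
  ends <- which(upper == "END")
  sp_end <- min(ends[ends > sp0], length(lines) + 1L) - 1L
  rx_end <- min(ends[ends > rx0], length(lines) + 1L) - 1L

  # species table
  species <- list()
  missing_id <- character()
  for (ln in lines[(sp0 + 1L):sp_end]) {
    raw <- trimws(ln)
    if (!nzchar(raw)) next
    has_comment <- grepl("!", raw, fixed = TRUE)
    body <- trimws(sub("!.*$", "", raw))
    if (!nzchar(body)) next
    names_ <- strsplit(body, "\\s+")[[1]]
    if (has_comment) {
      if (length(names_) != 1L)
        stop("one species per line required when an identifier comment is given: ", raw)
      ident <- trimws(sub("^[^!]*!", "", raw))
      ident <- strsplit(ident, "\\s+")[[1]][1]
      species[[names_[1]]] <- parse_identifier(ident)
    } else {
      missing_id <- c(missing_id, names_)
    }
  }
  if (length(missing_id))
    stop("species without identifier comment: ", paste(missing_id, collapse = ", "))

  records <- list(); skipped <- character(); rid <- 0L
  for (ln in lines[(rx0 + 1L):rx_end]) {
    raw <- trimws(sub("!.*$", "", ln))
    if (!nzchar(raw)) next
    up <- toupper(raw)
    # auxiliary lines: DUPLICATE, LOW/TROE/PLOG/REV/..., anything with "/"
    if (grepl("^(DUP|DUPLICATE|LOW|TROE|SRI|PLOG|REV|FORD|RORD|UNITS)", up) ||
        (grepl("/", raw, fixed = TRUE) && !grepl("=", raw, fixed = TRUE))) next
    if (!grepl("=", raw, fixed = TRUE)) next
    rid <- rid + 1L
    rec <- tryCatch(
      parse_chemkin_reaction(raw, species, sprintf("%s:%d", basename(path), rid)),
      error = function(e) { message("skipping reaction '", raw, "': ",
                                    conditionMessage(e)); NULL })
    if (is.null(rec)) skipped <- c(skipped, raw)
    else records[[length(records) + 1L]] <- rec
  }
  structure(corpus(records, provenance = path), skipped = skipped)
}

parse_chemkin_reaction <- function(raw, species, source_id) {
  # drop trailing rate coefficients (last 3 numeric tokens, if present)
  toks <- strsplit(raw, "\\s+")[[1]]
  is_num <- grepl("^[-+]?[0-9.]+([eEdD][-+]?[0-9]+)?$", toks)
  while (length(toks) > 1L && is_num[length(toks)]) {
    toks <- toks[-length(toks)]; is_num <- is_num[-length(is_num)]
  }
  eq <- paste(toks, collapse = "")
  # strip pressure-dependence third bodies
  eq <- gsub("\\(\\+[A-Za-z0-9]+\\)", "", eq)
  sides <- strsplit(eq, "<=>|=>|=")[[1]]
  if (length(sides) != 2L) stop("cannot split reaction equation: ", raw)
  parse_side <- function(sd) {
    out <- list()
    for (t in strsplit(sd, "+", fixed = TRUE)[[1]]) {
      t <- trimws(t)
      if (!nzchar(t) || toupper(t) == "M") next      # third body
      mult <- 1L
      m <- regmatches(t, regexec("^([0-9]+)(.+)$", t))[[1]]
      if (length(m) && !is.null(species[[m[3]]])) { mult <- as.integer(m[2]); t <- m[3] }
      if (is.null(species[[t]])) stop("unknown species '", t, "'")
      for (q in seq_len(mult)) out[[length(out) + 1L]] <- species[[t]]
    }
    out
  }
  rs <- parse_side(sides[1]); ps <- parse_side(sides[2])
  if (!length(rs) || !length(ps)) stop("empty reaction side in: ", raw)
  reaction_record(rs, ps, source_id = source_id, origin_format = "chemkin")
}

#' Read a structured identifier-list file
#'
#' One reaction per line: reactant identifiers, then `>>`, then product
#' identifiers; species separated by `+` (or `.` within a side). SMILES and
#' InChI may be mixed. Blank lines and lines starting with `#` are ignored;
#' unparsable lines are skipped with a logged message.
#'
#' @param path Text file path.
#' @param sep Side delimiter (default `">>"`).
#' @return An `rxn_corpus`; attribute `"skipped"` is a data frame of skipped
#'   line numbers and messages.
#' @export
read_identifier_list <- function(path, sep = ">>") {
  lines <- readLines(path, warn = FALSE)
  records <- list(); skip_line <- integer(); skip_msg <- character()
  for (i in seq_along(lines)) {
    raw <- trimws(lines[i])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    rec <- tryCatch({
      sides <- strsplit(raw, sep, fixed = TRUE)[[1]]
      if (length(sides) != 2L) stop("expected one '", sep, "' delimiter")
      parse_side <- function(sd) {
        # species separated by spaced " + " (so bracket charges survive) or "."
        idents <- unlist(strsplit(strsplit(sd, " + ", fixed = TRUE)[[1]], ".", fixed = TRUE))
        idents <- trimws(idents)
        idents <- idents[nzchar(idents)]
        if (!length(idents)) stop("empty side")
        lapply(idents, parse_identifier)
      }
      reaction_record(parse_side(sides[1]), parse_side(sides[2]),
                      source_id = sprintf("%s:%d", basename(path), i),
                      origin_format = "identifier_list")
    }, error = function(e) { message("skipping line ", i, ": ",
                                     conditionMessage(e)); NULL })
    if (is.null(rec)) { skip_line <- c(skip_line, i); skip_msg <- c(skip_msg, "parse error") }
    else records[[length(records) + 1L]] <- rec
  }
  structure(corpus(records, provenance = path),
            skipped = data.frame(line = skip_line, message = skip_msg,
                                 stringsAsFactors = FALSE))
}
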