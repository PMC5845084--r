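# End-to-end driver: ingest -> balance/arity filters -> mapping (pre-mapped
# or baseline, with resonance selection, symmetric-gap completion,
# hydroperoxyl correction and mechanism check) -> template extraction ->
# deduplication, reverse links, classification -> serialized outputs.

#' Run the template-extraction pipeline
#'
#' @param input Path to the input (file or RXN directory) or an
#'   `rxn_corpus` object.
#' @param format One of `"list"`, `"rxn"`, `"chemkin"`; ignored when `input`
#'   is already a corpus.
#' @param mapper `"baseline"` (compute mappings, resonance-aware) or
#'   `"premapped"` (only records that arrive with a complete mapping are
#'   analyzed). Records with a complete mapping always bypass the mapper.
#' @param include_hetero Expand reactive centers with adjacent hetero atoms
#'   (default TRUE).
#' @param max_reactants Arity filter (default 2).
#' @param outdir Optional output directory for `templates.json`,
#'   `distribution.csv` and `manifest.json`.
#' @return Invisible list: `manifest` (stage counts), `templates`
#'   (deduplicated table), `per_record` (data frame of per-record outcomes),
#'   `constraints_global`.
#' @export
run_pipeline <- function(input, format = c("list", "rxn", "chemkin"),
                         mapper = "baseline", include_hetero = TRUE,
                         max_reactants = 2L, outdir = NULL) {
  cp <- if (inherits(input, "rxn_corpus")) input
  else switch(match.arg(format),
              list = read_identifier_list(input),
              rxn = read_rxn_directory(input),
              chemkin = read_chemkin(input))
  n_parsed <- n_records(cp)
  cp_bal <- filter_unbalanced(cp)
  n_unbal <- n_parsed - n_records(cp_bal)
  cp_ok <- filter_arity(cp_bal, max_reactants)
  n_arity <- n_records(cp_bal) - n_records(cp_ok)

  per <- data.frame(source_id = character(), mapping = character(),
                    outcome = character(), stringsAsFactors = FALSE)
  templates <- list()
  map_states <- c(complete = 0L, heuristically_completed = 0L,
                  incomplete = 0L, failed = 0L)
  n_mech_fail <- 0L

  for (rec in cp_ok$records) {
    st <- validate_mapping(rec, rec$map)
    map <- rec$map
    used_rec <- rec
    if (st$state != "complete") {
      if (identical(mapper, "premapped")) {
        st <- if (is.null(rec$map)) mapping_status("failed", "no mapping provided")
              else st
      } else {
        sel <- select_resonance_combination(rec, mapper)
        used_rec <- sel$record; map <- sel$map; st <- sel$status
        if (st$state == "incomplete") {
          comp <- complete_symmetric_gap(used_rec, map)
          map <- comp$map; st <- comp$status
        }
      }
    }
    map_states[st$state] <- map_states[st$state] + 1L
    if (!st$state %in% c("complete", "heuristically_completed")) {
      per[nrow(per) + 1L, ] <- list(rec$source_id, st$state, "not_analyzed")
      next
    }
    map <- correct_peroxide_elimination(used_rec, map)
    changes <- detect_changes(used_rec, map)
    acc <- mechanism_acceptable(used_rec, changes)
    if (!isTRUE(as.logical(acc))) {
      n_mech_fail <- n_mech_fail + 1L
      per[nrow(per) + 1L, ] <- list(rec$source_id, st$state, "failure")
      next
    }
    tpl <- extract_template(used_rec, map, include_hetero = include_hetero)
    templates[[length(templates) + 1L]] <- tpl
    per[nrow(per) + 1L, ] <- list(rec$source_id, st$state, tpl$status)
  }

  table_ <- deduplicate_and_count(templates)
  classes <- vapply(table_, classify_template, "")
  n_reverse <- sum(vapply(table_, function(t) isTRUE(t$is_reverse), TRUE))

  manifest <- list(
    parsed = n_parsed,
    rejected_unbalanced = n_unbal,
    rejected_arity = n_arity,
    mapping = as.list(map_states),
    mechanism_failures = n_mech_fail,
    reactions_in_templates = sum(vapply(table_, function(t) t$count, 0L)),
    templates = length(table_),
    reverse_templates = n_reverse,
    identical_templates = sum(vapply(table_, function(t) t$status, "") == "identical"),
    class_distribution = as.list(table(classes))
  )

  for (i in seq_along(table_)) table_[[i]]$class <- classes[i]

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_templates_json(table_, cp_ok, file.path(outdir, "templates.json"))
    utils::write.csv(template_distribution(table_),
                     file.path(outdir, "distribution.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(manifest = manifest, templates = table_, per_record = per,
                 corpus = cp_ok))
}

#' Distribution table of a template list
#'
#' @param table_ List of deduplicated templates (with `class` set).
#' @return Data frame: id, class, count, status, reverse_of.
#' @export
template_distribution <- function(table_) {
  data.frame(
    id = seq_along(table_),
    class = vapply(table_, function(t)
      if (is.null(t$class)) classify_template(t) else t$class, ""),
    count = vapply(table_, function(t) t$count, 0L),
    status = vapply(table_, function(t) t$status, ""),
    reverse_of = vapply(table_, function(t)
      if (is.na(t$reverse_of)) NA_integer_ else t$reverse_of, 0L),
    stringsAsFactors = FALSE)
}

#' Serialize a template table to JSON
#'
#' Blocks per template: reactants (center SMARTS + per-atom patterns with
#' labels), recipe, constraints, an empty kinetics placeholder (path to a
#' group-additivity database to be filled in by the user), and provenance.
#'
#' @param table_ List of deduplicated templates.
#' @param corpus The analyzed corpus (for the global size constraint).
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_templates_json <- function(table_, corpus, path) {
  out <- lapply(seq_along(table_), function(i) {
    t <- table_[[i]]
    cons <- if (n_records(corpus)) generate_constraints(corpus, t) else NULL
    list(
      id = i,
      class = if (is.null(t$class)) classify_template(t) else t$class,
      status = t$status,
      reactants = lapply(seq_along(t$fragments), function(fi) {
        f <- t$fragments[[fi]]
        list(center_smarts = fragment_smarts(f),
             atoms = lapply(seq_along(f$labels), function(q) list(
               label = f$labels[q],
               element = f$element[q],
               role = f$role[q],
               smarts = fragment_smarts(f, q))))
      }),
      recipe = t$recipe,
      constraints = cons,
      kinetics = list(type = "group_additivity", database = ""),
      provenance = list(count = t$count,
                        source_ids = t$source_ids,
                        reverse_of = if (is.na(t$reverse_of)) NULL else t$reverse_of)
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
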