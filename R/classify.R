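# Rule-based typing: gate predicates per type template, then scored-position
# matching among the gate-passers. Unclassified is a first-class outcome.

#' Type template
#'
#' Gating predicates and scored positions defining one PETase type.
#' Gate fields set to `NA`/`NULL` are not evaluated.
#'
#' @param type_label `"I"`, `"IIa"`, `"IIb"` or `"III"`.
#' @param n_disulfides exact required number of disulfide pairs (NA = any).
#' @param n_canonical exact required number of canonical pairs (NA = any).
#' @param min_disulfides minimum number of pairs (NA = none).
#' @param all_noncanonical require every pair to be non-canonical.
#' @param extended_loop required extended-loop presence (TRUE/FALSE/NA).
#' @param motifs allowed lipase-box labels (NULL = any).
#' @param clamp required clamp status (TRUE/FALSE/NA).
#' @param loop3_delta_min minimum loop-3 length delta (NA = none).
#' @param scored_positions data.frame `ref_pos`, `expected`, `weight` of
#'   expected residues at annotated reference positions.
#' @return object of class `type_template`.
#' @export
type_template <- function(type_label, n_disulfides = NA, n_canonical = NA,
                          min_disulfides = NA, all_noncanonical = FALSE,
                          extended_loop = NA, motifs = NULL, clamp = NA,
                          loop3_delta_min = NA,
                          scored_positions = data.frame(ref_pos = integer(0),
                                                        expected = character(0),
                                                        weight = numeric(0))) {
  stopifnot(type_label %in% c("I", "IIa", "IIb", "III"))
  structure(list(type_label = type_label, n_disulfides = n_disulfides,
                 n_canonical = n_canonical, min_disulfides = min_disulfides,
                 all_noncanonical = isTRUE(all_noncanonical),
                 extended_loop = extended_loop, motifs = motifs, clamp = clamp,
                 loop3_delta_min = loop3_delta_min,
                 scored_positions = scored_positions),
            class = "type_template")
}

#' Default type templates
#'
#' The shipped gating rules: type I requires exactly one disulfide and no
#' extended loop; types IIa/IIb require two canonical disulfides and an
#' extended loop (discriminated by scored subsite-II / extended-loop
#' residues); type III requires the GHSQG lipase box, clamp absence, at
#' least two disulfides all at non-canonical positions, and a loop-3
#' insertion of at least `+3`. Scored positions refer to the packaged
#' synthetic reference annotation and are editable on disk
#' (`inst/extdata/type_templates.json`).
#'
#' @param path optional path to a template JSON file.
#' @return list of [type_template()] objects.
#' @export
default_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "type_templates.json", package = "petasetyper",
                        mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw$templates, function(tp) {
    sp <- tp$scored_positions
    sp <- if (is.null(sp) || !length(sp))
            data.frame(ref_pos = integer(0), expected = character(0),
                       weight = numeric(0))
          else
            data.frame(ref_pos = vapply(sp, function(x) as.integer(x$ref_pos), integer(1)),
                       expected = vapply(sp, function(x) x$expected, character(1)),
                       weight = vapply(sp, function(x) as.numeric(x$weight %||% 1), numeric(1)))
    type_template(type_label = tp$type_label,
                  n_disulfides = tp$n_disulfides %||% NA,
                  n_canonical = tp$n_canonical %||% NA,
                  min_disulfides = tp$min_disulfides %||% NA,
                  all_noncanonical = tp$all_noncanonical %||% FALSE,
                  extended_loop = tp$extended_loop %||% NA,
                  motifs = if (!is.null(tp$motifs)) unlist(tp$motifs),
                  clamp = tp$clamp %||% NA,
                  loop3_delta_min = tp$loop3_delta_min %||% NA,
                  scored_positions = sp)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eval_gates <- function(template, report) {
  n_db <- nrow(report$disulfide_pairs)
  n_canon <- sum(report$disulfide_pairs$canonical)
  gates <- list()
  if (!is.na(template$n_disulfides))
    gates$n_disulfides <- n_db == template$n_disulfides
  if (!is.na(template$n_canonical))
    gates$n_canonical <- n_canon == template$n_canonical
  if (!is.na(template$min_disulfides))
    gates$min_disulfides <- n_db >= template$min_disulfides
  if (template$all_noncanonical)
    gates$all_noncanonical <- n_db > 0L && n_canon == 0L
  if (!is.na(template$extended_loop))
    gates$extended_loop <- report$extended_loop_present == template$extended_loop
  if (!is.null(template$motifs))
    gates$motif <- report$lipase_box$label %in% template$motifs
  if (!is.na(template$clamp))
    gates$clamp <- !is.na(report$clamp$present) &&
      report$clamp$present == template$clamp
  if (!is.na(template$loop3_delta_min))
    gates$loop3_delta <- !is.na(report$loop_deltas[["loop3"]]) &&
      report$loop_deltas[["loop3"]] >= template$loop3_delta_min
  gates
}

score_template <- function(template, report) {
  sp <- template$scored_positions
  if (!nrow(sp)) return(1.0)
  got <- report$mapped_residues[as.character(sp$ref_pos)]
  hits <- !is.na(got) & got == sp$expected
  sum(sp$weight * hits) / sum(sp$weight)
}

#' Classify a feature report into a PETase type
#'
#' Evaluates every template's gates on the report; among gate-passing
#' templates the highest scored-position fraction wins. No passing template,
#' or a tie at the top, yields `"unclassified"`.
#'
#' @param report a [build_report()] result.
#' @param templates list of [type_template()] (default [default_templates()]).
#' @return object of class `type_call`: `query_id`, `call`,
#'   `per_template_score`, `gating_results`, `rationale`.
#' @export
classify_petase <- function(report, templates = default_templates()) {
  stopifnot(inherits(report, "petase_features"))
  if (isTRUE(report$blocked))
    pt_abort(sprintf("query '%s': catalytic serine undetectable by sequence or structure",
                     report$query_id),
             "petasetyper_blocked_call")
  labels <- vapply(templates, `[[`, character(1), "type_label")
  gating <- lapply(templates, eval_gates, report = report)
  names(gating) <- labels
  passed <- vapply(gating, function(g) all(unlist(g)), logical(1))
  scores <- vapply(templates, score_template, numeric(1), report = report)
  names(scores) <- labels

  call <- "unclassified"
  if (any(passed)) {
    cand <- scores[passed]
    top <- max(cand)
    winners <- names(cand)[cand == top]
    if (length(winners) == 1L) call <- winners
  }
  rationale <- character(0)
  for (lab in labels) {
    g <- gating[[lab]]
    line <- if (!length(g)) sprintf("type %s: no gates defined", lab)
            else sprintf("type %s gates: %s", lab,
                         paste(sprintf("%s=%s", names(g),
                                       ifelse(unlist(g), "pass", "fail")),
                               collapse = ", "))
    rationale <- c(rationale, line,
                   sprintf("type %s scored-position fraction: %.2f", lab, scores[[lab]]))
  }
  rationale <- c(sprintf("lipase box %s (%s)", report$lipase_box$motif,
                         report$lipase_box$label),
                 sprintf("clamp %s", if (is.na(report$clamp$present)) "undetermined"
                                     else if (report$clamp$present) "present" else "absent"),
                 sprintf("%d disulfide pair(s), %d canonical (%s)",
                         nrow(report$disulfide_pairs),
                         sum(report$disulfide_pairs$canonical),
                         report$disulfide_source),
                 sprintf("extended loop %s",
                         if (report$extended_loop_present) "present" else "absent"),
                 sprintf("loop deltas: %s",
                         paste(sprintf("%s %+.0f", names(report$loop_deltas),
                                       report$loop_deltas), collapse = ", ")),
                 rationale)
  structure(list(query_id = report$query_id, call = call,
                 per_template_score = scores, gating_results = gating,
                 rationale = rationale),
            class = "type_call")
}

#' Ordered rationale text for a type call
#' @param call a [classify_petase()] result.
#' @return character vector, one evidence line per element.
#' @export
explain <- function(call) {
  stopifnot(inherits(call, "type_call"))
  c(sprintf("%s -> type %s", call$query_id, call$call), call$rationale)
}

#' @export
print.type_call <- function(x, ...) {
  cat(sprintf("<type_call> %s: %s\n", x$query_id, x$call))
  cat(sprintf("  template scores: %s\n",
              paste(sprintf("%s=%.2f", names(x$per_template_score),
                            x$per_template_score), collapse = ", ")))
  invisible(x)
}

#' One-line-per-query summary of type calls
#' @param calls list of `type_call`.
#' @return data.frame `query_id`, `call`, plus one score column per template.
#' @export
calls_summary <- function(calls) {
  do.call(rbind, lapply(calls, function(x) {
    row <- data.frame(query_id = x$query_id, call = x$call,
                      stringsAsFactors = FALSE)
    for (nm in names(x$per_template_score))
      row[[paste0("score_", nm)]] <- x$per_template_score[[nm]]
    row
  }))
}
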