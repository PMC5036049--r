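# Template-based annotation transfer: map the catalytic residues of the
# most similar reference enzyme onto aligned query positions.

#' Construct a template hit
#'
#' @param template_id template identifier.
#' @param similarity alignment similarity score (structure- or
#'   profile-alignment scale).
#' @param mapping named integer vector: names are query residue indices,
#'   values are template residue indices (1-based, injective).
#' @return object of class `cr_template_hit`.
#' @export
template_hit <- function(template_id, similarity, mapping) {
  mapping <- setNames(as.integer(mapping), names(mapping))
  if (anyDuplicated(mapping[!is.na(mapping)]))
    stop("template mapping must be injective")
  if (!is.finite(similarity)) stop("similarity must be finite")
  structure(list(template_id = template_id, similarity = similarity,
                 mapping = mapping),
            class = "cr_template_hit")
}

#' Read template hits from TSV
#'
#' Dialect: tab-separated `query_id`, `template_id`, `similarity`,
#' comma-joined `qpos:tpos` pairs (1-based).
#'
#' @param path path to the hits file.
#' @return named list (by query id) of lists of [template_hit()] objects.
#' @export
read_template_hits <- function(path) {
  if (!file.exists(path)) stop("template hits file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in seq_along(lines)) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 4)
      stop("malformed template hit line ", ln, ": expected 4 fields")
    sim <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(sim)) stop("malformed template hit line ", ln, ": bad similarity")
    pairs <- strsplit(strsplit(parts[4], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    q <- vapply(pairs, function(p) as.integer(p[1]), integer(1))
    t <- vapply(pairs, function(p) as.integer(p[2]), integer(1))
    if (any(is.na(q)) || any(is.na(t)))
      stop("malformed template hit line ", ln, ": bad mapping pair")
    hit <- template_hit(parts[2], sim, setNames(t, q))
    out[[parts[1]]] <- c(out[[parts[1]]], list(hit))
  }
  out
}

#' Write template hits to TSV
#' @param hits named list (by query id) of lists of [template_hit()].
#' @param path output path.
#' @export
write_template_hits <- function(hits, path) {
  lines <- character(0)
  for (qid in names(hits)) {
    for (h in hits[[qid]]) {
      map <- paste(names(h$mapping), h$mapping, sep = ":", collapse = ",")
      lines <- c(lines, paste(qid, h$template_id,
                              format(h$similarity, digits = 10), map, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Transfer catalytic annotations from the top-ranked template
#'
#' Hits are ranked by similarity descending (ties broken by template id);
#' the top hit's catalytic residues are mapped onto the query: a query
#' position scores 1 exactly when it is aligned to an annotated catalytic
#' residue of the template, 0 otherwise (including unaligned positions).
#' An empty hit list yields all-zero scores with `best_similarity = -Inf`,
#' which suppresses the template channel at fusion time.
#'
#' @param query_length number of residues in the query.
#' @param hits list of [template_hit()] objects (any order).
#' @param template_annotations named list: template id -> integer vector of
#'   catalytic residue indices.
#' @param template_lengths optional named integer vector of template chain
#'   lengths, used to validate mapping targets.
#' @return list with `scores` (0/1 vector of length `query_length`) and
#'   `best_similarity`.
#' @export
template_predict <- function(query_length, hits, template_annotations,
                             template_lengths = NULL) {
  scores <- numeric(query_length)
  if (length(hits) == 0)
    return(list(scores = scores, best_similarity = -Inf))
  sims <- vapply(hits, function(h) h$similarity, numeric(1))
  ids <- vapply(hits, function(h) h$template_id, character(1))
  top <- hits[[order(-sims, ids)[1]]]
  qpos <- as.integer(names(top$mapping))
  tpos <- as.integer(top$mapping)
  if (any(tpos < 1)) stop("template mapping index out of range")
  if (!is.null(template_lengths) && top$template_id %in% names(template_lengths) &&
      any(tpos > template_lengths[[top$template_id]]))
    stop("template mapping index exceeds template length")
  ok <- qpos >= 1 & qpos <= query_length
  cat_idx <- template_annotations[[top$template_id]] %||% integer(0)
  scores[qpos[ok]] <- as.numeric(tpos[ok] %in% cat_idx)
  list(scores = scores, best_similarity = top$similarity)
}
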