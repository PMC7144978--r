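#' Parse an OBO ontology
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 flat file into an is_a DAG.
#' Only `is_a` relationships are kept (the usual convention for phenotype
#' propagation); other relationship types are ignored. Obsolete terms with a
#' `replaced_by` target are recorded as aliases resolving to the replacement;
#' obsolete terms without one are dropped with a warning.
#'
#' @param x Path to an OBO file (optionally gzip-compressed) or a character
#'   vector of OBO lines.
#' @return An object of class `hpo_ontology`: list with `ids`, `name`
#'   (named character), `parents` (named list of parent id vectors),
#'   `children` (named list), `alias` (named character, obsolete id ->
#'   replacement) and `root_id`.
#' @examples
#' obo <- c("[Term]", "id: HP:0000001", "name: All",
#'          "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001")
#' ont <- parse_obo(obo)
#' ont$root_id
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(if (grepl("\\.gz$", x)) gzfile(x) else x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)
  # split into stanzas
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) stop("no [Term] stanza found in OBO input")
  other <- which(grepl("^\\[", lines) & lines != "[Term]")
  bounds <- sort(c(starts, other, length(lines) + 1L))

  ids <- character(0)
  nm <- character(0)
  parents <- list()
  alias <- character(0)
  dropped <- 0L

  for (ord in seq_along(starts)) {
    s <- starts[ord]
    e <- min(bounds[bounds > s]) - 1L
    body <- lines[seq(s + 1L, length.out = max(0L, e - s))]
    field <- function(key) {
      hits <- body[startsWith(body, paste0(key, ":"))]
      vals <- sub("^[^:]+:\\s*", "", hits)
      sub("\\s*!.*$", "", vals)  # strip trailing comments
    }
    id <- field("id")
    if (length(id) == 0 || !nzchar(id[1])) {
      stop("malformed OBO stanza #", ord, ": missing id")
    }
    id <- id[1]
    obsolete <- any(tolower(field("is_obsolete")) == "true")
    if (obsolete) {
      rep_by <- field("replaced_by")
      if (length(rep_by) >= 1 && nzchar(rep_by[1])) {
        alias[id] <- rep_by[1]
      } else {
        dropped <- dropped + 1L
      }
      next
    }
    isa <- sub("\\s.*$", "", field("is_a"))
    ids <- c(ids, id)
    nm[id] <- if (length(field("name"))) field("name")[1] else id
    parents[[id]] <- unique(isa[nzchar(isa)])
  }
  if (dropped > 0) {
    warning(dropped, " obsolete term(s) without replaced_by were dropped")
  }
  if (anyDuplicated(ids)) stop("duplicate term id in OBO input")
  # resolve aliases pointing at aliases (single hop is the norm; iterate to fix)
  for (i in seq_len(5)) {
    redo <- alias %in% names(alias)
    if (!any(redo)) break
    alias[redo] <- alias[match(alias[redo], names(alias))]
  }
  # drop parent edges to unknown terms (resolving through aliases)
  parents <- lapply(parents, function(p) {
    p2 <- ifelse(p %in% names(alias), alias[p], p)
    unique(p2[p2 %in% ids])
  })
  names(parents) <- ids

  children <- rep(list(character(0)), length(ids))
  names(children) <- ids
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }

  roots <- ids[vapply(parents, length, 1L) == 0L]
  if (length(roots) == 0) stop("ontology has no root (cyclic is_a graph?)")

  ont <- structure(
    list(ids = ids, name = nm, parents = parents, children = children,
         alias = alias, root_id = roots[1]),
    class = "hpo_ontology"
  )
  cyc <- .find_cycle(ont)
  if (!is.null(cyc)) {
    stop("cyclic is_a graph: ", paste(cyc, collapse = " -> "))
  }
  ont
}

# Kahn topological sort; returns one cycle (as an id path) or NULL
.find_cycle <- function(ont) {
  indeg <- vapply(ont$parents, length, 1L)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in ont$children[[id]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(ont$ids)) return(NULL)
  # walk parent edges inside the residual subgraph until a repeat
  residual <- names(indeg)[indeg > 0L]
  cur <- residual[1]
  path <- character(0)
  while (!(cur %in% path)) {
    path <- c(path, cur)
    nxt <- intersect(ont$parents[[cur]], residual)
    cur <- nxt[1]
  }
  c(path[which(path == cur):length(path)], cur)
}

#' @export
print.hpo_ontology <- function(x, ...) {
  cat(sprintf("<hpo_ontology> %d terms, root %s (%s), %d alias(es)\n",
              length(x$ids), x$root_id, x$name[[x$root_id]], length(x$alias)))
  invisible(x)
}

#' Resolve a term id through obsolete-term aliases
#'
#' @param ontology An `hpo_ontology`.
#' @param term_id Term identifier (possibly obsolete).
#' @param error If `TRUE` (default) unknown ids raise an error; otherwise
#'   `NA_character_` is returned.
#' @return The resolved term id.
#' @export
resolve_term <- function(ontology, term_id, error = TRUE) {
  if (term_id %in% ontology$ids) return(term_id)
  if (term_id %in% names(ontology$alias)) {
    tgt <- ontology$alias[[term_id]]
    if (tgt %in% ontology$ids) return(tgt)
  }
  if (error) stop("unknown term id: ", term_id)
  NA_character_
}

#' Reflexive descendant closure of a term
#'
#' Returns the term itself plus every term reachable from it via child edges,
#' i.e. the set of terms whose annotation implies the query term. Case
#' membership for a phenotype is defined over exactly this closure.
#'
#' @inheritParams resolve_term
#' @return Character vector of term ids (unordered set; no duplicates).
#' @examples
#' obo <- c("[Term]", "id: HP:0000001", "name: root",
#'          "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001",
#'          "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000002")
#' hpo_descendants(parse_obo(obo), "HP:0000002")
#' @export
hpo_descendants <- function(ontology, term_id) {
  term_id <- resolve_term(ontology, term_id)
  out <- character(0)
  queue <- term_id
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    if (id %in% out) next
    out <- c(out, id)
    queue <- c(queue, ontology$children[[id]])
  }
  out
}

#' Split a cohort into cases and controls for a phenotype
#'
#' A patient is a case if annotated with the query term or any of its
#' descendants; everyone else is a control. The two sets partition the cohort.
#' When several term ids are supplied the case set is the intersection of the
#' per-term case sets (patients affected by all the phenotypes).
#'
#' @param ontology An `hpo_ontology`.
#' @param patients Data frame with columns `patient_id` and `hpo` (list column
#'   of character term-id vectors), as held in a [cohort_data()] object.
#' @param term_id One or more term ids.
#' @return List with character vectors `cases` and `controls` (patient ids).
#' @export
split_cases <- function(ontology, patients, term_id) {
  if (nrow(patients) == 0) {
    warning("empty patient list; empty case/control partition")
    return(list(cases = character(0), controls = character(0)))
  }
  case <- rep(TRUE, nrow(patients))
  for (tid in term_id) {
    closure <- hpo_descendants(ontology, tid)
    case <- case & vapply(patients$hpo, function(tt) any(tt %in% closure),
                          logical(1))
  }
  list(cases = patients$patient_id[case], controls = patients$patient_id[!case])
}

# terms x patients logical case matrix used by the screening hot path;
# closures are computed once per term
.case_matrix <- function(ontology, patients, terms) {
  term_of_patient <- patients$hpo
  # map each patient's annotations to ontology indices once
  idx <- lapply(term_of_patient, function(tt) {
    tt <- vapply(tt, function(t) resolve_term(ontology, t, error = FALSE),
                 character(1))
    tt[!is.na(tt)]
  })
  mat <- matrix(FALSE, nrow = length(terms), ncol = nrow(patients),
                dimnames = list(terms, patients$patient_id))
  for (t in terms) {
    closure <- hpo_descendants(ontology, t)
    mat[t, ] <- vapply(idx, function(tt) any(tt %in% closure), logical(1))
  }
  mat
}

#' Write an ontology to OBO format
#'
#' Emits a minimal OBO 1.2 document ([parse_obo()] round-trips it).
#'
#' @param ontology An `hpo_ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  out <- c("format-version: 1.2", "ontology: synthetic-hpo", "")
  for (id in ontology$ids) {
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", ontology$name[[id]]),
             paste0("is_a: ", ontology$parents[[id]]), "")
  }
  writeLines(out, path)
  invisible(path)
}
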