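# Ontology parsing and DAG queries.
#
# The ontology is held as a flat set of terms with per-term category
# (namespace) labels and parent edges restricted to is_a / part_of.  The GO
# categories are disjoint sub-ontologies, so every structural query
# (ancestors, descendants, propagation) stays within one category;
# cross-category parent edges are dropped at parse time.

#' Construct an ontology DAG
#'
#' Low-level constructor used by [parse_obo()] and by the synthetic
#' benchmark generator.  Validates the structural invariants: parent edges
#' never cross categories, the relation labels are `is_a`/`part_of`, and the
#' per-category parent relation is acyclic.
#'
#' @param terms character vector of term identifiers.
#' @param category named character vector, category (namespace) per term.
#' @param parents named list; for each term a data.frame with columns
#'   `parent` and `relation` (possibly 0-row).
#' @param obsolete named logical vector, one flag per term.
#' @param name optional named character vector of human-readable term names.
#' @return an object of class `ontology_dag` with elements `terms`,
#'   `category`, `parents`, `children` (named list of child term ids),
#'   `obsolete`, `name`.
#' @export
ontology_dag <- function(terms, category, parents, obsolete = NULL,
                         name = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop_("duplicated term identifiers")
  if (is.null(obsolete)) {
    obsolete <- stats::setNames(rep(FALSE, length(terms)), terms)
  }
  category <- category[terms]
  obsolete <- obsolete[terms]
  parents <- parents[terms]
  names(parents) <- terms
  for (t in terms) {
    p <- parents[[t]]
    if (is.null(p)) {
      parents[[t]] <- data.frame(parent = character(), relation = character(),
                                 stringsAsFactors = FALSE)
      next
    }
    if (!all(p$relation %in% c("is_a", "part_of")))
      stop_("term %s: parent relation must be is_a or part_of", t)
    bad <- !(p$parent %in% terms)
    if (any(bad))
      stop_("term %s: unknown parent %s", t, paste(p$parent[bad], collapse = ", "))
    cross <- category[p$parent] != category[t]
    if (any(cross))
      stop_("term %s: cross-category parent edge to %s", t,
            paste(p$parent[cross], collapse = ", "))
  }
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) children[[t]] <- character()
  for (t in terms) {
    for (p in unique(parents[[t]]$parent)) {
      children[[p]] <- c(children[[p]], t)
    }
  }
  dag <- structure(
    list(terms = terms, category = category, parents = parents,
         children = children, obsolete = obsolete,
         name = name %||% stats::setNames(terms, terms)),
    class = "ontology_dag")
  .check_acyclic(dag)
  dag
}

# Kahn topological sort per category; error on cycle.  Returns terms in an
# order where every parent precedes its children.
.topo_sort <- function(dag) {
  indeg <- vapply(dag$parents, nrow, integer(1))
  queue <- dag$terms[indeg == 0L]
  out <- character(0)
  indeg_left <- indeg
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, t)
    for (ch in dag$children[[t]]) {
      indeg_left[ch] <- indeg_left[ch] - sum(dag$parents[[ch]]$parent == t)
      if (indeg_left[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(dag$terms))
    stop_("cycle detected in ontology parent relation")
  out
}

.check_acyclic <- function(dag) invisible(.topo_sort(dag))

#' @export
print.ontology_dag <- function(x, ...) {
  cats <- table(x$category[!x$obsolete])
  cat(sprintf("ontology_dag: %d terms (%d obsolete) in %d categories\n",
              length(x$terms), sum(x$obsolete), length(cats)))
  for (cc in names(cats)) cat(sprintf("  %s: %d terms\n", cc, cats[[cc]]))
  invisible(x)
}

#' Parse an OBO 1.2/1.4 flat file
#'
#' Reads `[Term]` stanzas and retains `id`, `name`, `namespace`, `is_a`
#' parents, `relationship: part_of` parents and the `is_obsolete` flag.
#' Namespaces become category labels (falling back to the header
#' `default-namespace` when a stanza omits its own).  Parent edges that
#' would cross categories are dropped with a warning; all other relationship
#' types (e.g. `regulates`) are ignored.
#'
#' @param path path to an OBO file.
#' @return an [ontology_dag()].
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  default_ns <- NA_character_
  hdr <- grep("^default-namespace:", lines, value = TRUE)
  if (length(hdr)) default_ns <- trimws(sub("^default-namespace:", "", hdr[[1L]]))

  starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", trimws(lines))
  if (!length(term_starts)) stop_("no [Term] stanzas found in %s", path)

  ids <- character(); nm <- character(); ns <- character(); obs <- logical()
  plist <- list()
  raw_parents <- list()  # parent edges before the cross-namespace filter

  for (k in seq_along(term_starts)) {
    beg <- term_starts[[k]]
    nxt <- starts[starts > beg]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    stanza <- lines[(beg + 1L):end]
    stanza <- stanza[nzchar(trimws(stanza))]
    stanza <- stanza[!startsWith(trimws(stanza), "!")]

    field <- function(key) {
      v <- grep(paste0("^", key, ":"), stanza, value = TRUE)
      vapply(v, function(s) trimws(sub("!.*$", "", sub(paste0("^", key, ":"), "", s))),
             character(1), USE.NAMES = FALSE)
    }
    id <- field("id")
    if (length(id) != 1L)
      stop_("malformed [Term] stanza near line %d of %s: expected exactly one id", beg, path)
    ids <- c(ids, id)
    nmv <- field("name")
    nm <- c(nm, if (length(nmv)) nmv[[1L]] else id)
    nsv <- field("namespace")
    ns <- c(ns, if (length(nsv)) nsv[[1L]] else default_ns)
    obs <- c(obs, any(tolower(field("is_obsolete")) == "true"))

    isa <- vapply(strsplit(field("is_a"), "\\s+"), `[[`, character(1), 1L)
    rel <- field("relationship")
    po <- character(0)
    if (length(rel)) {
      parts <- strsplit(rel, "\\s+")
      keep <- vapply(parts, function(p) p[[1L]] == "part_of", logical(1))
      po <- vapply(parts[keep], `[[`, character(1), 2L)
    }
    raw_parents[[id]] <- data.frame(
      parent = c(isa, po),
      relation = c(rep("is_a", length(isa)), rep("part_of", length(po))),
      stringsAsFactors = FALSE)
  }

  if (anyNA(ns))
    stop_("terms without a namespace and no default-namespace header in %s", path)
  names(ns) <- ids; names(obs) <- ids; names(nm) <- ids

  for (id in ids) {
    p <- raw_parents[[id]]
    known <- p$parent %in% ids
    if (any(!known)) {
      warn_("term %s: dropping %d parent reference(s) to terms absent from the file",
            id, sum(!known))
      p <- p[known, , drop = FALSE]
    }
    cross <- ns[p$parent] != ns[id]
    if (any(cross)) {
      warn_("term %s: dropping %d cross-namespace parent edge(s)", id, sum(cross))
      p <- p[!cross, , drop = FALSE]
    }
    p <- unique(p)
    raw_parents[[id]] <- p
  }

  ontology_dag(ids, ns, raw_parents, obs, nm)
}

#' Descendants of a term
#'
#' Transitive closure under child edges within the term's own category,
#' excluding the term itself.
#'
#' @param dag an [ontology_dag()].
#' @param t a term identifier.
#' @return character vector of descendant term ids (possibly empty).
#' @export
descendants <- function(dag, t) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!t %in% dag$terms) stop_("unknown term: %s", t)
  seen <- character(0)
  queue <- dag$children[[t]]
  while (length(queue)) {
    x <- queue[[1L]]
    queue <- queue[-1L]
    if (x %in% seen) next
    seen <- c(seen, x)
    queue <- c(queue, dag$children[[x]])
  }
  seen
}

#' Ancestors of a term (internal)
#' @noRd
.ancestors <- function(dag, t) {
  seen <- character(0)
  queue <- dag$parents[[t]]$parent
  while (length(queue)) {
    x <- queue[[1L]]
    queue <- queue[-1L]
    if (x %in% seen) next
    seen <- c(seen, x)
    queue <- c(queue, dag$parents[[x]]$parent)
  }
  seen
}

#' Terms of one category
#'
#' @param dag an [ontology_dag()].
#' @param category a category (namespace) label.
#' @param include_obsolete keep obsolete terms? Default `FALSE`.
#' @return character vector of term ids.
#' @export
category_terms <- function(dag, category, include_obsolete = FALSE) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!category %in% dag$category) stop_("unknown category: %s", category)
  keep <- dag$category == category
  if (!include_obsolete) keep <- keep & !dag$obsolete
  dag$terms[keep]
}
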