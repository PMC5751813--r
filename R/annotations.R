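# Gene annotation parsing and true-path propagation.

#' Construct an annotation map
#'
#' @param direct named list of character vectors: directly annotated genes
#'   per term.
#' @param dag the [ontology_dag()] the annotations refer to.
#' @return an object of class `annotation_map` with elements `direct`,
#'   `propagated` (NULL until [propagate()] is run), `universe`,
#'   `term_category` and `dag_terms`.
#' @export
annotation_map <- function(direct, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  unknown <- setdiff(names(direct), dag$terms)
  if (length(unknown)) stop_("annotations to unknown terms: %s",
                             paste(unknown, collapse = ", "))
  obs <- names(direct)[dag$obsolete[names(direct)]]
  if (length(obs)) stop_("annotations to obsolete terms: %s",
                         paste(obs, collapse = ", "))
  direct <- lapply(direct, function(g) sort(unique(as.character(g))))
  structure(
    list(direct = direct, propagated = NULL, universe = NULL,
         term_category = dag$category, dag_terms = dag$terms),
    class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d terms with direct annotations, %d genes\n",
              length(x$direct), length(unique(unlist(x$direct)))))
  if (!is.null(x$propagated)) {
    for (cc in names(x$universe))
      cat(sprintf("  universe(%s): %d genes\n", cc, length(x$universe[[cc]])))
  } else cat("  (not yet propagated)\n")
  invisible(x)
}

#' Parse gene annotations (GAF 2.x or two-column TSV)
#'
#' Accepts either a GAF 2.x file (17-column TSV, `!` comment lines; the DB
#' Object ID column is taken as the gene identifier and the GO ID column as
#' the term) or a minimal two-column TSV `gene<TAB>term`.  Rows carrying a
#' `NOT` qualifier, rows annotating unknown or obsolete terms, and rows with
#' an excluded evidence code are dropped; the numbers dropped are reported.
#'
#' Gene identifiers are compared as bare case-sensitive strings; no
#' symbol/alias resolution is attempted.
#'
#' @param path path to the annotation file.
#' @param dag the parsed [ontology_dag()].
#' @param exclude_evidence character vector of GAF evidence codes to drop
#'   (e.g. `"IEA"`); default none, i.e. all evidence is kept.
#' @return an [annotation_map()] with direct sets populated (not yet
#'   propagated).
#' @export
parse_annotations <- function(path, dag, exclude_evidence = character()) {
  stopifnot(inherits(dag, "ontology_dag"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) stop_("no annotation rows in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1L]])
  is_gaf <- ncol1 >= 15L

  if (is_gaf) {
    gene <- vapply(fields, `[[`, character(1), 2L)
    qual <- vapply(fields, `[[`, character(1), 4L)
    term <- vapply(fields, `[[`, character(1), 5L)
    evid <- vapply(fields, `[[`, character(1), 7L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
    n_not <- sum(!keep)
    if (n_not) message(sprintf("dropped %d NOT-qualified row(s)", n_not))
    if (length(exclude_evidence)) {
      ev_drop <- keep & evid %in% exclude_evidence
      if (any(ev_drop))
        message(sprintf("dropped %d row(s) with excluded evidence code", sum(ev_drop)))
      keep <- keep & !ev_drop
    }
    gene <- gene[keep]; term <- term[keep]
  } else {
    bad <- vapply(fields, length, integer(1)) < 2L
    if (any(bad)) stop_("line %d of %s: expected 2 tab-separated columns",
                        which(bad)[[1L]], path)
    gene <- vapply(fields, `[[`, character(1), 1L)
    term <- vapply(fields, `[[`, character(1), 2L)
  }

  unknown <- !(term %in% dag$terms)
  if (any(unknown)) {
    warn_("dropped %d annotation(s) to terms absent from the ontology", sum(unknown))
    gene <- gene[!unknown]; term <- term[!unknown]
  }
  obs <- dag$obsolete[term]
  if (any(obs)) {
    warn_("dropped %d annotation(s) to obsolete terms", sum(obs))
    gene <- gene[!obs]; term <- term[!obs]
  }
  if (!length(gene)) stop_("no usable annotation rows in %s", path)

  annotation_map(split(gene, term), dag)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene directly annotated to a term is implicitly annotated to every
#' ancestor of that term via `is_a` and `part_of` edges, within the term's
#' category.  After propagation, `propagated(t)` is the union of the direct
#' gene sets over the descendant closure of `t` (including `t` itself), and
#' `universe(C)` is the set of genes annotated anywhere in category `C`.
#'
#' @param ann an [annotation_map()] with direct sets.
#' @param dag the matching [ontology_dag()].
#' @return the annotation map with `propagated` and `universe` filled in.
#'   Obsolete terms are excluded.
#' @export
propagate <- function(ann, dag) {
  stopifnot(inherits(ann, "annotation_map"), inherits(dag, "ontology_dag"))
  order <- rev(.topo_sort(dag))  # children before parents
  live <- dag$terms[!dag$obsolete]
  prop <- stats::setNames(vector("list", length(live)), live)
  for (t in order) {
    if (dag$obsolete[[t]]) next
    g <- ann$direct[[t]] %||% character(0)
    for (ch in dag$children[[t]]) {
      if (dag$obsolete[[ch]]) next
      g <- c(g, prop[[ch]])
    }
    prop[[t]] <- sort(unique(g))
  }
  cats <- unique(dag$category[live])
  universe <- stats::setNames(lapply(cats, function(cc) {
    sort(unique(unlist(prop[live[dag$category[live] == cc]], use.names = FALSE)))
  }), cats)
  ann$propagated <- prop
  ann$universe <- universe
  ann
}

#' Propagated gene set of a term
#'
#' @param ann a propagated [annotation_map()].
#' @param t a term identifier.
#' @return character vector of gene ids (possibly empty).
#' @export
term_genes <- function(ann, t) {
  if (is.null(ann$propagated)) stop_("annotation map has not been propagated")
  if (!t %in% names(ann$propagated)) stop_("unknown or obsolete term: %s", t)
  ann$propagated[[t]]
}
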