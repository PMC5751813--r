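# Synthetic benchmark generator: a two-category toy ontology, propagated
# annotations, a modular co-function network with planted cross-category
# relations, and the matching gold standard.  Planted relatedness is
# encoded purely in the network wiring -- never by sharing annotated genes
# -- so that the benchmark isolates the network pathway of the score.

#' Describe a synthetic benchmark
#'
#' The default instance (two 40-term categories, 400 genes, 8 planted leaf
#' pairs, dense within-module wiring at 0.8 against a 0.01 background) runs
#' through the whole pipeline in seconds while leaving planted pairs
#' clearly separable from random ones.
#'
#' @param n_terms_per_category terms per category (complete
#'   `dag_branching`-ary tree by index).
#' @param dag_branching children per internal term.
#' @param n_genes total gene universe (annotated blocks plus hub/background
#'   pool).
#' @param genes_per_leaf disjoint block size annotated to each leaf.
#' @param n_planted_pairs number of planted (leaf-A, leaf-B) related pairs.
#' @param within_module_edge_prob edge probability inside a planted module;
#'   must exceed `background_edge_prob`.
#' @param background_edge_prob edge probability elsewhere.
#' @param edge_weight_range length-2 numeric, uniform weight range.
#' @param indirect_only if `TRUE`, the two blocks of a planted pair are
#'   never wired directly; each block is wired to a small shared hub set
#'   instead, so the pair is related only through length-2 paths.
#' @param hub_genes_per_pair hub-set size in `indirect_only` mode.
#' @param seed integer seed; the bundle is fully deterministic given it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_terms_per_category = 40L, dag_branching = 3L,
                           n_genes = 400L, genes_per_leaf = 5L,
                           n_planted_pairs = 8L,
                           within_module_edge_prob = 0.8,
                           background_edge_prob = 0.01,
                           edge_weight_range = c(0.5, 1),
                           indirect_only = FALSE, hub_genes_per_pair = 3L,
                           seed = 1L) {
  spec <- structure(
    list(n_terms_per_category = as.integer(n_terms_per_category),
         dag_branching = as.integer(dag_branching),
         n_genes = as.integer(n_genes),
         genes_per_leaf = as.integer(genes_per_leaf),
         n_planted_pairs = as.integer(n_planted_pairs),
         within_module_edge_prob = within_module_edge_prob,
         background_edge_prob = background_edge_prob,
         edge_weight_range = as.numeric(edge_weight_range),
         indirect_only = isTRUE(indirect_only),
         hub_genes_per_pair = as.integer(hub_genes_per_pair),
         seed = as.integer(seed)),
    class = "synthetic_spec")
  .validate_spec(spec)
  spec
}

.validate_spec <- function(spec) {
  with(spec, {
    if (n_terms_per_category < 3L || dag_branching < 2L ||
        n_genes < 1L || genes_per_leaf < 1L || n_planted_pairs < 0L)
      stop_("counts must be positive (and >= 3 terms, branching >= 2)")
    if (within_module_edge_prob <= background_edge_prob)
      stop_("within_module_edge_prob must exceed background_edge_prob")
    if (any(c(within_module_edge_prob, background_edge_prob) < 0) ||
        any(c(within_module_edge_prob, background_edge_prob) > 1))
      stop_("edge probabilities must lie in [0, 1]")
    if (length(edge_weight_range) != 2L || any(edge_weight_range <= 0) ||
        diff(edge_weight_range) < 0)
      stop_("edge_weight_range must be a positive, non-decreasing interval")
  })
  n_leaves <- length(.tree_leaves(spec$n_terms_per_category,
                                  spec$dag_branching))
  need <- 2L * n_leaves * spec$genes_per_leaf +
    if (spec$indirect_only) spec$n_planted_pairs * spec$hub_genes_per_pair
    else 0L
  if (need > spec$n_genes)
    stop_("gene budget insufficient: %d genes needed for %d leaves per category%s, %d provided",
          need, n_leaves,
          if (spec$indirect_only) " plus hub sets" else "", spec$n_genes)
  if (spec$n_planted_pairs > n_leaves)
    stop_("n_planted_pairs exceeds the %d leaves per category", n_leaves)
  invisible(spec)
}

# Complete b-ary tree by index: parent(i) = floor((i - 2) / b) + 1.
.tree_parent <- function(i, b) as.integer(floor((i - 2L) / b) + 1L)
.tree_leaves <- function(n, b) {
  has_child <- rep(FALSE, n)
  if (n >= 2L) has_child[.tree_parent(2:n, b)] <- TRUE
  which(!has_child)
}

.category_dag_frames <- function(n, b, prefix, namespace) {
  ids <- sprintf("%s:%07d", prefix, seq_len(n))
  parents <- lapply(seq_len(n), function(i) {
    if (i == 1L) data.frame(parent = character(), relation = character(),
                            stringsAsFactors = FALSE)
    else data.frame(parent = ids[.tree_parent(i, b)], relation = "is_a",
                    stringsAsFactors = FALSE)
  })
  names(parents) <- ids
  list(ids = ids, parents = parents,
       category = stats::setNames(rep(namespace, n), ids))
}

#' Generate a synthetic benchmark in memory
#'
#' Builds the four objects the rest of the package consumes: an
#' [ontology_dag()] with categories `category_a` and `category_b`, a
#' propagated [annotation_map()] (disjoint gene blocks per leaf, propagated
#' up the trees), a [cofunction_network()] with the planted modules wired
#' densely, and a `gold_standard` of the planted pairs against an equal
#' number of uniformly sampled non-planted cross-category pairs.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `dag`, `ann`, `network`, `gold`, `planted`
#'   (data.frame `term1`, `term2`) and `spec`.
#' @export
synthetic_bundle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .validate_spec(spec)
  with_seed(spec$seed, .synthetic_bundle_impl(spec))
}

.synthetic_bundle_impl <- function(spec) {
  n <- spec$n_terms_per_category
  b <- spec$dag_branching
  A <- .category_dag_frames(n, b, "TA", "category_a")
  B <- .category_dag_frames(n, b, "TB", "category_b")
  dag <- ontology_dag(c(A$ids, B$ids), c(A$category, B$category),
                      c(A$parents, B$parents))

  leaves_a <- A$ids[.tree_leaves(n, b)]
  leaves_b <- B$ids[.tree_leaves(n, b)]
  g <- spec$genes_per_leaf
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  blocks <- list()
  next_gene <- 1L
  take <- function(k) {
    out <- genes[next_gene:(next_gene + k - 1L)]
    next_gene <<- next_gene + k
    out
  }
  direct <- list()
  for (t in leaves_a) direct[[t]] <- blocks[[t]] <- take(g)
  for (t in leaves_b) direct[[t]] <- blocks[[t]] <- take(g)
  ann <- propagate(annotation_map(direct, dag), dag)

  planted <- data.frame(term1 = character(), term2 = character(),
                        stringsAsFactors = FALSE)
  if (spec$n_planted_pairs > 0L)
    planted <- data.frame(
      term1 = sort(sample(leaves_a, spec$n_planted_pairs)),
      term2 = sort(sample(leaves_b, spec$n_planted_pairs)),
      stringsAsFactors = FALSE)

  # edge probabilities over the upper triangle of the gene-gene matrix
  gi <- stats::setNames(seq_len(spec$n_genes), genes)
  P <- matrix(spec$background_edge_prob, spec$n_genes, spec$n_genes)
  if (spec$n_planted_pairs > 0L) {
    for (k in seq_len(spec$n_planted_pairs)) {
      ia <- gi[blocks[[planted$term1[[k]]]]]
      ib <- gi[blocks[[planted$term2[[k]]]]]
      if (spec$indirect_only) {
        hub <- gi[take(spec$hub_genes_per_pair)]
        P[ia, ia] <- spec$within_module_edge_prob
        P[ib, ib] <- spec$within_module_edge_prob
        P[c(ia, ib), hub] <- spec$within_module_edge_prob
        P[hub, c(ia, ib)] <- spec$within_module_edge_prob
        P[hub, hub] <- spec$within_module_edge_prob
        P[ia, ib] <- 0                       # related only through the hubs
        P[ib, ia] <- 0
      } else {
        P[c(ia, ib), c(ia, ib)] <- spec$within_module_edge_prob
      }
    }
  }
  ut <- which(upper.tri(P))
  draw <- stats::runif(length(ut)) < P[ut]
  sel <- ut[draw]
  from_i <- ((sel - 1L) %% spec$n_genes) + 1L
  to_i <- ((sel - 1L) %/% spec$n_genes) + 1L
  w <- stats::runif(length(sel), spec$edge_weight_range[[1L]],
                    spec$edge_weight_range[[2L]])
  network <- cofunction_network(
    data.frame(from = genes[from_i], to = genes[to_i], weight = w,
               stringsAsFactors = FALSE),
    nodes = genes)

  gold <- .sample_gold(dag, planted, spec$n_planted_pairs)
  list(dag = dag, ann = ann, network = network, gold = gold,
       planted = planted, spec = spec)
}

# Random (negative) pairs: uniform over cross-category term pairs that are
# not planted, matched in number to the positives.
.sample_gold <- function(dag, planted, n_pos) {
  ta <- category_terms(dag, "category_a")
  tb <- category_terms(dag, "category_b")
  planted_key <- paste(planted$term1, planted$term2)
  rnd <- data.frame(term1 = character(), term2 = character(),
                    stringsAsFactors = FALSE)
  seen <- character(0)
  while (nrow(rnd) < n_pos) {
    t1 <- sample(ta, 1L); t2 <- sample(tb, 1L)
    key <- paste(t1, t2)
    if (key %in% planted_key || key %in% seen) next
    seen <- c(seen, key)
    rnd <- rbind(rnd, data.frame(term1 = t1, term2 = t2,
                                 stringsAsFactors = FALSE))
  }
  structure(list(positive = planted, random = rnd, provenance = "synthetic"),
            class = "gold_standard")
}

#' Named benchmark presets
#'
#' `default`: planted modules wired directly; `indirect`: planted modules
#' related only through shared hub genes (length-2 paths); `null`: no
#' planted pairs at all (for false-discovery calibration).
#'
#' @param preset one of `"default"`, `"indirect"`, `"null"`.
#' @param seed integer seed.
#' @return a [synthetic_spec()].
#' @export
synthetic_preset <- function(preset = c("default", "indirect", "null"),
                             seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
         default = synthetic_spec(seed = seed),
         indirect = synthetic_spec(indirect_only = TRUE, seed = seed),
         null = synthetic_spec(n_planted_pairs = 0L, seed = seed))
}

#' Write a synthetic benchmark bundle to disk
#'
#' Writes the four files every other module consumes -- `ontology.obo`,
#' `annotations.tsv` (two-column gene/term), `network.tsv` (weighted edge
#' list) and `gold_standard.tsv` -- byte-identically for a given spec.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the four file paths plus the
#'   in-memory bundle as attribute `bundle`.
#' @export
generate_benchmark <- function(spec, dir) {
  bundle <- synthetic_bundle(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(obo = file.path(dir, "ontology.obo"),
                annotations = file.path(dir, "annotations.tsv"),
                network = file.path(dir, "network.tsv"),
                gold_standard = file.path(dir, "gold_standard.tsv"))
  write_obo(bundle$dag, paths$obo)
  direct <- bundle$ann$direct
  ann_lines <- unlist(lapply(names(direct), function(t)
    sprintf("%s\t%s", direct[[t]], t)))
  writeLines(ann_lines, paths$annotations)
  writeLines(c("# gene_a\tgene_b\tweight",
               sprintf("%s\t%s\t%.17g", bundle$network$edges$from,
                       bundle$network$edges$to, bundle$network$edges$weight)),
             paths$network)
  gs <- rbind(
    if (nrow(bundle$gold$positive))
      cbind(bundle$gold$positive, label = "positive"),
    if (nrow(bundle$gold$random))
      cbind(bundle$gold$random, label = "random"))
  writeLines(c("# term1\tterm2\tlabel",
               if (!is.null(gs))
                 sprintf("%s\t%s\t%s", gs$term1, gs$term2, gs$label)),
             paths$gold_standard)
  attr(paths, "bundle") <- bundle
  invisible(paths)
}

#' Write an ontology as an OBO 1.2 flat file
#'
#' @param dag an [ontology_dag()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  out <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    out <- c(out, "[Term]", sprintf("id: %s", t),
             sprintf("name: %s", dag$name[[t]]),
             sprintf("namespace: %s", dag$category[[t]]))
    p <- dag$parents[[t]]
    if (nrow(p)) {
      isa <- p$parent[p$relation == "is_a"]
      po <- p$parent[p$relation == "part_of"]
      out <- c(out, sprintf("is_a: %s", isa),
               sprintf("relationship: part_of %s", po))
    }
    if (dag$obsolete[[t]]) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' A tiny hand-checkable worked example
#'
#' A fixed two-category instance (8 terms, 7 genes, 6 network edges) whose
#' similarity scores can be derived by hand: it contains a term pair with
#' identical propagated sets (`Sim_net = 1`), the two category roots
#' (`Sim = 0` by the shallow-annotation weight) and one network-related
#' pair of disjoint leaf terms.  The same instance ships as plain files
#' under `inst/extdata/worked_example/`.
#'
#' @return a list with `dag`, `ann` (propagated), `network`, and `pairs`
#'   (data.frame of the three pairs of interest).
#' @export
worked_example <- function() {
  terms <- c("TA:0000001", "TA:0000002", "TA:0000003", "TA:0000004",
             "TA:0000005",
             "TB:0000001", "TB:0000002", "TB:0000003")
  category <- stats::setNames(
    c(rep("category_a", 5L), rep("category_b", 3L)), terms)
  pf <- function(parent, relation = "is_a")
    data.frame(parent = parent, relation = rep(relation, length(parent)),
               stringsAsFactors = FALSE)
  none <- pf(character(0))
  parents <- list(
    "TA:0000001" = none,
    "TA:0000002" = pf("TA:0000001"),
    "TA:0000003" = pf("TA:0000001", "part_of"),
    "TA:0000004" = pf("TA:0000002"),
    "TA:0000005" = none,                     # obsolete
    "TB:0000001" = none,
    "TB:0000002" = pf("TB:0000001"),
    "TB:0000003" = pf("TB:0000001"))
  obsolete <- stats::setNames(terms == "TA:0000005", terms)
  dag <- ontology_dag(terms, category, parents, obsolete)
  direct <- list(
    "TA:0000004" = c("g1", "g2"),
    "TA:0000003" = c("g3", "g4"),
    "TB:0000002" = c("g1", "g2"),
    "TB:0000003" = c("g5", "g6"))
  ann <- propagate(annotation_map(direct, dag), dag)
  network <- cofunction_network(data.frame(
    from = c("g1", "g5", "g3", "g4", "g3", "g2"),
    to = c("g2", "g6", "g5", "g6", "g4", "g3"),
    weight = c(1, 1, 0.8, 0.8, 0.6, 0.2),
    stringsAsFactors = FALSE), nodes = sprintf("g%d", 1:7))
  pairs <- data.frame(
    t1 = c("TA:0000004", "TA:0000001", "TA:0000003"),
    t2 = c("TB:0000002", "TB:0000001", "TB:0000003"),
    note = c("identical propagated sets", "category roots",
             "network-related disjoint leaves"),
    stringsAsFactors = FALSE)
  list(dag = dag, ann = ann, network = network, pairs = pairs)
}
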