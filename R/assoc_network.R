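# Building the directed, FDR-filtered cross-category term association
# network from all pairwise scores.

#' Score every cross-category term pair
#'
#' One score per unordered pair of annotation-bearing, non-obsolete terms
#' drawn from the two categories, in lexicographic term-id order.
#'
#' @param ann a propagated [annotation_map()].
#' @param dag the [ontology_dag()].
#' @param R a [iterate_ranking()] result.
#' @param cat1,cat2 two *different* category labels.
#' @param verbose log stage counts (default `TRUE`).
#' @return a data.frame of [score_pair()] rows.
#' @export
score_all_pairs <- function(ann, dag, R, cat1, cat2, verbose = TRUE) {
  if (identical(cat1, cat2)) stop_("cat1 and cat2 must differ")
  t1s <- .scored_terms(ann, dag, cat1)
  t2s <- .scored_terms(ann, dag, cat2)
  if (!length(t1s) || !length(t2s))
    stop_("need at least one annotated term in each category")
  if (verbose)
    message(sprintf("scoring %d x %d = %d cross-category pairs (%s x %s)",
                    length(t1s), length(t2s), length(t1s) * length(t2s),
                    cat1, cat2))
  Rm <- .assoc_matrix(R)
  u1 <- length(ann$universe[[cat1]])
  u2 <- length(ann$universe[[cat2]])
  gsets1 <- ann$propagated[t1s]
  gsets2 <- ann$propagated[t2s]
  n1 <- lengths(gsets1); n2 <- lengths(gsets2)
  sg1 <- 1 - n1 / u1; sg2 <- 1 - n2 / u2

  rows <- vector("list", length(t1s) * length(t2s))
  k <- 0L
  for (a in seq_along(t1s)) {
    for (b in seq_along(t2s)) {
      k <- k + 1L
      sn <- .simnet_genes(gsets1[[a]], gsets2[[b]], Rm)
      sg <- sqrt(sg1[[a]] * sg2[[b]])
      rows[[k]] <- c(sn, sg, sn * sg)
    }
  }
  out <- data.frame(
    t1 = rep(t1s, each = length(t2s)),
    t2 = rep(t2s, times = length(t1s)),
    stringsAsFactors = FALSE)
  m <- do.call(rbind, rows)
  out$sim_net <- m[, 1L]; out$sim_go <- m[, 2L]; out$sim <- m[, 3L]
  out$n_genes_1 <- rep(unname(n1), each = length(t2s))
  out$n_genes_2 <- rep(unname(n2), times = length(t1s))
  out[order(out$t1, out$t2), , drop = FALSE]
}

# Annotation-bearing, non-obsolete terms of a category, sorted.
.scored_terms <- function(ann, dag, category) {
  ts <- category_terms(dag, category)
  sort(ts[vapply(ann$propagated[ts], length, integer(1)) > 0L])
}

#' Empirical FDR for term-pair scores
#'
#' Builds a null distribution by scoring `n_null` uniformly sampled random
#' cross-category term pairs (the same negative model the evaluation
#' protocol uses for its random set), attaches the empirical p-value
#' `(1 + #null >= score) / (1 + n_null)` to every observed score, and
#' converts p-values to Benjamini-Hochberg q-values.
#'
#' @param scores a data.frame from [score_all_pairs()] (columns `t1`, `t2`,
#'   `sim` required).
#' @param ann,dag,R the objects the scores were computed from.
#' @param n_null null-sample size, at least 100; default 10000.
#' @param seed integer seed for the null sampling.
#' @return `scores` with columns `p_value` and `q_value` appended.
#' @export
empirical_fdr <- function(scores, ann, dag, R, n_null = 10000L, seed = 1L) {
  if (n_null < 100L) stop_("'n_null' must be at least 100")
  if (!nrow(scores)) stop_("empty score list")
  cat1 <- unique(ann$term_category[scores$t1])
  cat2 <- unique(ann$term_category[scores$t2])
  if (length(cat1) != 1L || length(cat2) != 1L)
    stop_("scores must come from a single pair of categories")
  t1s <- .scored_terms(ann, dag, cat1)
  t2s <- .scored_terms(ann, dag, cat2)
  idx <- with_seed(seed, cbind(sample(length(t1s), n_null, replace = TRUE),
                               sample(length(t2s), n_null, replace = TRUE)))
  Rm <- .assoc_matrix(R)
  u1 <- length(ann$universe[[cat1]])
  u2 <- length(ann$universe[[cat2]])
  null_sim <- vapply(seq_len(n_null), function(k) {
    g1 <- ann$propagated[[t1s[idx[k, 1L]]]]
    g2 <- ann$propagated[[t2s[idx[k, 2L]]]]
    sn <- .simnet_genes(g1, g2, Rm)
    sn * sqrt((1 - length(g1) / u1) * (1 - length(g2) / u2))
  }, numeric(1))
  null_sorted <- sort(null_sim)
  n_ge <- n_null - findInterval(scores$sim, null_sorted, left.open = TRUE)
  scores$p_value <- (1 + n_ge) / (1 + n_null)
  scores$q_value <- stats::p.adjust(scores$p_value, method = "BH")
  scores
}

#' Assign edge directions and build the association network
#'
#' Every FDR-passing pair initially contributes both directed edges.  For a
#' term `t1` with cross-category neighbour set `T2`, the directed edge
#' `t1 -> t2` is deleted whenever some other neighbour `t3` in `T2` is a
#' descendant of `t2` -- edges point at the most specific related terms.
#' The rule is applied from both endpoints in one pass over the original
#' (pre-deletion) neighbour sets.
#'
#' @param edges data.frame of filtered pairs with columns `t1`, `t2`, `sim`
#'   and `q_value`.
#' @param dag the [ontology_dag()].
#' @param provenance optional named list recorded on the result (e.g.
#'   `alpha`, `fdr`, `n_null`, `seed`).
#' @return an object of class `association_network`: list with `nodes`
#'   (data.frame `term`, `category`), `edges` (data.frame `source`,
#'   `target`, `sim`, `q_value`) and `provenance`.
#' @export
assign_directions <- function(edges, dag, provenance = list()) {
  stopifnot(inherits(dag, "ontology_dag"))
  need <- c("t1", "t2", "sim", "q_value")
  miss <- setdiff(need, names(edges))
  if (length(miss)) stop_("edges lack column(s): %s", paste(miss, collapse = ", "))
  unknown <- setdiff(c(edges$t1, edges$t2), dag$terms)
  if (length(unknown)) stop_("term(s) absent from dag: %s",
                             paste(unknown, collapse = ", "))

  dir <- rbind(
    data.frame(source = edges$t1, target = edges$t2, sim = edges$sim,
               q_value = edges$q_value, stringsAsFactors = FALSE),
    data.frame(source = edges$t2, target = edges$t1, sim = edges$sim,
               q_value = edges$q_value, stringsAsFactors = FALSE))

  if (nrow(dir)) {
    desc <- lapply(stats::setNames(nm = unique(dir$target)),
                   function(t) descendants(dag, t))
    keep <- rep(TRUE, nrow(dir))
    for (s in unique(dir$source)) {
      rows <- which(dir$source == s)
      T2 <- dir$target[rows]
      for (r in rows) {
        others <- setdiff(T2, dir$target[[r]])
        if (any(others %in% desc[[dir$target[[r]]]])) keep[r] <- FALSE
      }
    }
    dir <- dir[keep, , drop = FALSE]
  }
  dir <- dir[order(dir$source, dir$target), , drop = FALSE]
  rownames(dir) <- NULL
  terms <- sort(unique(c(edges$t1, edges$t2)))
  structure(
    list(nodes = data.frame(term = terms,
                            category = unname(dag$category[terms]),
                            stringsAsFactors = FALSE),
         edges = dir, provenance = provenance),
    class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("association_network: %d terms, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), unlist(x$provenance),
                               sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Export an association network
#'
#' `tsv`: header + provenance comment lines; `sif`: Cytoscape simple
#' interaction format with interaction type `crogo2`; `graphml`: edge
#' attributes `sim` and `q_value` (written via igraph).
#'
#' @param net an [assign_directions()] result.
#' @param path output file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "association_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(net$provenance))
      writeLines(sprintf("# %s=%s", names(net$provenance),
                         vapply(net$provenance, function(v) base::format(v),
                                character(1))), con)
    writeLines("source\ttarget\tsim\tq_value", con)
    if (nrow(net$edges))
      writeLines(sprintf("%s\t%s\t%.17g\t%.17g", net$edges$source,
                         net$edges$target, net$edges$sim, net$edges$q_value),
                 con)
  } else if (format == "sif") {
    writeLines(sprintf("%s\tcrogo2\t%s", net$edges$source, net$edges$target),
               path)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(net$edges)) net$edges
      else data.frame(source = character(), target = character(),
                      sim = numeric(), q_value = numeric()),
      directed = TRUE, vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import an exported TSV association network
#'
#' @param path a file written by [export_network()] with `format = "tsv"`.
#' @return a data.frame with columns `source`, `target`, `sim`, `q_value`.
#' @export
import_network_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines) || lines[[1L]] != "source\ttarget\tsim\tq_value")
    stop_("%s is not an exported association-network TSV", path)
  if (length(lines) == 1L)
    return(data.frame(source = character(), target = character(),
                      sim = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE))
  utils::read.table(text = lines, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Run the full cross-category association pipeline
#'
#' Diffusion, all-pairs scoring, empirical FDR, filtering and direction
#' assignment in one call.
#'
#' @param dag an [ontology_dag()].
#' @param ann a (propagated or direct-only) [annotation_map()].
#' @param net a [cofunction_network()].
#' @param cat1,cat2 the two categories to relate.
#' @param alpha diffusion restart weight (default 0.1).
#' @param fdr q-value threshold (default 0.05).
#' @param sim_threshold optional similarity cutoff: when non-`NULL`, pairs
#'   with `sim >= sim_threshold` are kept *instead of* the FDR filter
#'   (q-values are still attached for reporting).  The empirical-null BH
#'   q-value is extremely conservative when all pairs of a small instance
#'   are scored -- the null is then the test population itself -- so a
#'   direct score cutoff is offered for exploratory use.
#' @param n_null null-sample size for the empirical FDR (default 10000).
#' @param seed integer seed (null sampling).
#' @param mode `"iterative"` (diffusion) or `"direct"` (raw adjacency).
#' @param theta_threshold,max_iter convergence controls for
#'   [iterate_ranking()].
#' @param verbose log stage counts.
#' @return an [assign_directions()] result whose provenance records all
#'   parameters.
#' @export
build_assoc_network <- function(dag, ann, net, cat1, cat2, alpha = 0.1,
                                fdr = 0.05, sim_threshold = NULL,
                                n_null = 10000L, seed = 1L,
                                mode = c("iterative", "direct"),
                                theta_threshold = 1e-6, max_iter = 1000L,
                                verbose = TRUE) {
  mode <- match.arg(mode)
  if (is.null(ann$propagated)) ann <- propagate(ann, dag)
  diff <- if (mode == "iterative")
    iterate_ranking(net, alpha = alpha, theta_threshold = theta_threshold,
                    max_iter = max_iter)
  else direct_association(net)
  if (verbose && mode == "iterative")
    message(sprintf("diffusion converged in %d iteration(s), theta = %.3g",
                    diff$iterations_run, diff$theta_final))
  scores <- score_all_pairs(ann, dag, diff, cat1, cat2, verbose = verbose)
  scores <- empirical_fdr(scores, ann, dag, diff, n_null = n_null, seed = seed)
  if (is.null(sim_threshold)) {
    passed <- scores[scores$q_value < fdr, , drop = FALSE]
    if (verbose)
      message(sprintf("%d of %d pairs pass FDR < %g", nrow(passed),
                      nrow(scores), fdr))
  } else {
    passed <- scores[scores$sim >= sim_threshold, , drop = FALSE]
    if (verbose)
      message(sprintf("%d of %d pairs pass sim >= %g", nrow(passed),
                      nrow(scores), sim_threshold))
  }
  assign_directions(passed, dag,
                    provenance = list(alpha = alpha, fdr = fdr,
                                      sim_threshold = sim_threshold %||% NA,
                                      n_null = n_null, seed = seed,
                                      mode = mode))
}
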