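# ROC/AUC evaluation against gold-standard term pairs and the
# edge-deletion robustness test.

#' Load a gold standard of positive and random term pairs
#'
#' Expects a TSV `term1<TAB>term2<TAB>label` with labels `positive` or
#' `random` (`#` comments ignored).  Duplicate pairs are dropped with a
#' warning; rows pairing two terms of the same category are rejected with a
#' warning when a `dag` is supplied; unequal class counts trigger a warning
#' (the ROC remains valid).
#'
#' @param path path to the TSV.
#' @param dag optional [ontology_dag()] used to enforce the cross-category
#'   constraint.
#' @return an object of class `gold_standard`: list with data.frames
#'   `positive` and `random` (columns `term1`, `term2`) and a `provenance`
#'   label.
#' @export
load_gold_standard <- function(path, dag = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop_("no rows in %s", path)
  tab <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           col.names = c("term1", "term2", "label"),
                           stringsAsFactors = FALSE)
  if (!all(tab$label %in% c("positive", "random")))
    stop_("labels must be 'positive' or 'random'")
  if (!is.null(dag)) {
    known <- tab$term1 %in% dag$terms & tab$term2 %in% dag$terms
    same <- known & dag$category[tab$term1] == dag$category[tab$term2]
    if (any(same)) {
      warn_("rejected %d same-category pair(s)", sum(same))
      tab <- tab[!same, , drop = FALSE]
    }
  }
  key <- paste(pmin(tab$term1, tab$term2), pmax(tab$term1, tab$term2),
               tab$label)
  if (anyDuplicated(key)) {
    warn_("dropped %d duplicate pair(s)", sum(duplicated(key)))
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  pos <- tab[tab$label == "positive", c("term1", "term2"), drop = FALSE]
  rnd <- tab[tab$label == "random", c("term1", "term2"), drop = FALSE]
  if (nrow(pos) != nrow(rnd))
    warn_("unequal class sizes: %d positive vs %d random", nrow(pos), nrow(rnd))
  structure(list(positive = pos, random = rnd, provenance = path),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard: %d positive / %d random pairs (%s)\n",
              nrow(x$positive), nrow(x$random), x$provenance))
  invisible(x)
}

#' Threshold-sweep ROC curve and AUC
#'
#' Ranks the pooled scores, groups tied scores into a single step, and
#' integrates the curve by the trapezoidal rule -- numerically identical to
#' the Mann-Whitney U estimator with ties counted one half.  True-positive
#' rates at target false-positive rates are read off conservatively: the
#' step value at the largest achieved FPR not exceeding the target, with no
#' interpolation.
#'
#' @param scores_pos numeric scores of the positive pairs.
#' @param scores_neg numeric scores of the negative (random) pairs.
#' @param fpr_levels FPR levels to tabulate TPR at; default
#'   `c(0.05, 0.10, 0.15)`.
#' @return an object of class `roc_result`: list with `auc`, `curve`
#'   (data.frame `fpr`, `tpr`, starting at (0,0) and ending at (1,1)) and
#'   `tpr_at_fpr` (named numeric).
#' @export
roc <- function(scores_pos, scores_neg, fpr_levels = c(0.05, 0.10, 0.15)) {
  if (!length(scores_pos) || !length(scores_neg))
    stop_("both score lists must be nonempty")
  s <- c(scores_pos, scores_neg)
  y <- c(rep(TRUE, length(scores_pos)), rep(FALSE, length(scores_neg)))
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  n <- length(s)
  last_of_group <- c(s[-n] != s[-1L], TRUE)  # last index of each tied block
  tpr <- cumsum(y)[last_of_group] / sum(y)
  fpr <- cumsum(!y)[last_of_group] / sum(!y)
  fprc <- c(0, fpr); tprc <- c(0, tpr)
  auc <- sum(diff(fprc) * (tprc[-1L] + tprc[-length(tprc)]) / 2)
  tpr_at <- vapply(fpr_levels, function(f) {
    ok <- fprc <= f
    max(tprc[ok & fprc == max(fprc[ok])])
  }, numeric(1))
  names(tpr_at) <- sprintf("fpr_%g", fpr_levels)
  structure(list(auc = auc,
                 curve = data.frame(fpr = fprc, tpr = tprc),
                 tpr_at_fpr = tpr_at),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f\n", x$auc))
  for (k in seq_along(x$tpr_at_fpr))
    cat(sprintf("  TPR at %s: %.3f\n",
                sub("fpr_", "FPR = ", names(x$tpr_at_fpr)[k]),
                x$tpr_at_fpr[[k]]))
  invisible(x)
}

#' Score the gold standard and compute its ROC
#'
#' Scores every positive and random pair with [score_pair()] machinery and
#' returns the [roc()] of positives against randoms.
#'
#' @param dag,ann,net the parsed inputs ([ontology_dag()],
#'   [annotation_map()], [cofunction_network()]).
#' @param gold a [load_gold_standard()] result.
#' @param alpha diffusion restart weight.
#' @param mode `"iterative"` or `"direct"` (raw adjacency, for benchmarking
#'   the value of indirect paths).
#' @param theta_threshold,max_iter convergence controls.
#' @return a [roc()] result.
#' @export
evaluate_gold_standard <- function(dag, ann, net, gold, alpha = 0.1,
                                   mode = c("iterative", "direct"),
                                   theta_threshold = 1e-6, max_iter = 1000L) {
  mode <- match.arg(mode)
  if (is.null(ann$propagated)) ann <- propagate(ann, dag)
  diff <- if (mode == "iterative")
    iterate_ranking(net, alpha = alpha, theta_threshold = theta_threshold,
                    max_iter = max_iter)
  else direct_association(net)
  score_set <- function(pairs) {
    vapply(seq_len(nrow(pairs)), function(k) {
      score_pair(pairs$term1[[k]], pairs$term2[[k]], ann, diff)$sim
    }, numeric(1))
  }
  roc(score_set(gold$positive), score_set(gold$random))
}

#' Edge-deletion robustness test
#'
#' For each seed, generates a synthetic benchmark, evaluates the
#' gold-standard ROC on the intact co-function network and on a copy with a
#' fraction of edges deleted uniformly at random, and reports the paired
#' AUCs.  Mirrors the evaluation design in which the seed pairs the two
#' conditions.
#'
#' @param spec a [synthetic_spec()] describing the benchmark (its own seed
#'   field is overridden per run).
#' @param fraction fraction of edges to delete, in `[0, 1)`; default 0.5.
#' @param seeds integer vector of seeds, one paired run each.
#' @param alpha,mode passed to [evaluate_gold_standard()].
#' @return a data.frame with columns `seed`, `auc_full`, `auc_deleted`,
#'   plus attributes `mean_full` and `mean_deleted`.
#' @export
robustness_test <- function(spec, fraction = 0.5, seeds = 1:5, alpha = 0.1,
                            mode = "iterative") {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop_("'fraction' must be in [0, 1)")
  rows <- lapply(seeds, function(sd) {
    spec$seed <- sd
    b <- synthetic_bundle(spec)
    full <- evaluate_gold_standard(b$dag, b$ann, b$network, b$gold,
                                   alpha = alpha, mode = mode)
    thin_net <- delete_random_edges(b$network, fraction, seed = sd)
    thin <- evaluate_gold_standard(b$dag, b$ann, thin_net, b$gold,
                                   alpha = alpha, mode = mode)
    data.frame(seed = sd, auc_full = full$auc, auc_deleted = thin$auc)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_full") <- mean(out$auc_full)
  attr(out, "mean_deleted") <- mean(out$auc_deleted)
  out
}
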