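# Cross-category term pair scoring.
#
# Sim_net compares the two terms' propagated gene sets through a soft set
# difference evaluated on the diffused association matrix; Sim_GO
# down-weights shallow (near-root) terms whose propagated sets approach the
# whole category universe; the final score is their product.

# Coerce a diffusion_result or a plain named matrix to the score matrix.
.assoc_matrix <- function(R) {
  if (inherits(R, "diffusion_result")) R <- R$R
  if (!is.matrix(R) || is.null(rownames(R)))
    stop_("'R' must be a diffusion_result or a gene-labeled matrix")
  if (min(R) < -1e-12 || max(R) > 1 + 1e-12)
    stop_("association scores outside [0, 1]; upstream invariant violated")
  R
}

# Pairwise association submatrix for gene vectors g1 x g2.  Genes absent
# from the matrix have zero association with everything except themselves.
.assoc_submatrix <- function(g1, g2, Rm) {
  i1 <- match(g1, rownames(Rm))
  i2 <- match(g2, colnames(Rm))
  M <- matrix(0, length(g1), length(g2))
  ok1 <- !is.na(i1); ok2 <- !is.na(i2)
  if (any(ok1) && any(ok2))
    M[ok1, ok2] <- Rm[i1[ok1], i2[ok2], drop = FALSE]
  # a gene missing from the network is still identical to itself
  if (any(!ok1)) {
    hit <- outer(g1, g2, `==`) & !ok1
    M[hit] <- 1
  }
  M
}

#' Soft set difference |G1 - G2| under network association
#'
#' Redefines the set difference so that a gene of `G1` is "covered" to the
#' extent that it is associated with at least one gene of `G2`:
#' `|G1 - G2| = |G1| - sum_{gi in G1} (1 - prod_{gj in G2} (1 - r_ij))`.
#' With unit self-association, identical sets give exactly 0; with all
#' cross associations zero it reduces to the crisp `|G1 \\ G2|`.
#'
#' @param G1,G2 character vectors of gene ids (`G1` nonempty).
#' @param R a [iterate_ranking()] result (or a gene-labeled matrix with
#'   entries in `[0, 1]`).
#' @return a scalar in `[0, |G1|]`.
#' @export
soft_difference <- function(G1, G2, R) {
  G1 <- unique(as.character(G1)); G2 <- unique(as.character(G2))
  if (!length(G1)) stop_("'G1' must be nonempty")
  Rm <- .assoc_matrix(R)
  M <- .assoc_submatrix(G1, G2, Rm)
  # |G1| - sum(1 - prod(1 - r)) == sum over genes of prod_j (1 - r_ij)
  sum(apply(1 - M, 1L, prod))
}

# Both soft differences from one submatrix (internal fast path).
.soft_diffs <- function(M) {
  Q <- 1 - M
  c(d12 = sum(apply(Q, 1L, prod)), d21 = sum(apply(Q, 2L, prod)))
}

.simnet_genes <- function(g1, g2, Rm) {
  u <- length(unique(c(g1, g2)))
  if (u == 0L) stop_("empty union of gene sets")
  d <- .soft_diffs(.assoc_submatrix(g1, g2, Rm))
  s <- (u - d[["d12"]] - d[["d21"]]) / u
  stopifnot(s <= 1 + 1e-9)
  if (s < -1e-9) warn_("sim_net below 0 (%.3g); upstream invariant suspect", s)
  s
}

#' Network-based similarity of two terms
#'
#' `(|G1 u G2| - |G1 - G2| - |G2 - G1|) / |G1 u G2|` with both differences
#' computed by [soft_difference()] and a crisp union count.  Equal to 1 for
#' identical propagated sets and 0 for disjoint sets with no network
#' association.
#'
#' @param t1,t2 term identifiers (any categories).
#' @param ann a propagated [annotation_map()].
#' @param R a [iterate_ranking()] result.
#' @return a scalar in `[0, 1]`.
#' @export
sim_net <- function(t1, t2, ann, R) {
  g1 <- term_genes(ann, t1); g2 <- term_genes(ann, t2)
  if (!length(g1) || !length(g2))
    stop_("both terms must have nonempty propagated gene sets")
  .simnet_genes(g1, g2, .assoc_matrix(R))
}

#' Shallow-annotation weight of a term pair
#'
#' `sqrt((1 - |G1|/|G_C1|) * (1 - |G2|/|G_C2|))`: close to 0 when either
#' term sits near its category root (annotating almost the whole category
#' universe), close to 1 for specific terms.
#'
#' @param t1,t2 term identifiers.
#' @param ann a propagated [annotation_map()].
#' @return a scalar in `[0, 1]`.
#' @export
sim_go <- function(t1, t2, ann) {
  g1 <- term_genes(ann, t1); g2 <- term_genes(ann, t2)
  if (!length(g1) || !length(g2))
    stop_("both terms must annotate at least one gene")
  u1 <- length(ann$universe[[ann$term_category[[t1]]]])
  u2 <- length(ann$universe[[ann$term_category[[t2]]]])
  sqrt((1 - length(g1) / u1) * (1 - length(g2) / u2))
}

#' Score a cross-category term pair
#'
#' Combines the network similarity and the shallow-annotation weight into
#' `Sim = Sim_net * Sim_GO`.  Symmetric in its two terms; edge directions
#' are assigned later, at the association-network stage.
#'
#' @param t1,t2 term identifiers from *different* categories.
#' @param ann a propagated [annotation_map()].
#' @param R a [iterate_ranking()] result.
#' @return a one-row data.frame with columns `t1`, `t2`, `sim_net`,
#'   `sim_go`, `sim`, `n_genes_1`, `n_genes_2`.
#' @export
score_pair <- function(t1, t2, ann, R) {
  c1 <- ann$term_category[[t1]]; c2 <- ann$term_category[[t2]]
  if (is.null(c1) || is.null(c2)) stop_("unknown term")
  if (identical(c1, c2))
    stop_("cross-category only: %s and %s are both in %s", t1, t2, c1)
  sn <- sim_net(t1, t2, ann, R)
  sg <- sim_go(t1, t2, ann)
  data.frame(t1 = t1, t2 = t2, sim_net = sn, sim_go = sg, sim = sn * sg,
             n_genes_1 = length(term_genes(ann, t1)),
             n_genes_2 = length(term_genes(ann, t2)),
             stringsAsFactors = FALSE)
}
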