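# Shared fixtures and independent oracles.

# --- tiny ontologies -------------------------------------------------------

# root <- a <- b chain in one category
chain_dag <- function() {
  pf <- function(p) data.frame(parent = p, relation = rep("is_a", length(p)),
                               stringsAsFactors = FALSE)
  ontology_dag(
    c("root", "a", "b"),
    stats::setNames(rep("cat1", 3), c("root", "a", "b")),
    list(root = pf(character(0)), a = pf("root"), b = pf("a")))
}

# diamond: top <- {l, r} <- bottom (two paths bottom -> top)
diamond_dag <- function() {
  pf <- function(p) data.frame(parent = p, relation = rep("is_a", length(p)),
                               stringsAsFactors = FALSE)
  ontology_dag(
    c("top", "l", "r", "bottom"),
    stats::setNames(rep("cat1", 4), c("top", "l", "r", "bottom")),
    list(top = pf(character(0)), l = pf("top"), r = pf("top"),
         bottom = pf(c("l", "r"))))
}

# random single-category DAG: term i (i >= 2) gets 1-2 parents among 1..i-1
random_dag <- function(n, seed) {
  withr::local_seed(seed)
  ids <- sprintf("T%03d", seq_len(n))
  parents <- lapply(seq_len(n), function(i) {
    if (i == 1L) return(data.frame(parent = character(),
                                   relation = character(),
                                   stringsAsFactors = FALSE))
    k <- sample(1:2, 1)
    p <- ids[sample.int(i - 1L, min(k, i - 1L))]
    data.frame(parent = p, relation = rep("is_a", length(p)),
               stringsAsFactors = FALSE)
  })
  names(parents) <- ids
  ontology_dag(ids, stats::setNames(rep("cat1", n), ids), parents)
}

# brute-force reachability: descendants of t by exhaustive path search
brute_descendants <- function(dag, t) {
  out <- character(0)
  for (x in dag$terms) {
    if (x == t) next
    # walk all ancestor chains of x and see whether t appears
    anc <- x
    frontier <- x
    while (length(frontier)) {
      ps <- unique(unlist(lapply(frontier, function(f) dag$parents[[f]]$parent)))
      ps <- setdiff(ps, anc)
      anc <- c(anc, ps)
      frontier <- ps
    }
    if (t %in% anc) out <- c(out, x)
  }
  out
}

# brute-force propagation: per-term DFS union of direct sets of descendants
brute_propagated <- function(dag, direct, t) {
  members <- c(t, brute_descendants(dag, t))
  sort(unique(as.character(unlist(direct[members], use.names = FALSE))))
}

# --- networks --------------------------------------------------------------

random_network <- function(n, p = 0.15, seed = 1) {
  withr::local_seed(seed)
  nodes <- sprintf("n%03d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)))
  pick <- idx[runif(length(idx)) < p]
  if (!length(pick)) pick <- idx[1L]  # keep at least one edge
  from <- ((pick - 1L) %% n) + 1L
  to <- ((pick - 1L) %/% n) + 1L
  cofunction_network(
    data.frame(from = nodes[from], to = nodes[to],
               weight = runif(length(pick), 0.1, 2)),
    nodes = nodes)
}

# closed-form diffusion oracle: solve (I - (1-alpha) U) R = alpha O, then
# the same post-processing as iterate_ranking (symmetrize, unit diagonal).
solve_diffusion <- function(net, alpha) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges$from[k]; j <- net$edges$to[k]; w <- net$edges$weight[k]
    A[i, j] <- w; A[j, i] <- w
  }
  deg <- rowSums(A)
  U <- A * ifelse(deg > 0, 1 / deg, 0)
  O <- if (max(A) > 0) A / max(A) else A
  R <- alpha * solve(diag(n) - (1 - alpha) * U) %*% O
  R <- (R + t(R)) / 2
  R[R < 0] <- 0; R[R > 1] <- 1
  diag(R) <- 1
  R
}

# brute-force Mann-Whitney AUC (ties counted one half)
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# literal evaluation of the soft set difference from an association matrix:
# |G1| - sum over gi of (1 - prod over gj of (1 - r_ij))
brute_soft_difference <- function(G1, G2, R) {
  covered <- 0
  for (gi in G1) {
    prod <- 1
    for (gj in G2) {
      r <- if (gi == gj) 1
      else if (gi %in% rownames(R) && gj %in% colnames(R)) R[gi, gj]
      else 0
      prod <- prod * (1 - r)
    }
    covered <- covered + (1 - prod)
  }
  length(G1) - covered
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
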