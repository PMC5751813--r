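# Iterative-ranking diffusion over the co-function network.
#
# The association matrix R is the fixed point of
#     R^{t+1} = alpha * O + (1 - alpha) * U %*% R^t,
# where U is the row-normalized adjacency (each row a weighted average of
# neighbours) and O the raw adjacency rescaled by its maximum weight so all
# entries lie in [0, 1].  With U row-(sub)stochastic and O in [0, 1], every
# iterate stays in [0, 1], so the converged scores are probabilities of
# association reachable through direct and indirect paths.  After
# convergence R is symmetrized (association is undirected) and the diagonal
# is set to 1 (a gene is maximally associated with itself; this convention
# is what makes the soft set difference of identical sets exactly zero).

# Raw adjacency matrices.  Returns list(U, O); sparse Matrix classes above
# `dense_limit` nodes, base matrices otherwise.  Both paths produce
# identical numbers up to BLAS rounding.
.adjacency_matrices <- function(net, dense_limit = 6000L) {
  n <- length(net$nodes)
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  w <- net$edges$weight
  sparse <- n > dense_limit
  if (sparse) {
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                              dims = c(n, n),
                              dimnames = list(net$nodes, net$nodes))
  } else {
    A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  deg <- if (sparse) Matrix::rowSums(A) else rowSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)           # isolated nodes: all-zero row
  U <- if (sparse) Matrix::Diagonal(x = inv) %*% A else A * inv
  maxw <- if (length(w)) max(w) else 0
  O <- if (maxw > 0) A / maxw else A
  list(U = U, O = O)
}

#' Row-normalized adjacency matrix
#'
#' Each entry is the edge weight divided by the total weight incident to the
#' row gene: `u_ij = e_ij / sum_k e_ik`.  Rows of isolated nodes are all
#' zero; every other row sums to 1.
#'
#' @param net a [cofunction_network()].
#' @return an `n x n` matrix (dense for small networks, sparse `Matrix`
#'   above 6000 nodes) with gene ids as dimnames.
#' @export
normalize_adjacency <- function(net) {
  stopifnot(inherits(net, "cofunction_network"))
  if (!length(net$nodes)) stop_("empty network")
  .adjacency_matrices(net)$U
}

#' Iterative-ranking gene association scores
#'
#' Iterates `R^{t+1} = alpha * O + (1 - alpha) * U R^t` from `R^0 = O`
#' until the L1-type gap `theta = max_j sum_i |(R^{t+1} - R^t)_{ij}|`
#' (maximum absolute column sum) falls below `theta_threshold`, then
#' symmetrizes the result by averaging with its transpose and sets the
#' diagonal to 1.  `alpha` weighs the original direct relations against
#' diffusion through neighbours; small `alpha` emphasises indirect
#' (multi-hop) associations.
#'
#' @param net a [cofunction_network()].
#' @param alpha restart weight in `(0, 1)`; default 0.1.
#' @param theta_threshold convergence threshold on the gap; default `1e-6`.
#' @param max_iter iteration cap; if reached a warning is raised and
#'   `converged` is `FALSE`.
#' @param dense_limit node count above which sparse matrices are used for
#'   `U` and `O`.
#' @param trace logical; keep the per-iteration theta values (attribute
#'   `theta_trace`).
#' @return an object of class `diffusion_result`: list with `R` (dense
#'   symmetric matrix, unit diagonal, entries in `[0, 1]`, gene dimnames),
#'   `alpha`, `iterations_run`, `theta_final`, `converged`.
#' @export
iterate_ranking <- function(net, alpha = 0.1, theta_threshold = 1e-6,
                            max_iter = 1000L, dense_limit = 6000L,
                            trace = FALSE) {
  stopifnot(inherits(net, "cofunction_network"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_("'alpha' must lie strictly between 0 and 1")
  if (theta_threshold <= 0) stop_("'theta_threshold' must be > 0")
  mats <- .adjacency_matrices(net, dense_limit)
  U <- mats$U
  O <- mats$O
  R <- O
  theta <- Inf
  it <- 0L
  thetas <- numeric(0)
  while (it < max_iter) {
    Rn <- alpha * O + (1 - alpha) * (U %*% R)
    theta <- max(Matrix::colSums(abs(Rn - R)))
    it <- it + 1L
    if (trace) thetas <- c(thetas, theta)
    R <- Rn
    if (theta < theta_threshold) break
  }
  converged <- theta < theta_threshold
  if (!converged)
    warn_("iterative ranking did not converge in %d iterations (theta = %g)",
          max_iter, theta)
  R <- as.matrix(R)
  R <- (R + t(R)) / 2
  # clamping must be a numerical no-op: scores are bounded by construction
  stopifnot(min(R) > -1e-9, max(R) < 1 + 1e-9)
  R[R < 0] <- 0
  R[R > 1] <- 1
  diag(R) <- 1
  dimnames(R) <- list(net$nodes, net$nodes)
  res <- structure(
    list(R = R, alpha = alpha, iterations_run = it, theta_final = theta,
         converged = converged),
    class = "diffusion_result")
  if (trace) attr(res, "theta_trace") <- thetas
  res
}

#' Raw-adjacency association scores (direct links only)
#'
#' Degenerate mode that skips the diffusion entirely: the association matrix
#' is the raw adjacency rescaled by its maximum weight, symmetrized, with
#' unit diagonal.  Only directly connected genes receive a nonzero score.
#' Exposed for benchmarking the contribution of indirect paths.
#'
#' @param net a [cofunction_network()].
#' @return a `diffusion_result` with `iterations_run = 0`.
#' @export
direct_association <- function(net) {
  stopifnot(inherits(net, "cofunction_network"))
  O <- as.matrix(.adjacency_matrices(net)$O)
  O <- (O + t(O)) / 2
  diag(O) <- 1
  dimnames(O) <- list(net$nodes, net$nodes)
  structure(
    list(R = O, alpha = NA_real_, iterations_run = 0L, theta_final = 0,
         converged = TRUE),
    class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf(
    "diffusion_result: %d genes, alpha = %s, %d iteration(s), theta = %.3g%s\n",
    nrow(x$R), format(x$alpha), x$iterations_run, x$theta_final,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Write / read a diffusion result as labeled TSV
#'
#' Caching helpers: the matrix is stored as a gene-labeled TSV (optionally
#' gzipped when the path ends in `.gz`) with provenance header comments.
#'
#' @param diff a [iterate_ranking()] result.
#' @param path output path.
#' @return `path`, invisibly (write); a `diffusion_result` (read).
#' @export
write_diffusion_tsv <- function(diff, path) {
  stopifnot(inherits(diff, "diffusion_result"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# alpha=%s iterations=%d theta=%.17g converged=%s",
                     format(diff$alpha), diff$iterations_run,
                     diff$theta_final, diff$converged), con)
  writeLines(paste(c("gene", colnames(diff$R)), collapse = "\t"), con)
  utils::write.table(format(diff$R, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_diffusion_tsv
#' @export
read_diffusion_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  hdr <- readLines(con, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z]+=[^ ]+", hdr))[[1L]]
  kv <- do.call(rbind, strsplit(meta, "=", fixed = TRUE))
  vals <- stats::setNames(kv[, 2L], kv[, 1L])
  tab <- utils::read.table(con, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  R <- as.matrix(tab)
  structure(
    list(R = R, alpha = as.numeric(vals[["alpha"]]),
         iterations_run = as.integer(vals[["iterations"]]),
         theta_final = as.numeric(vals[["theta"]]),
         converged = as.logical(vals[["converged"]])),
    class = "diffusion_result")
}
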