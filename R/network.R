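# Weighted undirected gene co-function network.

#' Construct a co-function network
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (undirected,
#'   one row per unordered pair).  Self-loops and duplicate pairs are
#'   rejected here; [load_network()] cleans raw files first.
#' @param nodes optional character vector of node ids; defaults to the
#'   sorted union of the edge endpoints.  Extra (isolated) nodes may be
#'   listed.
#' @return an object of class `cofunction_network` with elements `nodes`
#'   and `edges`.
#' @export
cofunction_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stop_("edge weights must be finite and >= 0")
  if (any(edges$from == edges$to)) stop_("self-loops are not allowed")
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to, sep = "\r"),
                paste(edges$to, edges$from, sep = "\r"))
  if (anyDuplicated(key)) stop_("duplicate edges for the same unordered pair")
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges[order(key), , drop = FALSE]),
            class = "cofunction_network")
}

#' @export
print.cofunction_network <- function(x, ...) {
  cat(sprintf("cofunction_network: %d genes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Load a co-function network from a TSV edge list
#'
#' Expects `geneA<TAB>geneB<TAB>weight` (weight defaults to 1 when only two
#' columns are present); lines starting with `#` are ignored.  Duplicate
#' unordered pairs are merged keeping the maximum weight and self-loops are
#' dropped, both with a warning.
#'
#' @param path path to the edge-list file.
#' @return a [cofunction_network()].
#' @export
load_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop_("no edges found in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 2L))
    stop_("line %d of %s: expected at least 2 tab-separated columns",
          lineno[which(nf < 2L)[1L]], path)
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), 2L)
  w <- rep(1, length(fields))
  has_w <- nf >= 3L
  if (any(has_w)) {
    wraw <- vapply(fields[has_w], `[[`, character(1), 3L)
    wnum <- suppressWarnings(as.numeric(wraw))
    if (anyNA(wnum))
      stop_("line %d of %s: non-numeric weight '%s'",
            lineno[has_w][which(is.na(wnum))[1L]], path,
            wraw[which(is.na(wnum))[1L]])
    w[has_w] <- wnum
  }
  self <- from == to
  if (any(self)) {
    warn_("dropped %d self-loop(s)", sum(self))
    from <- from[!self]; to <- to[!self]; w <- w[!self]
  }
  if (!length(from)) stop_("no usable edges in %s", path)
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    warn_("merged %d duplicate edge(s) keeping the maximum weight",
          sum(duplicated(key)))
    w <- as.numeric(tapply(w, key, max)[unique(key)])
    a <- a[!duplicated(key)]; b <- b[!duplicated(key)]
  }
  cofunction_network(data.frame(from = a, to = b, weight = w,
                                stringsAsFactors = FALSE))
}

#' Randomly delete a fraction of edges
#'
#' Removes `floor(fraction * |E|)` uniformly chosen edges; used by the
#' robustness test.  Deterministic given `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param net a [cofunction_network()].
#' @param fraction fraction of edges to delete, in `[0, 1)`.
#' @param seed integer seed.
#' @return a [cofunction_network()] with the surviving edges (the node set,
#'   including now-isolated nodes, is preserved).
#' @export
delete_random_edges <- function(net, fraction, seed) {
  stopifnot(inherits(net, "cofunction_network"))
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop_("'fraction' must be in [0, 1)")
  m <- nrow(net$edges)
  k <- floor(fraction * m)
  if (k == 0L) return(net)
  drop <- with_seed(seed, sample.int(m, k))
  cofunction_network(net$edges[-drop, , drop = FALSE], nodes = net$nodes)
}
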