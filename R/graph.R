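#' Sparsify a dense similarity matrix into a walkable weighted graph
#'
#' The unified similarity matrices are dense; truncated random walks on a
#' complete weighted graph mix almost uniformly, so each node keeps only its
#' `k` highest-similarity neighbours (ties broken by label order) and the
#' kept edge sets are union-symmetrised: an edge retained by either endpoint
#' is retained for both. Self-similarities (the diagonal) and zero-weight
#' pairs are dropped; `k >= |V|` keeps every positive off-diagonal edge.
#'
#' @param US a [similarity_matrix()] (any role; typically `"unified"`).
#' @param k number of neighbours retained per node (>= 1).
#' @return a `walk_graph`: list with `nodes` (labels) and `adjacency`
#'   (per-node list of `nbr` integer indices and positive `weight`s).
#' @export
sparsify <- function(US, k) {
  stopifnot(inherits(US, "similarity_matrix"), k >= 1L)
  W <- unclass(US)
  if (anyNA(W)) stop("similarity matrix with undefined entries cannot be sparsified; fuse it first")
  n <- nrow(W)
  labels <- rownames(W)
  diag(W) <- 0
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    wi <- W[i, ]
    pos <- which(wi > 0)
    if (length(pos) == 0L) next
    ord <- pos[order(-wi[pos], labels[pos])]
    keep[i, ord[seq_len(min(k, length(ord)))]] <- TRUE
  }
  keep <- keep | t(keep)
  adjacency <- lapply(seq_len(n), function(i) {
    nbr <- which(keep[i, ])
    list(nbr = nbr, weight = W[i, nbr])
  })
  structure(list(nodes = labels, adjacency = adjacency), class = "walk_graph")
}

#' @export
print.walk_graph <- function(x, ...) {
  n_edges <- sum(vapply(x$adjacency, function(a) length(a$nbr), 1L)) / 2
  cat(sprintf("walk_graph: %d nodes, %d undirected edges\n",
              length(x$nodes), n_edges))
  invisible(x)
}

#' Generate truncated random walks over a weighted graph
#'
#' Starts `gamma` walks at every node; each walk takes `t - 1` steps, at
#' each step sampling the next node among the current node's neighbours with
#' probability proportional to edge weight (or uniformly when
#' `uniform = TRUE`, the classic unweighted scheme). Walks started at
#' isolated nodes are the singleton sequence of that node.
#'
#' @param graph a `walk_graph` from [sparsify()].
#' @param gamma walks per node (>= 1).
#' @param t walk length (>= 2).
#' @param seed integer seed for the walk substream.
#' @param uniform ignore edge weights when sampling transitions.
#' @return a `walk_corpus`: list with `walks` (list of integer node-index
#'   vectors), `nodes` (labels), `gamma`, `t`.
#' @export
generate_walks <- function(graph, gamma, t, seed, uniform = FALSE) {
  stopifnot(inherits(graph, "walk_graph"))
  n <- length(graph$nodes)
  if (n == 0L) stop("empty graph")
  if (gamma < 1L) stop("gamma must be >= 1")
  if (t < 2L) stop("t must be >= 2")
  degs <- vapply(graph$adjacency, function(a) length(a$nbr), 1L)
  n_walks <- n * gamma
  # all walks advance in lock step: one vectorised sampling pass per step,
  # grouped by current node
  steps <- matrix(NA_integer_, n_walks, t)
  steps[, 1L] <- rep(seq_len(n), each = gamma)
  with_seed(seed, {
    active <- which(degs[steps[, 1L]] > 0L)
    for (j in seq.int(2L, t)) {
      if (length(active) == 0L) break
      cur <- steps[active, j - 1L]
      for (u in unique(cur)) {
        adj <- graph$adjacency[[u]]
        at_u <- active[cur == u]
        pick <- if (length(adj$nbr) == 1L) {
          rep.int(adj$nbr, length(at_u))
        } else if (uniform) {
          adj$nbr[sample.int(length(adj$nbr), length(at_u), replace = TRUE)]
        } else {
          adj$nbr[sample.int(length(adj$nbr), length(at_u), replace = TRUE,
                             prob = adj$weight)]
        }
        steps[at_u, j] <- pick
      }
    }
  })
  walks <- lapply(seq_len(n_walks), function(i) {
    row <- steps[i, ]
    row[!is.na(row)]
  })
  structure(list(walks = walks, nodes = graph$nodes,
                 gamma = as.integer(gamma), t = as.integer(t)),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("walk_corpus: %d walks over %d nodes (gamma=%d, t=%d)\n",
              length(x$walks), length(x$nodes), x$gamma, x$t))
  invisible(x)
}
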