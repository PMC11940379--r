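#' Gaussian interaction profile kernel bandwidth
#'
#' The kernel bandwidth is the scale r' normalised by the mean squared norm
#' of the interaction profiles:
#' \deqn{r_l = r' / \left( \frac{1}{n} \sum_i \lVert IP(i) \rVert^2 \right).}
#' For binary profiles the squared norm of a profile is its number of known
#' associations, so the bandwidth adapts to the overall density of the
#' association matrix.
#'
#' @param profiles numeric matrix, one interaction profile per row.
#' @param r_prime positive bandwidth scale (default 1).
#' @return a `gip_bandwidth` (list with `value`, `scale`).
#' @export
gip_bandwidth <- function(profiles, r_prime = 1) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1L, r_prime > 0)
  mean_sq <- mean(rowSums(profiles^2))
  if (mean_sq == 0) stop("bandwidth undefined on empty association matrix")
  structure(list(value = r_prime / mean_sq, scale = r_prime),
            class = "gip_bandwidth")
}

#' GIP kernel similarity from an association matrix
#'
#' \deqn{GS(i, j) = \exp(-r_l \lVert IP(i) - IP(j) \rVert^2)}
#' over the rows (miRNA axis) or columns (disease axis) of the binary
#' association matrix, with the bandwidth of [gip_bandwidth()]. Identical
#' profiles -- including two all-zero profiles -- get similarity 1; the
#' similarity of an all-zero profile to a profile with k associations is
#' `exp(-r_l * k)`.
#'
#' @param A an [association_matrix()].
#' @param axis `"mirna"` (rows) or `"disease"` (columns).
#' @param r_prime positive bandwidth scale (default 1).
#' @return a [similarity_matrix()] with role `"gip"`.
#' @export
gip_similarity <- function(A, axis = c("mirna", "disease"), r_prime = 1) {
  axis <- match.arg(axis)
  P <- if (axis == "mirna") unclass(A) else t(unclass(A))
  storage.mode(P) <- "double"
  rl <- gip_bandwidth(P, r_prime)$value
  sq <- rowSums(P^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0  # guard against round-off
  G <- exp(-rl * d2)
  diag(G) <- 1
  G <- (G + t(G)) / 2
  similarity_matrix(G, rownames(P), role = "gip")
}
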