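#' Semantic context: cached DAG contributions and disease values
#'
#' Precomputes, for every disease term P in the hierarchy, the semantic
#' contribution PP of each of its ancestors and the resulting disease DAG
#' value DV(P). The contribution of P to itself is exactly 1 and decays by
#' the factor `delta` per edge walked up the hierarchy, taking the maximum
#' over descent paths when a node has several children on the way down to P:
#'
#' \deqn{PP_P(c) = 1 \textrm{ if } c = P, \quad
#'       PP_P(c) = \Delta \max\{PP_P(c') : c' \in children(c) \cap (A(P))\}
#'       \textrm{ otherwise}}
#' \deqn{DV(P) = \sum_{c \in A(P)} PP_P(c) \ge 1}
#'
#' @param dag a [disease_dag()].
#' @param delta semantic contribution factor in (0, 1).
#' @return a `semantic_context` with per-node ancestor sets, PP caches and
#'   DV values.
#' @export
semantic_context <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!(delta > 0 && delta < 1)) stop("delta must lie in (0, 1)")
  pp <- lapply(dag$nodes, function(P) node_contributions(dag, P, delta))
  names(pp) <- dag$nodes
  dv <- vapply(pp, sum, numeric(1))
  structure(list(dag = dag, delta = delta, pp_cache = pp, dv_cache = dv),
            class = "semantic_context")
}

# PP_P(c) for all c in A(P), by memoised recursion down towards P.
node_contributions <- function(dag, P, delta) {
  anc <- dag_ancestors(dag, P)
  memo <- new.env(parent = emptyenv())
  assign(P, 1, envir = memo)
  rec <- function(c) {
    if (exists(c, envir = memo, inherits = FALSE)) {
      return(get(c, envir = memo, inherits = FALSE))
    }
    kids <- intersect(dag_children(dag, c), anc)
    val <- delta * max(vapply(kids, rec, numeric(1)))
    assign(c, val, envir = memo)
    val
  }
  out <- vapply(anc, rec, numeric(1))
  names(out) <- anc
  out
}

#' Semantic contribution of an ancestor to a disease term
#'
#' @param ctx a [semantic_context()].
#' @param P disease term.
#' @param c an ancestor of `P` (possibly `P` itself).
#' @return contribution in (0, 1]; exactly 1 when `c == P`.
#' @export
semantic_contribution <- function(ctx, P, c) {
  stopifnot(inherits(ctx, "semantic_context"))
  pp <- ctx$pp_cache[[P]]
  if (is.null(pp)) stop("unknown DAG node: ", P)
  if (!c %in% names(pp)) stop(c, " is not an ancestor of ", P)
  unname(pp[c])
}

#' Disease DAG value DV(P)
#'
#' Sum of semantic contributions over the ancestor set of `P` (including
#' `P` itself), hence always >= 1.
#'
#' @inheritParams semantic_contribution
#' @return a real number >= 1.
#' @export
dag_value <- function(ctx, P) {
  stopifnot(inherits(ctx, "semantic_context"))
  dv <- ctx$dv_cache[P]
  if (is.na(dv)) stop("unknown DAG node: ", P)
  unname(dv)
}

#' Semantic similarity between two disease terms
#'
#' Shared-ancestor similarity: the contributions each disease assigns to the
#' common ancestors, normalised by the two DAG values,
#' \deqn{SS(d_i, d_j) = \frac{\sum_{t \in A(i) \cap A(j)} (P_i(t) + P_j(t))}
#'                           {DV(i) + DV(j)}.}
#' Equal to 1 for identical terms and 0 for terms in disjoint components.
#'
#' @param ctx a [semantic_context()].
#' @param di,dj disease terms present in the DAG.
#' @return similarity in `[0, 1]`.
#' @export
semantic_similarity <- function(ctx, di, dj) {
  stopifnot(inherits(ctx, "semantic_context"))
  pi <- ctx$pp_cache[[di]]
  pj <- ctx$pp_cache[[dj]]
  if (is.null(pi)) stop("unknown DAG node: ", di)
  if (is.null(pj)) stop("unknown DAG node: ", dj)
  shared <- intersect(names(pi), names(pj))
  if (length(shared) == 0L) return(0)
  sum(pi[shared] + pj[shared]) / (ctx$dv_cache[[di]] + ctx$dv_cache[[dj]])
}

#' Disease semantic similarity matrix over a label set
#'
#' Entries are `NA` for pairs where semantic similarity is undefined: one of
#' the diseases is absent from the DAG, or the two terms share no ancestor.
#' `NA` entries fall through to the GIP branch of the fusion rule, see
#' [unified_disease_similarity()].
#'
#' @param ctx a [semantic_context()].
#' @param diseases character vector of disease labels (need not all be DAG
#'   members).
#' @return a [similarity_matrix()] with role `"semantic"`.
#' @export
semantic_similarity_matrix <- function(ctx, diseases) {
  stopifnot(inherits(ctx, "semantic_context"))
  n <- length(diseases)
  S <- matrix(NA_real_, n, n, dimnames = list(diseases, diseases))
  present <- which(diseases %in% ctx$dag$nodes)
  for (a in present) {
    S[a, a] <- 1
    for (b in present[present > a]) {
      s <- semantic_similarity(ctx, diseases[a], diseases[b])
      if (s > 0) {
        S[a, b] <- s
        S[b, a] <- s
      }
    }
  }
  similarity_matrix(S, diseases, role = "semantic")
}
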