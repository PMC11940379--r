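#' Fuse a curated similarity with the GIP kernel
#'
#' The unified similarity takes the curated score where one is defined and
#' falls back to the GIP kernel otherwise:
#' \deqn{US(i, j) = \begin{cases} C(i, j) & \textrm{if } (i, j)
#'       \textrm{ has a curated score} \\ GS(i, j) & \textrm{otherwise}
#'       \end{cases}}
#' where C is the miRNA functional similarity or the disease semantic
#' similarity. Undefined curated pairs are the `NA` entries of `curated`.
#'
#' @param curated a [similarity_matrix()] with role `"functional"` or
#'   `"semantic"` (entries `NA` where no score exists), or `NULL` when no
#'   curated similarity is available at all.
#' @param gip a [similarity_matrix()] with role `"gip"` on the same labels.
#' @return a [similarity_matrix()] with role `"unified"` and no `NA`s.
#' @keywords internal
fuse_similarity <- function(curated, gip) {
  stopifnot(inherits(gip, "similarity_matrix"))
  if (is.null(curated)) {
    return(similarity_matrix(unclass(gip), rownames(gip), role = "unified"))
  }
  stopifnot(inherits(curated, "similarity_matrix"))
  if (!identical(rownames(curated), rownames(gip))) {
    stop("label mismatch between curated similarity and GIP similarity")
  }
  U <- unclass(curated)
  miss <- is.na(U)
  U[miss] <- unclass(gip)[miss]
  similarity_matrix(U, rownames(gip), role = "unified")
}

#' Expand a similarity matrix to a larger label set
#'
#' Curated similarity files often cover only a subset of the entities in the
#' association matrix. This pads the matrix with `NA` (undefined) entries for
#' the missing labels, so that the fusion rule routes those pairs to the GIP
#' branch. A pair "has" a curated score exactly when both labels appear in
#' the curated file and the cell is non-`NA`.
#'
#' @param S a [similarity_matrix()].
#' @param labels superset of `rownames(S)`, in the desired order.
#' @return a [similarity_matrix()] over `labels` with the same role.
#' @export
expand_similarity <- function(S, labels) {
  stopifnot(inherits(S, "similarity_matrix"))
  missing_from <- setdiff(rownames(S), labels)
  if (length(missing_from) > 0L) {
    stop("labels absent from target set: ", paste(head(missing_from, 3L), collapse = ", "))
  }
  out <- matrix(NA_real_, length(labels), length(labels),
                dimnames = list(labels, labels))
  out[rownames(S), colnames(S)] <- unclass(S)
  similarity_matrix(out, labels, role = similarity_role(S))
}

#' Unified miRNA similarity network
#'
#' Functional similarity where the curated file defines a score for the
#' pair, GIP kernel similarity otherwise. The result is the edge-weight
#' matrix of the miRNA network handed to the embedding stage.
#'
#' @param FS a [similarity_matrix()] with role `"functional"` (entries `NA`
#'   where no curated score exists), or `NULL` if no functional similarity
#'   was supplied.
#' @param GS a [similarity_matrix()] with role `"gip"` on the same miRNA
#'   labels.
#' @return a [similarity_matrix()] with role `"unified"`.
#' @export
unified_mirna_similarity <- function(FS, GS) fuse_similarity(FS, GS)

#' Unified disease similarity network
#'
#' Semantic similarity where both diseases are DAG members with a shared
#' ancestor, GIP kernel similarity otherwise (in particular for every pair
#' involving a disease absent from the hierarchy, and for all pairs when no
#' hierarchy was supplied).
#'
#' @param SS a [similarity_matrix()] with role `"semantic"` (entries `NA`
#'   where undefined), or `NULL` if no disease hierarchy was supplied.
#' @param GS a [similarity_matrix()] with role `"gip"` on the same disease
#'   labels.
#' @return a [similarity_matrix()] with role `"unified"`.
#' @export
unified_disease_similarity <- function(SS, GS) fuse_similarity(SS, GS)
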