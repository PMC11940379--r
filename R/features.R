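#' Labelled miRNA-disease pair dataset
#'
#' @param pairs data frame with columns `mirna`, `disease` and optionally a
#'   binary `label` (1 = known association, 0 = presumed negative).
#' @param features numeric matrix, one row per pair.
#' @return a `pair_dataset` (list with `pairs`, `features`).
#' @export
pair_dataset <- function(pairs, features) {
  stopifnot(is.data.frame(pairs), is.matrix(features),
            nrow(pairs) == nrow(features))
  if (!is.null(pairs$label) && !all(pairs$label %in% c(0L, 1L))) {
    stop("pair labels must be binary")
  }
  if (nrow(pairs) > 0L &&
      anyDuplicated(paste(pairs$mirna, pairs$disease, sep = "\r"))) {
    stop("duplicated (miRNA, disease) pair in dataset")
  }
  structure(list(pairs = pairs, features = features), class = "pair_dataset")
}

#' Concatenated-embedding features for miRNA-disease pairs
#'
#' Each pair's feature row is the miRNA's embedding vector followed by the
#' disease's embedding vector, width `2 * d` (256 at the default d = 128).
#'
#' @param memb miRNA `embedding_matrix`.
#' @param demb disease `embedding_matrix`.
#' @param pairs data frame with `mirna`, `disease` and optional `label`.
#' @return a [pair_dataset()] whose feature width is `ncol(memb) + ncol(demb)`.
#' @export
build_pair_features <- function(memb, demb, pairs) {
  check_pair_labels(pairs, rownames(memb), rownames(demb))
  feats <- cbind(
    unclass(memb)[pairs$mirna, , drop = FALSE],
    unclass(demb)[pairs$disease, , drop = FALSE]
  )
  if (nrow(pairs) == 0L) feats <- matrix(0, 0L, ncol(memb) + ncol(demb))
  rownames(feats) <- NULL
  pair_dataset(pairs, feats)
}

#' Raw-similarity features (embedding-free ablation arm)
#'
#' Instead of learned embeddings, each pair is represented by the miRNA's
#' row of the unified miRNA similarity matrix concatenated with the
#' disease's row of the unified disease similarity matrix (width
#' `nm + nd`). This is the "without embedding" arm of the ablation
#' comparison.
#'
#' @param USm unified miRNA [similarity_matrix()].
#' @param USd unified disease [similarity_matrix()].
#' @param pairs data frame with `mirna`, `disease` and optional `label`.
#' @return a [pair_dataset()] of width `nrow(USm) + nrow(USd)`.
#' @export
ablation_features <- function(USm, USd, pairs) {
  check_pair_labels(pairs, rownames(USm), rownames(USd))
  feats <- cbind(
    unclass(USm)[pairs$mirna, , drop = FALSE],
    unclass(USd)[pairs$disease, , drop = FALSE]
  )
  if (nrow(pairs) == 0L) feats <- matrix(0, 0L, nrow(USm) + nrow(USd))
  rownames(feats) <- NULL
  pair_dataset(pairs, feats)
}

check_pair_labels <- function(pairs, mirnas, diseases) {
  stopifnot(is.data.frame(pairs), all(c("mirna", "disease") %in% names(pairs)))
  bad_m <- setdiff(pairs$mirna, mirnas)
  if (length(bad_m) > 0L) stop("unknown miRNA label: ", bad_m[1L])
  bad_d <- setdiff(pairs$disease, diseases)
  if (length(bad_d) > 0L) stop("unknown disease label: ", bad_d[1L])
  invisible(TRUE)
}

#' Sample presumed-negative pairs from the unknown cells
#'
#' Uniform sample without replacement from the `A == 0` cells, disjoint from
#' an optional exclusion set (e.g. associations held out by cross-
#' validation). Unknown pairs are treated as presumed negatives; some may be
#' undiscovered positives, a label noise inherent to the task.
#'
#' @param A an [association_matrix()].
#' @param n_neg number of negatives to draw.
#' @param exclude optional data frame of `mirna`, `disease` pairs that must
#'   not be sampled.
#' @param seed integer seed for the sampling substream.
#' @return data frame with columns `mirna`, `disease` and `label = 0`.
#' @export
sample_negatives <- function(A, n_neg, exclude = NULL, seed = 1L) {
  stopifnot(n_neg >= 0)
  zero <- which(A == 0L)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    ex_idx <- cbind(match(exclude$mirna, rownames(A)),
                    match(exclude$disease, colnames(A)))
    if (anyNA(ex_idx)) stop("exclusion pair with unknown label")
    zero <- setdiff(zero, (ex_idx[, 2L] - 1L) * nrow(A) + ex_idx[, 1L])
  }
  if (n_neg > length(zero)) {
    stop(sprintf("requested %d negatives but only %d unknown pairs are available",
                 n_neg, length(zero)))
  }
  if (n_neg == 0L) {
    return(data.frame(mirna = character(0), disease = character(0),
                      label = integer(0), stringsAsFactors = FALSE))
  }
  picked <- with_seed(seed, zero[sample.int(length(zero), n_neg)])
  data.frame(
    mirna = rownames(A)[(picked - 1L) %% nrow(A) + 1L],
    disease = colnames(A)[(picked - 1L) %/% nrow(A) + 1L],
    label = 0L,
    stringsAsFactors = FALSE
  )
}
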