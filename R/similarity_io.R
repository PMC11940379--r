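#' Square similarity matrix with a declared role
#'
#' Container for the four similarity roles used by the pipeline:
#' `functional` (curated miRNA functional similarity, possibly covering only
#' a subset of pairs), `semantic` (ontology-derived disease similarity),
#' `gip` (Gaussian interaction profile kernel), and `unified` (the fused
#' network whose entries serve as edge weights for the random walks).
#' Entries are in `[0, 1]`; `NA` marks a pair for which the score is
#' undefined (used by the `functional` and `semantic` roles to drive the
#' fusion rule). Matrices must be symmetric to within `1e-9`.
#'
#' @param values numeric square matrix.
#' @param labels node labels; defaults to `rownames(values)`.
#' @param role one of `"functional"`, `"semantic"`, `"gip"`, `"unified"`.
#' @return a `similarity_matrix` (numeric matrix with `role` attribute).
#' @export
similarity_matrix <- function(values, labels = rownames(values),
                              role = c("functional", "semantic", "gip", "unified")) {
  role <- match.arg(role)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("similarity matrix must be square")
  }
  if (is.null(labels) || length(labels) != nrow(values)) {
    stop("labels must match matrix dimension")
  }
  if (anyDuplicated(labels)) stop("duplicate similarity labels")
  dimnames(values) <- list(labels, labels)
  asym <- abs(values - t(values))
  asym[is.na(asym)] <- if (all(is.na(values) == t(is.na(values)))) 0 else 1
  if (any(asym > 1e-9)) {
    ij <- which(asym > 1e-9, arr.ind = TRUE)[1L, ]
    stop(sprintf("similarity matrix is asymmetric at pair (%s, %s): %g vs %g",
                 labels[ij[1L]], labels[ij[2L]],
                 values[ij[1L], ij[2L]], values[ij[2L], ij[1L]]))
  }
  out_of_range <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(out_of_range) > 0L) {
    warning(sprintf("%d similarity entries outside [0, 1] were clipped (range %g..%g)",
                    length(out_of_range),
                    min(values[out_of_range]), max(values[out_of_range])))
    values[out_of_range] <- pmin(pmax(values[out_of_range], 0), 1)
  }
  if (role %in% c("gip", "semantic", "unified")) {
    d <- diag(values)
    if (any(!is.na(d) & abs(d - 1) > 1e-9)) {
      stop("diagonal of a ", role, " similarity matrix must equal 1")
    }
  }
  structure(values, role = role,
            class = c("similarity_matrix", class(values)))
}

#' Role of a similarity matrix
#' @param S a [similarity_matrix()].
#' @return the role string.
#' @export
similarity_role <- function(S) attr(S, "role")

#' Read a square similarity matrix from TSV
#'
#' Format: first row and first column carry identical labels, cells are
#' decimal scores; empty cells or the token `NA` mark undefined pairs.
#'
#' @param path path to the TSV file.
#' @param role similarity role, see [similarity_matrix()].
#' @return a [similarity_matrix()].
#' @export
read_similarity <- function(path, role = "functional") {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) {
    stop(sprintf("similarity file is not square: %d rows, %d score columns",
                 nrow(values), ncol(values)))
  }
  if (!identical(labels, colnames(values))) {
    stop("row labels do not match column header in ", path)
  }
  similarity_matrix(values, labels, role = role)
}

#' Write a similarity matrix to TSV
#' @param S a [similarity_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(S, path) {
  labels <- rownames(S)
  df <- data.frame(label = labels, as.data.frame(unclass(S)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  # full precision so write -> read is the identity
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("label", labels), collapse = "\t"), con)
  for (i in seq_along(labels)) {
    writeLines(paste(c(labels[i], format(S[i, ], digits = 17, trim = TRUE,
                                         scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
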