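#' Binary miRNA-disease association matrix
#'
#' Builds the binary bipartite matrix A in which `A[i, j] = 1` records a
#' validated association between miRNA `i` and disease `j` and `A[i, j] = 0`
#' its absence. Row `i` of A, read as a vector, is the interaction profile
#' `IP(m(i))` of miRNA `i`; column `j` is the interaction profile
#' `IP(d(j))` of disease `j`. Labels are sorted lexicographically on
#' construction so that matrix indices are reproducible across runs.
#'
#' @param pairs data frame with character columns `mirna` and `disease`;
#'   duplicated rows collapse to a single association.
#' @return an `association_matrix`: an integer 0/1 matrix with miRNA row
#'   names and disease column names.
#' @export
association_matrix <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("mirna", "disease") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("association list is empty")
  m <- as.character(pairs$mirna)
  d <- as.character(pairs$disease)
  if (any(!nzchar(m)) || any(!nzchar(d))) stop("empty miRNA or disease label")
  mirnas <- sort(unique(m))
  diseases <- sort(unique(d))
  A <- matrix(0L, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  A[cbind(match(m, mirnas), match(d, diseases))] <- 1L
  structure(A, class = c("association_matrix", class(A)))
}

#' Read an association edge list from a two-column TSV
#'
#' Expected format: two tab-separated columns `mirna<TAB>disease`, one
#' association per line. A header line is detected by the literal token
#' `"mirna"` (case-insensitive) in its first field. Duplicate rows are
#' collapsed.
#'
#' @param path path to the TSV file.
#' @return an [association_matrix()].
#' @export
read_associations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty association file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (tolower(trimws(fields[[1L]][1L])) == "mirna") start <- 2L
  if (start > length(fields)) stop("association file has a header but no data rows: ", path)
  bad <- which(vapply(fields, length, 1L)[seq.int(start, length(fields))] != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed association row at line %d of %s (expected 2 tab-separated columns)",
                 bad[1L] + start - 1L, path))
  }
  rows <- fields[seq.int(start, length(fields))]
  association_matrix(data.frame(
    mirna = trimws(vapply(rows, `[`, "", 1L)),
    disease = trimws(vapply(rows, `[`, "", 2L)),
    stringsAsFactors = FALSE
  ))
}

#' Write an association matrix back to its edge-list TSV form
#'
#' @param A an [association_matrix()].
#' @param path output file.
#' @param header write a `mirna\tdisease` header line.
#' @return `path`, invisibly.
#' @export
write_associations <- function(A, path, header = TRUE) {
  p <- association_pairs(A)
  lines <- paste(p$mirna, p$disease, sep = "\t")
  if (header) lines <- c("mirna\tdisease", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Extract the (miRNA, disease) pairs with a recorded association
#'
#' @param A an [association_matrix()].
#' @return data frame with columns `mirna` and `disease`, one row per 1-entry.
#' @export
association_pairs <- function(A) {
  idx <- which(A == 1L, arr.ind = TRUE)
  data.frame(mirna = rownames(A)[idx[, 1L]],
             disease = colnames(A)[idx[, 2L]],
             stringsAsFactors = FALSE)
}
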