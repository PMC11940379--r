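#' Disease ontology hierarchy as a directed acyclic graph
#'
#' The disease hierarchy (a MeSH-style multi-DAG: several roots and
#' multi-parent "diamond" structure are allowed) supplies, for every disease
#' term P, its ancestor set A(P) -- always including P itself -- over which
#' semantic similarity is computed.
#'
#' @param edges data frame with character columns `parent` and `child`,
#'   one directed edge per row.
#' @return a `disease_dag` object (list with `nodes`, `edges` and the
#'   underlying igraph).
#' @export
disease_dag <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("parent", "child") %in% names(edges)))
  parent <- as.character(edges$parent)
  child <- as.character(edges$child)
  if (length(parent) == 0L) stop("DAG edge list is empty")
  self <- parent == child
  if (any(self)) {
    stop("self-edge in DAG: ", parent[which(self)[1L]])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = parent, to = child, stringsAsFactors = FALSE),
    directed = TRUE
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership == which(comp$csize > 1L)[1L]]
    stop("cycle in DAG involving nodes: ", paste(cyc, collapse = " -> "))
  }
  structure(
    list(nodes = sort(igraph::V(g)$name),
         edges = data.frame(parent = parent, child = child,
                            stringsAsFactors = FALSE),
         graph = g),
    class = "disease_dag"
  )
}

#' Read a disease DAG from a parent/child TSV
#'
#' Format: `parent<TAB>child`, one edge per line; a header line is detected
#' by the literal token `"parent"` in its first field.
#'
#' @param path path to the TSV file.
#' @return a [disease_dag()].
#' @export
read_dag <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty DAG file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- if (tolower(trimws(fields[[1L]][1L])) == "parent") 2L else 1L
  rows <- fields[seq.int(start, length(fields))]
  nf <- vapply(rows, length, 1L)
  if (any(nf != 2L)) {
    stop(sprintf("malformed DAG row at line %d of %s", which(nf != 2L)[1L] + start - 1L, path))
  }
  disease_dag(data.frame(parent = trimws(vapply(rows, `[`, "", 1L)),
                         child = trimws(vapply(rows, `[`, "", 2L)),
                         stringsAsFactors = FALSE))
}

#' Write a disease DAG to TSV
#' @param dag a [disease_dag()].
#' @param path output file.
#' @param header write a `parent\tchild` header line.
#' @return `path`, invisibly.
#' @export
write_dag <- function(dag, path, header = TRUE) {
  lines <- paste(dag$edges$parent, dag$edges$child, sep = "\t")
  if (header) lines <- c("parent\tchild", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Ancestor set of a DAG node (including the node itself)
#'
#' Computed by reverse reachability, so multi-parent diamonds and multiple
#' roots are handled naturally.
#'
#' @param dag a [disease_dag()].
#' @param node node label.
#' @return character vector of ancestor labels, `node` included.
#' @export
dag_ancestors <- function(dag, node) {
  if (!node %in% dag$nodes) stop("unknown DAG node: ", node)
  sort(igraph::subcomponent(dag$graph, node, mode = "in")$name)
}

# Direct children of a node.
dag_children <- function(dag, node) {
  if (!node %in% dag$nodes) stop("unknown DAG node: ", node)
  igraph::neighbors(dag$graph, node, mode = "out")$name
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease_dag: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
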