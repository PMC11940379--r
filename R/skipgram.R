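#' Train skip-gram node embeddings on a walk corpus
#'
#' Learns one d-dimensional vector per node by maximising the likelihood of
#' observing each context node within a window of `w` positions around each
#' centre node of every walk. The softmax objective is optimised with the
#' standard negative-sampling surrogate (unigram^0.75 noise distribution),
#' single-threaded SGD with a linearly decaying learning rate, so results
#' are bit-for-bit reproducible for a fixed seed.
#'
#' Nodes that never occur as a centre with at least one context (isolated
#' nodes whose walks are singletons) receive a zero vector.
#'
#' @param corpus a `walk_corpus` from [generate_walks()].
#' @param d embedding dimension.
#' @param w context window size (>= 1).
#' @param epochs passes over the corpus.
#' @param negatives negative samples per (centre, context) pair.
#' @param alpha initial learning rate.
#' @param seed integer seed for the skip-gram substream.
#' @return an `embedding_matrix`: numeric `|V| x d` matrix with node labels
#'   as row names and an `untrained` attribute listing zero-vector nodes.
#' @export
train_skipgram <- function(corpus, d = 128L, w = 5L, epochs = 5L,
                           negatives = 5L, alpha = 0.025, seed = 1L) {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (d < 1L) stop("d must be >= 1")
  if (w < 1L) stop("w must be >= 1")
  if (length(corpus$walks) == 0L) stop("empty walk corpus")
  seen <- unique(unlist(corpus$walks, use.names = FALSE))
  if (length(seen) < 2L) stop("walk corpus covers fewer than 2 nodes")
  n <- length(corpus$nodes)
  fit <- sg_train_cpp(corpus$walks, n, as.integer(d), as.integer(w),
                      as.integer(epochs), as.integer(negatives),
                      alpha, as.integer(seed))
  emb <- fit$embedding
  untrained <- which(fit$centre_pairs == 0L)
  if (length(untrained) > 0L) emb[untrained, ] <- 0
  rownames(emb) <- corpus$nodes
  structure(emb, d = as.integer(d),
            untrained = corpus$nodes[untrained],
            class = c("embedding_matrix", class(emb)))
}

#' Embed a similarity network
#'
#' Composes the three embedding stages -- kNN sparsification, truncated
#' random walks, skip-gram training -- on one unified similarity matrix.
#' The miRNA network and the disease network are embedded independently with
#' the same dimension. Nodes isolated after sparsification keep a zero
#' vector and are reported with a warning.
#'
#' @param US a [similarity_matrix()] (role `"unified"` in the pipeline).
#' @param cfg a [walkmda_config()].
#' @param stream extra tag mixed into the walk/skip-gram substream seeds so
#'   the two networks of a run draw independent randomness.
#' @return an `embedding_matrix`, rows aligned with `rownames(US)`.
#' @export
embed_network <- function(US, cfg, stream = "") {
  stopifnot(inherits(US, "similarity_matrix"), inherits(cfg, "walkmda_config"))
  g <- sparsify(US, cfg$knn_k)
  corpus <- generate_walks(g, cfg$gamma, cfg$t,
                           seed = substream_seed(cfg$seed, paste0("walks:", stream)),
                           uniform = cfg$uniform_walks)
  emb <- train_skipgram(corpus, d = cfg$d, w = cfg$w, epochs = cfg$sg_epochs,
                        negatives = cfg$sg_negatives, alpha = cfg$sg_alpha,
                        seed = substream_seed(cfg$seed, paste0("skipgram:", stream)))
  untrained <- attr(emb, "untrained")
  if (length(untrained) > 0L) {
    warning("nodes isolated after sparsification received zero embeddings: ",
            paste(head(untrained, 5L), collapse = ", "),
            if (length(untrained) > 5L) ", ..." else "")
  }
  emb
}

#' Write embeddings in word2vec text format
#'
#' First line `|V| d`, then one `label v1 ... vd` line per node.
#'
#' @param emb an `embedding_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  for (i in seq_len(nrow(emb))) {
    writeLines(paste(c(rownames(emb)[i],
                       format(emb[i, ], digits = 17, trim = TRUE)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read embeddings from word2vec text format
#' @param path input file.
#' @return an `embedding_matrix`.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("malformed word2vec header in ", path)
  body <- strsplit(lines[-1L], " ", fixed = TRUE)
  if (length(body) != hdr[1L]) stop("embedding row count does not match header")
  labels <- vapply(body, `[`, "", 1L)
  vals <- lapply(body, function(f) as.numeric(f[-1L]))
  if (any(lengths(vals) != hdr[2L])) stop("embedding row width does not match header")
  emb <- matrix(unlist(vals), nrow = hdr[1L], ncol = hdr[2L], byrow = TRUE,
                dimnames = list(labels, NULL))
  structure(emb, d = hdr[2L], untrained = character(0),
            class = c("embedding_matrix", class(emb)))
}
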