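# Shared fixtures: everything is generated in code at test time.

# Small association matrix with a clear 2-block structure plus one
# off-block association, handy for exercising GIP and LOOCV cheaply.
tiny_assoc <- function() {
  pairs <- data.frame(
    mirna = c("m1", "m1", "m2", "m2", "m3", "m3", "m4", "m4", "m1"),
    disease = c("d1", "d2", "d1", "d2", "d3", "d4", "d3", "d4", "d3")
  )
  association_matrix(pairs)
}

# Downsized configuration so unit tests stay fast; scientific defaults are
# exercised separately in the acceptance suite.
fast_config <- function(seed = 1L, dnn = list(), ...) {
  dnn_small <- utils::modifyList(
    list(hidden = c(32L, 16L), epochs = 40L, batch_size = 32L, patience = 5L),
    dnn
  )
  walkmda_config(
    d = 16L, gamma = 4L, t = 20L, w = 3L, knn_k = 5L,
    sg_epochs = 3L, dnn = dnn_small,
    loocv_batches = 4L, seed = seed, ...
  )
}

# Linearly separable toy pair set for classifier capacity checks.
toy_pair_dataset <- function(n = 40L, p = 8L, seed = 5L, margin = 2) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p, sd = 0.3), n, p)
  X[, 1L] <- X[, 1L] + ifelse(y == 1L, margin, -margin)
  pairs <- data.frame(mirna = sprintf("m%03d", seq_len(n)),
                      disease = sprintf("d%03d", seq_len(n)),
                      label = y)
  pair_dataset(pairs, X)
}

# Write lines to a temp file and return its path.
write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Two k-cliques joined by a single bridge, as a unified similarity matrix.
two_clique_similarity <- function(k = 10L, w_in = 0.9, w_bridge = 0.3) {
  n <- 2L * k
  labels <- sprintf("n%02d", seq_len(n))
  S <- matrix(0, n, n, dimnames = list(labels, labels))
  S[seq_len(k), seq_len(k)] <- w_in
  S[(k + 1L):n, (k + 1L):n] <- w_in
  S[k, k + 1L] <- w_bridge
  S[k + 1L, k] <- w_bridge
  diag(S) <- 1
  similarity_matrix(S, labels, role = "unified")
}

cosine_matrix <- function(E) {
  nrm <- sqrt(rowSums(E^2))
  nrm[nrm == 0] <- 1
  En <- E / nrm
  En %*% t(En)
}
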