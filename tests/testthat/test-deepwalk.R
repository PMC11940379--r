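test_that("sparsification keeps top-k neighbours with union symmetrisation", {
  labels <- c("a", "b", "c")
  M <- matrix(c(1, 0.9, 0.2,
                0.9, 1, 0.5,
                0.2, 0.5, 1), 3, 3, dimnames = list(labels, labels))
  S <- similarity_matrix(M, labels, role = "unified")
  g <- sparsify(S, 1L)
  # a keeps b; b keeps a; c keeps b -> union adds b~c
  expect_setequal(g$adjacency[[1]]$nbr, 2L)
  expect_setequal(g$adjacency[[2]]$nbr, c(1L, 3L))
  expect_setequal(g$adjacency[[3]]$nbr, 2L)

  # identity similarity -> empty graph
  I3 <- similarity_matrix(diag(3), labels, role = "unified")
  g0 <- sparsify(I3, 2L)
  expect_true(all(vapply(g0$adjacency, function(a) length(a$nbr), 1L) == 0L))

  # k >= |V| keeps every positive off-diagonal edge
  gall <- sparsify(S, 3L)
  expect_setequal(gall$adjacency[[1]]$nbr, c(2L, 3L))
  expect_setequal(gall$adjacency[[3]]$nbr, c(1L, 2L))
})

test_that("walk counts, lengths and start nodes follow the gamma/t contract", {
  labels <- c("a", "b", "c")
  M <- matrix(0.5, 3, 3, dimnames = list(labels, labels)); diag(M) <- 1
  g <- sparsify(similarity_matrix(M, labels, "unified"), 3L)
  corpus <- generate_walks(g, gamma = 2L, t = 5L, seed = 1L)
  expect_length(corpus$walks, 6L)
  expect_true(all(lengths(corpus$walks) == 5L))
  expect_equal(vapply(corpus$walks, `[`, 1L, 1L), rep(1:3, each = 2L))
  # consecutive nodes are graph neighbours
  for (wk in corpus$walks) {
    for (j in seq_len(length(wk) - 1L)) {
      expect_true(wk[j + 1L] %in% g$adjacency[[wk[j]]]$nbr)
    }
  }
})

test_that("forced transitions: single-neighbour nodes always walk there", {
  labels <- c("a", "b", "c")
  M <- matrix(0, 3, 3, dimnames = list(labels, labels))
  M[1, 2] <- M[2, 1] <- 0.8
  M[2, 3] <- M[3, 2] <- 0.6
  diag(M) <- 1
  g <- sparsify(similarity_matrix(M, labels, "unified"), 1L)
  corpus <- generate_walks(g, gamma = 3L, t = 6L, seed = 2L)
  from_a <- Filter(function(wk) wk[1L] == 1L, corpus$walks)
  expect_true(all(vapply(from_a, `[`, 1L, 2L) == 2L))

  # two-node graph: walks alternate a,b,a,b,...
  M2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  g2 <- sparsify(similarity_matrix(M2, c("a", "b"), "unified"), 1L)
  c2 <- generate_walks(g2, gamma = 2L, t = 7L, seed = 3L)
  for (wk in c2$walks) {
    expect_equal(wk, rep(c(wk[1L], setdiff(1:2, wk[1L])), length.out = 7L))
  }
})

test_that("isolated nodes yield singleton walks and zero embeddings with a warning", {
  labels <- c("a", "b", "z")
  M <- diag(3); M[1, 2] <- M[2, 1] <- 0.9
  dimnames(M) <- list(labels, labels)
  S <- similarity_matrix(M, labels, "unified")
  g <- sparsify(S, 2L)
  corpus <- generate_walks(g, gamma = 2L, t = 4L, seed = 4L)
  singles <- Filter(function(wk) length(wk) == 1L, corpus$walks)
  expect_length(singles, 2L)  # gamma singletons for the isolated node
  cfg <- fast_config()
  expect_warning(emb <- embed_network(S, cfg), "zero embeddings")
  expect_equal(unname(unclass(emb)["z", ]), rep(0, cfg$d))
  expect_false(all(unclass(emb)["a", ] == 0))
})

test_that("weighted transition frequencies match normalised edge weights", {
  # 3-node star: centre with weights 1 and 3 -> first-step split 0.25 / 0.75
  labels <- c("hub", "x", "y")
  M <- matrix(0, 3, 3, dimnames = list(labels, labels))
  M[1, 2] <- M[2, 1] <- 0.25
  M[1, 3] <- M[3, 1] <- 0.75
  diag(M) <- 1
  g <- sparsify(similarity_matrix(M, labels, "unified"), 2L)
  corpus <- generate_walks(g, gamma = 2000L, t = 2L, seed = 5L)
  from_hub <- Filter(function(wk) wk[1L] == 1L, corpus$walks)
  firsts <- vapply(from_hub, `[`, 1L, 2L)
  freq <- table(factor(firsts, levels = 2:3)) / length(firsts)
  expect_lt(abs(freq[[1]] - 0.25), 0.03)
  expect_lt(abs(freq[[2]] - 0.75), 0.03)

  # uniform mode ignores the weights
  cu <- generate_walks(g, gamma = 2000L, t = 2L, seed = 5L, uniform = TRUE)
  fu <- vapply(Filter(function(wk) wk[1L] == 1L, cu$walks), `[`, 1L, 2L)
  expect_lt(abs(mean(fu == 2L) - 0.5), 0.03)
})

test_that("skip-gram output has the contracted shape and is seed-deterministic", {
  S <- two_clique_similarity(k = 5L)
  g <- sparsify(S, 4L)
  corpus <- generate_walks(g, gamma = 5L, t = 15L, seed = 6L)
  e1 <- train_skipgram(corpus, d = 16L, w = 3L, epochs = 2L, seed = 9L)
  e2 <- train_skipgram(corpus, d = 16L, w = 3L, epochs = 2L, seed = 9L)
  expect_identical(unclass(e1), unclass(e2))
  expect_equal(dim(e1), c(10L, 16L))
  expect_true(all(is.finite(e1)))
  e3 <- train_skipgram(corpus, d = 16L, w = 3L, epochs = 2L, seed = 10L)
  expect_false(identical(unclass(e1), unclass(e3)))

  one_node <- structure(list(walks = list(1L, 1L), nodes = "a",
                             gamma = 2L, t = 1L), class = "walk_corpus")
  expect_error(train_skipgram(one_node, d = 4L), "fewer than 2")
})

test_that("embeddings separate planted communities and track edge weights", {
  # two 10-node cliques joined by one bridge: within-clique cosine exceeds
  # between-clique cosine for most seeds
  wins <- 0L
  spearmans <- numeric(0)
  for (s in 1:3) {
    cfg <- fast_config(seed = s)
    S <- two_clique_similarity(k = 10L)
    emb <- embed_network(S, cfg)
    cm <- cosine_matrix(unclass(emb))
    blocks <- rep(1:2, each = 10L)
    same <- outer(blocks, blocks, "==") & row(cm) != col(cm)
    if (mean(cm[same]) > mean(cm[!same & row(cm) != col(cm)])) wins <- wins + 1L
    ut <- upper.tri(cm)
    spearmans <- c(spearmans, cor(unclass(S)[ut], cm[ut], method = "spearman"))
  }
  expect_gte(wins, 2L)
  expect_gt(mean(spearmans), 0.3)
})

test_that("embedding a similarity network yields one labelled row per node", {
  sim <- simulate_mda(synthetic_spec(n_mirna = 30L, n_disease = 20L, seed = 3L))
  cfg <- fast_config(seed = 2L)
  st <- build_similarity_stack(sim$associations, sim$functional, sim$dag, cfg)
  emb <- embed_network(st$US_mirna, cfg)
  expect_equal(dim(emb), c(30L, cfg$d))
  expect_identical(rownames(emb), rownames(sim$associations))
  expect_true(all(is.finite(emb)))
})
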