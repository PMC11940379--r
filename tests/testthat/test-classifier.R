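test_that("pair features concatenate the two embeddings in order", {
  memb <- structure(matrix(c(1, 2, 5, 6), 2, 2, byrow = TRUE,
                           dimnames = list(c("m1", "m2"), NULL)),
                    class = c("embedding_matrix", "matrix", "array"))
  demb <- structure(matrix(c(3, 4, 7, 8), 2, 2, byrow = TRUE,
                           dimnames = list(c("d1", "d2"), NULL)),
                    class = c("embedding_matrix", "matrix", "array"))
  ds <- build_pair_features(memb, demb,
                            data.frame(mirna = "m1", disease = "d1", label = 1L))
  expect_equal(unname(ds$features[1, ]), c(1, 2, 3, 4))
  expect_equal(ncol(ds$features), 4L)

  empty <- build_pair_features(memb, demb,
                               data.frame(mirna = character(0),
                                          disease = character(0),
                                          label = integer(0)))
  expect_equal(dim(empty$features), c(0L, 4L))

  expect_error(build_pair_features(memb, demb,
                                   data.frame(mirna = "mX", disease = "d1")),
               "mX")
})

test_that("pair feature width is 2d, 256 at the default dimension", {
  labels_m <- sprintf("m%d", 1:3)
  labels_d <- sprintf("d%d", 1:2)
  memb <- structure(matrix(0, 3, 128, dimnames = list(labels_m, NULL)),
                    class = c("embedding_matrix", "matrix", "array"))
  demb <- structure(matrix(0, 2, 128, dimnames = list(labels_d, NULL)),
                    class = c("embedding_matrix", "matrix", "array"))
  ds <- build_pair_features(memb, demb,
                            data.frame(mirna = "m1", disease = "d2", label = 1L))
  expect_equal(ncol(ds$features), 256L)
})

test_that("raw-similarity ablation features have width nm + nd on the same pairs", {
  sim <- simulate_mda(synthetic_spec(n_mirna = 30L, n_disease = 20L, seed = 8L))
  cfg <- fast_config()
  st <- build_similarity_stack(sim$associations, sim$functional, sim$dag, cfg)
  pairs <- association_pairs(sim$associations)[1:10, ]
  pairs$label <- 1L
  ds <- ablation_features(st$US_mirna, st$US_disease, pairs)
  expect_equal(ncol(ds$features), 50L)
  expect_equal(ds$pairs$label, rep(1L, 10L))
  expect_error(ablation_features(st$US_mirna, st$US_disease,
                                 data.frame(mirna = "nope", disease = "d1")),
               "nope")
})

test_that("negative sampling stays inside the unknown cells and honours exclusions", {
  A <- association_matrix(data.frame(mirna = c("m1", "m1", "m2"),
                                     disease = c("d1", "d2", "d1")))
  # single zero cell
  n1 <- sample_negatives(A, 1L, seed = 1L)
  expect_equal(n1$mirna, "m2")
  expect_equal(n1$disease, "d2")
  expect_equal(nrow(sample_negatives(A, 0L, seed = 1L)), 0L)
  expect_error(sample_negatives(A, 2L, seed = 1L), "only 1")
  expect_error(sample_negatives(A, 1L, exclude = n1, seed = 1L), "only 0")

  # never samples a known positive, across many random matrices
  set.seed(77)
  for (rep in 1:200) {
    M <- matrix(rbinom(30, 1, 0.4), 5, 6,
                dimnames = list(sprintf("m%d", 1:5), sprintf("d%d", 1:6)))
    if (all(M == 1)) M[1, 1] <- 0L
    Am <- structure(M, class = c("association_matrix", "matrix", "array"))
    negs <- sample_negatives(Am, min(3L, sum(M == 0)), seed = rep)
    expect_true(all(Am[cbind(negs$mirna, negs$disease)] == 0L))
  }
})

test_that("the network overfits a separable toy set and scores it correctly", {
  ds <- toy_pair_dataset()
  cfg <- fast_config(dnn = list(hidden = c(32L, 16L), dropout = 0,
                                epochs = 200L, batch_size = 16L,
                                val_fraction = 0, learning_rate = 5e-3))
  model <- train_dnn(ds, cfg, seed = 2L)
  expect_lt(tail(model$history, 1L), 0.05)
  p <- predict_scores(model, ds)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(p[ds$pairs$label == 1L] > 0.9))
  expect_true(all(p[ds$pairs$label == 0L] < 0.1))
})

test_that("training is deterministic under a fixed seed and rejects one-class data", {
  ds <- toy_pair_dataset()
  cfg <- fast_config()
  m1 <- train_dnn(ds, cfg, seed = 4L)
  m2 <- train_dnn(ds, cfg, seed = 4L)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$W, m2$W)

  one_class <- pair_dataset(
    data.frame(mirna = c("a", "b"), disease = c("x", "y"), label = c(1L, 1L)),
    matrix(rnorm(4), 2, 2)
  )
  expect_error(train_dnn(one_class, cfg), "single class")
})

test_that("first hidden layer width is 256 under the default configuration", {
  ds <- toy_pair_dataset(n = 30L, p = 10L)
  cfg <- walkmda_config(dnn = list(epochs = 2L, val_fraction = 0))
  model <- train_dnn(ds, cfg, seed = 1L)
  expect_equal(model$widths, c(10L, 256L, 128L, 1L))
  expect_equal(ncol(model$W[[1]]), 256L)
})

test_that("inference is dropout-free and batch-order invariant", {
  ds <- toy_pair_dataset()
  cfg <- fast_config()
  model <- train_dnn(ds, cfg, seed = 3L)
  # duplicated row scores identically
  dup <- pair_dataset(data.frame(mirna = c("p", "q"), disease = c("u", "v"),
                                 label = c(1L, 1L)),
                      ds$features[c(1L, 1L), , drop = FALSE])
  pd <- predict_scores(model, dup)
  expect_identical(pd[1L], pd[2L])
  # permutation of the batch permutes the scores
  perm <- sample(nrow(ds$features))
  permuted <- pair_dataset(ds$pairs[perm, ], ds$features[perm, , drop = FALSE])
  expect_equal(predict_scores(model, permuted), predict_scores(model, ds)[perm])
  # width mismatch is refused
  narrow <- pair_dataset(ds$pairs[1:2, ], ds$features[1:2, 1:3, drop = FALSE])
  expect_error(predict_scores(model, narrow), "width")
})

test_that("training loss decreases over epochs for almost all seeds", {
  ds <- toy_pair_dataset()
  drops <- vapply(1:10, function(s) {
    cfg <- fast_config(dnn = list(hidden = c(32L, 16L), dropout = 0,
                                  epochs = 30L, val_fraction = 0,
                                  batch_size = 16L))
    m <- train_dnn(ds, cfg, seed = s)
    tail(m$history, 1L) <= m$history[1L]
  }, logical(1))
  expect_gte(sum(drops), 9L)
})

test_that("shuffled labels destroy held-out discrimination (negative control)", {
  set.seed(10)
  n <- 400L
  y <- rep(c(0L, 1L), each = n / 2L)
  X <- matrix(rnorm(n * 12), n, 12)
  X[, 1L] <- X[, 1L] + ifelse(y == 1L, 1.5, -1.5)
  y_shuf <- sample(y)
  tr <- sample(n, n * 0.7)
  cfg <- fast_config(dnn = list(hidden = c(32L, 16L), epochs = 30L,
                                val_fraction = 0))
  mk <- function(idx, lab) pair_dataset(
    data.frame(mirna = sprintf("m%d", idx), disease = sprintf("d%d", idx),
               label = lab[idx]),
    X[idx, , drop = FALSE]
  )
  m_real <- train_dnn(mk(tr, y), cfg, seed = 1L)
  m_null <- train_dnn(mk(tr, y_shuf), cfg, seed = 1L)
  te <- setdiff(seq_len(n), tr)
  auc_real <- roc_auc(predict_scores(m_real, mk(te, y)), y[te])
  auc_null <- roc_auc(predict_scores(m_null, mk(te, y_shuf)), y_shuf[te])
  expect_gt(auc_real, 0.9)
  expect_lt(abs(auc_null - 0.5), 0.1)
})
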