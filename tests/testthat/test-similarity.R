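test_that("semantic contributions and DAG values match hand-worked fixtures", {
  fx <- make_worked_dag()
  ctx <- semantic_context(fx$chain, delta = 0.5)
  # chain r -> a -> P
  expect_equal(semantic_contribution(ctx, "P", "P"), 1)
  expect_equal(semantic_contribution(ctx, "P", "a"), 0.5)
  expect_equal(semantic_contribution(ctx, "P", "r"), 0.25)
  expect_equal(dag_value(ctx, "P"), 1.75)
  expect_equal(dag_value(ctx, "a"), 1.5)
  expect_equal(dag_value(ctx, "r"), 1)
  expect_error(semantic_contribution(ctx, "a", "P"), "not an ancestor")
  expect_error(dag_value(ctx, "zzz"), "unknown")

  # diamond r -> {a, b} -> P: both length-2 paths, so the root contributes
  # delta * max(PP(a), PP(b)) = 0.5 * 0.5 = 0.25, same as the chain
  ctxd <- semantic_context(fx$diamond, delta = 0.5)
  expect_equal(semantic_contribution(ctxd, "P", "r"), 0.25)
  expect_equal(dag_value(ctxd, "P"), 1 + 0.5 + 0.5 + 0.25)
})

test_that("semantic similarity matches the sibling fixture and edge cases", {
  fx <- make_worked_dag()
  ctx <- semantic_context(fx$sibling, delta = 0.5)
  expect_equal(semantic_similarity(ctx, "d1", "d2"), 1 / 3)
  expect_equal(semantic_similarity(ctx, "d1", "d1"), 1)

  # disjoint components share nothing
  dag2 <- disease_dag(data.frame(parent = c("r1", "r2"), child = c("x", "y")))
  ctx2 <- semantic_context(dag2, delta = 0.5)
  expect_equal(semantic_similarity(ctx2, "x", "y"), 0)

  # matrix form: undefined entries are NA, defined ones match the scalar op
  S <- semantic_similarity_matrix(ctx2, c("x", "y", "not_in_dag"))
  expect_true(is.na(S["x", "y"]))
  expect_true(all(is.na(S["not_in_dag", ])))
  S2 <- semantic_similarity_matrix(ctx, c("d1", "d2"))
  expect_equal(S2["d1", "d2"], 1 / 3)
})

test_that("semantic similarity is monotone in the contribution factor", {
  # Holds on single-path hierarchies (chain, siblings). It does NOT hold for
  # every pair of a multi-parent DAG: in the diamond, SS(r, P) decreases in
  # delta because DV(P) grows faster than the root's shared contribution, so
  # the diamond is deliberately excluded here.
  fx <- make_worked_dag()
  for (dag in fx[c("chain", "sibling")]) {
    pairs <- utils::combn(dag$nodes, 2)
    lo <- semantic_context(dag, delta = 0.2)
    hi <- semantic_context(dag, delta = 0.8)
    for (k in seq_len(ncol(pairs))) {
      s_lo <- semantic_similarity(lo, pairs[1, k], pairs[2, k])
      s_hi <- semantic_similarity(hi, pairs[1, k], pairs[2, k])
      expect_gte(s_hi, s_lo)
    }
  }
})

test_that("GIP bandwidth follows the mean squared profile norm", {
  # every profile has exactly one association -> mean ||IP||^2 = 1
  P1 <- diag(3)
  expect_equal(gip_bandwidth(P1, 1)$value, 1)
  # profiles {[1,1],[0,0]} -> mean = 1
  P2 <- rbind(c(1, 1), c(0, 0))
  expect_equal(gip_bandwidth(P2, 1)$value, 1)
  # linear in the scale r'
  expect_equal(gip_bandwidth(P2, 2)$value, 2 * gip_bandwidth(P2, 1)$value)
  expect_error(gip_bandwidth(matrix(0, 2, 2)), "bandwidth undefined")
})

test_that("GIP similarity matches hand values and the brute-force oracle", {
  A <- association_matrix(data.frame(mirna = c("m1", "m2"),
                                     disease = c("d1", "d2")))
  G <- gip_similarity(A, "mirna")
  # profiles [1,0] vs [0,1], r_l = 1 -> exp(-2)
  expect_equal(G["m1", "m2"], exp(-2), tolerance = 1e-12)
  expect_equal(diag(unclass(G)), c(m1 = 1, m2 = 1))

  brute_gip <- function(P, r_prime = 1) {
    rl <- r_prime / mean(rowSums(P^2))
    n <- nrow(P)
    G <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        G[i, j] <- exp(-rl * sum((P[i, ] - P[j, ])^2))
      }
    }
    G
  }
  set.seed(11)
  for (rep in 1:20) {
    M <- matrix(rbinom(20 * 15, 1, 0.25), 20, 15)
    if (all(M == 0)) M[1, 1] <- 1L
    dimnames(M) <- list(sprintf("m%d", 1:20), sprintf("d%d", 1:15))
    Am <- structure(M, class = c("association_matrix", "matrix", "array"))
    expect_lt(max(abs(unclass(gip_similarity(Am, "mirna")) - brute_gip(M))), 1e-12)
    expect_lt(max(abs(unclass(gip_similarity(Am, "disease")) - brute_gip(t(M)))), 1e-12)
  }
})

test_that("GIP similarity is permutation-equivariant and monotone in shared associations", {
  set.seed(4)
  M <- matrix(rbinom(8 * 6, 1, 0.3), 8, 6,
              dimnames = list(sprintf("m%d", 1:8), sprintf("d%d", 1:6)))
  M[1, 1] <- 1L
  Am <- structure(M, class = c("association_matrix", "matrix", "array"))
  G <- unclass(gip_similarity(Am, "mirna"))
  perm <- sample(8)
  Mp <- M[perm, ]
  Gp <- unclass(gip_similarity(structure(Mp, class = class(Am)), "mirna"))
  expect_equal(Gp, G[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)

  # adding an association shared by two miRNAs cannot decrease their
  # similarity: the profile distance is unchanged while the bandwidth shrinks
  M2 <- M
  M2[1, 2] <- 1L
  M2[2, 2] <- 1L
  G2 <- unclass(gip_similarity(structure(M2, class = class(Am)), "mirna"))
  expect_gte(G2[1, 2], G[1, 2])
})

test_that("similarity fusion takes the curated branch exactly where defined", {
  labels <- c("m1", "m2", "m3")
  gs <- matrix(0.4, 3, 3); diag(gs) <- 1
  GS <- similarity_matrix(gs, labels, role = "gip")
  fs <- matrix(NA_real_, 3, 3); diag(fs) <- 1
  fs[1, 2] <- fs[2, 1] <- 0.8
  FS <- similarity_matrix(fs, labels, role = "functional")

  US <- unified_mirna_similarity(FS, GS)
  expect_equal(US["m1", "m2"], 0.8)   # curated branch
  expect_equal(US["m1", "m3"], 0.4)   # GIP branch
  expect_false(anyNA(unclass(US)))
  expect_equal(similarity_role(US), "unified")

  # fully defined curated matrix wins everywhere
  full <- matrix(0.6, 3, 3); diag(full) <- 1
  USf <- unified_mirna_similarity(similarity_matrix(full, labels, "functional"), GS)
  expect_equal(unclass(USf), unclass(similarity_matrix(full, labels, "functional")),
               ignore_attr = TRUE)

  # no curated input at all degenerates to GIP
  expect_equal(unclass(unified_disease_similarity(NULL, GS)), unclass(GS),
               ignore_attr = TRUE)

  bad <- similarity_matrix(fs, c("a", "b", "c"), role = "functional")
  expect_error(unified_mirna_similarity(bad, GS), "label mismatch")
})

test_that("partial curated coverage expands with NA and routes pairs correctly", {
  labels <- c("m1", "m2", "m3")
  small <- similarity_matrix(matrix(c(1, 0.7, 0.7, 1), 2, 2),
                             c("m1", "m2"), role = "functional")
  big <- expand_similarity(small, labels)
  expect_equal(big["m1", "m2"], 0.7)
  expect_true(is.na(big["m1", "m3"]))

  gs <- matrix(0.2, 3, 3); diag(gs) <- 1
  GS <- similarity_matrix(gs, labels, role = "gip")
  US <- unified_mirna_similarity(big, GS)
  expect_equal(US["m1", "m2"], 0.7)
  expect_equal(US["m2", "m3"], 0.2)
})

test_that("unified similarity from DAG semantic scores matches the sibling value", {
  fx <- make_worked_dag()
  ctx <- semantic_context(fx$sibling, delta = 0.5)
  diseases <- c("d1", "d2", "d9")  # d9 absent from the DAG
  SS <- semantic_similarity_matrix(ctx, diseases)
  gs <- matrix(0.25, 3, 3); diag(gs) <- 1
  GS <- similarity_matrix(gs, diseases, role = "gip")
  US <- unified_disease_similarity(SS, GS)
  expect_equal(US["d1", "d2"], 1 / 3)
  expect_equal(US["d1", "d9"], 0.25)
  expect_equal(US["d9", "d9"], 1)
})
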