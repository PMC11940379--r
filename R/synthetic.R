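#' Specification for the planted-block synthetic benchmark
#'
#' The generator emulates the statistical structure the predictor relies on:
#' miRNAs with similar function tend to associate with phenotypically
#' similar diseases. miRNAs and diseases are partitioned into matched
#' blocks; an association is present with probability `p_in` when the
#' miRNA's block matches the disease's block and `p_out` otherwise. The
#' curated functional similarity is block-consistent with additive Gaussian
#' noise and covers only a random subset of miRNA pairs (so both branches of
#' the fusion rule are exercised), and the disease hierarchy is a rooted
#' tree whose subtrees align with the disease blocks.
#'
#' @param n_mirna,n_disease entity counts (defaults 60 and 40).
#' @param n_mirna_blocks,n_disease_blocks community counts (default 4 each;
#'   block k of miRNAs is matched to block k of diseases, recycling if the
#'   counts differ).
#' @param p_in,p_out association probabilities for matched vs unmatched
#'   block pairs (defaults 0.35 and 0.03).
#' @param fs_base_in,fs_base_out functional similarity levels for same-block
#'   vs cross-block miRNA pairs (defaults 0.8 and 0.2).
#' @param fs_noise standard deviation of the Gaussian noise added to the
#'   functional similarity (default 0.05).
#' @param fs_coverage fraction of miRNA pairs for which a functional score
#'   is defined (default 0.7); the rest are `NA` and fall back to GIP.
#' @param dag_depth depth of each block's internal subtree in the disease
#'   hierarchy (default 3). Diseases attach at seeded random depths, so
#'   within-block semantic similarity is graded, as in a real ontology.
#' @param dag_branching branching factor of the internal subtrees
#'   (default 2).
#' @param dag_coverage fraction of diseases present in the hierarchy
#'   (default 0.7); absent diseases fall back to GIP similarity for every
#'   pair, exercising the second branch of the disease fusion rule.
#' @param seed integer seed; the simulation is fully determined by it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_mirna = 60L, n_disease = 40L,
                           n_mirna_blocks = 4L, n_disease_blocks = 4L,
                           p_in = 0.35, p_out = 0.03,
                           fs_base_in = 0.8, fs_base_out = 0.2,
                           fs_noise = 0.05, fs_coverage = 0.7,
                           dag_depth = 3L, dag_branching = 2L,
                           dag_coverage = 0.7, seed = 1L) {
  spec <- list(n_mirna = as.integer(n_mirna), n_disease = as.integer(n_disease),
               n_mirna_blocks = as.integer(n_mirna_blocks),
               n_disease_blocks = as.integer(n_disease_blocks),
               p_in = p_in, p_out = p_out,
               fs_base_in = fs_base_in, fs_base_out = fs_base_out,
               fs_noise = fs_noise, fs_coverage = fs_coverage,
               dag_depth = as.integer(dag_depth),
               dag_branching = as.integer(dag_branching),
               dag_coverage = dag_coverage,
               seed = as.integer(seed))
  if (!(spec$p_out >= 0 && spec$p_out < spec$p_in && spec$p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  if (spec$n_mirna < spec$n_mirna_blocks || spec$n_disease < spec$n_disease_blocks) {
    stop("entity counts must be >= block counts")
  }
  if (spec$n_mirna_blocks < 1L || spec$n_disease_blocks < 1L) stop("block counts must be >= 1")
  if (spec$fs_coverage < 0 || spec$fs_coverage > 1) stop("fs_coverage must lie in [0, 1]")
  if (spec$dag_coverage < 0 || spec$dag_coverage > 1) stop("dag_coverage must lie in [0, 1]")
  if (spec$dag_depth < 1L || spec$dag_branching < 1L) stop("DAG shape parameters must be >= 1")
  structure(spec, class = "synthetic_spec")
}

#' Simulate a planted-block association problem
#'
#' Fully determined by `spec$seed`. Returns the binary association matrix,
#' the partially observed functional similarity, the disease hierarchy, and
#' the ground-truth block labels of both axes.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `associations` ([association_matrix()]), `functional`
#'   ([similarity_matrix()], role `"functional"`, `NA` outside the covered
#'   pairs), `dag` ([disease_dag()]), `mirna_blocks`, `disease_blocks`
#'   (named integer vectors).
#' @export
simulate_mda <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mirnas <- sprintf("mir-%03d", seq_len(spec$n_mirna))
  diseases <- sprintf("disease-%03d", seq_len(spec$n_disease))
  mb <- sort(rep_len(seq_len(spec$n_mirna_blocks), spec$n_mirna))
  db <- sort(rep_len(seq_len(spec$n_disease_blocks), spec$n_disease))
  names(mb) <- mirnas
  names(db) <- diseases
  matched <- outer(mb, rep_len(seq_len(spec$n_mirna_blocks), spec$n_disease_blocks)[db],
                   "==")
  out <- with_seed(spec$seed, {
    p <- ifelse(matched, spec$p_in, spec$p_out)
    Av <- matrix(rbinom(length(p), 1L, p), nrow(p), ncol(p),
                 dimnames = list(mirnas, diseases))
    # block-consistent functional similarity with noise, partial coverage
    base <- ifelse(outer(mb, mb, "=="), spec$fs_base_in, spec$fs_base_out)
    noise <- matrix(rnorm(length(base), sd = spec$fs_noise), nrow(base))
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    FSv <- pmin(pmax(base + noise, 0), 1)
    covered <- matrix(TRUE, nrow(base), ncol(base))
    if (spec$fs_coverage < 1) {
      up <- which(upper.tri(covered))
      drop_n <- round((1 - spec$fs_coverage) * length(up))
      dropped <- up[sample.int(length(up), drop_n)]
      covered[dropped] <- FALSE
      covered <- covered & t(covered)
    }
    FSv[!covered] <- NA_real_
    diag(FSv) <- 1
    dag <- block_tree_dag(diseases, db, spec$dag_depth, spec$dag_branching,
                          spec$dag_coverage)
    list(Av = Av, FSv = FSv, dag = dag)
  })
  A <- structure(out$Av, class = c("association_matrix", "matrix", "array"))
  storage.mode(A) <- "integer"
  FS <- similarity_matrix(out$FSv, mirnas, role = "functional")
  list(associations = A, functional = FS, dag = out$dag,
       mirna_blocks = mb, disease_blocks = db)
}

# Disease hierarchy emulating a MeSH-like ontology at toy scale: one root,
# one balanced internal subtree (given depth and branching) per disease
# block, and each covered disease attached to a random internal node of its
# block's subtree, so within-block semantic similarity is graded by depth.
# Only a `coverage` fraction of diseases appears in the hierarchy at all.
# Uses the caller's RNG state (simulate_mda seeds it).
block_tree_dag <- function(diseases, blocks, depth, branching, coverage = 1) {
  n_blocks <- max(blocks)
  edges_p <- character(0)
  edges_c <- character(0)
  internal <- vector("list", n_blocks)
  for (k in seq_len(n_blocks)) {
    level <- sprintf("grp%d", k)
    edges_p <- c(edges_p, "disease_root")
    edges_c <- c(edges_c, level)
    nodes <- level
    for (lvl in seq_len(depth - 1L)) {
      children <- unlist(lapply(level, function(p) paste0(p, ".", seq_len(branching))))
      edges_p <- c(edges_p, rep(level, each = branching))
      edges_c <- c(edges_c, children)
      nodes <- c(nodes, children)
      level <- children
    }
    internal[[k]] <- nodes
  }
  covered <- as.logical(rbinom(length(diseases), 1L, coverage))
  if (!any(covered)) covered[1L] <- TRUE
  for (i in which(covered)) {
    anchor_pool <- internal[[blocks[i]]]
    anchor <- anchor_pool[sample.int(length(anchor_pool), 1L)]
    edges_p <- c(edges_p, anchor)
    edges_c <- c(edges_c, diseases[i])
  }
  disease_dag(data.frame(parent = edges_p, child = edges_c,
                         stringsAsFactors = FALSE))
}

#' Randomly rewire an association matrix (negative control)
#'
#' Keeps the number of associations but places them uniformly at random,
#' destroying the block structure. Used as the shuffled-label null in
#' evaluation experiments.
#'
#' @param A an [association_matrix()].
#' @param seed integer seed.
#' @return an [association_matrix()] of the same shape and density.
#' @export
shuffle_associations <- function(A, seed = 1L) {
  n1 <- sum(A == 1L)
  B <- A
  B[] <- 0L
  pick <- with_seed(seed, sample.int(length(A), n1))
  B[pick] <- 1L
  B
}

#' Hand-checkable disease hierarchy fixtures
#'
#' Three minimal DAGs whose semantic-similarity quantities can be evaluated
#' by hand and are frozen in the test suite: a two-edge chain
#' (`r -> a -> P`), one root with two sibling leaves, and a diamond
#' (`r -> a -> P`, `r -> b -> P`). At `delta = 0.5` the chain gives
#' `DV(P) = 1.75`, the one-edge sub-chain `DV(a) = 1.5`, the siblings
#' `SS(d1, d2) = 1/3`, and both diamond paths give the root contribution
#' `0.25`.
#'
#' @return named list of [disease_dag()] objects: `chain`, `sibling`,
#'   `diamond`.
#' @export
make_worked_dag <- function() {
  list(
    chain = disease_dag(data.frame(parent = c("r", "a"), child = c("a", "P"),
                                   stringsAsFactors = FALSE)),
    sibling = disease_dag(data.frame(parent = c("root", "root"),
                                     child = c("d1", "d2"),
                                     stringsAsFactors = FALSE)),
    diamond = disease_dag(data.frame(parent = c("r", "r", "a", "b"),
                                     child = c("a", "b", "P", "P"),
                                     stringsAsFactors = FALSE))
  )
}
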