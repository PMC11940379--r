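#' Build the unified similarity networks from an association matrix
#'
#' Computes the GIP kernel on both axes, the disease semantic similarity
#' when a hierarchy is supplied, aligns an optional curated miRNA functional
#' similarity to the association matrix labels, and fuses everything into
#' the two unified networks.
#'
#' @param A an [association_matrix()].
#' @param FS optional miRNA functional [similarity_matrix()] (role
#'   `"functional"`); may cover only a subset of the miRNAs.
#' @param dag optional [disease_dag()]; diseases absent from it fall back to
#'   GIP similarity.
#' @param cfg a [walkmda_config()].
#' @return list with `US_mirna`, `US_disease`, `GS_mirna`, `GS_disease`,
#'   `SS` (or `NULL`).
#' @export
build_similarity_stack <- function(A, FS = NULL, dag = NULL, cfg = walkmda_config()) {
  GS_m <- gip_similarity(A, "mirna", cfg$r_mirna)
  GS_d <- gip_similarity(A, "disease", cfg$r_disease)
  if (!is.null(FS)) {
    extra <- setdiff(rownames(FS), rownames(A))
    if (length(extra) > 0L) {
      FS <- similarity_matrix(
        unclass(FS)[setdiff(rownames(FS), extra), setdiff(rownames(FS), extra),
                    drop = FALSE],
        role = "functional")
    }
    FS <- expand_similarity(FS, rownames(A))
  }
  SS <- NULL
  if (!is.null(dag)) {
    ctx <- semantic_context(dag, cfg$delta)
    SS <- semantic_similarity_matrix(ctx, colnames(A))
  }
  list(US_mirna = unified_mirna_similarity(FS, GS_m),
       US_disease = unified_disease_similarity(SS, GS_d),
       GS_mirna = GS_m, GS_disease = GS_d, SS = SS)
}

#' Fit the full association model
#'
#' Builds the unified similarity networks, embeds the miRNA and disease
#' networks independently, trains the classifier on all known associations
#' (as positives) plus uniformly sampled unknown pairs (as presumed
#' negatives, `neg_ratio` per positive), and returns a model that can score
#' arbitrary pairs. In `raw_similarity` feature mode the unified similarity
#' rows replace the embeddings.
#'
#' @param A an [association_matrix()].
#' @param cfg a [walkmda_config()].
#' @param FS,dag optional curated inputs, see [build_similarity_stack()].
#' @return a `walkmda_model` (similarities, embeddings, classifier, config).
#' @export
fit_mda_model <- function(A, cfg = walkmda_config(), FS = NULL, dag = NULL) {
  space <- build_feature_space(A, FS, dag, cfg)
  pos <- association_pairs(A)
  pos$label <- 1L
  model <- train_fold_classifier(space, A, pos, cfg,
                                 seed = substream_seed(cfg$seed, "fit"))
  structure(c(space, list(classifier = model, cfg = cfg, A = A)),
            class = "walkmda_model")
}

#' Score miRNA-disease pairs with a fitted model
#'
#' @param model a `walkmda_model` from [fit_mda_model()].
#' @param pairs data frame with columns `mirna`, `disease`.
#' @return `pairs` with a `score` column appended.
#' @export
score_pairs <- function(model, pairs) {
  stopifnot(inherits(model, "walkmda_model"))
  ds <- space_features(model, pairs)
  pairs$score <- predict_scores(model$classifier, ds)
  pairs
}

#' @export
print.walkmda_model <- function(x, ...) {
  cat(sprintf("walkmda_model: %d miRNAs x %d diseases, feature mode %s\n",
              nrow(x$A), ncol(x$A), x$cfg$feature_mode))
  invisible(x)
}

# --- internal feature-space plumbing shared by fit and LOOCV -------------

# Build everything the classifier's features depend on (similarities and,
# in deepwalk mode, embeddings) from one association matrix.
build_feature_space <- function(A, FS, dag, cfg, stream = "") {
  sims <- build_similarity_stack(A, FS, dag, cfg)
  out <- list(US_mirna = sims$US_mirna, US_disease = sims$US_disease,
              feature_mode = cfg$feature_mode)
  if (cfg$feature_mode == "deepwalk") {
    out$mirna_embedding <- embed_network(sims$US_mirna, cfg,
                                         stream = paste0("mirna", stream))
    out$disease_embedding <- embed_network(sims$US_disease, cfg,
                                           stream = paste0("disease", stream))
  }
  out
}

space_features <- function(space, pairs) {
  if (space$feature_mode == "deepwalk") {
    build_pair_features(space$mirna_embedding, space$disease_embedding, pairs)
  } else {
    ablation_features(space$US_mirna, space$US_disease, pairs)
  }
}

# Train the classifier for one training matrix: positives are the 1-cells of
# A_train, negatives a seeded uniform sample of unknown cells of the original
# matrix, excluding any held-out positives.
train_fold_classifier <- function(space, A_train, positives, cfg, seed,
                                  exclude = NULL) {
  n_neg <- max(1L, round(cfg$neg_ratio * nrow(positives)))
  negs <- sample_negatives(A_train, n_neg, exclude = exclude,
                           seed = substream_seed(seed, "negatives"))
  train_pairs <- rbind(positives[, c("mirna", "disease", "label")], negs)
  ds <- space_features(space, train_pairs)
  train_dnn(ds, cfg, seed = substream_seed(seed, "weights"))
}
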