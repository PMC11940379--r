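#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated object. All
#' randomness (walks, skip-gram initialisation and negative sampling,
#' classifier negative sampling and initialisation, fold assignment) is
#' derived from the single `seed` through named substreams, so a run is
#' fully reproducible from this object.
#'
#' @param d embedding dimension (default 128).
#' @param gamma random walks started per node (default 10).
#' @param t walk length in nodes (default 80).
#' @param w skip-gram context window (default 5; must satisfy `1 <= w < t`).
#' @param delta semantic contribution factor in (0, 1) applied per DAG edge
#'   when propagating a disease's contribution to its ancestors
#'   (default 0.5, the usual choice in the disease-ontology similarity
#'   literature).
#' @param r_mirna,r_disease GIP bandwidth scale r' for the miRNA and disease
#'   kernels (default 1 for both).
#' @param knn_k neighbours retained per node when sparsifying a dense
#'   unified similarity matrix into a walkable graph (default 15).
#' @param neg_ratio negatives sampled per positive when training the
#'   classifier (default 1).
#' @param feature_mode `"deepwalk"` (concatenated node embeddings, width
#'   `2 * d`) or `"raw_similarity"` (concatenated unified-similarity rows,
#'   width `nm + nd`); the latter is the "- DW" ablation arm.
#' @param uniform_walks if `TRUE` walk transitions ignore edge weights and
#'   pick a neighbour uniformly (classic DeepWalk); default `FALSE`, i.e.
#'   transitions are proportional to the unified similarity edge weight.
#' @param sg_epochs,sg_negatives,sg_alpha skip-gram training passes over the
#'   walk corpus (default 5), negative samples per positive pair (default 5)
#'   and initial learning rate (default 0.025, linearly decayed).
#' @param dnn named list of classifier settings: `hidden` (widths of the two
#'   hidden layers, default `c(256, 128)`), `dropout` (rate after each
#'   hidden layer, default 0.5), `learning_rate` (RMSProp, default 1e-3),
#'   `epochs` (default 100), `batch_size` (default 128), `val_fraction`
#'   (early-stopping split, default 0.1), `patience` (default 10).
#' @param loocv_batches number of batches the held-out positives are grouped
#'   into when the classifier is retrained during transductive LOOCV
#'   (default 10).
#' @param seed master integer seed (default 42).
#' @return a `walkmda_config` list.
#' @export
walkmda_config <- function(d = 128L, gamma = 10L, t = 80L, w = 5L,
                           delta = 0.5, r_mirna = 1, r_disease = 1,
                           knn_k = 15L, neg_ratio = 1,
                           feature_mode = c("deepwalk", "raw_similarity"),
                           uniform_walks = FALSE,
                           sg_epochs = 5L, sg_negatives = 5L, sg_alpha = 0.025,
                           dnn = list(), loocv_batches = 10L, seed = 42L) {
  feature_mode <- match.arg(feature_mode)
  dnn_defaults <- list(hidden = c(256L, 128L), dropout = 0.5,
                       learning_rate = 1e-3, epochs = 100L, batch_size = 128L,
                       val_fraction = 0.1, patience = 10L)
  unknown <- setdiff(names(dnn), names(dnn_defaults))
  if (length(unknown) > 0L) stop("unknown dnn settings: ", paste(unknown, collapse = ", "))
  dnn <- utils::modifyList(dnn_defaults, dnn)
  cfg <- list(d = as.integer(d), gamma = as.integer(gamma), t = as.integer(t),
              w = as.integer(w), delta = delta,
              r_mirna = r_mirna, r_disease = r_disease,
              knn_k = as.integer(knn_k), neg_ratio = neg_ratio,
              feature_mode = feature_mode,
              uniform_walks = isTRUE(uniform_walks),
              sg_epochs = as.integer(sg_epochs),
              sg_negatives = as.integer(sg_negatives),
              sg_alpha = sg_alpha,
              dnn = dnn, loocv_batches = as.integer(loocv_batches),
              seed = as.integer(seed))
  if (cfg$d < 1L) stop("d must be >= 1")
  if (cfg$gamma < 1L) stop("gamma must be >= 1")
  if (cfg$t < 2L) stop("t must be >= 2")
  if (cfg$w < 1L || cfg$w >= cfg$t) stop("w must satisfy 1 <= w < t")
  if (!(cfg$delta > 0 && cfg$delta < 1)) stop("delta must lie in (0, 1)")
  if (cfg$r_mirna <= 0 || cfg$r_disease <= 0) stop("GIP bandwidth scales must be positive")
  if (cfg$knn_k < 1L) stop("knn_k must be >= 1")
  if (cfg$neg_ratio <= 0) stop("neg_ratio must be positive")
  if (cfg$dnn$dropout < 0 || cfg$dnn$dropout >= 1) stop("dropout must lie in [0, 1)")
  if (cfg$loocv_batches < 1L) stop("loocv_batches must be >= 1")
  structure(cfg, class = "walkmda_config")
}

#' @export
print.walkmda_config <- function(x, ...) {
  cat(sprintf(paste0("walkmda_config: d=%d gamma=%d t=%d w=%d delta=%g ",
                     "knn_k=%d feature_mode=%s seed=%d\n"),
              x$d, x$gamma, x$t, x$w, x$delta, x$knn_k, x$feature_mode, x$seed))
  invisible(x)
}
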