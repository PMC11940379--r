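#' Global leave-one-out cross-validation
#'
#' Every known association is held out in turn: it is zeroed in the
#' association matrix, the model is retrained without it, and the held-out
#' pair is scored against the candidate set of all unknown (`A == 0`) pairs.
#' Each held-out pair is ranked against the candidates as scored by its own
#' fold's model, and folds are pooled on the within-fold percentile scale
#' (raw sigmoid scores from differently calibrated fold models are not
#' comparable); candidates enter the pool with their average within-fold
#' percentile. ROC / precision-recall metrics are computed on that pooled
#' set; ACC and MCC use threshold 0.5 on a balanced, seeded sample.
#'
#' Two leakage policies are provided:
#' \describe{
#'   \item{`"transductive"`}{similarities and embeddings are computed once
#'     from the full matrix and only the classifier is retrained with the
#'     held-out associations masked; held-out positives are grouped into
#'     `cfg$loocv_batches` batches to amortise retraining. This matches
#'     common practice in the association-prediction literature but lets the
#'     held-out association influence the feature space -- a warning is
#'     issued.}
#'   \item{`"strict"`}{GIP similarities, embeddings and the classifier are
#'     all rebuilt from the masked matrix for every fold. Exact but
#'     expensive; combine with `max_folds` to evaluate a seeded subset of
#'     folds.}
#' }
#'
#' @param A an [association_matrix()] with at least 2 positives.
#' @param cfg a [walkmda_config()].
#' @param FS,dag optional curated inputs, see [build_similarity_stack()].
#' @param mode `"transductive"` (default) or `"strict"`.
#' @param max_folds optionally evaluate only this many held-out folds
#'   (seeded uniform subset); mainly useful with `mode = "strict"`.
#' @param scorer optional scoring oracle replacing the model pipeline, for
#'   testing: a `function(A_train, pairs)` returning one score per row of
#'   `pairs`.
#' @return a `metric_report`: list with `auc`, `auprc`, `acc`, `mcc`,
#'   `precision`, `recall`, `roc` and `pr` curve points, `n_folds`,
#'   `framework`, the pooled percentile `held_scores` / `candidate_scores`,
#'   and the corresponding raw sigmoid scores (`held_raw_scores`,
#'   `candidate_raw_scores`).
#' @export
loocv_global <- function(A, cfg = walkmda_config(), FS = NULL, dag = NULL,
                         mode = c("transductive", "strict"),
                         max_folds = NULL, scorer = NULL) {
  run_loocv(A, cfg, FS, dag, framework = "global",
            mode = match.arg(mode), max_folds = max_folds, scorer = scorer)
}

#' Local leave-one-out cross-validation
#'
#' Identical masking and retraining to [loocv_global()], but each held-out
#' association for disease j is ranked only against the miRNAs not known to
#' associate with j (the unknown cells of column j). Per-disease results are
#' pooled into one report; diseases whose candidate set is empty (every
#' miRNA already associated) contribute no folds and are reported with a
#' warning.
#'
#' @inheritParams loocv_global
#' @return a `metric_report`, `framework = "local"`.
#' @export
loocv_local <- function(A, cfg = walkmda_config(), FS = NULL, dag = NULL,
                        mode = c("transductive", "strict"),
                        max_folds = NULL, scorer = NULL) {
  run_loocv(A, cfg, FS, dag, framework = "local",
            mode = match.arg(mode), max_folds = max_folds, scorer = scorer)
}

run_loocv <- function(A, cfg, FS, dag, framework, mode, max_folds, scorer) {
  pos_idx <- which(A == 1L, arr.ind = TRUE)
  npos <- nrow(pos_idx)
  if (npos < 2L) stop("LOOCV needs at least 2 known associations")
  zero_idx <- which(A == 0L, arr.ind = TRUE)
  if (nrow(zero_idx) == 0L) stop("no unknown pairs: candidate set is empty")
  pos_pairs <- data.frame(mirna = rownames(A)[pos_idx[, 1L]],
                          disease = colnames(A)[pos_idx[, 2L]],
                          stringsAsFactors = FALSE)
  cand_pairs <- data.frame(mirna = rownames(A)[zero_idx[, 1L]],
                           disease = colnames(A)[zero_idx[, 2L]],
                           stringsAsFactors = FALSE)
  if (framework == "local") {
    no_cand <- setdiff(unique(pos_pairs$disease), unique(cand_pairs$disease))
    if (length(no_cand) > 0L) {
      warning("diseases with no unknown candidate miRNA contribute no folds: ",
              paste(no_cand, collapse = ", "))
    }
  }

  folds <- seq_len(npos)
  if (!is.null(max_folds) && max_folds < npos) {
    folds <- with_seed(substream_seed(cfg$seed, "folds"),
                       sort(sample.int(npos, max_folds)))
  }
  n_folds <- length(folds)

  if (mode == "strict") {
    batches <- as.list(folds)
  } else {
    nb <- min(cfg$loocv_batches, n_folds)
    perm <- with_seed(substream_seed(cfg$seed, "batching"),
                      sample(folds, n_folds))
    batches <- split(perm, rep_len(seq_len(nb), n_folds))
    message("transductive LOOCV: similarities and embeddings are computed once ",
            "from the full association matrix, so held-out associations ",
            "influence the feature space; use mode = \"strict\" for exact ",
            "per-fold recomputation")
    if (is.null(scorer)) {
      base_space <- build_feature_space(A, FS, dag, cfg)
    }
  }

  # Each held-out pair is ranked against the candidates AS SCORED BY ITS OWN
  # fold's model, then folds are pooled on the rank-percentile scale. Pooling
  # percentiles rather than raw scores keeps folds comparable: raw sigmoid
  # scores from differently calibrated fold models are not.
  n_cand <- nrow(cand_pairs)
  held_pct <- rep(NA_real_, npos)     # percentile of held pair among its candidates
  held_raw <- rep(NA_real_, npos)
  cand_pct_sum <- numeric(n_cand)
  cand_raw_sum <- numeric(n_cand)
  n_runs <- 0L
  if (framework == "local") {
    cand_by_disease <- split(seq_len(n_cand), cand_pairs$disease)
  }
  for (b in seq_along(batches)) {
    held <- batches[[b]]
    A_train <- A
    A_train[pos_idx[held, , drop = FALSE]] <- 0L
    held_pairs <- pos_pairs[held, , drop = FALSE]
    to_score <- rbind(held_pairs, cand_pairs)
    if (!is.null(scorer)) {
      s <- scorer(A_train, to_score)
    } else {
      space <- if (mode == "strict") {
        build_feature_space(A_train, FS, dag, cfg, stream = sprintf(":fold%d", b))
      } else {
        base_space
      }
      train_pos <- association_pairs(A_train)
      train_pos$label <- 1L
      clf <- train_fold_classifier(space, A_train, train_pos, cfg,
                                   seed = substream_seed(cfg$seed, sprintf("fold%d", b)),
                                   exclude = held_pairs)
      s <- predict_scores(clf, space_features(space, to_score))
    }
    if (length(s) != nrow(to_score)) stop("scorer returned wrong length")
    s_held <- s[seq_along(held)]
    s_cand <- s[-seq_along(held)]
    held_raw[held] <- s_held
    cand_raw_sum <- cand_raw_sum + s_cand
    if (framework == "global") {
      held_pct[held] <- score_percentile(s_held, s_cand)
      cand_pct_sum <- cand_pct_sum + (rank(s_cand) - 0.5) / n_cand
    } else {
      for (k in seq_along(held)) {
        ref <- cand_by_disease[[held_pairs$disease[k]]]
        if (is.null(ref)) next  # disease with empty candidate set
        held_pct[held[k]] <- score_percentile(s_held[k], s_cand[ref])
      }
      for (ref in cand_by_disease) {
        cand_pct_sum[ref] <- cand_pct_sum[ref] +
          (rank(s_cand[ref]) - 0.5) / length(ref)
      }
    }
    n_runs <- n_runs + 1L
  }
  cand_scores <- cand_pct_sum / n_runs
  held_used <- held_pct[folds]
  keep <- !is.na(held_used)
  scores <- c(held_used[keep], cand_scores)
  labels <- c(rep(1L, sum(keep)), rep(0L, n_cand))
  n_folds <- sum(keep)

  # threshold metrics on a balanced, seeded positive/candidate sample
  n_bal <- min(sum(labels == 1L), sum(labels == 0L))
  bal_cand <- with_seed(substream_seed(cfg$seed, "balanced"),
                        sample(which(labels == 0L), n_bal))
  bal_idx <- c(which(labels == 1L)[seq_len(n_bal)], bal_cand)
  cm <- confusion(scores[bal_idx], labels[bal_idx], threshold = 0.5)

  structure(list(auc = roc_auc(scores, labels),
                 auprc = auprc(scores, labels),
                 acc = accuracy(cm),
                 mcc = mcc(cm),
                 precision = precision(cm),
                 recall = recall(cm),
                 confusion = cm,
                 roc = roc_curve(scores, labels),
                 pr = pr_curve(scores, labels),
                 n_folds = n_folds,
                 framework = framework,
                 mode = mode,
                 held_scores = held_used[keep],
                 candidate_scores = cand_scores,
                 held_raw_scores = held_raw[folds][keep],
                 candidate_raw_scores = cand_raw_sum / n_runs),
            class = "metric_report")
}

# Percentile of each score within a reference score set: fraction of
# reference scores strictly below, ties counted half.
score_percentile <- function(s, ref) {
  vapply(s, function(x) (sum(ref < x) + 0.5 * sum(ref == x)) / length(ref),
         numeric(1))
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%s LOOCV (%s, %d folds): AUC %.4f  AUPRC %.4f  ACC %.4f  MCC %.4f\n",
              x$framework, x$mode, x$n_folds, x$auc, x$auprc, x$acc, x$mcc))
  invisible(x)
}
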