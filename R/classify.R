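#' Decision rule for interaction calls
#'
#' A pair is called interacting when at least one of its top `top_n` ranked
#' models receives a classifier probability strictly greater than
#' `probability_threshold`. The defaults (0.13, top 3) are the configuration
#' that maximizes the MCC in benchmark cross-validation.
#'
#' @param probability_threshold probability cutoff in [0, 1].
#' @param top_n number of top-ranked models considered (>= 1).
#' @return list of class `decision_rule`.
#' @export
decision_rule <- function(probability_threshold = 0.13, top_n = 3L) {
  if (probability_threshold < 0 || probability_threshold > 1) {
    stop("probability_threshold must be in [0, 1]")
  }
  if (top_n < 1) stop("top_n must be >= 1")
  structure(list(probability_threshold = probability_threshold,
                 top_n = as.integer(top_n)),
            class = "decision_rule")
}

# Assemble a labeled model matrix from positive/negative feature tables.
.training_frame <- function(positives, negatives) {
  cols <- energy_feature_names()
  if (nrow(positives) == 0L || nrow(negatives) == 0L) {
    stop("both classes must be non-empty")
  }
  x <- rbind(positives[, cols, drop = FALSE], negatives[, cols, drop = FALSE])
  y <- factor(c(rep("interacting", nrow(positives)),
                rep("non_interacting", nrow(negatives))),
              levels = c("non_interacting", "interacting"))
  list(x = x, y = y)
}

#' Train the interaction classifier
#'
#' Fits a random-forest ensemble on the ten binding-energy features, with
#' interacting pairs as positives and (typically ligand-swap) negatives.
#' Trees are grown as probability trees (terminal-node class frequencies,
#' averaged over the ensemble), which gives smoother probability scores
#' than majority votes; the terminal-node size scales with the training-set
#' size for the same reason. The returned model maps a feature vector to
#' the probability that the pair is biologically relevant.
#'
#' @param positives,negatives feature data.frames (canonical columns).
#' @param n_trees ensemble size (default 500).
#' @param seed integer seed; same seed and data give identical predictions.
#' @param min_node_size minimum terminal-node size; default 5% of the
#'   training rows (at least 10).
#' @return object of class `ppi_classifier`.
#' @export
train_classifier <- function(positives, negatives, n_trees = 500L, seed = 1L,
                             min_node_size = NULL) {
  tf <- .training_frame(positives, negatives)
  if (nlevels(droplevels(tf$y)) < 2L) stop("single-class input")
  if (is.null(min_node_size)) {
    min_node_size <- max(10L, as.integer(ceiling(0.05 * length(tf$y))))
  }
  # constant columns carry no signal and would produce unsplittable stump
  # trees whenever all mtry sampled features are constant
  informative <- vapply(tf$x, function(v) stats::var(v) > 0, logical(1))
  if (!any(informative)) stop("no informative (non-constant) features")
  dat <- cbind(tf$x[, informative, drop = FALSE], .class = tf$y)
  fit <- ranger::ranger(dependent.variable.name = ".class", data = dat,
                        num.trees = n_trees, probability = TRUE,
                        min.node.size = min_node_size,
                        seed = seed, num.threads = 1L)
  structure(list(forest = fit, features = energy_feature_names(),
                 used_features = energy_feature_names()[informative],
                 n_trees = n_trees, seed = seed,
                 min_node_size = min_node_size),
            class = "ppi_classifier")
}

#' Predict interaction probabilities
#'
#' @param object a `ppi_classifier`.
#' @param newdata feature data.frame (canonical columns).
#' @param ... unused.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict.ppi_classifier <- function(object, newdata, ...) {
  x <- newdata[, object$used_features, drop = FALSE]
  p <- stats::predict(object$forest, data = x, num.threads = 1L)$predictions
  unname(p[, "interacting"])
}

# Stratified fold assignment: within each class, a seeded permutation split
# into k nearly equal folds.
.stratified_folds <- function(n_pos, n_neg, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_of <- function(n) sample(rep_len(seq_len(k), n))
  list(pos = fold_of(n_pos), neg = fold_of(n_neg))
}

#' k-fold cross-validation of the interaction classifier
#'
#' Stratified k-fold cross-validation: each example is scored exactly once
#' by a forest trained on the other k-1 folds. Returns out-of-fold
#' probabilities and the resulting ROC curve.
#'
#' @param positives,negatives feature data.frames.
#' @param k number of folds (default 10).
#' @param n_trees trees per fold model.
#' @param seed integer seed (fold assignment and forests).
#' @return list with `scores` (out-of-fold probabilities), `labels`
#'   (1 = interacting), `fold` assignments, and `roc` (a `roc_curve` object).
#' @export
cross_validate <- function(positives, negatives, k = 10L, n_trees = 500L,
                           seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  np <- nrow(positives); nn <- nrow(negatives)
  if (np < k || nn < k) stop("each class needs at least k examples")
  folds <- .stratified_folds(np, nn, k, seed)
  scores <- numeric(np + nn)
  labels <- c(rep(1L, np), rep(0L, nn))
  for (f in seq_len(k)) {
    tr_pos <- positives[folds$pos != f, , drop = FALSE]
    tr_neg <- negatives[folds$neg != f, , drop = FALSE]
    model <- train_classifier(tr_pos, tr_neg, n_trees = n_trees,
                              seed = as.integer((seed * 131 + f) %% 2147483629))
    te_pos_idx <- which(folds$pos == f)
    te_neg_idx <- which(folds$neg == f)
    if (length(te_pos_idx) > 0) {
      scores[te_pos_idx] <- predict(model, positives[te_pos_idx, , drop = FALSE])
    }
    if (length(te_neg_idx) > 0) {
      scores[np + te_neg_idx] <- predict(model, negatives[te_neg_idx, , drop = FALSE])
    }
  }
  list(scores = scores, labels = labels,
       fold = c(folds$pos, folds$neg),
       roc = roc_curve(scores, labels))
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores and returns the (FPR, TPR)
#' staircase from (0,0) to (1,1) with the trapezoidal area under the curve.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 (or logical) true classes; both must be present.
#' @return list of class `roc_curve`: `points` (data.frame fpr, tpr,
#'   threshold) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities,
                    threshold = r$thresholds)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  structure(list(points = pts, auc = as.numeric(pROC::auc(r))),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Select the MCC-maximizing probability threshold
#'
#' Scans candidate thresholds at the unique score values (calls are strict:
#' score > threshold) and returns the threshold maximizing the Matthews
#' correlation coefficient; ties resolve to the lowest threshold.
#'
#' @param scores numeric scores.
#' @param labels 0/1 true classes; both present.
#' @return list with `threshold` and `metrics`
#'   (a `classification_metrics` at that threshold).
#' @export
select_threshold_max_mcc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  cand <- sort(unique(scores))
  best <- NULL
  for (t in cand) {
    pred <- scores > t
    m <- classify_metrics(sum(pred & labels == 1), sum(pred & labels == 0),
                          sum(!pred & labels == 0), sum(!pred & labels == 1))
    if (is.null(best) || m$mcc > best$metrics$mcc + 1e-12) {
      best <- list(threshold = t, metrics = m)
    }
  }
  best
}

#' Top-n aggregation of per-model probabilities
#'
#' Applies the pairwise decision rule: a pair is called interacting when any
#' of its first `min(top_n, length)` per-model probabilities (ordered by
#' model rank) is strictly greater than the probability threshold.
#'
#' @param per_model_probs numeric vector of probabilities ordered by model
#'   rank (rank 1 first); non-empty.
#' @param rule a `decision_rule`.
#' @return logical decision.
#' @export
aggregate_topn <- function(per_model_probs, rule = decision_rule()) {
  if (length(per_model_probs) == 0L) stop("empty probability list")
  considered <- per_model_probs[seq_len(min(rule$top_n, length(per_model_probs)))]
  any(considered > rule$probability_threshold)
}

#' Per-pair decisions from a scored feature table
#'
#' Groups a feature table (with a `prob` column of per-model probabilities)
#' by `pair_id`, orders models by rank and applies [aggregate_topn()].
#'
#' @param scored data.frame with `pair_id`, `model_rank`, `prob`.
#' @param rule a `decision_rule`.
#' @return data.frame: pair_id, n_models, max_considered_prob, decision.
#' @export
decide_pairs <- function(scored, rule = decision_rule()) {
  stopifnot(all(c("pair_id", "model_rank", "prob") %in% names(scored)))
  ids <- unique(scored$pair_id)
  rows <- lapply(ids, function(id) {
    sub <- scored[scored$pair_id == id, , drop = FALSE]
    sub <- sub[order(sub$model_rank), , drop = FALSE]
    considered <- sub$prob[seq_len(min(rule$top_n, nrow(sub)))]
    data.frame(pair_id = id, n_models = nrow(sub),
               max_considered_prob = max(considered),
               decision = aggregate_topn(sub$prob, rule))
  })
  do.call(rbind, rows)
}
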