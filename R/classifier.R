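## Three-class random forest and the evaluation protocol.
##
## The forest itself (bootstrap trees, vote-fraction probabilities, OOB
## permutation importance) is the randomForest package; this module owns
## the protocol around it: per-gene pool resampling, stratified repeated
## k-fold cross-validation, Hand-Till multiclass AUC and per-class
## precision/recall bookkeeping.

#' Train the three-class forest
#'
#' @param fm an imputed \code{moi_matrix} with class labels.
#' @param ntree number of trees (default 500).
#' @param mtry features tried per split (default floor(sqrt(p))).
#' @param seed RNG seed; identical seeds give bit-identical forests.
#' @return list of class \code{"moi_model"}: the forest plus training
#'   metadata (feature names, catalogue, encoding map, imputation vector,
#'   seed, tree count).
#' @export
moi_train <- function(fm, ntree = 500, mtry = NULL, seed = 1) {
  if (!inherits(fm, "moi_matrix")) stop_validation("fm must be an moi_matrix")
  if (anyNA(fm$x))
    stop_contract("feature matrix contains missing values; impute first")
  if (is.null(fm$labels)) stop_validation("training requires class labels")
  y <- droplevels(fm$labels)
  if (nlevels(y) < 2)
    stop_validation("training requires at least two classes, got %s",
                    paste(levels(y), collapse = ""))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(fm$x))))
  forest <- with_seed(seed,
    randomForest::randomForest(x = fm$x, y = y, ntree = ntree, mtry = mtry,
                               importance = TRUE, keep.forest = TRUE,
                               keep.inbag = TRUE))
  structure(list(forest = forest, feature_names = colnames(fm$x),
                 catalogue = fm$catalogue, encoding = fm$encoding,
                 fills = fm$fills, classes = levels(y), ntree = ntree,
                 mtry = mtry, seed = seed),
            class = "moi_model")
}

## Vote-fraction class probabilities for an encoded matrix, with the model
## contract checks.  Columns are always benign/dominant/recessive.
model_scores <- function(model, x) {
  miss <- setdiff(model$feature_names, colnames(x))
  extra <- setdiff(colnames(x), model$feature_names)
  if (length(miss) || length(extra))
    stop_contract("feature catalogue mismatch; missing: %s; extra: %s",
                  paste(miss, collapse = ",") , paste(extra, collapse = ","))
  if (anyNA(x)) stop_contract("prediction matrix contains missing values")
  p <- predict(model$forest, x[, model$feature_names, drop = FALSE],
               type = "prob")
  out <- matrix(0, nrow(p), length(MOI_CLASSES),
                dimnames = list(NULL, MOI_CLASSES))
  out[, colnames(p)] <- p
  out
}

## Argmax class call under the severity-ordered tie rule
## (dominant > recessive > benign).  Returns list(call, tie).
call_from_scores <- function(scores) {
  sc <- scores[, MOI_TIE_ORDER, drop = FALSE]
  best <- apply(sc, 1, max)
  tie <- rowSums(sc == best) > 1
  call <- MOI_TIE_ORDER[apply(sc, 1, which.max)]
  list(call = call, tie = tie)
}

#' Precision and recall
#'
#' Precision (positive predictive value) is TP / (TP + FP); recall
#' (sensitivity) is TP / (TP + FN).  A zero denominator yields NA
#' (undefined).
#'
#' @param tp,fp,fn non-negative counts.
#' @return numeric scalar or NA.
#' @export
precision <- function(tp, fp) {
  if (tp < 0 || fp < 0) stop_validation("counts must be non-negative")
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp)
}

#' @rdname precision
#' @export
recall <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop_validation("counts must be non-negative")
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn)
}

## Rank-based two-class AUC of `score` for is_pos vs the rest (ties give
## half credit via midranks).
auc_binary <- function(score, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) stop_validation("a class has zero rows")
  r <- rank(score)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass AUC (Hand-Till construction)
#'
#' Average over unordered class pairs (i, j) of the pairwise AUC computed
#' from the rows of the two classes only: for each pair, the two-class AUC
#' of class i's score column and of class j's score column are averaged.
#' For two classes with complementary scores this reduces to the standard
#' rank-sum AUC.
#'
#' @param scores matrix of per-row class probability vectors with class
#'   column names.
#' @param labels true class per row.
#' @return AUC in [0, 1].
#' @export
multiclass_auc <- function(scores, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop_validation("multiclass AUC needs at least two classes with rows")
  miss <- setdiff(classes, colnames(scores))
  if (length(miss))
    stop_validation("scores lack column(s): %s", paste(miss, collapse = ", "))
  pairs <- utils::combn(classes, 2)
  vals <- apply(pairs, 2, function(pr) {
    rows <- labels %in% pr
    a_ij <- auc_binary(scores[rows, pr[1]], labels[rows] == pr[1])
    a_ji <- auc_binary(scores[rows, pr[2]], labels[rows] == pr[2])
    (a_ij + a_ji) / 2
  })
  mean(vals)
}

## Per-class confusion counts from calls.
confusion_counts <- function(truth, call) {
  truth <- factor(as.character(truth), levels = MOI_CLASSES)
  call <- factor(as.character(call), levels = MOI_CLASSES)
  tab <- table(truth = truth, call = call)
  data.table(class = MOI_CLASSES,
             tp = vapply(MOI_CLASSES, function(c) tab[c, c], numeric(1)),
             fp = vapply(MOI_CLASSES,
                         function(c) sum(tab[, c]) - tab[c, c], numeric(1)),
             fn = vapply(MOI_CLASSES,
                         function(c) sum(tab[c, ]) - tab[c, c], numeric(1)))
}

#' Repeated stratified cross-validation
#'
#' Runs k-fold cross-validation \code{repeats} times.  Each repeat
#' re-draws the per-gene variant selection (when annotation pools are
#' given) and the stratified fold assignment; every selected row is scored
#' exactly once per repeat by a forest trained on the other folds, with
#' the missing-value imputation fitted inside each training fold by
#' default (no leakage).  Per repeat, the pooled out-of-fold scores give
#' the Hand-Till multiclass AUC and per-class precision/recall; per-fold
#' precision/recall are kept as well.
#'
#' @param x an \code{moi_matrix}, or \code{moi_annotations} records
#'   (then \code{labels} is required and per-gene resampling applies).
#' @param labels class labels parallel to the annotation records.
#' @param folds number of folds (default 10).
#' @param repeats number of repeats (default 40).
#' @param per_gene named per-class cap on variants per gene for pool
#'   resampling; default benign 1, dominant 2, recessive 1.
#' @param ntree,mtry forest parameters per fold model.
#' @param seed global seed; drives sampling, folds and forests.
#' @param impute_within_fold fit imputation inside each training fold
#'   (default) or once on the full matrix.
#' @param impute_weights weighting scheme passed to
#'   \code{\link{impute_features}}.
#' @return list of class \code{"moi_cv"}: \code{per_repeat} metrics table,
#'   \code{per_fold} confusion/metrics table, \code{summary}
#'   (min/mean/max per metric and class), \code{settings}.
#' @export
cross_validate <- function(x, labels = NULL, folds = 10, repeats = 40,
                           per_gene = c(benign = 1, dominant = 2,
                                        recessive = 1),
                           ntree = 500, mtry = NULL, seed = 1,
                           impute_within_fold = TRUE,
                           impute_weights = "observed_share") {
  pool_mode <- inherits(x, "moi_annotations")
  if (pool_mode && is.null(labels))
    stop_validation("labels required with annotation records")
  if (!pool_mode && !inherits(x, "moi_matrix"))
    stop_validation("x must be moi_annotations or an moi_matrix")
  if (!pool_mode && is.null(x$labels))
    stop_validation("feature matrix lacks labels")
  per_rep <- vector("list", repeats)
  per_fold <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    if (pool_mode) {
      lab <- assert_classes(labels)
      parts <- list()
      for (i in seq_along(MOI_CLASSES)) {
        cl <- MOI_CLASSES[i]
        recs <- x[as.character(lab) == cl, ]
        if (!nrow(recs)) next
        sel <- sample_training_pool(recs, per_gene[[cl]],
                                    seed = derive_seed(seed, r * 1000L + i))
        sel[, ".class" := cl]
        parts[[cl]] <- sel
      }
      pool <- data.table::rbindlist(parts)
      fm <- encode_features(pool, attr(x, "catalogue"),
                            labels = pool$.class)
    } else fm <- x
    y <- fm$labels
    cls_n <- table(y)
    if (any(cls_n < folds))
      stop_validation("class %s has %d rows, fewer than %d folds",
                      names(cls_n)[which.min(cls_n)], min(cls_n), folds)
    fold_id <- integer(length(y))
    with_seed(derive_seed(seed, r * 1000L + 99L), {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
      }
    })
    scores <- matrix(NA_real_, length(y), length(MOI_CLASSES),
                     dimnames = list(NULL, MOI_CLASSES))
    fold_rows <- list()
    for (k in seq_len(folds)) {
      test <- fold_id == k
      fm_tr <- fm; fm_tr$x <- fm$x[!test, , drop = FALSE]
      fm_tr$labels <- droplevels(y[!test])
      if (impute_within_fold || is.null(fm$fills)) {
        fm_tr <- impute_features(fm_tr, weights = impute_weights)
      }
      model <- moi_train(fm_tr, ntree = ntree, mtry = mtry,
                         seed = derive_seed(seed, r * 1000L + 100L + k))
      x_te <- fm$x[test, , drop = FALSE]
      for (j in seq_len(ncol(x_te))) {
        na <- is.na(x_te[, j])
        if (any(na)) x_te[na, j] <- fm_tr$fills[j]
      }
      sc <- model_scores(model, x_te)
      scores[test, ] <- sc
      cc <- confusion_counts(y[test], call_from_scores(sc)$call)
      cc[, "repeat" := r]; cc[, "fold" := k]
      fold_rows[[k]] <- cc
    }
    calls <- call_from_scores(scores)$call
    conf <- confusion_counts(y, calls)
    prec <- mapply(precision, conf$tp, conf$fp)
    rec <- mapply(recall, conf$tp, conf$fn)
    auc <- multiclass_auc(scores, y)
    row <- data.table(rep = r, auc = auc)
    for (i in seq_along(MOI_CLASSES)) {
      row[, (paste0("precision_", MOI_CLASSES[i])) := prec[i]]
      row[, (paste0("recall_", MOI_CLASSES[i])) := rec[i]]
    }
    per_rep[[r]] <- row
    per_fold[[r]] <- data.table::rbindlist(fold_rows)
  }
  per_rep <- data.table::rbindlist(per_rep)
  per_fold <- data.table::rbindlist(per_fold)
  per_fold[, "precision" := mapply(precision, per_fold$tp, per_fold$fp)]
  per_fold[, "recall" := mapply(recall, per_fold$tp, per_fold$fn)]
  metric_cols <- setdiff(names(per_rep), "rep")
  summ <- data.table::rbindlist(lapply(metric_cols, function(mc) {
    v <- per_rep[[mc]]
    data.table(metric = mc, min = min(v, na.rm = TRUE),
               mean = mean(v, na.rm = TRUE), max = max(v, na.rm = TRUE))
  }))
  structure(list(per_repeat = per_rep, per_fold = per_fold, summary = summ,
                 settings = list(folds = folds, repeats = repeats,
                                 per_gene = if (pool_mode) per_gene,
                                 ntree = ntree, seed = seed,
                                 impute_within_fold = impute_within_fold)),
            class = "moi_cv")
}

#' Out-of-bag permutation importance
#'
#' For each feature: the OOB prediction error of every tree is compared
#' with the OOB error after permuting the feature; the per-tree
#' differences are averaged over trees and normalized by their standard
#' deviation (a zero SD leaves the mean unnormalized, so a constant
#' feature scores exactly 0).  Computed by the forest during training.
#'
#' @param model an \code{moi_model} trained with this package.
#' @return data.frame with \code{feature} and normalized
#'   \code{importance} (mean decrease in accuracy), sorted decreasing.
#' @export
permutation_importance <- function(model) {
  if (!inherits(model, "moi_model")) stop_validation("not an moi_model")
  imp <- randomForest::importance(model$forest, type = 1, scale = TRUE)
  out <- data.frame(feature = rownames(imp),
                    importance = imp[, "MeanDecreaseAccuracy"],
                    row.names = NULL)
  out[order(-out$importance), ]
}

#' Save / load a trained model archive
#'
#' @param model an \code{moi_model}.
#' @param path archive path (.rds).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  m <- readRDS(path)
  if (!inherits(m, "moi_model")) stop_validation("%s is not a model archive", path)
  m
}
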