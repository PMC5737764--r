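## Applying a trained model and evaluation bookkeeping.

#' Score variants with a trained model
#'
#' Reduces annotation records to the longest transcript per variant,
#' encodes them under the model's catalogue and encoding map, fills
#' missing values with the model's training-derived imputation vector and
#' emits one prediction per variant: three class probabilities (summing to
#' one), a class call (argmax; exact ties broken dominant > recessive >
#' benign and flagged in the \code{tie} column) and a pathogenicity call.
#'
#' @param model an \code{moi_model}.
#' @param records \code{moi_annotations} rows, or an already-encoded
#'   \code{moi_matrix}.
#' @param pathogenicity_rule \code{"argmax"} (pathogenic iff the class
#'   call is not benign, default) or \code{"score_sum"} (pathogenic iff
#'   dominant + recessive scores exceed 0.5).
#' @return data.table of class \code{"moi_predictions"} with columns
#'   chrom, pos, ref, alt, gene, transcript, benign_score, dominant_score,
#'   recessive_score, class_call, pathogenicity_call, tie.
#' @export
score_variants <- function(model, records,
                           pathogenicity_rule = c("argmax", "score_sum")) {
  pathogenicity_rule <- match.arg(pathogenicity_rule)
  if (inherits(records, "moi_matrix")) {
    fm <- records
    if (is.null(fm$fills) && anyNA(fm$x))
      fm <- impute_features(fm, fills = model$fills)
    ids <- fm$ids
  } else {
    recs <- select_longest(records)
    fm <- encode_features(recs, model$catalogue)
    fm <- impute_features(fm, fills = model$fills)
    ids <- fm$ids
  }
  sc <- model_scores(model, fm$x)
  cl <- call_from_scores(sc)
  if (any(cl$tie))
    message(sum(cl$tie), " tied score vector(s) broken by severity order")
  pathogenic <- if (pathogenicity_rule == "argmax")
    cl$call != "benign"
  else sc[, "dominant"] + sc[, "recessive"] > 0.5
  out <- data.table::as.data.table(ids)
  out[, "benign_score" := sc[, "benign"]]
  out[, "dominant_score" := sc[, "dominant"]]
  out[, "recessive_score" := sc[, "recessive"]]
  out[, "class_call" := cl$call]
  out[, "pathogenicity_call" := ifelse(pathogenic, "pathogenic", "benign")]
  out[, "tie" := cl$tie]
  structure(out, class = c("moi_predictions", class(out)))
}

#' Accuracy bookkeeping for validation-style datasets
#'
#' Given per-variant truth labels (benign / dominant / recessive),
#' reports pathogenicity accuracy (fraction of variants whose
#' pathogenic-vs-benign call is correct; any pathogenic class counts as
#' pathogenic truth) and inheritance accuracy (fraction of
#' dominant/recessive-truth variants whose class call matches exactly),
#' both as k/n and percent.
#'
#' @param predictions \code{moi_predictions} table.
#' @param truth class labels parallel to the prediction rows.
#' @return data.table with columns metric, k, n, percent (percent NA when
#'   n = 0).
#' @export
evaluate_calls <- function(predictions, truth) {
  if (nrow(predictions) != length(truth))
    stop_validation("truth must cover all predictions (%d vs %d)",
                    length(truth), nrow(predictions))
  truth <- as.character(assert_classes(truth))
  path_truth <- ifelse(truth == "benign", "benign", "pathogenic")
  k_path <- sum(predictions$pathogenicity_call == path_truth)
  n_path <- length(truth)
  inh <- truth %in% c("dominant", "recessive")
  k_inh <- sum(predictions$class_call[inh] == truth[inh])
  n_inh <- sum(inh)
  data.table(metric = c("pathogenicity", "inheritance"),
             k = c(k_path, k_inh), n = c(n_path, n_inh),
             percent = c(100 * k_path / n_path,
                         if (n_inh) 100 * k_inh / n_inh else NA_real_))
}

#' Compare two score distributions
#'
#' Two-sided Wilcoxon rank-sum test between two samples of class scores
#' (e.g. dominant-class scores of dominant-truth versus recessive-truth
#' variants).
#'
#' @param scores_a,scores_b non-empty numeric samples.
#' @return list with \code{statistic}, \code{p_value} and
#'   \code{degenerate} (TRUE when every value in both samples is tied, in
#'   which case p_value is NA).
#' @export
compare_score_distributions <- function(scores_a, scores_b) {
  if (!length(scores_a) || !length(scores_b))
    stop_validation("both score groups must be non-empty")
  if (length(unique(c(scores_a, scores_b))) == 1L)
    return(list(statistic = length(scores_a) * length(scores_b) / 2,
                p_value = NA_real_, degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(scores_a, scores_b,
                                            alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       degenerate = FALSE)
}

#' Write / read a prediction table
#'
#' Tab-delimited with the columns of \code{\link{score_variants}}.
#'
#' @param predictions \code{moi_predictions} table.
#' @param path file path.
#' @export
write_predictions <- function(predictions, path) {
  dt <- data.table::copy(data.table::as.data.table(predictions))
  dt[, "tie" := as.integer(dt$tie)]
  write_tsv(dt, path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  dt <- read_tsv(path)
  dt[, "tie" := as.logical(dt$tie)]
  structure(dt, class = c("moi_predictions", class(dt)))
}
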