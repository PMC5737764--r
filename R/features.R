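## Training-pool assembly and the numeric feature matrix.

## One record per variant: the longest transcript containing the variant,
## ties toward the lexicographically smallest transcript id.
select_longest <- function(records) {
  dt <- data.table::as.data.table(records)
  key <- paste(dt$chrom, dt$pos, dt$ref, dt$alt)
  ord <- order(key, -dt$transcript_length, dt$transcript)
  dt <- dt[ord, ]
  dt[!duplicated(paste(dt$chrom, dt$pos, dt$ref, dt$alt)), ]
}

#' Sample a per-gene training pool
#'
#' Restricts a class-labelled pool of annotation records to one record per
#' variant (the longest transcript containing it) and then draws at most
#' \code{per_gene} variants per gene uniformly at random, so genes with
#' many curated mutations cannot dominate training.  One variant per gene
#' is the benign/recessive rule; two per gene is the dominant-class rule.
#'
#' @param records \code{moi_annotations} rows (must carry \code{gene}).
#' @param per_gene maximum variants kept per gene (>= 1).
#' @param seed RNG seed; identical seeds reproduce the selection.
#' @return the selected records (all transcripts reduced to the longest).
#' @export
sample_training_pool <- function(records, per_gene, seed) {
  if (!nrow(records)) stop_validation("empty training pool")
  if (!is.numeric(per_gene) || per_gene < 1)
    stop_validation("per_gene must be >= 1")
  dt <- select_longest(records)
  with_seed(seed, {
    ## scramble, then keep the first min(per_gene, n) rows of each gene
    dt <- dt[sample.int(nrow(dt)), ]
    idx <- stats::ave(seq_len(nrow(dt)), dt$gene, FUN = seq_along)
    dt <- dt[idx <= per_gene, ]
  })
  data.table::setorder(dt, chrom, pos, ref, alt)
  dt
}

#' Encode annotation records to a numeric feature matrix
#'
#' Numeric features pass through unchanged.  Flags and two-level
#' categorical features become a single -1/+1 column (first declared level
#' maps to +1); categorical features with more than two levels expand to
#' one -1/+1 column per level.  Missing values stay missing until
#' \code{\link{impute_features}}.
#'
#' @param records \code{moi_annotations} rows.
#' @param catalogue feature catalogue shared by all records.
#' @param labels optional class labels (benign/dominant/recessive).
#' @return list of class \code{"moi_matrix"}: \code{x} numeric matrix,
#'   \code{ids} identification columns, \code{labels}, \code{catalogue},
#'   \code{encoding} (level-to-value maps), \code{fills} (NULL until
#'   imputed).
#' @export
encode_features <- function(records, catalogue = attr(records, "catalogue"),
                            labels = NULL) {
  validate_catalogue(catalogue)
  dt <- data.table::as.data.table(records)
  miss <- setdiff(catalogue$name, names(dt))
  if (length(miss))
    stop_validation("records lack catalogue feature(s): %s",
                    paste(head(miss, 5), collapse = ", "))
  cols <- list(); encoding <- list()
  for (i in seq_len(nrow(catalogue))) {
    f <- catalogue$name[i]; tp <- catalogue$type[i]
    vals <- dt[[f]]
    if (tp == "numeric") {
      cols[[f]] <- as.numeric(vals)
    } else if (tp == "flag") {
      encoding[[f]] <- c("TRUE" = 1, "FALSE" = -1)
      cols[[f]] <- ifelse(is.na(vals), NA_real_, ifelse(as.logical(vals), 1, -1))
    } else {
      lv <- strsplit(catalogue$levels[i], ",", fixed = TRUE)[[1]]
      obs <- setdiff(unique(vals[!is.na(vals)]), lv)
      if (length(obs))
        stop_validation("feature %s: unknown level '%s'", f, obs[1])
      if (length(lv) == 2) {
        enc <- c(1, -1); names(enc) <- lv
        encoding[[f]] <- enc
        cols[[f]] <- unname(enc[vals])
      } else {
        for (l in lv) {
          nm <- paste0(f, "_", l)
          enc <- c(1, -1); names(enc) <- c(l, paste0("not_", l))
          encoding[[nm]] <- enc
          cols[[nm]] <- ifelse(is.na(vals), NA_real_, ifelse(vals == l, 1, -1))
        }
      }
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  id_cols <- intersect(c("chrom", "pos", "ref", "alt", "gene", "transcript",
                         "row_id"), names(dt))
  if (!is.null(labels)) labels <- assert_classes(labels)
  structure(list(x = x, ids = as.data.frame(dt[, id_cols, with = FALSE]),
                 labels = labels, catalogue = catalogue,
                 encoding = encoding, fills = NULL),
            class = "moi_matrix")
}

#' Impute missing feature values with three-class weighted averages
#'
#' The fill value of a feature is the weighted average of its per-class
#' means, each class weighted by its share of the rows in which the feature
#' is observed (\code{weights = "observed_share"}, the default; equivalent
#' to the pooled mean over observed rows).  \code{weights = "equal"}
#' averages the class means with equal weight.  Fitted fills are stored in
#' the matrix so prediction-time records reuse training fills; observed
#' values are never altered.
#'
#' @param fm an \code{moi_matrix}.
#' @param weights weighting scheme for the class means.
#' @param fills optional previously fitted fill vector (prediction time);
#'   when supplied, labels are not needed and no fitting happens.
#' @return the matrix with no missing values and \code{fills} recorded.
#' @export
impute_features <- function(fm, weights = c("observed_share", "equal"),
                            fills = NULL) {
  weights <- match.arg(weights)
  x <- fm$x
  if (is.null(fills)) {
    if (is.null(fm$labels))
      stop_validation("imputation fitting requires class labels")
    lab <- fm$labels
    fills <- numeric(ncol(x)); names(fills) <- colnames(x)
    all_missing <- colnames(x)[colSums(!is.na(x)) == 0]
    if (length(all_missing))
      stop_validation("feature(s) missing in every row: %s",
                      paste(all_missing, collapse = ", "))
    for (j in seq_len(ncol(x))) {
      obs <- !is.na(x[, j])
      cls <- lab[obs]
      means <- tapply(x[obs, j], cls, mean)
      counts <- table(cls)[names(means)]
      keep <- !is.na(means)
      w <- if (weights == "observed_share")
        as.numeric(counts[keep]) else rep(1, sum(keep))
      fills[j] <- sum(w * means[keep]) / sum(w)
    }
  } else {
    miss <- setdiff(colnames(x), names(fills))
    if (length(miss))
      stop_contract("imputation vector lacks feature(s): %s",
                    paste(head(miss, 5), collapse = ", "))
    fills <- fills[colnames(x)]
  }
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    if (any(na)) x[na, j] <- fills[j]
  }
  fm$x <- x
  fm$fills <- fills
  fm
}
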