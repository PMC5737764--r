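#' @import data.table
#' @importFrom stats rnorm rbinom rpois runif rlnorm plogis qlogis sd wilcox.test
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Error conditions map to CLI exit codes: validation/parse -> 2, contract -> 3.
stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("varmoi_validation_error", "varmoi_error")))
}

stop_contract <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("varmoi_contract_error", "varmoi_error")))
}

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_validation("seed must be a single finite number, got %s",
                    deparse(substitute(seed)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Per-component seed derivation from one global seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

MOI_CLASSES <- c("benign", "dominant", "recessive")

## Severity-ordered preference used for argmax tie-breaking.
MOI_TIE_ORDER <- c("dominant", "recessive", "benign")

assert_classes <- function(labels) {
  bad <- setdiff(unique(as.character(labels)), MOI_CLASSES)
  if (length(bad))
    stop_validation("unknown class label(s): %s (expected %s)",
                    paste(bad, collapse = ", "),
                    paste(MOI_CLASSES, collapse = "/"))
  factor(as.character(labels), levels = MOI_CLASSES)
}

## Missing marker in all tab-delimited files.
NA_TOKEN <- "."

fmt_num <- function(x) {
  out <- ifelse(is.na(x), NA_TOKEN, format(x, digits = 15, scientific = FALSE,
                                           trim = TRUE))
  out
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = NA_TOKEN,
                    data.table = TRUE, ...)
}

write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", na = NA_TOKEN, quote = FALSE)
  invisible(path)
}
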