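# Calling positive binders from array fluorescence. Background (non-binding)
# RFUs on a glycan microarray are approximately log-normal and binders are a
# small minority, so the median and the median absolute deviation (MAD) of
# the log-transformed values estimate the background location and spread
# robustly; spots far above the background on that scale are binders.

#' Log-transform RFU values
#'
#' Applies `x_i = log10(RFU_i - min(RFU) + 1)`, anchoring the minimum spot at
#' zero before taking logs.
#'
#' @param values Non-negative, finite RFU vector.
#' @return Transformed vector with minimum 0.
#' @export
transform_rfu <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("RFU values must be finite numbers", call. = FALSE)
  }
  log10(values - min(values) + 1)
}

degenerate_error <- function() {
  stop(errorCondition(
    paste("MAD of transformed RFUs is zero; the distribution is degenerate.",
          "Assign binding thresholds manually (see",
          "assign_binding_classes(pos_threshold=, int_threshold=))."),
    class = "degenerate_distribution_error"
  ))
}

#' Modified z-scores from MAD
#'
#' Computes `M_i = 0.6745 * (x_i - median(x)) / MAD` where
#' `MAD = median(|x_i - median(x)|)`. The factor 0.6745 is the standard
#' normal quantile at the 75th percentile, which calibrates M against an
#' ordinary z-score when the background is roughly normal.
#'
#' @param x Transformed values (see [transform_rfu()]).
#' @return Numeric vector of modified z-scores.
#' @export
modified_z_scores <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("input must be finite numbers", call. = FALSE)
  }
  med <- stats::median(x)
  mad_val <- stats::median(abs(x - med))
  if (mad_val == 0) degenerate_error()
  0.6745 * (x - med) / mad_val
}

#' Assign binding classes from RFU values
#'
#' Transforms RFUs ([transform_rfu()]), computes modified z-scores
#' ([modified_z_scores()]) and classifies each spot: positive for
#' `M > pos_threshold`, intermediate for `int_threshold < M <= pos_threshold`,
#' negative otherwise. Intermediate binders are conventionally discarded
#' before motif mining and training, since their class is ambiguous.
#'
#' @param values RFU vector (length at least 3).
#' @param pos_threshold Positive-binder threshold on the modified z-score
#'   (default 3.5).
#' @param int_threshold Intermediate threshold (default 1.5).
#' @return A factor with levels `negative < intermediate < positive`;
#'   attributes `x` (transformed values) and `m` (modified z-scores).
#' @export
assign_binding_classes <- function(values, pos_threshold = 3.5, int_threshold = 1.5) {
  if (length(values) < 3L) {
    stop("need at least 3 spots to estimate the background", call. = FALSE)
  }
  stopifnot(pos_threshold > int_threshold)
  x <- transform_rfu(values)
  m <- modified_z_scores(x)
  cls <- ifelse(m > pos_threshold, "positive",
                ifelse(m > int_threshold, "intermediate", "negative"))
  out <- factor(cls, levels = c("negative", "intermediate", "positive"),
                ordered = TRUE)
  attr(out, "x") <- x
  attr(out, "m") <- m
  out
}

#' Stratified train/test split
#'
#' Splits spot indices into train and test sets preserving the
#' positive:negative ratio. Intermediate binders must already have been
#' removed.
#'
#' @param classes Factor or character vector of `"positive"`/`"negative"`
#'   labels (no intermediates).
#' @param test_fraction Fraction of each class routed to the test set.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(classes, test_fraction = 0.2, seed = 1L) {
  cls <- as.character(classes)
  if (any(cls == "intermediate")) {
    stop("remove intermediate binders before splitting", call. = FALSE)
  }
  stopifnot(test_fraction >= 0, test_fraction < 1)
  if (sum(cls == "positive") < 2L) {
    stop("need at least 2 positive binders to stratify", call. = FALSE)
  }
  test <- integer(0)
  with_seed(seed, {
    for (lv in c("negative", "positive")) {
      idx <- which(cls == lv)
      k <- round(test_fraction * length(idx))
      if (k > 0L) test <- c(test, sample(idx, k))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(cls), test), test = test)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# derive a stage-specific seed below 2^31 from a root seed
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}
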