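# Final interpretable model: weighted logistic regression on the selected
# motif features with a small amount of L2 regularisation (cost
# -C * sum(alpha_t ll) + ||w||_2 with C = 100), plus ROC/AUC evaluation.

#' Train the final L2-regularised logistic model
#'
#' @param X Binary motif-occurrence matrix over the training glycans
#'   (columns in motif order).
#' @param y Binary labels.
#' @param C Inverse regularisation strength (default 100, i.e. weak
#'   regularisation).
#' @return List with `coef`, `intercept` and `C`. With zero columns an
#'   intercept-only model is returned (with a warning).
#' @export
train_final_model <- function(X, y, C = 100) {
  if (length(unique(y)) < 2L) stop("both classes required for training", call. = FALSE)
  if (is.null(dim(X)) || ncol(X) == 0L) {
    warning("no motifs selected; training an intercept-only model")
    w <- class_weights(y)
    return(list(coef = numeric(0),
                intercept = stats::qlogis(sum(w * y) / sum(w)), C = C))
  }
  fit <- fit_weighted_logistic(X, y, C, alpha = 0)
  list(coef = fit$coef, intercept = fit$intercept, C = C)
}

logistic_score <- function(model, X) {
  eta <- rep(model$intercept, nrow(X))
  if (length(model$coef)) eta <- eta + as.numeric(X %*% model$coef)
  stats::plogis(eta)
}

#' Predict binding probabilities for glycans
#'
#' Augments each glycan with restricted-linkage nodes using the capability
#' map frozen at training time, evaluates motif containment, and applies the
#' fitted logistic model.
#'
#' @param model A `trained_model` from [run_pipeline()] or
#'   [fit_motif_model()].
#' @param glycans List of `glycan_tree` objects or a character vector of CFG
#'   glycan strings.
#' @return Numeric vector of binding probabilities in (0, 1). Unparseable
#'   strings yield `NA` with a warning; the rest are still scored.
#' @export
predict_binding <- function(model, glycans) {
  stopifnot(inherits(model, "trained_model"))
  if (is.character(glycans)) {
    parsed <- lapply(glycans, function(s) {
      tryCatch(parse_cfg_glycan(s), glycan_parse_error = function(e) e)
    })
  } else {
    parsed <- glycans
  }
  bad <- vapply(parsed, inherits, logical(1), what = "condition")
  if (any(bad)) {
    warning(sprintf("failed to parse %d glycan(s): %s", sum(bad),
                    paste(which(bad), collapse = ", ")))
  }
  out <- rep(NA_real_, length(parsed))
  if (any(!bad)) {
    aug <- lapply(parsed[!bad], add_restricted_linkages, cap = model$capability_map)
    mat <- compute_feature_matrix(aug, model$motifs)
    out[!bad] <- logistic_score(model, mat)
  }
  out
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores and reports the ROC points and
#' the trapezoidal area under the curve (equivalently the normalised
#' Mann-Whitney U statistic; score ties contribute half).
#'
#' @param labels Binary labels with both classes present.
#' @param scores Finite numeric scores, larger meaning more positive.
#' @return List of class `evaluation_result` with elements `roc` (data frame
#'   `fpr`, `tpr`, `threshold`), `auc` and `confusion` (counts at probability
#'   0.5).
#' @export
roc_auc <- function(labels, scores) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  co <- pROC::coords(r, x = "all", ret = c("threshold", "specificity", "sensitivity"),
                     transpose = FALSE)
  roc_df <- data.frame(fpr = 1 - co$specificity, tpr = co$sensitivity,
                       threshold = co$threshold)
  roc_df <- roc_df[order(roc_df$fpr, roc_df$tpr), , drop = FALSE]
  rownames(roc_df) <- NULL
  pred <- as.integer(scores > 0.5)
  structure(
    list(roc = roc_df, auc = as.numeric(pROC::auc(r)),
         confusion = c(tp = sum(pred == 1 & y == 1), tn = sum(pred == 0 & y == 0),
                       fp = sum(pred == 1 & y == 0), fn = sum(pred == 0 & y == 1))),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation: AUC %.4f over %d ROC points>\n", x$auc, nrow(x$roc)))
  invisible(x)
}
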