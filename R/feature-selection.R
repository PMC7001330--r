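# Second-stage motif selection: anomeric augmentation of the mRMR picks,
# a second mRMR round over the pooled features, sparsity-inducing weighted
# L1 logistic regression with the regularisation strength tuned by
# cross-validated Matthews correlation, and step-wise removal of perfectly
# collinear features by variance inflation factors.

#' Augment motifs with parent-edge anomer constraints
#'
#' For each motif, emits up to three additional variants requiring the edge
#' entering the motif root to be alpha-linked, beta-linked, or merely present
#' (alpha/beta). Variants that occur in no glycan of the collection are
#' dropped; the unconstrained originals are always retained.
#'
#' @param motifs Character vector of canonical codes, or anything accepted by
#'   [compute_feature_matrix()] with unconstrained parent anomer.
#' @param glycans List of augmented `glycan_tree` objects (the training
#'   collection).
#' @return A data frame with columns `code` and `parent_anomer` (NA for the
#'   originals), deduplicated; the occurrence matrix of all retained motifs
#'   over `glycans` is attached as attribute `matrix`.
#' @export
augment_with_parent_anomer <- function(motifs, glycans) {
  spec <- as_motif_spec(motifs)
  stopifnot(all(is.na(spec$parent_anomer)))
  gkids <- lapply(glycans, tree_children)
  n <- length(glycans)
  pool_code <- character(0)
  pool_pan <- character(0)
  cols <- list()
  for (j in seq_len(nrow(spec))) {
    m <- decode_canonical_code(spec$code[j])
    mk <- tree_children(m)
    occ <- integer(n)
    fa <- integer(n)
    fb <- integer(n)
    flink <- integer(n)
    for (i in seq_len(n)) {
      g <- glycans[[i]]
      roots <- motif_root_matches(g, m, gkids[[i]], mk)
      if (!length(roots)) next
      occ[i] <- 1L
      par <- g$parent[roots]
      an <- ifelse(par == 0L, "none", substr(g$elab[roots], 1L, 1L))
      fa[i] <- as.integer(any(an == "a"))
      fb[i] <- as.integer(any(an == "b"))
      flink[i] <- as.integer(any(an != "none"))
    }
    pool_code <- c(pool_code, spec$code[j])
    pool_pan <- c(pool_pan, NA_character_)
    cols <- c(cols, list(occ))
    for (variant in list(list("a", fa), list("b", fb), list("ab", flink))) {
      if (any(variant[[2]] > 0L)) {
        pool_code <- c(pool_code, spec$code[j])
        pool_pan <- c(pool_pan, variant[[1]])
        cols <- c(cols, list(variant[[2]]))
      }
    }
  }
  keep <- !duplicated(paste(pool_code, pool_pan))
  out <- data.frame(code = pool_code[keep], parent_anomer = pool_pan[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  mat <- do.call(cbind, cols[keep])
  colnames(mat) <- motif_spec_text(out)
  attr(out, "matrix") <- mat
  out
}

#' Second mRMR round over original and anomer-augmented motifs
#'
#' Pools the first-round motifs with their parent-anomer variants, recomputes
#' the occurrence matrix and reruns [mrmr_select()] with the same feature
#' budget.
#'
#' @param pool Data frame from [augment_with_parent_anomer()].
#' @param glycans List of augmented `glycan_tree` objects for the training
#'   set (ignored when `pool` already carries its occurrence matrix).
#' @param y Binary class labels.
#' @param n_features mRMR feature budget.
#' @return The pooled motif data frame restricted to the selected features,
#'   in selection order, with columns `relevance` and the occurrence matrix
#'   as attribute `matrix`.
#' @export
second_round_mrmr <- function(pool, glycans, y, n_features = 10L) {
  mat <- attr(pool, "matrix")
  if (is.null(mat)) mat <- compute_feature_matrix(glycans, pool)
  sel <- mrmr_select(mat, y, n_features)
  out <- pool[sel, , drop = FALSE]
  out$relevance <- attr(sel, "relevance")
  rownames(out) <- NULL
  attr(out, "matrix") <- mat[, sel, drop = FALSE]
  out
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the value
#' defined as 0 when any marginal is zero.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return A number in `[-1, 1]`.
#' @export
mcc <- function(tp, tn, fp, fn) {
  denom <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

mcc_at_half <- function(y, prob) {
  pred <- as.integer(prob > 0.5)
  mcc(sum(pred == 1 & y == 1), sum(pred == 0 & y == 0),
      sum(pred == 1 & y == 0), sum(pred == 0 & y == 1))
}

# class weights alpha_c = N / (2 * N_c), one entry per sample; they sum to N
class_weights <- function(y) {
  n <- length(y)
  n1 <- sum(y == 1)
  n0 <- n - n1
  ifelse(y == 1, n / (2 * n1), n / (2 * n0))
}

# weighted penalised logistic fit via glmnet at the lambda corresponding to
# the cost  -C * sum_i alpha_i * ll_i + ||w||_p  (lambda = 1 / (N * C)).
# glmnet needs >= 2 columns; a zero dummy column pads narrow problems.
fit_weighted_logistic <- function(X, y, C, alpha, weights = class_weights(y),
                                  lambda_path = NULL) {
  n <- nrow(X)
  pad <- ncol(X) < 2L
  Xf <- if (pad) cbind(X, `..pad` = 0) else X
  lam <- 1 / (n * C)
  path <- sort(unique(c(lambda_path, lam)), decreasing = TRUE)
  fit <- glmnet::glmnet(Xf, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = alpha, lambda = path, weights = weights,
                        standardize = FALSE, thresh = 1e-10, maxit = 1e6)
  cf <- as.numeric(stats::coef(fit, s = lam, exact = FALSE))
  list(intercept = cf[1], coef = cf[seq_len(ncol(X)) + 1L])
}

#' L1-regularised logistic feature selection
#'
#' Fits weighted L1 logistic regressions over a grid of regularisation
#' strengths `C` (cost `-C * sum(alpha_t ll) + ||w||_1`), scores each `C` by
#' mean Matthews correlation (probability cut-off 0.5) over stratified
#' cross-validation folds, refits on the full data at the best `C` (ties go
#' to the smallest, i.e. most regularised, `C`) and keeps the features with
#' non-zero coefficients.
#'
#' @param X Binary feature matrix.
#' @param y Binary labels (both classes present, at least 2 samples each).
#' @param c_grid Grid of `C` values; default 100 log-spaced values in
#'   `[1e-4, 1e4]`.
#' @param folds Number of CV folds.
#' @param seed Integer seed controlling fold assignment.
#' @return List with `selected` (column indices), `coef`, `intercept`,
#'   `c_best`, `cv_mcc` (mean MCC per grid value) and `fold_id`.
#' @export
l1_select <- function(X, y, c_grid = default_c_grid(), folds = 5L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (sum(y == 1) < 2L || sum(y == 0) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  c_grid <- sort(c_grid)
  fold_id <- stratified_folds(y, folds, seed)
  cv_mcc <- matrix(NA_real_, nrow = folds, ncol = length(c_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    n_tr <- nrow(Xtr)
    lam <- sort(1 / (n_tr * c_grid), decreasing = TRUE)
    pad <- ncol(Xtr) < 2L
    Xf <- if (pad) cbind(Xtr, `..pad` = 0) else Xtr
    fit <- tryCatch(
      glmnet::glmnet(Xf, factor(ytr, levels = c(0, 1)), family = "binomial",
                     alpha = 1, lambda = lam, weights = class_weights(ytr),
                     standardize = FALSE, thresh = 1e-10, maxit = 1e6),
      error = function(e) {
        warning(sprintf("L1 fit failed in fold %d: %s", f, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(fit)) next
    Xv <- X[!tr, , drop = FALSE]
    if (pad) Xv <- cbind(Xv, 0)
    for (ci in seq_along(c_grid)) {
      prob <- tryCatch(
        as.numeric(stats::predict(fit, Xv, s = 1 / (n_tr * c_grid[ci]),
                                  type = "response")),
        error = function(e) NULL
      )
      if (is.null(prob)) next
      cv_mcc[f, ci] <- mcc_at_half(y[!tr], prob)
    }
  }
  mean_mcc <- colMeans(cv_mcc, na.rm = TRUE)
  best <- which(mean_mcc >= max(mean_mcc) - 1e-12)[1L]  # smallest C on ties
  c_best <- c_grid[best]
  full <- fit_weighted_logistic(X, y, c_best, alpha = 1,
                                lambda_path = 1 / (nrow(X) * c_grid))
  selected <- which(abs(full$coef) > 1e-8)
  list(selected = selected, coef = full$coef[selected],
       intercept = full$intercept, c_best = c_best,
       cv_mcc = stats::setNames(mean_mcc, signif(c_grid, 6)),
       fold_id = fold_id)
}

#' @rdname l1_select
#' @export
default_c_grid <- function() 10^seq(-4, 4, length.out = 100)

stratified_folds <- function(y, k, seed) {
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (lv in unique(y)) {
      idx <- which(y == lv)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold_id
}

#' Prune perfectly collinear features by variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of feature j on the remaining features plus an intercept.
#' While any VIF is infinite (`R^2 >= 1 - 1e-10`), the offending feature
#' with the lowest mRMR relevance is removed and VIFs are recomputed. The
#' last remaining feature is never removed.
#'
#' @param X Feature matrix restricted to the candidate features.
#' @param relevance Per-feature relevance used to order removals (lowest
#'   removed first); defaults to equal relevance.
#' @return List with `keep` (column indices into `X`) and `vif` (finite VIFs
#'   for the kept features).
#' @export
vif_prune <- function(X, relevance = rep(0, ncol(X))) {
  stopifnot(is.matrix(X), ncol(X) >= 1L, length(relevance) == ncol(X))
  keep <- seq_len(ncol(X))
  repeat {
    vifs <- vapply(seq_along(keep), function(j) {
      xj <- X[, keep[j]]
      tss <- sum((xj - mean(xj))^2)
      if (tss == 0) return(Inf)
      others <- cbind(1, X[, keep[-j], drop = FALSE])
      res <- stats::lm.fit(others, xj)$residuals
      r2 <- 1 - sum(res^2) / tss
      if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
    }, numeric(1))
    inf <- which(is.infinite(vifs))
    if (length(inf) == 0L || length(keep) == 1L) {
      return(list(keep = keep, vif = vifs))
    }
    drop_j <- inf[order(relevance[keep[inf]], keep[inf])][1L]
    keep <- keep[-drop_j]
  }
}
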