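# Minimum-redundancy maximum-relevance feature selection over binary motif
# features. Relevance and redundancy are plug-in mutual information of
# empirical 2x2 joint distributions, in bits; selection is greedy on the
# difference criterion (relevance minus mean redundancy with the already
# selected features).

#' Mutual information of two binary vectors
#'
#' Plug-in estimate from the empirical 2x2 joint distribution, in bits.
#' Zero when either variable is constant.
#'
#' @param f,y Binary (0/1 or logical) vectors of equal length.
#' @return A non-negative number.
#' @export
mutual_information_binary <- function(f, y) {
  f <- as.integer(f)
  y <- as.integer(y)
  if (length(f) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(f)
  if (n == 0L) stop("empty vectors", call. = FALSE)
  n11 <- sum(f & y)
  n10 <- sum(f) - n11
  n01 <- sum(y) - n11
  n00 <- n - n11 - n10 - n01
  mi_from_counts(n11, n10, n01, n00)
}

mi_from_counts <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  pf <- (n11 + n10) / n
  py <- (n11 + n01) / n
  term <- function(nab, pa, pb) {
    p <- nab / n
    ifelse(p > 0, p * log2(p / (pa * pb)), 0)
  }
  term(n11, pf, py) + term(n10, pf, 1 - py) +
    term(n01, 1 - pf, py) + term(n00, 1 - pf, 1 - py)
}

# vectorised MI of every column of X against y
mi_columns <- function(X, y) {
  y <- as.numeric(y)
  n <- nrow(X)
  s1 <- as.numeric(crossprod(X, y))        # n11 per column
  cs <- colSums(X)
  mi_from_counts(s1, cs - s1, sum(y) - s1, n - cs - sum(y) + s1)
}

# vectorised MI of every column of X against one reference column xj
mi_columns_pair <- function(X, xj) mi_columns(X, xj)

#' Greedy mRMR feature selection
#'
#' The first pick maximises mutual information with the class labels; each
#' later pick maximises relevance minus the mean mutual information with the
#' features already selected. Ties (scores within `1e-12`) resolve to the
#' lowest column index, making the output deterministic.
#'
#' @param X Binary feature matrix (rows = glycans, columns = motifs).
#' @param y Binary class labels.
#' @param n_features Number of features to select (capped at `ncol(X)`).
#' @return Integer vector of column indices in selection order; attribute
#'   `relevance` holds MI(f; y) for the selected columns.
#' @export
mrmr_select <- function(X, y, n_features = 10L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), ncol(X) >= 1L)
  if (n_features < 1L) stop("n_features must be at least 1", call. = FALSE)
  k <- min(as.integer(n_features), ncol(X))
  relevance <- mi_columns(X, y)
  pick_max <- function(score, excluded) {
    score[excluded] <- -Inf
    top <- max(score)
    which(score >= top - 1e-12)[1L]
  }
  selected <- pick_max(relevance, integer(0))
  red_sum <- rep(0, ncol(X))
  while (length(selected) < k) {
    red_sum <- red_sum + mi_columns_pair(X, X[, selected[length(selected)]])
    score <- relevance - red_sum / length(selected)
    selected <- c(selected, pick_max(score, selected))
  }
  structure(selected, relevance = relevance[selected])
}
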