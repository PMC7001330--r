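# End-to-end orchestration: binding assignment -> split -> restricted-linkage
# augmentation -> frequent subtree mining -> mRMR -> anomeric augmentation ->
# mRMR -> L1 selection -> VIF pruning -> final L2 model -> evaluation.

default_pipeline_config <- function() {
  list(
    pos_threshold = 3.5,
    int_threshold = 1.5,
    global_min_support = 0.05,
    positive_min_support = 0.40,
    mrmr_features = 10L,
    c_grid = default_c_grid(),
    l1_folds = 5L,
    final_C = 100,
    test_fraction = 0.2,
    max_nodes = 12L
  )
}

#' Fit a motif model on labelled, augmented glycans
#'
#' The selection cascade on a prepared training set: mine candidate motifs
#' (global + positive-set supports), select `mrmr_features` by mRMR, extend
#' with parent-edge anomer variants, rerun mRMR on the pooled features, keep
#' the features given non-zero coefficients by cross-validated L1 logistic
#' regression, remove perfectly collinear features by VIFs, and fit the
#' final weighted L2 logistic model.
#'
#' @param glycans List of augmented `glycan_tree` objects (training set).
#' @param y Binary labels (1 = positive binder).
#' @param capability_map The `capability_map` used for augmentation; frozen
#'   into the model for later prediction.
#' @param config Pipeline configuration (see `default_pipeline_config()`);
#'   missing entries take defaults.
#' @param seed Integer seed (controls L1 cross-validation folds).
#' @return A `trained_model`.
#' @export
fit_motif_model <- function(glycans, y, capability_map,
                            config = list(), seed = 1L) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  y <- as.integer(y)
  stopifnot(length(glycans) == length(y))

  cand <- mine_candidate_motifs(glycans, positive = which(y == 1),
                                global_min_support = cfg$global_min_support,
                                positive_min_support = cfg$positive_min_support,
                                max_nodes = cfg$max_nodes)
  stage_counts <- c(candidates = nrow(cand))
  X_all <- matrix_from_occ(length(glycans), cand$occ)

  sel1 <- mrmr_select(X_all, y, cfg$mrmr_features)
  round1 <- cand$code[sel1]

  pool <- augment_with_parent_anomer(round1, glycans)
  round2 <- second_round_mrmr(pool, glycans, y, cfg$mrmr_features)
  X2 <- attr(round2, "matrix")
  stage_counts <- c(stage_counts, pooled = nrow(pool), round2 = nrow(round2))

  l1 <- l1_select(X2, y, c_grid = cfg$c_grid, folds = cfg$l1_folds,
                  seed = derive_seed(seed, "l1"))
  stage_counts <- c(stage_counts, l1_selected = length(l1$selected))

  if (length(l1$selected) == 0L) {
    final <- train_final_model(matrix(0, nrow = length(y), ncol = 0), y,
                               C = cfg$final_C)
    motifs <- data.frame(code = character(0), parent_anomer = character(0),
                         text = character(0), coef = numeric(0),
                         relevance = numeric(0), vif = numeric(0),
                         support_pos = numeric(0), support_neg = numeric(0),
                         stringsAsFactors = FALSE)
  } else {
    Xs <- X2[, l1$selected, drop = FALSE]
    pruned <- vif_prune(Xs, relevance = round2$relevance[l1$selected])
    kept <- l1$selected[pruned$keep]
    Xf <- X2[, kept, drop = FALSE]
    final <- train_final_model(Xf, y, C = cfg$final_C)
    motifs <- round2[kept, c("code", "parent_anomer", "relevance"), drop = FALSE]
    motifs$text <- motif_spec_text(motifs)
    motifs$coef <- final$coef
    motifs$vif <- pruned$vif
    motifs$support_pos <- colMeans(Xf[y == 1, , drop = FALSE])
    motifs$support_neg <- colMeans(Xf[y == 0, , drop = FALSE])
    motifs <- motifs[, c("code", "parent_anomer", "text", "coef", "relevance",
                         "vif", "support_pos", "support_neg")]
    rownames(motifs) <- NULL
  }

  structure(
    list(motifs = motifs, coef = motifs$coef, intercept = final$intercept,
         C = cfg$final_C, capability_map = capability_map,
         config = cfg[setdiff(names(cfg), "c_grid")], seed = seed,
         selection = list(c_best = l1$c_best,
                          stage_counts = as.list(stage_counts))),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model: %d motifs, intercept %.3f, C = %g>\n",
              nrow(x$motifs), x$intercept, x$C))
  if (nrow(x$motifs)) {
    print(x$motifs[, c("text", "coef", "support_pos", "support_neg", "vif")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Run the full motif-discovery pipeline on an array experiment
#'
#' Assigns binding classes by the MAD outlier rule, discards intermediate
#' binders, splits off a stratified test set, augments glycans with
#' restricted linkages (capability map built from every structure on the
#' array — structures only, so no label leakage), runs the selection cascade
#' on the training set, and evaluates the final model on the held-out test
#' set.
#'
#' @param experiment An `array_experiment` (or a data frame with
#'   `glycan_text` and `rfu`, or a path readable by [read_array_table()]).
#' @param config Named list overriding `default_pipeline_config()` entries.
#' @param seed Integer root seed; split and fold randomness derive from it.
#' @return List of class `pipeline_result`: `model` (a `trained_model`),
#'   `evaluation` (test-set [roc_auc()], `NULL` when `test_fraction` is 0),
#'   `classes`, `split`, and `motif_report` (the model's motif table).
#' @export
run_pipeline <- function(experiment, config = list(), seed = 1L) {
  if (is.character(experiment)) experiment <- read_array_table(experiment)
  if (is.data.frame(experiment)) experiment <- array_experiment(experiment)
  stopifnot(inherits(experiment, "array_experiment"))
  cfg <- utils::modifyList(default_pipeline_config(), config)

  classes <- assign_binding_classes(experiment$table$rfu,
                                    pos_threshold = cfg$pos_threshold,
                                    int_threshold = cfg$int_threshold)
  keep <- which(classes != "intermediate")
  y <- as.integer(classes[keep] == "positive")

  cap <- build_capability_map(experiment$glycans)
  aug <- lapply(experiment$glycans[keep], add_restricted_linkages, cap = cap)

  if (cfg$test_fraction > 0) {
    split <- stratified_split(ifelse(y == 1, "positive", "negative"),
                              test_fraction = cfg$test_fraction,
                              seed = derive_seed(seed, "split"))
  } else {
    warning("test_fraction is 0; validation skipped")
    split <- list(train = seq_along(y), test = integer(0))
  }

  model <- fit_motif_model(aug[split$train], y[split$train],
                           capability_map = cap, config = cfg, seed = seed)

  evaluation <- NULL
  if (length(split$test) && length(unique(y[split$test])) == 2L) {
    Xt <- compute_feature_matrix(aug[split$test], model$motifs)
    evaluation <- roc_auc(y[split$test], logistic_score(model, Xt))
  }

  structure(
    list(model = model, evaluation = evaluation, classes = classes,
         split = split, keep = keep, motif_report = model$motifs),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  tab <- table(x$classes)
  cat(sprintf("<pipeline_result: %d negative / %d intermediate / %d positive spots>\n",
              tab[["negative"]], tab[["intermediate"]], tab[["positive"]]))
  print(x$model)
  if (!is.null(x$evaluation)) {
    cat(sprintf("test-set AUC: %.4f\n", x$evaluation$auc))
  }
  invisible(x)
}

#' Stratified k-fold cross-validation of the whole pipeline
#'
#' Re-runs the complete selection cascade (mining, mRMR, anomeric
#' augmentation, L1, VIF, final model) inside each fold on that fold's
#' training data only, then scores the held-out fold, so no glycan
#' contributes to both the mining input and the validation AUC of a fold.
#'
#' @param experiment An `array_experiment`.
#' @param k Number of folds.
#' @param config Pipeline configuration overrides.
#' @param seed Integer root seed.
#' @return List with `mean_auc`, `sd_auc`, `fold_auc`, `fold_train_auc` and
#'   `fold_id`.
#' @export
cross_validate_pipeline <- function(experiment, k = 5L, config = list(), seed = 1L) {
  if (is.data.frame(experiment)) experiment <- array_experiment(experiment)
  stopifnot(inherits(experiment, "array_experiment"))
  cfg <- utils::modifyList(default_pipeline_config(), config)

  classes <- assign_binding_classes(experiment$table$rfu,
                                    pos_threshold = cfg$pos_threshold,
                                    int_threshold = cfg$int_threshold)
  keep <- which(classes != "intermediate")
  y <- as.integer(classes[keep] == "positive")
  if (sum(y == 1) < k) stop("fewer positive binders than folds", call. = FALSE)

  cap <- build_capability_map(experiment$glycans)
  aug <- lapply(experiment$glycans[keep], add_restricted_linkages, cap = cap)

  fold_id <- stratified_folds(y, k, derive_seed(seed, "cvfolds"))
  fold_auc <- numeric(k)
  fold_train_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(fold_id != f)
    va <- which(fold_id == f)
    model <- fit_motif_model(aug[tr], y[tr], capability_map = cap,
                             config = cfg, seed = derive_seed(seed, paste0("fold", f)))
    Xv <- compute_feature_matrix(aug[va], model$motifs)
    fold_auc[f] <- roc_auc(y[va], logistic_score(model, Xv))$auc
    Xt <- compute_feature_matrix(aug[tr], model$motifs)
    fold_train_auc[f] <- roc_auc(y[tr], logistic_score(model, Xt))$auc
  }
  list(mean_auc = mean(fold_auc), sd_auc = stats::sd(fold_auc),
       fold_auc = fold_auc, fold_train_auc = fold_train_auc, fold_id = fold_id)
}
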