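# Cost-balanced RBF support vector machine, rank-based AUC and
# cross-validated evaluation with nested feature selection.

#' Classifier configuration
#'
#' @param gamma RBF kernel width; the conventional grid is
#'   \{10, 1, 0.1, 0.01, 0.001\} with 1 as the headline default.
#' @param base_cost base misclassification cost C.
#' @param cv_folds outer cross-validation folds (K).
#' @param n_repeats repeats of the whole cross-validation with fresh
#'   random partitions.
#' @param seed seed for the outer partitions.
#' @param sens_levels sensitivity levels (percent) at which specificity is
#'   reported.
#' @return named list.
#' @export
classifier_config <- function(gamma = 1, base_cost = 1, cv_folds = 10,
                              n_repeats = 10, seed = 1,
                              sens_levels = c(90, 95, 99)) {
  as.list(environment())
}

#' Cost ratio balancing false positives and false negatives
#'
#' C+/C- = (number of negative examples) / (number of positive examples),
#' making the potential total cost of the two error types equal.
#'
#' @param y binary labels (0 = negative/benign, 1 = positive/cancer).
#' @return positive real.
#' @export
cost_ratio <- function(y) {
  n_neg <- sum(y == 0); n_pos <- sum(y == 1)
  if (n_neg == 0L || n_pos == 0L)
    stop("cost_ratio: both classes must be present")
  n_neg / n_pos
}

#' Train a cost-balanced RBF-SVM
#'
#' Features are z-scored by the training data's statistics before the
#' kernel (mixed-unit morphological features make the raw RBF distance
#' ill-posed); the positive-class cost is scaled by
#' \code{\link{cost_ratio}}.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y binary labels (0/1).
#' @param features subset of column names to use; default all.
#' @param cfg \code{\link{classifier_config}}.
#' @return object of class \code{hm_svm}; use \code{predict} to obtain
#'   decision scores (higher = more cancer-like).
#' @export
train_svm <- function(X, y, features = colnames(X),
                      cfg = classifier_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.null(features)) features <- colnames(X)
  if (!all(features %in% colnames(X)))
    stop("train_svm: unknown feature id(s)")
  Xs <- X[, features, drop = FALSE]
  if (nrow(unique(Xs)) < 2L)
    stop("train_svm: degenerate training data (all rows identical)")
  ctr <- colMeans(Xs)
  scl <- apply(Xs, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- scale(Xs, center = ctr, scale = scl)
  ratio <- cost_ratio(y)
  model <- e1071::svm(x = Z, y = factor(y, levels = c(0, 1)),
                      kernel = "radial", gamma = cfg$gamma,
                      cost = cfg$base_cost,
                      class.weights = c(`0` = 1, `1` = ratio),
                      scale = FALSE)
  structure(list(model = model, center = ctr, scale = scl,
                 features = features, cost_ratio = ratio),
            class = "hm_svm")
}

#' Decision scores of a trained SVM
#'
#' @param object \code{hm_svm}.
#' @param newdata matrix with (at least) the training feature columns.
#' @param ... unused.
#' @return numeric vector of signed margins, oriented so that larger
#'   scores indicate the positive (cancer) class.
#' @export
predict.hm_svm <- function(object, newdata, ...) {
  Z <- scale(as.matrix(newdata)[, object$features, drop = FALSE],
             center = object$center, scale = object$scale)
  pr <- predict(object$model, Z, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lab <- strsplit(colnames(dv)[1], "/")[[1]]
  sc <- as.numeric(dv[, 1])
  if (lab[1] != "1") sc <- -sc
  sc
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a positive sample scores above a negative one, ties
#' counted 0.5.
#'
#' @param scores numeric decision scores.
#' @param y binary labels (0/1).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, y) {
  pos <- y == 1; neg <- y == 0
  n1 <- sum(pos); n0 <- sum(neg)
  if (n1 == 0L || n0 == 0L) stop("auc: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Specificity at fixed sensitivity levels
#'
#' For each level, takes the highest threshold achieving sensitivity at
#' least that level (classifying positive when score >= threshold) and
#' reports the specificity there.
#'
#' @param scores numeric decision scores.
#' @param y binary labels (0/1).
#' @param sens_levels sensitivity levels in percent.
#' @return data.frame with \code{sensitivity} (level, percent) and
#'   \code{specificity} (percent).
#' @export
spec_at_sensitivity <- function(scores, y, sens_levels = c(90, 95, 99)) {
  sp <- scores[y == 1]; sn <- scores[y == 0]
  thr <- sort(unique(scores), decreasing = TRUE)
  out <- vapply(sens_levels, function(lv) {
    ok <- vapply(thr, function(t) mean(sp >= t) >= lv / 100, logical(1))
    if (!any(ok)) return(0)
    t <- thr[which(ok)[1]]     # highest threshold reaching the level
    100 * mean(sn < t)
  }, numeric(1))
  data.frame(sensitivity = sens_levels, specificity = out)
}

#' Repeated stratified K-fold cross-validation with nested selection
#'
#' For each repeat, the cohort is split into stratified folds; within each
#' fold the full two-stage feature selection runs on the training split
#' only, a cost-balanced RBF-SVM is trained on the selected features, and
#' the held-out fold is scored. Held-out scores are pooled per repeat into
#' one ROC; AUC and specificity-at-sensitivity are averaged over repeats.
#' The held-out data never influences selection, standardisation or
#' training.
#'
#' @param X numeric feature matrix with column names.
#' @param y binary labels (0/1).
#' @param cfg \code{\link{classifier_config}}.
#' @param sel_cfg \code{\link{selection_config}}.
#' @param select run nested feature selection per fold (TRUE) or use all
#'   features (FALSE).
#' @return object of class \code{eval_report}: \code{auc_mean},
#'   \code{auc_sd}, \code{spec_at_sens} (level, mean, sd),
#'   \code{per_repeat}, \code{scores} (pooled held-out scores of the last
#'   repeat), \code{selected_features_per_fold}.
#' @export
cross_validate <- function(X, y, cfg = classifier_config(),
                           sel_cfg = selection_config(), select = TRUE) {
  X <- as.matrix(X)
  if (min(table(y)) < 2L)
    stop("cross_validate: need at least 2 samples per class")
  k <- min(cfg$cv_folds, min(table(y)))
  aucs <- numeric(cfg$n_repeats)
  specs <- vector("list", cfg$n_repeats)
  sel_sets <- list()
  scores <- NULL
  for (r in seq_len(cfg$n_repeats)) {
    folds <- make_folds(y, k, cfg$seed + r)
    sc <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      feats <- colnames(X)
      if (select) {
        sel <- select_features(X[tr, , drop = FALSE], y[tr], cfg, sel_cfg)
        feats <- sel$final_set
        sel_sets[[length(sel_sets) + 1L]] <- feats
      }
      model <- train_svm(X[tr, , drop = FALSE], y[tr], feats, cfg)
      sc[!tr] <- predict(model, X[!tr, , drop = FALSE])
    }
    aucs[r] <- auc(sc, y)
    specs[[r]] <- spec_at_sensitivity(sc, y, cfg$sens_levels)
    scores <- sc
  }
  sm <- do.call(rbind, specs)
  sas <- aggregate(specificity ~ sensitivity, sm,
                   function(v) c(mean = mean(v), sd = sd(v)))
  sas <- data.frame(sensitivity = sas$sensitivity,
                    mean = sas$specificity[, "mean"],
                    sd = ifelse(is.finite(sas$specificity[, "sd"]),
                                sas$specificity[, "sd"], 0))
  structure(list(auc_mean = mean(aucs),
                 auc_sd = if (length(aucs) > 1L) sd(aucs) else 0,
                 auc_per_repeat = aucs, spec_at_sens = sas,
                 scores = scores, labels = y,
                 selected_features_per_fold = sel_sets,
                 n_folds = k, n_repeats = cfg$n_repeats),
            class = "eval_report")
}

#' Train on one cohort, test on another
#'
#' Feature selection, standardisation and training use the training cohort
#' only; the test cohort is scored once.
#'
#' @param X_train,y_train training cohort.
#' @param X_test,y_test test cohort; columns must match the training
#'   matrix.
#' @param cfg \code{\link{classifier_config}}.
#' @param sel_cfg \code{\link{selection_config}}.
#' @param select run feature selection (TRUE) or use all features.
#' @return \code{eval_report} for the single test evaluation.
#' @export
train_test_transfer <- function(X_train, y_train, X_test, y_test,
                                cfg = classifier_config(),
                                sel_cfg = selection_config(),
                                select = TRUE) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (!identical(colnames(X_train), colnames(X_test)))
    stop("train_test_transfer: feature columns of the two cohorts differ")
  feats <- colnames(X_train)
  sel_sets <- list()
  if (select) {
    sel <- select_features(X_train, y_train, cfg, sel_cfg)
    feats <- sel$final_set
    sel_sets <- list(feats)
  }
  model <- train_svm(X_train, y_train, feats, cfg)
  sc <- predict(model, X_test)
  sas <- spec_at_sensitivity(sc, y_test, cfg$sens_levels)
  structure(list(auc_mean = auc(sc, y_test), auc_sd = 0,
                 auc_per_repeat = auc(sc, y_test),
                 spec_at_sens = data.frame(sensitivity = sas$sensitivity,
                                           mean = sas$specificity, sd = 0),
                 scores = sc, labels = y_test,
                 selected_features_per_fold = sel_sets,
                 n_folds = 1L, n_repeats = 1L),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Cross-validated evaluation: AUC %.3f (sd %.4f) over %d repeat(s), %d fold(s)\n",
              x$auc_mean, x$auc_sd, x$n_repeats, x$n_folds))
  for (i in seq_len(nrow(x$spec_at_sens)))
    cat(sprintf("  specificity at %d%% sensitivity: %.2f%% (sd %.2f)\n",
                x$spec_at_sens$sensitivity[i], x$spec_at_sens$mean[i],
                x$spec_at_sens$sd[i]))
  invisible(x)
}
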