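# Two-stage feature selection: mRMR ranking (MID form, discrete mutual
# information on 3-bin discretised features) builds a candidate prefix of
# at most 30 features by cross-validated AUC, then sequential floating
# forward selection (SFFS) refines it with a 20-step add/remove budget.

# Evaluate `code` under a fixed RNG seed, restoring the caller's state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Stratified fold assignment (1..k), as balanced as possible.
make_folds <- function(y, k, seed) {
  with_local_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(sample(k), length(idx))
    }
    f
  })
}

#' Selection configuration
#'
#' @param i_max maximum mRMR prefix length considered for the candidate
#'   set.
#' @param budget maximum total additions + deletions in the SFFS stage.
#' @param inner_folds folds of the cross-validation that scores feature
#'   sets during selection.
#' @param inner_seed fixed seed of that cross-validation (so set scores
#'   are comparable across steps).
#' @return named list.
#' @export
selection_config <- function(i_max = 30, budget = 20, inner_folds = 5,
                             inner_seed = 42) {
  as.list(environment())
}

#' Discretise a numeric vector into 3 bins at mean +/- sd
#'
#' @param x numeric vector.
#' @return integer vector in \{1, 2, 3\}.
#' @export
discretize3 <- function(x) {
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(2L, length(x)))
  findInterval(x, c(m - s, m + s)) + 1L
}

#' Mutual information of two discrete vectors (bits)
#'
#' @param a,b vectors coercible to factors.
#' @return nonnegative mutual information in bits.
#' @export
mutual_info <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj); pb <- colSums(pj)
  pe <- outer(pa, pb)
  ok <- pj > 0
  sum(pj[ok] * log2(pj[ok] / pe[ok]))
}

#' mRMR feature ranking
#'
#' Greedy minimum-redundancy-maximal-relevance ordering in the MID
#' (mutual-information difference) form: the first feature maximises
#' I(f; y); each subsequent feature maximises
#' I(f; y) - mean over chosen g of I(f; g). Features are discretised into
#' 3 bins at mean +/- sd. Ties break towards the lower column index.
#'
#' @param X numeric matrix or data.frame of features (samples x features).
#' @param y binary labels (0/1), one per row of X.
#' @return list: \code{order} (feature names in rank order),
#'   \code{relevance} (named I(f; y) per feature, original column order).
#' @export
mrmr_rank <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("mrmr_rank: X rows and y length differ")
  if (length(unique(y)) < 2L) stop("mrmr_rank: y must contain two classes")
  M <- ncol(X)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(M))
  D <- apply(X, 2, discretize3)
  rel <- vapply(seq_len(M), function(j) mutual_info(D[, j], y), numeric(1))
  names(rel) <- ids
  chosen <- integer(0)
  remaining <- seq_len(M)
  red_sum <- numeric(M)   # sum of MI(f, g) over chosen g
  while (length(remaining)) {
    score <- if (length(chosen) == 0L) rel[remaining]
             else rel[remaining] - red_sum[remaining] / length(chosen)
    j <- remaining[which.max(score)]   # first max = lowest index tie-break
    chosen <- c(chosen, j)
    remaining <- setdiff(remaining, j)
    if (length(remaining))
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(k) mutual_info(D[, k], D[, j]),
               numeric(1))
  }
  list(order = ids[chosen], relevance = rel)
}

# Cross-validated AUC of a feature subset with the configured classifier:
# stratified inner folds at a fixed seed, training-fold standardisation,
# held-out scores pooled into a single AUC.
cv_auc <- function(X, y, features, clf_cfg, sel_cfg = selection_config()) {
  X <- as.matrix(X)
  k <- min(sel_cfg$inner_folds, min(table(y)))
  if (k < 2L) stop("cv_auc: need at least 2 samples per class")
  folds <- make_folds(y, k, sel_cfg$inner_seed)
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- tryCatch(
      train_svm(X[tr, , drop = FALSE], y[tr], features, clf_cfg),
      error = function(e) NULL)
    # a degenerate subset (e.g. all-constant features) carries no
    # information: score it at chance level
    if (is.null(model)) return(0.5)
    scores[!tr] <- predict(model, X[!tr, , drop = FALSE])
  }
  auc(scores, y)
}

#' Best mRMR prefix by cross-validated AUC
#'
#' @param order feature ids in mRMR rank order.
#' @param X,y feature matrix and labels.
#' @param clf_cfg \code{\link{classifier_config}}.
#' @param sel_cfg \code{\link{selection_config}}; \code{i_max} caps the
#'   prefix length.
#' @return list: \code{candidate_set} (feature ids), \code{aucs} (AUC per
#'   prefix length). Ties break towards the smaller prefix.
#' @export
best_prefix <- function(order, X, y, clf_cfg = classifier_config(),
                        sel_cfg = selection_config()) {
  if (length(order) == 0L) stop("best_prefix: empty feature order")
  imax <- min(sel_cfg$i_max, length(order))
  aucs <- vapply(seq_len(imax), function(i)
    cv_auc(X, y, order[seq_len(i)], clf_cfg, sel_cfg), numeric(1))
  i_best <- which.max(aucs)
  list(candidate_set = order[seq_len(i_best)], aucs = aucs)
}

#' Sequential floating forward selection
#'
#' Starting from the candidate set, repeatedly adds the feature whose
#' inclusion maximises the cross-validated AUC, then conditionally removes
#' features as long as a removal strictly improves the best AUC seen.
#' Stops when the AUC reaches 1.0 or the number of additions plus
#' deletions reaches \code{sel_cfg$budget}; returns the best set
#' encountered.
#'
#' @param candidate_set starting feature ids (nonempty).
#' @param X,y feature matrix and labels.
#' @param clf_cfg \code{\link{classifier_config}}.
#' @param sel_cfg \code{\link{selection_config}}.
#' @return object of class \code{selection_result} with fields
#'   \code{final_set}, \code{final_auc}, \code{trace} (data.frame of step,
#'   action, feature_id, auc).
#' @export
sffs_refine <- function(candidate_set, X, y, clf_cfg = classifier_config(),
                        sel_cfg = selection_config()) {
  if (length(candidate_set) == 0L) stop("sffs_refine: empty candidate set")
  X <- as.matrix(X)
  all_feats <- colnames(X)
  S <- candidate_set
  best_auc <- cv_auc(X, y, S, clf_cfg, sel_cfg)
  best_set <- S
  trace <- data.frame(step = integer(0), action = character(0),
                      feature_id = character(0), auc = numeric(0))
  steps <- 0L
  while (best_auc < 1 && steps < sel_cfg$budget) {
    pool <- setdiff(all_feats, S)
    if (length(pool) == 0L) break
    add_aucs <- vapply(pool, function(x)
      cv_auc(X, y, c(S, x), clf_cfg, sel_cfg), numeric(1))
    jx <- which.max(add_aucs)
    S <- c(S, pool[jx])
    steps <- steps + 1L
    trace <- rbind(trace, data.frame(step = steps, action = "add",
                                     feature_id = pool[jx],
                                     auc = add_aucs[jx]))
    if (add_aucs[jx] > best_auc ||
        (add_aucs[jx] == best_auc && length(S) < length(best_set))) {
      best_auc <- add_aucs[jx]; best_set <- S
    }
    # conditional deletions while they strictly improve the best AUC seen
    while (length(S) > 1L && best_auc < 1 && steps < sel_cfg$budget) {
      rm_aucs <- vapply(S, function(x)
        cv_auc(X, y, setdiff(S, x), clf_cfg, sel_cfg), numeric(1))
      kx <- which.max(rm_aucs)
      if (rm_aucs[kx] > best_auc) {
        removed <- S[kx]
        S <- setdiff(S, removed)
        steps <- steps + 1L
        best_auc <- rm_aucs[kx]; best_set <- S
        trace <- rbind(trace, data.frame(step = steps, action = "remove",
                                         feature_id = removed,
                                         auc = rm_aucs[kx]))
      } else break
    }
  }
  structure(list(final_set = best_set, final_auc = best_auc, trace = trace),
            class = "selection_result")
}

#' Two-stage feature selection
#'
#' mRMR ranking, candidate prefix by cross-validated AUC, then SFFS
#' refinement.
#'
#' @param X numeric feature matrix with column names.
#' @param y binary labels (0/1).
#' @param clf_cfg \code{\link{classifier_config}}.
#' @param sel_cfg \code{\link{selection_config}}.
#' @return \code{selection_result} with \code{mrmr_order},
#'   \code{relevance}, \code{candidate_set}, \code{final_set},
#'   \code{final_auc} and the SFFS \code{trace}.
#' @export
select_features <- function(X, y, clf_cfg = classifier_config(),
                            sel_cfg = selection_config()) {
  rk <- mrmr_rank(X, y)
  bp <- best_prefix(rk$order, X, y, clf_cfg, sel_cfg)
  sf <- sffs_refine(bp$candidate_set, X, y, clf_cfg, sel_cfg)
  structure(list(mrmr_order = rk$order, relevance = rk$relevance,
                 candidate_set = bp$candidate_set,
                 prefix_aucs = bp$aucs,
                 final_set = sf$final_set, final_auc = sf$final_auc,
                 trace = sf$trace),
            class = "selection_result")
}
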