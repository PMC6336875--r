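## Depth-limited decision-tree models of binarized permissibility.
##
## Greedy CART growth on Gini impurity with deterministic tie-breaking
## (largest impurity decrease; ties resolved toward the lowest feature index,
## then the lowest threshold), stratified k-fold cross-validation with pooled
## out-of-fold ROC / precision-recall / accuracy curves, Gini-decrease
## feature importances, and feature-withholding comparisons.

.gini <- function(n1, n) {
  p <- n1 / n
  1 - p^2 - (1 - p)^2
}

# best split of one node; returns NULL when no admissible split improves
.best_split <- function(x, y, min_leaf) {
  n <- length(y)
  parent <- .gini(sum(y), n)
  best <- NULL
  for (f in seq_len(ncol(x))) {
    xf <- x[, f]
    o <- order(xf)
    sx <- xf[o]
    cum1 <- cumsum(y[o])
    i <- seq_len(n - 1)
    cand <- which(sx[i] < sx[i + 1] & i >= min_leaf & (n - i) >= min_leaf)
    if (length(cand) == 0) next
    n_l <- cand
    n_r <- n - cand
    g_l <- .gini(cum1[cand], n_l)
    g_r <- .gini(cum1[n] - cum1[cand], n_r)
    dec <- parent - (n_l * g_l + n_r * g_r) / n
    k <- which.max(dec)            # first maximum = lowest threshold
    if (dec[k] <= 1e-12) next
    thr <- (sx[cand[k]] + sx[cand[k] + 1]) / 2
    if (is.null(best) || dec[k] > best$decrease + 1e-12) {
      best <- list(feature = f, threshold = thr, decrease = dec[k])
    }
    # ties across features fall through: earlier (lower) index wins
  }
  best
}

#' Fit a depth-limited CART decision tree
#'
#' Binary classification tree grown greedily on Gini impurity. Splits are
#' deterministic: the split with the largest impurity decrease wins, with
#' ties broken toward the lowest feature index and then the lowest
#' threshold; leaves hold class-1 probabilities. Depth 4 (the default)
#' limits overfitting; `min_leaf` guards degenerate splits.
#'
#' @param x numeric matrix or data frame of features (rows = residues)
#' @param y binary labels (0/1, logical, or two-level factor)
#' @param max_depth maximum tree depth (root = depth 0)
#' @param min_leaf minimum observations per leaf
#' @return a `dip_tree`: list with `nodes` (data frame), `features`
#' @export
fit_tree <- function(x, y, max_depth = 4, min_leaf = 5) {
  x <- as.matrix(x)
  y <- as.integer(if (is.factor(y)) y == levels(y)[2] else y > 0)
  if (length(unique(y)) < 2) stop_invalid("labels contain a single class")
  if (nrow(x) != length(y)) stop_invalid("x and y sizes differ")
  nodes <- list()
  grow <- function(idx, depth) {
    id <- length(nodes) + 1L
    nodes[id] <<- list(NULL)       # reserve slot
    n <- length(idx)
    n1 <- sum(y[idx])
    leaf <- function() {
      nodes[[id]] <<- data.frame(id = id, depth = depth, is_leaf = TRUE,
                                 feature = NA_integer_,
                                 threshold = NA_real_, left = NA_integer_,
                                 right = NA_integer_, n = n, p1 = n1 / n,
                                 improve = 0)
      id
    }
    if (depth >= max_depth || n1 == 0 || n1 == n || n < 2 * min_leaf) {
      return(leaf())
    }
    sp <- .best_split(x[idx, , drop = FALSE], y[idx], min_leaf)
    if (is.null(sp)) return(leaf())
    go_left <- x[idx, sp$feature] <= sp$threshold
    left <- grow(idx[go_left], depth + 1L)
    right <- grow(idx[!go_left], depth + 1L)
    nodes[[id]] <<- data.frame(id = id, depth = depth, is_leaf = FALSE,
                               feature = sp$feature,
                               threshold = sp$threshold, left = left,
                               right = right, n = n, p1 = n1 / n,
                               improve = sp$decrease * n)
    id
  }
  grow(seq_along(y), 0L)
  structure(list(nodes = do.call(rbind, nodes), features = colnames(x),
                 max_depth = max_depth, min_leaf = min_leaf),
            class = "dip_tree")
}

#' Predict class-1 probabilities from a fitted tree
#'
#' @param object a `dip_tree`
#' @param newdata feature matrix or data frame with the training columns
#' @param ... unused
#' @return numeric vector of leaf class-1 probabilities
#' @export
predict.dip_tree <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(x))) {
    x <- x[, object$features, drop = FALSE]
  }
  nd <- object$nodes
  node <- rep(1L, nrow(x))
  repeat {
    open <- which(!nd$is_leaf[node])
    if (length(open) == 0) break
    cur <- node[open]
    go_left <- x[cbind(open, nd$feature[cur])] <= nd$threshold[cur]
    node[open] <- ifelse(go_left, nd$left[cur], nd$right[cur])
  }
  nd$p1[node]
}

#' Feature importances of a fitted tree
#'
#' Importance of a feature is its total Gini impurity decrease (weighted by
#' node size) summed over the splits that use it, normalized to sum 1.
#'
#' @param model a `dip_tree`
#' @param n number of top features to return
#' @return data frame `feature`, `importance`, sorted decreasing
#' @export
top_features <- function(model, n = 4) {
  if (!inherits(model, "dip_tree")) stop_invalid("not a fitted dip_tree")
  nd <- model$nodes[!model$nodes$is_leaf, , drop = FALSE]
  if (nrow(nd) == 0) {
    return(data.frame(feature = character(0), importance = numeric(0)))
  }
  imp <- tapply(nd$improve, model$features[nd$feature], sum)
  imp <- imp / sum(imp)
  out <- data.frame(feature = names(imp), importance = as.numeric(imp))
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n)
}

roc_points <- function(label, score) {
  o <- order(score, decreasing = TRUE)
  lab <- label[o]
  sc <- score[o]
  np <- sum(lab)
  nn <- length(lab) - np
  tp <- cumsum(lab)
  fp <- cumsum(1 - lab)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)   # collapse tied scores
  data.frame(threshold = c(Inf, sc[last]),
             fpr = c(0, fp[last] / nn),
             tpr = c(0, tp[last] / np))
}

auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

cutoff_curves <- function(label, score) {
  cuts <- sort(unique(score))
  out <- lapply(cuts, function(ct) {
    pred <- as.integer(score >= ct)
    tp <- sum(pred == 1 & label == 1)
    fp <- sum(pred == 1 & label == 0)
    fn <- sum(pred == 0 & label == 1)
    data.frame(cutoff = ct,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / (tp + fn),
               accuracy = mean(pred == label))
  })
  do.call(rbind, out)
}

#' Stratified k-fold cross-validation of the decision-tree model
#'
#' Folds are stratified by class (each class shuffled with the seed and
#' dealt round-robin into `k` folds). Out-of-fold leaf probabilities are
#' pooled into one ROC curve (AUC by the trapezoid rule) and
#' precision/recall/accuracy-vs-cutoff curves.
#'
#' @param x feature matrix or data frame
#' @param y binary labels
#' @param k number of folds (default 10)
#' @param seed integer seed for the fold assignment
#' @param max_depth,min_leaf passed to [fit_tree()]
#' @return a `dip_cv`: list with `auc`, `roc`, `curves`, `prob`, `label`,
#'   `fold`, `per_fold_auc`
#' @export
cross_validate <- function(x, y, k = 10, seed = 1, max_depth = 4,
                           min_leaf = 5) {
  x <- as.matrix(x)
  y <- as.integer(if (is.factor(y)) y == levels(y)[2] else y > 0)
  n <- length(y)
  if (k > n) stop_invalid("k exceeds the number of observations")
  fold <- integer(n)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  prob <- numeric(n)
  per_fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test <- fold == f
    tree <- fit_tree(x[!test, , drop = FALSE], y[!test],
                     max_depth = max_depth, min_leaf = min_leaf)
    prob[test] <- predict.dip_tree(tree, x[test, , drop = FALSE])
    if (length(unique(y[test])) == 2) {
      per_fold_auc[f] <- auc_trapezoid(roc_points(y[test], prob[test]))
    }
  }
  roc <- roc_points(y, prob)
  structure(list(auc = auc_trapezoid(roc), roc = roc,
                 curves = cutoff_curves(y, prob), prob = prob, label = y,
                 fold = fold, per_fold_auc = per_fold_auc, k = k),
            class = "dip_cv")
}

#' Cross-validated comparison with features withheld
#'
#' Refits and cross-validates the model without the withheld features and
#' reports the AUC change. `withhold` may name individual features or one of
#' the categories `"static"`, `"conservation"`, `"dynamic"` (resolved via
#' the feature table's `categories` attribute).
#'
#' @param x feature matrix or `dip_features`
#' @param y binary labels
#' @param withhold feature names or a category name; empty vector compares
#'   the full model with itself
#' @param categories optional named character vector feature -> category
#'   (defaults to `attr(x, "categories")`)
#' @param ... passed to [cross_validate()] (`k`, `seed`, `max_depth`, ...)
#' @return list with `full` and `withheld` `dip_cv` reports, `delta_auc`
#'   (full minus withheld) and the resolved `withheld_features`
#' @export
withhold_features <- function(x, y, withhold, categories = NULL, ...) {
  if (is.null(categories)) categories <- attr(x, "categories")
  x <- as.matrix(x)
  feats <- colnames(x)
  if (length(withhold) == 1 && !is.null(categories) &&
      withhold %in% categories) {
    withhold <- names(categories)[categories == withhold]
  }
  if (!all(withhold %in% feats)) {
    stop_invalid("withheld features absent from the feature table")
  }
  keep <- setdiff(feats, withhold)
  if (length(keep) == 0) stop_invalid("cannot withhold every feature")
  full <- cross_validate(x, y, ...)
  reduced <- cross_validate(x[, keep, drop = FALSE], y, ...)
  list(full = full, withheld = reduced,
       delta_auc = full$auc - reduced$auc, withheld_features = withhold)
}
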