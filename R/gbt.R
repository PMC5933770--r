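#' Fit a single regression tree
#'
#' Exact greedy least-squares tree: at each node every midpoint between
#' consecutive distinct values of every feature is scored by the reduction
#' in summed squared error, the best split is taken, and leaves carry the
#' mean response of their samples. No split is made when none reduces the
#' SSE or when a child would fall below `min_leaf` samples. Ties in gain
#' (agreement to a relative 1e-9, so that distinct features inducing the
#' same partition compare as equal despite summation order) go to the
#' lowest feature index, then the lowest threshold, making the fit
#' deterministic under any permutation of the samples.
#'
#' @param X numeric matrix of predictors (rows = samples).
#' @param y numeric response (for boosting: the current residuals).
#' @param max_depth maximum number of split levels, default 8.
#' @param min_leaf minimum samples per leaf, default 1.
#' @return an object of class `reg_tree` wrapping the node table.
#' @export
reg_tree <- function(X, y, max_depth = 8L, min_leaf = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L) stop("cannot fit a tree on zero samples")
  if (length(y) != nrow(X))
    stop(sprintf("%d responses for %d samples", length(y), nrow(X)))
  if (!all(is.finite(y))) stop("responses must be finite")
  nodes <- cpp_fit_tree(X, as.numeric(y), as.integer(max_depth),
                        as.integer(min_leaf))
  structure(list(nodes = nodes, p = ncol(X), max_depth = as.integer(max_depth)),
            class = "reg_tree")
}

#' @param object a `reg_tree`.
#' @param newdata numeric matrix with the training number of columns.
#' @param ... unused.
#' @rdname reg_tree
#' @export
predict.reg_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$p)
    stop(sprintf("model was fit on %d features, newdata has %d",
                 object$p, ncol(newdata)))
  as.numeric(cpp_predict_tree(object$nodes, newdata))
}

#' @export
print.reg_tree <- function(x, ...) {
  n_leaves <- sum(x$nodes[, "feature"] == 0)
  cat(sprintf("<reg_tree> %d nodes (%d leaves), %d features, max depth %d\n",
              nrow(x$nodes), n_leaves, x$p, x$max_depth))
  invisible(x)
}

#' Gradient-boosted regression trees
#'
#' Least-squares boosting on 0/1 targets: starting from `f_0 = 0`, each of
#' `ntree` rounds fits a depth-limited regression tree to the residuals
#' `y - f` and adds it with shrinkage, `f <- f + shrinkage * T_m(x)`. The
#' ensemble score is the raw shrunken sum; no clipping happens at this
#' layer. Defaults (2000 trees, shrinkage 0.005, depth 8) are the reference
#' operating point; smaller `ntree` is a supported configuration for
#' desk-scale work.
#'
#' @param X numeric matrix of predictors.
#' @param y 0/1 response (1 = disease-associated, 0 = neutral).
#' @param ntree number of boosting rounds, default 2000.
#' @param shrinkage learning rate, default 0.005.
#' @param max_depth per-tree depth limit, default 8.
#' @param min_leaf minimum samples per leaf, default 1.
#' @return an object of class `gbt`.
#' @export
gbt <- function(X, y, ntree = 2000L, shrinkage = 0.005, max_depth = 8L,
                min_leaf = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 1L) stop("cannot fit on zero samples")
  if (length(y) != nrow(X))
    stop(sprintf("%d responses for %d samples", length(y), nrow(X)))
  if (!all(y %in% c(0, 1)))
    stop("y must be binary 0/1 (1 = disease-associated, 0 = neutral)")
  ntree <- as.integer(ntree)
  trees <- vector("list", ntree)
  f <- numeric(length(y))
  train_sse <- numeric(ntree)
  for (m in seq_len(ntree)) {
    tr <- reg_tree(X, y - f, max_depth = max_depth, min_leaf = min_leaf)
    f <- f + shrinkage * predict(tr, X)
    trees[[m]] <- tr
    train_sse[m] <- sum((y - f)^2)
  }
  structure(list(trees = trees, shrinkage = shrinkage, ntree = ntree,
                 max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf), p = ncol(X),
                 feature_names = colnames(X), train_sse = train_sse),
            class = "gbt")
}

#' @param object a `gbt` model.
#' @param newdata numeric matrix (or vector for a single sample).
#' @param ... unused.
#' @rdname gbt
#' @export
predict.gbt <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (object$ntree == 0L) return(numeric(nrow(newdata)))
  if (ncol(newdata) != object$p)
    stop(sprintf("model was fit on %d features, newdata has %d",
                 object$p, ncol(newdata)))
  out <- numeric(nrow(newdata))
  for (tr in object$trees)
    out <- out + object$shrinkage * as.numeric(cpp_predict_tree(tr$nodes, newdata))
  out
}

#' @export
print.gbt <- function(x, ...) {
  cat(sprintf("<gbt> %d trees, shrinkage %g, max depth %d, %d features\n",
              x$ntree, x$shrinkage, x$max_depth, x$p))
  if (x$ntree > 0)
    cat(sprintf("  final training SSE: %.6g\n", x$train_sse[x$ntree]))
  invisible(x)
}

gbt_to_list <- function(model) {
  list(type = "gbt", version = 1L,
       shrinkage = model$shrinkage, ntree = model$ntree,
       max_depth = model$max_depth, min_leaf = model$min_leaf,
       p = model$p, feature_names = model$feature_names,
       trees = lapply(model$trees, function(tr)
         as.data.frame(tr$nodes)))
}

gbt_from_list <- function(x) {
  trees <- lapply(x$trees, function(tb) {
    nodes <- as.matrix(as.data.frame(tb))
    colnames(nodes) <- c("feature", "threshold", "left", "right", "value", "n")
    structure(list(nodes = nodes, p = x$p,
                   max_depth = as.integer(x$max_depth)),
              class = "reg_tree")
  })
  structure(list(trees = trees, shrinkage = x$shrinkage,
                 ntree = as.integer(x$ntree),
                 max_depth = as.integer(x$max_depth),
                 min_leaf = as.integer(x$min_leaf), p = as.integer(x$p),
                 feature_names = x$feature_names,
                 train_sse = numeric(0)),
            class = "gbt")
}
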