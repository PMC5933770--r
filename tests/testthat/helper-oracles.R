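# Independent brute-force oracles for the tree and boosting learners.
# Deliberately naive: every (feature, midpoint) candidate is scored by
# directly computing the two children's SSE from scratch, and the boosting
# loop re-fits trees on explicit residual vectors. Tie-breaks mirror the
# stated contract (lowest feature index, then lowest threshold, strict
# improvement required).

brute_tree_fit <- function(X, y, max_depth, min_leaf = 1L, depth = 0L) {
  n <- nrow(X)
  node <- list(value = mean(y))
  if (depth >= max_depth || n < 2L * min_leaf) return(node)
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  # same numerical reading of "reduces the SSE" as the contract: gains at
  # float-noise scale relative to sum(y^2) do not count
  best <- list(gain = 1e-12 * sum(y^2))
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2L) next
    for (t in (u[-length(u)] + diff(u) / 2)) {
      left <- X[, j] <= t
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      gain <- sse(y) - sse(y[left]) - sse(y[!left])
      # ties within relative 1e-9 keep the incumbent (lowest feature, then
      # lowest threshold), as the split contract states
      if (gain > best$gain + 1e-9 * max(gain, best$gain))
        best <- list(gain = gain, j = j, t = t)
    }
  }
  if (best$gain <= 0) return(node)
  left <- X[, best$j] <= best$t
  node$feature <- best$j
  node$threshold <- best$t
  node$left <- brute_tree_fit(X[left, , drop = FALSE], y[left],
                              max_depth, min_leaf, depth + 1L)
  node$right <- brute_tree_fit(X[!left, , drop = FALSE], y[!left],
                               max_depth, min_leaf, depth + 1L)
  node
}

brute_tree_predict <- function(node, X) {
  apply(X, 1L, function(x) {
    nd <- node
    while (!is.null(nd$feature))
      nd <- if (x[nd$feature] <= nd$threshold) nd$left else nd$right
    nd$value
  })
}

brute_gbt_predict <- function(X, y, Xnew, ntree, shrinkage, max_depth,
                              min_leaf = 1L) {
  f <- numeric(nrow(X))
  fnew <- numeric(nrow(Xnew))
  for (m in seq_len(ntree)) {
    tr <- brute_tree_fit(X, y - f, max_depth, min_leaf)
    f <- f + shrinkage * brute_tree_predict(tr, X)
    fnew <- fnew + shrinkage * brute_tree_predict(tr, Xnew)
  }
  fnew
}
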