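#' Confusion counts at a score cutoff
#'
#' Pathogenic is the positive class; the call is inclusive
#' (`score >= cutoff` is a positive call).
#'
#' @param scores numeric prediction scores.
#' @param labels `"pathogenic"` / `"neutral"`, same length as `scores`.
#' @param cutoff call threshold, default 0.5.
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion <- function(scores, labels, cutoff = 0.5) {
  if (length(scores) != length(labels))
    stop(sprintf("%d scores for %d labels", length(scores), length(labels)))
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("pathogenic", "neutral"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  pos <- labels == "pathogenic"
  call <- scores >= cutoff
  c(TP = sum(call & pos), FP = sum(call & !pos),
    TN = sum(!call & !pos), FN = sum(!call & pos))
}

#' Classification metrics from confusion counts
#'
#' Matthews correlation coefficient, sensitivity, specificity, F-score,
#' false positive rate and false discovery rate. Degenerate cases: MCC is 0
#' when any of its four denominator factors is 0; the F-score is 0 when
#' TP = 0; the FDR is 0 when nothing is called positive; sensitivity and
#' specificity are `NaN` when their class is empty.
#'
#' @param counts named vector with `TP`, `FP`, `TN`, `FN` (from
#'   [confusion()]).
#' @return named numeric vector `mcc`, `sensitivity`, `specificity`,
#'   `f_score`, `fpr`, `fdr`, `precision`.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop("confusion counts must be nonnegative")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  sens <- if (tp + fn == 0) NaN else tp / (tp + fn)
  spec <- if (tn + fp == 0) NaN else tn / (tn + fp)
  prec <- if (tp + fp == 0) NaN else tp / (tp + fp)
  f <- if (tp == 0) 0 else 2 * prec * sens / (prec + sens)
  fdr <- if (tp + fp == 0) 0 else fp / (tp + fp)
  c(mcc = mcc, sensitivity = sens, specificity = spec, f_score = f,
    fpr = if (is.nan(spec)) NaN else 1 - spec, fdr = fdr, precision = prec)
}

#' Receiver operating characteristic points
#'
#' Sweeps over every distinct score threshold (inclusive calls) and returns
#' the (FPR, TPR) staircase from (0, 0) to (1, 1), monotone non-decreasing
#' in both coordinates.
#'
#' @inheritParams confusion
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "pathogenic"
  if (!any(pos) || all(pos))
    stop("ROC requires both classes to be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # cumulative counts at each distinct threshold (call iff score >= t)
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(p)[last]; fp <- cumsum(!p)[last]
  data.frame(threshold = c(Inf, s[last], -Inf),
             fpr = c(0, fp / sum(!pos), 1),
             tpr = c(0, tp / sum(pos), 1))
}

#' Area under a ROC staircase (trapezoidal rule)
#' @param roc data.frame from [roc_points()].
#' @return scalar AUC.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Pairwise global sequence identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, gap open and
#' extension -1 each); identity is the number of identical aligned positions
#' divided by the shorter sequence length — the conservative convention for
#' homology-leakage control.
#'
#' @param seq_a,seq_b amino-acid strings or character vectors of residues.
#' @return identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (length(seq_a) > 1L) seq_a <- paste(seq_a, collapse = "")
  if (length(seq_b) > 1L) seq_b <- paste(seq_b, collapse = "")
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  letters_all <- sort(unique(c(AA20, strsplit(paste0(seq_a, seq_b), "")[[1L]])))
  subst <- matrix(0, length(letters_all), length(letters_all),
                  dimnames = list(letters_all, letters_all))
  diag(subst) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = subst,
    gapOpening = 1, gapExtension = 1)
  Biostrings::nmatch(aln) / min(nchar(seq_a), nchar(seq_b))
}

#' Cluster proteins by sequence identity
#'
#' Single-linkage clustering: any two proteins with pairwise identity at or
#' above the cutoff are joined, and the transitive closure (union-find)
#' defines the clusters. Used to keep homologous proteins inside the same
#' cross-validation fold.
#'
#' @param proteins named list of [protein_record()]s, or a named character
#'   vector of sequences.
#' @param cutoff identity cutoff, default 0.35.
#' @return object of class `cluster_partition`: list with `clusters` (list
#'   of protein-id character vectors) and `identity_cutoff`.
#' @export
cluster_sequences <- function(proteins, cutoff = 0.35) {
  if (length(proteins) == 0L) stop("at least one protein required")
  seqs <- if (is.character(proteins)) proteins
          else vapply(proteins, function(p) paste(p$sequence, collapse = ""),
                      character(1))
  ids <- names(seqs)
  if (is.null(ids)) stop("proteins must be named")
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ri <- find(i); rj <- find(j)
    if (ri != rj && pairwise_identity(seqs[i], seqs[j]) >= cutoff)
      parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(n), find, integer(1))
  clusters <- unname(split(ids, root))
  structure(list(clusters = clusters, identity_cutoff = cutoff),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition> %d proteins in %d clusters (identity cutoff %g)\n",
              sum(lengths(x$clusters)), length(x$clusters), x$identity_cutoff))
  invisible(x)
}

# Merge the smallest clusters until exactly n remain (used by the
# leave-one-cluster-out feature-reduction protocol, which works on a fixed
# number of clusters regardless of how many the identity cutoff produced).
cluster_to_n <- function(partition, n) {
  cl <- partition$clusters
  if (n < 1L || n > length(cl))
    stop(sprintf("cannot merge %d clusters into %d", length(cl), n))
  while (length(cl) > n) {
    sz <- lengths(cl)
    two <- order(sz)[1:2]
    cl[[two[1L]]] <- c(cl[[two[1L]]], cl[[two[2L]]])
    cl <- cl[-two[2L]]
  }
  structure(list(clusters = cl, identity_cutoff = partition$identity_cutoff),
            class = "cluster_partition")
}

#' Homology-clustered k-fold assignment
#'
#' Assigns whole clusters to folds so that no two proteins sharing identity
#' at or above the clustering cutoff end up in different folds. Clusters are
#' shuffled with the seed, ordered by decreasing size, and dealt round-robin
#' for balance.
#'
#' @param partition a [cluster_sequences()] partition.
#' @param k number of folds; must not exceed the number of clusters.
#' @param seed integer seed for the shuffle.
#' @return list of k character vectors of protein ids, one per fold.
#' @export
clustered_kfold <- function(partition, k, seed = 1L) {
  cl <- partition$clusters
  if (k > length(cl))
    stop(sprintf("k = %d folds but only %d clusters", k, length(cl)))
  ord <- with_local_seed(seed, sample(length(cl)))
  cl <- cl[ord][order(lengths(cl)[ord], decreasing = TRUE)]
  folds <- rep(list(character(0)), k)
  for (i in seq_along(cl)) {
    f <- ((i - 1L) %% k) + 1L
    folds[[f]] <- c(folds[[f]], cl[[i]])
  }
  folds
}

# Cross-validated held-out scores from a precomputed feature matrix.
# `folds` is a list of protein-id vectors; returns the variant table of
# scored rows with a `score` column, in input order.
cv_scores <- function(X, variants, folds, ntree, shrinkage, max_depth,
                      min_leaf, seed) {
  scores <- rep(NA_real_, nrow(variants))
  for (f in seq_along(folds)) {
    test <- variants$protein_id %in% folds[[f]]
    if (!any(test)) next
    train <- !test
    y_tr <- variants$label[train]
    if (length(unique(y_tr)) < 2L)
      stop(sprintf("fold %d: training set has a single class", f))
    fit <- truncpath(X[train, , drop = FALSE], y_tr, ntree = ntree,
                     shrinkage = shrinkage, max_depth = max_depth,
                     min_leaf = min_leaf, seed = seed + f)
    scores[test] <- predict(fit, X[test, , drop = FALSE])
  }
  scores
}

#' Homology-clustered cross-validation
#'
#' Clusters the cohort's proteins by sequence identity, assigns whole
#' clusters to k folds, and for each fold trains a dual balanced
#' boosted-tree pair on the other folds' variants and scores the held-out
#' ones. All held-out scores are pooled, optionally restricted to one
#' variant type, and summarised at the given cutoff. Setting k to the
#' number of clusters gives leave-one-cluster-out validation.
#'
#' @param proteins named list of [protein_record()]s.
#' @param variants labelled variant data.frame (`protein_id`, `position`,
#'   `type`, `label` in pathogenic/neutral).
#' @param schema a [feature_schema()].
#' @param k number of folds, default 10.
#' @param seed integer seed driving the fold shuffle and the per-fold
#'   pathogenic half-splits.
#' @param ntree,shrinkage,max_depth,min_leaf hyperparameters passed to
#'   [truncpath()].
#' @param eval_subset evaluate `"both"` types pooled (default), or only
#'   `"frameshift"` / `"nonsense"` variants; the training sets always
#'   contain both types.
#' @param cutoff call threshold for the summary metrics, default 0.5.
#' @param identity_cutoff clustering identity cutoff, default 0.35.
#' @param partition optional precomputed [cluster_sequences()] partition of
#'   the cohort's proteins, to avoid re-aligning when cross-validating the
#'   same cohort repeatedly.
#' @return object of class `cv_report`: list with `metrics`, `counts`,
#'   `roc`, `auc`, `scores` (pooled held-out scores with labels), `folds`
#'   and `n_clusters`.
#' @export
crossvalidate <- function(proteins, variants, schema = feature_schema(),
                          k = 10L, seed = 1L, ntree = 2000L,
                          shrinkage = 0.005, max_depth = 8L, min_leaf = 1L,
                          eval_subset = c("both", "frameshift", "nonsense"),
                          cutoff = 0.5, identity_cutoff = 0.35,
                          partition = NULL) {
  eval_subset <- match.arg(eval_subset)
  if (!all(variants$label %in% c("pathogenic", "neutral")))
    stop("cross-validation needs pathogenic/neutral labels")
  X <- build_feature_matrix(proteins, variants, schema)
  variants <- attr(X, "variants")
  part <- if (is.null(partition))
    cluster_sequences(proteins[unique(variants$protein_id)],
                      cutoff = identity_cutoff)
  else partition
  folds <- clustered_kfold(part, k, seed = seed)
  scores <- cv_scores(X, variants, folds, ntree, shrinkage, max_depth,
                      min_leaf, seed)
  keep <- if (eval_subset == "both") rep(TRUE, nrow(variants))
          else variants$type == eval_subset
  cm <- confusion(scores[keep], variants$label[keep], cutoff = cutoff)
  roc <- roc_points(scores[keep], variants$label[keep])
  structure(
    list(metrics = classification_metrics(cm), counts = cm, roc = roc,
         auc = roc_auc(roc),
         scores = data.frame(variants[keep, , drop = FALSE],
                             score = scores[keep]),
         folds = folds, n_clusters = length(part$clusters),
         eval_subset = eval_subset, cutoff = cutoff),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Clustered %d-fold cross-validation (%d clusters, subset: %s)\n",
              length(x$folds), x$n_clusters, x$eval_subset))
  m <- x$metrics
  cat(sprintf("  MCC %.3f | sens %.3f | spec %.3f | F %.3f | FPR %.1f%% | FDR %.1f%% | AUC %.3f\n",
              m["mcc"], m["sensitivity"], m["specificity"], m["f_score"],
              100 * m["fpr"], 100 * m["fdr"], x$auc))
  invisible(x)
}

#' Leave-one-cluster-out feature-group reduction
#'
#' Starting from the candidate schema, evaluates the leave-one-cluster-out
#' (LOOCV) MCC at the default 0.5 cutoff with all feature groups, then — in
#' one pass over the groups in schema order — removes each group in turn,
#' re-runs the LOOCV, and discards the group iff its removal strictly
#' improves the MCC over the all-groups baseline. The cohort's proteins are
#' clustered at the identity cutoff and the smallest clusters merged until
#' exactly `n_clusters` remain, each serving once as the held-out set.
#'
#' @param proteins named list of [protein_record()]s.
#' @param variants labelled variant data.frame.
#' @param schema candidate [feature_schema()] (default `candidate66`).
#' @param seed integer seed.
#' @param n_clusters number of LOOCV clusters, default 10.
#' @param ntree,shrinkage,max_depth,min_leaf [truncpath()] hyperparameters.
#' @param cutoff MCC cutoff, default 0.5.
#' @param identity_cutoff clustering identity cutoff, default 0.35.
#' @return list with `schema` (retained [feature_schema()] slots),
#'   `discarded` (character vector of group ids), `baseline_mcc`, and
#'   `ledger` (data.frame of group, mcc_without, discarded).
#' @export
reduce_features <- function(proteins, variants,
                            schema = feature_schema("candidate66"),
                            seed = 1L, n_clusters = 10L, ntree = 2000L,
                            shrinkage = 0.005, max_depth = 8L, min_leaf = 1L,
                            cutoff = 0.5, identity_cutoff = 0.35) {
  groups <- schema_groups(schema)
  if (length(groups) < 2L) stop("candidate schema needs at least two groups")
  X <- build_feature_matrix(proteins, variants, schema)
  variants <- attr(X, "variants")
  part <- cluster_sequences(proteins[unique(variants$protein_id)],
                            cutoff = identity_cutoff)
  part <- cluster_to_n(part, min(n_clusters, length(part$clusters)))
  folds <- clustered_kfold(part, length(part$clusters), seed = seed)
  loocv_mcc <- function(cols) {
    s <- cv_scores(X[, cols, drop = FALSE], variants, folds, ntree,
                   shrinkage, max_depth, min_leaf, seed)
    classification_metrics(confusion(s, variants$label, cutoff))[["mcc"]]
  }
  baseline <- loocv_mcc(seq_len(nrow(schema)))
  ledger <- data.frame(group = groups, mcc_without = NA_real_,
                       discarded = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    cols <- which(schema$group != groups[i])
    ledger$mcc_without[i] <- loocv_mcc(cols)
    ledger$discarded[i] <- ledger$mcc_without[i] > baseline  # strict improvement
  }
  kept <- schema[!(schema$group %in% groups[ledger$discarded]), , drop = FALSE]
  attr(kept, "schema_id") <- attr(schema, "schema_id")
  class(kept) <- class(schema)
  list(schema = kept, discarded = groups[ledger$discarded],
       baseline_mcc = baseline, ledger = ledger)
}
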