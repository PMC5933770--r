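# Run an expression under a temporary RNG state so model fitting is
# deterministic in `seed` without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

as_binary_label <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("pathogenic", "neutral"))
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  as.integer(labels == "pathogenic")
}

#' Fit a truncating-variant pathogenicity classifier
#'
#' Trains the dual balanced boosted-tree model: the pathogenic variants are
#' randomly split into two halves (sizes `ceiling(n/2)` and `floor(n/2)`),
#' and two gradient-boosted regression-tree ensembles are fitted, each on
#' one pathogenic half together with all neutral variants, so that both see
#' a roughly class-balanced training set. A variant's score is the average
#' of the two ensembles' raw scores, clipped to `[0, 1]`; scores at or above
#' the cutoff (default 0.5) are called disease-associated.
#'
#' @param x numeric feature matrix, one row per labelled variant (typically
#'   from [build_feature_matrix()]).
#' @param y labels: `"pathogenic"`/`"neutral"` or 0/1 (1 = pathogenic).
#' @param ntree boosting rounds per model, default 2000.
#' @param shrinkage learning rate, default 0.005.
#' @param max_depth per-tree depth limit, default 8.
#' @param min_leaf minimum samples per leaf, default 1.
#' @param seed integer seed for the pathogenic half-split; the fit is
#'   bit-reproducible given the seed.
#' @return an object of class `truncpath` holding the two `gbt` models.
#' @examples
#' set.seed(7)
#' X <- matrix(rnorm(200 * 3), 200)
#' y <- as.integer(X[, 1] > 0)
#' fit <- truncpath(X, y, ntree = 50, seed = 1)
#' mean((predict(fit, X) >= 0.5) == y)
#' @export
truncpath <- function(x, y, ntree = 2000L, shrinkage = 0.005, max_depth = 8L,
                      min_leaf = 1L, seed = 1L) {
  x <- as.matrix(x)
  y <- as_binary_label(y)
  if (nrow(x) != length(y))
    stop(sprintf("%d labels for %d rows", length(y), nrow(x)))
  path_idx <- which(y == 1L)
  neut_idx <- which(y == 0L)
  if (length(path_idx) == 0L || length(neut_idx) == 0L)
    stop("both classes must be non-empty to train the balanced pair")
  perm <- with_local_seed(seed, sample(path_idx))
  n_half <- ceiling(length(perm) / 2)
  half_a <- sort(perm[seq_len(n_half)])
  half_b <- sort(perm[-seq_len(n_half)])
  fit_one <- function(half) {
    idx <- c(half, neut_idx)
    gbt(x[idx, , drop = FALSE], y[idx], ntree = ntree, shrinkage = shrinkage,
        max_depth = max_depth, min_leaf = min_leaf)
  }
  model_a <- fit_one(half_a)
  model_b <- fit_one(half_b)
  out <- structure(
    list(model_a = model_a, model_b = model_b, split_seed = as.integer(seed),
         half_a = half_a, half_b = half_b,
         n_pathogenic = length(path_idx), n_neutral = length(neut_idx),
         feature_names = colnames(x), call = match.call()),
    class = "truncpath")
  out$fitted <- predict(out, x)
  out$y <- y
  out
}

#' Predict pathogenicity scores
#'
#' @param object a fitted [truncpath()] model.
#' @param newdata numeric feature matrix (or a single row as a vector).
#' @param type `"score"` for the reporting score (mean of the two models,
#'   clipped to `[0, 1]`), `"raw"` for the unclipped mean, or `"call"` for
#'   the binary call at `cutoff`.
#' @param cutoff call threshold, default 0.5; the comparison is inclusive
#'   (`score >= cutoff` is disease-associated).
#' @param evd optional [fit_evd()] null parameters; when supplied the return
#'   value carries a `p_value` attribute with the score p-values.
#' @param ... unused.
#' @return numeric scores (or a character vector of calls for
#'   `type = "call"`).
#' @export
predict.truncpath <- function(object, newdata, type = c("score", "raw", "call"),
                              cutoff = 0.5, evd = NULL, ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  raw <- (predict(object$model_a, newdata) +
            predict(object$model_b, newdata)) / 2
  if (type == "raw") return(raw)
  score <- pmin(pmax(raw, 0), 1)
  if (type == "call")
    return(ifelse(score >= cutoff, "disease-associated", "neutral"))
  if (!is.null(evd)) attr(score, "p_value") <- evd_pvalue(score, evd)
  score
}

#' @export
print.truncpath <- function(x, ...) {
  cat("Truncating-variant pathogenicity classifier (dual balanced boosted trees)\n")
  cat(sprintf("  training set: %d pathogenic (halves %d/%d), %d neutral\n",
              x$n_pathogenic, length(x$half_a), length(x$half_b), x$n_neutral))
  cat(sprintf("  per model: %d trees, shrinkage %g, max depth %d; split seed %d\n",
              x$model_a$ntree, x$model_a$shrinkage, x$model_a$max_depth,
              x$split_seed))
  invisible(x)
}

#' @method summary truncpath
#' @export
summary.truncpath <- function(object, cutoff = 0.5, ...) {
  cm <- confusion(object$fitted, ifelse(object$y == 1L, "pathogenic", "neutral"),
                  cutoff = cutoff)
  met <- classification_metrics(cm)
  out <- list(model = object, cutoff = cutoff, confusion = cm, metrics = met)
  class(out) <- "summary.truncpath"
  out
}

#' @export
print.summary.truncpath <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training confusion at cutoff %.2f: TP=%d FP=%d TN=%d FN=%d\n",
              x$cutoff, x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  cat(sprintf("  training MCC %.3f, F-score %.3f, sens %.3f, spec %.3f\n",
              x$metrics["mcc"], x$metrics["f_score"],
              x$metrics["sensitivity"], x$metrics["specificity"]))
  invisible(x)
}

#' @export
fitted.truncpath <- function(object, ...) object$fitted

#' @method residuals truncpath
#' @export
residuals.truncpath <- function(object, ...) object$y - object$fitted

#' Plot the fitted score distribution by class
#'
#' Overlays the training-score histograms of the two label classes and marks
#' the call threshold.
#'
#' @param x a fitted `truncpath` model.
#' @param cutoff threshold to mark, default 0.5.
#' @param ... passed to [graphics::hist()].
#' @method plot truncpath
#' @export
plot.truncpath <- function(x, cutoff = 0.5, ...) {
  br <- seq(0, 1, by = 0.05)
  h1 <- hist(x$fitted[x$y == 1L], breaks = br, plot = FALSE)
  h0 <- hist(x$fitted[x$y == 0L], breaks = br, plot = FALSE)
  ylim <- c(0, max(h1$density, h0$density))
  plot(h0, freq = FALSE, border = NA, col = grDevices::adjustcolor("steelblue", 0.6),
       xlab = "score", main = "Training scores by class", ylim = ylim, ...)
  plot(h1, freq = FALSE, border = NA, col = grDevices::adjustcolor("firebrick", 0.6),
       add = TRUE)
  abline(v = cutoff, lty = 2)
  legend("top", fill = c("steelblue", "firebrick"),
         legend = c("neutral", "pathogenic"), bty = "n")
  invisible(x)
}

#' Save / load a fitted classifier as portable JSON
#'
#' The two tree ensembles are dumped as flat node tables, so a model file is
#' plain text and readable across platforms.
#'
#' @param model a fitted [truncpath()] model.
#' @param path JSON file path.
#' @return `truncpath_save` returns `path` invisibly; `truncpath_load`
#'   returns the restored `truncpath` model.
#' @export
truncpath_save <- function(model, path) {
  obj <- list(type = "truncpath", version = 1L,
              split_seed = model$split_seed,
              n_pathogenic = model$n_pathogenic,
              n_neutral = model$n_neutral,
              feature_names = model$feature_names,
              model_a = gbt_to_list(model$model_a),
              model_b = gbt_to_list(model$model_b))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path JSON file path.
#' @rdname truncpath_save
#' @export
truncpath_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "truncpath")) stop("not a truncpath model file")
  structure(
    list(model_a = gbt_from_list(obj$model_a),
         model_b = gbt_from_list(obj$model_b),
         split_seed = as.integer(obj$split_seed),
         half_a = integer(0), half_b = integer(0),
         n_pathogenic = as.integer(obj$n_pathogenic),
         n_neutral = as.integer(obj$n_neutral),
         feature_names = obj$feature_names, call = NULL,
         fitted = NULL, y = NULL),
    class = "truncpath")
}
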