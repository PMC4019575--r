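# Random-forest training, variable importance, the two-rule incremental
# feature-selection procedure, and full-map prediction.

#' Random-forest configuration
#'
#' @param ntree number of trees (default 200).
#' @param m predictors drawn at random at each split; `NULL` (default) uses
#'   `floor(sqrt(p))` at fit time.
#' @param seed RNG seed.
#' @param min_node minimum node size (1 grows trees to purity).
#' @return list of class `RFConfig`.
#' @export
rf_config <- function(ntree = 200, m = NULL, seed = 1L, min_node = 1L) {
  stopifnot(ntree >= 1)
  structure(list(ntree = as.integer(ntree),
                 m = if (is.null(m)) NULL else as.integer(m),
                 seed = as.integer(seed), min_node = as.integer(min_node)),
            class = "RFConfig")
}

#' Train a random forest
#'
#' Breiman-style forest: `cfg$ntree` CART trees on bootstrap samples, each
#' split chosen among `m = floor(sqrt(p))` random candidate predictors by Gini
#' impurity. Variable importance defaults to mean decrease in impurity, with
#' out-of-bag permutation importance behind the `importance` flag (the
#' original study does not name its measure; both are exposed). Importances
#' are scaled so the largest value is 1. Deterministic under `cfg$seed`.
#'
#' @param features data.frame/matrix of predictors (no missing values).
#' @param labels class labels (character or factor), length `nrow(features)`.
#' @param cfg an [rf_config()].
#' @param importance `"impurity"` (default) or `"permutation"` (mean decrease
#'   in out-of-bag accuracy when the variable is permuted).
#' @return object of class `bs_rf` with elements `trees`, `classes`,
#'   `variables`, `importance` (data.frame: variable, raw, scaled, sorted
#'   descending), `cfg`.
#' @export
train_rf <- function(features, labels, cfg = rf_config(),
                     importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  X <- as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("train_rf: predictor table contains missing values")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stop("train_rf: need at least 2 classes")
  y <- match(as.character(labels), classes) - 1L
  p <- ncol(X)
  m <- if (is.null(cfg$m)) max(1L, as.integer(floor(sqrt(p)))) else min(cfg$m, p)
  set.seed(cfg$seed)
  fit <- .rf_train_cpp(X, y, length(classes), cfg$ntree, m, cfg$min_node)
  raw <- if (identical(importance, "permutation"))
    .permutation_importance(fit$trees, X, y, length(classes))
  else as.numeric(fit$importance)
  scaled <- if (max(raw) > 0) raw / max(raw) else raw
  imp <- data.frame(variable = colnames(X), raw = raw, scaled = scaled,
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$scaled, imp$variable), ]
  rownames(imp) <- NULL
  structure(list(trees = fit$trees, classes = classes,
                 variables = colnames(X), importance = imp, m = m, cfg = cfg),
            class = "bs_rf")
}

# mean decrease in out-of-bag accuracy when one predictor is permuted,
# averaged over trees (negative contributions floored at 0 before scaling)
.permutation_importance <- function(trees, X, y, n_classes) {
  p <- ncol(X)
  imp <- numeric(p)
  for (tr in trees) {
    oob <- setdiff(seq_len(nrow(X)), tr$inbag + 1L)
    if (length(oob) < 2) next
    one <- list(tr)
    base_pred <- max.col(.rf_votes_cpp(one, X[oob, , drop = FALSE], n_classes),
                         ties.method = "first")
    acc0 <- mean(base_pred - 1L == y[oob])
    for (j in seq_len(p)) {
      Xp <- X[oob, , drop = FALSE]
      Xp[, j] <- Xp[sample(length(oob)), j]
      pj <- max.col(.rf_votes_cpp(one, Xp, n_classes), ties.method = "first")
      imp[j] <- imp[j] + (acc0 - mean(pj - 1L == y[oob]))
    }
  }
  pmax(imp / length(trees), 0)
}

#' @export
print.bs_rf <- function(x, ...) {
  cat(sprintf("Random forest: %d trees, m = %d, %d classes (%s)\n",
              length(x$trees), x$m, length(x$classes),
              paste(x$classes, collapse = ", ")))
  cat("Top importance:\n")
  print(utils::head(x$importance, 5))
  invisible(x)
}

#' Predict classes for a feature table
#'
#' Majority vote over the trees; ties broken by the lowest class id (first in
#' the forest's sorted class vocabulary).
#'
#' @param object a `bs_rf` forest.
#' @param newdata data.frame/matrix with (at least) the forest's variables.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.bs_rf <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  miss <- setdiff(object$variables, names(nd))
  if (length(miss))
    stop(sprintf("missing predictor(s): %s", paste(miss, collapse = ", ")))
  X <- as.matrix(nd[, object$variables, drop = FALSE])
  storage.mode(X) <- "double"
  votes <- .rf_votes_cpp(object$trees, X, length(object$classes))
  object$classes[apply(votes, 1L, which.max)]
}

#' Incremental variable subsets from an importance ranking
#'
#' Encodes the two addition rules of the importance-driven selection
#' procedure: starting from the variables with scaled importance 1, groups of
#' further variables are appended walking down the ranking such that (1) at
#' most three variables are added at a time and (2) the spread of scaled
#' importance within an added group is less than 0.2. Variables with scaled
#' importance at or below `floor` are treated as negligible and never added
#' automatically. Subsets are strictly nested.
#'
#' @param ranking data.frame with `variable` and `scaled` (descending), e.g.
#'   `fit$importance` from [train_rf()].
#' @param floor scaled importance at or below this value is never added
#'   (default 0.05).
#' @param max_add largest group addition (default 3).
#' @param gap importance-spread bound within one addition (default 0.2).
#' @return list of character vectors (nested variable subsets).
#' @export
select_features <- function(ranking, floor = 0.05, max_add = 3, gap = 0.2) {
  r <- ranking[order(-ranking$scaled), , drop = FALSE]
  tol <- 1e-9
  top <- r$scaled >= 1 - tol
  if (!any(top)) top[1] <- TRUE # degenerate ranking: start from the leader
  subsets <- list(r$variable[top])
  rest <- r[!top & r$scaled > floor, , drop = FALSE]
  current <- subsets[[1]]
  i <- 1L
  while (i <= nrow(rest)) {
    grp <- i
    while (length(grp) < max_add && i + length(grp) <= nrow(rest) &&
           (rest$scaled[grp[1]] - rest$scaled[i + length(grp)]) < gap) {
      grp <- c(grp, i + length(grp))
    }
    current <- c(current, rest$variable[grp])
    subsets[[length(subsets) + 1L]] <- current
    i <- i + length(grp)
  }
  subsets
}

#' Train on a subset and evaluate on the held-out split
#'
#' Restricts the feature table to `subset`, trains on the `train` rows,
#' predicts the `test` rows and computes the error matrix and its accuracy
#' statistics. Test predictions never see training rows.
#'
#' @param feature_table data.frame of predictors (one row per ground-truth
#'   point).
#' @param labels,split character vectors aligned with `feature_table`
#'   (`split` in `train`/`test`).
#' @param subset variable names to use (duplicates dropped with a warning).
#' @param cfg an [rf_config()].
#' @return list of class `ModelRun`: `subset`, `fit`, `predictions`,
#'   `truth`, `matrix` (an [error_matrix()]), `stats` (an
#'   [accuracy_stats()] result).
#' @export
run_model <- function(feature_table, labels, split, subset, cfg = rf_config()) {
  if (length(subset) == 0) stop("run_model: empty variable subset")
  if (anyDuplicated(subset)) {
    warning("duplicated variable(s) in subset; deduplicated")
    subset <- unique(subset)
  }
  miss <- setdiff(subset, names(feature_table))
  if (length(miss))
    stop(sprintf("subset variable(s) not in feature table: %s",
                 paste(miss, collapse = ", ")))
  ft <- as.data.frame(feature_table)[, subset, drop = FALSE]
  tr <- split == "train"; te <- split == "test"
  fit <- train_rf(ft[tr, , drop = FALSE], labels[tr], cfg)
  pred <- predict(fit, ft[te, , drop = FALSE])
  em <- error_matrix(pred, labels[te], classes = fit$classes)
  structure(list(subset = subset, fit = fit, predictions = pred,
                 truth = labels[te], matrix = em,
                 stats = accuracy_stats(em)),
            class = "ModelRun")
}

#' @export
print.ModelRun <- function(x, ...) {
  cat(sprintf("ModelRun: %d variables; overall accuracy %.1f%%, kappa %.3f\n",
              length(x$subset), x$stats$overall_accuracy, x$stats$kappa))
  invisible(x)
}

#' Predict a full habitat map from a layer stack
#'
#' Applies the forest to every pixel; pixels with nodata in any of the
#' forest's layers are nodata. Vote ties go to the lowest class id.
#'
#' @param fit a `bs_rf` forest.
#' @param stack a [stack_layers()] result containing the forest's variables.
#' @param subset optional variable subset (defaults to the forest's
#'   variables).
#' @return `RasterGrid` of integer class ids (index into `fit$classes`), with
#'   a `labels` field.
#' @export
predict_map <- function(fit, stack, subset = fit$variables) {
  miss <- setdiff(subset, stack$names)
  if (length(miss))
    stop(sprintf("stack is missing layer(s): %s", paste(miss, collapse = ", ")))
  ref <- stack$layers[[1]]
  X <- vapply(subset, function(nm) as.numeric(stack$layers[[nm]]$values),
              numeric(length(ref$values)))
  colnames(X) <- subset
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    votes <- .rf_votes_cpp(fit$trees, X[ok, , drop = FALSE],
                           length(fit$classes))
    out[ok] <- apply(votes, 1L, which.max)
  }
  g <- with_values(ref, matrix(out, nrow(ref$values), ncol(ref$values)))
  g$labels <- fit$classes
  g
}
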