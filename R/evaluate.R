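# Thematic-map accuracy assessment: error matrix, overall accuracy, Kappa
# with its large-sample (delta-method) variance, pairwise Z tests between
# independent error matrices, per-class user's/producer's accuracy, and the
# all-pairs R^2 layer-correlation table.
#
# Orientation convention (fixed and documented): rows = predicted class,
# columns = reference class.

#' Build an error matrix
#'
#' @param predicted,reference equal-length class label vectors.
#' @param classes class vocabulary (default: sorted union of both vectors).
#' @return object of class `ErrorMatrix`: `counts` (k x k integer matrix,
#'   rows = predicted, cols = reference), `classes`, `N`.
#' @export
error_matrix <- function(predicted, reference, classes = NULL) {
  predicted <- as.character(predicted); reference <- as.character(reference)
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(predicted, reference)))
  bad <- setdiff(unique(c(predicted, reference)), classes)
  if (length(bad))
    stop(sprintf("label(s) outside the class vocabulary: %s",
                 paste(bad, collapse = ", ")))
  counts <- table(factor(predicted, levels = classes),
                  factor(reference, levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(predicted = classes, reference = classes))
  structure(list(counts = counts, classes = classes, N = sum(counts)),
            class = "ErrorMatrix")
}

#' @export
print.ErrorMatrix <- function(x, ...) {
  cat(sprintf("ErrorMatrix (%d classes, N = %d); rows = predicted, cols = reference\n",
              length(x$classes), x$N))
  print(x$counts)
  invisible(x)
}

# the four theta terms of the delta-method kappa variance
.kappa_terms <- function(counts) {
  N <- sum(counts)
  rs <- rowSums(counts); cs <- colSums(counts)
  th1 <- sum(diag(counts)) / N
  th2 <- sum(rs * cs) / N^2
  th3 <- sum(diag(counts) * (rs + cs)) / N^2
  # theta4 = sum_ij x_ij (x_j+ + x_+i)^2 / N^3 : for cell (i,j) the sum of the
  # row total of its *reference* class j and the column total of its
  # *predicted* class i.
  k <- nrow(counts)
  th4 <- 0
  for (i in seq_len(k)) for (j in seq_len(k))
    th4 <- th4 + counts[i, j] * (rs[j] + cs[i])^2
  th4 <- th4 / N^3
  list(th1 = th1, th2 = th2, th3 = th3, th4 = th4, N = N)
}

#' Kappa coefficient and its large-sample variance
#'
#' `kappa = (N * sum x_ii - sum x_i+ x_+i) / (N^2 - sum x_i+ x_+i)`; the
#' variance is the standard four-term delta-method estimator:
#' `var = (1/N) * [ t1(1-t1)/(1-t2)^2 + 2(1-t1)(2 t1 t2 - t3)/(1-t2)^3 +
#' (1-t1)^2 (t4 - 4 t2^2)/(1-t2)^4 ]` with `t1` the observed agreement, `t2`
#' the chance agreement, `t3 = sum x_ii (x_i+ + x_+i)/N^2` and
#' `t4 = sum_ij x_ij (x_j+ + x_+i)^2 / N^3`.
#'
#' @param em an [error_matrix()] (or bare counts matrix).
#' @return list with `kappa`, `variance`.
#' @export
kappa_statistic <- function(em) {
  counts <- if (inherits(em, "ErrorMatrix")) em$counts else em
  t <- .kappa_terms(counts)
  if (t$th2 >= 1) return(list(kappa = NA_real_, variance = NA_real_))
  kappa <- (t$th1 - t$th2) / (1 - t$th2)
  v <- (1 / t$N) * (t$th1 * (1 - t$th1) / (1 - t$th2)^2 +
                      2 * (1 - t$th1) * (2 * t$th1 * t$th2 - t$th3) / (1 - t$th2)^3 +
                      (1 - t$th1)^2 * (t$th4 - 4 * t$th2^2) / (1 - t$th2)^4)
  list(kappa = unname(kappa), variance = unname(v))
}

#' Accuracy statistics of an error matrix
#'
#' @param em an [error_matrix()].
#' @return list of class `EvaluationResult`: `overall_accuracy` (percent),
#'   `kappa`, `kappa_variance`, and `per_class` data.frame with user's,
#'   producer's and mean accuracy (percent; `NA` where a row/column is empty).
#' @export
accuracy_stats <- function(em) {
  counts <- em$counts
  N <- em$N
  if (N <= 0) stop("error matrix is empty")
  rs <- rowSums(counts); cs <- colSums(counts)
  users <- ifelse(rs > 0, 100 * diag(counts) / rs, NA_real_)
  producers <- ifelse(cs > 0, 100 * diag(counts) / cs, NA_real_)
  kap <- kappa_statistic(em)
  structure(list(overall_accuracy = 100 * sum(diag(counts)) / N,
                 kappa = kap$kappa, kappa_variance = kap$variance,
                 per_class = data.frame(class = em$classes,
                                        users = as.numeric(users),
                                        producers = as.numeric(producers),
                                        mean = (as.numeric(users) + as.numeric(producers)) / 2,
                                        stringsAsFactors = FALSE)),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf("Overall accuracy %.2f%%, kappa %.4f (var %.3g)\n",
              x$overall_accuracy, x$kappa, x$kappa_variance))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Pairwise Z test between two error matrices
#'
#' `Z = |kappa_a - kappa_b| / sqrt(var_a + var_b)`, treating the two samples
#' as independent (as in the standard accuracy-assessment practice; note the
#' test is approximate when the two models share test points). Significant at
#' the 95% level iff `Z > 1.96`.
#'
#' @param em_a,em_b [error_matrix()] objects.
#' @return list with `z`, `significant`, `critical` (1.96).
#' @export
z_test <- function(em_a, em_b) {
  ka <- kappa_statistic(em_a); kb <- kappa_statistic(em_b)
  vsum <- ka$variance + kb$variance
  if (!isTRUE(vsum > 0)) {
    warning("zero kappa variance in both matrices; Z undefined")
    return(list(z = NA_real_, significant = NA, critical = 1.96))
  }
  z <- abs(ka$kappa - kb$kappa) / sqrt(vsum)
  list(z = z, significant = z > 1.96, critical = 1.96)
}

#' All-pairs layer correlation (R-squared)
#'
#' Squared Pearson correlation between every pair of layers over the pixels
#' valid in both (pairwise nodata exclusion), with an optional pixel stride
#' for very large grids. Values above `flag_above` mark strongly redundant
#' layers.
#'
#' @param stack a [stack_layers()] result with >= 2 layers.
#' @param stride sample every `stride`-th pixel (default 1 = all pixels).
#' @param flag_above redundancy threshold for the `flagged` matrix (default
#'   0.5).
#' @return list: `r2` (symmetric matrix, diagonal 1, `NA` against constant
#'   layers), `flagged` (logical matrix `r2 > flag_above`).
#' @export
layer_correlation <- function(stack, stride = 1L, flag_above = 0.5) {
  nms <- stack$names
  if (length(nms) < 2) stop("need at least 2 layers")
  vals <- lapply(stack$layers, function(g) {
    v <- as.numeric(g$values)
    if (stride > 1L) v[seq(1L, length(v), by = stride)] else v
  })
  k <- length(nms)
  r2 <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  diag(r2) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- vals[[i]]; b <- vals[[j]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) >= 3 && sd(a[ok]) > 0 && sd(b[ok]) > 0) {
      r <- stats::cor(a[ok], b[ok])
      r2[i, j] <- r2[j, i] <- r^2
    }
  }
  const <- vapply(vals, function(v) {
    f <- v[is.finite(v)]
    length(f) == 0 || sd(f) == 0
  }, logical(1))
  if (any(const))
    warning(sprintf("constant layer(s): %s; R^2 undefined against them",
                    paste(nms[const], collapse = ", ")))
  list(r2 = r2, flagged = r2 > flag_above & row(r2) != col(r2))
}

#' Write evaluation reports as CSV
#'
#' Emits the standard report set for a list of model runs: one error-matrix
#' CSV per run, an accuracy summary (overall accuracy and kappa per run), and
#' the pairwise Z table.
#'
#' @param runs named list of `ModelRun`s.
#' @param dir output directory (created if needed).
#' @param stack optional [stack_layers()] result; when given, the all-pairs
#'   layer R-squared table is written as `layer_r2.csv`.
#' @return invisible vector of files written.
#' @export
write_evaluation_reports <- function(runs, dir, stack = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  summ <- data.frame(model = names(runs),
                     n_variables = vapply(runs, function(r) length(r$subset), 0L),
                     overall_accuracy = vapply(runs, function(r) r$stats$overall_accuracy, 0),
                     kappa = vapply(runs, function(r) r$stats$kappa, 0))
  f <- file.path(dir, "accuracy_summary.csv")
  utils::write.csv(summ, f, row.names = FALSE); files <- c(files, f)
  for (nm in names(runs)) {
    f <- file.path(dir, sprintf("error_matrix_%s.csv", nm))
    utils::write.csv(as.data.frame(runs[[nm]]$matrix$counts), f)
    files <- c(files, f)
  }
  if (length(runs) >= 2) {
    combos <- utils::combn(names(runs), 2)
    zt <- apply(combos, 2L, function(pr) {
      z <- z_test(runs[[pr[1]]]$matrix, runs[[pr[2]]]$matrix)
      data.frame(model_a = pr[1], model_b = pr[2], z = z$z,
                 significant = z$significant)
    })
    f <- file.path(dir, "pairwise_z.csv")
    utils::write.csv(do.call(rbind, zt), f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(stack)) {
    f <- file.path(dir, "layer_r2.csv")
    utils::write.csv(as.data.frame(layer_correlation(stack)$r2), f)
    files <- c(files, f)
  }
  invisible(files)
}
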