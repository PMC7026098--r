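#' Genotype-phenotype classification: process feature matrix, permutation
#' importance, Bernoulli Naive Bayes with IC-stratified evaluation
#'
#' @name classify
NULL

#' Assemble the individuals x processes feature matrix
#'
#' Inner join of the binary process profiles with the cluster labels on
#' individual id; rows without any disrupted process are dropped (and
#' counted).  Columns are ordered by enrichment p-value when supplied.
#' The positive class is the "more severe" cluster.
#'
#' @param profile Binary matrix (rownames = individual ids) from
#'   [individual_ic()].
#' @param labels Named cluster labels.
#' @param ic_sum Named IC sums.
#' @param positive Label value of the more-severe cluster.
#' @param term_order Optional character vector fixing column order
#'   (e.g. terms by increasing p-value).
#' @return List with `x` (binary matrix), `y` (factor, levels
#'   c(negative, positive)), `ic` (numeric), `n_dropped_zero`,
#'   `n_dropped_unlabelled`.
#' @export
build_matrix <- function(profile, labels, ic_sum, positive,
                         term_order = NULL) {
  ids <- intersect(rownames(profile), names(labels))
  if (!length(ids)) stop("no individuals shared between profiles and labels")
  n_unlab <- nrow(profile) - length(ids)
  x <- profile[ids, , drop = FALSE]
  zero <- rowSums(x) == 0
  x <- x[!zero, , drop = FALSE]
  ids <- rownames(x)
  if (!is.null(term_order)) x <- x[, term_order, drop = FALSE]
  lab <- labels[ids]
  if (!positive %in% lab) stop("positive class absent after joining")
  y <- factor(ifelse(lab == positive, "positive", "negative"),
              levels = c("negative", "positive"))
  list(x = x, y = y, ic = ic_sum[ids], n_dropped_zero = sum(zero),
       n_dropped_unlabelled = n_unlab)
}

fold_accuracy <- function(fit, x, y) mean(stats::predict(fit, x) == y)

#' Permutation feature importance under stratified cross-validation
#'
#' For each of `n_folds` stratified folds, a random forest is fit on the
#' training split and its held-out accuracy recorded; each feature's
#' held-out column is then permuted `n_perm` times and the mean accuracy
#' drop recorded.  A feature's importance (mean decrease in accuracy) is
#' the average drop across folds; ranking is descending.
#'
#' @param x Binary feature matrix.
#' @param y Two-level factor.
#' @param n_folds Folds, default 10.
#' @param n_perm Permutation repeats per feature per fold, default 10.
#' @param n_trees Trees per forest, default 200.
#' @param seed Integer seed.
#' @return data.frame with `feature`, `importance`, `rank`, ordered by
#'   rank, plus a `fold_accuracy` attribute.
#' @export
rf_importance <- function(x, y, n_folds = 10L, n_perm = 10L, n_trees = 200L,
                          seed = 1L) {
  y <- droplevels(as.factor(y))
  folds <- stratified_folds(y, n_folds, seed = stage_seed(seed, "folds"))
  p <- ncol(x)
  drops <- matrix(0, n_folds, p, dimnames = list(NULL, colnames(x)))
  accs <- numeric(n_folds)
  xdf <- as.data.frame(x)
  with_seed(stage_seed(seed, "rf"), {
    for (fold in seq_len(n_folds)) {
      tr <- folds != fold; te <- !tr
      if (length(unique(y[tr])) < 2)
        stop("a class is absent from a training fold")
      fit <- randomForest::randomForest(x = xdf[tr, , drop = FALSE], y = y[tr],
                                        ntree = n_trees)
      base <- fold_accuracy(fit, xdf[te, , drop = FALSE], y[te])
      accs[fold] <- base
      for (j in seq_len(p)) {
        drop_j <- numeric(n_perm)
        for (r in seq_len(n_perm)) {
          xp <- xdf[te, , drop = FALSE]
          xp[[j]] <- sample(xp[[j]])
          drop_j[r] <- base - fold_accuracy(fit, xp, y[te])
        }
        drops[fold, j] <- mean(drop_j)
      }
    }
  })
  importance <- colMeans(drops)
  out <- data.frame(feature = colnames(x), importance = importance,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "fold_accuracy") <- accs
  attr(out, "fold_drops") <- drops
  out
}

#' Fit a Bernoulli Naive Bayes classifier
#'
#' Class priors are class frequencies; class-conditional feature
#' probabilities use Laplace smoothing,
#' P(x_f = 1 | y) = (count + alpha) / (n_y + 2 alpha).  With the default
#' alpha = 1 no conditional probability can be 0 or 1, so posteriors are
#' always well defined.
#'
#' @param x Binary matrix (0/1).
#' @param y Two-level factor; both classes must be present.
#' @param alpha Laplace smoothing count, default 1.
#' @return An `nb_model` list with `prior`, `prob1` (classes x features)
#'   and `classes`.
#' @export
nb_fit <- function(x, y, alpha = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("need exactly two classes in training data")
  if (alpha < 0) stop("alpha must be non-negative")
  x <- as.matrix(x)
  classes <- levels(y)
  prior <- as.numeric(table(y)[classes]) / length(y)
  prob1 <- vapply(classes, function(cl) {
    rows <- y == cl
    (colSums(x[rows, , drop = FALSE]) + alpha) / (sum(rows) + 2 * alpha)
  }, numeric(ncol(x)))
  prob1 <- t(matrix(prob1, nrow = ncol(x), ncol = length(classes)))
  dimnames(prob1) <- list(classes, colnames(x))
  structure(list(prior = stats::setNames(prior, classes), prob1 = prob1,
                 classes = classes), class = "nb_model")
}

#' Posterior probabilities from a Bernoulli Naive Bayes model
#'
#' @param model An `nb_model`.
#' @param x Binary matrix with the training features.
#' @return Matrix rows = observations, columns = classes; rows sum to 1.
#' @export
nb_posterior <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(colnames(model$prob1)))
    x <- x[, colnames(model$prob1), drop = FALSE]
  loglik <- vapply(model$classes, function(cl) {
    p <- model$prob1[cl, ]
    as.numeric(x %*% log(p) + (1 - x) %*% log(1 - p)) + log(model$prior[[cl]])
  }, numeric(nrow(x)))
  if (nrow(x) == 1) loglik <- matrix(loglik, 1, dimnames = list(NULL, model$classes))
  m <- apply(loglik, 1, max)
  post <- exp(loglik - m)
  post / rowSums(post)
}

#' Predict classes at the 0.5 posterior threshold
#' @inheritParams nb_posterior
#' @return Factor of predicted classes.
#' @export
nb_predict <- function(model, x) {
  post <- nb_posterior(model, x)
  factor(model$classes[max.col(post, ties.method = "first")],
         levels = model$classes)
}

confusion_metrics <- function(truth, pred, positive = "positive") {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  safe <- function(num, den) if (den > 0) num / den else 0
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  specificity <- safe(tn, tn + fp)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, specificity = specificity,
    f_score = f,
    undefined = as.numeric((tp + fp) == 0 || (tp + fn) == 0 || (tn + fp) == 0))
}

#' Stratified cross-validated Naive Bayes evaluation
#'
#' Stratified `n_folds`-fold split (equal class probabilities per fold);
#' each fold is predicted once by a model trained on the others.
#' Precision, recall, specificity and F score are reported per fold and
#' as means; a metric with a zero denominator in some fold is reported as
#' 0 there and flagged.
#'
#' @param x Binary matrix.
#' @param y Two-level factor (positive = more severe cluster).
#' @param n_folds Folds, default 5.
#' @param alpha Laplace smoothing, default 1.
#' @param seed Integer seed.
#' @return List with `per_fold` (data.frame), `mean` (named numeric),
#'   `n`, `n_undefined_folds`.
#' @export
nb_cv_evaluate <- function(x, y, n_folds = 5L, alpha = 1, seed = 1L) {
  y <- droplevels(as.factor(y))
  folds <- stratified_folds(y, n_folds, seed = stage_seed(seed, "nbcv"))
  per_fold <- t(vapply(seq_len(n_folds), function(fold) {
    tr <- folds != fold
    model <- nb_fit(x[tr, , drop = FALSE], y[tr], alpha = alpha)
    pred <- nb_predict(model, x[!tr, , drop = FALSE])
    confusion_metrics(y[!tr], pred)
  }, numeric(5)))
  per_fold <- as.data.frame(per_fold)
  per_fold$fold <- seq_len(n_folds)
  metric_cols <- c("precision", "recall", "specificity", "f_score")
  list(per_fold = per_fold[c("fold", metric_cols, "undefined")],
       mean = colMeans(per_fold[metric_cols]),
       n = length(y), n_undefined_folds = sum(per_fold$undefined))
}

#' IC-stratified classifier evaluation on cumulative quantile subsets
#'
#' Splits individuals into `q` IC quantiles (1 = highest IC) and runs
#' [nb_cv_evaluate()] on the cumulative subsets Q1, Q1+Q2, ..., all rows.
#' Subsets too small for stratified folds are flagged and skipped.
#'
#' @param x Binary matrix.
#' @param y Two-level factor.
#' @param ic Named IC sums aligned with rows of `x`.
#' @param q Quantiles, default 4.
#' @param n_folds Folds per evaluation, default 5.
#' @param alpha Laplace smoothing, default 1.
#' @param seed Integer seed.
#' @return data.frame with one row per subset: `subset`, `n`,
#'   `precision`, `recall`, `specificity`, `f_score`, `computed`.
#' @export
ic_stratified_evaluation <- function(x, y, ic, q = 4L, n_folds = 5L,
                                     alpha = 1, seed = 1L) {
  quant <- ic_quantiles(ic, q)
  out <- vector("list", q)
  for (m in seq_len(q)) {
    rows <- which(quant <= m)
    subset_name <- if (m == q) "all" else if (m == 1) "Q1" else paste0("Q1-", m)
    ys <- droplevels(as.factor(y[rows]))
    ok <- nlevels(ys) == 2 && all(table(ys) >= n_folds)
    if (ok) {
      ev <- nb_cv_evaluate(x[rows, , drop = FALSE], y[rows],
                           n_folds = n_folds, alpha = alpha,
                           seed = stage_seed(seed, subset_name))
      out[[m]] <- data.frame(subset = subset_name, n = length(rows),
                             t(ev$mean), computed = TRUE,
                             stringsAsFactors = FALSE)
    } else {
      out[[m]] <- data.frame(subset = subset_name, n = length(rows),
                             precision = NA_real_, recall = NA_real_,
                             specificity = NA_real_, f_score = NA_real_,
                             computed = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
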