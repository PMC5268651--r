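# Supervised classification of nuclei: normal vs dysmorphic, with balanced
# sampling, stratified 2/3-1/3 split, 10-fold cross-validated tuning and
# MCR/FNR reporting. "dysmorphic" is the positive class: a false negative is
# a missed dysmorphic nucleus.

#' Split/cross-validation specification
#'
#' @param test_fraction fraction held out as the test set (default 1/3),
#'   stratified so class ratios are preserved.
#' @param cv_folds folds for cross-validated tuning (default 10, stratified).
#' @param seed RNG seed controlling split, folds and model randomness.
#' @return a `split_spec` list.
#' @export
split_spec <- function(test_fraction = 1 / 3, cv_folds = 10, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, cv_folds >= 2)
  structure(list(test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)), class = "split_spec")
}

#' Downsample the majority class to the minority class size
#'
#' @param table data frame with a label column of exactly two classes.
#' @param label_col name of the label column.
#' @param seed RNG seed (same seed, same selection).
#' @return balanced data frame.
#' @export
balance_dataset <- function(table, label_col = "class", seed = 1L) {
  lab <- as.character(table[[label_col]])
  tabs <- table(lab)
  if (length(tabs) != 2) stop("balance_dataset requires exactly two classes")
  nmin <- min(tabs)
  with_seed(seed, {
    keep <- unlist(lapply(names(tabs), function(cl) {
      idx <- which(lab == cl)
      if (length(idx) > nmin) sort(sample(idx, nmin)) else idx
    }))
  })
  table[sort(keep), , drop = FALSE]
}

feature_columns <- function(df, label_col) {
  setdiff(names(df)[vapply(df, is.numeric, TRUE)],
          c(label_col, "nucleus_id", "border_flag"))
}

mcr_fnr <- function(truth, pred, positive = "dysmorphic") {
  mcr <- mean(truth != pred)
  pos <- truth == positive
  fnr <- if (any(pos)) mean(pred[pos] != positive) else NA_real_
  c(mcr = mcr, fnr = fnr)
}

stratified_folds <- function(lab, k) {
  fold <- integer(length(lab))
  for (cl in unique(lab)) {
    idx <- sample(which(lab == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_model <- function(model, x, y, par) {
  switch(model,
    svm_rbf = e1071::svm(x, y, kernel = "radial", cost = par$cost,
                         gamma = par$gamma, probability = FALSE),
    rf = randomForest::randomForest(x, y, ntree = par$ntree, mtry = par$mtry),
    lda = MASS::lda(x, grouping = y),
    qda = MASS::qda(x, grouping = y),
    nb = e1071::naiveBayes(x, y))
}

param_grid <- function(model, p) {
  switch(model,
    svm_rbf = expand.grid(cost = c(0.1, 1, 10, 100),
                          gamma = (1 / p) * c(0.25, 1, 4)),
    rf = expand.grid(ntree = 500, # exposed defaults; the grid tunes mtry
                     mtry = unique(pmin(p, c(2, 3, max(1, floor(sqrt(p))))))),
    data.frame(dummy = 0))
}

#' Train and evaluate a nucleus classifier
#'
#' Stratified 2/3-1/3 train/test split with equal class ratios; features are
#' z-scored using training-set parameters only; hyperparameters are tuned by
#' stratified 10-fold cross-validation on the training set; train (CV) and
#' test misclassification and false-negative rates are reported.
#'
#' @param features data frame of numeric features.
#' @param labels class labels (two classes; `"dysmorphic"` is positive).
#' @param model one of `"svm_rbf"`, `"rf"`, `"lda"`, `"qda"`, `"nb"`.
#' @param split a [split_spec()].
#' @param positive positive class label.
#' @return a `classifier_report`: rates, confusion matrix, best
#'   hyperparameters, and the fitted `model` object reusable with
#'   [predict_nuclei()] / [retrain_from_labels()].
#' @export
train_evaluate <- function(features, labels, model = "svm_rbf",
                           split = split_spec(), positive = "dysmorphic") {
  stopifnot(model %in% c("svm_rbf", "rf", "lda", "qda", "nb"))
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2) stop("exactly two classes required")
  x <- as.matrix(features[vapply(features, is.numeric, TRUE)])
  if (anyNA(x)) stop("features contain missing values")
  with_seed(split$seed, {
    lab <- as.character(labels)
    test_idx <- unlist(lapply(unique(lab), function(cl) {
      idx <- which(lab == cl)
      sample(idx, round(length(idx) * split$test_fraction))
    }))
    train_idx <- setdiff(seq_along(lab), test_idx)
    xtr <- x[train_idx, , drop = FALSE]; ytr <- labels[train_idx]
    xte <- x[test_idx, , drop = FALSE]; yte <- labels[test_idx]
    ctr <- colMeans(xtr); scl <- apply(xtr, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    ztr <- scale(xtr, ctr, scl); zte <- scale(xte, ctr, scl)
    k <- split$cv_folds
    min_class <- min(table(ytr))
    if (min_class < k) {
      warning("reducing CV folds from ", k, " to ", max(2, min_class))
      k <- max(2, min_class)
    }
    fold <- stratified_folds(as.character(ytr), k)
    grid <- param_grid(model, ncol(ztr))
    cv_eval <- function(par) {
      preds <- factor(rep(NA_character_, length(ytr)), levels = levels(ytr))
      for (f in seq_len(k)) {
        tr <- fold != f
        fit <- fit_model(model, ztr[tr, , drop = FALSE], ytr[tr], par)
        p <- switch(model,
          lda = , qda = predict(fit, ztr[!tr, , drop = FALSE])$class,
          nb = predict(fit, as.data.frame(ztr[!tr, , drop = FALSE])),
          predict(fit, ztr[!tr, , drop = FALSE]))
        preds[!tr] <- factor(as.character(p), levels = levels(ytr))
      }
      mcr_fnr(as.character(ytr), as.character(preds), positive)
    }
    cv_rates <- t(apply(grid, 1, function(g) cv_eval(as.list(g))))
    best <- which.min(cv_rates[, "mcr"])
    best_par <- as.list(grid[best, , drop = FALSE])
    final <- fit_model(model, ztr, ytr, best_par)
    pte <- switch(model,
      lda = , qda = predict(final, zte)$class,
      nb = predict(final, as.data.frame(zte)),
      predict(final, zte))
    test <- mcr_fnr(as.character(yte), as.character(pte), positive)
    conf <- table(truth = as.character(yte), predicted = as.character(pte))
  })
  fitted <- structure(list(model = model, fit = final, center = ctr,
                           scale = scl, features = colnames(x),
                           levels = levels(labels), positive = positive,
                           train_table = cbind(as.data.frame(x),
                                               .label = as.character(labels)),
                           split = split, best_par = best_par),
                      class = "nucleus_classifier")
  structure(list(model = model, train_mcr = unname(cv_rates[best, "mcr"]),
                 train_fnr = unname(cv_rates[best, "fnr"]),
                 test_mcr = unname(test["mcr"]), test_fnr = unname(test["fnr"]),
                 confusion = conf, best_par = best_par, classifier = fitted),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("%s: train(CV) MCR %.3f FNR %.3f | test MCR %.3f FNR %.3f\n",
              x$model, x$train_mcr, x$train_fnr, x$test_mcr, x$test_fnr))
  invisible(x)
}

#' Predict nucleus classes with a fitted classifier
#'
#' @param classifier a `nucleus_classifier` from [train_evaluate()].
#' @param features data frame whose columns match the training schema
#'   (mismatches are reported with the missing/extra column names).
#' @return data frame with `label` (and decision scores where the underlying
#'   model provides them).
#' @export
predict_nuclei <- function(classifier, features) {
  stopifnot(inherits(classifier, "nucleus_classifier"))
  have <- names(features)[vapply(features, is.numeric, TRUE)]
  need <- classifier$features
  missing <- setdiff(need, have)
  if (length(missing))
    stop("feature schema mismatch; missing: ", paste(missing, collapse = ", "))
  x <- as.matrix(features[need])
  z <- scale(x, classifier$center, classifier$scale)
  p <- switch(classifier$model,
    lda = , qda = predict(classifier$fit, z)$class,
    nb = predict(classifier$fit, as.data.frame(z)),
    predict(classifier$fit, z))
  data.frame(label = as.character(p), stringsAsFactors = FALSE)
}

#' Retrain a classifier with additional labeled rows
#'
#' Appends newly labeled feature rows to the stored training table and refits
#' with the same split/CV protocol and seed, supporting iterative improvement
#' of predictions as labels accumulate.
#'
#' @param classifier a `nucleus_classifier`.
#' @param new_rows data frame of new feature rows (same schema).
#' @param new_labels their class labels.
#' @return a new `classifier_report` (with the refitted classifier inside).
#' @export
retrain_from_labels <- function(classifier, new_rows = NULL, new_labels = NULL) {
  stopifnot(inherits(classifier, "nucleus_classifier"))
  tab <- classifier$train_table
  feats <- tab[setdiff(names(tab), ".label")]
  labs <- tab$.label
  if (!is.null(new_rows) && nrow(new_rows)) {
    missing <- setdiff(classifier$features, names(new_rows))
    if (length(missing))
      stop("feature schema mismatch; missing: ", paste(missing, collapse = ", "))
    feats <- rbind(feats, new_rows[classifier$features])
    labs <- c(labs, as.character(new_labels))
  }
  train_evaluate(feats, labs, model = classifier$model,
                 split = classifier$split, positive = classifier$positive)
}
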