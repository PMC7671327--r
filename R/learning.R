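#' Classifier specification
#'
#' The four model families used for tissue classification, each with a
#' hyperparameter grid searched in the inner cross-validation loop.
#' Default grids: logistic regression (one-vs-rest, ridge) and linear SVM
#' search C in {0.01, 0.1, 1, 10, 100}; RBF SVM crosses the same C with
#' gamma in {1/p ("scale"), 0.01, 0.1}; random forest searches trees in
#' {100, 300} x mtry in {sqrt(p), p/3}. OVR logistic regression is fitted
#' with glmnet ridge per class at lambda = 1/(C * n_train).
#'
#' @param family One of `"logreg_ovr"`, `"linear_svm"`, `"rbf_svm"`,
#'   `"random_forest"`.
#' @param grid Named list of candidate hyperparameter values (defaults per
#'   family when NULL).
#' @param seed Integer seed for stochastic fits (random forest).
#' @return A list of class `rf_model_spec`.
#' @export
model_spec <- function(family = c("logreg_ovr", "linear_svm", "rbf_svm",
                                  "random_forest"),
                       grid = NULL, seed = 0L) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      logreg_ovr = list(C = c(0.01, 0.1, 1, 10, 100)),
      linear_svm = list(C = c(0.01, 0.1, 1, 10, 100)),
      rbf_svm = list(C = c(0.01, 0.1, 1, 10, 100),
                     gamma = c(NA, 0.01, 0.1)),  # NA = 1/p ("scale")
      random_forest = list(ntree = c(100, 300), mtry_rule = c("sqrt", "third")))
  }
  stopifnot(length(grid) > 0, all(lengths(grid) > 0))
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "rf_model_spec")
}

#' All four default model specifications
#' @param seed Seed shared by the specs.
#' @return Named list of [model_spec()]s.
#' @export
default_model_specs <- function(seed = 0L) {
  fams <- c("logreg_ovr", "linear_svm", "rbf_svm", "random_forest")
  setNames(lapply(fams, model_spec, grid = NULL, seed = seed), fams)
}

#' Cross-validation scheme
#'
#' The evaluation protocol: the data are split `outer_splits` times into
#' stratified train/test partitions with a `test_fraction` held out
#' (default three 90/10 splits); within each training set, hyperparameters
#' are chosen by stratified `inner_folds`-fold CV grid search.
#'
#' @param outer_splits Number of outer repetitions (default 3).
#' @param test_fraction Held-out fraction per split (default 0.10).
#' @param inner_folds Inner CV folds (default 5).
#' @param stratified Stratify splits/folds by class (default TRUE).
#' @param seed Integer seed controlling every split.
#' @return A list of class `rf_cv_scheme`.
#' @export
cv_scheme <- function(outer_splits = 3L, test_fraction = 0.10,
                      inner_folds = 5L, stratified = TRUE, seed = 0L) {
  stopifnot(test_fraction > 0, test_fraction < 1, inner_folds >= 2)
  structure(list(outer_splits = as.integer(outer_splits),
                 test_fraction = test_fraction,
                 inner_folds = as.integer(inner_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "rf_cv_scheme")
}

# ---- internal: splits, fits, grids -------------------------------------

stratified_split <- function(y, test_fraction, seed, stratified = TRUE) {
  set.seed(seed)
  n <- length(y)
  if (!stratified) {
    test <- sample(n, max(1L, round(test_fraction * n)))
    return(list(train = setdiff(seq_len(n), test), test = sort(test)))
  }
  test <- unlist(lapply(split(seq_len(n), y), function(idx) {
    k <- max(1L, round(test_fraction * length(idx)))
    sample(idx, k)
  }), use.names = FALSE)
  list(train = setdiff(seq_len(n), test), test = sort(test))
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (idx in split(seq_along(y), y)) {
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_clf <- function(family, x, y, hyper, seed = 0L) {
  y <- droplevels(factor(y))
  switch(family,
    logreg_ovr = {
      n <- nrow(x)
      lam <- 1 / (hyper$C * n)
      # suppressWarnings: glmnet warns about small per-class counts at
      # desk-scale fold sizes; expected and harmless here
      fits <- lapply(levels(y), function(cl)
        suppressWarnings(
          glmnet::glmnet(x, as.numeric(y == cl), family = "binomial",
                         alpha = 0, lambda = lam, standardize = FALSE)))
      structure(list(fits = fits, classes = levels(y), lambda = lam),
                class = "rf_fit_logreg")
    },
    linear_svm = structure(list(
      model = e1071::svm(x, y, kernel = "linear", cost = hyper$C,
                         scale = FALSE)), class = "rf_fit_svm"),
    rbf_svm = {
      g <- if (is.na(hyper$gamma)) 1 / ncol(x) else hyper$gamma
      structure(list(
        model = e1071::svm(x, y, kernel = "radial", cost = hyper$C,
                           gamma = g, scale = FALSE)), class = "rf_fit_svm")
    },
    random_forest = {
      p <- ncol(x)
      mtry <- if (identical(hyper$mtry_rule, "third"))
        max(1L, floor(p / 3)) else max(1L, floor(sqrt(p)))
      set.seed(seed)
      structure(list(
        model = randomForest::randomForest(x, y, ntree = hyper$ntree,
                                           mtry = mtry)),
        class = "rf_fit_svm")
    },
    stop("unknown model family: ", family))
}

predict_clf <- function(fit, x) {
  if (inherits(fit, "rf_fit_logreg")) {
    scores <- vapply(fit$fits, function(f)
      as.numeric(predict(f, newx = x, s = fit$lambda, type = "link")),
      numeric(nrow(x)))
    if (nrow(x) == 1L) scores <- matrix(scores, nrow = 1)
    fit$classes[max.col(scores, ties.method = "first")]
  } else {
    as.character(predict(fit$model, x))
  }
}

expand_grid_list <- function(grid) {
  df <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# Inner k-fold grid search maximising accuracy; deterministic tie-break on
# grid order. Returns list(hyper, cv_accuracy).
grid_search <- function(x, y, spec, inner_folds, seed, stratified = TRUE) {
  y <- droplevels(factor(y))
  counts <- table(y)
  if (any(counts < inner_folds))
    stop("tissue category '", names(counts)[which.min(counts)], "' has ",
         min(counts), " training samples, fewer than the ", inner_folds,
         " inner folds; merge categories or reduce folds")
  fold <- if (stratified) stratified_folds(y, inner_folds, seed)
          else { set.seed(seed); sample(rep_len(seq_len(inner_folds), length(y))) }
  cands <- expand_grid_list(spec$grid)
  acc <- vapply(cands, function(h) {
    correct <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      fit <- fit_clf(spec$family, x[tr, , drop = FALSE], y[tr], h,
                     seed = spec$seed + f)
      pred <- predict_clf(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == as.character(y[!tr]))
    }
    correct / length(y)
  }, numeric(1))
  best <- which.max(acc)
  list(hyper = cands[[best]], cv_accuracy = acc[best])
}

# Min-Max parameters fitted on training rows only (leakage guard: test
# rows never contribute to the mins/maxs, so transformed test values may
# legitimately fall outside [0, 1]).
fit_minmax_train <- function(xtr) {
  mins <- apply(xtr, 2, min)
  maxs <- apply(xtr, 2, max)
  list(mins = mins, rngs = ifelse(maxs > mins, maxs - mins, 1))
}

apply_minmax_train <- function(x, fit) {
  sweep(sweep(x, 2, fit$mins), 2, fit$rngs, "/")
}

# ---- metrics -----------------------------------------------------------

#' Multiclass classification metrics
#'
#' Accuracy, macro-averaged F1 (unweighted mean of per-class F1; a class
#' with zero precision + recall contributes 0), support-weighted F1, and
#' the multiclass Matthews correlation coefficient (Gorodkin's R_K,
#' computed from the confusion matrix; equals the Pearson correlation of
#' one-hot-encoded predictions and truth, and reduces to the familiar
#' binary MCC for two classes). Metrics are invariant under consistent
#' relabelling of classes.
#'
#' @param predictions,truth Equal-length label vectors (length >= 1).
#' @return List: `accuracy`, `macro_f1`, `weighted_f1`, `mcc`,
#'   `confusion` (truth rows x prediction columns).
#' @export
multiclass_metrics <- function(predictions, truth) {
  if (length(predictions) == 0L || length(predictions) != length(truth))
    stop("predictions and truth must be non-empty and of equal length")
  classes <- sort(unique(c(as.character(predictions), as.character(truth))))
  p <- factor(as.character(predictions), levels = classes)
  t <- factor(as.character(truth), levels = classes)
  cm <- table(truth = t, predicted = p)
  s <- sum(cm)
  diag_sum <- sum(diag(cm))
  tk <- rowSums(cm)  # truth counts
  pk <- colSums(cm)  # prediction counts
  f1 <- vapply(seq_along(classes), function(k) {
    tp <- cm[k, k]
    prec <- if (pk[k] > 0) tp / pk[k] else 0
    rec <- if (tk[k] > 0) tp / tk[k] else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  support <- tk / s
  denom <- sqrt((s^2 - sum(pk^2)) * (s^2 - sum(tk^2)))
  mcc <- if (denom == 0) 0 else (diag_sum * s - sum(tk * pk)) / denom
  list(accuracy = diag_sum / s,
       macro_f1 = mean(f1),
       weighted_f1 = sum(f1 * support),
       mcc = mcc,
       confusion = cm)
}

# ---- nested CV ---------------------------------------------------------

#' Nested cross-validated tissue classification
#'
#' For each outer split: Min-Max scaling is fitted per gene on the
#' training rows only and applied to both partitions (no leakage from test
#' samples); hyperparameters are grid-searched by stratified inner k-fold
#' CV on the training set; the best model is refitted on the full training
#' set and evaluated on the held-out test set. Accuracy, macro-F1 and MCC
#' are aggregated as mean and standard deviation over splits. With a fixed
#' scheme seed the whole procedure is bit-reproducible.
#'
#' @param m An `rf_expr` with tissue categories assigned (values may be
#'   unscaled; scaling happens per split).
#' @param specs A [model_spec()] or list of them.
#' @param scheme A [cv_scheme()].
#' @param labels Optional label vector overriding
#'   `m$sample_meta$tissue_category`.
#' @return Named list (one entry per spec) of lists: `per_split` tibble
#'   (split, accuracy, macro_f1, weighted_f1, mcc), `mean_*`/`sd_*`
#'   scalars, `chosen_hyper` (list per split), `confusion` (pooled).
#' @export
nested_cv <- function(m, specs = default_model_specs(), scheme = cv_scheme(),
                      labels = NULL) {
  if (inherits(specs, "rf_model_spec")) specs <- list(specs)
  x_all <- t(m$values)
  if (anyNA(x_all)) stop("nested_cv requires a complete matrix")
  y_all <- labels %||% m$sample_meta$tissue_category
  if (anyNA(y_all)) stop("assign tissue categories first")
  y_all <- factor(y_all)
  out <- lapply(specs, function(spec) {
    rows <- list(); hypers <- list()
    pooled_pred <- character(); pooled_truth <- character()
    for (s in seq_len(scheme$outer_splits)) {
      split <- stratified_split(y_all, scheme$test_fraction,
                                seed = scheme$seed * 1000L + s,
                                stratified = scheme$stratified)
      xtr <- x_all[split$train, , drop = FALSE]
      xte <- x_all[split$test, , drop = FALSE]
      # per-gene Min-Max fitted on training rows only
      sc <- fit_minmax_train(xtr)
      xtr <- apply_minmax_train(xtr, sc)
      xte <- apply_minmax_train(xte, sc)
      ytr <- droplevels(y_all[split$train])
      gs <- grid_search(xtr, ytr, spec, scheme$inner_folds,
                        seed = scheme$seed * 1000L + 500L + s,
                        stratified = scheme$stratified)
      fit <- fit_clf(spec$family, xtr, ytr, gs$hyper, seed = spec$seed + s)
      pred <- predict_clf(fit, xte)
      truth <- as.character(y_all[split$test])
      met <- multiclass_metrics(pred, truth)
      rows[[s]] <- tibble::tibble(split = s, accuracy = met$accuracy,
                                  macro_f1 = met$macro_f1,
                                  weighted_f1 = met$weighted_f1,
                                  mcc = met$mcc)
      hypers[[s]] <- gs$hyper
      pooled_pred <- c(pooled_pred, pred)
      pooled_truth <- c(pooled_truth, truth)
    }
    per_split <- dplyr::bind_rows(rows)
    list(family = spec$family,
         per_split = per_split,
         mean_accuracy = mean(per_split$accuracy),
         sd_accuracy = sd(per_split$accuracy),
         mean_macro_f1 = mean(per_split$macro_f1),
         sd_macro_f1 = sd(per_split$macro_f1),
         mean_mcc = mean(per_split$mcc),
         sd_mcc = sd(per_split$mcc),
         chosen_hyper = hypers,
         confusion = multiclass_metrics(pooled_pred, pooled_truth)$confusion)
  })
  names(out) <- vapply(specs, `[[`, character(1), "family")
  out
}

# ---- cross-species transfer --------------------------------------------

#' Exact one-tailed binomial significance
#'
#' Upper-tail probability `P(X >= n_correct)` for
#' `X ~ Binomial(n, p0)` — the significance of a cross-species tissue
#' prediction tally under a chance null.
#'
#' @param n_correct,n Correct predictions and total predictions.
#' @param p0 Null success probability in (0, 1).
#' @return The exact one-tailed p-value.
#' @export
binomial_significance <- function(n_correct, n, p0) {
  stopifnot(n_correct >= 0, n_correct <= n, n >= 1)
  if (!is.numeric(p0) || length(p0) != 1 || is.na(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must be a single number strictly between 0 and 1")
  pbinom(n_correct - 1, n, p0, lower.tail = FALSE)
}

#' Cross-species tissue-prediction transfer test
#'
#' Trains a tissue classifier on one species (typically human) and asks
#' whether it predicts tissue identity in another species better than
#' chance. Genes are intersected (test genes with any missing value are
#' dropped, since classifiers need complete features), training samples
#' are restricted to the tissue categories present in the test set, and
#' both matrices are Min-Max scaled independently per gene — deliberately
#' mirroring the protocol in which train and test are normalised
#' separately. Hyperparameters are grid-searched by inner CV on the
#' training set; the tally of correct test predictions is scored with an
#' exact one-tailed binomial test against `p0` (default: uniform chance,
#' 1/number of test categories; `p0 = "majority"` uses the training
#' majority-class frequency instead).
#'
#' @param train,test `rf_expr` objects with tissue categories assigned;
#'   `test` holds one species.
#' @param spec A [model_spec()].
#' @param scheme A [cv_scheme()] (only `inner_folds`, `stratified` and
#'   `seed` are used).
#' @param p0 Null probability: a number, or `"uniform"`/`"majority"`.
#' @return A list of class `rf_transfer`: `species`, `tissues_used`,
#'   `genes_used`, `n_test`, `n_correct`, `chance_p0`, `binomial_p`,
#'   `predictions` tibble.
#' @export
cross_species_transfer <- function(train, test, spec = model_spec("logreg_ovr"),
                                   scheme = cv_scheme(), p0 = "uniform") {
  if (anyNA(test$sample_meta$tissue_category) ||
      anyNA(train$sample_meta$tissue_category))
    stop("assign tissue categories to both matrices first")
  complete_test <- rownames(test$values)[
    rowSums(is.na(test$values)) == 0]
  genes <- intersect(rownames(train$values), complete_test)
  if (length(genes) == 0L) stop("no shared complete genes between matrices")
  test_tissues <- unique(test$sample_meta$tissue_category)
  if (length(test_tissues) < 2L)
    stop("test set has fewer than 2 tissue categories")
  missing_cat <- setdiff(test_tissues, train$sample_meta$tissue_category)
  if (length(missing_cat))
    stop("test categories absent from training data: ",
         paste(missing_cat, collapse = ", "))
  tr_cols <- train$sample_meta$tissue_category %in% test_tissues
  xtr <- t(train$values[genes, tr_cols, drop = FALSE])
  ytr <- factor(train$sample_meta$tissue_category[tr_cols])
  xte <- t(test$values[genes, , drop = FALSE])
  yte <- test$sample_meta$tissue_category
  # independent per-gene Min-Max on each matrix
  xtr <- apply(xtr, 2, minmax_vec)
  xte <- apply(xte, 2, minmax_vec)
  if (is.null(dim(xte))) xte <- matrix(xte, nrow = 1, dimnames = list(NULL, genes))
  gs <- grid_search(xtr, ytr, spec, scheme$inner_folds,
                    seed = scheme$seed, stratified = scheme$stratified)
  fit <- fit_clf(spec$family, xtr, ytr, gs$hyper, seed = spec$seed)
  pred <- predict_clf(fit, xte)
  n_correct <- sum(pred == yte)
  chance <- if (identical(p0, "uniform")) 1 / length(test_tissues)
            else if (identical(p0, "majority")) max(table(ytr)) / length(ytr)
            else p0
  structure(list(
    species = unique(test$sample_meta$species)[1],
    tissues_used = sort(test_tissues),
    genes_used = genes,
    n_test = length(yte),
    n_correct = n_correct,
    chance_p0 = chance,
    binomial_p = binomial_significance(n_correct, length(yte), chance),
    chosen_hyper = gs$hyper,
    predictions = tibble::tibble(sample_id = test$sample_meta$sample_id,
                                 truth = yte, predicted = pred)),
    class = "rf_transfer")
}
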