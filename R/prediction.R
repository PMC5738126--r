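FEATURE_FAMILIES <- c("BFI", "personality", "mobility", "network")

BFI_TRAITS <- c("openness", "conscientiousness", "extraversion",
                "agreeableness", "neuroticism")

#' Assemble the participant x indicator feature table
#'
#' Joins trait scores, mobility indicators and network indicators for a
#' common filtered cohort into one row per participant, and tags every
#' column with its feature family (BFI, other personality traits, mobility,
#' network). Missing stage data stays missing here; imputation happens
#' downstream.
#'
#' @param cohort a filtered [cohort()].
#' @param traits trait table with an `id` column.
#' @param mobility output of [mobility_indicator_table()].
#' @param network output of [network_indicator_table()].
#' @return List with `features` (data frame, rownames = id), `labels`
#'   (factor with levels `c("M", "F")`; `"F"` is the positive class) and
#'   `families` (named character vector column -> family).
#' @export
assemble_features <- function(cohort, traits, mobility, network) {
  ids <- cohort$participants$id
  lab <- gender_labels(cohort)
  if (anyNA(lab)) stop("every participant needs a gender label")
  tr <- traits[match(ids, traits$id), setdiff(names(traits), "id"),
               drop = FALSE]
  rownames(tr) <- ids
  features <- cbind(tr, mobility[ids, , drop = FALSE],
                    network[ids, , drop = FALSE])
  families <- c(
    setNames(ifelse(names(tr) %in% BFI_TRAITS, "BFI", "personality"),
             names(tr)),
    setNames(rep("mobility", ncol(mobility)), names(mobility)),
    setNames(rep("network", ncol(network)), names(network)))
  list(features = features,
       labels = factor(lab[ids], levels = c("M", "F")),
       families = families[names(features)])
}

#' F1 score for the positive class
#'
#' Harmonic mean of precision (fraction of predicted positives that are
#' positive) and recall (fraction of positives identified); 0 when both
#' are undefined or zero.
#'
#' @param truth,pred factors or character vectors of labels.
#' @param positive positive-class label (default `"F"`).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(truth, pred, positive = "F") {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' ROC-AUC with the female class as positive
#'
#' @param truth factor/character labels.
#' @param score numeric scores, higher = more likely positive.
#' @param positive positive-class label.
#' @return Area under the ROC curve.
#' @export
roc_auc <- function(truth, score, positive = "F") {
  if (length(unique(score)) < 2) return(0.5)
  r <- pROC::roc(response = as.character(truth), predictor = score,
                 levels = c(setdiff(unique(as.character(truth)), positive),
                            positive),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Imbalance-aware random-classifier baselines
#'
#' A random classifier has ROC-AUC 0.5 regardless of class balance. A
#' classifier that predicts the positive class with probability equal to
#' its prevalence p has expected precision p and expected recall p, hence
#' expected F1 = p.
#'
#' @param labels factor/character gender labels, both classes present.
#' @param positive positive-class label.
#' @return List with `auc_random` and `f1_random`.
#' @export
random_baselines <- function(labels, positive = "F") {
  if (length(unique(as.character(labels))) < 2)
    stop("random_baselines requires both classes")
  p <- mean(labels == positive)
  list(auc_random = 0.5, f1_random = p)
}

#' Monte-Carlo estimate of the random-classifier F1
#'
#' Simulates `n_sim` random prediction vectors (each participant predicted
#' positive independently with probability equal to the prevalence) and
#' averages the resulting F1 scores, confirming the analytic baseline.
#'
#' @param labels gender labels.
#' @param n_sim number of simulated prediction vectors.
#' @param seed optional seed.
#' @param positive positive-class label.
#' @return Mean simulated F1.
#' @export
random_f1_montecarlo <- function(labels, n_sim = 1e5, seed = NULL,
                                 positive = "F") {
  if (!is.null(seed)) set.seed(seed)
  n_pos <- sum(labels == positive)
  n_neg <- sum(labels != positive)
  p <- n_pos / (n_pos + n_neg)
  tp <- rbinom(n_sim, n_pos, p)
  fp <- rbinom(n_sim, n_neg, p)
  fn <- n_pos - tp
  f1 <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  mean(f1)
}

#' Hyperparameter grids for the five classifier families
#'
#' `default_model_grid()` reproduces the published tuning grid: logistic
#' regression C in \{0.1, 1, 0.2, 0.5, 1, 2, 5, 10\} (the printed grid
#' lists 1 twice; 0.1 is included as the likely intended value), forests
#' and boosting with 1000 estimators and max-features in
#' \{all, sqrt, log2\}, AdaBoost/gradient-boosting learning-rate grids,
#' and SVC over four kernels with C in \{0.01 ... 10\}.
#' `small_model_grid()` is a desk-scale reduction (200 estimators, one or
#' two values per knob) for tests and quick runs.
#'
#' @param n_estimators trees/rounds for the ensemble families.
#' @return Named list family -> data frame of parameter combinations.
#' @export
default_model_grid <- function(n_estimators = 1000L) {
  list(
    logistic = data.frame(C = c(0.1, 1, 0.2, 0.5, 1, 2, 5, 10)),
    random_forest = expand.grid(
      max_features = c("all", "sqrt", "log2"),
      n_estimators = n_estimators, stringsAsFactors = FALSE),
    gradient_boosting = expand.grid(
      max_features = c("all", "sqrt", "log2"),
      learning_rate = c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05),
      n_estimators = n_estimators, stringsAsFactors = FALSE),
    adaboost = expand.grid(
      learning_rate = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1.0),
      n_estimators = n_estimators, stringsAsFactors = FALSE),
    svc = expand.grid(
      C = c(0.01, 0.05, 0.1, 0.5, 1, 5, 10),
      kernel = c("linear", "poly", "rbf", "sigmoid"),
      stringsAsFactors = FALSE))
}

#' @rdname default_model_grid
#' @export
small_model_grid <- function(n_estimators = 200L) {
  list(
    logistic = data.frame(C = c(0.1, 1, 10)),
    random_forest = expand.grid(
      max_features = "sqrt", n_estimators = n_estimators,
      stringsAsFactors = FALSE),
    gradient_boosting = expand.grid(
      max_features = "log2", learning_rate = 0.02,
      n_estimators = n_estimators, stringsAsFactors = FALSE),
    adaboost = expand.grid(
      learning_rate = 0.2, n_estimators = n_estimators,
      stringsAsFactors = FALSE),
    svc = expand.grid(C = c(1, 10), kernel = c("linear", "rbf"),
                      stringsAsFactors = FALSE))
}

mtry_from_max_features <- function(max_features, p) {
  switch(max_features,
         all = p,
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         stop("unknown max_features: ", max_features))
}

# Fit one configured model on (xtr, ytr), return scores and hard labels
# for xte. y levels are c("M", "F"): "F" is the positive class.
fit_score_model <- function(family, params, xtr, ytr, xte) {
  p <- ncol(xtr)
  if (family == "logistic") {
    fit <- glmnet::glmnet(as.matrix(xtr), ytr, family = "binomial",
                          alpha = 0,
                          lambda = 1 / (params$C * nrow(xtr)))
    score <- as.numeric(predict(fit, as.matrix(xte), type = "link"))
    cls <- factor(ifelse(score > 0, "F", "M"), levels = levels(ytr))
  } else if (family == "random_forest") {
    fit <- randomForest::randomForest(
      x = xtr, y = ytr, ntree = params$n_estimators,
      mtry = mtry_from_max_features(params$max_features, p))
    score <- predict(fit, xte, type = "prob")[, "F"]
    cls <- predict(fit, xte, type = "response")
  } else if (family == "gradient_boosting") {
    dtr <- xgboost::xgb.DMatrix(as.matrix(xtr),
                                label = as.integer(ytr == "F"))
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = params$learning_rate, max_depth = 3,
                    colsample_bynode =
                      mtry_from_max_features(params$max_features, p) / p,
                    nthread = 1),
      data = dtr, nrounds = params$n_estimators, verbose = 0)
    score <- predict(fit, xgboost::xgb.DMatrix(as.matrix(xte)))
    cls <- factor(ifelse(score > 0.5, "F", "M"), levels = levels(ytr))
  } else if (family == "adaboost") {
    fit <- adaboost_fit(xtr, ytr, n_rounds = params$n_estimators,
                        learning_rate = params$learning_rate)
    score <- predict(fit, xte, type = "score")
    cls <- predict(fit, xte, type = "class")
  } else if (family == "svc") {
    kern <- switch(params$kernel, linear = "linear",
                   poly = "polynomial", rbf = "radial",
                   sigmoid = "sigmoid",
                   stop("unknown kernel: ", params$kernel))
    fit <- e1071::svm(x = as.matrix(xtr), y = ytr, cost = params$C,
                      kernel = kern, scale = TRUE)
    pr <- predict(fit, as.matrix(xte), decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    score <- if (colnames(dv)[1] == "F/M") dv[, 1] else -dv[, 1]
    cls <- pr
  } else stop("unknown model family: ", family)
  list(score = as.numeric(score), class = cls)
}

#' Cross-validated grid search and evaluation of the classifier families
#'
#' For every model family and every grid point, runs stratified k-fold
#' cross-validation, averages ROC-AUC and F1 over the held-out folds, and
#' selects — per family — the configuration with the highest harmonic mean
#' of the two averages. The reported scores are the held-out means of the
#' selected configuration. Feature importance is taken from a random
#' forest refitted on the full data with the selected forest parameters.
#'
#' @param features complete (imputed) numeric feature data frame.
#' @param labels factor with levels `c("M", "F")`.
#' @param grid model grid, see [default_model_grid()].
#' @param n_folds number of stratified folds (default 10).
#' @param seed integer seed controlling fold assignment and all stochastic
#'   learners; fixed seed means bit-reproducible evaluation.
#' @return Object of class `evaluation_report`: list with `models` (data
#'   frame: family, selected params, mean AUC, mean F1, harmonic mean),
#'   `baselines`, `importance` (ranked data frame), `n_folds`, `grid`.
#' @export
tune_and_evaluate <- function(features, labels, grid = default_model_grid(),
                              n_folds = 10L, seed = NULL) {
  stopifnot(is.factor(labels), nlevels(labels) == 2)
  if (anyNA(features)) stop("features must be complete; impute first")
  if (!is.null(seed)) set.seed(seed)
  folds <- caret::createFolds(labels, k = n_folds)
  if (any(vapply(folds, function(i) length(unique(labels[-i])) < 2 ||
                 length(unique(labels[i])) < 2, logical(1))))
    stop("stratification error: a fold lacks one of the classes")

  eval_config <- function(family, params) {
    aucs <- numeric(length(folds)); f1s <- numeric(length(folds))
    for (fi in seq_along(folds)) {
      te <- folds[[fi]]
      res <- fit_score_model(family, params,
                             features[-te, , drop = FALSE], labels[-te],
                             features[te, , drop = FALSE])
      aucs[fi] <- roc_auc(labels[te], res$score)
      f1s[fi] <- f1_score(labels[te], res$class)
    }
    c(auc = mean(aucs), f1 = mean(f1s))
  }

  rows <- list()
  for (family in names(grid)) {
    gr <- grid[[family]]
    best <- NULL
    for (ri in seq_len(nrow(gr))) {
      params <- as.list(gr[ri, , drop = FALSE])
      sc <- eval_config(family, params)
      hm <- if (sc[["auc"]] + sc[["f1"]] == 0) 0 else
        2 * sc[["auc"]] * sc[["f1"]] / (sc[["auc"]] + sc[["f1"]])
      if (is.null(best) || hm > best$hm)
        best <- list(params = params, auc = sc[["auc"]],
                     f1 = sc[["f1"]], hm = hm)
    }
    rows[[family]] <- data.frame(
      model = family,
      params = paste(names(best$params),
                     vapply(best$params, as.character, ""),
                     sep = "=", collapse = ", "),
      auc = best$auc, f1 = best$f1, harmonic_mean = best$hm,
      stringsAsFactors = FALSE)
  }
  models <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  rf_params <- if ("random_forest" %in% names(grid)) {
    sel <- strsplit(models$params[models$model == "random_forest"],
                    ", ")[[1]]
    mf <- sub("max_features=", "", sel[grepl("max_features=", sel)])
    nt <- as.integer(sub("n_estimators=", "",
                         sel[grepl("n_estimators=", sel)]))
    list(max_features = mf, n_estimators = nt)
  } else list(max_features = "all", n_estimators = 1000L)
  importance <- feature_importance(
    features, labels, n_estimators = rf_params$n_estimators,
    max_features = rf_params$max_features)

  structure(list(models = models, baselines = random_baselines(labels),
                 importance = importance, n_folds = n_folds),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation report> %d-fold stratified CV\n", x$n_folds))
  print(transform(x$models, auc = round(auc, 3), f1 = round(f1, 3),
                  harmonic_mean = round(harmonic_mean, 3)))
  cat(sprintf("baselines: AUC %.2f, F1 %.2f\n", x$baselines$auc_random,
              x$baselines$f1_random))
  cat("top features:",
      paste(utils::head(x$importance$feature, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Random-forest feature-importance ranking
#'
#' Fits a random forest to the complete feature table and returns the
#' per-feature mean decrease in Gini impurity, normalized to sum to 1 and
#' sorted in descending order.
#'
#' @param features complete numeric feature data frame.
#' @param labels factor gender labels.
#' @param n_estimators number of trees.
#' @param max_features `"all"`, `"sqrt"` or `"log2"`.
#' @param seed optional seed.
#' @return Data frame with columns `feature`, `importance` (sums to 1).
#' @export
feature_importance <- function(features, labels, n_estimators = 1000L,
                               max_features = "all", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fit <- randomForest::randomForest(
    x = features, y = labels, ntree = n_estimators,
    mtry = mtry_from_max_features(max_features, ncol(features)))
  imp <- fit$importance[, "MeanDecreaseGini"]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}
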