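#' Discrete AdaBoost (SAMME) over decision stumps
#'
#' Classic discrete AdaBoost for a binary outcome: depth-1 rpart trees are
#' fitted to reweighted samples; each round's stump gets voting weight
#' `learning_rate * log((1-err)/err)` and sample weights are tilted toward
#' the points it misclassified. The decision score is the weighted vote
#' margin for the positive class, a monotone ranking score suitable for
#' ROC analysis.
#'
#' @param x data frame or matrix of numeric features.
#' @param y factor with exactly two levels; the second level is the
#'   positive class.
#' @param n_rounds number of boosting rounds.
#' @param learning_rate shrinkage applied to each stump's vote.
#' @return Object of class `adaboost`.
#' @export
adaboost_fit <- function(x, y, n_rounds = 200L, learning_rate = 1) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  stopifnot(nlevels(y) == 2)
  yy <- ifelse(y == levels(y)[2], 1, -1)
  n <- length(yy)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  dat <- cbind(.y = factor(yy, levels = c(-1, 1)), x)
  used <- 0L
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w,
                        method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = -1, minsplit = 2,
                          minbucket = 1, xval = 0))
    pred <- ifelse(predict(fit, dat, type = "class") == "1", 1, -1)
    err <- sum(w[pred != yy])
    if (err <= 0) { # perfect stump: give it a large finite vote and stop
      stumps[[r]] <- fit; alphas[r] <- learning_rate * 10; used <- r
      break
    }
    if (err >= 0.5) { used <- r - 1L; break }
    alpha <- learning_rate * log((1 - err) / err)
    stumps[[r]] <- fit
    alphas[r] <- alpha
    w <- w * exp(alpha * (pred != yy))
    w <- w / sum(w)
    used <- r
  }
  structure(list(stumps = stumps[seq_len(used)],
                 alphas = alphas[seq_len(used)],
                 levels = levels(y)),
            class = "adaboost")
}

#' @rdname adaboost_fit
#' @param object fitted `adaboost` model.
#' @param newdata data frame of features.
#' @param type `"score"` for the signed vote margin (positive = positive
#'   class), `"class"` for hard labels.
#' @param ... unused.
#' @export
predict.adaboost <- function(object, newdata,
                             type = c("score", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  score <- rep(0, nrow(newdata))
  for (r in seq_along(object$stumps)) {
    pred <- ifelse(predict(object$stumps[[r]], newdata,
                           type = "class") == "1", 1, -1)
    score <- score + object$alphas[r] * pred
  }
  total <- sum(abs(object$alphas))
  if (total > 0) score <- score / total
  if (type == "score") return(score)
  factor(ifelse(score > 0, object$levels[2], object$levels[1]),
         levels = object$levels)
}
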