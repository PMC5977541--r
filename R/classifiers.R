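# Thin, uniformly-scored wrappers around the four patch classifiers.
# Every classifier returns scores in (0, 1) with 0.5 as the positive-call
# threshold (margin-based classifiers are passed through a logistic link,
# which leaves ROC/AUC unchanged).

classifierKinds <- c("random_forest", "neural_net", "svm", "lda")

#' Fit one of the four patch-level classifiers
#'
#' \code{"random_forest"}: bagging of 50 classification trees
#' (\code{randomForest} with \code{mtry = p}); \code{"neural_net"}: a
#' 10-node single-hidden-layer feedforward network (\code{nnet});
#' \code{"svm"}: a degree-3 polynomial-kernel support vector machine
#' (\code{e1071}); \code{"lda"}: pseudolinear discriminant analysis with a
#' pseudo-inverse pooled covariance, robust to rank deficiency. Features are
#' expected to be standardized by the caller.
#'
#' @param X training patches x features matrix.
#' @param y binary labels (0/1).
#' @param kind classifier kind.
#' @param seed integer seed for the stochastic fits.
#' @param hyperparams optional list overriding the defaults
#'   (\code{ntree}, \code{size}, \code{decay}, \code{maxit},
#'   \code{degree}, \code{cost}).
#' @return an opaque model object for \code{\link{predictScores}}.
#' @export
fitClassifier <- function(X, y, kind = classifierKinds, seed = 1L,
                          hyperparams = list()) {
  kind <- match.arg(kind)
  y <- asBinaryLabels(y)
  hp <- function(name, default) hyperparams[[name]] %||% default
  model <- switch(kind,
    random_forest = withSeed(seed, randomForest::randomForest(
      x = X, y = factor(y, levels = c(0, 1)),
      ntree = hp("ntree", 50L), mtry = ncol(X))),
    neural_net = withSeed(seed, nnet::nnet(
      x = X, y = y, size = hp("size", 10L), decay = hp("decay", 1e-2),
      maxit = hp("maxit", 150L), entropy = TRUE, trace = FALSE,
      MaxNWts = 100000L)),
    svm = withSeed(seed, e1071::svm(
      x = X, y = factor(y, levels = c(0, 1)), kernel = "polynomial",
      degree = hp("degree", 3L), cost = hp("cost", 1), scale = FALSE)),
    lda = fitPseudoLda(X, y)
  )
  structure(list(kind = kind, model = model), class = "nucmorphClassifier")
}

fitPseudoLda <- function(X, y) {
  X <- as.matrix(X)
  i1 <- y == 1; i0 <- y == 0
  mu0 <- colMeans(X[i0, , drop = FALSE])
  mu1 <- colMeans(X[i1, , drop = FALSE])
  n0 <- sum(i0); n1 <- sum(i1)
  C0 <- crossprod(sweep(X[i0, , drop = FALSE], 2, mu0))
  C1 <- crossprod(sweep(X[i1, , drop = FALSE], 2, mu1))
  pooled <- (C0 + C1) / max(1, n0 + n1 - 2)
  W <- MASS::ginv(pooled)
  w <- drop(W %*% (mu1 - mu0))
  b <- -sum(w * (mu0 + mu1) / 2) + log(n1 / n0)
  list(w = w, b = b)
}

#' Score patches with a fitted classifier
#'
#' @param model a \code{\link{fitClassifier}} result.
#' @param X patches x features matrix (same columns as at fit time).
#' @return numeric scores in (0, 1); >= 0.5 is the positive call.
#' @export
predictScores <- function(model, X) {
  stopifnot(inherits(model, "nucmorphClassifier"))
  X <- as.matrix(X)
  switch(model$kind,
    random_forest = {
      unname(stats::predict(model$model, X, type = "prob")[, "1"])
    },
    neural_net = as.numeric(stats::predict(model$model, X)),
    svm = {
      pr <- stats::predict(model$model, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      s <- as.numeric(dv[, 1])
      # orient the margin so positive values favor class "1"
      if (startsWith(colnames(dv)[1], "0")) s <- -s
      stats::plogis(s)
    },
    lda = stats::plogis(drop(X %*% model$model$w) + model$model$b)
  )
}
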