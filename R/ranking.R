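# The four feature-ranking schemes: Wilcoxon rank-sum, PLS-VIP, and the two
# minimum-redundancy maximum-relevance variants (MID, MIQ).

asBinaryLabels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  u <- sort(unique(y))
  stopIfNot(length(u) == 2, "labels must have exactly two classes")
  as.integer(y == u[2])
}

#' Wilcoxon rank-sum feature ranking
#'
#' Orders features by the two-sided rank-sum p-value (normal approximation
#' with tie and continuity correction) of the class difference. Constant
#' features get p = 1 by convention. Ties in p are broken by |z| descending,
#' then by catalog (column) order.
#'
#' @param X patches x features numeric matrix (no NaN rows).
#' @param y binary labels (two classes, both non-empty).
#' @return a \linkS4class{RankingResult} with p-values as scores.
#' @export
ranksumRank <- function(X, y) {
  y <- asBinaryLabels(y)
  stopIfNot(any(y == 1) && any(y == 0), "both classes must be non-empty")
  n1 <- sum(y == 1); n2 <- sum(y == 0); n <- n1 + n2
  res <- vapply(seq_len(ncol(X)), function(j) {
    r <- rank(X[, j])
    R1 <- sum(r[y == 1])
    mu <- n1 * (n + 1) / 2
    ties <- table(X[, j])
    tieAdj <- sum(ties^3 - ties) / (n * (n - 1))
    s2 <- n1 * n2 / 12 * ((n + 1) - tieAdj)
    if (s2 <= 0) return(c(p = 1, z = 0))
    d <- R1 - mu
    z <- (d - sign(d) * 0.5) / sqrt(s2)
    c(p = min(1, 2 * pnorm(-abs(z))), z = z)
  }, numeric(2))
  ord <- order(res["p", ], -abs(res["z", ]), seq_len(ncol(X)))
  new("RankingResult", method = "ranksum",
      orderedFeatures = colnames(X)[ord], scores = res["p", ord])
}

#' PLS-VIP feature ranking
#'
#' Fits a projection-to-latent-structures (PLS1, NIPALS) regression of the
#' binary class on the z-scored features and ranks features by their
#' Variable Importance in Projection,
#' \deqn{VIP_j = \sqrt{p \sum_k SS_k w_{jk}^2 / \sum_k SS_k}}
#' with \eqn{SS_k} the y-variance explained by component k and \eqn{w_k}
#' the (unit-norm) component weights; the identity
#' \eqn{(1/p)\sum_j VIP_j^2 = 1} holds for any fit.
#'
#' @param X patches x features matrix.
#' @param y binary labels.
#' @param nComponents number of latent components (default 2).
#' @return a \linkS4class{RankingResult} with VIP scores (descending).
#' @export
plsVipRank <- function(X, y, nComponents = 2L) {
  y <- asBinaryLabels(y)
  p <- ncol(X); n <- nrow(X)
  if (p < nComponents)
    stop("fewer features than PLS components", call. = FALSE)
  nComponents <- min(nComponents, n - 1L)
  mu <- colMeans(X)
  sdev <- apply(X, 2, popSd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  y0 <- y - mean(y)
  W <- matrix(0, p, nComponents)
  SS <- numeric(nComponents)
  Xk <- Xs
  used <- 0L
  for (k in seq_len(nComponents)) {
    wv <- drop(crossprod(Xk, y0))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break
    wv <- wv / nw
    tv <- drop(Xk %*% wv)
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    q <- sum(tv * y0) / tt
    pl <- drop(crossprod(Xk, tv)) / tt
    Xk <- Xk - tcrossprod(tv, pl)
    y0 <- y0 - q * tv
    W[, k] <- wv
    SS[k] <- q^2 * tt
    used <- k
  }
  if (used == 0L) {
    vip <- rep(1, p)  # uninformative fit: all features equally (un)important
  } else {
    W <- W[, seq_len(used), drop = FALSE]
    SS <- SS[seq_len(used)]
    vip <- sqrt(p * drop(W^2 %*% SS) / sum(SS))
  }
  ord <- order(-vip, seq_len(p))
  new("RankingResult", method = "pls_vip",
      orderedFeatures = colnames(X)[ord], scores = vip[ord])
}

#' Three-level discretization at mean +/- SD
#'
#' @param values numeric vector (>= 2 samples).
#' @return integer vector in \{-1, 0, +1\}.
#' @export
discretize <- function(values) {
  mu <- mean(values)
  s <- popSd(values)
  out <- integer(length(values))
  out[values < mu - s] <- -1L
  out[values > mu + s] <- 1L
  out
}

#' Empirical mutual information in bits
#'
#' MI of the empirical joint distribution of two discrete vectors, log
#' base 2.
#'
#' @param a,b aligned discrete vectors.
#' @return mutual information in bits (>= 0).
#' @export
mutualInformation <- function(a, b) {
  stopIfNot(length(a) == length(b) && length(a) >= 2,
            "need two aligned vectors with >= 2 samples")
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  pp <- outer(pa, pb)
  pos <- tab > 0
  sum(tab[pos] * log2(tab[pos] / pp[pos]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy forward selection on mean mutual information with the class
#' (relevance) against mean mutual information with the already selected
#' features (redundancy). Features are discretized at mean +/- SD into
#' three levels first. The first feature maximizes MI with the class;
#' thereafter MID maximizes relevance minus mean redundancy and MIQ
#' relevance over mean redundancy (floored at 1e-12). Ties break by catalog
#' order.
#'
#' @param X patches x features matrix.
#' @param y binary labels.
#' @param variant \code{"MID"} or \code{"MIQ"}.
#' @param k number of features to select (default all).
#' @return a \linkS4class{RankingResult} with the greedy objective values as
#'   scores.
#' @export
mrmrRank <- function(X, y, variant = c("MID", "MIQ"), k = ncol(X)) {
  variant <- match.arg(variant)
  y <- asBinaryLabels(y)
  p <- ncol(X)
  stopIfNot(k <= p, "cannot select more features than available")
  disc <- apply(X, 2, discretize)
  rel <- vapply(seq_len(p), function(j) mutualInformation(disc[, j], y),
                numeric(1))
  pairMI <- matrix(NA_real_, p, p)
  getPairMI <- function(i, j) {
    if (is.na(pairMI[i, j])) {
      v <- mutualInformation(disc[, i], disc[, j])
      pairMI[i, j] <<- v; pairMI[j, i] <<- v
    }
    pairMI[i, j]
  }
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    obj <- vapply(remaining, function(j) {
      if (length(selected) == 0) return(rel[j])
      red <- mean(vapply(selected, function(s) getPairMI(j, s), numeric(1)))
      if (variant == "MID") rel[j] - red
      else rel[j] / max(red, 1e-12)
    }, numeric(1))
    pick <- remaining[which.max(obj)]
    selected <- c(selected, pick)
    scores <- c(scores, max(obj))
    remaining <- setdiff(remaining, pick)
  }
  new("RankingResult",
      method = if (variant == "MID") "mrmr_mid" else "mrmr_miq",
      orderedFeatures = colnames(X)[selected], scores = scores)
}

#' Run one of the four ranking schemes by name
#'
#' @param X patches x features matrix.
#' @param y binary labels.
#' @param method \code{"ranksum"}, \code{"pls_vip"}, \code{"mrmr_mid"} or
#'   \code{"mrmr_miq"}.
#' @param nTop for the MRMR schemes: how many features to select greedily.
#' @param nComponents for \code{"pls_vip"}.
#' @return a \linkS4class{RankingResult}.
#' @export
rankFeatures <- function(X, y,
                         method = c("ranksum", "pls_vip", "mrmr_mid",
                                    "mrmr_miq"),
                         nTop = ncol(X), nComponents = 2L) {
  method <- match.arg(method)
  switch(method,
         ranksum = ranksumRank(X, y),
         pls_vip = plsVipRank(X, y, nComponents = nComponents),
         mrmr_mid = mrmrRank(X, y, variant = "MID", k = min(nTop, ncol(X))),
         mrmr_miq = mrmrRank(X, y, variant = "MIQ", k = min(nTop, ncol(X))))
}
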