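test_that("rank-sum ranking puts a perfectly separating feature first", {
  withr::with_seed(12, {
    y <- rep(0:1, each = 20)
    X <- matrix(rnorm(40 * 30), 40, 30)
    colnames(X) <- sprintf("f%02d", 1:30)
    X[, 17] <- y  # perfect separation
    rr <- ranksumRank(X, y)
    expect_identical(rr@orderedFeatures[1], "f17")
    expect_true(all(diff(rr@scores) >= 0))  # ordered by ascending p
  })
})

test_that("rank-sum p matches the exhaustive permutation null on tiny samples", {
  # 4 vs 4, distinct values: the exact two-sided permutation p of the
  # rank-sum statistic, enumerated over all C(8,4) assignments
  x <- c(2, 6, 7, 8, 1, 3, 4, 5)
  y <- rep(0:1, each = 4)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "f"))
  pImpl <- ranksumRank(X, y)@scores[1]
  r <- rank(x)
  W <- sum(r[y == 1])
  mu <- 4 * 9 / 2
  stats <- apply(combn(8, 4), 2, function(i) sum(r[i]))
  pExact <- mean(abs(stats - mu) >= abs(W - mu))
  expect_lt(abs(pImpl - pExact), 0.02)
})

test_that("rank-sum tie and convention rules hold", {
  withr::with_seed(3, {
    y <- rep(0:1, each = 10)
    base <- rnorm(20) + y
    X <- cbind(a = base, b = base, const = rep(2, 20))
    rr <- ranksumRank(X, y)
    # identical features occupy adjacent ranks in catalog order
    ia <- which(rr@orderedFeatures == "a")
    expect_identical(rr@orderedFeatures[ia + 1], "b")
    expect_equal(rr@scores[rr@orderedFeatures == "const"], 1,
                 ignore_attr = TRUE)
    # invariance under strictly monotone transforms
    rr2 <- ranksumRank(cbind(a = exp(base), b = exp(base),
                             const = rep(7, 20)), y)
    expect_identical(rr@orderedFeatures, rr2@orderedFeatures)
    expect_equal(rr@scores, rr2@scores)
  })
})

test_that("PLS-VIP satisfies its identity, symmetry, and finds the signal", {
  withr::with_seed(21, {
    y <- rep(0:1, each = 50)
    X <- matrix(rnorm(100 * 15), 100, 15)
    colnames(X) <- sprintf("f%02d", 1:15)
    X[, 7] <- X[, 7] + 2 * y
    X[, 8] <- X[, 7]  # exact duplicate of the informative feature
    rr <- plsVipRank(X, y)
    vip <- rr@scores
    expect_equal(mean(vip^2), 1, tolerance = 1e-8)
    expect_true(rr@orderedFeatures[1] %in% c("f07", "f08"))
    expect_equal(vip[1], vip[2], tolerance = 1e-6)  # duplicates tie
    expect_error(plsVipRank(X[, 1, drop = FALSE], y), "fewer features")
  })
})

test_that("PLS-VIP agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(4, {
    X <- matrix(rnorm(60 * 12), 60, 12)
    colnames(X) <- sprintf("f%02d", 1:12)
    y <- rep(0:1, each = 30)
    X[, 4] <- X[, 4] + 1.5 * y
  })
  mine <- plsVipRank(X, y, nComponents = 2)
  v1 <- setNames(mine@scores, mine@orderedFeatures)[colnames(X)]
  fit <- mixOmics::pls(X, y, ncomp = 2, mode = "regression", scale = TRUE)
  v2 <- mixOmics::vip(fit)[, 2]
  expect_equal(unname(v1), unname(v2), tolerance = 1e-8)
})

test_that("a lone informative feature wins the VIP ranking in nearly all runs", {
  hits <- 0L
  for (s in 1:100) {
    withr::with_seed(s, {
      y <- rep(0:1, each = 100)
      X <- matrix(rnorm(200 * 25), 200, 25)
      colnames(X) <- sprintf("f%02d", 1:25)
      X[, 13] <- X[, 13] + 2 * y  # 2-sigma effect
    })
    if (plsVipRank(X, y)@orderedFeatures[1] == "f13") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("discretization and mutual information behave as information theory demands", {
  withr::with_seed(6, {
    vals <- c(rep(0, 20), -10, -9, 9, 10)
    expect_identical(discretize(vals), c(rep(0L, 20), -1L, -1L, 1L, 1L))
    da <- rep(c(-1L, 1L), 5000)  # two equiprobable levels
    expect_equal(mutualInformation(da, da), 1)  # MI(a, a) = H(a) = 1 bit
    u <- sample(c(-1, 0, 1), 10000, replace = TRUE)
    v <- sample(c(-1, 0, 1), 10000, replace = TRUE)
    expect_lt(mutualInformation(u, v), 0.01)
    expect_equal(mutualInformation(u, v), mutualInformation(v, u))
    expect_gte(mutualInformation(u, v), 0)
  })
})

test_that("MRMR starts from max relevance and avoids redundant duplicates", {
  withr::with_seed(30, {
    y <- rep(0:1, each = 40)
    sig <- rnorm(80) + 2 * y
    weak <- rnorm(80) + 0.8 * y
    X <- cbind(s1 = sig, s1dup = sig + rnorm(80, 0, 1e-3), w = weak,
               noise = rnorm(80))
  })
  disc <- apply(X, 2, discretize)
  rel <- vapply(1:4, function(j) mutualInformation(disc[, j], y), numeric(1))
  for (variant in c("MID", "MIQ")) {
    rr <- mrmrRank(X, y, variant, k = 2)
    expect_identical(rr@orderedFeatures[1], colnames(X)[which.max(rel)])
    # the near-duplicate of the first pick must not be selected second
    expect_false(rr@orderedFeatures[2] %in% c("s1", "s1dup"))
  }
})

test_that("greedy MRMR equals the brute-force argmax at every step", {
  bruteStep <- function(disc, y, selected, remaining, variant) {
    rel <- vapply(remaining, function(j)
      mutualInformation(disc[, j], y), numeric(1))
    obj <- vapply(seq_along(remaining), function(i) {
      j <- remaining[i]
      if (!length(selected)) return(rel[i])
      red <- mean(vapply(selected, function(s)
        mutualInformation(disc[, j], disc[, s]), numeric(1)))
      if (variant == "MID") rel[i] - red else rel[i] / max(red, 1e-12)
    }, numeric(1))
    remaining[which.max(obj)]
  }
  for (s in 1:5) {
    withr::with_seed(400 + s, {
      y <- rep(0:1, each = 25)
      X <- matrix(rnorm(50 * 8), 50, 8)
      X[, 2] <- X[, 2] + 1.2 * y
      X[, 5] <- X[, 5] - 0.9 * y
      colnames(X) <- sprintf("f%d", 1:8)
    })
    disc <- apply(X, 2, discretize)
    for (variant in c("MID", "MIQ")) {
      got <- match(mrmrRank(X, y, variant, k = 3)@orderedFeatures,
                   colnames(X))
      sel <- integer(0)
      for (step in 1:3) {
        want <- bruteStep(disc, y, sel, setdiff(1:8, sel), variant)
        expect_identical(got[step], want)
        sel <- c(sel, want)
      }
    }
  }
})

test_that("rankers are invariant to feature column order up to tie rules", {
  withr::with_seed(50, {
    y <- rep(0:1, each = 30)
    X <- matrix(rnorm(60 * 10), 60, 10)
    X[, 3] <- X[, 3] + y
    X[, 9] <- X[, 9] - 1.5 * y
    colnames(X) <- sprintf("f%02d", 1:10)
  })
  perm <- c(7, 2, 9, 1, 10, 3, 5, 8, 4, 6)
  for (m in c("ranksum", "pls_vip", "mrmr_mid", "mrmr_miq")) {
    r1 <- rankFeatures(X, y, m, nTop = 10)
    r2 <- rankFeatures(X[, perm], y, m, nTop = 10)
    expect_identical(r1@orderedFeatures, r2@orderedFeatures)
  }
  # MRMR is invariant to affine transforms (level assignment preserved)
  r1 <- mrmrRank(X, y, "MID", k = 4)
  r2 <- mrmrRank(sweep(X * 3.7, 2, rnorm(10), `+`), y, "MID", k = 4)
  expect_identical(r1@orderedFeatures, r2@orderedFeatures)
})
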