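test_that("nnlsSolve handles the elementary instances", {
  # unconstrained mean, constraint slack
  s <- nnlsSolve(matrix(1, 2, 1), c(1, 2))
  expect_equal(s@beta, 1.5)
  expect_length(s@activeSet, 0)

  # constraint binds at zero
  s2 <- nnlsSolve(matrix(1, 2, 1), c(-1, -1))
  expect_identical(s2@beta, 0)
  expect_equal(s2@residualNorm, sqrt(2))
  expect_identical(s2@activeSet, 1L)

  expect_error(nnlsSolve(matrix(NA_real_, 1, 1), 1), "non-finite")
  expect_error(nnlsSolve(matrix(1, 2, 1), c(1, 2, 3)), "length")
})

test_that("nnlsSolve matches the brute-force support-enumeration oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    k <- sample(1:4, 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- rnorm(n)
    sol <- nnlsSolve(X, y)
    oracle <- bruteForceNNLS(X, y)
    expect_lt(abs(nnlsObjective(X, y, sol@beta) - oracle$objective), 1e-8)
    expect_true(all(sol@beta >= 0))
  }
})

test_that("nnlsSolve satisfies the KKT conditions with exact zeros", {
  set.seed(17)
  for (i in 1:50) {
    X <- matrix(rnorm(30), 10, 3)
    y <- rnorm(10)
    s <- nnlsSolve(X, y)
    w <- as.numeric(crossprod(X, y - X %*% s@beta))
    expect_true(all(abs(w[s@beta > 0]) <= 1e-8))
    expect_true(all(w[s@beta == 0] <= 1e-8))
    expect_identical(s@beta[s@activeSet], rep(0, length(s@activeSet)))
  }
})

test_that("nnlsSolve agrees with an independent active-set implementation", {
  set.seed(23)
  for (i in 1:30) {
    X <- matrix(abs(rnorm(24)), 8, 3)
    y <- rnorm(8)
    mine <- nnlsSolve(X, y)@beta
    ref <- pracma::lsqnonneg(X, y)$x
    expect_equal(mine, ref, tolerance = 1e-7)
  }
})

test_that("nnlsSolve is scaling-equivariant and reduces to OLS when slack", {
  set.seed(31)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  b <- nnlsSolve(X, y)@beta
  expect_equal(nnlsSolve(X, 2.5 * y)@beta, 2.5 * b, tolerance = 1e-10)

  # when the unconstrained solution is non-negative, NNLS returns it
  for (i in 1:20) {
    X <- matrix(abs(rnorm(30)) + 0.1, 10, 3)
    betaTrue <- runif(3, 0.5, 2)
    y <- as.numeric(X %*% betaTrue)      # exact, interior optimum
    ols <- solve(crossprod(X), crossprod(X, y))
    expect_equal(nnlsSolve(X, y)@beta, as.numeric(ols), tolerance = 1e-8)
  }
})

test_that("fitCellTypeExpression recovers exact mixtures and handles edge cases", {
  set.seed(41)
  k <- 4; n <- 12; g <- 30
  P <- matrix(rgamma(k * n, 1), k, n)
  P <- sweep(P, 2, colSums(P), "/")
  dimnames(P) <- list(paste0("ct", 1:k), paste0("s", 1:n))
  B <- matrix(rlnorm(g * k), g, k,
              dimnames = list(paste0("t", 1:g), rownames(P)))
  B[1, ] <- 0                                  # all-zero transcript
  bulk <- ExpressionMatrix(B %*% P, "arbitrary")
  expect_message(fit <- fitCellTypeExpression(bulk, ProportionMatrix(P)),
                 "all-zero")
  expect_lt(max(abs(coefValues(fit) - B)), 1e-8)
  expect_identical(unname(coefValues(fit)[1, ]), rep(0, k))

  # sample alignment: shuffled proportion columns give the same fit
  Pshuf <- ProportionMatrix(P[, sample(n), drop = FALSE])
  fit2 <- suppressMessages(fitCellTypeExpression(bulk, Pshuf))
  expect_equal(coefValues(fit2), coefValues(fit), tolerance = 1e-10)

  # mismatched sample ids error
  Pbad <- P; colnames(Pbad) <- paste0("x", 1:n)
  expect_error(fitCellTypeExpression(bulk, ProportionMatrix(Pbad)),
               "sample ids")
})

test_that("single-cell-type fit is the per-transcript mean", {
  n <- 6
  P <- matrix(1, 1, n, dimnames = list("only", paste0("s", 1:n)))
  y <- matrix(c(1, 2, 3, 4, 5, 6), 1, n,
              dimnames = list("t1", colnames(P)))
  fit <- fitCellTypeExpression(ExpressionMatrix(y, "TPM"),
                               ProportionMatrix(P))
  expect_equal(unname(coefValues(fit)[1, 1]), mean(y))
})

test_that("fits can be stratified by sample groups", {
  set.seed(43)
  k <- 3; n <- 10
  P <- matrix(rgamma(k * n, 1), k, n)
  P <- sweep(P, 2, colSums(P), "/")
  dimnames(P) <- list(paste0("ct", 1:k), paste0("s", 1:n))
  B1 <- matrix(rlnorm(2 * k), 2, k, dimnames = list(c("a", "b"), rownames(P)))
  B2 <- B1 * 3
  grp <- rep(c("g1", "g2"), each = 5)
  bulk <- cbind(B1 %*% P[, 1:5], B2 %*% P[, 6:10])
  fits <- fitCellTypeExpression(ExpressionMatrix(bulk, "arbitrary"),
                                ProportionMatrix(P),
                                groups = setNames(grp, colnames(P)))
  expect_named(fits, c("g1", "g2"))
  expect_lt(max(abs(coefValues(fits$g1) - B1)), 1e-8)
  expect_lt(max(abs(coefValues(fits$g2) - B2)), 1e-8)
})
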