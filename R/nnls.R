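#' Non-negative least squares by the Lawson-Hanson active-set algorithm
#'
#' Minimizes \eqn{\|X\beta - y\|_2} subject to \eqn{\beta \ge 0}. This is a
#' convex problem with a unique optimum objective; the active-set algorithm
#' terminates at the global optimum with the zero-constrained coefficients
#' held at exact (binary) zero, so downstream exclusivity calls need no
#' numeric tolerance. At the solution the KKT conditions hold: the gradient
#' component \eqn{w_j = x_j^T (y - X\beta)} satisfies \eqn{|w_j| \le tol}
#' for passive (positive) coefficients and \eqn{w_j \le tol} for active
#' (zero) ones.
#'
#' Ties in the most-positive-gradient selection are broken by lowest column
#' index, making the iteration path deterministic. The inner feasibility
#' loop uses the standard line search toward the restricted least-squares
#' solution, dropping variables that hit the bound; the outer loop is capped
#' at \code{maxIter} as an anti-cycling safeguard (unreachable for
#' well-posed inputs).
#'
#' @param X numeric design matrix, n x k, finite.
#' @param y numeric response of length n, finite.
#' @param tol nonnegativity/KKT tolerance on the gradient.
#' @param maxIter cap on outer iterations (default 3k, plus a generous cap
#'   on inner-loop steps).
#' @return An \linkS4class{NNLSSolution}.
#' @examples
#' s <- nnlsSolve(matrix(1, 2, 1), c(1, 2))   # unconstrained mean, 1.5
#' s@beta
#' nnlsSolve(matrix(1, 2, 1), c(-1, -1))@beta # constraint binds at 0
#' @export
nnlsSolve <- function(X, y, tol = 1e-10, maxIter = 3L * ncol(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (n < 1L || k < 1L) stop("X must be at least 1 x 1")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in X or y")

  beta <- numeric(k)
  passive <- logical(k)
  iter <- 0L
  innerCap <- 30L * k + 100L
  inner <- 0L

  repeat {
    w <- as.numeric(crossprod(X, y - X %*% beta))
    candidates <- which(!passive)
    if (length(candidates) == 0L || max(w[candidates]) <= tol) break
    iter <- iter + 1L
    if (iter > maxIter)
      stop(sprintf("nnlsSolve failed to converge within %d outer iterations (n=%d, k=%d)",
                   maxIter, n, k))
    t <- candidates[which.max(w[candidates])]  # which.max: lowest index on ties
    passive[t] <- TRUE

    repeat {
      P <- which(passive)
      z <- qr.coef(qr(X[, P, drop = FALSE]), y)
      z[is.na(z)] <- 0   # rank-deficient restricted design: drop redundant column
      # relative epsilon: coefficients that are zero up to rounding (e.g.
      # 1e-20 left by a column that entered before the true support) are
      # treated as bound violations so they leave with an exact zero
      innerEps <- 1e-12 * max(abs(z))
      if (all(z > innerEps)) {
        beta[] <- 0
        beta[P] <- z
        break
      }
      inner <- inner + 1L
      if (inner > innerCap)
        stop(sprintf("nnlsSolve inner loop exceeded %d steps (n=%d, k=%d)",
                     innerCap, n, k))
      bp <- beta[P]
      neg <- which(z <= innerEps)
      alpha <- min(bp[neg] / (bp[neg] - z[neg]))
      beta[P] <- bp + alpha * (z - bp)
      # variables driven to the bound leave the passive set exactly
      atZero <- P[abs(beta[P]) <= tol]
      if (length(atZero) == 0L) atZero <- P[which.min(beta[P])]
      beta[atZero] <- 0
      passive[atZero] <- FALSE
    }
  }

  resid <- y - X %*% beta
  new("NNLSSolution", beta = beta,
      residualNorm = sqrt(sum(resid^2)),
      activeSet = which(beta == 0),
      iterations = iter)
}

#' Fit cell-type-specific expression by per-transcript NNLS
#'
#' Models each transcript's bulk expression across samples as a non-negative
#' linear combination of the per-sample cell-type proportions: for
#' transcript g, \code{y_g ~ t(fractions) beta_g} with \code{beta_g >= 0}
#' and no intercept (bulk expression is a proportion-weighted mixture of
#' cell-type profiles, so the model has no constant term). The stacked
#' \code{beta_g} form the coefficient matrix whose product with the
#' proportions reconstructs the modeled bulk.
#'
#' Samples are aligned by id (proportions reordered to the bulk order); an
#' all-zero transcript gets an all-zero coefficient row without solving.
#'
#' @param bulk \linkS4class{ExpressionMatrix} (transcripts x samples).
#' @param proportions \linkS4class{ProportionMatrix} covering the same
#'   samples.
#' @param groups optional per-sample group labels (character/factor named by
#'   sample id or in bulk sample order); when given, one fit per group is
#'   returned as a named list of \linkS4class{CoefficientMatrix}.
#' @param tol tolerance passed to \code{\link{nnlsSolve}}.
#' @return A \linkS4class{CoefficientMatrix}, or a named list of them when
#'   \code{groups} is given.
#' @export
fitCellTypeExpression <- function(bulk, proportions, groups = NULL,
                                  tol = 1e-10) {
  stopifnot(is(bulk, "ExpressionMatrix"), is(proportions, "ProportionMatrix"))
  bs <- sampleIds(bulk)
  ps <- sampleIds(proportions)
  if (!setequal(bs, ps))
    stop("sample ids of bulk and proportions do not match; bulk-only: ",
         paste(utils::head(setdiff(bs, ps), 5L), collapse = ", "),
         "; proportions-only: ",
         paste(utils::head(setdiff(ps, bs), 5L), collapse = ", "))
  if (length(bs) < 2L) stop("at least 2 samples are required")
  P <- fractions(proportions)[, bs, drop = FALSE]

  if (!is.null(groups)) {
    if (!is.null(names(groups))) groups <- groups[bs]
    if (length(groups) != length(bs))
      stop("groups must have one label per sample")
    out <- lapply(split(bs, as.character(groups)), function(ss) {
      sub <- ExpressionMatrix(exprValues(bulk)[, ss, drop = FALSE],
                              unitLabel(bulk))
      subProp <- ProportionMatrix(P[, ss, drop = FALSE])
      fitCellTypeExpression(sub, subProp, groups = NULL, tol = tol)
    })
    return(out)
  }

  X <- t(P)
  Y <- exprValues(bulk)
  B <- matrix(0, nrow(Y), ncol(X),
              dimnames = list(rownames(Y), rownames(P)))
  nonzero <- rowSums(Y) > 0
  if (any(!nonzero))
    message(sum(!nonzero), " all-zero transcript(s) given all-zero coefficients")
  for (g in which(nonzero))
    B[g, ] <- nnlsSolve(X, Y[g, ], tol = tol)@beta
  CoefficientMatrix(B)
}
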