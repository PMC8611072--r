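#' Elastic-net fit by coordinate descent
#'
#' Minimizes \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i'\beta)^2 +
#' \lambda(\alpha\|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2)} by cyclic
#' coordinate descent with an unpenalized intercept. Multiple
#' \code{lambda} values are solved warm-started along the decreasing path;
#' results are returned in the order given.
#'
#' @param X predictor matrix (observations x predictors).
#' @param y response vector.
#' @param alpha mixing parameter in [0, 1] (1 = lasso, 0 = ridge).
#' @param lambda penalty strength(s), all > 0 unless alpha allows 0.
#' @param tol convergence tolerance on coefficient updates.
#' @param maxit maximum coordinate-descent sweeps per lambda.
#' @param trace record the objective after every sweep (for diagnostics).
#' @return list with \code{beta} (p x length(lambda)), \code{b0},
#'   \code{iterations}, and (if \code{trace}) \code{objective_trace}.
#' @export
enetFit <- function(X, y, alpha, lambda, tol = 1e-7, maxit = 100000L,
                    trace = FALSE) {
    X <- as.matrix(X)
    if (any(!is.finite(X)) || any(!is.finite(y)))
        stop("non-finite values in the design or response")
    if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
    if (any(lambda < 0)) stop("lambda must be non-negative")
    ord <- order(lambda, decreasing = TRUE)
    fit <- enetPathCpp(X, as.numeric(y), alpha, as.numeric(lambda[ord]),
                       tol, as.integer(maxit), trace)
    inv <- match(seq_along(lambda), ord)
    beta <- fit$beta[, inv, drop = FALSE]
    rownames(beta) <- colnames(X)
    out <- list(beta = beta, b0 = fit$b0[inv],
                iterations = fit$iterations[inv], alpha = alpha,
                lambda = lambda)
    if (trace) out$objective_trace <- fit$objective_trace[inv]
    out
}

#' Karush-Kuhn-Tucker residuals of an elastic-net solution
#'
#' For each predictor j returns \code{(1/n) x_j'(y - yhat) -
#' lambda*(1-alpha)*beta_j} minus the subgradient of the L1 term: for
#' active coefficients the stationarity residual (should be ~0), for zero
#' coefficients the amount by which \code{|gradient|} exceeds
#' \code{lambda*alpha} (should be <= 0 up to tolerance).
#'
#' @param X,y the design and response the fit used.
#' @param beta,b0 coefficients and intercept.
#' @param alpha,lambda the penalty used.
#' @return list with \code{active} (named stationarity residuals) and
#'   \code{inactive} (named excess gradients).
#' @export
enetKkt <- function(X, y, beta, b0, alpha, lambda) {
    X <- as.matrix(X)
    n <- nrow(X)
    r <- y - b0 - as.vector(X %*% beta)
    grad <- as.vector(crossprod(X - rep(colMeans(X), each = n), r)) / n
    names(grad) <- colnames(X)
    act <- beta != 0
    list(active = grad[act] - lambda * alpha * sign(beta[act]) -
             lambda * (1 - alpha) * beta[act],
         inactive = abs(grad[!act]) - lambda * alpha)
}

## smallest lambda (given alpha > 0) that zeroes every lasso coefficient
lassoNullLambda <- function(X, y, alpha) {
    Xc <- scale(X, scale = FALSE)
    yc <- y - mean(y)
    max(abs(crossprod(Xc, yc))) / (nrow(X) * alpha)
}
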