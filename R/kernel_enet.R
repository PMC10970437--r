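# Kernel-weighted recursive (adaptive) elastic net for a single target gene.
#
# The work happens on Gram quantities G = X'KX, c = X'Ky so that the
# coordinate-descent cost per sweep is O(p^2) regardless of n, and so that
# all targets of one cell line can share a single Gram matrix (see
# netprofiler()).

# Solve the penalized problem along a lambda grid for fixed penalty weights
# `w` (non-finite entries = excluded coordinates).  Returns list with the
# coefficient path and per-lambda weighted RSS / df / BIC.
enet_gram_path <- function(G, c_vec, yy, n_eff, w, lambda, delta,
                           tol = 1e-8, max_sweeps = 10000L) {
  beta <- .cd_enet_path(G, c_vec, w, lambda, delta, tol, max_sweeps)
  rss <- yy - 2 * colSums(beta * c_vec) + colSums(beta * (G %*% beta))
  rss <- pmax(rss, 0)
  df <- colSums(beta != 0)
  bic <- n_eff * log(pmax(rss, 1e-300) / n_eff) + log(n_eff) * df
  list(beta = beta, rss = rss, df = df, bic = bic)
}

# Largest lambda with an all-zero solution under penalty weights w:
# max_j |c_j| / (delta * w_j) (KKT threshold of the weighted objective).
lambda_max_gram <- function(c_vec, w, delta) {
  ok <- is.finite(w) & w > 0
  if (!any(ok)) return(0)
  max(abs(c_vec[ok]) / (delta * w[ok]))
}

make_lambda_grid <- function(lambda_max, nlambda, lambda_min_ratio) {
  if (lambda_max <= 0) return(1e-12)  # degenerate: any lambda gives beta = 0
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = nlambda))
}

# Full recursive (adaptive) fit on Gram quantities.  Iteration 1 uses unit
# penalty weights; iteration k+1 uses w_j = 1/(|beta_j^(k)| + eps) from the
# selected solution of iteration k.  Selection by kernel-weighted BIC.
enet_gram_adaptive <- function(G, c_vec, yy, n_eff, delta,
                               exclude = integer(0),
                               lambda = NULL, nlambda = 20L,
                               lambda_min_ratio = 1e-3,
                               adaptive_iterations = 2L,
                               adaptive_epsilon = 1e-6,
                               tol = 1e-8, max_sweeps = 10000L) {
  p <- length(c_vec)
  w <- rep(1, p)
  w[exclude] <- Inf
  beta <- numeric(p)
  sel <- list()
  w_used <- w
  for (it in seq_len(adaptive_iterations)) {
    grid <- if (is.null(lambda)) {
      make_lambda_grid(lambda_max_gram(c_vec, w, delta), nlambda,
                       lambda_min_ratio)
    } else {
      sort(as.numeric(lambda), decreasing = TRUE)
    }
    fit <- enet_gram_path(G, c_vec, yy, n_eff, w, grid, delta, tol, max_sweeps)
    best <- which.min(fit$bic)
    beta <- fit$beta[, best]
    w_used <- w
    sel <- list(lambda = grid[best], lambda_grid = grid, bic = fit$bic,
                rss = fit$rss[best], df = fit$df[best], path = fit$beta)
    wa <- 1 / (abs(beta) + adaptive_epsilon)
    wa[exclude] <- Inf
    w <- wa
  }
  c(list(beta = beta, weights = w_used), sel)
}

#' Kernel-weighted recursive elastic net for one target gene
#'
#' Fits the penalized weighted regression
#' \deqn{\frac12\sum_i K_i (y_i - \beta^\top x_i)^2 +
#'   \lambda \sum_j \left[\tfrac12(1-\delta)\beta_j^2 +
#'   \delta w_j |\beta_j|\right]}{
#'   1/2 sum_i K_i (y_i - b'x_i)^2 +
#'   lambda sum_j [(1-delta)/2 b_j^2 + delta w_j |b_j|]}
#' by cyclic coordinate descent, where the observation weights `K_i` are
#' typically Gaussian kernel weights in drug-sensitivity space
#' ([gaussian_kernel()]).  The penalty is recursive (adaptive): the first
#' pass uses unit weights `w_j = 1`, each later pass uses
#' `w_j = 1/(|beta_j| + adaptive_epsilon)` from the previously selected
#' solution.  `lambda` is selected per pass by a kernel-weighted BIC
#' (weighted RSS with effective sample size `sum(K_i)`, degrees of freedom =
#' number of nonzero coefficients) or by weighted cross-validation.
#'
#' @param x Numeric matrix of regulator expression, observations in rows.
#' @param y Numeric response vector (target-gene expression).
#' @param weights Nonnegative observation weights (kernel weights); must not
#'   be all zero.
#' @param lambda Optional user lambda grid; by default `nlambda` values
#'   log-spaced from the smallest lambda with an all-zero solution down by a
#'   factor `lambda_min_ratio`.
#' @param nlambda,lambda_min_ratio Size and extent of the automatic grid.
#' @param delta Elastic-net mixing weight in (0, 1); `delta` multiplies the
#'   lasso part, `1 - delta` the ridge part.
#' @param adaptive_iterations Number of recursive passes (>= 1).
#' @param adaptive_epsilon Stabilizer added to `|beta_j|` in the adaptive
#'   weights.
#' @param selection `"bic"` (default) or `"cv"` (weighted K-fold
#'   cross-validation).
#' @param nfolds Folds for `selection = "cv"`.
#' @param exclude Integer indices of columns of `x` barred from the model
#'   (their coefficients are fixed at zero); used to remove self-regulation.
#' @param tol,max_sweeps Coordinate-descent convergence controls: stop when
#'   the largest coefficient change in a sweep falls below `tol`, or after
#'   `max_sweeps` sweeps.
#' @return An object of class `"kernel_enet"`: list with `coefficients`,
#'   selected `lambda`, the final `lambda_grid`, `bic` values along it, the
#'   adaptive penalty `weights` in effect for the returned fit, the final
#'   coefficient `path` (p x nlambda), `df` and weighted `rss`.
#' @seealso [netprofiler()] for fitting all targets over all cell lines.
#' @export
kernel_enet <- function(x, y, weights, lambda = NULL, nlambda = 20L,
                        lambda_min_ratio = 1e-3, delta = 0.5,
                        adaptive_iterations = 2L, adaptive_epsilon = 1e-6,
                        selection = c("bic", "cv"), nfolds = 5L,
                        exclude = integer(0), tol = 1e-8,
                        max_sweeps = 10000L) {
  selection <- match.arg(selection)
  x <- as.matrix(x)
  stopifnot_matrix(x, "x")
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y))) stop("'y' contains non-finite values")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  weights <- as.numeric(weights)
  if (length(weights) != nrow(x) || any(weights < 0)) {
    stop("'weights' must be nonnegative, one per observation")
  }
  if (sum(weights) <= 0) stop("total kernel weight is zero")
  if (delta <= 0 || delta >= 1) stop("'delta' must be in (0, 1)")
  if (adaptive_iterations < 1L) stop("'adaptive_iterations' must be >= 1")

  G <- crossprod(x * sqrt(weights))
  c_vec <- drop(crossprod(x, weights * y))
  yy <- sum(weights * y^2)
  n_eff <- sum(weights)

  if (selection == "cv") {
    fit <- enet_cv(x, y, weights, lambda, nlambda, lambda_min_ratio, delta,
                   exclude, adaptive_iterations, adaptive_epsilon, nfolds,
                   tol, max_sweeps)
  } else {
    fit <- enet_gram_adaptive(G, c_vec, yy, n_eff, delta, exclude, lambda,
                              nlambda, lambda_min_ratio, adaptive_iterations,
                              adaptive_epsilon, tol, max_sweeps)
  }
  structure(
    list(coefficients = stats::setNames(fit$beta, colnames(x)),
         lambda = fit$lambda, lambda_grid = fit$lambda_grid,
         bic = fit$bic, weights = fit$weights, path = fit$path,
         df = fit$df, rss = fit$rss,
         delta = delta, selection = selection, exclude = exclude),
    class = "kernel_enet")
}

# Weighted K-fold cross-validation over the lambda grid, with the adaptive
# recursion re-run inside each training fold at the grid of the full fit.
enet_cv <- function(x, y, weights, lambda, nlambda, lambda_min_ratio, delta,
                    exclude, adaptive_iterations, adaptive_epsilon, nfolds,
                    tol, max_sweeps) {
  n <- nrow(x)
  p <- ncol(x)
  folds <- rep_len(seq_len(nfolds), n)[sample.int(n)]
  w_pen <- rep(1, p)
  w_pen[exclude] <- Inf
  full_c <- drop(crossprod(x, weights * y))
  grid <- if (is.null(lambda)) {
    make_lambda_grid(lambda_max_gram(full_c, w_pen, delta), nlambda,
                     lambda_min_ratio)
  } else {
    sort(as.numeric(lambda), decreasing = TRUE)
  }
  err <- matrix(0, nfolds, length(grid))
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    Gt <- crossprod(x[tr, , drop = FALSE] * sqrt(weights[tr]))
    ct <- drop(crossprod(x[tr, , drop = FALSE], weights[tr] * y[tr]))
    yyt <- sum(weights[tr] * y[tr]^2)
    net <- sum(weights[tr])
    w <- w_pen
    beta <- NULL
    for (it in seq_len(adaptive_iterations)) {
      path <- enet_gram_path(Gt, ct, yyt, max(net, 1e-12), w, grid, delta,
                             tol, max_sweeps)
      beta <- path$beta
      best <- which.min(path$bic)
      w <- 1 / (abs(beta[, best]) + adaptive_epsilon)
      w[exclude] <- Inf
    }
    pred <- x[!tr, , drop = FALSE] %*% beta
    err[f, ] <- colSums(weights[!tr] * (y[!tr] - pred)^2) /
      max(sum(weights[!tr]), 1e-12)
  }
  cv_err <- colMeans(err)
  best <- which.min(cv_err)
  # refit on all data with the adaptive recursion fixed to the chosen lambda
  G <- crossprod(x * sqrt(weights))
  yy <- sum(weights * y^2)
  n_eff <- sum(weights)
  fit <- enet_gram_adaptive(G, full_c, yy, n_eff, delta, exclude,
                            lambda = grid, adaptive_iterations =
                              adaptive_iterations,
                            adaptive_epsilon = adaptive_epsilon,
                            tol = tol, max_sweeps = max_sweeps)
  idx <- which.min(abs(fit$lambda_grid - grid[best]))
  list(beta = fit$path[, idx], lambda = grid[best], lambda_grid = grid,
       bic = cv_err, weights = fit$weights, df = sum(fit$path[, idx] != 0),
       rss = NA_real_)
}

#' @export
print.kernel_enet <- function(x, ...) {
  cat("Kernel-weighted recursive elastic net fit\n")
  cat(sprintf("  nonzero coefficients: %d of %d\n",
              sum(x$coefficients != 0), length(x$coefficients)))
  cat(sprintf("  selected lambda: %.4g (%s), delta: %.2f\n",
              x$lambda, x$selection, x$delta))
  invisible(x)
}

#' @export
coef.kernel_enet <- function(object, ...) object$coefficients
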