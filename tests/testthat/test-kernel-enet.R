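make_reg_data <- function(n = 120, p = 6, seed = 31, beta = NULL,
                          noise = 0.2) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  beta <- beta %||% c(1.5, -1, 0.8, rep(0, p - 3))
  y <- drop(x %*% beta + rnorm(n, sd = noise))
  K <- gaussian_kernel(runif(n), 0.5, 0.5)
  list(x = x, y = y, K = K, beta = beta)
}

test_that("zero response gives the zero solution", {
  d <- make_reg_data()
  fit <- kernel_enet(d$x, rep(0, nrow(d$x)), d$K)
  expect_identical(unname(coef(fit)), rep(0, ncol(d$x)))
})

test_that("the KKT threshold lambda_max separates zero from nonzero fits", {
  d <- make_reg_data()
  delta <- 0.5
  lam_max <- max(abs(crossprod(d$x, d$K * d$y))) / delta
  hi <- kernel_enet(d$x, d$y, d$K, lambda = lam_max * 1.001, delta = delta,
                    adaptive_iterations = 1L)
  expect_true(all(coef(hi) == 0))
  lo <- kernel_enet(d$x, d$y, d$K, lambda = lam_max * 0.9, delta = delta,
                    adaptive_iterations = 1L)
  expect_gt(sum(coef(lo) != 0), 0)
})

test_that("the unpenalized limit matches the weighted-least-squares oracle", {
  set.seed(41)
  n <- 400
  p <- 20
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  y <- drop(2 * x[, 1] + rnorm(n, sd = 0.1))
  K <- rep(1, n)  # large-bandwidth limit: uniform weights
  fit <- kernel_enet(x, y, K, lambda = 1e-8, delta = 0.99,
                     adaptive_iterations = 1L)
  oracle <- sum(K * x[, 1] * y) / sum(K * x[, 1]^2)
  expect_lt(abs(coef(fit)[1] - oracle) / abs(oracle), 0.05)
})

test_that("returned solutions satisfy the subgradient equations", {
  for (seed in c(51, 52, 53)) {
    d <- make_reg_data(seed = seed)
    fit <- kernel_enet(d$x, d$y, d$K, delta = 0.4, exclude = 2L)
    beta <- unname(coef(fit))
    G <- crossprod(d$x * sqrt(d$K))
    cv <- drop(crossprod(d$x, d$K * d$y))
    g <- cv - drop(G %*% beta)
    lam <- fit$lambda
    w <- fit$weights
    for (j in seq_along(beta)) {
      if (!is.finite(w[j])) {
        expect_identical(beta[j], 0)
      } else if (beta[j] != 0) {
        resid <- g[j] - lam * (1 - fit$delta) * beta[j] -
          lam * fit$delta * w[j] * sign(beta[j])
        expect_lt(abs(resid), 1e-6)
      } else {
        expect_lte(abs(g[j]), lam * fit$delta * w[j] + 1e-6)
      }
    }
  }
})

test_that("sparsity is monotone along the lambda path", {
  d <- make_reg_data(seed = 61)
  fit <- kernel_enet(d$x, d$y, d$K, nlambda = 30L, adaptive_iterations = 1L)
  nnz <- colSums(fit$path != 0)  # path ordered from largest lambda down
  expect_true(all(diff(nnz) >= 0))
})

test_that("the fit never scores worse than the null model", {
  for (seed in c(71, 72, 73, 74)) {
    d <- make_reg_data(seed = seed)
    fit <- kernel_enet(d$x, d$y, d$K, delta = 0.6)
    obj_fit <- enet_objective(d$x, d$y, d$K, unname(coef(fit)), fit$lambda,
                              fit$delta, fit$weights)
    obj_null <- enet_objective(d$x, d$y, d$K, rep(0, ncol(d$x)), fit$lambda,
                               fit$delta, fit$weights)
    expect_lte(obj_fit, obj_null + 1e-10)
  }
})

test_that("the solver agrees with an exhaustive 2-d grid minimizer", {
  set.seed(81)
  n <- 60
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(x %*% c(1.2, -0.7) + rnorm(n, sd = 0.3))
  K <- gaussian_kernel(runif(n), 0.5, 0.3)
  lam <- 2
  delta <- 0.5
  fit <- kernel_enet(x, y, K, lambda = lam, delta = delta,
                     adaptive_iterations = 1L)
  # coarse-to-fine exhaustive search over beta in [-2, 2]^2
  G <- crossprod(x * sqrt(K))
  cv <- drop(crossprod(x, K * y))
  yy <- sum(K * y^2)
  obj2 <- function(b1, b2) {
    0.5 * (yy - 2 * (b1 * cv[1] + b2 * cv[2]) +
             G[1, 1] * b1^2 + 2 * G[1, 2] * b1 * b2 + G[2, 2] * b2^2) +
      lam * (0.5 * (1 - delta) * (b1^2 + b2^2) +
               delta * (abs(b1) + abs(b2)))
  }
  centre <- c(0, 0)
  width <- 2
  for (step in c(0.01, 1e-4)) {
    g1 <- seq(centre[1] - width, centre[1] + width, by = step)
    g2 <- seq(centre[2] - width, centre[2] + width, by = step)
    vals <- outer(g1, g2, obj2)
    idx <- arrayInd(which.min(vals), dim(vals))
    centre <- c(g1[idx[1]], g2[idx[2]])
    width <- 2 * step
  }
  expect_lt(max(abs(unname(coef(fit)) - centre)), 1e-3)
})

test_that("weighted cross-validation selection returns a valid fit", {
  d <- make_reg_data(seed = 85)
  set.seed(85)
  fit <- kernel_enet(d$x, d$y, d$K, selection = "cv", nfolds = 4L,
                     nlambda = 12L)
  expect_length(coef(fit), ncol(d$x))
  expect_true(fit$lambda %in% fit$lambda_grid)
  # strong true coefficients survive selection with the right signs
  expect_gt(coef(fit)[1], 0)
  expect_lt(coef(fit)[2], 0)
})

test_that("errors are raised on degenerate inputs", {
  d <- make_reg_data()
  expect_error(kernel_enet(d$x, d$y, rep(0, nrow(d$x))), "zero")
  expect_error(kernel_enet(d$x, d$y, d$K, delta = 1), "delta")
  xb <- d$x
  xb[1, 1] <- NA
  expect_error(kernel_enet(xb, d$y, d$K), "finite|missing")
})
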