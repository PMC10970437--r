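test_that("all-zero expression yields all-zero networks", {
  x <- matrix(0, 5, 4, dimnames = list(paste0("c", 1:5), paste0("g", 1:4)))
  m <- stats::setNames(1:5 / 5, rownames(x))
  fit <- netprofiler(x, m, bandwidth = 0.1)
  for (B in coef(fit)) expect_true(all(B == 0))
})

test_that("cell lines sharing a sensitivity value share a network", {
  sim <- small_sim(seed = 13, n = 30, p = 5, edges = 5)
  m <- sim$sensitivity
  m[2] <- m[1]  # force a tie
  fit <- netprofiler(sim$expression, m, bandwidth = 0.05, nlambda = 8)
  expect_identical(coef(fit, names(m)[1]), coef(fit, names(m)[2]))
})

test_that("networks do not depend on the order of requested cell lines", {
  sim <- small_sim(seed = 14, n = 40, p = 6, edges = 6)
  ids <- rownames(sim$expression)[1:10]
  f1 <- netprofiler(sim$expression, sim$sensitivity, bandwidth = 0.08,
                    at = ids, nlambda = 8)
  f2 <- netprofiler(sim$expression, sim$sensitivity, bandwidth = 0.08,
                    at = rev(ids), nlambda = 8)
  for (id in ids) expect_identical(coef(f1, id), coef(f2, id))
})

test_that("a planted logistic edge is stronger at the resistant end", {
  edges <- data.frame(regulator = "G001", target = "G002",
                      value_sensitive = 0, value_resistant = 1.5)
  cfg <- sim_config(n_cell_lines = 300, n_genes = 20, noise_sd = 0.3,
                    edges = edges, seed = 303)
  sim <- simulate_grn(cfg)
  ord <- order(sim$sensitivity)
  lo <- names(sim$sensitivity)[ord[1:50]]           # resistant end
  hi <- names(sim$sensitivity)[ord[251:300]]        # sensitive end
  fit <- netprofiler(sim$expression, sim$sensitivity, at = c(lo, hi))
  b_lo <- mean(vapply(coef(fit, lo), function(B) B["G002", "G001"],
                      numeric(1)))
  b_hi <- mean(vapply(coef(fit, hi), function(B) B["G002", "G001"],
                      numeric(1)))
  expect_gt(b_lo, b_hi)
  expect_gt(b_lo, 0.5)   # close to the planted 1.5 at the resistant end
})

test_that("self-regulation is excluded and outputs are well-formed", {
  sim <- small_sim(seed = 15, n = 30, p = 5, edges = 5)
  fit <- netprofiler(sim$expression, sim$sensitivity, bandwidth = 0.1,
                     nlambda = 8)
  B <- coef(fit, rownames(sim$expression)[3])
  expect_identical(dim(B), c(5L, 5L))
  expect_true(all(diag(B) == 0))
  expect_identical(dimnames(B), list(colnames(sim$expression),
                                     colnames(sim$expression)))
})

test_that("predict and residuals reconstruct the training panel", {
  sim <- small_sim(seed = 16, n = 40, p = 6, edges = 6, noise = 0.2)
  fit <- netprofiler(sim$expression, sim$sensitivity, bandwidth = 0.08,
                     nlambda = 10)
  fitted <- predict(fit)
  expect_identical(dim(fitted), dim(sim$expression))
  res <- residuals(fit)
  expect_equal(sim$expression[fit$at, ] - fitted[fit$at, ], res)
  # one-network prediction agrees with the manual linear combination
  id <- fit$at[5]
  B <- coef(fit, id)
  xc <- sweep(sim$expression, 2, fit$centers)
  manual <- t(B %*% t(xc)) + rep(fit$centers, each = nrow(xc))
  expect_equal(unname(predict(fit, newdata = sim$expression,
                              cell_line = id)),
               unname(manual))
})

test_that("prediction and summaries work for subset fits", {
  sim <- small_sim(seed = 20, n = 30, p = 5, edges = 5)
  ids <- rownames(sim$expression)[c(3, 9, 21)]
  fit <- netprofiler(sim$expression, sim$sensitivity, bandwidth = 0.1,
                     at = ids, nlambda = 6)
  fitted <- predict(fit)
  expect_identical(rownames(fitted), ids)
  expect_identical(dim(residuals(fit)), c(3L, 5L))
  expect_output(print(summary(fit)), "3 networks")
})

test_that("print, summary and plot methods run", {
  sim <- small_sim(seed = 17, n = 30, p = 5, edges = 5)
  fit <- netprofiler(sim$expression, sim$sensitivity, bandwidth = 0.1,
                     nlambda = 8)
  expect_output(print(fit), "networks")
  expect_output(print(summary(fit)), "bandwidth")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, top = 3))
})

test_that("misaligned or malformed inputs are rejected", {
  sim <- small_sim(seed = 18, n = 20, p = 4, edges = 4)
  m <- sim$sensitivity
  names(m) <- paste0("other", seq_along(m))
  expect_error(netprofiler(sim$expression, m, bandwidth = 0.1), "shared")
  expect_error(netprofiler(sim$expression, sim$sensitivity,
                           bandwidth = -1), "bandwidth")
  expect_error(netprofiler(sim$expression, sim$sensitivity, bandwidth = 0.1,
                           at = "nope"), "unknown")
})
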