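#' Fit drug-sensitivity-specific gene regulatory networks
#'
#' Fits the varying coefficient model
#' \deqn{y_{il} = \beta_l^\top(m_\alpha)\, x_i + \varepsilon_{il}}{
#'   y_il = beta_l(m_alpha)' x_i + e_il}
#' in which the directed regulatory effect of every gene `j` on every target
#' gene `l` is a function of the cell line's drug-sensitivity value
#' `m_alpha`.  For each requested cell line the coefficients are estimated by
#' the kernel-weighted recursive elastic net ([kernel_enet()]): all `n` cell
#' lines contribute to every network, weighted by the Gaussian kernel
#' [gaussian_kernel()] of their sensitivity distance to `m_alpha`.  Each of
#' the `p` genes is treated both as a target (one penalized regression per
#' gene, self-regulation excluded) and as a candidate regulator of every
#' other gene.  Targets are fitted independently, so results do not depend
#' on evaluation order, and cell lines sharing a sensitivity value share a
#' network.
#'
#' @param x Numeric expression matrix, cell lines in rows (rownames = cell
#'   line ids), genes in columns (colnames = gene ids).
#' @param m Sensitivity profile: numeric vector, one value per cell line.
#'   If named, it is matched to `rownames(x)` (the intersection is used);
#'   otherwise it must align positionally.
#' @param bandwidth Gaussian kernel bandwidth (squared-sensitivity units),
#'   or `"auto"` to call [select_bandwidth()] with `ess_fraction`.
#' @param ess_fraction Target mean effective sample size, as a fraction of
#'   `n`, for automatic bandwidth selection.
#' @param at Optional character vector of cell-line ids (subset of
#'   `rownames(x)`) whose networks should be estimated; default all.  All
#'   cell lines always contribute observations regardless of `at`.
#' @param standardize Z-score each gene across cell lines before fitting
#'   (coefficients are returned on the original scale); default `TRUE`.
#' @inheritParams kernel_enet
#' @return An object of class `"netprofiler"`.  `coef()` extracts the
#'   p x p coefficient matrix of one cell line (entry `[l, j]` = effect of
#'   regulator `j` on target `l`; zero diagonal) or a named list of them.
#'   `predict()` and `residuals()` give model-implied expression and
#'   residuals, `summary()` network-level statistics, and `plot()` edge
#'   coefficient trajectories against sensitivity.
#' @examples
#' sim <- simulate_grn(sim_config(n_cell_lines = 60, n_genes = 6,
#'                                n_true_edges = 5, seed = 1))
#' fit <- netprofiler(sim$expression, sim$sensitivity, nlambda = 10)
#' fit
#' coef(fit, cell_line = rownames(sim$expression)[1])[1:3, 1:3]
#' @export
netprofiler <- function(x, m, bandwidth = "auto", ess_fraction = 1 / 3,
                        at = NULL, standardize = TRUE,
                        lambda = NULL, nlambda = 20L, lambda_min_ratio = 1e-3,
                        delta = 0.5, adaptive_iterations = 2L,
                        adaptive_epsilon = 1e-6, tol = 1e-8,
                        max_sweeps = 10000L) {
  x <- as.matrix(x)
  stopifnot_matrix(x, "x")
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("cl", seq_len(nrow(x)))
  if (anyDuplicated(colnames(x))) stop("gene ids must be unique")
  if (anyDuplicated(rownames(x))) stop("cell line ids must be unique")

  m <- align_profile(m, rownames(x))
  x <- x[names(m), , drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)

  if (identical(bandwidth, "auto")) {
    bandwidth <- select_bandwidth(m, fraction = ess_fraction)
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("'bandwidth' must be positive or \"auto\"")
  }

  at <- at %||% rownames(x)
  missing_at <- setdiff(at, rownames(x))
  if (length(missing_at)) {
    stop("unknown cell line(s) in 'at': ", paste(missing_at, collapse = ", "))
  }

  centers <- rep(0, p)
  scales <- rep(1, p)
  xs <- x
  if (standardize) {
    centers <- colMeans(x)
    scales <- apply(x, 2, sd)
    scales[scales == 0] <- 1  # constant genes stay constant (zero signal)
    xs <- sweep(sweep(x, 2, centers), 2, scales, "/")
  }

  m_at <- m[at]
  um <- sort(unique(unname(m_at)))
  fits <- vector("list", length(um))
  for (k in seq_along(um)) {
    fits[[k]] <- fit_networks_at_m(xs, m, um[k], bandwidth, lambda, nlambda,
                                   lambda_min_ratio, delta,
                                   adaptive_iterations, adaptive_epsilon,
                                   tol, max_sweeps)
    if (standardize) {
      # back to the original expression scale: b_lj * sd_l / sd_j
      fits[[k]] <- fits[[k]] * (scales %o% (1 / scales))
    }
    dimnames(fits[[k]]) <- list(colnames(x), colnames(x))
  }
  fit_index <- match(unname(m_at), um)
  names(fit_index) <- at

  structure(
    list(fits = fits, fit_index = fit_index, m = m, at = at,
         bandwidth = bandwidth, gene_ids = colnames(x),
         cell_line_ids = rownames(x), x = x, standardize = standardize,
         centers = centers, scales = scales,
         config = list(delta = delta, nlambda = nlambda,
                       lambda_min_ratio = lambda_min_ratio,
                       adaptive_iterations = adaptive_iterations,
                       adaptive_epsilon = adaptive_epsilon,
                       ess_fraction = ess_fraction, tol = tol,
                       max_sweeps = max_sweeps),
         call = match.call()),
    class = "netprofiler")
}

# Fit all p targets at a single sensitivity value; returns the p x p
# coefficient matrix (rows = targets, cols = regulators) on the working
# (possibly standardized) scale.  One Gram matrix serves every target.
fit_networks_at_m <- function(xs, m, m_alpha, bandwidth, lambda, nlambda,
                              lambda_min_ratio, delta, adaptive_iterations,
                              adaptive_epsilon, tol, max_sweeps) {
  p <- ncol(xs)
  K <- gaussian_kernel(m, m_alpha, bandwidth)
  n_eff <- sum(K)
  if (n_eff <= 0) stop("zero total kernel weight at m = ", m_alpha)
  G <- crossprod(xs * sqrt(K))
  C <- crossprod(xs, K * xs)        # column l = X' K y_l
  B <- matrix(0, p, p)
  for (l in seq_len(p)) {
    fit <- enet_gram_adaptive(G, C[, l], C[l, l], n_eff, delta,
                              exclude = l, lambda = lambda,
                              nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio,
                              adaptive_iterations = adaptive_iterations,
                              adaptive_epsilon = adaptive_epsilon,
                              tol = tol, max_sweeps = max_sweeps)
    B[l, ] <- fit$beta
  }
  B
}

# Match a (possibly named) sensitivity vector to cell-line ids.
align_profile <- function(m, ids) {
  if (is.list(m) || is.data.frame(m)) stop("'m' must be a numeric vector")
  m <- unlist(m)
  if (!is.null(names(m))) {
    common <- intersect(ids, names(m))
    if (!length(common)) stop("no cell lines shared between 'x' and 'm'")
    if (length(common) < length(ids)) {
      message(sprintf("using %d cell lines present in both expression and sensitivity data",
                      length(common)))
    }
    m <- m[common]
  } else {
    if (length(m) != length(ids)) {
      stop("unnamed 'm' must have one value per row of 'x'")
    }
    names(m) <- ids
  }
  if (anyNA(m) || any(!is.finite(m))) stop("'m' contains non-finite values")
  m
}

#' Extract cell-line-specific coefficient matrices
#'
#' @param object A [netprofiler()] fit.
#' @param cell_line Cell-line id(s); default all estimated networks.
#' @param ... Unused.
#' @return A single p x p matrix (one id) or a named list of matrices.
#'   Entry `[l, j]` is the estimated effect of regulator gene `j` on target
#'   gene `l` at that cell line's sensitivity value.
#' @export
coef.netprofiler <- function(object, cell_line = NULL, ...) {
  cell_line <- cell_line %||% object$at
  unknown <- setdiff(cell_line, names(object$fit_index))
  if (length(unknown)) {
    stop("no estimated network for cell line(s): ",
         paste(unknown, collapse = ", "))
  }
  out <- lapply(cell_line, function(id) object$fits[[object$fit_index[[id]]]])
  names(out) <- cell_line
  if (length(out) == 1L) out[[1L]] else out
}

#' @export
print.netprofiler <- function(x, ...) {
  cat("Drug-sensitivity-specific gene regulatory networks\n")
  cat(sprintf("  genes: %d   cell lines: %d   networks estimated: %d (%d distinct m)\n",
              length(x$gene_ids), length(x$cell_line_ids), length(x$at),
              length(x$fits)))
  cat(sprintf("  kernel bandwidth: %.4g   mean effective sample size: %.1f\n",
              x$bandwidth, mean_ess(x)))
  dens <- mean(vapply(x$fits, function(B) mean(B != 0), numeric(1)))
  cat(sprintf("  mean edge density: %.3f (of %d possible directed edges)\n",
              dens, length(x$gene_ids) * (length(x$gene_ids) - 1L)))
  invisible(x)
}

mean_ess <- function(object) {
  um <- sort(unique(unname(object$m[object$at])))
  mean(vapply(um, function(mu)
    sum(gaussian_kernel(object$m, mu, object$bandwidth)), numeric(1)))
}

#' @export
summary.netprofiler <- function(object, ...) {
  nnz <- vapply(seq_along(object$at), function(i)
    sum(object$fits[[object$fit_index[i]]] != 0), integer(1))
  res <- residuals(object)
  out <- list(n_genes = length(object$gene_ids),
              n_cell_lines = length(object$cell_line_ids),
              n_networks = length(object$at),
              bandwidth = object$bandwidth,
              mean_ess = mean_ess(object),
              edges_per_network = summary(nnz),
              resid_sd = sd(res),
              config = object$config)
  class(out) <- "summary.netprofiler"
  out
}

#' @export
print.summary.netprofiler <- function(x, ...) {
  cat("Drug-sensitivity-specific network fit\n")
  cat(sprintf("  %d genes, %d cell lines, %d networks\n",
              x$n_genes, x$n_cell_lines, x$n_networks))
  cat(sprintf("  bandwidth %.4g (mean effective sample size %.1f)\n",
              x$bandwidth, x$mean_ess))
  cat("  directed edges per network:\n")
  print(x$edges_per_network)
  cat(sprintf("  residual sd: %.4g\n", x$resid_sd))
  invisible(x)
}

#' Model-implied expression under a cell line's network
#'
#' For each target gene `l`, computes `sum_j beta_lj (x_j - center_j) +
#' center_l` under the coefficient matrix of `cell_line` (centering terms
#' are zero when the fit was not standardized).
#'
#' @param object A [netprofiler()] fit.
#' @param newdata Expression matrix with the fit's genes as columns;
#'   default the training matrix.
#' @param cell_line Id of the network to use; default each training cell
#'   line's own network (only valid with the training data).
#' @param ... Unused.
#' @return Matrix of fitted expression values; for the default
#'   (training-data) call, one row per estimated network (the fit's `at`
#'   cell lines), otherwise the shape of `newdata`.
#' @export
predict.netprofiler <- function(object, newdata = NULL, cell_line = NULL,
                                ...) {
  own <- is.null(newdata) && is.null(cell_line)
  newdata <- newdata %||% object$x
  newdata <- as.matrix(newdata)[, object$gene_ids, drop = FALSE]
  xc <- sweep(newdata, 2, object$centers)
  if (own) {
    ids <- object$at  # only cell lines with an estimated network
    fitted <- matrix(0, length(ids), ncol(newdata),
                     dimnames = list(ids, colnames(newdata)))
    for (id in ids) {
      B <- object$fits[[object$fit_index[[id]]]]
      fitted[id, ] <- drop(B %*% xc[id, ]) + object$centers
    }
    return(fitted)
  }
  if (is.null(cell_line) || length(cell_line) != 1L) {
    stop("supply a single 'cell_line' whose network should be used")
  }
  B <- coef(object, cell_line)
  out <- t(B %*% t(xc)) + rep(object$centers, each = nrow(xc))
  dimnames(out) <- dimnames(newdata)
  out
}

#' @export
residuals.netprofiler <- function(object, ...) {
  object$x[object$at, , drop = FALSE] - predict(object)
}

#' Plot edge-coefficient trajectories against drug sensitivity
#'
#' Shows how selected directed edge coefficients vary across the estimated
#' networks as a function of the sensitivity value, the model's central
#' object of interest.
#'
#' @param x A [netprofiler()] fit.
#' @param edges Two-column matrix or data.frame (target, regulator) of gene
#'   ids; default the `top` edges with the largest coefficient range.
#' @param top Number of edges to pick automatically.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.netprofiler <- function(x, edges = NULL, top = 6L, ...) {
  ord <- order(x$m[x$at])
  ids <- x$at[ord]
  ms <- x$m[ids]
  arr <- vapply(ids, function(id) x$fits[[x$fit_index[[id]]]],
                matrix(0, length(x$gene_ids), length(x$gene_ids)))
  if (is.null(edges)) {
    rng <- apply(arr, c(1, 2), function(v) diff(range(v)))
    diag(rng) <- -Inf
    sel <- arrayInd(order(rng, decreasing = TRUE)[seq_len(top)], dim(rng))
    edges <- data.frame(target = x$gene_ids[sel[, 1]],
                        regulator = x$gene_ids[sel[, 2]])
  }
  edges <- as.data.frame(edges)
  traj <- sapply(seq_len(nrow(edges)), function(e)
    arr[match(edges[[1]][e], x$gene_ids),
        match(edges[[2]][e], x$gene_ids), ])
  graphics::matplot(ms, traj, type = "l", lty = 1,
                    xlab = "drug sensitivity (m)",
                    ylab = "edge coefficient", ...)
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = seq_len(nrow(edges)),
                   legend = paste(edges[[2]], "->", edges[[1]]))
  invisible(x)
}
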