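#' Configuration for the synthetic network generator
#'
#' Describes a panel of cell lines with a continuous drug-sensitivity value
#' and a planted, sensitivity-varying directed regulatory network.  The
#' planted network is a DAG so that expression can be generated by forward
#' simulation in topological order; genes without regulators are drawn
#' i.i.d. standard normal and every other gene is the linear combination of
#' its regulators' expression (with coefficients evaluated at the cell
#' line's sensitivity value) plus Gaussian noise.
#'
#' Differential edges follow a logistic transition in `m` between a
#' "sensitive-end" value (large `m`) and a "resistant-end" value (small
#' `m`); non-differential edges are constant in `m`.
#'
#' @param n_cell_lines,n_genes Panel dimensions.
#' @param n_true_edges Number of planted directed edges; at most
#'   `n_genes * (n_genes - 1) / 2` (the largest DAG under a fixed
#'   topological order).
#' @param n_differential How many planted edges differ between the
#'   sensitive and resistant ends (default 0 = all edges constant).
#' @param sensitivity_range Interval from which sensitivity values are
#'   drawn.
#' @param m_distribution `"uniform"` over the range, or `"bimodal"`
#'   (half the panel in the lower quarter of the range, half in the upper
#'   quarter), mimicking a design that keeps only extreme responders.
#' @param effect_profile List with the differential-edge profile:
#'   `value_sensitive` (coefficient at the sensitive end, default 0),
#'   `value_resistant` (default 1.5), `midpoint` (logistic transition
#'   midpoint; default the median of the drawn `m`), `steepness` (logistic
#'   slope per unit `m`, default 10 on a unit-length range, scaled by the
#'   range length).
#' @param constant_effect_range Magnitude range for constant edges; each
#'   constant edge gets a coefficient drawn uniformly from this range with
#'   random sign.
#' @param noise_sd Standard deviation of the additive expression noise
#'   (must be positive).
#' @param edges Optional explicit edge table overriding the random DAG:
#'   data.frame with columns `regulator`, `target`, `value_sensitive`,
#'   `value_resistant` and optionally `midpoint`, `steepness` (gene names
#'   or 1-based indices).  Must be acyclic.
#' @param seed RNG seed for reproducibility (`NULL` = ambient stream).
#' @return An object of class `"sim_config"`.
#' @seealso [simulate_grn()], [simulate_null_grn()]
#' @export
sim_config <- function(n_cell_lines = 120L, n_genes = 15L,
                       n_true_edges = 20L, n_differential = 0L,
                       sensitivity_range = c(0, 1),
                       m_distribution = c("uniform", "bimodal"),
                       effect_profile = list(),
                       constant_effect_range = c(0.5, 1.5),
                       noise_sd = 0.3, edges = NULL, seed = NULL) {
  m_distribution <- match.arg(m_distribution)
  stopifnot(n_cell_lines >= 2, n_genes >= 2, noise_sd > 0,
            length(sensitivity_range) == 2,
            sensitivity_range[1] < sensitivity_range[2])
  if (is.null(edges)) {
    max_edges <- n_genes * (n_genes - 1) / 2
    if (n_true_edges > max_edges) {
      stop(sprintf("n_true_edges (%d) exceeds the acyclic maximum %d for %d genes",
                   n_true_edges, max_edges, n_genes))
    }
    if (n_differential > n_true_edges) {
      stop("n_differential cannot exceed n_true_edges")
    }
  }
  span <- diff(sensitivity_range)
  profile <- modifyList(list(value_sensitive = 0, value_resistant = 1.5,
                             midpoint = NULL, steepness = 10 / span),
                        effect_profile)
  structure(list(n_cell_lines = as.integer(n_cell_lines),
                 n_genes = as.integer(n_genes),
                 n_true_edges = as.integer(n_true_edges),
                 n_differential = as.integer(n_differential),
                 sensitivity_range = as.numeric(sensitivity_range),
                 m_distribution = m_distribution,
                 effect_profile = profile,
                 constant_effect_range = as.numeric(constant_effect_range),
                 noise_sd = noise_sd, edges = edges, seed = seed),
            class = "sim_config")
}

#' Generate a synthetic expression panel with a planted varying network
#'
#' Draws sensitivity values, plants a directed acyclic regulatory network
#' whose coefficients vary with sensitivity as configured, and simulates
#' expression for every cell line from the linear model target-by-target in
#' topological order.  Fixing `config$seed` makes the output bit-identical
#' across calls.
#'
#' @param config A [sim_config()].
#' @return List with `expression` (cell lines x genes matrix),
#'   `sensitivity` (named vector) and `truth`, an object of class
#'   `"synthetic_truth"` holding the planted edge table
#'   (`regulator`, `target`, `value_sensitive`, `value_resistant`,
#'   `differential`, `midpoint`, `steepness`), the sensitivity vector,
#'   tercile group labels (resistant / moderate / sensitive) and the noise
#'   level.  [true_network()] evaluates the planted coefficient matrix at
#'   any sensitivity value.
#' @export
simulate_grn <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_cell_lines
    p <- config$n_genes
    genes <- sprintf("G%03d", seq_len(p))
    cells <- sprintf("CL%04d", seq_len(n))
    lo <- config$sensitivity_range[1]
    hi <- config$sensitivity_range[2]
    m <- switch(config$m_distribution,
      uniform = runif(n, lo, hi),
      bimodal = {
        q <- (hi - lo) / 4
        lower <- runif(ceiling(n / 2), lo, lo + q)
        upper <- runif(floor(n / 2), hi - q, hi)
        sample(c(lower, upper))
      })
    names(m) <- cells

    edges <- config$edges %||% draw_random_dag(config, genes)
    edges <- normalize_edge_table(edges, genes, config, m)
    check_acyclic(edges, genes)

    X <- matrix(0, n, p, dimnames = list(cells, genes))
    ord <- topological_order(edges, genes)
    for (g in ord) {
      inc <- edges[edges$target == g, , drop = FALSE]
      if (nrow(inc) == 0L) {
        X[, g] <- rnorm(n)
      } else {
        mu <- rep(0, n)
        for (e in seq_len(nrow(inc))) {
          mu <- mu + edge_value(inc[e, ], m) * X[, inc$regulator[e]]
        }
        X[, g] <- mu + rnorm(n, sd = config$noise_sd)
      }
    }

    terc <- cut(m, breaks = quantile(m, c(0, 1 / 3, 2 / 3, 1)),
                labels = c("resistant", "moderate", "sensitive"),
                include.lowest = TRUE)
    truth <- structure(list(edges = edges, sensitivity = m,
                            group_labels = stats::setNames(as.character(terc),
                                                           cells),
                            noise_sd = config$noise_sd, gene_ids = genes,
                            config = config),
                       class = "synthetic_truth")
    list(expression = X, sensitivity = m, truth = truth)
  })
}

#' Generate a null panel (no differential structure)
#'
#' Same generative process as [simulate_grn()] but every planted edge is
#' constant in sensitivity, so the true network is identical for all cell
#' lines and the differential edge set is empty.  Used to study the size of
#' the permutation test.
#'
#' @param config A [sim_config()]; its `n_differential` and any
#'   differential entries of an explicit edge table are overridden to zero.
#' @return As [simulate_grn()].
#' @export
simulate_null_grn <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$n_differential <- 0L
  if (!is.null(config$edges)) {
    config$edges$value_sensitive <- config$edges$value_resistant
  }
  simulate_grn(config)
}

# Random DAG: random topological order, n_true_edges ordered pairs drawn
# uniformly among forward pairs; the first n_differential get the logistic
# differential profile, the rest constant random-sign magnitudes.
draw_random_dag <- function(config, genes) {
  p <- config$n_genes
  ord <- sample(p)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pick <- pairs[sample(nrow(pairs), config$n_true_edges), , drop = FALSE]
  reg <- genes[ord[pick[, 1]]]
  tgt <- genes[ord[pick[, 2]]]
  k <- config$n_true_edges
  kd <- config$n_differential
  const <- runif(k, config$constant_effect_range[1],
                 config$constant_effect_range[2]) *
    sample(c(-1, 1), k, replace = TRUE)
  is_diff <- seq_len(k) <= kd
  data.frame(regulator = reg, target = tgt,
             value_sensitive = ifelse(is_diff,
                                      config$effect_profile$value_sensitive,
                                      const),
             value_resistant = ifelse(is_diff,
                                      config$effect_profile$value_resistant,
                                      const),
             stringsAsFactors = FALSE)
}

normalize_edge_table <- function(edges, genes, config, m) {
  edges <- as.data.frame(edges)
  req <- c("regulator", "target", "value_sensitive", "value_resistant")
  if (!all(req %in% names(edges))) {
    stop("edge table needs columns: ", paste(req, collapse = ", "))
  }
  for (col in c("regulator", "target")) {
    if (is.numeric(edges[[col]])) edges[[col]] <- genes[edges[[col]]]
    if (!all(edges[[col]] %in% genes)) stop("unknown gene in edge table")
  }
  if (any(edges$regulator == edges$target)) stop("self-edges are not allowed")
  if (anyDuplicated(edges[c("regulator", "target")])) {
    stop("duplicate edges in edge table")
  }
  if (is.null(edges$midpoint)) {
    edges$midpoint <- config$effect_profile$midpoint %||% median(m)
  }
  if (is.null(edges$steepness)) {
    edges$steepness <- config$effect_profile$steepness
  }
  edges$differential <- edges$value_sensitive != edges$value_resistant
  edges
}

# Coefficient of one edge at sensitivity value(s) m: logistic transition
# from the resistant-end value (small m) to the sensitive-end value
# (large m); constant edges short-circuit to their value.
edge_value <- function(edge, m) {
  if (!edge$differential) return(rep(edge$value_resistant, length(m)))
  s <- stats::plogis(edge$steepness * (m - edge$midpoint))
  edge$value_resistant + (edge$value_sensitive - edge$value_resistant) * s
}

check_acyclic <- function(edges, genes) {
  g <- igraph::graph_from_data_frame(edges[c("regulator", "target")],
                                     vertices = genes)
  if (!igraph::is_dag(g)) {
    stop("planted edge set contains a cycle; forward generation needs a DAG")
  }
  invisible(TRUE)
}

topological_order <- function(edges, genes) {
  g <- igraph::graph_from_data_frame(edges[c("regulator", "target")],
                                     vertices = genes)
  names(igraph::topo_sort(g, mode = "out"))
}

#' Evaluate the planted coefficient matrix at a sensitivity value
#'
#' @param truth A `"synthetic_truth"` object from [simulate_grn()].
#' @param m Sensitivity value(s).
#' @return For a single `m`, the p x p true coefficient matrix (entry
#'   `[l, j]` = effect of regulator `j` on target `l`); for several, a list
#'   of matrices.
#' @export
true_network <- function(truth, m) {
  stopifnot(inherits(truth, "synthetic_truth"))
  one <- function(mv) {
    p <- length(truth$gene_ids)
    B <- matrix(0, p, p, dimnames = list(truth$gene_ids, truth$gene_ids))
    for (e in seq_len(nrow(truth$edges))) {
      ed <- truth$edges[e, ]
      B[ed$target, ed$regulator] <- edge_value(ed, mv)
    }
    B
  }
  if (length(m) == 1L) one(m) else lapply(m, one)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Planted sensitivity-varying regulatory network\n")
  cat(sprintf("  genes: %d   cell lines: %d   edges: %d (%d differential)\n",
              length(x$gene_ids), length(x$sensitivity), nrow(x$edges),
              sum(x$edges$differential)))
  cat(sprintf("  noise sd: %.3g\n", x$noise_sd))
  invisible(x)
}

#' Write synthetic data in the formats the pipeline reads
#'
#' `write_expression_csv()` writes the DepMap-dialect expression CSV (first
#' column `cell_line`, one column per gene); `write_sensitivity_csv()` the
#' two-column sensitivity CSV; `write_truth_tsv()` the planted edge table
#' with its sensitive- and resistant-end values.
#'
#' @param x Expression matrix / named sensitivity vector / truth object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(x, path) {
  df <- data.frame(cell_line = rownames(x), x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_csv
#' @export
write_sensitivity_csv <- function(x, path) {
  df <- data.frame(cell_line = names(x), sensitivity = unname(x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_csv
#' @export
write_truth_tsv <- function(x, path) {
  stopifnot(inherits(x, "synthetic_truth"))
  cols <- c("regulator", "target", "value_sensitive", "value_resistant")
  utils::write.table(x$edges[cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
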