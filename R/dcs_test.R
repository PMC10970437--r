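#' Permutation test for differential regulation of a gene subnetwork
#'
#' Computes the observed DCS statistic ([dcs_statistic()]) on a random
#' pairing of the sensitive and resistant groups, then re-computes it for
#' `n_permutations` permutations in which the pooled cell lines are
#' shuffled into two new groups of the same size and re-paired at random.
#'
#' Two tail conventions are available.  Small topological-overlap
#' dissimilarity entries are what flags jointly rewired gene sets, so the
#' default `tail = "small-is-extreme"` counts permutations with
#' `DCS_pm <= DCS` — small observed DCS relative to the permutation
#' distribution yields a small p-value.  `tail = "literal"` counts
#' `DCS <= DCS_pm` instead, the printed form of the original recipe, whose
#' direction is inverted relative to its own decision rule `p < tau`; it is
#' kept for fidelity and equals `1 - p_small - P(tie)` up to ties.
#'
#' @param networks A [netprofiler()] fit or named list of coefficient
#'   matrices covering all listed cell lines.
#' @param sensitive,resistant Equal-size character vectors of cell-line
#'   ids (see [define_extreme_cell_lines()]).
#' @param genes Gene ids of the subnetwork to test (default: all genes of
#'   the networks).
#' @param gamma,normalize,include_diagonal Passed down the DCS chain.
#' @param n_permutations Number of permutations `T` (>= 1); the p-value
#'   denominator is `T` exactly, or `T + 1` with `add_one`.
#' @param tau Significance level; `significant` is `p_value < tau`.
#' @param tail `"small-is-extreme"` (default) or `"literal"`, see Details.
#' @param add_one Use the `(b + 1) / (T + 1)` finite-sample correction.
#' @param seed Seed controlling the observed pairing and the permutation
#'   stream.
#' @return Object of class `"dcs_test"`: list with `dcs`, `dcs_permuted`,
#'   `p_value`, `significant`, `tau`, `tail`, `n_permutations`, `gamma`,
#'   `genes`, `design`.
#' @export
dcs_test <- function(networks, sensitive, resistant, genes = NULL,
                     gamma = 1, normalize = TRUE, include_diagonal = TRUE,
                     n_permutations = 500L, tau = 0.05,
                     tail = c("small-is-extreme", "literal"),
                     add_one = FALSE, seed = NULL) {
  tail <- match.arg(tail)
  if (n_permutations < 1L) stop("'n_permutations' must be >= 1")
  if (length(sensitive) != length(resistant)) {
    stop("groups must have equal size")
  }
  nets <- as_network_list(networks, c(sensitive, resistant))
  genes <- genes %||% colnames(nets[[1]])
  W <- lapply(nets, edge_weight_matrix, genes = genes)
  dcs_of <- function(s_ids, r_ids) {
    mean(vapply(seq_along(s_ids), function(a)
      pair_ave_tom(W[[s_ids[a]]], W[[r_ids[a]]], gamma, normalize,
                   include_diagonal), numeric(1)))
  }

  with_seed(seed, {
    design <- build_paired_design(sensitive, resistant)
    dcs <- dcs_of(design$sensitive, design$resistant)
    pooled <- c(sensitive, resistant)
    k <- length(sensitive)
    dcs_pm <- vapply(seq_len(n_permutations), function(pm) {
      shuffled <- sample(pooled)
      d <- build_paired_design(shuffled[seq_len(k)], shuffled[k + seq_len(k)])
      dcs_of(d$sensitive, d$resistant)
    }, numeric(1))
    b <- if (tail == "small-is-extreme") sum(dcs_pm <= dcs) else
      sum(dcs <= dcs_pm)
    p <- if (add_one) (b + 1) / (n_permutations + 1) else b / n_permutations
    structure(list(dcs = dcs, dcs_permuted = dcs_pm, p_value = p,
                   significant = p < tau, tau = tau, tail = tail,
                   n_permutations = n_permutations, gamma = gamma,
                   normalize = normalize, genes = genes, design = design,
                   add_one = add_one),
              class = "dcs_test")
  })
}

#' @export
print.dcs_test <- function(x, ...) {
  cat("Differential regulation permutation test (DCS)\n")
  cat(sprintf("  genes: %d   pairs: %d   permutations: %d\n",
              length(x$genes), nrow(x$design), x$n_permutations))
  cat(sprintf("  DCS = %.4f   p = %.4g (%s tail)   %s at tau = %.3g\n",
              x$dcs, x$p_value, x$tail,
              if (x$significant) "significant" else "not significant",
              x$tau))
  invisible(x)
}

#' Test a list of subnetworks for differential regulation
#'
#' Runs [dcs_test()] on each subnetwork.  Each subnetwork gets its own RNG
#' stream derived from `seed` and the subnetwork id, so results do not
#' depend on the order of the input list.
#'
#' @param networks A [netprofiler()] fit or named list of coefficient
#'   matrices.
#' @param subnets List of `"subnetwork"` objects (see [subnetworks()]), or
#'   a named list of gene-id vectors.
#' @param sensitive,resistant Cell-line id groups.
#' @inheritParams dcs_test
#' @return Object of class `"dcs_screen"`: a data.frame with one row per
#'   subnetwork (`subnetwork`, `n_genes`, `dcs`, `p_value`, `significant`),
#'   sorted by p-value then subnetwork id, with the individual
#'   `"dcs_test"` objects in `attr(, "tests")`.
#' @export
dcs_screen <- function(networks, subnets, sensitive, resistant, gamma = 1,
                       normalize = TRUE, include_diagonal = TRUE,
                       n_permutations = 500L, tau = 0.05,
                       tail = c("small-is-extreme", "literal"),
                       add_one = FALSE, seed = NULL) {
  tail <- match.arg(tail)
  if (!length(subnets)) {
    out <- data.frame(subnetwork = character(), n_genes = integer(),
                      dcs = numeric(), p_value = numeric(),
                      significant = logical())
    class(out) <- c("dcs_screen", "data.frame")
    return(out)
  }
  ids <- vapply(seq_along(subnets), function(i) {
    s <- subnets[[i]]
    if (inherits(s, "subnetwork")) return(s$id)
    nm <- names(subnets)[i]
    if (!is.null(names(subnets)) && !is.na(nm) && nzchar(nm)) nm else
      sprintf("subnet_%02d", i)
  }, character(1))
  if (anyDuplicated(ids)) stop("subnetwork ids must be unique")
  tests <- lapply(seq_along(subnets), function(i) {
    s <- subnets[[i]]
    genes <- if (inherits(s, "subnetwork")) s$gene_ids else s
    dcs_test(networks, sensitive, resistant, genes = genes, gamma = gamma,
             normalize = normalize, include_diagonal = include_diagonal,
             n_permutations = n_permutations, tau = tau, tail = tail,
             add_one = add_one, seed = derive_seed(seed, ids[i]))
  })
  names(tests) <- ids
  out <- data.frame(subnetwork = ids,
                    n_genes = vapply(tests, function(t) length(t$genes),
                                     integer(1)),
                    dcs = vapply(tests, `[[`, numeric(1), "dcs"),
                    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
                    significant = vapply(tests, `[[`, logical(1),
                                         "significant"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$subnetwork), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  attr(out, "params") <- list(gamma = gamma, tau = tau,
                              n_permutations = n_permutations, tail = tail,
                              normalize = normalize, seed = seed)
  class(out) <- c("dcs_screen", "data.frame")
  out
}

#' @export
print.dcs_screen <- function(x, ...) {
  p <- attr(x, "params")
  cat("Differential regulation screen\n")
  if (!is.null(p)) {
    cat(sprintf("  gamma = %g, T = %d, tau = %g, tail = %s\n",
                p$gamma, p$n_permutations, p$tau, p$tail))
  }
  print.data.frame(x)
  invisible(x)
}
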