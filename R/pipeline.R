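#' Run the full differential network analysis
#'
#' End-to-end panel analysis: variance-filter genes, define extreme
#' sensitive/resistant groups, estimate sensitivity-specific networks for
#' the extreme cell lines (all cell lines contribute observations), extract
#' the strongest edges from the resistant-group networks, decompose them
#' into connected subnetworks, and score each subnetwork with the DCS
#' permutation test.
#'
#' @param expression Expression matrix (cell lines x genes) or path to a
#'   DepMap-dialect CSV ([load_expression()]).
#' @param sensitivity Named sensitivity vector or path to a two-column CSV
#'   ([load_sensitivity()]).  Cell lines present in both inputs are used.
#' @param n_top_genes Number of highest-variance genes kept (default 1000,
#'   capped at the number of genes).
#' @param n_extreme Size of each extreme group (default 100, capped at half
#'   the panel).
#' @param edge_fraction Fraction of top edges extracted from the resistant
#'   networks (default 0.01).
#' @param estimate_all Also estimate networks for non-extreme cell lines
#'   (the full panel sweep); default `FALSE`, since only the extreme
#'   networks enter the differential test.
#' @param gamma,tau,n_permutations,tail Differential-test settings
#'   (defaults: `gamma = 1`, `tau = 0.05`, `n_permutations = 500`).
#' @param p_adjust Multiple-testing adjustment across subnetworks applied
#'   to the significance call: `"none"` (default, raw `p < tau`) or any
#'   method of [stats::p.adjust()].
#' @param estimator Named list of overrides passed to [netprofiler()]
#'   (e.g. `bandwidth`, `delta`, `nlambda`).
#' @param seed Seed for pairing and permutations; the estimation stage is
#'   deterministic.
#' @param output_dir If non-`NULL`, intermediate and final tables are
#'   written there as TSVs, each with a header comment carrying the config
#'   hash and seed.
#' @return Object of class `"drgnet_pipeline"`: list with `networks` (the
#'   [netprofiler()] fit), `groups`, `top_edges`, `subnets`, `results` (the
#'   [dcs_screen()] table), `summaries` (median edge weights per
#'   subnetwork over the resistant and sensitive networks) and `config`.
#' @export
run_pipeline <- function(expression, sensitivity, n_top_genes = 1000L,
                         n_extreme = 100L, edge_fraction = 0.01,
                         estimate_all = FALSE, gamma = 1, tau = 0.05,
                         n_permutations = 500L,
                         tail = c("small-is-extreme", "literal"),
                         p_adjust = "none", estimator = list(),
                         seed = NULL, output_dir = NULL) {
  tail <- match.arg(tail)
  if (is.character(expression)) expression <- load_expression(expression)
  if (is.character(sensitivity)) sensitivity <- load_sensitivity(sensitivity)

  m <- align_profile(sensitivity, rownames(expression))
  expression <- expression[names(m), , drop = FALSE]
  config <- list(n_top_genes = n_top_genes, n_extreme = n_extreme,
                 edge_fraction = edge_fraction, estimate_all = estimate_all,
                 gamma = gamma, tau = tau, n_permutations = n_permutations,
                 tail = tail, p_adjust = p_adjust, estimator = estimator,
                 seed = seed)
  cfg_hash <- sprintf("%08x", hash32(paste(deparse(config), collapse = "")))
  header <- sprintf("config=%s seed=%s", cfg_hash,
                    if (is.null(seed)) "none" else seed)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[drgnet] ", fmt),
                                                  ...))

  n_top_genes <- min(n_top_genes, ncol(expression))
  expr_f <- select_top_variance_genes(expression, n_top_genes)
  log_stage("genes kept after variance filter: %d of %d", ncol(expr_f),
            ncol(expression))
  log_stage("cell lines with expression and sensitivity: %d", nrow(expr_f))

  n_extreme <- min(n_extreme, floor(nrow(expr_f) / 2))
  groups <- define_extreme_cell_lines(m, n_extreme)
  log_stage("extreme groups: %d sensitive, %d resistant",
            length(groups$sensitive), length(groups$resistant))

  at <- if (estimate_all) rownames(expr_f) else
    c(groups$sensitive, groups$resistant)
  fit <- do.call(netprofiler,
                 c(list(x = expr_f, m = m, at = at), estimator))
  log_stage("networks estimated: %d (bandwidth %.4g)", length(fit$at),
            fit$bandwidth)

  top_edges <- extract_top_edges(as_network_list(fit, groups$resistant),
                                 fraction = edge_fraction)
  log_stage("top edges extracted from resistant networks: %d",
            nrow(top_edges))

  subnets <- if (nrow(top_edges)) subnetworks(top_edges) else list()
  log_stage("connected subnetworks: %d", length(subnets))

  results <- dcs_screen(fit, subnets, groups$sensitive, groups$resistant,
                        gamma = gamma, n_permutations = n_permutations,
                        tau = tau, tail = tail, seed = seed)
  if (nrow(results) && p_adjust != "none") {
    results$p_adjusted <- stats::p.adjust(results$p_value, method = p_adjust)
    results$significant <- results$p_adjusted < tau
  }
  log_stage("subnetworks flagged significant: %d", sum(results$significant))

  summaries <- lapply(subnets, function(s) {
    res <- median_edge_summary(fit, s, cell_lines = groups$resistant)
    sen <- median_edge_summary(fit, s, cell_lines = groups$sensitive)
    res$median_weight_sensitive <- sen$median_weight
    names(res)[names(res) == "median_weight"] <- "median_weight_resistant"
    res$subnetwork <- s$id
    res
  })

  out <- structure(list(networks = fit, groups = groups,
                        top_edges = top_edges, subnets = subnets,
                        results = results, summaries = summaries,
                        config = config, config_hash = cfg_hash),
                   class = "drgnet_pipeline")
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir, header)
  out
}

write_pipeline_outputs <- function(out, output_dir, header) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(output_dir, f)
  write_tsv_commented(out$top_edges, fp("top_edges.tsv"), header)
  res <- as.data.frame(out$results)
  write_tsv_commented(res, fp("results.tsv"), header)
  subs <- do.call(rbind, lapply(out$summaries, function(s)
    s[c("subnetwork", "regulator", "target", "median_weight_resistant",
        "median_weight_sensitive", "sign")]))
  if (is.null(subs)) {
    subs <- data.frame(subnetwork = character(), regulator = character(),
                       target = character(),
                       median_weight_resistant = numeric(),
                       median_weight_sensitive = numeric(),
                       sign = numeric())
  }
  write_tsv_commented(subs, fp("subnetworks.tsv"), header)
  write_edge_list(out$networks, fp("networks.tsv"), header)
  invisible(output_dir)
}

#' @export
print.drgnet_pipeline <- function(x, ...) {
  cat("Differential network analysis pipeline\n")
  cat(sprintf("  %d genes, %d networks, %d sensitive / %d resistant\n",
              length(x$networks$gene_ids), length(x$networks$at),
              length(x$groups$sensitive), length(x$groups$resistant)))
  cat(sprintf("  top edges: %d   subnetworks: %d   significant: %d\n",
              nrow(x$top_edges), length(x$subnets),
              sum(x$results$significant)))
  print(x$results)
  invisible(x)
}
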