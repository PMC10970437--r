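# Panel-scale screening steps: variance filtering, extreme-group
# definition, top-edge extraction and subnetwork decomposition.

#' Keep the k genes with the highest expression variance
#'
#' @param x Expression matrix (cell lines x genes).
#' @param k Number of genes to keep; ties at the variance boundary are
#'   broken by gene-id lexicographic order, so the result is deterministic.
#' @return The filtered matrix, columns in their original order.
#' @export
select_top_variance_genes <- function(x, k) {
  x <- as.matrix(x)
  stopifnot_matrix(x, "x")
  if (k <= 0) stop("'k' must be positive")
  if (k > ncol(x)) stop("'k' exceeds the number of genes")
  v <- apply(x, 2, var)
  ord <- order(-v, colnames(x))
  keep <- sort(ord[seq_len(k)])
  x[, keep, drop = FALSE]
}

#' Define drug-sensitive and drug-resistant extreme groups
#'
#' The sensitive group holds the `k` cell lines with the largest
#' sensitivity values, the resistant group the `k` with the smallest; the
#' groups are disjoint.  Boundary ties are broken by cell-line-id order and
#' reported via a message.
#'
#' @param m Named numeric sensitivity vector.
#' @param k Group size; `2 * k` must not exceed the panel size.
#' @return List with character vectors `sensitive` and `resistant`.
#' @export
define_extreme_cell_lines <- function(m, k) {
  if (is.null(names(m))) stop("'m' must be named by cell line id")
  n <- length(m)
  if (2 * k > n) stop("2 * k exceeds the number of cell lines")
  ord_hi <- order(-m, names(m))
  ord_lo <- order(m, names(m))
  sensitive <- names(m)[ord_hi[seq_len(k)]]
  resistant <- names(m)[ord_lo[seq_len(k)]]
  for (grp in list(c("sensitive", k), c("resistant", k))) {
    side <- grp[1]
    sel <- if (side == "sensitive") sensitive else resistant
    boundary <- if (side == "sensitive") min(m[sel]) else max(m[sel])
    if (sum(m == boundary) > sum(m[sel] == boundary)) {
      message(sprintf("ties at the %s boundary broken by cell-line id order",
                      side))
    }
  }
  list(sensitive = sensitive, resistant = resistant)
}

#' Extract the strongest edges across a collection of networks
#'
#' Ranks every directed edge by the median of its absolute coefficient
#' across the networks and returns the top `ceiling(fraction * E)` edges,
#' where `E` counts edges with a nonzero median (zero-median edges are
#' treated as non-edges).  With `mode = "per-network"` the alternative
#' reading is used: the union over networks of each network's own top
#' fraction of nonzero edges.
#'
#' @param networks A [netprofiler()] fit or a list of p x p coefficient
#'   matrices sharing dimnames.
#' @param fraction Fraction of edges to keep, in (0, 1].
#' @param mode `"median"` (default) or `"per-network"`.
#' @return data.frame with columns `regulator`, `target`,
#'   `median_coefficient` (signed) and `median_abs` (ranking key), ordered
#'   by decreasing `median_abs` with ties broken by (regulator, target) id
#'   order.
#' @export
extract_top_edges <- function(networks, fraction = 0.01,
                              mode = c("median", "per-network")) {
  mode <- match.arg(mode)
  nets <- as_network_list(networks)
  if (!length(nets)) stop("empty network collection")
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  genes <- colnames(nets[[1]])
  arr <- simplify2array(nets)                   # p x p x n
  med_signed <- apply(arr, c(1, 2), median)
  med_abs <- apply(abs(arr), c(1, 2), median)
  diag(med_abs) <- 0

  edge_df <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    df <- data.frame(regulator = genes[idx[, 2]], target = genes[idx[, 1]],
                     median_coefficient = med_signed[mask],
                     median_abs = med_abs[mask], stringsAsFactors = FALSE)
    df[order(-df$median_abs, df$regulator, df$target), , drop = FALSE]
  }

  if (mode == "median") {
    mask <- med_abs != 0
    if (!any(mask)) {
      warning("all edges have zero median strength; returning no edges")
      return(edge_df(mask))
    }
    df <- edge_df(mask)
    head(df, ceiling(fraction * nrow(df)))
  } else {
    keep <- matrix(FALSE, length(genes), length(genes))
    for (B in nets) {
      a <- abs(B)
      diag(a) <- 0
      nz <- a[a != 0]
      if (!length(nz)) next
      kth <- sort(nz, decreasing = TRUE)[ceiling(fraction * length(nz))]
      keep <- keep | (a >= kth & a != 0)
    }
    if (!any(keep)) {
      warning("all edges have zero strength; returning no edges")
    }
    edge_df(keep)
  }
}

# Accept either a netprofiler fit (optionally subset by cell line ids) or a
# plain list of coefficient matrices.
as_network_list <- function(networks, cell_lines = NULL) {
  if (inherits(networks, "netprofiler")) {
    ids <- cell_lines %||% networks$at
    out <- coef(networks, cell_line = ids)
    if (is.matrix(out)) out <- stats::setNames(list(out), ids)
    return(out)
  }
  if (is.matrix(networks)) return(list(networks))
  stopifnot(is.list(networks), length(networks) > 0)
  if (!is.null(cell_lines)) {
    missing <- setdiff(cell_lines, names(networks))
    if (length(missing)) {
      stop("no network available for cell line(s): ",
           paste(missing, collapse = ", "))
    }
    networks <- networks[cell_lines]
  }
  networks
}

#' Decompose an edge set into connected subnetworks
#'
#' Components are taken on the undirected view of the directed edge set;
#' each component is returned with its induced directed edges.  Components
#' are ordered by decreasing gene count, then by smallest gene id.
#'
#' @param edges data.frame with columns `regulator` and `target` (e.g. from
#'   [extract_top_edges()]); extra columns are carried along.
#' @return List of objects of class `"subnetwork"`, each with `id`,
#'   `gene_ids` and `edges`.
#' @export
subnetworks <- function(edges) {
  edges <- as.data.frame(edges)
  if (!nrow(edges)) stop("empty edge set")
  g <- igraph::graph_from_data_frame(edges[c("regulator", "target")],
                                     directed = TRUE)
  comp <- igraph::components(igraph::as_undirected(g))
  members <- split(names(comp$membership), comp$membership)
  ord <- order(-lengths(members),
               vapply(members, function(v) min(sort(v)), character(1)))
  members <- members[ord]
  out <- lapply(seq_along(members), function(i) {
    gs <- sort(members[[i]])
    sub <- edges[edges$regulator %in% gs & edges$target %in% gs, ,
                 drop = FALSE]
    rownames(sub) <- NULL
    structure(list(id = sprintf("subnet_%02d", i), gene_ids = gs,
                   edges = sub),
              class = "subnetwork")
  })
  out
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("Subnetwork %s: %d genes, %d directed edges\n", x$id,
              length(x$gene_ids), nrow(x$edges)))
  cat("  genes:", paste(x$gene_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Median edge strengths of a subnetwork across a network collection
#'
#' For each directed edge of the subnetwork, the median over the collection
#' of the signed coefficient (even counts use the midpoint of the two
#' central values).  The sign is reported separately from the magnitude,
#' matching the convention of drawing positive and negative regulation in
#' different colours.
#'
#' @param networks A [netprofiler()] fit or list of coefficient matrices.
#' @param subnet A `"subnetwork"` object (or anything with `edges`).
#' @param cell_lines Optional subset of networks to summarize over.
#' @return The subnetwork's edge table with columns `median_weight` (signed
#'   median), `magnitude` and `sign` appended.
#' @export
median_edge_summary <- function(networks, subnet, cell_lines = NULL) {
  nets <- as_network_list(networks, cell_lines)
  edges <- if (inherits(subnet, "subnetwork")) subnet$edges else
    as.data.frame(subnet)
  med <- vapply(seq_len(nrow(edges)), function(e) {
    vals <- vapply(nets, function(B) B[edges$target[e], edges$regulator[e]],
                   numeric(1))
    median(vals)
  }, numeric(1))
  edges$median_weight <- med
  edges$magnitude <- abs(med)
  edges$sign <- sign(med)
  edges
}
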