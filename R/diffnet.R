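# Differential-network statistic: edge-weight matrices, adjacency
# difference, topological-overlap dissimilarity and the DCS statistic over
# a paired sensitive/resistant design.

#' Symmetric edge-weight matrix of a directed network
#'
#' Undirected edge weight between genes `i` and `j`:
#' `w_ij = (|beta_ij| + |beta_ji|) / 2`, the average absolute regulatory
#' strength in the two directions.  The diagonal is zero.
#'
#' @param network p x p coefficient matrix (entry `[l, j]` = effect of
#'   regulator `j` on target `l`), with dimnames.
#' @param genes Optional subset of gene ids to restrict to.
#' @return Symmetric nonnegative matrix over `genes`.
#' @export
edge_weight_matrix <- function(network, genes = NULL) {
  network <- as.matrix(network)
  stopifnot_matrix(network, "network")
  if (!is.null(genes)) {
    unknown <- setdiff(genes, colnames(network))
    if (length(unknown)) {
      stop("unknown gene(s): ", paste(unknown, collapse = ", "))
    }
    network <- network[genes, genes, drop = FALSE]
  }
  W <- (abs(network) + t(abs(network))) / 2
  diag(W) <- 0
  W
}

#' Adjacency difference matrix between paired edge-weight matrices
#'
#' Entrywise
#' \deqn{d_{ij} = \left(\tfrac12\,\bigl|\mathrm{sign}(w^S_{ij})(w^S_{ij})^2 -
#'   \mathrm{sign}(w^R_{ij})(w^R_{ij})^2\bigr|\right)^{\gamma}}{
#'   d_ij = (1/2 |sign(wS) wS^2 - sign(wR) wR^2|)^gamma}
#' with the exponent `gamma` applied to the whole halved absolute
#' difference.  Edge weights are nonnegative, so the sign factors are
#' vacuous here; they matter for the signed-correlation variant
#' ([diffcoex_adjacency()]), which shares this formula.  With
#' `normalize = TRUE` (recommended for regression-coefficient-based
#' weights, which are not bounded by 1 the way correlations are) both
#' matrices are first divided by the largest entry across the pair, so
#' `d_ij` lies in `[0, (1/2)^gamma]`.
#'
#' @param w_sensitive,w_resistant Symmetric nonnegative edge-weight
#'   matrices on the same genes (see [edge_weight_matrix()]).
#' @param gamma Positive exponent emphasizing large differences.
#' @param normalize Divide both matrices by their joint maximum first.
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
adjacency_difference <- function(w_sensitive, w_resistant, gamma = 1,
                                 normalize = TRUE) {
  check_square_symmetric(w_sensitive, "w_sensitive")
  check_square_symmetric(w_resistant, "w_resistant")
  if (!identical(dim(w_sensitive), dim(w_resistant))) {
    stop("edge-weight matrices must have the same dimensions")
  }
  if (any(w_sensitive < 0) || any(w_resistant < 0)) {
    stop("edge weights must be nonnegative")
  }
  if (gamma <= 0) stop("'gamma' must be positive")
  if (normalize) {
    mx <- max(w_sensitive, w_resistant)
    if (mx > 0) {
      w_sensitive <- w_sensitive / mx
      w_resistant <- w_resistant / mx
    }
  }
  D <- (0.5 * abs(sign(w_sensitive) * w_sensitive^2 -
                    sign(w_resistant) * w_resistant^2))^gamma
  diag(D) <- 0
  D
}

#' Adjacency difference from signed correlation matrices
#'
#' The co-expression-based variant: the same halved squared-difference
#' formula as [adjacency_difference()], applied to signed correlation
#' matrices of the sensitive and resistant groups, so that sign changes of
#' a correlation contribute fully.  With `gamma = 1` entries lie in
#' `[0, 1]`.
#'
#' @param corr_sensitive,corr_resistant Symmetric correlation matrices
#'   (entries in `[-1, 1]`, unit diagonal).
#' @param gamma Positive exponent.
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
diffcoex_adjacency <- function(corr_sensitive, corr_resistant, gamma = 1) {
  check_square_symmetric(corr_sensitive, "corr_sensitive")
  check_square_symmetric(corr_resistant, "corr_resistant")
  if (!identical(dim(corr_sensitive), dim(corr_resistant))) {
    stop("correlation matrices must have the same dimensions")
  }
  if (max(abs(corr_sensitive)) > 1 + 1e-8 ||
      max(abs(corr_resistant)) > 1 + 1e-8) {
    stop("correlation entries must lie in [-1, 1]")
  }
  if (gamma <= 0) stop("'gamma' must be positive")
  D <- (0.5 * abs(sign(corr_sensitive) * corr_sensitive^2 -
                    sign(corr_resistant) * corr_resistant^2))^gamma
  diag(D) <- 0
  D
}

#' Topological-overlap dissimilarity of an adjacency-difference matrix
#'
#' For `i != j`,
#' \deqn{t_{ij} = 1 - \frac{\sum_{k \notin \{i,j\}} d_{ik} d_{jk} + d_{ij}}
#'   {\min\left(\sum_{k \ne i} d_{ik}, \sum_{k \ne j} d_{jk}\right) + 1 -
#'   d_{ij}}}{t_ij = 1 - (sum_k d_ik d_jk + d_ij) /
#'   (min(sum d_ik, sum d_jk) + 1 - d_ij)}
#' with `t_ii = 1` (standard topological-overlap index conventions: the
#' shared-neighbour sum skips `i` and `j`, connectivities skip the self
#' term, the diagonal of `D` is zero).  Small `t_ij` means genes `i` and
#' `j` change their connections jointly within the same neighbourhood,
#' i.e. belong to a differentially regulated set.
#'
#' @param D Symmetric nonnegative matrix with zero diagonal (see
#'   [adjacency_difference()]).
#' @return Symmetric dissimilarity matrix with unit diagonal.
#' @export
tom_dissimilarity <- function(D) {
  check_square_symmetric(D, "D")
  if (any(D < 0)) stop("'D' must be nonnegative")
  if (any(diag(D) != 0)) stop("'D' must have a zero diagonal")
  A <- D %*% D           # A_ij = sum_k d_ik d_jk; diag(D)=0 already skips i,j
  s <- rowSums(D)
  denom <- outer(s, s, pmin) + 1 - D
  T <- 1 - (A + D) / denom
  diag(T) <- 1
  dimnames(T) <- dimnames(D)
  T
}

#' Average entry of a dissimilarity matrix
#'
#' Mean of all `p^2` entries including the unit diagonal (the literal
#' definition); `include_diagonal = FALSE` averages the off-diagonal
#' entries only.
#'
#' @param T Dissimilarity matrix (see [tom_dissimilarity()]).
#' @param include_diagonal Include the diagonal in the average.
#' @return A single number.
#' @export
average_dissimilarity <- function(T, include_diagonal = TRUE) {
  T <- as.matrix(T)
  if (include_diagonal) return(mean(T))
  p <- nrow(T)
  if (p < 2) stop("need at least 2 genes for an off-diagonal average")
  (sum(T) - sum(diag(T))) / (p * (p - 1))
}

# Validation-free evaluation of the chain adjacency difference ->
# topological-overlap dissimilarity -> average entry for one pair of
# (already symmetric, nonnegative, zero-diagonal) edge-weight matrices.
# Used in permutation loops; the exported functions validate and delegate
# to the same arithmetic.
pair_ave_tom <- function(W_s, W_r, gamma, normalize, include_diagonal) {
  if (normalize) {
    mx <- max(W_s, W_r)
    if (mx > 0) {
      W_s <- W_s / mx
      W_r <- W_r / mx
    }
  }
  D <- (0.5 * abs(W_s * W_s - W_r * W_r))^gamma  # weights >= 0: signs vacuous
  diag(D) <- 0
  A <- D %*% D
  s <- rowSums(D)
  T <- 1 - (A + D) / (outer(s, s, pmin) + 1 - D)
  diag(T) <- 1
  p <- nrow(T)
  if (include_diagonal) mean(T) else (sum(T) - p) / (p * (p - 1))
}

#' Randomly pair sensitive with resistant cell lines
#'
#' Draws a uniformly random perfect matching between the two groups; the
#' DCS statistic is an average over these pairs.
#'
#' @param sensitive,resistant Equal-length character vectors of cell-line
#'   ids.
#' @param seed Optional seed for a reproducible matching.
#' @return data.frame of class `"paired_design"` with columns `sensitive`
#'   and `resistant`, one row per pair.
#' @export
build_paired_design <- function(sensitive, resistant, seed = NULL) {
  if (length(sensitive) != length(resistant)) {
    stop("groups must have equal size")
  }
  if (anyDuplicated(c(sensitive, resistant))) {
    stop("a cell line may be used at most once")
  }
  with_seed(seed, {
    design <- data.frame(sensitive = sensitive,
                         resistant = resistant[sample(length(resistant))],
                         stringsAsFactors = FALSE)
    class(design) <- c("paired_design", "data.frame")
    design
  })
}

#' Dissimilarity statistic over a paired design (DCS)
#'
#' For each pair, the chain edge-weight matrices -> adjacency difference ->
#' topological-overlap dissimilarity -> average entry is evaluated on the
#' subnetwork's genes; DCS is the mean of those averages over pairs.  When
#' each sensitive network equals its resistant partner the chain gives
#' `D = 0`, `t_ij = 1` and `DCS = 1`; genuine rewiring drives DCS below 1.
#'
#' @param networks A [netprofiler()] fit or named list of coefficient
#'   matrices covering every cell line in the design.
#' @param design A [build_paired_design()] result (or data.frame with
#'   columns `sensitive`, `resistant`).
#' @param genes Gene ids of the subnetwork to score (default: all genes of
#'   the first network).
#' @param gamma,normalize Passed to [adjacency_difference()].
#' @param include_diagonal Passed to [average_dissimilarity()].
#' @return The DCS value (a single number).
#' @export
dcs_statistic <- function(networks, design, genes = NULL, gamma = 1,
                          normalize = TRUE, include_diagonal = TRUE) {
  ids <- c(design$sensitive, design$resistant)
  nets <- as_network_list(networks, ids)
  genes <- genes %||% colnames(nets[[1]])
  ave <- vapply(seq_len(nrow(design)), function(a) {
    W_s <- edge_weight_matrix(nets[[design$sensitive[a]]], genes)
    W_r <- edge_weight_matrix(nets[[design$resistant[a]]], genes)
    D <- adjacency_difference(W_s, W_r, gamma = gamma, normalize = normalize)
    average_dissimilarity(tom_dissimilarity(D),
                          include_diagonal = include_diagonal)
  }, numeric(1))
  mean(ave)
}
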