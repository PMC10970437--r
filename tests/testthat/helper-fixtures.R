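# Shared fixtures and independent oracles used across test files.

# Small expression panel with a planted constant-coefficient network.
small_sim <- function(seed = 11, n = 80, p = 8, edges = 8, diff = 0,
                      noise = 0.3) {
  simulate_grn(sim_config(n_cell_lines = n, n_genes = p, n_true_edges = edges,
                          n_differential = diff, noise_sd = noise,
                          seed = seed))
}

# Named list of constant coefficient matrices (one per cell line id).
constant_networks <- function(B, ids) {
  stats::setNames(lapply(ids, function(i) B), ids)
}

rand_coef_matrix <- function(p, genes = sprintf("G%03d", seq_len(p)),
                             density = 0.4) {
  B <- matrix(rnorm(p * p) * (runif(p * p) < density), p, p,
              dimnames = list(genes, genes))
  diag(B) <- 0
  B
}

# Triple-loop reference implementation of the topological-overlap
# dissimilarity (independent of the matrix-algebra version).
tom_oracle <- function(D) {
  p <- nrow(D)
  T <- matrix(1, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      num <- D[i, j]
      for (k in seq_len(p)) {
        if (k != i && k != j) num <- num + D[i, k] * D[j, k]
      }
      si <- 0
      sj <- 0
      for (k in seq_len(p)) {
        if (k != i) si <- si + D[i, k]
        if (k != j) sj <- sj + D[j, k]
      }
      T[i, j] <- 1 - num / (min(si, sj) + 1 - D[i, j])
    }
  }
  T
}

# Independent union-find used as the connected-components oracle.
uf_components <- function(edges) {
  verts <- unique(c(edges$regulator, edges$target))
  parent <- stats::setNames(verts, verts)
  find <- function(v) {
    while (parent[[v]] != v) {
      parent[[v]] <<- parent[[parent[[v]]]]
      v <- parent[[v]]
    }
    v
  }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges$regulator[e])
    b <- find(edges$target[e])
    if (a != b) parent[[a]] <- b
  }
  length(unique(vapply(verts, find, character(1))))
}

# Value of the penalized kernel-weighted objective at beta.
enet_objective <- function(x, y, K, beta, lambda, delta, w = NULL) {
  w <- w %||% rep(1, length(beta))
  r <- y - drop(x %*% beta)
  l1 <- ifelse(beta == 0, 0, w * abs(beta))  # excluded coords: w=Inf, beta=0
  0.5 * sum(K * r^2) +
    lambda * sum(0.5 * (1 - delta) * beta^2 + delta * l1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
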