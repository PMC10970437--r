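test_that("edge weights average the two directed strengths", {
  genes <- c("A", "B")
  B <- matrix(c(0, -1, 2, 0), 2, 2, dimnames = list(genes, genes))
  # B["A","B"] = 2 (B regulates A), B["B","A"] = -1 (A regulates B)
  W <- edge_weight_matrix(B)
  expect_identical(W["A", "B"], 1.5)
  expect_identical(W["B", "A"], 1.5)
  expect_true(all(diag(W) == 0))
  expect_identical(edge_weight_matrix(matrix(0, 3, 3)),
                   matrix(0, 3, 3))
})

test_that("edge weights match the scalar loop oracle on random input", {
  set.seed(91)
  B <- rand_coef_matrix(10)
  W <- edge_weight_matrix(B)
  for (i in 1:10) for (j in 1:10) {
    expect_identical(W[i, j],
                     if (i == j) 0 else (abs(B[i, j]) + abs(B[j, i])) / 2)
  }
  expect_error(edge_weight_matrix(B, genes = "nope"), "unknown")
})

test_that("adjacency difference follows the halved squared-difference form", {
  z <- matrix(0, 1, 1)
  expect_identical(adjacency_difference(z + 1, z + 1)[1, 1], 0)
  W1 <- matrix(c(0, 1, 1, 0), 2, 2)
  W0 <- matrix(0, 2, 2)
  expect_identical(adjacency_difference(W1, W0, gamma = 1)[1, 2], 0.5)
  Wa <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  Wb <- matrix(c(0, 0.6, 0.6, 0), 2, 2)
  d <- adjacency_difference(Wa, Wb, gamma = 2, normalize = FALSE)
  expect_equal(d[1, 2], (0.5 * abs(0.64 - 0.36))^2, tolerance = 1e-15)
  expect_equal(d[1, 2], 0.0196, tolerance = 1e-12)
})

test_that("normalization bounds the adjacency difference by (1/2)^gamma", {
  set.seed(92)
  for (r in 1:5) {
    Ws <- edge_weight_matrix(rand_coef_matrix(8) * 5)
    Wr <- edge_weight_matrix(rand_coef_matrix(8) * 5)
    d1 <- adjacency_difference(Ws, Wr, gamma = 1, normalize = TRUE)
    expect_true(all(d1 >= 0 & d1 <= 0.5))
    d2 <- adjacency_difference(Ws, Wr, gamma = 2, normalize = TRUE)
    expect_true(all(d2 <= 0.25))
    expect_true(isSymmetric(d1))
  }
})

test_that("the correlation-based adjacency difference handles signs", {
  one <- function(v) matrix(c(1, v, v, 1), 2, 2)
  expect_identical(diffcoex_adjacency(one(0.4), one(0.4))[1, 2], 0)
  expect_identical(diffcoex_adjacency(one(1), one(-1), gamma = 1)[1, 2], 1)
  d <- diffcoex_adjacency(one(0.6), one(-0.3), gamma = 1)
  expect_equal(d[1, 2], 0.5 * (0.36 + 0.09), tolerance = 1e-15)
  expect_equal(d[1, 2], 0.225, tolerance = 1e-12)
  expect_error(diffcoex_adjacency(one(1.4), one(0.2)), "\\[-1, 1\\]")
})

test_that("the TOM dissimilarity matches hand-computed values", {
  D0 <- matrix(0, 4, 4)
  expect_true(all(tom_dissimilarity(D0) == 1))
  D <- matrix(0.5, 3, 3)
  diag(D) <- 0
  T <- tom_dissimilarity(D)
  # numerator 0.25 + 0.5; denominator min(1,1) + 1 - 0.5
  expect_equal(T[1, 2], 1 - 0.75 / 1.5, tolerance = 1e-15)
  expect_equal(T[1, 2], 0.5, tolerance = 1e-12)
  expect_true(all(diag(T) == 1))
})

test_that("the TOM dissimilarity equals the triple-loop oracle", {
  set.seed(93)
  for (r in 1:5) {
    D <- edge_weight_matrix(rand_coef_matrix(20))
    D <- D / max(D)
    T <- tom_dissimilarity(D)
    expect_lt(max(abs(T - tom_oracle(D))), 1e-12)
    expect_true(isSymmetric(T))
  }
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(tom_dissimilarity(bad), "symmetric")
  expect_error(tom_dissimilarity(matrix(-1, 2, 2)), "nonnegative|diagonal")
})

test_that("average dissimilarity follows the literal and off-diagonal modes", {
  T1 <- matrix(1, 3, 3)
  expect_identical(average_dissimilarity(T1), 1)
  T2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  expect_identical(average_dissimilarity(T2), 0.8)
  expect_equal(average_dissimilarity(T2, include_diagonal = FALSE), 0.6)
  set.seed(94)
  Tr <- tom_dissimilarity(edge_weight_matrix(rand_coef_matrix(6)))
  perm <- sample(6)
  expect_equal(average_dissimilarity(Tr[perm, perm]),
               average_dissimilarity(Tr))
})

test_that("paired designs are perfect matchings, reproducible under seed", {
  d1 <- build_paired_design("s1", "r1")
  expect_identical(nrow(d1), 1L)
  s <- sprintf("s%03d", 1:100)
  r <- sprintf("r%03d", 1:100)
  d <- build_paired_design(s, r, seed = 5)
  expect_identical(sort(d$sensitive), s)
  expect_identical(sort(d$resistant), r)
  expect_identical(build_paired_design(s, r, seed = 5), d)
  d2 <- build_paired_design(s, r, seed = 6)
  if (identical(d2$resistant, d$resistant)) {
    d2 <- build_paired_design(s, r, seed = 7)   # one retry on collision
  }
  expect_false(identical(d2$resistant, d$resistant))
  expect_error(build_paired_design(s, r[1:3]), "equal")
  expect_error(build_paired_design(c("a", "b"), c("b", "c")), "once")
})

test_that("DCS is exactly 1 for self-similar pairs and averages otherwise", {
  set.seed(95)
  B <- rand_coef_matrix(6)
  ids_s <- sprintf("s%d", 1:4)
  ids_r <- sprintf("r%d", 1:4)
  nets <- c(constant_networks(B, ids_s), constant_networks(B, ids_r))
  design <- build_paired_design(ids_s, ids_r, seed = 1)
  expect_identical(dcs_statistic(nets, design), 1)

  # single pair: DCS equals that pair's average dissimilarity
  B2 <- rand_coef_matrix(6)
  nets2 <- list(s1 = B, r1 = B2)
  d1 <- data.frame(sensitive = "s1", resistant = "r1")
  W_s <- edge_weight_matrix(B)
  W_r <- edge_weight_matrix(B2)
  mx <- max(W_s, W_r)
  D <- adjacency_difference(W_s / mx, W_r / mx, normalize = FALSE)
  expect_equal(dcs_statistic(nets2, d1),
               average_dissimilarity(tom_dissimilarity(D)),
               tolerance = 1e-15)

  # invariance to the order of pairs in the design
  nets3 <- c(lapply(1:4, function(i) rand_coef_matrix(6)),
             lapply(1:4, function(i) rand_coef_matrix(6)))
  names(nets3) <- c(ids_s, ids_r)
  design3 <- build_paired_design(ids_s, ids_r, seed = 2)
  shuf <- design3[c(3, 1, 4, 2), ]
  expect_equal(dcs_statistic(nets3, design3), dcs_statistic(nets3, shuf),
               tolerance = 1e-15)
})

test_that("symmetry is preserved along the whole chain", {
  set.seed(96)
  for (r in 1:3) {
    Ws <- edge_weight_matrix(rand_coef_matrix(7))
    Wr <- edge_weight_matrix(rand_coef_matrix(7))
    expect_true(isSymmetric(Ws))
    D <- adjacency_difference(Ws, Wr)
    expect_true(isSymmetric(D))
    expect_true(all(D >= 0) && all(diag(D) == 0))
    T <- tom_dissimilarity(D)
    expect_true(isSymmetric(T))
  }
})
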