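test_that("identical networks give p = 1 in both tail modes", {
  set.seed(101)
  B <- rand_coef_matrix(5)
  s <- sprintf("s%d", 1:6)
  r <- sprintf("r%d", 1:6)
  nets <- c(constant_networks(B, s), constant_networks(B, r))
  for (tail in c("small-is-extreme", "literal")) {
    t1 <- dcs_test(nets, s, r, n_permutations = 25, tail = tail, seed = 1)
    expect_identical(t1$dcs, 1)
    expect_true(all(t1$dcs_permuted == 1))
    expect_identical(t1$p_value, 1)   # ties count under <=
    expect_false(t1$significant)
  }
})

test_that("strong rewiring gives opposite extremes in the two tail modes", {
  set.seed(102)
  s <- sprintf("s%02d", 1:10)
  r <- sprintf("r%02d", 1:10)
  dense <- abs(rand_coef_matrix(6, density = 1))
  nets <- c(constant_networks(dense * 0, s),
            constant_networks(dense * 3, r))
  small <- dcs_test(nets, s, r, n_permutations = 60,
                    tail = "small-is-extreme", seed = 3)
  literal <- dcs_test(nets, s, r, n_permutations = 60, tail = "literal",
                      seed = 3)
  expect_identical(small$p_value, 0)
  expect_identical(literal$p_value, 1)
  expect_true(small$significant)
  expect_lt(small$dcs, min(small$dcs_permuted))
})

test_that("the add-one correction changes only the denominator", {
  set.seed(103)
  s <- sprintf("s%d", 1:5)
  r <- sprintf("r%d", 1:5)
  nets <- c(constant_networks(abs(rand_coef_matrix(4)), s),
            constant_networks(abs(rand_coef_matrix(4)), r))
  raw <- dcs_test(nets, s, r, n_permutations = 40, seed = 9)
  adj <- dcs_test(nets, s, r, n_permutations = 40, seed = 9, add_one = TRUE)
  b <- sum(raw$dcs_permuted <= raw$dcs)
  expect_identical(raw$p_value, b / 40)
  expect_identical(adj$p_value, (b + 1) / 41)
})

test_that("screening an empty subnetwork list returns an empty table", {
  out <- dcs_screen(list(), list(), character(0), character(0))
  expect_s3_class(out, "dcs_screen")
  expect_identical(nrow(out), 0L)
})

test_that("a planted differential module attains the smallest p-value", {
  # three 4-gene modules; only module 1 rewires between the ends
  genes <- sprintf("G%03d", 1:12)
  mods <- split(genes, rep(1:3, each = 4))
  edge_in <- function(gs, vs, vr) {
    data.frame(regulator = gs[c(1, 1, 2)], target = gs[c(2, 3, 4)],
               value_sensitive = vs, value_resistant = vr)
  }
  edges <- rbind(edge_in(mods[[1]], 0, 1.5),
                 edge_in(mods[[2]], 1, 1),
                 edge_in(mods[[3]], -0.8, -0.8))
  cfg <- sim_config(n_cell_lines = 120, n_genes = 12, noise_sd = 0.3,
                    edges = edges, seed = 404)
  sim <- simulate_grn(cfg)
  g <- define_extreme_cell_lines(sim$sensitivity, 30)
  fit <- netprofiler(sim$expression, sim$sensitivity,
                     at = c(g$sensitive, g$resistant))
  out <- dcs_screen(fit, mods, g$sensitive, g$resistant,
                    n_permutations = 49, seed = 11)
  expect_identical(nrow(out), 3L)
  p_planted <- out$p_value[out$subnetwork == "1"]
  expect_identical(p_planted, min(out$p_value))
  tests <- attr(out, "tests")
  expect_lt(tests[["1"]]$dcs, tests[["2"]]$dcs)
})

test_that("screen results are invariant to subnetwork input order", {
  set.seed(105)
  s <- sprintf("s%02d", 1:8)
  r <- sprintf("r%02d", 1:8)
  nets <- c(lapply(seq_along(s), function(i) rand_coef_matrix(9)),
            lapply(seq_along(r), function(i) rand_coef_matrix(9)))
  names(nets) <- c(s, r)
  subs <- list(one = sprintf("G%03d", 1:3), two = sprintf("G%03d", 4:6),
               three = sprintf("G%03d", 7:9))
  a <- dcs_screen(nets, subs, s, r, n_permutations = 30, seed = 21)
  b <- dcs_screen(nets, rev(subs), s, r, n_permutations = 30, seed = 21)
  strip <- function(x) {
    x <- as.data.frame(x)
    attributes(x)[c("tests", "params")] <- NULL
    x
  }
  expect_identical(strip(a), strip(b))
})

test_that("raising the planted effect does not raise the median p-value", {
  run_once <- function(effect, seed) {
    edges <- data.frame(regulator = c("G001", "G001"),
                        target = c("G002", "G003"),
                        value_sensitive = 0, value_resistant = effect)
    cfg <- sim_config(n_cell_lines = 80, n_genes = 8, n_true_edges = 2,
                      noise_sd = 0.3, edges = edges, seed = seed)
    sim <- simulate_grn(cfg)
    g <- define_extreme_cell_lines(sim$sensitivity, 20)
    fit <- netprofiler(sim$expression, sim$sensitivity,
                       at = c(g$sensitive, g$resistant), nlambda = 10)
    dcs_test(fit, g$sensitive, g$resistant, genes = c("G001", "G002", "G003"),
             n_permutations = 29, seed = seed)$p_value
  }
  p_null <- vapply(1:4, function(i) run_once(0, 500 + i), numeric(1))
  p_alt <- vapply(1:4, function(i) run_once(1.5, 500 + i), numeric(1))
  expect_lte(median(p_alt), median(p_null))
})

test_that("missing networks and invalid settings raise errors", {
  set.seed(106)
  nets <- constant_networks(rand_coef_matrix(4), c("s1", "r1"))
  expect_error(dcs_test(nets, c("s1", "s2"), c("r1", "r2")), "s2")
  expect_error(dcs_test(nets, "s1", "r1", n_permutations = 0), ">= 1")
})
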