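test_that("connection networks follow the threshold and row-standardize", {
  net <- suppressWarnings(build_network(c(0, 1, 10), 2, c("a", "b", "c")))
  expect_equal(net$A["a", "b"], 1)
  expect_equal(sum(net$A), 2)              # only the 0-1 edge, both directions
  expect_equal(net$degree, c(a = 1, b = 1, c = 0))

  expect_warning(full <- build_network(c(0, 1, 2), 5), "complete")
  expect_equal(sum(full$A), 6)
  net3 <- suppressWarnings(build_network(c(0, 1, 2), 1.5))
  expect_equal(unname(net3$W[2, ]), c(0.5, 0, 0.5))
  expect_equal(unname(rowSums(net3$W)), rep(1, 3))
})

test_that("individual allele matrix encodes dosages and centres correctly", {
  l1 <- rbind(c(101L, 103L), c(101L, 101L), c(103L, 103L))
  l2 <- rbind(c(201L, 201L), c(201L, 203L), c(203L, 203L))
  tab <- toy_table(pad_monomorphic(l1, l2))
  X <- individual_allele_matrix(tab)
  expect_equal(unname(X[1, c("L1_101", "L1_103")]), c(0.5, 0.5))
  expect_equal(unname(X[2, "L1_101"]), 1)
  Xc <- individual_allele_matrix(tab, center = TRUE)
  expect_equal(unname(colSums(Xc)), rep(0, ncol(Xc)), tolerance = 1e-12)
  # clone rows identical
  geno <- random_genotypes(4)
  geno[3, ] <- geno[1, ]
  Xc2 <- individual_allele_matrix(toy_table(geno), center = TRUE)
  expect_equal(Xc2[3, ], Xc2[1, ])
})

test_that("spca eigenvalues decompose into variance times Moran's I", {
  reef <- make_fixture("cline_strong", loggers = FALSE)
  col <- reef$colonies
  X <- individual_allele_matrix(col, center = TRUE)
  dd <- distance_matrix(col$depth, col$colony_id, "depth")
  net <- suppressWarnings(
    build_network(col$depth, as.numeric(quantile(offdiag(dd), 0.1)),
                  col$colony_id))
  sp <- spca(X, net)
  ok <- is.finite(sp$moran)
  expect_equal(sp$eigenvalues[ok], (sp$var * sp$moran)[ok], tolerance = 1e-8)
  # trace identity: sum of eigenvalues equals trace of H
  W <- net$W
  H <- crossprod(X, (W + t(W)) %*% X) / (2 * nrow(X))
  expect_equal(sum(sp$eigenvalues), sum(diag(H)), tolerance = 1e-8)
  expect_equal(unname(colSums(sp$loadings^2)), rep(1, ncol(sp$loadings)),
               tolerance = 1e-8)
})

test_that("two isolated clusters of clones give a positive leading structure", {
  g1 <- random_genotypes(1); g2 <- random_genotypes(1)
  geno <- rbind(g1[rep(1, 4), ], g2[rep(1, 4), ])
  tab <- toy_table(geno, x = c(0, 1, 0, 1, 10, 11, 10, 11),
                   y = c(0, 0, 1, 1, 0, 0, 1, 1))
  X <- individual_allele_matrix(tab, center = TRUE)
  net <- build_network(tab[, c("x", "y")], 2)
  sp <- spca(X, net)
  expect_gt(sp$eigenvalues[1], 0)
  s1 <- sp$scores[, 1]
  expect_true(all(sign(s1[1:4]) == sign(s1[1])) &&
                all(sign(s1[5:8]) == -sign(s1[1])))
  # longhand H for this two-cluster system matches the implementation's lambda
  W <- net$W
  H <- crossprod(X, (W + t(W)) %*% X) / (2 * nrow(X))
  expect_equal(sp$eigenvalues, eigen((H + t(H)) / 2, symmetric = TRUE,
                                     only.values = TRUE)$values,
               tolerance = 1e-10)
})

test_that("identically zero allele matrices are rejected", {
  geno <- random_genotypes(1)[rep(1, 5), ]
  tab <- toy_table(geno)
  X <- individual_allele_matrix(tab, center = TRUE)
  net <- suppressWarnings(build_network(seq_len(5), 2))
  expect_error(spca(X, net), "zero")
})

test_that("lagged scores average neighbours and smooth clines", {
  # chain 1-2, 2-3: node 1 has a single neighbour (2)
  net <- suppressWarnings(build_network(c(0, 1, 2), 1.2))
  fake <- list(scores = matrix(c(5, 7, 9), 3, 1))
  lag <- lagged_scores(fake, net)
  expect_equal(lag[1, 1], 7)               # its only neighbour's score
  expect_equal(lag[2, 1], 7)               # mean of 5 and 9
  const <- lagged_scores(list(scores = matrix(2, 3, 1)), net)
  expect_equal(as.vector(const), rep(2, 3))

  reef <- make_fixture("cline_strong", loggers = FALSE)
  col <- reef$colonies
  X <- individual_allele_matrix(col, center = TRUE)
  dd <- distance_matrix(col$depth, col$colony_id, "depth")
  net2 <- suppressWarnings(
    build_network(col$depth, as.numeric(quantile(offdiag(dd), 0.1))))
  sp <- spca(X, net2)
  lag2 <- lagged_scores(sp, net2)
  expect_lte(var(lag2[, 1]), var(sp$scores[, 1]))
})

test_that("MEM filters are centred, orthogonal, and match a hand eigen-solve", {
  # path graph on 4 nodes
  net <- suppressWarnings(build_network(c(0, 1, 2, 3), 1.1))
  flt <- mem_filters(net)
  all_f <- cbind(flt$global, flt$local)
  expect_equal(unname(colSums(all_f)), rep(0, ncol(all_f)), tolerance = 1e-10)
  gram <- crossprod(all_f)
  expect_equal(unname(gram), diag(ncol(all_f)), tolerance = 1e-10)

  A <- net$A
  n <- 4
  Cen <- diag(n) - matrix(1 / n, n, n)
  ev <- eigen(Cen %*% A %*% Cen, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(abs(ev))
  expect_equal(ncol(flt$global), sum(ev > tol))
  expect_equal(ncol(flt$local), sum(ev < -tol))
  expect_equal(sort(c(flt$values_global, flt$values_local)),
               sort(ev[abs(ev) > tol]), tolerance = 1e-10)
})

test_that("global/local randomization test behaves at its extremes", {
  set.seed(81)
  net <- suppressWarnings(build_network(cbind(runif(30), runif(30)), 0.3))
  flt <- mem_filters(net)
  # a column equal to a global filter projects perfectly
  X <- cbind(flt$global[, 1])
  res <- global_local_test(X, flt$global, n_perm = 99, seed = 7)
  expect_equal(res$statistic, 1, tolerance = 1e-10)
  expect_equal(res$p, 1 / 100)
  # column order / relabeling invariance
  set.seed(82)
  X2 <- matrix(rnorm(90), 30, 3)
  X2 <- sweep(X2, 2, colMeans(X2))
  a <- global_local_test(X2, flt$global, n_perm = 0)
  b <- global_local_test(X2[, 3:1], flt$global, n_perm = 0)
  expect_equal(a$statistic, b$statistic)
})

test_that("randomization test holds its size under a spatially random null", {
  set.seed(83)
  net <- suppressWarnings(build_network(cbind(runif(40), runif(40)), 0.25))
  flt <- mem_filters(net)
  reps <- 200
  p <- replicate(reps, {
    X <- matrix(rnorm(40 * 4), 40, 4)
    X <- sweep(X, 2, colMeans(X))
    global_local_test(X, flt$global, n_perm = 49)$p
  })
  rate <- mean(p <= 0.05)
  ci <- stats::binom.test(round(0.05 * reps), reps)$conf.int
  expect_gte(rate, ci[1] - 0.01)
  expect_lte(rate, ci[2] + 0.01)
})
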