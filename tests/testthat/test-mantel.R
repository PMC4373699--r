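test_that("distance matrices match hand values and are translation-invariant", {
  d <- distance_matrix(c(1, 2, 4), c("a", "b", "c"), "depth-distance")
  expect_equal(sort(offdiag(d)), c(1, 2, 3))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  xy <- rbind(c(0, 0), c(3, 4))
  expect_equal(distance_matrix(xy)[1, 2], 5)
  xy2 <- xy + 17
  expect_equal(unclass(distance_matrix(xy2)), unclass(distance_matrix(xy)))
  expect_error(distance_matrix(c(1, NA, 3), c("a", "b", "c")), "b")
})

test_that("simple Mantel: self-correlation, monotone invariance, vegan agreement", {
  set.seed(51)
  n <- 12
  A <- as.matrix(dist(cbind(rnorm(n), rnorm(n))))
  B <- as.matrix(dist(rnorm(n)))
  expect_equal(simple_mantel(A, A, n_perm = 19)$r, 1.0)
  expect_equal(simple_mantel(A, 2 + 3 * A, n_perm = 19)$r, 1.0)
  r <- simple_mantel(A, B, n_perm = 99, seed = 1)$r
  expect_equal(r, unname(vegan::mantel(as.dist(A), as.dist(B),
                                       method = "spearman",
                                       permutations = 0)$statistic))
  expect_error(simple_mantel(A, matrix(1, n, n) - diag(n) + diag(n),
                             n_perm = 9), "constant")
})

test_that("simple Mantel exact p matches full enumeration at n = 5", {
  set.seed(52)
  A <- as.matrix(dist(rnorm(5)))
  B <- as.matrix(dist(rnorm(5)))
  got <- simple_mantel(A, B, exact = TRUE)
  expect_equal(got$n_perm, 120L)
  r_obs <- naive_mantel_r(A, B)
  r_all <- vapply(perms_of(1:5), function(p)
    naive_mantel_r(A, B[p, p]), numeric(1))
  expect_equal(got$r, r_obs)
  expect_equal(got$p, mean(abs(r_all) >= abs(r_obs) - 1e-12))
})

test_that("partial Mantel r equals the rank-residual correlation (and vegan)", {
  set.seed(53)
  n <- 15
  A <- as.matrix(dist(rnorm(n)))
  B <- as.matrix(dist(rnorm(n)))
  C <- as.matrix(dist(cbind(rnorm(n), rnorm(n))))
  got <- partial_mantel(A, B, C, n_perm = 49, seed = 2)
  expect_equal(got$r, naive_partial_r(A, B, C))
  vg <- vegan::mantel.partial(as.dist(A), as.dist(B), as.dist(C),
                              method = "spearman", permutations = 0)
  expect_equal(got$r, unname(vg$statistic), tolerance = 1e-10)
})

test_that("partial Mantel degenerates properly", {
  set.seed(54)
  n <- 10
  A <- as.matrix(dist(rnorm(n)))
  B <- as.matrix(dist(rnorm(n)))
  Cc <- matrix(1, n, n); diag(Cc) <- 0
  expect_warning(res <- partial_mantel(A, B, Cc, n_perm = 49, seed = 3),
                 "constant")
  expect_equal(res$r, simple_mantel(A, B, n_perm = 49, seed = 3)$r)
  # B == C: residuals of B on C vanish up to rank noise -> r ~ 0
  expect_lt(abs(suppressWarnings(partial_mantel(A, B, B, n_perm = 49))$r), 1e-8)
})

test_that("partial Mantel exact p matches full enumeration at n = 5", {
  set.seed(55)
  A <- as.matrix(dist(rnorm(5)))
  B <- as.matrix(dist(rnorm(5)))
  C <- as.matrix(dist(rnorm(5)))
  got <- partial_mantel(A, B, C, exact = TRUE)
  r_obs <- naive_partial_r(A, B, C)
  r_all <- vapply(perms_of(1:5), function(p)
    naive_partial_r(A[p, p], B, C), numeric(1))
  expect_equal(got$r, r_obs)
  expect_equal(got$p, mean(abs(r_all) >= abs(r_obs) - 1e-12))
})

test_that("Mantel r is invariant to a common relabeling of both matrices", {
  set.seed(56)
  n <- 9
  A <- as.matrix(dist(rnorm(n)))
  B <- as.matrix(dist(rnorm(n)))
  p <- sample(n)
  expect_equal(simple_mantel(A[p, p], B[p, p], n_perm = 9)$r,
               simple_mantel(A, B, n_perm = 9)$r)
})

test_that("autocorrelogram bins are equal-count and envelopes behave", {
  set.seed(57)
  n <- 60
  xy <- cbind(runif(n, 0, 30), runif(n, 0, 30))
  dsp <- distance_matrix(xy)
  flat <- matrix(0.01, n, n); diag(flat) <- NA
  ac <- autocorrelogram(flat, dsp, n_bins = 8, n_perm = 50, seed = 4)
  expect_lte(max(ac$n_pairs) / min(ac$n_pairs), 1.2)
  expect_true(all(ac$mean_rel <= ac$hi + 1e-12 &
                    ac$mean_rel >= ac$lo - 1e-12))
})

test_that("isolation by distance shows up in the first autocorrelogram bin", {
  reef <- make_fixture("ibd_only", loggers = FALSE)
  col <- reef$colonies
  rel <- moran_relationship(col)
  dsp <- distance_matrix(col[, c("x", "y")], col$colony_id, "space-distance")
  ac <- autocorrelogram(rel, dsp, n_bins = 10, n_perm = 200, seed = 5)
  expect_gt(ac$mean_rel[1], ac$hi[1])
  expect_gt(neighbor_threshold(ac), 0)
})

test_that("neighbor threshold picks the farthest significant bin", {
  fake <- function(mean_rel, hi) {
    structure(data.frame(bin = seq_along(mean_rel),
                         mean_dist = seq_along(mean_rel), mean_rel = mean_rel,
                         n_pairs = 10L, lo = -hi, hi = hi),
              class = c("autocorrelogram", "data.frame"))
  }
  expect_equal(neighbor_threshold(fake(c(0.5, 0, 0), c(0.1, 0.1, 0.1))), 1)
  expect_equal(neighbor_threshold(fake(c(0.5, 0, 0.3), c(0.1, 0.1, 0.1))), 3)
  expect_error(neighbor_threshold(fake(c(0, 0, 0), c(0.1, 0.1, 0.1))),
               "manually")
})

test_that("size-class tests: degenerate bin reproduces the whole-data test", {
  set.seed(58)
  reef <- make_fixture("cline_weak", loggers = FALSE)
  col <- reef$colonies
  col$area[is.na(col$area)] <- 20           # give everyone an area
  rel <- moran_relationship(col)
  dists <- list(space = distance_matrix(col[, c("x", "y")], col$colony_id, "space"),
                depth = distance_matrix(col$depth, col$colony_id, "depth"))
  allbin <- list(list(label = "all", lower = -Inf, upper = Inf))
  t2 <- size_class_tests(col, rel, dists, allbin, n_perm = 49)
  whole <- partial_mantel(rel, dists$depth, dists$space, n_perm = 49)
  expect_equal(t2$r[t2$variable == "depth"], whole$r)
  expect_equal(t2$N, rep(nrow(col), 2))
})

test_that("size-class tests exclude missing areas and skip tiny bins", {
  set.seed(59)
  reef <- make_fixture("null", loggers = FALSE)
  col <- reef$colonies
  n_area <- sum(!is.na(col$area))
  rel <- moran_relationship(col)
  dists <- list(space = distance_matrix(col[, c("x", "y")], col$colony_id, "space"),
                depth = distance_matrix(col$depth, col$colony_id, "depth"))
  bins <- list(list(label = "all", lower = -Inf, upper = Inf),
               list(label = ">1e6", lower = 1e6, upper = Inf))
  expect_warning(t2 <- size_class_tests(col, rel, dists, bins, n_perm = 19),
                 "skipped")
  expect_equal(unique(t2$N), n_area)
})

test_that("an age-coupled cline strengthens with size class", {
  cfg <- reef_config(n_colonies = 260, cline_strength = 1.2, ibd_scale = Inf,
                     clonality_rate = 0, area_missing_rate = 0,
                     cline_area_threshold = 30, seed = 60)
  col <- generate_reef(cfg, loggers = FALSE)$colonies
  rel <- moran_relationship(col)
  dists <- list(space = distance_matrix(col[, c("x", "y")], col$colony_id, "space"),
                depth = distance_matrix(col$depth, col$colony_id, "depth"))
  bins <- make_size_bins(10, 30)
  t2 <- size_class_tests(col, rel, dists, bins, n_perm = 99, seed = 6)
  r_small <- abs(t2$r[t2$bin == "<10" & t2$variable == "depth"])
  r_large <- abs(t2$r[t2$bin == ">30" & t2$variable == "depth"])
  expect_gt(r_large, r_small)
})
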